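# Internal array plumbing.  Feature maps are H x W x C arrays ("FeatureMap");
# the layer machinery works on H x W x C x N batches throughout.

`%||%` <- function(a, b) if (is.null(a)) b else a

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L, 4L)))
    stop("expected an H x W [x C [x N]] array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

unbatch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

check_feature_map <- function(x, name = "x") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("'%s' must be an H x W x C array", name))
  invisible(d)
}

# channel-indexed vector -> recyclable vector for an (H, W, C, N) array
chan_rep <- function(a, d) rep(a, each = d[1] * d[2])

# per-channel column matrix view: rows ordered (i, j, n), one column per channel
to_channel_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
}

from_channel_mat <- function(m, d) {
  aperm(array(m, dim = d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
}

bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)]))
    stop(sprintf("cannot concatenate %s with %s along channels",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# run code under a temporary RNG state so generators are pure in their seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= 1
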