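# Independent straight-line oracles used to pin down the numerical layers.
# These deliberately share no code with the package internals: nested loops
# and direct formula transcription only.

# direct nested-loop dilated cross-correlation with zero padding
conv_oracle <- function(x, w, rate, pad = rate, stride = 1) {
  d <- dim(x); dw <- dim(w); K <- dw[1]
  span <- rate * (K - 1) + 1
  Ho <- (d[1] + 2 * pad - span) %/% stride + 1
  Wo <- (d[2] + 2 * pad - span) %/% stride + 1
  y <- array(0, c(Ho, Wo, dw[4]))
  for (oc in seq_len(dw[4]))
    for (io in seq_len(Ho)) for (jo in seq_len(Wo))
      for (c in seq_len(dw[3])) for (ki in seq_len(K)) for (kj in seq_len(K)) {
        i <- (io - 1) * stride - pad + (ki - 1) * rate + 1
        j <- (jo - 1) * stride - pad + (kj - 1) * rate + 1
        if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2])
          y[io, jo, oc] <- y[io, jo, oc] + x[i, j, c] * w[ki, kj, c, oc]
      }
  y
}

# Gaussian-excitation channel gates computed by direct transcription
gct_gate_oracle <- function(x, c0 = 2, eps = 1e-5) {
  C <- dim(x)[3]
  m <- vapply(seq_len(C), function(c) mean(x[, , c]), 1)
  mu <- mean(m)
  s <- sqrt(mean((m - mu)^2))
  z <- (m - mu) / (s + eps)
  exp(-z^2 / (2 * c0^2))
}

# per-channel batch norm at initialization, eval mode (running mean 0, var 1)
bn_init_eval_oracle <- function(x, eps = 1e-5) x / sqrt(1 + eps)

# brute-force pixel-by-pixel confusion enumeration
confusion_oracle <- function(pred, gt, cls) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == cls; g <- gt[i, j] == cls
    if (p && g) tp <- tp + 1
    if (p && !g) fp <- fp + 1
    if (!p && g) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

seeded_map <- function(seed, d) {
  set.seed(seed)
  array(rnorm(prod(d)), d)
}

# small phantom set shared by engine tests
tiny_phantoms <- function(n = 4, size = 32L, seed = 11L) {
  generate_phantom_dataset(n, phantom_spec(size, size, n_tumors = c(1L, 2L),
                                           tumor_radius = c(2, 6)), seed = seed)
}
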