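# The four building blocks of the architecture: the spatial pyramid
# convolution block (SPCB), the spatial pyramid pooling block (SPPB), the
# bilinear upsample-and-concatenate step, and the residual attention decoder
# block (RA-Block).  Module constructors draw their weights from the current
# RNG state; seed the RNG before construction for reproducible weights.

#' Spatial pyramid convolution block configuration
#'
#' @param in_channels,out_channels positive integers.
#' @param dilation_rates exactly three positive integer rates for the three
#'   parallel dilated convolutions (default `c(1, 2, 4)`).
#' @param kernel_size kernel side; only 3 is supported (the architecture uses
#'   3x3 dilated convolutions exclusively).
#' @param use_channel_attention gate the fused map with GCT-B0 (default TRUE).
#' @param attention_before_norm if TRUE (default) the attention is applied to
#'   the branch sum before batch normalization; FALSE swaps the two, exposed
#'   so the alternative ordering is testable.
#' @return an object of class `spcb_config`.
#' @export
spcb_config <- function(in_channels, out_channels, dilation_rates = c(1L, 2L, 4L),
                        kernel_size = 3L, use_channel_attention = TRUE,
                        attention_before_norm = TRUE) {
  stopifnot(is_count(in_channels), is_count(out_channels))
  if (length(dilation_rates) != 3L || any(dilation_rates < 1) ||
      any(dilation_rates != as.integer(dilation_rates)))
    stop("'dilation_rates' must be three positive integers")
  if (kernel_size != 3L) stop("only kernel_size = 3 is supported")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rates = as.integer(dilation_rates),
                 kernel_size = 3L,
                 use_channel_attention = isTRUE(use_channel_attention),
                 attention_before_norm = isTRUE(attention_before_norm)),
            class = "spcb_config")
}

#' Spatial pyramid pooling block configuration
#'
#' @param in_channels,out_channels positive integers.
#' @param mode `"conv_plus_pool"` (default) uses the two-branch downsampler;
#'   `"conv_only"` forces the stride-2 convolution alone (the downsampling
#'   ablation axis).
#' @return an object of class `sppb_config`.
#' @export
sppb_config <- function(in_channels, out_channels,
                        mode = c("conv_plus_pool", "conv_only")) {
  stopifnot(is_count(in_channels), is_count(out_channels))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 mode = match.arg(mode)),
            class = "sppb_config")
}

#' Residual attention block configuration
#'
#' @param in_channels,out_channels positive integers; both branches emit
#'   `out_channels` so their elementwise sum is well defined.
#' @param use_coordinate_attention gate the shortcut branch with coordinate
#'   attention (default TRUE).
#' @return an object of class `rablock_config`.
#' @export
rablock_config <- function(in_channels, out_channels,
                           use_coordinate_attention = TRUE) {
  stopifnot(is_count(in_channels), is_count(out_channels))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 use_coordinate_attention = isTRUE(use_coordinate_attention)),
            class = "rablock_config")
}

new_module <- function(kind) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- list()
  m$children <- list()
  m
}

# ---- SPCB ------------------------------------------------------------------

#' @rdname spcb_forward
#' @export
spcb_block <- function(cfg) {
  stopifnot(inherits(cfg, "spcb_config"))
  m <- new_module("spcb")
  m$cfg <- cfg
  r <- cfg$dilation_rates
  m$children <- list(
    conv1 = layer_conv2d(cfg$in_channels, cfg$out_channels, 3L, pad = r[1],
                         dilation = r[1], bias = FALSE),
    conv2 = layer_conv2d(cfg$in_channels, cfg$out_channels, 3L, pad = r[2],
                         dilation = r[2], bias = FALSE),
    conv3 = layer_conv2d(cfg$in_channels, cfg$out_channels, 3L, pad = r[3],
                         dilation = r[3], bias = FALSE),
    gct = layer_gct(),
    bn = layer_bn(cfg$out_channels),
    act = layer_prelu(cfg$out_channels))
  m$forward <- function(x, training = FALSE) {
    ch <- m$children
    s <- ch$conv1$forward(x, training) + ch$conv2$forward(x, training) +
      ch$conv3$forward(x, training)
    m$branch_sum <- s
    if (m$cfg$use_channel_attention && m$cfg$attention_before_norm)
      s <- ch$gct$forward(s, training)
    s <- ch$bn$forward(s, training)
    if (m$cfg$use_channel_attention && !m$cfg$attention_before_norm)
      s <- ch$gct$forward(s, training)
    ch$act$forward(s, training)
  }
  m$backward <- function(gy, need_gx = TRUE) {
    ch <- m$children
    g <- ch$act$backward(gy)
    if (m$cfg$use_channel_attention && !m$cfg$attention_before_norm)
      g <- ch$gct$backward(g)
    g <- ch$bn$backward(g)
    if (m$cfg$use_channel_attention && m$cfg$attention_before_norm)
      g <- ch$gct$backward(g)
    g1 <- ch$conv1$backward(g, need_gx)
    g2 <- ch$conv2$backward(g, need_gx)
    g3 <- ch$conv3$backward(g, need_gx)
    if (need_gx) g1 + g2 + g3 else NULL
  }
  m
}

#' Spatial pyramid convolution block
#'
#' Runs a feature map through the encoder block: three parallel 3x3 dilated
#' convolutions (rates `cfg$dilation_rates`, each mapping
#' `in_channels -> out_channels`) summed elementwise, gated by GCT-B0 channel
#' attention when enabled, batch-normalized, then PReLU-activated.  Spatial
#' size is preserved.
#'
#' `spcb_block()` builds a reusable unit (weights drawn from the current RNG
#' state); `spcb_forward()` runs one, building a fresh unit when `block` is
#' not given.
#'
#' @param x an `H x W x in_channels` array.
#' @param cfg an [spcb_config()].
#' @param block optional prebuilt unit from `spcb_block()`.
#' @param training use batch statistics (TRUE) or running statistics (FALSE)
#'   in the normalization.
#' @return an `H x W x out_channels` array.
#' @export
spcb_forward <- function(x, cfg, block = NULL, training = FALSE) {
  d <- check_feature_map(x)
  b <- block %||% spcb_block(cfg)
  if (d[3] != b$cfg$in_channels)
    stop(sprintf("SPCB configured for %d input channels, got %d",
                 b$cfg$in_channels, d[3]))
  unbatch(b$forward(as_batch(x), training))
}

# ---- SPPB ------------------------------------------------------------------

#' @rdname sppb_forward
#' @export
sppb_block <- function(cfg) {
  stopifnot(inherits(cfg, "sppb_config"))
  m <- new_module("sppb")
  m$cfg <- cfg
  use_pool <- cfg$mode == "conv_plus_pool" && cfg$in_channels < cfg$out_channels
  conv_out <- if (use_pool) cfg$out_channels - cfg$in_channels else cfg$out_channels
  m$use_pool <- use_pool
  m$conv_out <- conv_out
  m$children <- list(
    conv = layer_conv2d(cfg$in_channels, conv_out, 3L, stride = 2L, pad = 1L,
                        bias = FALSE),
    bn = layer_bn(conv_out),
    act = layer_prelu(conv_out),
    pool = layer_maxpool2())
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
      stop(sprintf("SPPB requires even spatial size, got %dx%d", d[1], d[2]))
    ch <- m$children
    cv <- ch$act$forward(ch$bn$forward(ch$conv$forward(x, training), training), training)
    if (m$use_pool) bind_channels(ch$pool$forward(x, training), cv) else cv
  }
  m$backward <- function(gy, need_gx = TRUE) {
    ch <- m$children
    if (m$use_pool) {
      cin <- m$cfg$in_channels
      gp <- gy[, , seq_len(cin), , drop = FALSE]
      gc_ <- gy[, , cin + seq_len(m$conv_out), , drop = FALSE]
      gxc <- ch$conv$backward(ch$bn$backward(ch$act$backward(gc_)), need_gx)
      if (need_gx) ch$pool$backward(gp) + gxc else NULL
    } else {
      ch$conv$backward(ch$bn$backward(ch$act$backward(gy)), need_gx)
    }
  }
  m
}

#' Spatial pyramid pooling block (downsampler)
#'
#' Halves the spatial size of a feature map using two branches.  When
#' `in_channels < out_channels`, 2x2 non-overlapping max pooling carries the
#' `in_channels` original channels and a 3x3 stride-2 convolution produces
#' the remaining `out_channels - in_channels`; the two are concatenated along
#' channels (pool branch first).  Otherwise the pooling branch is ignored and
#' the convolution alone produces all `out_channels`.
#'
#' @param x an `H x W x in_channels` array with even `H` and `W`.
#' @param cfg an [sppb_config()].
#' @param block optional prebuilt unit from `sppb_block()`.
#' @param training batch vs running normalization statistics.
#' @return an `H/2 x W/2 x out_channels` array.
#' @export
sppb_forward <- function(x, cfg, block = NULL, training = FALSE) {
  d <- check_feature_map(x)
  b <- block %||% sppb_block(cfg)
  if (d[3] != b$cfg$in_channels)
    stop(sprintf("SPPB configured for %d input channels, got %d",
                 b$cfg$in_channels, d[3]))
  unbatch(b$forward(as_batch(x), training))
}

# ---- Upsample --------------------------------------------------------------

upsample_module <- function() {
  m <- new_module("upsample")
  m$children <- list(up = layer_upsample2())
  m$forward <- function(x, skip, training = FALSE) {
    u <- m$children$up$forward(x, training)
    du <- dim(u); ds <- dim(skip)
    if (du[1] != ds[1] || du[2] != ds[2])
      stop(sprintf("upsampled map %s does not match skip map %s",
                   paste(du[1:3], collapse = "x"), paste(ds[1:3], collapse = "x")))
    m$nx <- du[3]
    bind_channels(u, skip)
  }
  m$backward <- function(gy, need_gx = TRUE) {
    nx <- m$nx
    gu <- gy[, , seq_len(nx), , drop = FALSE]
    gskip <- gy[, , -seq_len(nx), , drop = FALSE]
    list(gx = m$children$up$backward(gu), gskip = gskip)
  }
  m
}

#' Bilinear upsample and skip concatenation
#'
#' Doubles the spatial size of `x` by bilinear interpolation (half-pixel-
#' center convention) and concatenates the result with the encoder skip map
#' along channels (upsampled channels first).  The skip map must be exactly
#' twice the spatial size of `x`.
#'
#' @param x an `H x W x C` array.
#' @param skip a `2H x 2W x C_skip` array from the encoder path.
#' @return a `2H x 2W x (C + C_skip)` array.
#' @export
upsample_forward <- function(x, skip) {
  check_feature_map(x)
  check_feature_map(skip, "skip")
  dx <- dim(x); ds <- dim(skip)
  if (ds[1] != 2L * dx[1] || ds[2] != 2L * dx[2])
    stop(sprintf("skip map %s must be twice the spatial size of x %s",
                 paste(ds, collapse = "x"), paste(dx, collapse = "x")))
  m <- upsample_module()
  unbatch(m$forward(as_batch(x), as_batch(skip)))
}

# ---- RA-Block --------------------------------------------------------------

#' @rdname rablock_forward
#' @export
ra_block <- function(cfg) {
  stopifnot(inherits(cfg, "rablock_config"))
  m <- new_module("rablock")
  m$cfg <- cfg
  m$children <- list(
    conv1 = layer_conv2d(cfg$in_channels, cfg$out_channels, 3L, pad = 1L, bias = FALSE),
    bn1 = layer_bn(cfg$out_channels),
    act1 = layer_prelu(cfg$out_channels),
    conv2 = layer_conv2d(cfg$out_channels, cfg$out_channels, 3L, pad = 1L, bias = FALSE),
    bn2 = layer_bn(cfg$out_channels),
    conv3 = layer_conv2d(cfg$in_channels, cfg$out_channels, 1L, pad = 0L, bias = FALSE),
    bn3 = layer_bn(cfg$out_channels),
    act_out = layer_prelu(cfg$out_channels))
  if (cfg$use_coordinate_attention)
    m$children$ca <- layer_ca(cfg$out_channels)
  m$forward <- function(x, training = FALSE) {
    ch <- m$children
    b1 <- ch$bn2$forward(ch$conv2$forward(
      ch$act1$forward(ch$bn1$forward(ch$conv1$forward(x, training), training), training),
      training), training)
    b2 <- ch$bn3$forward(ch$conv3$forward(x, training), training)
    if (m$cfg$use_coordinate_attention) b2 <- ch$ca$forward(b2, training)
    m$branches <- list(main = b1, shortcut = b2, sum = b1 + b2)
    ch$act_out$forward(m$branches$sum, training)
  }
  m$backward <- function(gy, need_gx = TRUE) {
    ch <- m$children
    g <- ch$act_out$backward(gy)
    g2 <- g
    if (m$cfg$use_coordinate_attention) g2 <- ch$ca$backward(g2)
    gx2 <- ch$conv3$backward(ch$bn3$backward(g2), need_gx)
    gx1 <- ch$conv1$backward(ch$bn1$backward(ch$act1$backward(
      ch$conv2$backward(ch$bn2$backward(g)))), need_gx)
    if (need_gx) gx1 + gx2 else NULL
  }
  m
}

#' Residual attention decoder block
#'
#' Two-branch residual block: the main branch applies two successive 3x3
#' convolutions (each batch-normalized, PReLU between them); the shortcut
#' branch applies a 1x1 convolution followed by coordinate attention.  The
#' two branch outputs (post-normalization, pre-activation) are summed
#' elementwise and a single PReLU follows the sum.  Spatial size is
#' preserved; both branches emit `out_channels`.
#'
#' @param x an `H x W x in_channels` array.
#' @param cfg an [rablock_config()].
#' @param block optional prebuilt unit from `ra_block()`.
#' @param training batch vs running normalization statistics.
#' @return an `H x W x out_channels` array.
#' @export
rablock_forward <- function(x, cfg, block = NULL, training = FALSE) {
  d <- check_feature_map(x)
  b <- block %||% ra_block(cfg)
  if (d[3] != b$cfg$in_channels)
    stop(sprintf("RA-Block configured for %d input channels, got %d",
                 b$cfg$in_channels, d[3]))
  unbatch(b$forward(as_batch(x), training))
}
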