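#' Dilated 3x3 convolution
#'
#' Applies a 2-D cross-correlation with a 3x3 kernel whose taps are spaced
#' `rate` pixels apart.  Zero padding equal to the dilation rate is used, so
#' the output has the same spatial size as the input.  This is the primitive
#' from which the encoder's spatial pyramid convolution blocks are built.
#'
#' @param x an `H x W x C` feature-map array.
#' @param weights kernel array of shape `3 x 3 x C x out_channels`.
#' @param rate positive integer dilation rate.
#' @param out_channels number of output channels; defaults to the last
#'   dimension of `weights`.
#' @param bias optional length-`out_channels` bias vector.
#' @return an `H x W x out_channels` array.
#' @examples
#' x <- array(rnorm(3 * 32 * 32), dim = c(32, 32, 3))
#' w <- array(rnorm(3 * 3 * 3 * 8, sd = 0.1), dim = c(3, 3, 3, 8))
#' dim(dilated_conv_3x3(x, w, rate = 2))
#' @export
dilated_conv_3x3 <- function(x, weights, rate, out_channels = dim(weights)[4],
                             bias = NULL) {
  d <- check_feature_map(x)
  if (!is_count(rate)) stop("dilation 'rate' must be a positive integer")
  dw <- dim(weights)
  if (length(dw) != 4L || dw[1] != 3L || dw[2] != 3L)
    stop("'weights' must be a 3 x 3 x in_channels x out_channels array")
  if (dw[3] != d[3])
    stop(sprintf("weights expect %d input channels, feature map has %d", dw[3], d[3]))
  if (dw[4] != out_channels)
    stop("out_channels does not match dim(weights)[4]")
  span <- 2L * rate + 1L
  if (d[1] < span || d[2] < span)
    stop(sprintf("input %dx%d is smaller than the dilated kernel footprint; minimum size is %dx%d",
                 d[1], d[2], span, span))
  xb <- as_batch(x)
  y <- cpp_conv2d_fw(xb, as.integer(dim(xb)), matrix(weights, nrow = 9L * d[3]),
                     bias %||% numeric(0), 3L, 1L, as.integer(rate), as.integer(rate))
  unbatch(y)
}

#' Parametric rectified linear unit
#'
#' `prelu(x) = x` for `x >= 0` and `slope * x` otherwise.  The slope is a
#' per-channel learnable parameter in the network; its initial value 0.25
#' makes the activation at initialization exactly the fixed-slope form used
#' throughout the architecture description.
#'
#' @param x numeric scalar, vector or array.  If `x` is `H x W x C` and
#'   `slope` has length `C`, the slope is applied per channel.
#' @param slope negative-side slope(s); default 0.25.
#' @return object of the same shape as `x`.
#' @export
prelu <- function(x, slope = 0.25) {
  d <- dim(x)
  if (!is.null(d) && length(d) == 3L && length(slope) == d[3]) {
    sv <- rep(slope, each = d[1] * d[2])
    return(ifelse(x >= 0, x, sv * x))
  }
  if (length(slope) != 1L) stop("'slope' must be scalar or one value per channel")
  ifelse(x >= 0, x, slope * x)
}

#' Parameter-free Gaussian-excitation channel attention (GCT-B0)
#'
#' Rescales each channel of a feature map by a gate computed from global
#' channel statistics: channels are average-pooled, the pooled vector is
#' standardized across channels (epsilon `eps` guards degenerate spatial
#' sizes), and each channel is multiplied by the Gaussian excitation
#' `exp(-z^2 / (2 c0^2))`.  Gates lie in (0, 1]; a channel whose mean sits at
#' the across-channel average is passed through unchanged.
#'
#' @param x an `H x W x C` feature-map array.
#' @param c0 width of the Gaussian excitation (default 2).
#' @param eps standardisation guard (default 1e-5).
#' @param return_gates if `TRUE`, return `list(output, gates)`.
#' @return gated array of the same shape (or a list when `return_gates`).
#' @export
gct_b0 <- function(x, c0 = 2, eps = 1e-5, return_gates = FALSE) {
  check_feature_map(x)
  l <- layer_gct(c0 = c0, eps = eps)
  y <- unbatch(l$forward(as_batch(x)))
  if (return_gates) list(output = y, gates = as.vector(l$cache$g)) else y
}

#' Coordinate attention
#'
#' Multiplies a feature map by two factorized positional gates, one varying
#' along rows and one along columns.  Row- and column-pooled descriptors pass
#' through a shared bottleneck transform and two sigmoid gate heads; gates lie
#' strictly in (0, 1).  The transform weights are drawn at call time unless a
#' prebuilt `block` (from [ca_block()]) is supplied.
#'
#' @param x an `H x W x C` feature-map array.
#' @param block optional prebuilt attention unit from [ca_block()].
#' @param reduction bottleneck reduction ratio (default 32).
#' @param min_mid floor on the bottleneck width (default 8).
#' @param return_gates if `TRUE`, return `list(output, row_gates, col_gates)`
#'   where `row_gates` is `C x H` and `col_gates` is `C x W`.
#' @return gated array of the same shape (or a list when `return_gates`).
#' @export
coordinate_attention <- function(x, block = NULL, reduction = 32L, min_mid = 8L,
                                 return_gates = FALSE) {
  d <- check_feature_map(x)
  l <- block %||% layer_ca(d[3], reduction = reduction, min_mid = min_mid)
  y <- unbatch(l$forward(as_batch(x)))
  if (return_gates) {
    cc <- l$cache$caches[[1]]
    list(output = y, row_gates = cc$ah, col_gates = cc$aw)
  } else y
}

#' @rdname coordinate_attention
#' @param channels number of channels the unit is built for.
#' @export
ca_block <- function(channels, reduction = 32L, min_mid = 8L) {
  layer_ca(channels, reduction = reduction, min_mid = min_mid)
}

#' Bilinear resize
#'
#' Resizes the spatial dimensions of a matrix or feature map by separable
#' linear interpolation under the half-pixel-center convention (no corner
#' alignment).  Constant inputs are preserved exactly.
#'
#' @param x an `H x W` matrix or `H x W x C` array.
#' @param height,width target spatial size.
#' @return resized array of the same rank as `x`.
#' @export
resize_bilinear <- function(x, height, width) {
  d <- dim(x)
  two_d <- length(d) == 2L
  y <- resize_bilinear_batch(as_batch(x), height, width)
  y <- unbatch(y)
  if (two_d) dim(y) <- dim(y)[1:2]
  y
}
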