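# Full encoder-decoder assembly: five SPCBs and four SPPBs on the encoding
# path, four Upsample + RA-Block pairs on the decoding path, and a 1x1
# segmentation head.  Skip connections come from the SPCB outputs
# (pre-downsampling), which is what the concatenated channel counts
# (1024 + 512 = 1536, ...) force.

#' Network configuration
#'
#' @param in_channels channels of the network input (default 3; single-channel
#'   CT slices are replicated across 3 channels by the engine).
#' @param num_classes output classes (default 3: background, liver, tumor).
#' @param encoder_channels strictly increasing integer ladder of length 5
#'   (default `c(64, 128, 256, 512, 1024)`); the channel counts after each
#'   encoder SPCB.
#' @param dilation_rates three dilation rates shared by every SPCB
#'   (default `c(1, 2, 4)`).
#' @param use_gct enable GCT-B0 channel attention inside the SPCBs.
#' @param use_ca enable coordinate attention inside the RA-Blocks.
#' @param sppb_mode `"conv_plus_pool"` or `"conv_only"` downsampling.
#' @return an object of class `network_config`.
#' @export
network_config <- function(in_channels = 3L, num_classes = 3L,
                           encoder_channels = c(64L, 128L, 256L, 512L, 1024L),
                           dilation_rates = c(1L, 2L, 4L),
                           use_gct = TRUE, use_ca = TRUE,
                           sppb_mode = c("conv_plus_pool", "conv_only")) {
  stopifnot(is_count(in_channels), is_count(num_classes))
  if (length(encoder_channels) != 5L || any(diff(encoder_channels) <= 0))
    stop("'encoder_channels' must be a strictly increasing ladder of length 5")
  if (length(dilation_rates) != 3L || any(dilation_rates < 1))
    stop("'dilation_rates' must be three positive integers")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 encoder_channels = as.integer(encoder_channels),
                 dilation_rates = as.integer(dilation_rates),
                 use_gct = isTRUE(use_gct), use_ca = isTRUE(use_ca),
                 sppb_mode = match.arg(sppb_mode)),
            class = "network_config")
}

#' Build the segmentation network
#'
#' Assembles the encoder (SPCB/SPPB ladder), decoder (Upsample/RA-Block
#' pairs) and 1x1 segmentation head from a [network_config()].  Weights are
#' drawn from the current RNG state; call `set.seed()` first for
#' reproducible initialization.
#'
#' @param cfg a [network_config()].
#' @return an object of class `spaunet_network`.
#' @examples
#' set.seed(1)
#' net <- build_network(network_config(encoder_channels = c(8, 16, 32, 64, 128)))
#' x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
#' dim(net_forward(net, x))
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  ec <- cfg$encoder_channels
  net <- new_module("spaunet")
  net$cfg <- cfg
  sp <- function(i, o) spcb_block(spcb_config(i, o, cfg$dilation_rates,
                                              use_channel_attention = cfg$use_gct))
  dn <- function(i, o) sppb_block(sppb_config(i, o, mode = cfg$sppb_mode))
  ra <- function(i, o) ra_block(rablock_config(i, o, use_coordinate_attention = cfg$use_ca))
  net$children <- list(
    spcb1 = sp(cfg$in_channels, ec[1]),
    sppb1 = dn(ec[1], ec[2]),
    spcb2 = sp(ec[2], ec[2]),
    sppb2 = dn(ec[2], ec[3]),
    spcb3 = sp(ec[3], ec[3]),
    sppb3 = dn(ec[3], ec[4]),
    spcb4 = sp(ec[4], ec[4]),
    sppb4 = dn(ec[4], ec[5]),
    spcb5 = sp(ec[5], ec[5]),
    up4 = upsample_module(),
    ra4 = ra(ec[5] + ec[4], ec[4]),
    up3 = upsample_module(),
    ra3 = ra(ec[4] + ec[3], ec[3]),
    up2 = upsample_module(),
    ra2 = ra(ec[3] + ec[2], ec[2]),
    up1 = upsample_module(),
    ra1 = ra(ec[2] + ec[1], ec[1]),
    head = layer_conv2d(ec[1], cfg$num_classes, 1L, pad = 0L, bias = TRUE))
  class(net) <- c("spaunet_network", class(net))
  net
}

net_forward_batch <- function(net, x, training = FALSE, audit = NULL) {
  ch <- net$children
  rec <- function(name, y) {
    if (!is.null(audit)) {
      d <- dim(y)
      audit$rows[[length(audit$rows) + 1L]] <-
        data.frame(stage = name, channels = d[3], height = d[1], width = d[2])
    }
    y
  }
  e1 <- rec("spcb1", ch$spcb1$forward(x, training))
  d1 <- rec("sppb1", ch$sppb1$forward(e1, training))
  e2 <- rec("spcb2", ch$spcb2$forward(d1, training))
  d2 <- rec("sppb2", ch$sppb2$forward(e2, training))
  e3 <- rec("spcb3", ch$spcb3$forward(d2, training))
  d3 <- rec("sppb3", ch$sppb3$forward(e3, training))
  e4 <- rec("spcb4", ch$spcb4$forward(d3, training))
  d4 <- rec("sppb4", ch$sppb4$forward(e4, training))
  e5 <- rec("spcb5", ch$spcb5$forward(d4, training))
  u4 <- rec("upsample4", ch$up4$forward(e5, e4, training))
  r4 <- rec("rablock4", ch$ra4$forward(u4, training))
  u3 <- rec("upsample3", ch$up3$forward(r4, e3, training))
  r3 <- rec("rablock3", ch$ra3$forward(u3, training))
  u2 <- rec("upsample2", ch$up2$forward(r3, e2, training))
  r2 <- rec("rablock2", ch$ra2$forward(u2, training))
  u1 <- rec("upsample1", ch$up1$forward(r2, e1, training))
  r1 <- rec("rablock1", ch$ra1$forward(u1, training))
  rec("head", ch$head$forward(r1, training))
}

net_backward_batch <- function(net, gy, need_gx = FALSE) {
  ch <- net$children
  g <- ch$head$backward(gy)
  b <- ch$up1$backward(ch$ra1$backward(g)); g <- b$gx; gs1 <- b$gskip
  b <- ch$up2$backward(ch$ra2$backward(g)); g <- b$gx; gs2 <- b$gskip
  b <- ch$up3$backward(ch$ra3$backward(g)); g <- b$gx; gs3 <- b$gskip
  b <- ch$up4$backward(ch$ra4$backward(g)); g <- b$gx; gs4 <- b$gskip
  g <- ch$spcb5$backward(g)
  g <- ch$spcb4$backward(ch$sppb4$backward(g) + gs4)
  g <- ch$spcb3$backward(ch$sppb3$backward(g) + gs3)
  g <- ch$spcb2$backward(ch$sppb2$backward(g) + gs2)
  g <- ch$sppb1$backward(g)
  ch$spcb1$backward(g + gs1, need_gx = need_gx)
}

check_net_input <- function(net, d) {
  if (d[3] != net$cfg$in_channels)
    stop(sprintf("network expects %d input channels, got %d",
                 net$cfg$in_channels, d[3]))
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop(sprintf("input spatial size %dx%d must be divisible by 16 (four 2x downsamplings)",
                 d[1], d[2]))
}

#' Run the network forward
#'
#' Computes per-pixel unnormalized class scores (logits) for an input slice.
#' In evaluation mode (`training = FALSE`, the default) normalization layers
#' use their running statistics, so the output is deterministic given fixed
#' weights.
#'
#' @param net a network from [build_network()].
#' @param image an `H x W x in_channels` array (or `H x W x C x N` batch)
#'   with `H`, `W` divisible by 16.
#' @param training use batch statistics in normalization layers.
#' @return logits with spatial size equal to the input and `num_classes`
#'   channels.
#' @export
net_forward <- function(net, image, training = FALSE) {
  xb <- as_batch(image)
  check_net_input(net, dim(xb))
  y <- net_forward_batch(net, xb, training)
  if (length(dim(image)) == 3L) unbatch(y) else y
}

#' Predict a label mask
#'
#' Forward pass followed by per-pixel argmax over the class axis.
#'
#' @inheritParams net_forward
#' @return an `H x W` integer matrix over `0..num_classes-1`.
#' @export
predict_mask <- function(net, image) {
  logits <- net_forward(net, image)
  d <- dim(logits)
  matrix(max.col(matrix(logits, d[1] * d[2], d[3]), ties.method = "first") - 1L,
         d[1], d[2])
}

#' Audit the shape contract of every stage
#'
#' Runs a forward pass on a dummy input and records the output shape of each
#' named stage: 5 SPCBs, 4 SPPBs, 4 Upsamples, 4 RA-Blocks and the head.
#' Materializes the architecture's channel ladder mechanically so it can be
#' asserted rather than read off a diagram.
#'
#' @param net a network from [build_network()].
#' @param input_size `c(H, W)`, both divisible by 16.
#' @return a data frame with columns `stage`, `channels`, `height`, `width`.
#' @export
audit_shapes <- function(net, input_size = c(64L, 64L)) {
  x <- array(0, dim = c(input_size[1], input_size[2], net$cfg$in_channels, 1L))
  check_net_input(net, dim(x))
  audit <- new.env()
  audit$rows <- list()
  net_forward_batch(net, x, training = FALSE, audit = audit)
  do.call(rbind, audit$rows)
}

#' One-axis receptive field of a dilated 3x3 convolution
#'
#' For a single 3x3 convolution with dilation `rate`, the input pixels
#' influencing one output pixel span `3 + 2 * (rate - 1)` positions per axis
#' (rates 1 and 2 give 3 and 5; rate 4 gives 9 by this formula -- see the
#' methods vignette for discussion of the rate-4 case).
#'
#' @param rate positive integer dilation rate.
#' @return integer receptive-field span in pixels.
#' @export
receptive_field_3x3 <- function(rate) {
  if (!is_count(rate)) stop("'rate' must be a positive integer >= 1")
  as.integer(3 + 2 * (rate - 1))
}

#' Count learnable parameters
#'
#' @param net a network or block module.
#' @return total number of learnable scalar parameters.
#' @export
n_parameters <- function(net) {
  tot <- 0
  walk_layers(net, function(l) tot <<- tot + sum(vapply(l$params, length, 1L)))
  tot
}

# ---- checkpointing ---------------------------------------------------------

collect_state <- function(m, prefix = "") {
  out <- list()
  if (length(m$params) || length(m$buffers))
    out[[sub("/$", "", prefix)]] <- list(params = m$params, buffers = m$buffers)
  for (nm in names(m$children))
    out <- c(out, collect_state(m$children[[nm]], paste0(prefix, nm, "/")))
  out
}

restore_state <- function(m, state, prefix = "") {
  key <- sub("/$", "", prefix)
  if (!is.null(state[[key]])) {
    st <- state[[key]]
    if (!identical(lapply(m$params, length), lapply(st$params, length)))
      stop(sprintf("checkpoint state for '%s' does not match the network", key))
    m$params <- st$params
    m$buffers <- st$buffers
  }
  for (nm in names(m$children))
    restore_state(m$children[[nm]], state, paste0(prefix, nm, "/"))
  invisible(m)
}

#' Save / load a network checkpoint
#'
#' A checkpoint stores a version string, the [network_config()] used, the
#' training seed and every parameter and normalization buffer.  Loading
#' rebuilds the network from the stored configuration; supplying a `cfg`
#' that differs from the stored one is an error, never a silent reshape.
#'
#' @param net a network from [build_network()].
#' @param path file path.
#' @param seed integer seed recorded for provenance.
#' @param extra optional named list stored alongside (e.g. the training
#'   configuration).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored network with attributes `seed` and `extra`.
#' @export
save_checkpoint <- function(net, path, seed = NA_integer_, extra = NULL) {
  obj <- list(version = "spaunet-checkpoint-1",
              cfg = net$cfg, seed = seed, extra = extra,
              state = collect_state(net))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param cfg optional [network_config()] the caller expects; must match the
#'   stored configuration exactly.
#' @export
load_checkpoint <- function(path, cfg = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$version, "spaunet-checkpoint-1"))
    stop("not a recognized checkpoint file")
  if (!is.null(cfg) && !identical(unclass(cfg), unclass(obj$cfg)))
    stop("checkpoint was trained with a different network configuration")
  net <- build_network(obj$cfg)
  restore_state(net, obj$state)
  attr(net, "seed") <- obj$seed
  attr(net, "extra") <- obj$extra
  net
}
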