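# Training and evaluation orchestration: SGD with momentum on pixelwise
# cross-entropy, matching the published recipe (SGD, lr 0.01, momentum 0.9,
# weight decay 4e-5, batch size 4, 50 epochs), plus the ablation harness
# over dilation sets, attention toggles and the downsampling branches.

#' Training configuration
#'
#' Defaults reproduce the published training recipe exactly: SGD optimizer,
#' learning rate 0.01, momentum 0.9, weight decay 4e-5, batch size 4, 50
#' epochs, unweighted pixelwise cross-entropy, constant learning rate.
#'
#' @param learning_rate initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to convolution and attention
#'   weights (not to biases, normalization or activation parameters).
#' @param batch_size slices per optimization step.
#' @param epochs passes over the training set.
#' @param seed integer seed governing initialization and shuffling.
#' @param schedule `"constant"` (default) or `"poly"` (polynomial decay,
#'   power 0.9).
#' @param class_weights optional per-class loss weights (length
#'   `num_classes`); `NULL` (default) is the unweighted recipe.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         weight_decay = 4e-5, batch_size = 4L, epochs = 50L,
                         seed = 1L, schedule = c("constant", "poly"),
                         class_weights = NULL) {
  stopifnot(learning_rate > 0, momentum >= 0, weight_decay >= 0,
            is_count(batch_size), epochs >= 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 schedule = match.arg(schedule), class_weights = class_weights),
            class = "train_config")
}

#' Pixelwise softmax cross-entropy
#'
#' @param logits `H x W x K x N` unnormalized class scores.
#' @param labels `H x W x N` (or `H x W`) integer labels over `0..K-1`.
#' @param class_weights optional length-`K` per-class weights.
#' @return `list(loss, grad)`: the mean loss over pixels and its gradient
#'   with respect to the logits.
#' @export
cross_entropy_loss <- function(logits, labels, class_weights = NULL) {
  d <- dim(logits)
  K <- d[3]
  lm <- matrix(aperm(logits, c(1L, 2L, 4L, 3L)), ncol = K)
  lab <- as.integer(labels) + 1L
  M <- nrow(lm)
  mx <- lm[, 1]
  for (k in 2:K) mx <- pmax(mx, lm[, k])
  z <- lm - mx
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  wts <- if (is.null(class_weights)) rep(1, M) else class_weights[lab]
  nll <- -logp[cbind(seq_len(M), lab)] * wts
  denom <- sum(wts)
  p <- exp(logp) * wts
  p[cbind(seq_len(M), lab)] <- p[cbind(seq_len(M), lab)] - wts
  g <- from_channel_mat(p / denom, d)
  list(loss = sum(nll) / denom, grad = g)
}

sgd_step <- function(net, lr, momentum, weight_decay) {
  walk_layers(net, function(l) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0 && nm %in% l$decay) g <- g + weight_decay * l$params[[nm]]
      v <- l$vel[[nm]]
      v <- if (is.null(v)) g else momentum * v + g
      l$vel[[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] - lr * v
    }
  })
}

# stack slice pairs into network input/label batch arrays, replicating the
# single-channel windowed image across the configured input channels
make_batch <- function(pairs, in_channels) {
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  N <- length(pairs)
  x <- array(0, dim = c(H, W, in_channels, N))
  y <- array(0L, dim = c(H, W, N))
  for (n in seq_len(N)) {
    for (c in seq_len(in_channels)) x[, , c, n] <- pairs[[n]]$image
    y[, , n] <- pairs[[n]]$mask
  }
  list(x = x, y = y)
}

#' Train the segmentation network
#'
#' Runs the SGD loop on a list of slice pairs.  Per-epoch mean training loss
#' (and validation IoU, when a validation set is given) is logged; training
#' aborts with an informative error if the loss becomes non-finite.  The run
#' is fully reproducible: the seed fixes initialization and shuffling.
#'
#' @param net_cfg a [network_config()].
#' @param tr_cfg a [train_config()].
#' @param dataset non-empty list of slice pairs (`list(image, mask)`), all of
#'   one spatial size divisible by 16.
#' @param val_dataset optional validation slice pairs; when given, per-epoch
#'   validation mean (liver, tumor) IoU is logged and the best-epoch weights
#'   are retained in the result.
#' @param checkpoint_path optional path; the final (or best, if validation is
#'   used) checkpoint is written there.
#' @param verbose print per-epoch progress.
#' @return `list(network, log, config, seed, best)` where `log` is a data
#'   frame with one row per epoch.
#' @export
train_network <- function(net_cfg, tr_cfg, dataset, val_dataset = NULL,
                          checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(net_cfg, "network_config"), inherits(tr_cfg, "train_config"))
  if (length(dataset) == 0L) stop("training dataset is empty")
  set.seed(tr_cfg$seed)
  net <- build_network(net_cfg)
  n <- length(dataset)
  steps_per_epoch <- ceiling(n / tr_cfg$batch_size)
  total_iters <- max(1L, tr_cfg$epochs * steps_per_epoch)
  iter <- 0L
  log <- vector("list", tr_cfg$epochs)
  best <- list(iou = -Inf, state = NULL, epoch = NA_integer_)
  for (ep in seq_len(tr_cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq_len(steps_per_epoch)) {
      take <- ord[((s - 1L) * tr_cfg$batch_size + 1L):min(s * tr_cfg$batch_size, n)]
      bt <- make_batch(dataset[take], net_cfg$in_channels)
      lr <- if (tr_cfg$schedule == "poly")
        tr_cfg$learning_rate * (1 - iter / total_iters)^0.9
      else tr_cfg$learning_rate
      zero_grads(net)
      logits <- net_forward_batch(net, bt$x, training = TRUE)
      ce <- cross_entropy_loss(logits, bt$y, tr_cfg$class_weights)
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d, step %d", ep, s))
      net_backward_batch(net, ce$grad)
      sgd_step(net, lr, tr_cfg$momentum, tr_cfg$weight_decay)
      iter <- iter + 1L
      losses <- c(losses, ce$loss)
    }
    row <- data.frame(epoch = ep, loss = mean(losses))
    if (!is.null(val_dataset)) {
      vm <- evaluate_network(net, val_dataset)
      row$val_liver_iou <- vm$classes$liver$iou
      row$val_tumor_iou <- vm$classes$tumor$iou
      mean_iou <- (row$val_liver_iou + row$val_tumor_iou) / 2
      if (mean_iou > best$iou)
        best <- list(iou = mean_iou, state = collect_state(net), epoch = ep)
    }
    log[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f", ep, row$loss))
  }
  log <- if (tr_cfg$epochs > 0) do.call(rbind, log) else
    data.frame(epoch = integer(0), loss = numeric(0))
  if (!is.null(checkpoint_path)) {
    if (!is.null(best$state)) {
      final <- build_network(net_cfg)
      restore_state(final, best$state)
      save_checkpoint(final, checkpoint_path, seed = tr_cfg$seed,
                      extra = list(train_config = tr_cfg, best_epoch = best$epoch))
    } else {
      save_checkpoint(net, checkpoint_path, seed = tr_cfg$seed,
                      extra = list(train_config = tr_cfg))
    }
  }
  list(network = net, log = log, config = list(network = net_cfg, train = tr_cfg),
       seed = tr_cfg$seed, best = best[c("iou", "epoch")])
}

#' Evaluate a network on a dataset
#'
#' Eval-mode forward pass, per-pixel argmax, then [evaluate_dataset()].
#'
#' @param net a network from [build_network()], a training result from
#'   [train_network()], or a checkpoint path.
#' @param dataset non-empty list of slice pairs with ground-truth masks.
#' @param mode metric aggregation, `"micro"` (default) or `"macro"`.
#' @param report_path optional path for the JSON metrics report.
#' @return a `spaunet_metrics` object.
#' @export
evaluate_network <- function(net, dataset, mode = "micro", report_path = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  if (is.list(net) && !is.environment(net) && !is.null(net$network)) net <- net$network
  pairs <- lapply(dataset, function(p) {
    xb <- make_batch(list(p), net$cfg$in_channels)
    list(pred = predict_mask(net, xb$x[, , , 1]), gt = p$mask)
  })
  rep <- evaluate_dataset(pairs, mode = mode)
  if (!is.null(report_path)) write_metrics_report(rep, report_path)
  rep
}

#' Ablation axis configuration
#'
#' One point on the ablation grid: the dilation-rate set of the encoder
#' blocks, the two attention toggles, and the downsampling mode.
#'
#' @param dilation_set three dilation rates.
#' @param gct,ca attention toggles.
#' @param sppb_mode `"conv_plus_pool"` or `"conv_only"`.
#' @return an object of class `ablation_config`.
#' @export
ablation_config <- function(dilation_set = c(1, 2, 4), gct = TRUE, ca = TRUE,
                            sppb_mode = "conv_plus_pool") {
  structure(list(dilation_set = as.integer(dilation_set), gct = isTRUE(gct),
                 ca = isTRUE(ca), sppb_mode = sppb_mode),
            class = "ablation_config")
}

#' The four studied dilation-rate sets
#'
#' @return list of the four rate triples compared in the dilation ablation.
#' @export
dilation_rate_sets <- function() {
  list(c(1L, 2L, 2L), c(2L, 2L, 4L), c(2L, 4L, 4L), c(1L, 2L, 4L))
}

#' Run an ablation grid
#'
#' Trains and evaluates one network per [ablation_config()] under a shared
#' seed and returns a comparison table with per-class IoU, precision and
#' recall.
#'
#' @param grid list of [ablation_config()]s.
#' @param net_cfg base [network_config()]; each grid point overrides its
#'   dilation rates, attention toggles and downsampling mode.
#' @param tr_cfg a [train_config()]; the same seed is used for every row.
#' @param dataset training slice pairs.
#' @param eval_dataset slices to score; defaults to `dataset`.
#' @return data frame with one row per configuration.
#' @export
run_ablation <- function(grid, net_cfg, tr_cfg, dataset, eval_dataset = NULL) {
  eval_dataset <- eval_dataset %||% dataset
  rows <- lapply(grid, function(ab) {
    stopifnot(inherits(ab, "ablation_config"))
    cfg <- net_cfg
    cfg$dilation_rates <- ab$dilation_set
    cfg$use_gct <- ab$gct
    cfg$use_ca <- ab$ca
    cfg$sppb_mode <- ab$sppb_mode
    fit <- train_network(cfg, tr_cfg, dataset)
    m <- evaluate_network(fit$network, eval_dataset)
    data.frame(dilation = paste(ab$dilation_set, collapse = ","),
               gct = ab$gct, ca = ab$ca, sppb_mode = ab$sppb_mode,
               liver_iou = m$classes$liver$iou,
               liver_precision = m$classes$liver$precision,
               liver_recall = m$classes$liver$recall,
               tumor_iou = m$classes$tumor$iou,
               tumor_precision = m$classes$tumor$precision,
               tumor_recall = m$classes$tumor$recall)
  })
  do.call(rbind, rows)
}
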