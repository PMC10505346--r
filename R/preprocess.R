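# CT slice preprocessing: Hounsfield-unit windowing, liver-slice filtering,
# seeded dataset splitting and training-time augmentation.

#' Hounsfield-unit windowing
#'
#' Clips CT intensities to `[level - width/2, level + width/2]` and linearly
#' rescales that interval to `[0, 1]`.  The defaults (width 200 HU, level
#' 60 HU) select the soft-tissue window used for liver work: air maps to 0,
#' bone to 1, and the window level to 0.5.  The map is monotone
#' non-decreasing.
#'
#' @param image numeric array of CT intensities in Hounsfield units.
#' @param width window width in HU (> 0).
#' @param level window level (center) in HU.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
hu_window <- function(image, width = 200, level = 60) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("window 'width' must be a single positive number")
  lo <- level - width / 2
  pmin(pmax((image - lo) / width, 0), 1)
}

#' Keep only slices with liver labels
#'
#' Returns exactly the slices whose mask contains at least one pixel labeled
#' liver (1) or tumor (2), in their original order.  Slices labeled only
#' background are dropped (they show other abdominal organs and carry no
#' supervision for this task).
#'
#' @param pairs list of slice pairs (`list(image, mask, ...)`).
#' @return filtered list.
#' @export
filter_liver_slices <- function(pairs) {
  keep <- vapply(pairs, function(p) any(p$mask == 1L | p$mask == 2L), logical(1))
  pairs[keep]
}

#' Seeded random train/validation/test split
#'
#' Randomly partitions slices into three disjoint sets.  Validation and test
#' receive `ceiling(fraction * N)` slices each and the remainder goes to
#' training, which reproduces the published LiTS slice counts
#' (19,211 -> 15,367 / 1,922 / 1,922 at fractions 0.8/0.1/0.1).
#'
#' @param pairs list of slices (any list; elements are not inspected).
#' @param fractions `c(train, val, test)`, summing to 1.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return `list(train =, val =, test =)` of disjoint sublists whose union is
#'   `pairs`.
#' @export
split_dataset <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(pairs)
  if (n < 3L) stop("need at least 3 slices to form a three-way split")
  if (abs(sum(fractions) - 1) > 1e-6) stop("'fractions' must sum to 1")
  n_val <- as.integer(ceiling(fractions[2] * n - 1e-9))
  n_test <- as.integer(ceiling(fractions[3] * n - 1e-9))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("fractions leave no training slices")
  idx <- with_seed(seed, sample.int(n))
  list(train = pairs[idx[seq_len(n_train)]],
       val = pairs[idx[n_train + seq_len(n_val)]],
       test = pairs[idx[n_train + n_val + seq_len(n_test)]])
}

#' Augmentation configuration
#'
#' The four training-time augmentations: random scaling, random horizontal
#' flipping, random padding-and-cropping back to the original size, and
#' random photometric distortion (brightness/contrast jitter, image only).
#'
#' @param scale_range multiplicative scale range (default 0.8-1.2).
#' @param flip_prob probability of a horizontal flip (default 0.5).
#' @param distortion maximum absolute brightness offset and relative contrast
#'   change (default 0.1, i.e. +/-10%).
#' @param do_scale,do_flip,do_crop,do_distort toggles for each augmentation.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(scale_range = c(0.8, 1.2), flip_prob = 0.5,
                           distortion = 0.1, do_scale = TRUE, do_flip = TRUE,
                           do_crop = TRUE, do_distort = TRUE) {
  structure(list(scale_range = scale_range, flip_prob = flip_prob,
                 distortion = distortion, do_scale = do_scale,
                 do_flip = do_flip, do_crop = do_crop,
                 do_distort = do_distort),
            class = "augment_config")
}

# nearest-neighbor resize for integer masks (half-pixel-center convention,
# matching the bilinear path so image and mask stay registered)
resize_nearest <- function(m, out_h, out_w) {
  d <- dim(m)
  src_i <- pmin(pmax(round((seq_len(out_h) - 0.5) * d[1] / out_h - 0.5) + 1, 1), d[1])
  src_j <- pmin(pmax(round((seq_len(out_w) - 0.5) * d[2] / out_w - 0.5) + 1, 1), d[2])
  m[src_i, src_j, drop = FALSE]
}

#' Augment a slice pair
#'
#' Applies the configured augmentations with seeded randomness.  Image and
#' mask receive identical geometric transforms; the mask is interpolated
#' nearest-neighbor (no new labels can appear); photometric distortion
#' touches the image only.  The output always has the input's original size.
#'
#' @param pair a slice pair (`list(image, mask, ...)`).
#' @param ops an [augment_config()].
#' @param seed integer seed for this call's randomness.
#' @return augmented slice pair of the same spatial size.
#' @export
augment <- function(pair, ops = augment_config(), seed = 1L) {
  with_seed(seed, {
    img <- pair$image
    msk <- pair$mask
    H <- nrow(img); W <- ncol(img)
    if (ops$do_scale) {
      s <- runif(1, ops$scale_range[1], ops$scale_range[2])
      h2 <- max(1L, as.integer(round(H * s)))
      w2 <- max(1L, as.integer(round(W * s)))
      img <- resize_bilinear(img, h2, w2)
      msk <- resize_nearest(msk, h2, w2)
    }
    if (ops$do_flip && runif(1) < ops$flip_prob) {
      img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (ops$do_crop || nrow(img) != H || ncol(img) != W) {
      h2 <- nrow(img); w2 <- ncol(img)
      out_i <- matrix(0, H, W); out_m <- matrix(0L, H, W)
      ch <- min(H, h2); cw <- min(W, w2)
      si <- if (h2 > ch) sample.int(h2 - ch + 1L, 1) else 1L
      sj <- if (w2 > cw) sample.int(w2 - cw + 1L, 1) else 1L
      ti <- if (H > ch) sample.int(H - ch + 1L, 1) else 1L
      tj <- if (W > cw) sample.int(W - cw + 1L, 1) else 1L
      out_i[ti:(ti + ch - 1L), tj:(tj + cw - 1L)] <- img[si:(si + ch - 1L), sj:(sj + cw - 1L)]
      out_m[ti:(ti + ch - 1L), tj:(tj + cw - 1L)] <- msk[si:(si + ch - 1L), sj:(sj + cw - 1L)]
      img <- out_i; msk <- out_m
    }
    if (ops$do_distort) {
      b <- runif(1, -ops$distortion, ops$distortion)
      cgain <- 1 + runif(1, -ops$distortion, ops$distortion)
      img <- (img - mean(img)) * cgain + mean(img) + b
    }
    out <- pair
    out$image <- img
    out$mask <- msk
    out
  })
}
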