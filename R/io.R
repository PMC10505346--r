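# Volume and mask I/O.  Volumes follow the LiTS layout: a NIfTI image volume
# and a voxel-aligned label volume over {0 background, 1 liver, 2 tumor}.
# Axial slices are extracted along the third axis in row-major order.

#' Read a CT volume (and optional label volume) into slice pairs
#'
#' @param image_path path to a NIfTI image volume (`.nii` / `.nii.gz`).
#' @param mask_path optional path to the voxel-aligned label volume; must
#'   have exactly the image volume's dimensions.
#' @return list of slice pairs `list(image, mask, provenance)`, one per axial
#'   slice; `mask` is `NULL` when no label volume is given.
#' @export
read_volume <- function(image_path, mask_path = NULL) {
  img <- RNifti::readNifti(image_path)
  iv <- array(as.numeric(img), dim = dim(img))
  if (length(dim(iv)) == 2L) dim(iv) <- c(dim(iv), 1L)
  mv <- NULL
  if (!is.null(mask_path)) {
    msk <- RNifti::readNifti(mask_path)
    mv <- array(as.integer(msk), dim = dim(msk))
    if (length(dim(mv)) == 2L) dim(mv) <- c(dim(mv), 1L)
    if (!identical(dim(iv), dim(mv)))
      stop(sprintf("image volume %s and label volume %s have mismatched shapes",
                   paste(dim(iv), collapse = "x"), paste(dim(mv), collapse = "x")))
  }
  vol_id <- basename(image_path)
  lapply(seq_len(dim(iv)[3]), function(z) {
    list(image = iv[, , z],
         mask = if (is.null(mv)) NULL else mv[, , z],
         provenance = list(volume = vol_id, slice = z))
  })
}

#' Write a predicted label mask
#'
#' Dispatches on the file extension: `.nii` / `.nii.gz` writes an integer
#' NIfTI volume (2-D masks become single-slice volumes, 3-D arrays are
#' written as-is); `.png` writes a paletted overlay with background black,
#' liver red and tumor yellow.
#'
#' @param mask integer matrix (or 3-D array, NIfTI only) over `{0, 1, 2}`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(dim(mask)) != 2L) stop("PNG export requires a 2-D mask")
    H <- nrow(mask); W <- ncol(mask)
    rgb <- array(0, dim = c(H, W, 3))
    rgb[, , 1] <- (mask >= 1L)             # red channel: liver and tumor
    rgb[, , 2] <- (mask == 2L)             # green channel: tumor -> yellow
    png::writePNG(rgb, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    m <- mask
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(m), dim = dim(m))), path)
  } else {
    stop("unsupported mask format; use .nii, .nii.gz or .png")
  }
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' Inverse of the PNG palette (black/red/yellow -> 0/1/2) or a plain NIfTI
#' integer read.
#'
#' @param path mask file path.
#' @return integer matrix or 3-D array over `{0, 1, 2}`.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    rgb <- png::readPNG(path)
    m <- matrix(0L, dim(rgb)[1], dim(rgb)[2])
    m[rgb[, , 1] > 0.5] <- 1L
    m[rgb[, , 1] > 0.5 & rgb[, , 2] > 0.5] <- 2L
    m
  } else {
    v <- RNifti::readNifti(path)
    arr <- array(as.integer(v), dim = dim(v))
    if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) dim(arr) <- dim(arr)[1:2]
    arr
  }
}
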