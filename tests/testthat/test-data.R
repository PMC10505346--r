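test_that("HU windowing maps the soft-tissue window onto [0, 1]", {
  expect_equal(hu_window(60), 0.5)       # window level -> midpoint
  expect_equal(hu_window(-1000), 0)      # air, below level - width/2 = -40
  expect_equal(hu_window(400), 1)        # bone, above level + width/2 = 160
  expect_equal(hu_window(-40), 0)
  expect_equal(hu_window(160), 1)
  # retained interval spans exactly the window width
  expect_equal(hu_window(160) - hu_window(-40), 1)
  expect_equal(diff(c(-40, 160)), 200)
  # monotone non-decreasing
  v <- sort(runif(200, -1200, 1200))
  expect_true(all(diff(hu_window(v)) >= 0))
  expect_error(hu_window(0, width = -5), "positive")
})

test_that("slice filtering keeps exactly the slices with liver or tumor labels", {
  mk <- function(vals) list(image = matrix(0, 2, 2),
                            mask = matrix(vals, 2, 2))
  slices <- c(lapply(1:4, function(i) mk(0L)),
              lapply(1:3, function(i) mk(c(0L, 1L, 0L, 0L))),
              lapply(1:2, function(i) mk(c(0L, 1L, 2L, 0L))),
              list(mk(c(0L, 0L, 2L, 0L))))       # tumor-only slice
  kept <- filter_liver_slices(slices)
  expect_length(kept, 6L)
  # tumor-only slice is retained under the inclusive rule
  expect_true(any(vapply(kept, function(p) all(p$mask %in% c(0L, 2L)) &&
                           any(p$mask == 2L), logical(1))))
  expect_length(filter_liver_slices(list()), 0L)
})

test_that("dataset split reproduces the published slice counts exactly", {
  pairs <- as.list(seq_len(19211))
  sp <- split_dataset(pairs, c(0.8, 0.1, 0.1), seed = 4L)
  expect_length(sp$train, 15367L)
  expect_length(sp$val, 1922L)
  expect_length(sp$test, 1922L)
})

test_that("splits are disjoint, exhaustive, seeded and follow the rounding rule", {
  pairs <- as.list(1:10)
  s1 <- split_dataset(pairs, seed = 9L)
  s2 <- split_dataset(pairs, seed = 9L)
  expect_identical(s1, s2)
  expect_length(s1$train, 8L)
  expect_length(s1$val, 1L)
  expect_length(s1$test, 1L)
  all_ids <- c(unlist(s1$train), unlist(s1$val), unlist(s1$test))
  expect_setequal(all_ids, 1:10)
  expect_length(all_ids, 10L)
  expect_error(split_dataset(as.list(1:2)), "at least 3")
  expect_error(split_dataset(pairs, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("horizontal flip is an involution and augmentation is seeded", {
  p <- generate_phantom(phantom_spec(seed = 5L))
  flip_only <- augment_config(do_scale = FALSE, do_crop = FALSE,
                              do_distort = FALSE, flip_prob = 1)
  f1 <- augment(p, flip_only, seed = 1L)
  expect_false(identical(f1$image, p$image))
  f2 <- augment(f1, flip_only, seed = 2L)
  expect_identical(f2$image, p$image)
  expect_identical(f2$mask, p$mask)

  a1 <- augment(p, augment_config(), seed = 33L)
  a2 <- augment(p, augment_config(), seed = 33L)
  expect_identical(a1, a2)
})

test_that("augmentation conserves the label alphabet and output size", {
  p <- generate_phantom(phantom_spec(seed = 6L, n_tumors = c(2L, 2L)))
  before <- sort(unique(as.vector(p$mask)))
  for (s in 1:10) {
    a <- augment(p, augment_config(), seed = s)
    expect_equal(dim(a$mask), dim(p$mask))
    expect_equal(dim(a$image), dim(p$image))
    expect_true(all(unique(as.vector(a$mask)) %in% before))
    expect_true(all(a$mask == as.integer(a$mask)))
  }
})

test_that("phantom generation is a pure function of its seed", {
  s <- phantom_spec(seed = 42L)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom(phantom_spec(seed = 43L))
  expect_false(identical(p1$mask, p3$mask))
})

test_that("phantom geometry: tumors sit strictly inside the liver", {
  for (seed in 1:60) {
    p <- generate_phantom(phantom_spec(seed = seed, n_tumors = c(1L, 3L)))
    m <- p$mask
    expect_true(all(m %in% 0:2))
    tum <- which(m == 2L, arr.ind = TRUE)
    if (nrow(tum) == 0) next
    # no tumor pixel touches background: the 4-neighborhood is liver/tumor
    for (k in seq_len(nrow(tum))) {
      i <- tum[k, 1]; j <- tum[k, 2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(m) & nb[, 2] >= 1 & nb[, 2] <= ncol(m), , drop = FALSE]
      expect_true(all(m[nb] > 0L))
    }
    # per-blob area agrees with the disc area up to discretization
    for (tm in p$provenance$tumors) {
      r <- tm$radius
      yy <- (seq_len(nrow(m)) - tm$center[1])
      xx <- (seq_len(ncol(m)) - tm$center[2])
      inside <- outer(yy^2, xx^2, `+`) <= r^2
      expect_true(all(m[inside] == 2L))
      expect_lt(abs(sum(inside) - pi * r^2), 3 * (2 * pi * r + 4))
    }
  }
})

test_that("zero-tumor phantoms contain only background and liver labels", {
  p <- generate_phantom(phantom_spec(seed = 7L, n_tumors = c(0L, 0L)))
  expect_setequal(unique(as.vector(p$mask)), c(0L, 1L))
  expect_error(phantom_spec(height = 60), "divisible by 16")
})

test_that("phantom rendering shows the intended contrast ordering", {
  p <- generate_phantom(phantom_spec(seed = 8L, n_tumors = c(2L, 2L),
                                     tumor_radius = c(5, 8), noise_sigma = 0))
  liver_core <- mean(p$image[p$mask == 1L])
  bg <- mean(p$image[p$mask == 0L])
  tum <- mean(p$image[p$mask == 2L])
  expect_gt(liver_core, bg)     # liver brighter than background
  expect_lt(tum, liver_core)    # tumors hypodense relative to liver
  expect_gt(tum, bg)            # but still above background
})

test_that("phantom generation is fast enough for in-test data synthesis", {
  spec <- phantom_spec(64, 64)
  t0 <- proc.time()[["elapsed"]]
  invisible(generate_phantom_dataset(50, spec, seed = 1L))
  expect_lt((proc.time()[["elapsed"]] - t0) / 50, 0.010)
})

test_that("NIfTI volumes round-trip and shape mismatches are reported", {
  img <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  msk <- array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 2))
  fi <- tempfile(fileext = ".nii.gz")
  fm <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), fi)
  write_mask(msk, fm)
  pairs <- read_volume(fi, fm)
  expect_length(pairs, 2L)
  expect_equal(pairs[[1]]$mask, msk[, , 1])
  expect_equal(pairs[[2]]$mask, msk[, , 2])
  expect_equal(pairs[[1]]$image, img[, , 1], tolerance = 1e-6)
  # mask write -> read is lossless
  expect_equal(read_mask(fm), msk)
  bad <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0L, c(4, 4, 2))), bad)
  expect_error(read_volume(fi, bad), "mismatched shapes")
})

test_that("PNG masks use the black/red/yellow palette and round-trip", {
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 1L; m[3, 3] <- 2L
  fp <- tempfile(fileext = ".png")
  write_mask(m, fp)
  rgb <- png::readPNG(fp)
  expect_equal(rgb[1, 1, ], c(0, 0, 0))       # background black
  expect_equal(rgb[2, 2, 1:3], c(1, 0, 0))    # liver red
  expect_equal(rgb[3, 3, 1:3], c(1, 1, 0))    # tumor yellow
  expect_identical(read_mask(fp), m)
  expect_error(write_mask(m, tempfile(fileext = ".tif")), "unsupported")
})
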