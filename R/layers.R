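# Differentiable layer primitives.  Each layer is an environment holding its
# parameters, gradient accumulators, optimiser state and closures
# $forward(x, training) / $backward(gy).  Batches are H x W x C x N arrays.
# Backward passes are exact adjoints of the forward computation; they are
# checked against finite differences in the test suite.

new_layer <- function(kind) {
  l <- new.env(parent = emptyenv())
  l$kind <- kind
  l$params <- list()
  l$grads <- list()
  l$buffers <- list()
  l$vel <- list()
  l$decay <- character(0)   # param names subject to weight decay
  l$children <- list()
  l
}

acc_grad <- function(l, name, g) {
  l$grads[[name]] <- if (is.null(l$grads[[name]])) g else l$grads[[name]] + g
}

walk_layers <- function(m, fn) {
  if (length(m$params)) fn(m)
  for (ch in m$children) walk_layers(ch, fn)
  invisible(NULL)
}

zero_grads <- function(m) {
  walk_layers(m, function(l) l$grads <- list())
}

# ---- convolution -----------------------------------------------------------

layer_conv2d <- function(in_c, out_c, kernel = 3L, stride = 1L, pad = 0L,
                         dilation = 1L, bias = TRUE) {
  l <- new_layer("conv2d")
  l$in_c <- as.integer(in_c); l$out_c <- as.integer(out_c)
  l$kernel <- as.integer(kernel); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad); l$dilation <- as.integer(dilation)
  fan_in <- kernel^2 * in_c
  l$params$w <- array(stats::rnorm(kernel^2 * in_c * out_c, sd = sqrt(2 / fan_in)),
                      dim = c(kernel, kernel, in_c, out_c))
  if (bias) l$params$b <- numeric(out_c)
  l$decay <- "w"
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[3] != l$in_c)
      stop(sprintf("conv2d expects %d input channels, got %d", l$in_c, d[3]))
    span <- l$dilation * (l$kernel - 1L) + 1L
    if (d[1] + 2 * l$pad < span || d[2] + 2 * l$pad < span)
      stop(sprintf("input %dx%d smaller than the dilated kernel footprint; minimum padded size is %dx%d",
                   d[1], d[2], span, span))
    l$cache <- x
    cpp_conv2d_fw(x, as.integer(d), matrix(l$params$w, nrow = l$kernel^2 * l$in_c),
                  l$params$b %||% numeric(0), l$kernel, l$stride, l$pad, l$dilation)
  }
  l$backward <- function(gy, need_gx = TRUE) {
    r <- cpp_conv2d_bw(l$cache, as.integer(dim(l$cache)),
                       matrix(l$params$w, nrow = l$kernel^2 * l$in_c), gy,
                       l$kernel, l$stride, l$pad, l$dilation, need_gx)
    acc_grad(l, "w", array(r$gw, dim = dim(l$params$w)))
    if (!is.null(l$params$b)) acc_grad(l, "b", r$gb)
    if (need_gx) r$gx else NULL
  }
  l
}

# ---- batch normalization ---------------------------------------------------

layer_bn <- function(channels, eps = 1e-5, momentum = 0.9) {
  l <- new_layer("bn")
  l$eps <- eps; l$momentum <- momentum
  l$params$gamma <- rep(1, channels)
  l$params$beta <- rep(0, channels)
  l$buffers$running_mean <- rep(0, channels)
  l$buffers$running_var <- rep(1, channels)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- to_channel_mat(x)
    if (training) {
      mu <- colMeans(xm)
      v <- colMeans(xm * xm) - mu^2
      v[v < 0] <- 0
      l$buffers$running_mean <- l$momentum * l$buffers$running_mean + (1 - l$momentum) * mu
      l$buffers$running_var <- l$momentum * l$buffers$running_var + (1 - l$momentum) * v
    } else {
      mu <- l$buffers$running_mean
      v <- l$buffers$running_var
    }
    istd <- 1 / sqrt(v + l$eps)
    nr <- nrow(xm)
    xhat <- (xm - rep(mu, each = nr)) * rep(istd, each = nr)
    ym <- xhat * rep(l$params$gamma, each = nr) + rep(l$params$beta, each = nr)
    l$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
    from_channel_mat(ym, d)
  }
  l$backward <- function(gy, need_gx = TRUE) {
    cc <- l$cache
    gym <- to_channel_mat(gy)
    nr <- nrow(gym)
    acc_grad(l, "beta", colSums(gym))
    acc_grad(l, "gamma", colSums(gym * cc$xhat))
    if (!need_gx) return(NULL)
    gxh <- gym * rep(l$params$gamma, each = nr)
    if (cc$training) {
      s1 <- colSums(gxh)
      s2 <- colSums(gxh * cc$xhat)
      gxm <- (gxh - rep(s1 / nr, each = nr) - cc$xhat * rep(s2 / nr, each = nr)) *
        rep(cc$istd, each = nr)
    } else {
      gxm <- gxh * rep(cc$istd, each = nr)
    }
    from_channel_mat(gxm, cc$d)
  }
  l
}

# ---- PReLU -----------------------------------------------------------------

layer_prelu <- function(channels, init = 0.25) {
  l <- new_layer("prelu")
  l$params$a <- rep(init, channels)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    neg <- x < 0
    av <- chan_rep(l$params$a, d)
    l$cache <- list(x = x, neg = neg, d = d)
    x * ifelse(neg, av, 1)
  }
  l$backward <- function(gy, need_gx = TRUE) {
    cc <- l$cache
    gneg <- gy * cc$x * cc$neg
    ga <- colSums(to_channel_mat(gneg))
    acc_grad(l, "a", ga)
    if (!need_gx) return(NULL)
    av <- chan_rep(l$params$a, cc$d)
    gy * ifelse(cc$neg, av, 1)
  }
  l
}

# ---- 2x2 max pooling -------------------------------------------------------

layer_maxpool2 <- function() {
  l <- new_layer("maxpool2")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
      stop(sprintf("2x2 max pooling requires even spatial size, got %dx%d", d[1], d[2]))
    ii <- seq(1L, d[1], 2L); jj <- seq(1L, d[2], 2L)
    mm <- cbind(c(x[ii, jj, , , drop = FALSE]),
                c(x[ii + 1L, jj, , , drop = FALSE]),
                c(x[ii, jj + 1L, , , drop = FALSE]),
                c(x[ii + 1L, jj + 1L, , , drop = FALSE]))
    idx <- max.col(mm, ties.method = "first")
    out <- array(mm[cbind(seq_len(nrow(mm)), idx)],
                 dim = c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
    l$cache <- list(idx = idx, d = d)
    out
  }
  l$backward <- function(gy, need_gx = TRUE) {
    cc <- l$cache; d <- cc$d
    if (!need_gx) return(NULL)
    ii <- seq(1L, d[1], 2L); jj <- seq(1L, d[2], 2L)
    dq <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
    gx <- array(0, dim = d)
    pick <- function(k) array(c(gy) * (cc$idx == k), dim = dq)
    gx[ii, jj, , ] <- pick(1L)
    gx[ii + 1L, jj, , ] <- pick(2L)
    gx[ii, jj + 1L, , ] <- pick(3L)
    gx[ii + 1L, jj + 1L, , ] <- pick(4L)
    gx
  }
  l
}

# ---- bilinear resize (half-pixel centers) ----------------------------------

# Interpolation matrix mapping n_in samples to n_out under the half-pixel-
# center convention: output sample i sits at (i + 0.5) * n_in / n_out - 0.5
# in input coordinates, clamped at the borders.
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    A[i, i0[i] + 1] <- A[i, i0[i] + 1] + (1 - w1[i])
    A[i, i1[i] + 1] <- A[i, i1[i] + 1] + w1[i]
  }
  A
}

apply_rows <- function(x, A) {
  d <- dim(x)
  array(A %*% matrix(x, d[1]), dim = c(nrow(A), d[-1]))
}

apply_cols <- function(x, B) {
  y <- aperm(x, c(2L, 1L, 3L, 4L))
  y <- apply_rows(y, B)
  aperm(y, c(2L, 1L, 3L, 4L))
}

resize_bilinear_batch <- function(x, out_h, out_w) {
  d <- dim(x)
  A <- interp_matrix(d[1], out_h)
  B <- interp_matrix(d[2], out_w)
  apply_cols(apply_rows(x, A), B)
}

layer_upsample2 <- function() {
  l <- new_layer("upsample2")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    l$cache <- list(A = interp_matrix(d[1], 2L * d[1]),
                    B = interp_matrix(d[2], 2L * d[2]))
    apply_cols(apply_rows(x, l$cache$A), l$cache$B)
  }
  l$backward <- function(gy, need_gx = TRUE) {
    if (!need_gx) return(NULL)
    apply_cols(apply_rows(gy, t(l$cache$A)), t(l$cache$B))
  }
  l
}

# ---- GCT-B0 channel attention (parameter-free) -----------------------------

# Gaussian-excitation channel gating: per-channel global average pooling,
# standardisation of the channel-mean vector across channels, then the gate
# g_c = exp(-z_c^2 / (2 c0^2)) multiplied back per channel.  No learned
# parameters; gradients flow through both the gate and the identity path.
layer_gct <- function(c0 = 2, eps = 1e-5) {
  l <- new_layer("gct")
  l$c0 <- c0; l$eps <- eps
  l$forward <- function(x, training = FALSE) {
    d <- dim(x)
    hw <- d[1] * d[2]
    M <- matrix(colMeans(matrix(x, hw)), d[3], d[4])      # channel means, C x N
    mu <- colMeans(M)
    v <- colMeans(M * M) - mu^2
    s <- sqrt(pmax(v, 0))
    e <- s + l$eps
    z <- sweep(sweep(M, 2, mu, "-"), 2, e, "/")
    g <- exp(-z^2 / (2 * l$c0^2))
    l$cache <- list(x = x, z = z, g = g, s = s, e = e, d = d)
    x * rep(as.vector(g), each = hw)
  }
  l$backward <- function(gy, need_gx = TRUE) {
    if (!need_gx) return(NULL)
    cc <- l$cache; d <- cc$d
    hw <- d[1] * d[2]; C <- d[3]
    tg <- matrix(colSums(matrix(gy * cc$x, hw)), C, d[4])  # dL/dg, C x N
    dz <- tg * cc$g * (-cc$z / l$c0^2)
    dM <- sweep(sweep(dz, 2, colMeans(dz), "-"), 2, cc$e, "/")
    ok <- cc$s > 1e-12
    fac <- ifelse(ok, colSums(dz * cc$z) / (C * pmax(cc$s, 1e-12)), 0)
    dM <- dM - sweep(cc$z, 2, fac, "*")
    gy * rep(as.vector(cc$g), each = hw) + rep(as.vector(dM / hw), each = hw)
  }
  l
}

# ---- coordinate attention --------------------------------------------------

# Factorized positional attention: feature maps are average-pooled along each
# spatial axis, passed through a shared 1x1 bottleneck transform (ReLU), then
# split into row- and column-gate heads with sigmoid outputs; the input is
# multiplied by both gates.  Bottleneck width = max(min_mid, C / reduction).
layer_ca <- function(channels, reduction = 32L, min_mid = 8L) {
  l <- new_layer("ca")
  C <- as.integer(channels)
  mid <- max(as.integer(min_mid), C %/% as.integer(reduction))
  l$channels <- C; l$mid <- mid
  l$params$w1 <- matrix(stats::rnorm(mid * C, sd = sqrt(2 / C)), mid, C)
  l$params$b1 <- numeric(mid)
  l$params$wh <- matrix(stats::rnorm(C * mid, sd = sqrt(2 / mid)), C, mid)
  l$params$bh <- numeric(C)
  l$params$ww <- matrix(stats::rnorm(C * mid, sd = sqrt(2 / mid)), C, mid)
  l$params$bw <- numeric(C)
  l$decay <- c("w1", "wh", "ww")
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
    if (d[3] != l$channels)
      stop(sprintf("coordinate attention built for %d channels, got %d", l$channels, d[3]))
    y <- array(0, dim = d)
    caches <- vector("list", N)
    for (n in seq_len(N)) {
      xs <- array(x[, , , n], dim = d[1:3])
      ph <- t(matrix(colMeans(matrix(aperm(xs, c(2, 1, 3)), nrow = W)), H, C))  # C x H
      pw <- t(matrix(colMeans(matrix(xs, nrow = H)), W, C))                     # C x W
      u <- cbind(ph, pw)
      t1 <- l$params$w1 %*% u + l$params$b1
      h <- pmax(t1, 0)
      sh <- h[, seq_len(H), drop = FALSE]
      sw <- h[, H + seq_len(W), drop = FALSE]
      ah <- stats::plogis(l$params$wh %*% sh + l$params$bh)  # C x H
      aw <- stats::plogis(l$params$ww %*% sw + l$params$bw)  # C x W
      ah_arr <- aperm(array(t(ah), c(H, C, W)), c(1, 3, 2))
      aw_arr <- aperm(array(t(aw), c(W, C, H)), c(3, 1, 2))
      y[, , , n] <- xs * ah_arr * aw_arr
      caches[[n]] <- list(xs = xs, u = u, t1 = t1, sh = sh, sw = sw,
                          ah = ah, aw = aw, ah_arr = ah_arr, aw_arr = aw_arr)
    }
    l$cache <- list(caches = caches, d = d)
    y
  }
  l$backward <- function(gy, need_gx = TRUE) {
    d <- l$cache$d; H <- d[1]; W <- d[2]; N <- d[4]
    gx <- if (need_gx) array(0, dim = d) else NULL
    gw1 <- 0 * l$params$w1; gb1 <- 0 * l$params$b1
    gwh <- 0 * l$params$wh; gbh <- 0 * l$params$bh
    gww <- 0 * l$params$ww; gbw <- 0 * l$params$bw
    for (n in seq_len(N)) {
      cc <- l$cache$caches[[n]]
      gs <- array(gy[, , , n], dim = d[1:3])
      P <- gs * cc$xs * cc$aw_arr
      dah <- t(matrix(colSums(matrix(aperm(P, c(2, 1, 3)), nrow = W)), H, C))
      Q <- gs * cc$xs * cc$ah_arr
      daw <- t(matrix(colSums(matrix(Q, nrow = H)), W, C))
      dth <- dah * cc$ah * (1 - cc$ah)
      dtw <- daw * cc$aw * (1 - cc$aw)
      gwh <- gwh + dth %*% t(cc$sh); gbh <- gbh + rowSums(dth)
      gww <- gww + dtw %*% t(cc$sw); gbw <- gbw + rowSums(dtw)
      dh <- cbind(t(l$params$wh) %*% dth, t(l$params$ww) %*% dtw)
      dt1 <- dh * (cc$t1 > 0)
      gw1 <- gw1 + dt1 %*% t(cc$u); gb1 <- gb1 + rowSums(dt1)
      du <- t(l$params$w1) %*% dt1
      if (need_gx) {
        dph <- du[, seq_len(H), drop = FALSE]
        dpw <- du[, H + seq_len(W), drop = FALSE]
        gx[, , , n] <- gs * cc$ah_arr * cc$aw_arr +
          aperm(array(t(dph) / W, c(H, C, W)), c(1, 3, 2)) +
          aperm(array(t(dpw) / H, c(W, C, H)), c(3, 1, 2))
      }
    }
    acc_grad(l, "w1", gw1); acc_grad(l, "b1", gb1)
    acc_grad(l, "wh", gwh); acc_grad(l, "bh", gbh)
    acc_grad(l, "ww", gww); acc_grad(l, "bw", gbw)
    gx
  }
  l
}
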