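# Minimal 3D convolutional network engine.
#
# Feature maps are C x N matrices (channels x voxels) over a spatial grid
# sdim = c(h, w, t) stored h-fastest (R array order). Convolutions are
# im2col gathers (C++ kernels) feeding BLAS GEMMs; every layer implements an
# explicit backward pass. This keeps training deterministic under a fixed
# seed and free of external deep-learning dependencies.

MAX_COL_ELEMENTS <- 2^25  # cap on im2col buffer size (doubles)

nb_cache_get <- function(sdim, kernel, stride, pad_lo, pad_hi, reflect) {
  key <- paste(c("nb", sdim, kernel, stride, pad_lo, pad_hi, reflect),
               collapse = "_")
  hit <- .tvigan_env[[key]]
  if (is.null(hit)) {
    hit <- cpp_build_nb(as.integer(sdim), as.integer(kernel),
                        as.integer(stride), as.integer(pad_lo),
                        as.integer(pad_hi), reflect)
    .tvigan_env[[key]] <- hit
  }
  hit
}

upsample_index <- function(sdim, f) {
  key <- paste(c("up", sdim, f), collapse = "_")
  hit <- .tvigan_env[[key]]
  if (is.null(hit)) {
    h <- sdim[1]; w <- sdim[2]; t <- sdim[3]
    oh <- h * f[1]; ow <- w * f[2]; ot <- t * f[3]
    ih <- (seq_len(oh) - 1L) %/% f[1]
    iw <- (seq_len(ow) - 1L) %/% f[2]
    it <- (seq_len(ot) - 1L) %/% f[3]
    idx <- 1L + rep(ih, times = ow * ot) +
      h * rep(rep(iw, each = oh), times = ot) +
      h * w * rep(it, each = oh * ow)
    nb <- matrix(as.integer(idx), 1L)
    attr(nb, "out_dims") <- c(oh, ow, ot)
    hit <- nb
    .tvigan_env[[key]] <- hit
  }
  hit
}

# ---- layer constructors ------------------------------------------------

nn_conv <- function(cin, cout, k, s = c(1L, 1L, 1L), pad = (k - 1L) %/% 2L,
                    pad_hi = k - 1L - pad, reflect = TRUE, init_sd = 0.02) {
  list(type = "conv", cin = cin, cout = cout,
       k = as.integer(rep(k, length.out = 3)),
       s = as.integer(rep(s, length.out = 3)),
       pad_lo = as.integer(rep(pad, length.out = 3)),
       pad_hi = as.integer(rep(pad_hi, length.out = 3)),
       reflect = reflect,
       W = matrix(rnorm(cout * cin * prod(rep(k, length.out = 3)), 0, init_sd),
                  cout),
       b = numeric(cout))
}

nn_in <- function(eps = 1e-5) list(type = "in", eps = eps)
nn_relu <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_noise <- function(channels) list(type = "noise", s = numeric(channels))
nn_upsample <- function(f) list(type = "upsample", f = as.integer(f))

nn_resblock <- function(channels, stochastic = FALSE, init_sd = 0.02) {
  sub <- list(nn_conv(channels, channels, 3L, init_sd = init_sd))
  if (stochastic) sub <- c(sub, list(nn_noise(channels)))
  sub <- c(sub, list(nn_in(), nn_relu(),
                     nn_conv(channels, channels, 3L, init_sd = init_sd)))
  if (stochastic) sub <- c(sub, list(nn_noise(channels)))
  sub <- c(sub, list(nn_in()))
  list(type = "resblock", sub = sub)
}

# ---- forward / backward ------------------------------------------------

conv_fwd <- function(layer, x, sdim) {
  nb <- nb_cache_get(sdim, layer$k, layer$s, layer$pad_lo, layer$pad_hi,
                     layer$reflect)
  C <- nrow(x); K <- nrow(nb); P <- ncol(nb)
  if (K >= 100L) {
    # wide kernels: direct convolution avoids the huge im2col buffer
    y <- cpp_conv3d_direct(x, layer$W, layer$b, nb)
    return(list(y = y, sdim = attr(nb, "out_dims"),
                cache = list(x = x, sdim = sdim)))
  }
  blk <- max(1L, as.integer(MAX_COL_ELEMENTS %/% (as.double(C) * K)))
  if (P <= blk) {
    y <- layer$W %*% cpp_im2col(x, nb)
  } else {
    y <- matrix(0, layer$cout, P)
    starts <- seq(1L, P, by = blk)
    for (s0 in starts) {
      ii <- s0:min(s0 + blk - 1L, P)
      y[, ii] <- layer$W %*% cpp_im2col(x, nb[, ii, drop = FALSE])
    }
  }
  y <- y + layer$b
  list(y = y, sdim = attr(nb, "out_dims"), cache = list(x = x, sdim = sdim))
}

conv_bwd <- function(layer, dy, cache) {
  x <- cache$x; sdim <- cache$sdim
  nb <- nb_cache_get(sdim, layer$k, layer$s, layer$pad_lo, layer$pad_hi,
                     layer$reflect)
  C <- nrow(x); K <- nrow(nb); P <- ncol(nb); N <- ncol(x)
  if (K >= 100L) {
    r <- cpp_conv3d_direct_bwd(x, layer$W, dy, nb, N)
    return(list(dx = r$dX, g = list(W = r$dW, b = as.numeric(r$db))))
  }
  blk <- max(1L, as.integer(MAX_COL_ELEMENTS %/% (as.double(C) * K)))
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  dX <- matrix(0, C, N)
  starts <- seq(1L, P, by = blk)
  for (s0 in starts) {
    ii <- s0:min(s0 + blk - 1L, P)
    nbi <- nb[, ii, drop = FALSE]
    cols <- cpp_im2col(x, nbi)
    dyi <- dy[, ii, drop = FALSE]
    dW <- dW + tcrossprod(dyi, cols)
    dcols <- crossprod(layer$W, dyi)
    dX <- dX + cpp_col2im(dcols, nbi, C, N)
  }
  list(dx = dX, g = list(W = dW, b = rowSums(dy)))
}

in_fwd <- function(layer, x) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- xc * inv
  list(y = xhat, cache = list(xhat = xhat, inv = inv))
}

in_bwd <- function(layer, dy, cache) {
  xhat <- cache$xhat
  dx <- cache$inv * (dy - rowMeans(dy) - xhat * rowMeans(dy * xhat))
  list(dx = dx, g = NULL)
}

lay_fwd <- function(layer, x, sdim, precision = "single") {
  out <- switch(layer$type,
    conv = {
      r <- conv_fwd(layer, x, sdim)
      if (precision == "mixed") r$y <- to_float32(r$y)
      r
    },
    "in" = { r <- in_fwd(layer, x); r$sdim <- sdim; r },
    relu = {
      mask <- x > 0
      list(y = x * mask, sdim = sdim, cache = list(mask = mask))
    },
    lrelu = {
      mask <- x > 0
      y <- x * mask + layer$alpha * x * (!mask)
      list(y = y, sdim = sdim, cache = list(mask = mask))
    },
    noise = {
      n <- rnorm(sdim[1] * sdim[2])
      nfull <- rep(n, times = sdim[3])
      list(y = x + outer(layer$s, nfull), sdim = sdim,
           cache = list(nfull = nfull))
    },
    upsample = {
      nb <- upsample_index(sdim, layer$f)
      list(y = cpp_im2col(x, nb), sdim = attr(nb, "out_dims"),
           cache = list(sdim = sdim))
    },
    resblock = {
      h <- x; caches <- vector("list", length(layer$sub)); sd2 <- sdim
      for (i in seq_along(layer$sub)) {
        r <- lay_fwd(layer$sub[[i]], h, sd2, precision)
        h <- r$y; sd2 <- r$sdim; caches[[i]] <- r$cache
      }
      if (!identical(sd2, sdim)) stop("resblock changed the grid shape")
      list(y = x + h, sdim = sdim, cache = list(sub = caches))
    },
    stop("unknown layer type ", layer$type))
  out
}

lay_bwd <- function(layer, dy, cache) {
  switch(layer$type,
    conv = conv_bwd(layer, dy, cache),
    "in" = in_bwd(layer, dy, cache),
    relu = list(dx = dy * cache$mask, g = NULL),
    lrelu = list(dx = dy * cache$mask + layer$alpha * dy * (!cache$mask),
                 g = NULL),
    noise = list(dx = dy, g = list(s = as.numeric(dy %*% cache$nfull))),
    upsample = {
      nb <- upsample_index(cache$sdim, layer$f)
      list(dx = cpp_col2im(dy, nb, nrow(dy), prod(cache$sdim)), g = NULL)
    },
    resblock = {
      d <- dy
      gs <- vector("list", length(layer$sub))
      for (i in rev(seq_along(layer$sub))) {
        r <- lay_bwd(layer$sub[[i]], d, cache$sub[[i]])
        d <- r$dx
        gs[i] <- list(r$g)   # keep NULL placeholders
      }
      list(dx = dy + d, g = list(sub = gs))
    },
    stop("unknown layer type ", layer$type))
}

net_fwd <- function(net, x, sdim, keep_cache = TRUE,
                    precision = "single") {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    r <- lay_fwd(net$layers[[i]], x, sdim, precision)
    x <- r$y; sdim <- r$sdim
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(y = x, sdim = sdim, caches = caches)
}

net_bwd <- function(net, dy, caches) {
  gs <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- lay_bwd(net$layers[[i]], dy, caches[[i]])
    dy <- r$dx
    gs[i] <- list(r$g)       # keep NULL placeholders
  }
  list(dx = dy, grads = gs)
}

# ---- gradient bookkeeping and Adam ------------------------------------

grads_zero_like <- function(g) {
  if (is.null(g)) return(NULL)
  lapply(g, function(e) if (is.list(e)) grads_zero_like(e) else e * 0)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(g, f) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, f = f))
  g * f
}

adam_init <- function() list(t = 0L, m = list(), v = list())

# Applies one Adam step to every parameterized layer of `net` given grads
# parallel to net$layers. Returns list(net, state).
adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t_ <- state$t
  upd_layer <- function(layer, g, path) {
    if (is.null(g)) return(layer)
    if (layer$type == "resblock") {
      for (i in seq_along(layer$sub))
        layer$sub[[i]] <- upd_layer(layer$sub[[i]], g$sub[[i]],
                                    paste0(path, ".", i))
      return(layer)
    }
    for (pn in intersect(names(g), c("W", "b", "s"))) {
      key <- paste0(path, ".", pn)
      gm <- g[[pn]]
      m <- state$m[[key]] %||% (gm * 0)
      v <- state$v[[key]] %||% (gm * 0)
      m <- beta1 * m + (1 - beta1) * gm
      v <- beta2 * v + (1 - beta2) * gm * gm
      state$m[[key]] <<- m
      state$v[[key]] <<- v
      mhat <- m / (1 - beta1^t_)
      vhat <- v / (1 - beta2^t_)
      layer[[pn]] <- layer[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    layer
  }
  for (i in seq_along(net$layers))
    net$layers[[i]] <- upd_layer(net$layers[[i]], grads[[i]], as.character(i))
  list(net = net, state = state)
}

# Count of trainable parameters in a network.
n_params <- function(net) {
  cnt <- function(layer) {
    if (layer$type == "resblock") return(sum(vapply(layer$sub, cnt, 0)))
    sum(vapply(intersect(names(layer), c("W", "b", "s")),
               function(p) length(layer[[p]]), 0))
  }
  sum(vapply(net$layers, cnt, 0))
}
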