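# Reverse-mode automatic differentiation on a linear tape.
#
# Activations are dense numeric arrays of shape (H, W, C) in R's column-major
# layout; scalars are length-1 numerics. Convolution is im2col + BLAS matmul
# with cached gather indices, so the per-op R overhead stays small enough for
# CPU training of the small network configurations used throughout.

.ad_cache <- new.env(parent = emptyenv())

#' Create an empty computation graph (tape)
#'
#' With `keep = FALSE` the graph runs in inference mode: nodes carry values
#' only (no tape, no parents, no backward closures), so intermediate
#' activations are garbage-collected as soon as they fall out of scope.
#' @return an environment holding the tape
#' @keywords internal
ad_graph <- function(keep = TRUE) {
  g <- new.env(parent = emptyenv())
  g$tape <- vector("list", 256L)
  g$n <- 0L
  g$keep <- isTRUE(keep)
  g
}

ad_node <- function(g, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!g$keep) return(nd)
  nd$parents <- parents
  nd$backfn <- backfn
  n <- g$n + 1L
  if (n > length(g$tape)) g$tape <- c(g$tape, vector("list", length(g$tape)))
  g$tape[[n]] <- nd
  g$n <- n
  nd
}

ad_leaf <- function(g, value) ad_node(g, value)

ad_detach <- function(g, x) ad_leaf(g, x$value)

.ad_accum <- function(nd, grad) {
  nd$grad <- if (is.null(nd$grad)) grad else nd$grad + grad
  invisible(NULL)
}

# reduce a broadcast gradient back to a scalar parent if needed
.ad_fit <- function(grad, v) if (length(v) == 1L && length(grad) > 1L) sum(grad) else grad

#' Run backpropagation from a scalar root node
#' @keywords internal
ad_backward <- function(g, root, seed = 1) {
  root$grad <- seed
  for (i in rev(seq_len(g$n))) {
    nd <- g$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pg <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(pg[[j]])) .ad_accum(ps[[j]], pg[[j]])
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(g) {
  for (i in seq_len(g$n)) g$tape[[i]]$grad <- NULL
  invisible(NULL)
}

## ---- elementwise arithmetic (shapes equal, or one operand scalar) ----

ad_add <- function(g, x, y) {
  xv <- x$value; yv <- y$value
  ad_node(g, xv + yv, list(x, y),
          function(grad) list(.ad_fit(grad, xv), .ad_fit(grad, yv)))
}

ad_sub <- function(g, x, y) {
  xv <- x$value; yv <- y$value
  ad_node(g, xv - yv, list(x, y),
          function(grad) list(.ad_fit(grad, xv), .ad_fit(-grad, yv)))
}

ad_mul <- function(g, x, y) {
  xv <- x$value; yv <- y$value
  ad_node(g, xv * yv, list(x, y),
          function(grad) list(.ad_fit(grad * yv, xv), .ad_fit(grad * xv, yv)))
}

ad_div <- function(g, x, y) {
  xv <- x$value; yv <- y$value
  ad_node(g, xv / yv, list(x, y),
          function(grad) list(.ad_fit(grad / yv, xv),
                              .ad_fit(-grad * xv / (yv * yv), yv)))
}

# affine transform with numeric constants: a*x + b
ad_affine <- function(g, x, a = 1, b = 0) {
  ad_node(g, a * x$value + b, list(x), function(grad) list(a * grad))
}

ad_neg <- function(g, x) ad_affine(g, x, -1, 0)

ad_square <- function(g, x) {
  xv <- x$value
  ad_node(g, xv * xv, list(x), function(grad) list(2 * grad * xv))
}

ad_abs <- function(g, x) {
  xv <- x$value
  ad_node(g, abs(xv), list(x), function(grad) list(grad * sign(xv)))
}

## ---- activations ----

ad_relu <- function(g, x) {
  xv <- x$value
  m <- xv > 0
  ad_node(g, xv * m, list(x), function(grad) list(grad * m))
}

ad_lrelu <- function(g, x, slope = 0.2) {
  xv <- x$value
  f <- 1 + (slope - 1) * (xv <= 0)
  ad_node(g, xv * f, list(x), function(grad) list(grad * f))
}

ad_tanh <- function(g, x) {
  y <- tanh(x$value)
  ad_node(g, y, list(x), function(grad) list(grad * (1 - y * y)))
}

ad_sigmoid <- function(g, x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(g, y, list(x), function(grad) list(grad * y * (1 - y)))
}

## ---- reductions ----

ad_mean <- function(g, x) {
  n <- length(x$value)
  ad_node(g, mean(x$value), list(x),
          function(grad) list(array(grad / n, dim = dim(x$value) %||% n)))
}

ad_sum <- function(g, x) {
  ad_node(g, sum(x$value), list(x),
          function(grad) list(array(grad, dim = dim(x$value) %||% length(x$value))))
}

# weighted sum with a constant weight array (used by Grad-CAM targets)
ad_wsum <- function(g, x, w) {
  ad_node(g, sum(x$value * w), list(x), function(grad) list(grad * w))
}

## ---- structure ops ----

ad_concat_c <- function(g, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(dx[1] == dy[1], dx[2] == dy[2])
  v <- array(c(x$value, y$value), dim = c(dx[1], dx[2], dx[3] + dy[3]))
  ad_node(g, v, list(x, y), function(grad) {
    list(grad[, , seq_len(dx[3]), drop = FALSE],
         grad[, , dx[3] + seq_len(dy[3]), drop = FALSE])
  })
}

ad_flatten <- function(g, x) {
  d <- dim(x$value)
  ad_node(g, as.vector(x$value), list(x),
          function(grad) list(array(grad, dim = d)))
}

ad_crop <- function(g, x, rows, cols) {
  d <- dim(x$value)
  ad_node(g, x$value[rows, cols, , drop = FALSE], list(x), function(grad) {
    dx <- array(0, dim = d)
    dx[rows, cols, ] <- grad
    list(dx)
  })
}

## ---- convolution ----

# cached gather map: linear indices into the (H, W, C) input for every
# (output-position, kernel-tap) pair, reflection padding folded in
.conv_index <- function(H, W, C, k, stride, pad) {
  key <- paste("cv", H, W, C, k, stride, pad, sep = "_")
  got <- .ad_cache[[key]]
  if (!is.null(got)) return(got)
  stopifnot(pad < H, pad < W)
  # reflect-101 coordinate map for one axis
  refl <- function(n) {
    j <- seq_len(n + 2L * pad) - pad
    j[j < 1L] <- 2L - j[j < 1L]
    j[j > n] <- 2L * n - j[j > n]
    j
  }
  ri <- refl(H); rj <- refl(W)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  di <- rep(seq_len(k), times = k)
  dj <- rep(seq_len(k), each = k)
  # padded-grid coordinates for every (q, tap)
  Ri <- outer((oi - 1L) * stride, di, "+")   # (HoWo x k2) row in padded grid
  Cj <- outer((oj - 1L) * stride, dj, "+")
  # map through reflection to source coordinates, then to linear index
  lin1 <- matrix(ri[Ri], nrow(Ri), ncol(Ri)) +
          (matrix(rj[Cj], nrow(Cj), ncol(Cj)) - 1L) * H
  k2 <- k * k
  idx <- matrix(0L, Ho * Wo, k2 * C)
  for (ch in seq_len(C)) {
    idx[, (ch - 1L) * k2 + seq_len(k2)] <- lin1 + (ch - 1L) * (H * W)
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo, key = key)
  .ad_cache[[key]] <- out
  out
}

# sparse scatter operator (adjoint of the gather); built lazily on the first
# backward pass for a given signature
.conv_scat <- function(cm, n_in) {
  skey <- paste0(cm$key, "_scat")
  got <- .ad_cache[[skey]]
  if (is.null(got)) {
    got <- Matrix::sparseMatrix(i = as.vector(cm$idx), j = seq_along(cm$idx),
                                x = 1, dims = c(n_in, length(cm$idx)))
    .ad_cache[[skey]] <- got
  }
  got
}

# inference-only convolution: chunked over output positions, no caching, no
# closure retention; keeps peak memory flat for full-scale tiles
.conv_infer <- function(xv, Wv, bv, stride, pad) {
  d <- dim(xv)
  k <- attr(Wv, "k")
  Cout <- ncol(Wv)
  H <- d[1]; W <- d[2]; C <- d[3]
  refl <- function(n) {
    j <- seq_len(n + 2L * pad) - pad
    j[j < 1L] <- 2L - j[j < 1L]
    j[j > n] <- 2L * n - j[j > n]
    j
  }
  ri <- refl(H); rj <- refl(W)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  k2 <- k * k
  di <- rep(seq_len(k), times = k)
  dj <- rep(seq_len(k), each = k)
  npos <- Ho * Wo
  chunk <- max(1L, min(npos, as.integer(8e6 / (k2 * C))))
  Y <- matrix(0, npos, Cout)
  q0 <- 1L
  while (q0 <= npos) {
    q1 <- min(npos, q0 + chunk - 1L)
    qs <- q0:q1
    oi <- ((qs - 1L) %% Ho) + 1L
    oj <- ((qs - 1L) %/% Ho) + 1L
    Ri <- outer((oi - 1L) * stride, di, "+")
    Cj <- outer((oj - 1L) * stride, dj, "+")
    lin1 <- matrix(ri[Ri], nrow(Ri), ncol(Ri)) +
            (matrix(rj[Cj], nrow(Cj), ncol(Cj)) - 1L) * H
    Xc <- matrix(0, length(qs), k2 * C)
    for (ch in seq_len(C)) {
      Xc[, (ch - 1L) * k2 + seq_len(k2)] <- xv[lin1 + (ch - 1L) * (H * W)]
    }
    Y[qs, ] <- Xc %*% Wv
    q0 <- q1 + 1L
  }
  Y <- Y + rep(bv, each = npos)
  dim(Y) <- c(Ho, Wo, Cout)
  Y
}

#' 2-D convolution node (reflection padding)
#'
#' `W` is a matrix of shape (k*k*C_in) x C_out with attribute `k`; `b` a
#' length-C_out vector. Taps are ordered row-fastest within the kernel window,
#' then by input channel, matching the gather map.
#' @keywords internal
ad_conv2d <- function(g, x, W, b, stride = 1L, pad = 1L) {
  xv <- x$value
  d <- dim(xv)
  Wv <- W$value
  if (!g$keep) {
    return(ad_node(g, .conv_infer(xv, Wv, b$value,
                                  as.integer(stride), as.integer(pad))))
  }
  k <- attr(Wv, "k")
  Cout <- ncol(Wv)
  cm <- .conv_index(d[1], d[2], d[3], k, as.integer(stride), as.integer(pad))
  X <- xv[cm$idx]
  dim(X) <- dim(cm$idx)
  Y <- X %*% Wv
  Y <- Y + rep(b$value, each = nrow(Y))
  dim(Y) <- c(cm$Ho, cm$Wo, Cout)
  ad_node(g, Y, list(x, W, b), function(grad) {
    Gm <- grad
    dim(Gm) <- c(cm$Ho * cm$Wo, Cout)
    dW <- crossprod(X, Gm)
    attr(dW, "k") <- k
    db <- colSums(Gm)
    dXc <- tcrossprod(Gm, Wv)
    dim(dXc) <- NULL
    dx <- as.vector(.conv_scat(cm, prod(d)) %*% dXc)
    dim(dx) <- d
    list(dx, dW, db)
  })
}

## ---- instance normalisation (no affine parameters) ----

ad_instance_norm <- function(g, x, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  n <- d[1] * d[2]
  xm <- xv
  dim(xm) <- c(n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  s <- sqrt(colMeans(xc * xc) + eps)
  y <- xc / rep(s, each = n)
  yv <- y
  dim(yv) <- d
  ad_node(g, yv, list(x), function(grad) {
    Gm <- grad
    dim(Gm) <- c(n, d[3])
    gm <- colMeans(Gm)
    gym <- colMeans(Gm * y)
    dx <- (Gm - rep(gm, each = n) - y * rep(gym, each = n)) / rep(s, each = n)
    dim(dx) <- d
    list(dx)
  })
}

## ---- pooling / resampling ----

ad_avgpool2 <- function(g, x) {
  xv <- x$value
  d <- dim(xv)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  o1 <- seq(1L, d[1], by = 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], by = 2L); e2 <- o2 + 1L
  v <- 0.25 * (xv[o1, o2, , drop = FALSE] + xv[e1, o2, , drop = FALSE] +
               xv[o1, e2, , drop = FALSE] + xv[e1, e2, , drop = FALSE])
  ad_node(g, v, list(x), function(grad) {
    dx <- array(0, dim = d)
    q <- 0.25 * grad
    dx[o1, o2, ] <- q; dx[e1, o2, ] <- q
    dx[o1, e2, ] <- q; dx[e1, e2, ] <- q
    list(dx)
  })
}

# dense interpolation matrix mapping n source pixels to m target pixels
# (half-pixel centre convention, clamped at the borders)
.interp_matrix <- function(n, m) {
  key <- paste("ip", n, m, sep = "_")
  got <- .ad_cache[[key]]
  if (!is.null(got)) return(got)
  sc <- n / m
  src <- (seq_len(m) - 0.5) * sc - 0.5          # 0-based source coordinate
  src <- pmin(pmax(src, 0), n - 1)
  f <- floor(src)
  w <- src - f
  U <- matrix(0, m, n)
  i0 <- as.integer(f) + 1L
  i1 <- pmin(i0 + 1L, n)
  U[cbind(seq_len(m), i0)] <- U[cbind(seq_len(m), i0)] + (1 - w)
  U[cbind(seq_len(m), i1)] <- U[cbind(seq_len(m), i1)] + w
  .ad_cache[[key]] <- U
  U
}

#' Bilinear resize of an (H, W, C) array (plain, no autodiff)
#' @keywords internal
bilinear_resize <- function(a, out_h, out_w) {
  d <- dim(a)
  UH <- .interp_matrix(d[1], out_h)
  UW <- .interp_matrix(d[2], out_w)
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- UH %*% a[, , ch] %*% t(UW)
  out
}

ad_upsample2 <- function(g, x) {
  xv <- x$value
  d <- dim(xv)
  UH <- .interp_matrix(d[1], 2L * d[1])
  UW <- .interp_matrix(d[2], 2L * d[2])
  v <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  for (ch in seq_len(d[3])) v[, , ch] <- UH %*% xv[, , ch] %*% t(UW)
  ad_node(g, v, list(x), function(grad) {
    dx <- array(0, dim = d)
    for (ch in seq_len(d[3])) dx[, , ch] <- crossprod(UH, grad[, , ch]) %*% UW
    list(dx)
  })
}

## ---- dense layer ----

ad_dense <- function(g, x, W, b) {
  xv <- as.vector(x$value)
  Wv <- W$value
  y <- drop(crossprod(Wv, xv)) + b$value   # W is (d_in x d_out)
  ad_node(g, y, list(x, W, b), function(grad) {
    list(array(Wv %*% grad, dim = dim(x$value) %||% length(xv)),
         outer(xv, grad),
         grad)
  })
}

## ---- composite: global SSIM between two nodes (population moments) ----

ad_ssim_global <- function(g, x, y, c1 = 1e-4, c2 = 9e-4) {
  mx <- ad_mean(g, x); my <- ad_mean(g, y)
  xx <- ad_mean(g, ad_square(g, x))
  yy <- ad_mean(g, ad_square(g, y))
  xy <- ad_mean(g, ad_mul(g, x, y))
  vx <- ad_sub(g, xx, ad_mul(g, mx, mx))
  vy <- ad_sub(g, yy, ad_mul(g, my, my))
  cv <- ad_sub(g, xy, ad_mul(g, mx, my))
  num <- ad_mul(g, ad_affine(g, ad_mul(g, mx, my), 2, c1),
                   ad_affine(g, cv, 2, c2))
  den <- ad_mul(g, ad_affine(g, ad_add(g, ad_mul(g, mx, mx), ad_mul(g, my, my)), 1, c1),
                   ad_affine(g, ad_add(g, vx, vy), 1, c2))
  ad_div(g, num, den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- Adam optimiser ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-4,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    at <- attributes(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * as.vector(gr)
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * as.vector(gr)^2
    upd <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - array(upd, dim = dim(params[[nm]]) %||% length(params[[nm]]))
    attributes(params[[nm]]) <- at
  }
  list(params = params, state = state)
}
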