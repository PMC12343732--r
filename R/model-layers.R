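# Layer primitives for the spherical CNN and the MLP baseline, with
# hand-derived backward passes (verified against finite differences in the
# test suite). Batched features live in matrices of shape (B*K) x C with row
# index r = (k-1)*B + b: voxel fastest, SH coefficient slowest. This keeps
# every heavy operation a single BLAS call.

leaky_relu <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

# ---- degree bookkeeping -----------------------------------------------------

# k indices grouped by even degree, and the batched row indices they expand to.
degree_blocks <- function(lmax) {
  idx <- sh_indexing(lmax)
  lapply(seq(0L, lmax, by = 2L), function(l) which(idx$l == l))
}

degree_rows <- function(blocks, B) {
  lapply(blocks, function(ks)
    as.vector(vapply(ks, function(k) (k - 1L) * B + seq_len(B), integer(B))))
}

# ---- equivariant convolution ------------------------------------------------

#' Initialize an equivariant spherical convolution layer
#'
#' One learnable scalar weight per (output channel, input channel, even
#' degree), broadcast over all orders m of the degree, plus an optional bias
#' on the l = 0 coefficient (the only bias that preserves SO(3)
#' equivariance). A residual connection is added when `residual = TRUE` and
#' the channel counts match.
#'
#' @param c_in,c_out channel counts.
#' @param lmax even band limit.
#' @param bias include an l = 0 bias.
#' @param residual add the input back to the output (requires c_in == c_out).
#' @return parameter list with `W` (array [c_out, c_in, L]), `b`, `residual`.
#' @export
conv_params <- function(c_in, c_out, lmax = 8L, bias = TRUE,
                        residual = FALSE) {
  L <- lmax / 2 + 1
  if (residual && c_in != c_out)
    stop("residual connection requires c_in == c_out")
  list(W = array(stats::rnorm(c_out * c_in * L, sd = 1 / sqrt(c_in)),
                 dim = c(c_out, c_in, L)),
       b = if (bias) numeric(c_out) else NULL,
       residual = residual)
}

conv_fwd <- function(X, p, ctx) {
  if (isTRUE(ctx$fast))
    return(conv_fwd_cpp(X, p$W, p$b, ctx$B, isTRUE(p$residual)))
  c_out <- dim(p$W)[1L]
  Y <- matrix(0, nrow(X), c_out)
  for (d in seq_along(ctx$rows)) {
    r <- ctx$rows[[d]]
    Y[r, ] <- X[r, , drop = FALSE] %*% t(matrix(p$W[, , d], c_out))
  }
  if (!is.null(p$b))
    Y[ctx$rows[[1L]], ] <- Y[ctx$rows[[1L]], , drop = FALSE] +
      rep(p$b, each = ctx$B)
  if (isTRUE(p$residual)) Y <- Y + X
  Y
}

conv_bwd <- function(dY, X, p, ctx) {
  if (isTRUE(ctx$fast)) {
    r <- conv_bwd_cpp(dY, X, p$W, !is.null(p$b), ctx$B, isTRUE(p$residual))
    return(list(dX = r$dX,
                grads = list(W = r$dW, b = if (!is.null(p$b)) drop(r$db))))
  }
  c_out <- dim(p$W)[1L]; c_in <- dim(p$W)[2L]
  dX <- matrix(0, nrow(X), c_in)
  dW <- array(0, dim = dim(p$W))
  for (d in seq_along(ctx$rows)) {
    r <- ctx$rows[[d]]
    Wd <- matrix(p$W[, , d], c_out)
    dX[r, ] <- dY[r, , drop = FALSE] %*% Wd
    dW[, , d] <- crossprod(dY[r, , drop = FALSE], X[r, , drop = FALSE])
  }
  db <- if (!is.null(p$b))
    colSums(dY[ctx$rows[[1L]], , drop = FALSE]) else NULL
  if (isTRUE(p$residual)) dX <- dX + dY
  list(dX = dX, grads = list(W = dW, b = db))
}

# batch-norm followed by ReLU, with a fused compiled path
bnrelu_fwd <- function(X, p, st, training, fast) {
  if (isTRUE(fast)) {
    r <- bn_relu_fwd_cpp(X, p$gamma, p$beta, st$mean, st$var, training,
                         0.1, 1e-5, TRUE)
    return(list(Y = r$Y,
                state = list(mean = drop(r$mean), var = drop(r$var)),
                cache = list(Y_act = r$Y, xhat = r$xhat,
                             istd = drop(r$istd))))
  }
  b <- bn_fwd(X, p, st, training)
  list(Y = pmax(b$Y, 0), state = b$state,
       cache = list(Y_act = pmax(b$Y, 0), xhat = b$cache$xhat,
                    istd = b$cache$istd))
}

bnrelu_bwd <- function(dY, p, cache, fast) {
  if (isTRUE(fast)) {
    r <- bn_relu_bwd_cpp(dY, cache$Y_act, cache$xhat, cache$istd,
                         p$gamma, TRUE)
    return(list(dX = r$dX, grads = list(gamma = drop(r$dgamma),
                                        beta = drop(r$dbeta))))
  }
  dr <- dY * (cache$Y_act > 0)
  bn_bwd(dr, p, list(xhat = cache$xhat, istd = cache$istd))
}

# ---- spatial-domain nonlinearity -------------------------------------------

# (B*K) x C  ->  (B*C) x K and back.
kb_to_ck <- function(X, B, K, C) {
  dim(X) <- c(B, K, C)
  X <- aperm(X, c(1L, 3L, 2L))
  dim(X) <- c(B * C, K)
  X
}

ck_to_kb <- function(X, B, K, C) {
  dim(X) <- c(B, C, K)
  X <- aperm(X, c(1L, 3L, 2L))
  dim(X) <- c(B * K, C)
  X
}

nonlin_fwd <- function(X, ctx) {
  C <- ncol(X)
  if (isTRUE(ctx$fast)) {
    r <- nonlin_fwd_cpp(X, ctx$B, ctx$K, C, ctx$Ut, ctx$Vt, ctx$slope)
    return(list(Y = r$Y, mask = r$pos))
  }
  Xk <- kb_to_ck(X, ctx$B, ctx$K, C)
  A <- Xk %*% ctx$Ut                    # (B*C) x N amplitudes
  mask <- A >= 0
  A[!mask] <- ctx$slope * A[!mask]
  Y <- ck_to_kb(A %*% ctx$Vt, ctx$B, ctx$K, C)
  list(Y = Y, mask = mask)
}

nonlin_bwd <- function(dY, mask, ctx) {
  C <- ncol(dY)
  if (isTRUE(ctx$fast))
    return(nonlin_bwd_cpp(dY, mask, ctx$B, ctx$K, C, ctx$V, ctx$U, ctx$slope))
  dA <- kb_to_ck(dY, ctx$B, ctx$K, C) %*% ctx$V
  dA[!mask] <- ctx$slope * dA[!mask]
  ck_to_kb(dA %*% ctx$U, ctx$B, ctx$K, C)
}

# ---- shell attention --------------------------------------------------------

#' Initialize shell-attention parameters
#'
#' Two-layer feedforward head on the concatenated per-shell global average
#' pooled features (3 x 16 channels -> 48), producing one softmax weight per
#' shell.
#'
#' @param n_shells number of shells (3).
#' @param channels feature channels per shell (16).
#' @param hidden hidden width (24).
#' @return parameter list W1 (hidden x in), b1, W2 (n_shells x hidden), b2.
#'   The Leaky ReLU slope (0.1) is part of the model config, not a parameter.
#' @export
attention_params <- function(n_shells = 3L, channels = 16L, hidden = 24L) {
  d_in <- n_shells * channels
  list(W1 = matrix(stats::rnorm(hidden * d_in, sd = 1 / sqrt(d_in)),
                   hidden, d_in),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(n_shells * hidden, sd = 1 / sqrt(hidden)),
                   n_shells, hidden),
       b2 = numeric(n_shells))
}

softmax_rows <- function(x) {
  x <- exp(x - apply(x, 1L, max))
  x / rowSums(x)
}

# mean over the SH dimension per (voxel, channel): (B*K) x C -> B x C
gap_sh <- function(X, B, K) {
  C <- ncol(X)
  dim(X) <- c(B, K, C)
  colMeans(aperm(X, c(2L, 1L, 3L)), dims = 1L)
}

attention_fwd <- function(Xs, p, ctx) {
  B <- ctx$B; K <- ctx$K
  Z <- do.call(cbind, lapply(Xs, gap_sh, B = B, K = K))   # B x 48
  H <- Z %*% t(p$W1) + rep(p$b1, each = B)
  Ha <- leaky_relu(H, ctx$slope)
  logits <- Ha %*% t(p$W2) + rep(p$b2, each = B)
  a <- softmax_rows(logits)
  Ys <- lapply(seq_along(Xs), function(s) Xs[[s]] * rep(a[, s], times = K))
  list(Y = do.call(cbind, Ys), a = a,
       cache = list(Z = Z, H = H, Ha = Ha, Xs = Xs))
}

attention_bwd <- function(dY, a, cache, p, ctx) {
  B <- ctx$B; K <- ctx$K
  n_s <- length(cache$Xs)
  C <- ncol(cache$Xs[[1L]])
  da <- matrix(0, B, n_s)
  dXs <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    dYs <- dY[, (s - 1L) * C + seq_len(C), drop = FALSE]
    dXs[[s]] <- dYs * rep(a[, s], times = K)
    v <- rowSums(dYs * cache$Xs[[s]])
    da[, s] <- rowSums(matrix(v, B, K))
  }
  dlogit <- a * (da - rowSums(a * da))
  dHa <- dlogit %*% p$W2
  dH <- dHa * ifelse(cache$H >= 0, 1, ctx$slope)
  dZ <- dH %*% p$W1
  dW2 <- crossprod(dlogit, cache$Ha); db2 <- colSums(dlogit)
  dW1 <- crossprod(dH, cache$Z); db1 <- colSums(dH)
  for (s in seq_len(n_s)) {
    dZs <- dZ[, (s - 1L) * C + seq_len(C), drop = FALSE]
    dXs[[s]] <- dXs[[s]] + dZs[rep(seq_len(B), times = K), , drop = FALSE] / K
  }
  list(dXs = dXs,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- dense / batch-norm -----------------------------------------------------

linear_params <- function(d_in, d_out, he = TRUE) {
  sd <- if (he) sqrt(2 / d_in) else 1 / sqrt(d_in)
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(X, p) X %*% p$W + rep(p$b, each = nrow(X))
linear_bwd <- function(dY, X, p)
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))

bn_params <- function(d) list(gamma = rep(1, d), beta = numeric(d))
bn_state <- function(d) list(mean = numeric(d), var = rep(1, d))

bn_fwd <- function(X, p, st, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * v
  } else {
    mu <- st$mean; v <- st$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - rep(mu, each = nrow(X))) * rep(istd, each = nrow(X))
  Y <- xhat * rep(p$gamma, each = nrow(X)) + rep(p$beta, each = nrow(X))
  list(Y = Y, state = st, cache = list(xhat = xhat, istd = istd))
}

bn_bwd <- function(dY, p, cache) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(p$gamma, each = n)
  dX <- (dxhat - rep(colMeans(dxhat), each = n) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
    rep(cache$istd, each = n)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- parameter-tree utilities ----------------------------------------------

# Apply f to every numeric leaf of (possibly nested) parameter lists.
tree_map <- function(f, a, b = NULL) {
  if (is.numeric(a)) return(if (is.null(b)) f(a) else f(a, b))
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) {
      if (is.numeric(a[[i]]) || is.list(a[[i]]))
        out[[i]] <- tree_map(f, a[[i]], if (!is.null(b)) b[[i]])
    }
    return(out)
  }
  a
}

tree_sum <- function(f, a) {
  if (is.numeric(a)) return(f(a))
  if (is.list(a))
    return(sum(vapply(a, function(el)
      if (is.numeric(el) || is.list(el)) tree_sum(f, el) else 0,
      numeric(1L))))
  0
}

grad_global_norm <- function(g) sqrt(tree_sum(function(x) sum(x^2), g))

# Flatten the numeric leaves of a parameter/gradient tree into one vector
# (fixed traversal order shared by params and grads), and write one back.
tree_flatten_num <- function(tr) {
  acc <- list(); i <- 0L
  walk <- function(x) {
    if (is.numeric(x)) {
      i <<- i + 1L
      acc[[i]] <<- as.vector(x)
    } else if (is.list(x)) {
      for (el in x) if (is.numeric(el) || is.list(el)) walk(el)
    }
  }
  walk(tr)
  unlist(acc, use.names = FALSE)
}

tree_unflatten <- function(tr, flat) {
  pos <- 0L
  walk <- function(x) {
    if (is.numeric(x)) {
      n <- length(x)
      x[] <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      return(x)
    }
    if (is.list(x)) {
      for (i in seq_along(x))
        if (is.numeric(x[[i]]) || is.list(x[[i]])) x[[i]] <- walk(x[[i]])
    }
    x
  }
  out <- walk(tr)
  stopifnot(pos == length(flat))
  out
}

# flat logical mask marking weight-matrix entries (leaves named W/W1/W2),
# for decoupled weight decay
tree_decay_mask <- function(tr) {
  acc <- list(); i <- 0L
  walk <- function(x, name) {
    if (is.numeric(x)) {
      i <<- i + 1L
      acc[[i]] <<- rep(grepl("^W", name), length(x))
    } else if (is.list(x)) {
      for (j in seq_along(x)) {
        nm <- if (is.null(names(x))) "" else names(x)[j]
        if (is.numeric(x[[j]]) || is.list(x[[j]])) walk(x[[j]], nm)
      }
    }
  }
  walk(tr, "")
  unlist(acc, use.names = FALSE)
}
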