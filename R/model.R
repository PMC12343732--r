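# The equivariant spherical CNN (sCNN) and the MLP baseline.
#
# The sCNN maps a per-voxel stack of three shell SH vectors (3 x 45 at
# lmax = 8) to 45 FOD SH coefficients: shell-specific equivariant
# convolutions (1 -> 16 channels each), softmax shell attention, a fusing
# convolution (48 -> 16), an encoder (16 -> 32 -> 64) and symmetric decoder
# (64 -> 32 -> 16) of equivariant convolutions with ISFT/LeakyReLU/SFT
# nonlinearities, and a fully connected head with batch normalization and
# ReLU. Only the head is non-equivariant.

#' Construct an untrained spherical CNN
#'
#' @param lmax even SH band limit (default 8, K = 45).
#' @param shell_channels feature channels per shell-specific convolution.
#' @param channels encoder channel plan; the decoder mirrors it.
#' @param head hidden sizes of the fully connected head. The default
#'   (240, 96) is the largest plan that keeps the sCNN parameter count
#'   (~232k) below the 4x256 MLP baseline (~246k).
#' @param attn_hidden hidden width of the attention head.
#' @param slope Leaky ReLU negative slope used throughout (0.1).
#' @param nonlin_n number of sphere points for the spatial-domain
#'   nonlinearity (>= 2K; default 724, reducible for CPU budgets).
#' @param n_shells number of shells.
#' @param seed RNG seed for the parameter initialization.
#' @return object of class `scnn_model`.
#' @export
scnn_model <- function(lmax = 8L, shell_channels = 16L,
                       channels = c(16L, 32L, 64L), head = c(240L, 96L),
                       attn_hidden = 24L, slope = 0.1, nonlin_n = 724L,
                       n_shells = 3L, seed = 1L) {
  lmax <- check_lmax(lmax)
  K <- sh_basis_size(lmax)
  sampling <- make_sampling(nonlin_n, "fibonacci", lmax)
  withr::with_seed(seed, {
    params <- list(
      shell = lapply(seq_len(n_shells), function(s)
        conv_params(1L, shell_channels, lmax)),
      attn = attention_params(n_shells, shell_channels, attn_hidden),
      fuse = conv_params(n_shells * shell_channels, channels[1L], lmax),
      enc = lapply(seq_len(length(channels) - 1L), function(i)
        conv_params(channels[i], channels[i + 1L], lmax)),
      dec = lapply(rev(seq_len(length(channels) - 1L)), function(i)
        conv_params(channels[i + 1L], channels[i], lmax)),
      head = list(
        fc1 = linear_params(channels[1L] * K, head[1L]),
        bn1 = bn_params(head[1L]),
        fc2 = linear_params(head[1L], head[2L]),
        bn2 = bn_params(head[2L]),
        fc3 = linear_params(head[2L], K)))
  })
  state <- list(bn1 = bn_state(head[1L]), bn2 = bn_state(head[2L]))
  structure(list(kind = "scnn", params = params, state = state,
                 config = list(lmax = lmax, K = K,
                               shell_channels = shell_channels,
                               channels = channels, head = head,
                               attn_hidden = attn_hidden, slope = slope,
                               nonlin_n = sampling$n, n_shells = n_shells,
                               seed = seed),
                 sampling = sampling),
            class = "scnn_model")
}

scnn_ctx <- function(model, B, fast = TRUE) {
  s <- model$sampling
  list(B = B, K = model$config$K, slope = model$config$slope,
       rows = degree_rows(degree_blocks(model$config$lmax), B),
       U = s$U, Ut = t(s$U), V = s$U_pinv, Vt = t(s$U_pinv),
       fast = fast)
}

#' Forward pass of the spherical CNN
#'
#' @param model an [scnn_model()].
#' @param x input: array [B, 3, K] of per-shell SH stacks (a
#'   `multishell_sh`), or a single 3 x K matrix.
#' @param training use batch statistics in the head's batch norm and return
#'   the cache needed for the backward pass.
#' @param fast use the single-precision compiled path for the
#'   spatial-domain nonlinearity (the double-precision R path is the
#'   reference; both are tested against each other).
#' @return B x K matrix of FOD SH coefficients (training = FALSE), or a list
#'   with `out` and `cache` (training = TRUE).
#' @export
scnn_forward <- function(model, x, training = FALSE, fast = TRUE) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L || dim(x)[2L] != model$config$n_shells ||
      dim(x)[3L] != model$config$K)
    stop("input must be [B, ", model$config$n_shells, ", ",
         model$config$K, "]")
  B <- dim(x)[1L]; K <- model$config$K
  ctx <- scnn_ctx(model, B, fast)
  p <- model$params
  cache <- list(ctx = ctx)

  Xs <- lapply(seq_len(model$config$n_shells), function(s)
    matrix(as.vector(x[, s, ]), ncol = 1L))
  Hs <- lapply(seq_along(Xs), function(s) conv_fwd(Xs[[s]], p$shell[[s]], ctx))
  att <- attention_fwd(Hs, p$attn, ctx)
  cache$Xs <- Xs; cache$Hs <- Hs; cache$att <- att

  F0 <- conv_fwd(att$Y, p$fuse, ctx)
  nl <- nonlin_fwd(F0, ctx)
  cache$F0 <- F0; cache$masks <- list(nl$mask); cache$acts <- list(nl$Y)
  cur <- nl$Y
  stages <- c(p$enc, p$dec)
  for (i in seq_along(stages)) {
    Fi <- conv_fwd(cur, stages[[i]], ctx)
    nl <- nonlin_fwd(Fi, ctx)
    cache$convs_in[[i]] <- cur
    cache$convs_out[[i]] <- Fi
    cache$masks[[i + 1L]] <- nl$mask
    cache$acts[[i + 1L]] <- nl$Y
    cur <- nl$Y
  }

  Fl <- cur; dim(Fl) <- c(B, K * model$config$channels[1L])
  h1 <- linear_fwd(Fl, p$head$fc1)
  b1 <- bnrelu_fwd(h1, p$head$bn1, model$state$bn1, training, ctx$fast)
  h2 <- linear_fwd(b1$Y, p$head$fc2)
  b2 <- bnrelu_fwd(h2, p$head$bn2, model$state$bn2, training, ctx$fast)
  out <- linear_fwd(b2$Y, p$head$fc3)

  if (!training) return(out)
  cache$Fl <- Fl; cache$bn1 <- b1$cache; cache$bn2 <- b2$cache
  cache$r1 <- b1$Y; cache$r2 <- b2$Y
  list(out = out,
       cache = cache,
       state = list(bn1 = b1$state, bn2 = b2$state),
       attention = att$a)
}

scnn_backward <- function(model, cache, dout) {
  p <- model$params
  ctx <- cache$ctx
  B <- ctx$B; K <- ctx$K

  l3 <- linear_bwd(dout, cache$r2, p$head$fc3)
  bb2 <- bnrelu_bwd(l3$dX, p$head$bn2, cache$bn2, ctx$fast)
  l2 <- linear_bwd(bb2$dX, cache$r1, p$head$fc2)
  bb1 <- bnrelu_bwd(l2$dX, p$head$bn1, cache$bn1, ctx$fast)
  l1 <- linear_bwd(bb1$dX, cache$Fl, p$head$fc1)
  dcur <- l1$dX; dim(dcur) <- c(B * K, model$config$channels[1L])

  stages <- c(p$enc, p$dec)
  g_stages <- vector("list", length(stages))
  for (i in rev(seq_along(stages))) {
    dFi <- nonlin_bwd(dcur, cache$masks[[i + 1L]], ctx)
    cb <- conv_bwd(dFi, cache$convs_in[[i]], stages[[i]], ctx)
    g_stages[[i]] <- cb$grads
    dcur <- cb$dX
  }
  dF0 <- nonlin_bwd(dcur, cache$masks[[1L]], ctx)
  cb0 <- conv_bwd(dF0, cache$att$Y, p$fuse, ctx)
  ab <- attention_bwd(cb0$dX, cache$att$a, cache$att$cache, p$attn, ctx)
  g_shell <- vector("list", length(cache$Hs))
  for (s in seq_along(cache$Hs)) {
    sb <- conv_bwd(ab$dXs[[s]], cache$Xs[[s]], p$shell[[s]], ctx)
    g_shell[[s]] <- sb$grads
  }

  ne <- length(p$enc)
  list(shell = g_shell, attn = ab$grads, fuse = cb0$grads,
       enc = g_stages[seq_len(ne)],
       dec = g_stages[ne + seq_len(length(p$dec))],
       head = list(fc1 = l1$grads, bn1 = bb1$grads,
                   fc2 = l2$grads, bn2 = bb2$grads, fc3 = l3$grads))
}

#' Construct the MLP baseline
#'
#' Four fully connected layers of 256 units, each followed by batch
#' normalization and ReLU, then a linear layer to the 45 FOD SH
#' coefficients. Input is the flattened per-shell SH stack (3 x 45 = 135).
#'
#' @param d_in input length.
#' @param hidden units per hidden layer.
#' @param n_layers number of hidden layers.
#' @param lmax even band limit of the output.
#' @param seed RNG seed for initialization.
#' @return object of class `mlp_model`.
#' @export
mlp_model <- function(d_in = 3L * 45L, hidden = 256L, n_layers = 4L,
                      lmax = 8L, seed = 1L) {
  K <- sh_basis_size(lmax)
  withr::with_seed(seed, {
    dims <- c(d_in, rep(hidden, n_layers))
    params <- list(
      fc = lapply(seq_len(n_layers), function(i)
        linear_params(dims[i], dims[i + 1L])),
      bn = lapply(seq_len(n_layers), function(i) bn_params(hidden)),
      out = linear_params(hidden, K))
  })
  structure(list(kind = "mlp", params = params,
                 state = lapply(seq_len(n_layers), function(i) bn_state(hidden)),
                 config = list(d_in = d_in, hidden = hidden,
                               n_layers = n_layers, lmax = lmax, K = K,
                               seed = seed)),
            class = "mlp_model")
}

#' Forward pass of the MLP baseline
#'
#' @param model an [mlp_model()].
#' @param x B x d_in matrix (flattened per-shell SH stacks), or a
#'   `multishell_sh` array which is flattened internally.
#' @param training as in [scnn_forward()].
#' @param fast use the single-precision compiled stack.
#' @return B x K matrix, or list(out, cache, state) when training.
#' @export
mlp_forward <- function(model, x, training = FALSE, fast = TRUE) {
  if (length(dim(x)) == 3L) {
    B <- dim(x)[1L]
    x <- matrix(x, B, prod(dim(x)[-1L]))
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$d_in)
    stop("input length ", ncol(x), " does not match d_in = ",
         model$config$d_in)
  p <- model$params
  if (fast) {
    Ws <- c(lapply(p$fc, `[[`, "W"), list(p$out$W))
    bs <- c(lapply(p$fc, `[[`, "b"), list(p$out$b))
    r <- mlp_stack_fwd_cpp(x, Ws, bs,
                           lapply(p$bn, `[[`, "gamma"),
                           lapply(p$bn, `[[`, "beta"),
                           lapply(model$state, `[[`, "mean"),
                           lapply(model$state, `[[`, "var"),
                           training, 0.1, 1e-5)
    if (!training) return(r$out)
    return(list(out = r$out,
                cache = list(fast = TRUE, cpp = r),
                state = lapply(seq_along(model$state), function(i)
                  list(mean = drop(r$means[[i]]), var = drop(r$vars[[i]])))))
  }
  cache <- list(x0 = x, fast = FALSE)
  states <- vector("list", model$config$n_layers)
  cur <- x
  for (i in seq_len(model$config$n_layers)) {
    h <- linear_fwd(cur, p$fc[[i]])
    b <- bn_fwd(h, p$bn[[i]], model$state[[i]], training)
    r <- pmax(b$Y, 0)
    cache$ins[[i]] <- cur
    cache$bn[[i]] <- b
    cache$relu[[i]] <- r
    states[[i]] <- b$state
    cur <- r
  }
  out <- linear_fwd(cur, p$out)
  if (!training) return(out)
  list(out = out, cache = cache, state = states)
}

mlp_backward <- function(model, cache, dout) {
  p <- model$params
  if (isTRUE(cache$fast)) {
    Ws <- c(lapply(p$fc, `[[`, "W"), list(p$out$W))
    g <- mlp_stack_bwd_cpp(dout, cache$cpp, Ws,
                           lapply(p$bn, `[[`, "gamma"))
    nl <- model$config$n_layers
    return(list(
      fc = lapply(seq_len(nl), function(i)
        list(W = g$dWs[[i]], b = drop(g$dbs[[i]]))),
      bn = lapply(seq_len(nl), function(i)
        list(gamma = drop(g$dgammas[[i]]), beta = drop(g$dbetas[[i]]))),
      out = list(W = g$dWs[[nl + 1L]], b = drop(g$dbs[[nl + 1L]]))))
  }
  lo <- linear_bwd(dout, cache$relu[[model$config$n_layers]], p$out)
  dcur <- lo$dX
  g_fc <- vector("list", model$config$n_layers)
  g_bn <- vector("list", model$config$n_layers)
  for (i in rev(seq_len(model$config$n_layers))) {
    dr <- dcur * (cache$bn[[i]]$Y > 0)
    bb <- bn_bwd(dr, p$bn[[i]], cache$bn[[i]]$cache)
    lb <- linear_bwd(bb$dX, cache$ins[[i]], p$fc[[i]])
    g_bn[[i]] <- bb$grads
    g_fc[[i]] <- lb$grads
    dcur <- lb$dX
  }
  list(fc = g_fc, bn = g_bn, out = lo$grads)
}

# Dispatch helpers used by the trainer.
model_forward <- function(model, x, training = FALSE) {
  switch(model$kind,
         scnn = scnn_forward(model, x, training),
         mlp = mlp_forward(model, x, training),
         stop("unknown model kind"))
}

model_backward <- function(model, cache, dout) {
  switch(model$kind,
         scnn = scnn_backward(model, cache, dout),
         mlp = mlp_backward(model, cache, dout))
}

model_update_state <- function(model, st) {
  if (model$kind == "scnn") model$state <- st else model$state <- st
  model
}

#' Number of trainable parameters of a model
#' @param model an `scnn_model` or `mlp_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  as.integer(tree_sum(length, model$params))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the full model (config,
#' parameters, batch-norm state, nonlinearity sampling). The config
#' additionally round-trips through YAML via [write_model_config()].
#'
#' @param model a model object.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @rdname save_checkpoint
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(c(list(kind = model$kind), model$config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
read_model_config <- function(path) yaml::yaml.load_file(path)

# ---- spec-level standalone operations --------------------------------------

#' Equivariant spherical convolution of a single feature map
#'
#' Standalone form of the sCNN's convolution: `x` holds C_in spherical
#' functions as rows of SH coefficients; each output channel mixes input
#' channels with one scalar weight per even degree.
#'
#' @param x C_in x K matrix of SH coefficients.
#' @param params a [conv_params()] list.
#' @param lmax even band limit (default from K).
#' @return C_out x K matrix.
#' @export
equivariant_conv <- function(x, params, lmax = 8L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  K <- sh_basis_size(lmax)
  if (ncol(x) != K) stop("x must have K = ", K, " columns")
  if (dim(params$W)[2L] != nrow(x))
    stop("params expect C_in = ", dim(params$W)[2L], ", got ", nrow(x))
  blocks <- degree_blocks(lmax)
  c_out <- dim(params$W)[1L]
  y <- matrix(0, c_out, K)
  for (d in seq_along(blocks)) {
    ks <- blocks[[d]]
    y[, ks] <- matrix(params$W[, , d], c_out) %*% x[, ks, drop = FALSE]
  }
  if (!is.null(params$b)) y[, 1L] <- y[, 1L] + params$b
  if (isTRUE(params$residual)) y <- y + x
  y
}

#' Spatial-domain SH nonlinearity of a single feature map
#'
#' ISFT to the sampling's points, Leaky ReLU, SFT back: the sCNN's
#' approximately equivariant activation.
#'
#' @param x C x K matrix of SH coefficients (or length-K vector).
#' @param sampling a [make_sampling()] object with matching lmax.
#' @param slope Leaky ReLU negative slope.
#' @return same shape as `x`.
#' @export
sh_nonlinearity <- function(x, sampling, slope = 0.1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != sampling$K) stop("x must have K = ", sampling$K, " columns")
  a <- leaky_relu(x %*% t(sampling$U), slope)
  y <- a %*% t(sampling$U_pinv)
  if (vec) drop(y) else y
}

#' Shell attention on three single-voxel feature maps
#'
#' @param x1,x2,x3 C x K matrices (one per shell).
#' @param params an [attention_params()] list.
#' @param slope Leaky ReLU negative slope.
#' @return list with `a` (length-3 simplex weights) and `y`
#'   (3C x K attention-weighted concatenation).
#' @export
shell_attention <- function(x1, x2, x3, params, slope = 0.1) {
  xs <- list(x1, x2, x3)
  C <- nrow(x1)
  if (ncol(params$W1) != 3L * C)
    stop("params expect ", ncol(params$W1) / 3L, " channels per shell")
  if (!all(vapply(xs, nrow, 1L) == C)) stop("shells must share channel count")
  z <- unlist(lapply(xs, rowMeans))
  h <- leaky_relu(drop(params$W1 %*% z) + params$b1, slope)
  logits <- drop(params$W2 %*% h) + params$b2
  a <- exp(logits - max(logits)); a <- a / sum(a)
  y <- do.call(rbind, lapply(seq_len(3L), function(s) a[s] * xs[[s]]))
  list(a = a, y = y)
}
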