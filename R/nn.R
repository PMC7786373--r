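# Minimal mutable layer framework for the residual classifiers.
#
# A layer is an environment with fields:
#   type      dispatch class
#   params    named list of numeric arrays (learnable)
#   grads     named list, same shapes, filled by ly_backward
#   buffers   named list of non-learnable state (e.g. BN running stats)
#   cache     forward-pass intermediates needed by the backward pass
# Containers hold child layers in $children (named list). Parameter and
# state names are dot-joined along the tree, e.g. "layer2.0.conv1.W".

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list(); e$grads <- list(); e$buffers <- list()
  e$cache <- NULL; e$children <- list()
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  class(e) <- c(type, "nn_layer")
  e
}

ly_forward <- function(layer, x, training = FALSE) UseMethod("ly_forward")
ly_backward <- function(layer, dy) UseMethod("ly_backward")

he_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

# ------------------------------------------------------------ convolution

nn_conv <- function(ndim, in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                    bias = FALSE) {
  ly <- new_layer(if (ndim == 2L) "conv2d" else "conv3d",
                  stride = as.integer(stride), pad = as.integer(pad))
  wd <- c(rep(kernel, ndim), in_ch, out_ch)
  ly$params$W <- he_uniform(wd, fan_in = kernel^ndim * in_ch)
  if (bias) ly$params$b <- numeric(out_ch)
  ly
}

#' @export
ly_forward.conv2d <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  conv2d_fwd_cpp(x, layer$params$W, layer$params$b, layer$stride, layer$pad)
}

#' @export
ly_backward.conv2d <- function(layer, dy) {
  if (is.null(layer$grads$W)) layer$grads$W <- layer$params$W * 0
  g <- conv2d_bwd_cpp(layer$cache, layer$params$W, dy, layer$stride,
                      layer$pad, !isTRUE(layer$is_input),
                      !is.null(layer$params$b), layer$grads$W)
  if (!is.null(layer$params$b)) layer$grads$b <- g$db
  layer$cache <- NULL
  g$dx
}

#' @export
ly_forward.conv3d <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  conv3d_fwd_cpp(x, layer$params$W, layer$params$b, layer$stride, layer$pad)
}

#' @export
ly_backward.conv3d <- function(layer, dy) {
  if (is.null(layer$grads$W)) layer$grads$W <- layer$params$W * 0
  g <- conv3d_bwd_cpp(layer$cache, layer$params$W, dy, layer$stride,
                      layer$pad, !isTRUE(layer$is_input),
                      !is.null(layer$params$b), layer$grads$W)
  if (!is.null(layer$params$b)) layer$grads$b <- g$db
  layer$cache <- NULL
  g$dx
}

# -------------------------------------------------------- batch norm

# Channel axis is the second-to-last array dimension for both the 2D
# (H,W,C,N) and 3D (H,W,L,C,N) layouts. Running statistics are buffers,
# never learnable parameters; with affine = FALSE the layer has no
# parameters at all.
nn_batchnorm <- function(channels, affine = TRUE, eps = 1e-5,
                         momentum = 0.1) {
  ly <- new_layer("batchnorm", channels = channels, affine = affine,
                  eps = eps, momentum = momentum)
  if (affine) {
    ly$params$gamma <- rep(1, channels)
    ly$params$beta <- rep(0, channels)
  }
  ly$buffers$running_mean <- rep(0, channels)
  ly$buffers$running_var <- rep(1, channels)
  ly
}

bn_channel_stat <- function(xm, C, N, f) {
  # xm: (spatial, C*N) matrix; reduce to per-channel values
  rowMeans(matrix(f(xm), C, N))
}

#' @export
ly_forward.batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- layer$channels; N <- d[length(d)]
  sp <- prod(d[-c(length(d) - 1L, length(d))])
  xm <- matrix(x, sp, C * N)
  if (training) {
    mu <- bn_channel_stat(xm, C, N, colMeans)
    ex2 <- rowMeans(matrix(.colMeans(xm * xm, sp, C * N), C, N))
    v <- pmax(ex2 - mu^2, 0)
    m <- layer$momentum
    layer$buffers$running_mean <- (1 - m) * layer$buffers$running_mean + m * mu
    layer$buffers$running_var <- (1 - m) * layer$buffers$running_var +
      m * v * (sp * N) / max(sp * N - 1, 1)
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  ivar <- 1 / sqrt(v + layer$eps)
  g <- if (layer$affine) layer$params$gamma else rep(1, C)
  b <- if (layer$affine) layer$params$beta else rep(0, C)
  a <- g * ivar
  bb <- b - mu * a
  acol <- rep(rep(a, each = sp), N)
  bcol <- rep(rep(bb, each = sp), N)
  y <- array(x * acol + bcol, d)
  if (training) layer$cache <- list(x = x, mu = mu, ivar = ivar, sp = sp,
                                    C = C, N = N)
  y
}

#' @export
ly_backward.batchnorm <- function(layer, dy) {
  cc <- layer$cache
  sp <- cc$sp; C <- cc$C; N <- cc$N
  m <- sp * N
  d <- dim(dy)
  mucol <- rep(rep(cc$mu, each = sp), N)
  xc <- cc$x - mucol
  ivcol <- rep(rep(cc$ivar, each = sp), N)
  xhat <- xc * ivcol
  csum <- function(z) rowSums(matrix(.colSums(matrix(z, sp, C * N), sp, C * N),
                                     C, N))
  if (layer$affine) {
    layer$grads$gamma <- csum(dy * xhat)
    layer$grads$beta <- csum(dy)
    gcol <- rep(rep(layer$params$gamma, each = sp), N)
    dxhat <- dy * gcol
  } else {
    dxhat <- dy
  }
  s1 <- csum(dxhat)
  s2 <- csum(dxhat * xhat)
  s1col <- rep(rep(s1, each = sp), N)
  s2col <- rep(rep(s2, each = sp), N)
  dx <- ivcol * (dxhat - s1col / m - xhat * s2col / m)
  layer$cache <- NULL
  array(dx, d)
}

# -------------------------------------------------------------- pointwise

nn_relu <- function() new_layer("relu")

#' @export
ly_forward.relu <- function(layer, x, training = FALSE) {
  y <- x * (x > 0)
  if (training) layer$cache <- x > 0
  y
}

#' @export
ly_backward.relu <- function(layer, dy) {
  dx <- dy * layer$cache
  layer$cache <- NULL
  dx
}

nn_dropout <- function(rate) new_layer("dropout", rate = rate)

#' @export
ly_forward.dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$rate <= 0) return(x)
  keep <- 1 - layer$rate
  mask <- (array(runif(length(x)), dim(x)) < keep) / keep
  layer$cache <- mask
  x * mask
}

#' @export
ly_backward.dropout <- function(layer, dy) {
  if (is.null(layer$cache)) return(dy)
  dx <- dy * layer$cache
  layer$cache <- NULL
  dx
}

# ----------------------------------------------------------------- pooling

nn_maxpool <- function(ndim, kernel = 3L, stride = 2L, pad = 1L) {
  new_layer(if (ndim == 2L) "maxpool2d" else "maxpool3d",
            kernel = kernel, stride = stride, pad = pad)
}

#' @export
ly_forward.maxpool2d <- function(layer, x, training = FALSE) {
  r <- maxpool2d_fwd_cpp(x, layer$kernel, layer$stride, layer$pad)
  if (training) layer$cache <- list(idx = r$idx, xdim = dim(x))
  r$y
}

#' @export
ly_backward.maxpool2d <- function(layer, dy) {
  dx <- maxpool_bwd_cpp(layer$cache$idx, dy, layer$cache$xdim)
  layer$cache <- NULL
  dx
}

#' @export
ly_forward.maxpool3d <- function(layer, x, training = FALSE) {
  r <- maxpool3d_fwd_cpp(x, layer$kernel, layer$stride, layer$pad)
  if (training) layer$cache <- list(idx = r$idx, xdim = dim(x))
  r$y
}

#' @export
ly_backward.maxpool3d <- function(layer, dy) {
  dx <- maxpool_bwd_cpp(layer$cache$idx, dy, layer$cache$xdim)
  layer$cache <- NULL
  dx
}

# Global average pool over all spatial axes -> (C, N) matrix.
nn_gap <- function() new_layer("gap")

#' @export
ly_forward.gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- d[length(d) - 1L]; N <- d[length(d)]
  sp <- prod(d[-c(length(d) - 1L, length(d))])
  if (training) layer$cache <- d
  matrix(.colMeans(matrix(x, sp, C * N), sp, C * N), C, N)
}

#' @export
ly_backward.gap <- function(layer, dy) {
  d <- layer$cache
  sp <- prod(d[-c(length(d) - 1L, length(d))])
  layer$cache <- NULL
  array(rep(as.numeric(dy), each = sp) / sp, d)
}

# ------------------------------------------------------------------ linear

nn_linear <- function(in_features, out_features, bias = TRUE) {
  ly <- new_layer("linear")
  ly$params$W <- he_uniform(c(out_features, in_features), fan_in = in_features)
  if (bias) ly$params$b <- numeric(out_features)
  ly
}

#' @export
ly_forward.linear <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  y <- layer$params$W %*% x
  if (!is.null(layer$params$b)) y <- y + layer$params$b
  y
}

#' @export
ly_backward.linear <- function(layer, dy) {
  layer$grads$W <- dy %*% t(layer$cache)
  if (!is.null(layer$params$b)) layer$grads$b <- rowSums(dy)
  dx <- t(layer$params$W) %*% dy
  layer$cache <- NULL
  dx
}

# -------------------------------------------------------------- containers

nn_sequential <- function(children) {
  ly <- new_layer("sequential")
  if (is.null(names(children)))
    names(children) <- sprintf("%d", seq_along(children) - 1L)
  ly$children <- children
  ly
}

#' @export
ly_forward.sequential <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- ly_forward(ch, x, training)
  x
}

#' @export
ly_backward.sequential <- function(layer, dy) {
  for (ch in rev(layer$children)) dy <- ly_backward(ch, dy)
  dy
}

# Basic residual block: conv-bn-relu-conv-bn + identity (or projection),
# then relu. y = F(x) + x.
nn_basic_block <- function(ndim, in_ch, out_ch, stride,
                           conv_bias = FALSE, down_bias = FALSE) {
  ly <- new_layer("basic_block")
  kids <- list(
    conv1 = nn_conv(ndim, in_ch, out_ch, 3L, stride, 1L, bias = conv_bias),
    bn1 = nn_batchnorm(out_ch),
    relu1 = nn_relu(),
    conv2 = nn_conv(ndim, out_ch, out_ch, 3L, 1L, 1L, bias = conv_bias),
    bn2 = nn_batchnorm(out_ch),
    relu2 = nn_relu())
  if (stride != 1L || in_ch != out_ch) {
    kids$downsample <- nn_sequential(list(
      conv = nn_conv(ndim, in_ch, out_ch, 1L, stride, 0L, bias = down_bias),
      bn = nn_batchnorm(out_ch)))
  }
  ly$children <- kids
  ly
}

#' @export
ly_forward.basic_block <- function(layer, x, training = FALSE) {
  k <- layer$children
  out <- ly_forward(k$conv1, x, training)
  out <- ly_forward(k$bn1, out, training)
  out <- ly_forward(k$relu1, out, training)
  out <- ly_forward(k$conv2, out, training)
  out <- ly_forward(k$bn2, out, training)
  identity <- if (!is.null(k$downsample)) ly_forward(k$downsample, x, training)
              else x
  ly_forward(k$relu2, out + identity, training)
}

#' @export
ly_backward.basic_block <- function(layer, dy) {
  k <- layer$children
  dsum <- ly_backward(k$relu2, dy)
  dout <- ly_backward(k$bn2, dsum)
  dout <- ly_backward(k$conv2, dout)
  dout <- ly_backward(k$relu1, dout)
  dout <- ly_backward(k$bn1, dout)
  dx <- ly_backward(k$conv1, dout)
  did <- if (!is.null(k$downsample)) ly_backward(k$downsample, dsum) else dsum
  dx + did
}

# ------------------------------------------------- parameter bookkeeping

walk_layers <- function(layer, prefix = "") {
  out <- list()
  if (length(layer$params) || length(layer$buffers))
    out[[if (nzchar(prefix)) prefix else "root"]] <- layer
  for (nm in names(layer$children)) {
    child_prefix <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    out <- c(out, walk_layers(layer$children[[nm]], child_prefix))
  }
  out
}

# Named flat list of all learnable arrays (and optionally buffers).
layer_state <- function(layer, buffers = TRUE) {
  leaves <- walk_layers(layer)
  out <- list()
  for (nm in names(leaves)) {
    for (p in names(leaves[[nm]]$params))
      out[[paste(nm, p, sep = ".")]] <- leaves[[nm]]$params[[p]]
    if (buffers)
      for (b in names(leaves[[nm]]$buffers))
        out[[paste(nm, b, sep = ".")]] <- leaves[[nm]]$buffers[[b]]
  }
  out
}

# -------------------------------------------------------------------- SGD

sgd_step <- function(param_layers, lr, momentum = 0.9) {
  for (ly in param_layers) {
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      if (is.null(ly$vel)) ly$vel <- list()
      if (is.null(ly$vel[[nm]])) ly$vel[[nm]] <- g * 0
      # updates parameters and velocity in place; the layer owns both
      sgd_update_cpp(ly$params[[nm]], ly$vel[[nm]], g, lr, momentum)
    }
  }
}

# Numerically stable softmax cross-entropy.
# logits: (K, N); target: integer class index 1..K per column.
# Returns list(loss, probs, dlogits).
softmax_ce <- function(logits, target) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  ez <- exp(z)
  probs <- sweep(ez, 2, colSums(ez), "/")
  picked <- probs[cbind(target, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(target, seq_len(N))] <-
    dlogits[cbind(target, seq_len(N))] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / N)
}
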