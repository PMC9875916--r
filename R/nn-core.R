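# Minimal reverse-mode layer library used by the GANCMLAE networks.
#
# Layers are plain lists; a network is a list of layers. Spatial activations
# are kept channels-first as [C, H, W, N] arrays so that convolution outputs
# and per-channel batch-norm statistics are plain dim() views (no array
# transposition in the hot path); flattened activations are n x features
# matrices. Convolutions are evaluated as one BLAS matrix product over
# im2col patches (C++ kernels in src/).

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    init_sd = sqrt(2 / (k * k * cin))) {
  list(type = "conv",
       W = matrix(stats::rnorm(cout * k * k * cin, sd = init_sd), cout, k * k * cin),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout))
}

# Stride-2 transposed convolution (fractionally-strided convolution),
# realized as the adjoint of a stride-2 "same" convolution: the forward pass
# scatter-adds weighted input patches onto the doubled grid (col2im), the
# backward pass gathers them (im2col). W has shape (cin, k*k*cout).
nn_tconv <- function(cin, cout, k = 3L, init_sd = sqrt(2 / (k * k * cin))) {
  list(type = "tconv",
       W = matrix(stats::rnorm(cin * k * k * cout, sd = init_sd), cin, k * k * cout),
       b = numeric(cout),
       k = as.integer(k), pad = (as.integer(k) - 1L) %/% 2L,
       cin = as.integer(cin), cout = as.integer(cout))
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), momentum = momentum, eps = eps,
       c = as.integer(c))
}

nn_relu  <- function() list(type = "relu")
nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_tanh  <- function() list(type = "tanh")
nn_sigmoid <- function() list(type = "sigmoid")
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(h, w, c) list(type = "reshape", h = as.integer(h),
                                     w = as.integer(w), c = as.integer(c))
nn_upsample <- function() list(type = "upsample") # nearest neighbour, factor 2

nn_dense <- function(din, dout, init_sd = sqrt(2 / din)) {
  list(type = "dense",
       W = matrix(stats::rnorm(dout * din, sd = init_sd), dout, din),
       b = numeric(dout), din = as.integer(din), dout = as.integer(dout))
}

nn_resblock <- function(main, shortcut) {
  list(type = "resblock", main = main, shortcut = shortcut)
}

.tconv_forward <- function(layer, x) {
  d <- dim(x)
  u <- x
  dim(u) <- c(d[1], d[2] * d[3] * d[4])
  cols <- crossprod(layer$W, u)
  y <- col2im_cpp(cols, layer$cout, 2L * d[2], 2L * d[3], d[4],
                  layer$k, 2L, layer$pad)
  y <- y + layer$b
  list(out = y, cache = list(u = u, din = d))
}

.tconv_backward <- function(layer, cache, dout) {
  d <- cache$din
  dyd <- dim(dout)
  dcols <- im2col_cpp(dout, layer$cout, dyd[2], dyd[3], dyd[4],
                      layer$k, 2L, layer$pad)
  du <- layer$W %*% dcols
  dim(du) <- d
  dy <- dout
  dim(dy) <- c(layer$cout, length(dy) %/% layer$cout)
  list(dx = du, grads = list(W = tcrossprod(cache$u, dcols), b = rowSums(dy)))
}

.conv_forward <- function(layer, x) {
  d <- dim(x)
  if (layer$k == 1L && layer$pad == 0L) {
    xs <- if (layer$stride > 1L)
      x[, seq(1L, d[2], by = layer$stride), seq(1L, d[3], by = layer$stride), ,
        drop = FALSE] else x
    ds <- dim(xs)
    cols <- xs
    dim(cols) <- c(d[1], ds[2] * ds[3] * d[4])
    ho <- ds[2]; wo <- ds[3]
  } else {
    cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                       layer$pad)
    ho <- (d[2] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
    wo <- (d[3] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  }
  y <- layer$W %*% cols + layer$b
  dim(y) <- c(layer$cout, ho, wo, d[4])
  list(out = y, cache = list(cols = cols, din = d))
}

.conv_backward <- function(layer, cache, dout) {
  d <- cache$din
  dy <- dout
  dim(dy) <- c(layer$cout, length(dy) %/% layer$cout)
  dW <- tcrossprod(dy, cache$cols)
  db <- rowSums(dy)
  dcols <- crossprod(layer$W, dy)
  if (layer$k == 1L && layer$pad == 0L) {
    if (layer$stride > 1L) {
      dx <- array(0, d)
      dim(dcols) <- c(d[1], (d[2] - 1L) %/% layer$stride + 1L,
                      (d[3] - 1L) %/% layer$stride + 1L, d[4])
      dx[, seq(1L, d[2], by = layer$stride),
         seq(1L, d[3], by = layer$stride), ] <- dcols
    } else {
      dx <- dcols
      dim(dx) <- d
    }
  } else {
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                     layer$pad)
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = .conv_forward(layer, x),
    tconv = .tconv_forward(layer, x),
    bn = {
      d <- dim(x)
      m <- x
      dim(m) <- c(d[1], length(m) %/% d[1])
      if (training) {
        mu <- rowMeans(m)
        v <- rowMeans(m * m) - mu^2
        layer$rm <- layer$momentum * layer$rm + (1 - layer$momentum) * mu
        layer$rv <- layer$momentum * layer$rv + (1 - layer$momentum) * v
      } else {
        mu <- layer$rm
        v <- layer$rv
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- (m - mu) * inv              # per-row (channel) recycling
      out <- xhat * layer$gamma + layer$beta
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, inv = inv, d = d),
           layer = layer)
    },
    relu = list(out = x * (x > 0), cache = list(mask = x > 0)),
    lrelu = {
      s <- 1 + (layer$slope - 1) * (x <= 0)
      list(out = x * s, cache = list(s = s))
    },
    tanh = {
      y <- tanh(x)
      list(out = y, cache = list(y = y))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = list(y = y))
    },
    flatten = {
      d <- dim(x)
      m <- x
      dim(m) <- c(d[1] * d[2] * d[3], d[4])
      list(out = t(m), cache = list(d = d))
    },
    reshape = {
      m <- t(x)
      dim(m) <- c(layer$c, layer$h, layer$w, nrow(x))
      list(out = m, cache = list(n = nrow(x)))
    },
    upsample = {
      d <- dim(x)
      list(out = x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2),
                   , drop = FALSE],
           cache = list(d = d))
    },
    dense = {
      list(out = tcrossprod(x, layer$W) + rep(layer$b, each = nrow(x)),
           cache = list(x = x))
    },
    resblock = {
      fm <- net_forward(layer$main, x, training)
      fs <- net_forward(layer$shortcut, x, training)
      layer$main <- fm$net
      layer$shortcut <- fs$net
      list(out = fm$out + fs$out,
           cache = list(main = fm$caches, shortcut = fs$caches), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = .conv_backward(layer, cache, dout),
    tconv = .tconv_backward(layer, cache, dout),
    bn = {
      d <- cache$d
      dy <- dout
      dim(dy) <- c(d[1], length(dy) %/% d[1])
      dgamma <- rowSums(dy * cache$xhat)
      dbeta <- rowSums(dy)
      n <- ncol(dy)
      # batch statistics participate in the forward pass, so their gradient
      # terms (the two mean corrections) are included
      dm <- (dy - dbeta / n - cache$xhat * (dgamma / n)) *
        (layer$gamma * cache$inv)
      dim(dm) <- d
      list(dx = dm, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    lrelu = list(dx = dout * cache$s, grads = NULL),
    tanh = list(dx = dout * (1 - cache$y^2), grads = NULL),
    sigmoid = list(dx = dout * cache$y * (1 - cache$y), grads = NULL),
    flatten = {
      m <- t(dout)
      dim(m) <- cache$d
      list(dx = m, grads = NULL)
    },
    reshape = {
      m <- dout
      dim(m) <- c(layer$c * layer$h * layer$w, cache$n)
      list(dx = t(m), grads = NULL)
    },
    upsample = {
      d <- cache$d
      dx <- dout[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
            dout[, seq(2, 2 * d[2], 2), , , drop = FALSE]
      dx <- dx[, , seq(1, 2 * d[3], 2), , drop = FALSE] +
            dx[, , seq(2, 2 * d[3], 2), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = dout %*% layer$W,
           grads = list(W = crossprod(dout, cache$x), b = colSums(dout)))
    },
    resblock = {
      bm <- net_backward(layer$main, cache$main, dout)
      bs <- net_backward(layer$shortcut, cache$shortcut, dout)
      list(dx = bm$dx + bs$dx, grads = list(main = bm$grads, shortcut = bs$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Forward through a layer list. Returns the output, per-layer caches and the
# (possibly updated, for batch-norm running statistics) network.
net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) net[[i]] <- r$layer
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dout, grads = grads)
}

# Set the batch-norm momentum of every bn layer (recursively through
# residual blocks). With momentum 0 a single training-mode pass overwrites
# the running statistics with the statistics of that pass.
net_set_bn_momentum <- function(net, momentum) {
  for (i in seq_along(net)) {
    if (net[[i]]$type == "bn") net[[i]]$momentum <- momentum
    else if (net[[i]]$type == "resblock") {
      net[[i]]$main <- net_set_bn_momentum(net[[i]]$main, momentum)
      net[[i]]$shortcut <- net_set_bn_momentum(net[[i]]$shortcut, momentum)
    }
  }
  net
}

# --- parameter bookkeeping (flat named access for Adam and weight tying) ---

.param_names <- c("W", "b", "gamma", "beta")

net_params <- function(net, prefix = "") {
  out <- list()
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$type == "resblock") {
      out <- c(out, net_params(l$main, paste0(prefix, i, ".main.")),
               net_params(l$shortcut, paste0(prefix, i, ".shortcut.")))
    } else {
      for (p in .param_names)
        if (!is.null(l[[p]])) out[[paste0(prefix, i, ".", p)]] <- l[[p]]
    }
  }
  out
}

net_set_params <- function(net, params, prefix = "") {
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$type == "resblock") {
      net[[i]]$main <- net_set_params(l$main, params, paste0(prefix, i, ".main."))
      net[[i]]$shortcut <- net_set_params(l$shortcut, params,
                                          paste0(prefix, i, ".shortcut."))
    } else {
      for (p in .param_names) {
        nm <- paste0(prefix, i, ".", p)
        if (!is.null(params[[nm]])) net[[i]][[p]] <- params[[nm]]
      }
    }
  }
  net
}

grads_flatten <- function(net, grads, prefix = "") {
  out <- list()
  for (i in seq_along(net)) {
    l <- net[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "resblock") {
      out <- c(out, grads_flatten(l$main, g$main, paste0(prefix, i, ".main.")),
               grads_flatten(l$shortcut, g$shortcut, paste0(prefix, i, ".shortcut.")))
    } else {
      for (p in names(g)) out[[paste0(prefix, i, ".", p)]] <- g[[p]]
    }
  }
  out
}

# --- Adam ---

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
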