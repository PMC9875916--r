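# Independent oracles used to validate the package implementations.
# Deliberately written as direct, loop-based transcriptions of the
# definitions, sharing no code with the package internals.

# per-window SSIM by explicit loops (population moments, valid windows)
oracle_ssim_windowed <- function(x, y, w = 7L, data_range = 1) {
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in seq_len(nrow(x) - w + 1L)) {
    for (j in seq_len(ncol(x) - w + 1L)) {
      a <- x[i:(i + w - 1L), j:(j + w - 1L)]
      b <- y[i:(i + w - 1L), j:(j + w - 1L)]
      ma <- mean(a); mb <- mean(b)
      va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
      cab <- mean((a - ma) * (b - mb))
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                  ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# connected components by breadth-first flood fill
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) == 2L) { d <- c(d, 1L); dim(mask) <- d }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- if (connectivity %in% c(6L, 4L))
    offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else
    offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # 2D masks are reshaped to depth 1; out-of-bounds dk offsets fall away
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      p <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1L) || any(q > d)) next
        qi <- (q[3] - 1L) * d[1] * d[2] + (q[2] - 1L) * d[1] + q[1]
        if (mask[qi] && labels[qi] == 0L) {
          labels[qi] <- lab
          queue <- c(queue, qi)
        }
      }
    }
  }
  list(labels = labels, sizes = if (lab > 0) tabulate(labels[labels > 0]) else integer(0))
}

# AUC by all-pairs counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# gradient norm of the critic at given points by central finite differences
oracle_critic_gradnorm <- function(model, Z, h = 1e-5) {
  sapply(seq_len(nrow(Z)), function(i) {
    g <- sapply(seq_len(ncol(Z)), function(j) {
      zp <- Z; zp[i, j] <- zp[i, j] + h
      zm <- Z; zm[i, j] <- zm[i, j] - h
      (discriminate(model, zp)[i] - discriminate(model, zm)[i]) / (2 * h)
    })
    sqrt(sum(g^2))
  })
}

# small architecture used across unit tests
tiny_arch <- function(...) {
  architecture_spec(input_size = 16, base_filters = 2, n_down_blocks = 2,
                    latent_dim = 4, discriminator_widths = c(8, 5, 1), ...)
}

tiny_slices <- function(n = 8, size = 16, seed = 42) {
  set.seed(seed)
  array(runif(size * size * n, -0.5, 0.5), c(size, size, n))
}

# all model parameters as one flat list (for identity comparisons)
net_params_public <- function(m) {
  c(gancmlae:::net_params(m$encoder), gancmlae:::net_params(m$decoder),
    gancmlae:::net_params(m$critic))
}

# a critic computing exactly D(z) = sum(w * z) + b (single dense layer)
linear_critic_model <- function(w, b = 0) {
  sp <- architecture_spec(input_size = 16, base_filters = 2, n_down_blocks = 2,
                          latent_dim = length(w), discriminator_widths = 1L)
  m <- build_model(sp, seed = 1)
  m$critic[[1]]$W <- matrix(w, nrow = 1)
  m$critic[[1]]$b <- b
  m
}
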