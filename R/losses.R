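#' Loss weights for the combined objective
#'
#' The balanced objective is `L1 + mu * L2 + gamma * L3`: adversarial latent
#' regularization, pixel (least-absolute-error) reconstruction, and latent
#' consistency. `lambda_gp` weights the critic's one-sided gradient penalty
#' (default 10).
#'
#' The default `gamma` is small because L3 is a squared Euclidean norm over
#' the whole latent vector: at initialization it sits two to three orders of
#' magnitude above the pixel loss, and an unscaled consistency term drives
#' the optimization into the degenerate constant-decoder solution (z and z'
#' trivially agree when the decoder ignores its input). `gamma = 1e-3` makes
#' the term commensurate with the pixel loss at the start and leaves it
#' active as a mild regularizer near convergence.
#'
#' @param mu Weight of the pixel loss L2 (>= 0).
#' @param gamma Weight of the latent-consistency loss L3 (>= 0).
#' @param lambda_gp Gradient-penalty weight (>= 0).
#' @param penalty `"one_sided"` for `max(0, |grad| - 1)` (the default) or
#'   `"squared"` for the common `(|grad| - 1)^2` variant.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(mu = 1, gamma = 0.001, lambda_gp = 10,
                         penalty = c("one_sided", "squared")) {
  penalty <- match.arg(penalty)
  stopifnot(is.finite(mu), mu >= 0, is.finite(gamma), gamma >= 0,
            is.finite(lambda_gp), lambda_gp >= 0)
  structure(list(mu = mu, gamma = gamma, lambda_gp = lambda_gp,
                 penalty = penalty), class = "loss_weights")
}

# --- internal critic algebra -------------------------------------------------
# The critic is a stack of dense layers with LeakyReLU between them (and an
# optional final sigmoid). These helpers expose the forward pass, the gradient
# of the score with respect to the input, and the analytic gradient of the
# one-sided penalty with respect to the critic parameters (second-order in the
# critic, with the LeakyReLU slope masks held fixed, which is exact almost
# everywhere).

.critic_parts <- function(critic) {
  dense <- critic[vapply(critic, function(l) l$type == "dense", logical(1))]
  slope <- 0.2
  for (l in critic) if (l$type == "lrelu") slope <- l$slope
  sigmoid <- any(vapply(critic, function(l) l$type == "sigmoid", logical(1)))
  list(dense = dense, slope = slope, sigmoid = sigmoid)
}

.critic_fwd <- function(parts, Z) {
  m <- length(parts$dense)
  H <- vector("list", m + 1L); H[[1L]] <- Z
  S <- vector("list", m)
  A <- Z
  for (i in seq_len(m)) {
    l <- parts$dense[[i]]
    A <- H[[i]] %*% t(l$W) + rep(l$b, each = nrow(Z))
    if (i < m) {
      S[[i]] <- ifelse(A > 0, 1, parts$slope)
      H[[i + 1L]] <- A * S[[i]]
    } else H[[i + 1L]] <- A
  }
  y <- drop(A)
  if (parts$sigmoid) y <- 1 / (1 + exp(-y))
  list(y = y, H = H, S = S, pre = drop(A))
}

# Gradient of the critic score w.r.t. each input row, plus the per-layer
# pre-activation sensitivities R_i = dy/dA_i needed by the penalty gradient.
.critic_input_grad <- function(parts, fwd) {
  m <- length(parts$dense)
  n <- length(fwd$y)
  R <- vector("list", m)
  dA <- matrix(1, n, 1L)
  if (parts$sigmoid) dA <- dA * (fwd$y * (1 - fwd$y))
  for (i in rev(seq_len(m))) {
    R[[i]] <- dA
    dH <- dA %*% parts$dense[[i]]$W
    if (i > 1L) dA <- dH * fwd$S[[i - 1L]]
  }
  list(g = dH, R = R)
}

.penalty_value <- function(gnorm, type) {
  if (type == "one_sided") pmax(0, gnorm - 1) else (gnorm - 1)^2
}

# d penalty / d gnorm
.penalty_slope <- function(gnorm, type) {
  if (type == "one_sided") as.numeric(gnorm > 1) else 2 * (gnorm - 1)
}

# Gradient penalty and its gradient w.r.t. critic weights at interpolates Zh.
.critic_penalty_grads <- function(parts, Zh, lambda, type) {
  fwd <- .critic_fwd(parts, Zh)
  ig <- .critic_input_grad(parts, fwd)
  g <- ig$g
  gnorm <- sqrt(rowSums(g * g))
  pen <- lambda * mean(.penalty_value(gnorm, type))
  n <- nrow(Zh)
  coef <- lambda / n * .penalty_slope(gnorm, type) / pmax(gnorm, 1e-12)
  Q <- g * coef
  m <- length(parts$dense)
  grads <- vector("list", m)
  Cj <- Q
  for (j in seq_len(m)) {
    if (j > 1L)
      Cj <- tcrossprod(Cj, parts$dense[[j - 1L]]$W) * fwd$S[[j - 1L]]
    grads[[j]] <- list(W = crossprod(ig$R[[j]], Cj),
                       b = numeric(length(parts$dense[[j]]$b)))
  }
  list(penalty = pen, grads = grads)
}

# First-order backprop of sum(w_out * y) through the critic.
.critic_score_grads <- function(parts, fwd, w_out) {
  m <- length(parts$dense)
  dA <- matrix(w_out, ncol = 1L)
  if (parts$sigmoid) dA <- dA * (fwd$y * (1 - fwd$y))
  grads <- vector("list", m)
  for (i in rev(seq_len(m))) {
    grads[[i]] <- list(W = crossprod(dA, fwd$H[[i]]), db = colSums(dA))
    grads[[i]]$b <- grads[[i]]$db; grads[[i]]$db <- NULL
    if (i > 1L) dA <- (dA %*% parts$dense[[i]]$W) * fwd$S[[i - 1L]]
  }
  list(grads = grads, dZ = dA %*% parts$dense[[1L]]$W)
}

.sum_grad_lists <- function(a, b) {
  for (i in seq_along(b)) for (p in names(b[[i]]))
    a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  a
}

#' Wasserstein critic loss with one-sided gradient penalty
#'
#' `mean D(z_q) - mean D(z_p) + lambda * mean(max(0, |grad_z D| - 1))`, the
#' gradient norm evaluated at uniform random convex combinations of paired
#' `z_q`, `z_p` rows (the intermediate distribution). The interpolation draws
#' use the current RNG stream; seed it for reproducibility, or pass `eps`.
#'
#' @param model A `gancmlae_model`.
#' @param z_q Encoder codes, `n x latent_dim`.
#' @param z_p Prior samples (standard normal), `n x latent_dim`.
#' @param weights A [loss_weights()].
#' @param eps Optional length-`n` vector of interpolation coefficients in
#'   \[0, 1\] (drawn uniformly when `NULL`).
#' @return A list with `loss` and `gradient_penalty` (both scalars).
#' @export
critic_loss <- function(model, z_q, z_p, weights = loss_weights(), eps = NULL) {
  stopifnot(inherits(model, "gancmlae_model"))
  if (!is.matrix(z_q)) z_q <- as.matrix(z_q)
  if (!is.matrix(z_p)) z_p <- as.matrix(z_p)
  if (!identical(dim(z_q), dim(z_p)))
    stop("z_q and z_p must have matching dimensions")
  parts <- .critic_parts(model$critic)
  dq <- .critic_fwd(parts, z_q)$y
  dp <- .critic_fwd(parts, z_p)$y
  if (is.null(eps)) eps <- stats::runif(nrow(z_q))
  zh <- z_q * eps + z_p * (1 - eps)
  fwd <- .critic_fwd(parts, zh)
  g <- .critic_input_grad(parts, fwd)$g
  gnorm <- sqrt(rowSums(g * g))
  pen <- weights$lambda_gp * mean(.penalty_value(gnorm, weights$penalty))
  list(loss = mean(dq) - mean(dp) + pen, gradient_penalty = pen)
}

#' Encoder-side adversarial loss
#'
#' `-mean D(z_q)`: the encoder ascends the critic's score of its codes so the
#' aggregated posterior approaches the standard-normal prior.
#'
#' @inheritParams critic_loss
#' @return A scalar.
#' @export
encoder_adversarial_loss <- function(model, z_q) {
  stopifnot(inherits(model, "gancmlae_model"))
  if (!is.matrix(z_q)) z_q <- as.matrix(z_q)
  if (nrow(z_q) == 0L) stop("empty batch")
  parts <- .critic_parts(model$critic)
  -mean(.critic_fwd(parts, z_q)$y)
}

#' Pixel reconstruction loss (least absolute error)
#'
#' Mean absolute elementwise difference between a batch and its
#' reconstruction.
#'
#' @param x,x_prime Arrays of matching shape.
#' @return A scalar.
#' @export
reconstruction_loss <- function(x, x_prime) {
  if (!identical(dim(x), dim(x_prime)) || length(x) != length(x_prime))
    stop("x and x_prime must have matching shapes")
  mean(abs(x - x_prime))
}

#' Latent-consistency loss
#'
#' Mean over the batch of the squared Euclidean norm of `z - z'`, tying the
#' code of a reconstruction to the code of its source image.
#'
#' @param z,z_prime `n x latent_dim` matrices.
#' @return A scalar.
#' @export
latent_consistency_loss <- function(z, z_prime) {
  if (!is.matrix(z)) z <- as.matrix(z)
  if (!is.matrix(z_prime)) z_prime <- as.matrix(z_prime)
  if (!identical(dim(z), dim(z_prime)))
    stop("z and z_prime must have matching shapes")
  mean(rowSums((z - z_prime)^2))
}

#' Combined generator objective
#'
#' `l1_enc + mu * l2 + gamma * l3`.
#'
#' @param l1_enc Encoder adversarial loss.
#' @param l2 Pixel reconstruction loss.
#' @param l3 Latent-consistency loss.
#' @param weights A [loss_weights()].
#' @return A scalar.
#' @export
total_generator_loss <- function(l1_enc, l2, l3, weights = loss_weights()) {
  vals <- c(l1_enc, l2, l3)
  if (!all(is.finite(vals))) stop("non-finite loss component")
  l1_enc + weights$mu * l2 + weights$gamma * l3
}
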