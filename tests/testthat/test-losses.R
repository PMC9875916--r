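test_that("constant and linear critics give the predicted critic loss", {
  # constant critic: both expectations equal, zero gradient, one-sided hinge 0
  mc <- linear_critic_model(rep(0, 4), b = 3)
  zq <- matrix(rnorm(6 * 4), 6, 4)
  zp <- matrix(rnorm(6 * 4), 6, 4)
  r <- critic_loss(mc, zq, zp, loss_weights(), eps = runif(6))
  expect_equal(r$loss, 0)
  expect_equal(r$gradient_penalty, 0)
  # linear critic D(z) = 2 z1: |grad| = 2 everywhere, penalty = 10 * (2 - 1)
  ml <- linear_critic_model(c(2, 0, 0, 0))
  r2 <- critic_loss(ml, zq, zp, loss_weights(lambda_gp = 10), eps = runif(6))
  expect_equal(r2$gradient_penalty, 10)
  expect_equal(r2$loss, 2 * mean(zq[, 1]) - 2 * mean(zp[, 1]) + 10)
})

test_that("expectation terms are antisymmetric under swapping z_q and z_p", {
  m <- build_model(tiny_arch(), seed = 7)
  zq <- matrix(rnorm(8 * 4), 8, 4)
  zp <- matrix(rnorm(8 * 4), 8, 4)
  eps <- runif(8)
  a <- critic_loss(m, zq, zp, eps = eps)
  b <- critic_loss(m, zp, zq, eps = 1 - eps)   # same interpolates
  expect_equal(a$loss - a$gradient_penalty, -(b$loss - b$gradient_penalty))
  expect_equal(a$gradient_penalty, b$gradient_penalty)
})

test_that("gradient norms at interpolates match finite differences", {
  set.seed(8)
  for (rep in 1:3) {
    m <- build_model(tiny_arch(), seed = rep)
    zh <- matrix(rnorm(5 * 4), 5, 4)
    parts <- gancmlae:::.critic_parts(m$critic)
    fwd <- gancmlae:::.critic_fwd(parts, zh)
    g <- gancmlae:::.critic_input_grad(parts, fwd)$g
    expect_equal(sqrt(rowSums(g^2)), oracle_critic_gradnorm(m, zh),
                 tolerance = 1e-4)
  }
})

test_that("gradient penalty is non-negative and zero inside the Lipschitz ball", {
  set.seed(9)
  for (rep in 1:5) {
    m <- build_model(tiny_arch(), seed = 20 + rep)
    # shrink the critic weights until it is everywhere below 1-Lipschitz
    for (i in seq_along(m$critic))
      if (!is.null(m$critic[[i]]$W)) m$critic[[i]]$W <- 0.05 * m$critic[[i]]$W
    zq <- matrix(rnorm(6 * 4), 6, 4)
    zp <- matrix(rnorm(6 * 4), 6, 4)
    r <- critic_loss(m, zq, zp, eps = runif(6))
    expect_equal(r$gradient_penalty, 0)
    m2 <- build_model(tiny_arch(), seed = 40 + rep)
    r2 <- critic_loss(m2, zq, zp, eps = runif(6))
    expect_gte(r2$gradient_penalty, 0)
  }
})

test_that("encoder adversarial loss is the negated mean critic score", {
  m <- linear_critic_model(c(1, 0, 0, 0))
  zq <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(encoder_adversarial_loss(m, zq), -mean(zq[, 1]))
  expect_error(encoder_adversarial_loss(m, zq[0, , drop = FALSE]), "empty")
  mc <- linear_critic_model(rep(0, 4), b = 2)
  expect_equal(encoder_adversarial_loss(mc, zq), -2)
})

test_that("pixel loss is the mean absolute difference", {
  x <- array(1, c(3, 3, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, x * 0), 1)
  set.seed(10)
  a <- array(rnorm(60), c(5, 4, 3))
  b <- array(rnorm(60), c(5, 4, 3))
  expect_equal(reconstruction_loss(a, b), mean(abs(a - b)), tolerance = 1e-12)
  expect_error(reconstruction_loss(a, array(0, c(4, 5, 3))), "shape")
})

test_that("latent consistency is the mean squared code displacement", {
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(latent_consistency_loss(z, z), 0)
  e <- matrix(0, 1, 4); e[1] <- 1
  expect_equal(latent_consistency_loss(matrix(0, 1, 4), e), 1)
  zp <- matrix(rnorm(12), 3, 4)
  brute <- mean(apply((z - zp)^2, 1, sum))
  expect_equal(latent_consistency_loss(z, zp), brute, tolerance = 1e-12)
  expect_error(latent_consistency_loss(z, matrix(0, 2, 4)), "shape")
})

test_that("the combined objective composes the three terms linearly", {
  expect_equal(total_generator_loss(0.2, 0.3, 0.5,
                                    loss_weights(mu = 1, gamma = 1)), 1.0)
  expect_equal(total_generator_loss(0.7, 9, 9, loss_weights(mu = 0, gamma = 0)),
               0.7)
  expect_equal(total_generator_loss(0, 0, 0, loss_weights()), 0)
  expect_equal(total_generator_loss(1, 2, 3, loss_weights(mu = 0.5, gamma = 2)),
               1 + 0.5 * 2 + 2 * 3)
  expect_error(total_generator_loss(Inf, 0, 0, loss_weights()), "finite")
})

test_that("penalty gradients w.r.t. critic parameters match finite differences", {
  set.seed(11)
  m <- build_model(tiny_arch(), seed = 12)
  parts <- gancmlae:::.critic_parts(m$critic)
  zh <- matrix(rnorm(4 * 4), 4, 4)
  pen <- gancmlae:::.critic_penalty_grads(parts, zh, 10, "one_sided")
  pen_at <- function(model) {
    p <- gancmlae:::.critic_parts(model$critic)
    fw <- gancmlae:::.critic_fwd(p, zh)
    g <- gancmlae:::.critic_input_grad(p, fw)$g
    10 * mean(pmax(0, sqrt(rowSums(g^2)) - 1))
  }
  h <- 1e-6
  dense_idx <- which(vapply(m$critic, function(l) l$type == "dense", logical(1)))
  for (j in seq_along(dense_idx)) {
    l <- dense_idx[j]
    for (ii in sample(length(m$critic[[l]]$W), 4)) {
      m2 <- m
      m2$critic[[l]]$W[ii] <- m2$critic[[l]]$W[ii] + h
      up <- pen_at(m2)
      m2$critic[[l]]$W[ii] <- m2$critic[[l]]$W[ii] - 2 * h
      dn <- pen_at(m2)
      expect_equal(pen$grads[[j]]$W[ii], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})
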