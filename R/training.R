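#' Training configuration
#'
#' Defaults follow the reference regimen: Adam for both networks at learning
#' rate 2e-4 (the two time-scale update rule is realized as independently
#' tunable rates plus the critic:generator update ratio), batch size 32, and
#' the critic updated twice per generator step. `max_batches` counts
#' generator steps; the full-scale regimen uses 70,000, the desk-scale
#' default here is 2,000.
#'
#' @param batch_size Minibatch size.
#' @param lr_generator,lr_critic Adam learning rates.
#' @param critic_steps_per_generator_step Critic updates per generator step.
#' @param max_batches Number of generator steps.
#' @param adam_beta1,adam_beta2 Adam moment decay rates (adversarial-training
#'   practice: 0.5 and 0.9).
#' @param seed Run seed: batch order, prior draws, interpolation coefficients.
#' @param loss_variant One of `"full"`, `"L1+L2"`, `"L1+L3"`, `"L2+L3"`,
#'   `"AE-only"` (ablations; `"AE-only"` is the plain autoencoder, no critic).
#' @param weights A [loss_weights()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, lr_generator = 2e-4,
                         lr_critic = 2e-4,
                         critic_steps_per_generator_step = 2L,
                         max_batches = 2000L, adam_beta1 = 0.5,
                         adam_beta2 = 0.9, seed = 1L,
                         loss_variant = c("full", "L1+L2", "L1+L3", "L2+L3",
                                          "AE-only"),
                         weights = loss_weights()) {
  loss_variant <- match.arg(loss_variant)
  stopifnot(batch_size >= 1, lr_generator > 0, lr_critic > 0,
            critic_steps_per_generator_step >= 1, max_batches >= 1,
            inherits(weights, "loss_weights"))
  structure(list(batch_size = as.integer(batch_size),
                 lr_generator = lr_generator, lr_critic = lr_critic,
                 critic_steps_per_generator_step =
                   as.integer(critic_steps_per_generator_step),
                 max_batches = as.integer(max_batches),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 seed = as.integer(seed), loss_variant = loss_variant,
                 weights = weights), class = "train_config")
}

.variant_flags <- function(variant) {
  switch(variant,
         "full" = c(l1 = TRUE, l2 = TRUE, l3 = TRUE),
         "L1+L2" = c(l1 = TRUE, l2 = TRUE, l3 = FALSE),
         "L1+L3" = c(l1 = TRUE, l2 = FALSE, l3 = TRUE),
         "L2+L3" = c(l1 = FALSE, l2 = TRUE, l3 = TRUE),
         "AE-only" = c(l1 = FALSE, l2 = TRUE, l3 = FALSE))
}

#' Pool preprocessed axial slices from a set of subjects
#'
#' Preprocesses each subject's volume ([preprocess_volume()]) and pools all
#' slices into one `H x W x N` array. Subjects flagged anomalous are
#' propagated through the `anomalous` attribute so that [train()] can refuse
#' them.
#'
#' @param subjects A `phantom_population`, a list of subjects with `volume`
#'   elements, or a list of 3D arrays.
#' @param size Model input side length.
#' @param min_foreground Drop slices whose foreground fraction (see
#'   [slice_foreground_fraction()]) is below this value (default 0: keep all).
#' @return An `H x W x N` array with attribute `anomalous` (logical flag per
#'   pooled slice).
#' @export
pool_slices <- function(subjects, size = 64L, min_foreground = 0) {
  slices <- list()
  anom <- logical(0)
  for (s in subjects) {
    vol <- if (is.list(s)) s$volume else s
    flag <- if (is.list(s) && !is.null(s$is_anomalous)) s$is_anomalous else FALSE
    st <- preprocess_volume(vol, size = size)
    keep <- vapply(st$slices, function(sl)
      slice_foreground_fraction(sl) >= min_foreground, logical(1))
    slices <- c(slices, st$slices[keep])
    anom <- c(anom, rep(flag, sum(keep)))
  }
  x <- simplify2array(slices)
  attr(x, "anomalous") <- anom
  x
}

# internal: prefix the names of a flat parameter/gradient list
.prefix <- function(lst, p) {
  names(lst) <- paste0(p, names(lst))
  lst
}

.add_flat <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

# One generator forward/backward pass. Returns loss components, flat encoder
# and decoder gradients, and the updated (batch-norm stats) networks.
.generator_pass <- function(model, xb, weights, flags) {
  n <- dim(xb)[4]
  f1 <- net_forward(model$encoder, xb, training = TRUE)
  z <- f1$out
  f2 <- net_forward(model$decoder, z, training = TRUE)
  xp <- f2$out
  l3 <- 0; zp <- NULL; f3 <- NULL
  if (flags[["l3"]]) {
    f3 <- net_forward(f1$net, xp, training = TRUE)
    zp <- f3$out
    l3 <- mean(rowSums((z - zp)^2))
  }
  l2 <- if (flags[["l2"]]) mean(abs(xb - xp)) else 0
  parts <- .critic_parts(model$critic)
  l1_enc <- if (flags[["l1"]]) -mean(.critic_fwd(parts, z)$y) else 0

  enc_grads <- list()
  dxp <- array(0, dim(xp))
  dz <- matrix(0, n, ncol(z))
  enc_net <- if (flags[["l3"]]) f3$net else f1$net
  if (flags[["l3"]]) {
    dzp <- weights$gamma * 2 * (zp - z) / n
    b3 <- net_backward(enc_net, f3$caches, dzp)
    enc_grads <- .add_flat(enc_grads, grads_flatten(enc_net, b3$grads))
    dxp <- dxp + b3$dx
    dz <- dz + weights$gamma * 2 * (z - zp) / n
  }
  if (flags[["l2"]])
    dxp <- dxp + weights$mu * sign(xp - xb) / length(xb)
  b2 <- net_backward(f2$net, f2$caches, dxp)
  dec_grads <- grads_flatten(f2$net, b2$grads)
  dz <- dz + b2$dx
  if (flags[["l1"]]) {
    fwd <- .critic_fwd(parts, z)
    g <- .critic_input_grad(parts, fwd)$g
    dz <- dz - g / n
  }
  b1 <- net_backward(enc_net, f1$caches, dz)
  enc_grads <- .add_flat(enc_grads, grads_flatten(enc_net, b1$grads))

  list(l1_enc = l1_enc, l2 = l2, l3 = l3,
       total = l1_enc + weights$mu * l2 + weights$gamma * l3,
       enc_grads = enc_grads, dec_grads = dec_grads,
       encoder = enc_net, decoder = f2$net)
}

# One critic update. Returns the loss pieces and flat critic gradients.
.critic_pass <- function(model, zq, zp, weights) {
  parts <- .critic_parts(model$critic)
  nq <- nrow(zq)
  fwd <- .critic_fwd(parts, rbind(zq, zp))
  w_out <- c(rep(1 / nq, nq), rep(-1 / nq, nq))
  main <- .critic_score_grads(parts, fwd, w_out)
  eps <- stats::runif(nq)
  zh <- zq * eps + zp * (1 - eps)
  pen <- .critic_penalty_grads(parts, zh, weights$lambda_gp, weights$penalty)
  dense_idx <- which(vapply(model$critic, function(l) l$type == "dense",
                            logical(1)))
  grads <- list()
  for (j in seq_along(dense_idx)) {
    gj <- main$grads[[j]]
    gj$W <- gj$W + pen$grads[[j]]$W
    grads[[paste0(dense_idx[j], ".W")]] <- gj$W
    grads[[paste0(dense_idx[j], ".b")]] <- gj$b
  }
  loss <- mean(fwd$y[seq_len(nq)]) - mean(fwd$y[nq + seq_len(nq)]) + pen$penalty
  list(loss = loss, penalty = pen$penalty, grads = grads)
}

#' Train a GANCMLAE model on normal-control slices
#'
#' Alternating optimization: for each generator step the critic is first
#' updated `critic_steps_per_generator_step` times on fresh encoder codes and
#' standard-normal prior samples (skipped entirely for variants without the
#' adversarial loss), then the shared encoder and the decoder are updated on
#' the combined objective restricted to the configured `loss_variant`. The
#' run is deterministic given the config seed.
#'
#' @param model A [build_model()] result.
#' @param normal_slices Training slices: an `H x W x N` array (e.g. from
#'   [pool_slices()]), a list of matrices, or a `slice_stack`. If an
#'   `anomalous` attribute (or per-subject `is_anomalous` flags) marks any
#'   slice as anomalous, training refuses to proceed: the model must only
#'   ever see normal anatomy.
#' @param config A [train_config()].
#' @return A list with `model` (trained) and `history` (a tibble of class
#'   `gancmlae_history`: per generator step `step`, `l1_critic`,
#'   `gradient_penalty`, `l1_encoder`, `l2`, `l3`, `total`; attribute
#'   `critic_updates` counts critic updates).
#' @export
train <- function(model, normal_slices, config = train_config()) {
  stopifnot(inherits(model, "gancmlae_model"), inherits(config, "train_config"))
  if (model$spec$final_sigmoid && .variant_flags(config$loss_variant)[["l1"]])
    stop("adversarial training requires an unbounded critic ",
         "(final_sigmoid = FALSE); the sigmoid head is for scoring only")
  x <- normal_slices
  if (inherits(x, "slice_stack")) x <- simplify2array(x$slices)
  if (is.list(x) && is.null(dim(x))) x <- simplify2array(x)
  anom <- attr(x, "anomalous")
  if (!is.null(anom) && any(anom))
    stop("training set contains ", sum(anom), " slices from anomalous ",
         "subjects; the model must be trained on normal controls only")
  b <- .as_batch(x, model$spec$input_size)
  n <- dim(b)[4]
  if (n == 0L) stop("empty training set")

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  flags <- .variant_flags(config$loss_variant)
  w <- config$weights
  bs <- min(config$batch_size, n)
  zdim <- model$spec$latent_dim

  gen_params <- c(.prefix(net_params(model$encoder), "enc."),
                  .prefix(net_params(model$decoder), "dec."))
  gen_state <- adam_init(gen_params)
  cr_params <- net_params(model$critic)
  cr_state <- adam_init(cr_params)

  perm <- sample.int(n)
  cursor <- 1L
  next_batch <- function() {
    if (cursor + bs - 1L > n) {
      perm <<- sample.int(n)
      cursor <<- 1L
    }
    idx <- perm[cursor:(cursor + bs - 1L)]
    cursor <<- cursor + bs
    b[, , , idx, drop = FALSE]
  }

  steps <- config$max_batches
  hist <- list(step = seq_len(steps), l1_critic = rep(NA_real_, steps),
               gradient_penalty = rep(NA_real_, steps),
               l1_encoder = numeric(steps), l2 = numeric(steps),
               l3 = numeric(steps), total = numeric(steps))
  critic_updates <- 0L

  for (step in seq_len(steps)) {
    if (flags[["l1"]]) {
      for (cs in seq_len(config$critic_steps_per_generator_step)) {
        xb <- next_batch()
        zq <- net_forward(model$encoder, xb, training = TRUE)$out
        zp <- matrix(stats::rnorm(bs * zdim), bs, zdim)
        cp <- .critic_pass(model, zq, zp, w)
        upd <- adam_step(cr_params, cp$grads, cr_state, config$lr_critic,
                         config$adam_beta1, config$adam_beta2)
        cr_params <- upd$params
        cr_state <- upd$state
        model$critic <- net_set_params(model$critic, cr_params)
        critic_updates <- critic_updates + 1L
      }
      hist$l1_critic[step] <- cp$loss
      hist$gradient_penalty[step] <- cp$penalty
    }
    xb <- next_batch()
    gp <- .generator_pass(model, xb, w, flags)
    model$encoder <- gp$encoder
    model$decoder <- gp$decoder
    grads <- c(.prefix(gp$enc_grads, "enc."), .prefix(gp$dec_grads, "dec."))
    upd <- adam_step(gen_params, grads, gen_state, config$lr_generator,
                     config$adam_beta1, config$adam_beta2)
    gen_params <- upd$params
    gen_state <- upd$state
    model$encoder <- net_set_params(model$encoder, gen_params, prefix = "enc.")
    model$decoder <- net_set_params(model$decoder, gen_params, prefix = "dec.")
    hist$l1_encoder[step] <- gp$l1_enc
    hist$l2[step] <- gp$l2
    hist$l3[step] <- gp$l3
    hist$total[step] <- gp$total
    if (!all(is.finite(c(gp$l1_enc, gp$l2, gp$l3))))
      stop("non-finite loss at step ", step, ": training diverged")
  }

  # Freeze evaluation-mode batch-norm statistics under the final weights:
  # the exponentially averaged running statistics lag the moving parameters,
  # and the resulting affine offset in evaluation mode is poison for
  # residual-based scoring. One momentum-0 pass over a representative slice
  # subset writes exact statistics.
  idx <- unique(round(seq(1L, n, length.out = min(n, 256L))))
  xb <- b[, , , idx, drop = FALSE]
  enc0 <- net_set_bn_momentum(model$encoder, 0)
  f1 <- net_forward(enc0, xb, training = TRUE)
  dec0 <- net_set_bn_momentum(model$decoder, 0)
  f2 <- net_forward(dec0, f1$out, training = TRUE)
  model$encoder <- net_set_bn_momentum(f1$net, 0.9)
  model$decoder <- net_set_bn_momentum(f2$net, 0.9)

  model$step <- model$step + steps
  model$trained <- TRUE
  history <- tibble::as_tibble(hist)
  class(history) <- c("gancmlae_history", class(history))
  attr(history, "critic_updates") <- critic_updates
  attr(history, "loss_variant") <- config$loss_variant
  list(model = model, history = history)
}

#' Reconstruct a subject volume through the model
#'
#' Preprocesses the volume ([preprocess_volume()]), reconstructs every axial
#' slice in evaluation mode and restores the reconstruction to the source 3D
#' geometry ([stack_to_volume()]).
#'
#' @param model A trained `gancmlae_model`.
#' @param volume A 3D array (raw intensities).
#' @return A list with `input` (the normalized input volume),
#'   `reconstruction` (3D array, same shape), `input_slices` and
#'   `recon_slices` (`H x W x N` model-space arrays).
#' @export
reconstruct_volume <- function(model, volume) {
  st <- preprocess_volume(volume, size = model$spec$input_size)
  xs <- simplify2array(st$slices)
  z <- encode(model, xs)
  xp <- decode(model, z)
  rst <- st
  rst$slices <- lapply(seq_len(dim(xp)[3]), function(k) xp[, , k])
  rst$normalized_volume <- NULL
  list(input = st$normalized_volume,
       reconstruction = stack_to_volume(rst),
       input_slices = xs, recon_slices = xp)
}

#' Per-subject reconstruction quality
#'
#' Reconstructs every slice of every subject and averages SSIM/PSNR/MSE per
#' subject ([subject_metrics()]); metrics are computed on \[0, 1\]-rescaled
#' slices with unit data range.
#'
#' @param model A `gancmlae_model` (a warning is issued if untrained).
#' @param subjects A `phantom_population` or list of subjects with `volume`
#'   (and optionally `is_anomalous`, `subject_id`) elements, or a list of 3D
#'   arrays.
#' @param mode,window Passed to [ssim()].
#' @return A tibble with one row per subject: `subject_id`, `is_anomalous`,
#'   `ssim`, `psnr`, `mse`, `n_slices`.
#' @export
evaluate <- function(model, subjects, mode = "windowed", window = 7L) {
  stopifnot(inherits(model, "gancmlae_model"))
  if (!model$trained)
    warning("model is untrained; metrics reflect the random initialization")
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    vol <- if (is.list(s)) s$volume else s
    rec <- reconstruct_volume(model, vol)
    mr <- subject_metrics(.to_unit(rec$input_slices),
                          .to_unit(rec$recon_slices),
                          mode = mode, window = window)
    tibble::tibble(
      subject_id = if (is.list(s) && !is.null(s$subject_id)) s$subject_id
                   else sprintf("S%03d", i),
      is_anomalous = if (is.list(s) && !is.null(s$is_anomalous)) s$is_anomalous
                     else NA,
      ssim = mr$ssim, psnr = mr$psnr, mse = mr$mse,
      n_slices = mr$n_slices_averaged)
  })
  do.call(rbind, rows)
}

#' Loss-ablation comparison
#'
#' Trains one model per loss variant on identical data and seed and reports
#' mean and standard deviation of the per-subject SSIM/PSNR/MSE on the
#' training and held-out subject splits.
#'
#' @param train_subjects,heldout_subjects Subject lists as in [evaluate()]
#'   (training subjects must all be normal).
#' @param arch An [architecture_spec()] shared by all variants.
#' @param base_config A [train_config()]; its `loss_variant` is overridden.
#' @param variants Character vector of variants to compare.
#' @return A tibble with one row per variant and mean/sd columns for each
#'   metric and split; trained models are attached as the `models` attribute.
#' @export
run_ablation <- function(train_subjects, heldout_subjects, arch,
                         base_config = train_config(),
                         variants = c("full", "L1+L2", "L1+L3", "L2+L3",
                                      "AE-only")) {
  slices <- pool_slices(train_subjects, size = arch$input_size)
  models <- list()
  rows <- lapply(variants, function(v) {
    cfg <- base_config
    cfg$loss_variant <- v
    fit <- train(build_model(arch, seed = cfg$seed), slices, cfg)
    models[[v]] <<- fit$model
    agg <- function(subjects, prefix) {
      ev <- evaluate(fit$model, subjects)
      out <- tibble::tibble(
        ssim_mean = mean(ev$ssim), ssim_sd = stats::sd(ev$ssim),
        psnr_mean = mean(ev$psnr[is.finite(ev$psnr)]),
        psnr_sd = stats::sd(ev$psnr[is.finite(ev$psnr)]),
        mse_mean = mean(ev$mse), mse_sd = stats::sd(ev$mse))
      names(out) <- paste0(prefix, "_", names(out))
      out
    }
    cbind(tibble::tibble(variant = v),
          agg(train_subjects, "train"), agg(heldout_subjects, "test"))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "models") <- models
  out
}
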