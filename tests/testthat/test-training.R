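test_that("the critic is updated the configured number of times per step", {
  m <- build_model(tiny_arch(), seed = 1)
  sl <- tiny_slices(n = 12)
  fit <- train(m, sl, train_config(max_batches = 10, batch_size = 8, seed = 1))
  expect_identical(nrow(fit$history), 10L)
  expect_identical(attr(fit$history, "critic_updates"), 20L)  # ratio 2:1
  fit3 <- train(m, sl, train_config(max_batches = 4, batch_size = 8, seed = 1,
                                    critic_steps_per_generator_step = 3))
  expect_identical(attr(fit3$history, "critic_updates"), 12L)
})

test_that("training is bit-reproducible for identical configs and seeds", {
  m <- build_model(tiny_arch(), seed = 2)
  sl <- tiny_slices(n = 10)
  cfg <- train_config(max_batches = 8, batch_size = 6, seed = 3)
  f1 <- train(m, sl, cfg)
  f2 <- train(m, sl, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(net_params_public(f1$model), net_params_public(f2$model))
  f3 <- train(m, sl, train_config(max_batches = 8, batch_size = 6, seed = 4))
  expect_false(identical(f1$history, f3$history))
})

test_that("all logged losses stay finite on a short run", {
  m <- build_model(tiny_arch(), seed = 5)
  fit <- train(m, tiny_slices(n = 10), train_config(max_batches = 15,
                                                    batch_size = 8, seed = 5))
  h <- fit$history
  expect_true(all(is.finite(h$l1_critic)))
  expect_true(all(is.finite(h$gradient_penalty)))
  expect_true(all(is.finite(c(h$l1_encoder, h$l2, h$l3, h$total))))
})

test_that("training refuses anomalous subjects and empty data", {
  pop <- make_population(phantom_spec(n_subjects = 4, grid_shape = c(16, 16, 4),
                                      atrophy_fraction = 0.5, seed = 6))
  sl <- pool_slices(pop, size = 16)
  m <- build_model(tiny_arch(), seed = 6)
  expect_error(train(m, sl, train_config(max_batches = 2)), "normal controls")
  normals <- Filter(function(s) !s$is_anomalous, pop)
  sln <- pool_slices(normals, size = 16)
  expect_no_error(train(m, sln, train_config(max_batches = 2, batch_size = 4)))
})

test_that("ablation variants restrict the losses they train on", {
  m <- build_model(tiny_arch(), seed = 7)
  sl <- tiny_slices(n = 10)
  # AE-only: no critic updates, critic parameters untouched
  fae <- train(m, sl, train_config(max_batches = 5, batch_size = 6, seed = 7,
                                   loss_variant = "AE-only"))
  expect_identical(attr(fae$history, "critic_updates"), 0L)
  expect_identical(gancmlae:::net_params(fae$model$critic),
                   gancmlae:::net_params(m$critic))
  expect_true(all(fae$history$l1_encoder == 0))
  expect_true(all(fae$history$l3 == 0))
  # L1+L2: latent-consistency inactive
  f12 <- train(m, sl, train_config(max_batches = 3, batch_size = 6, seed = 7,
                                   loss_variant = "L1+L2"))
  expect_true(all(f12$history$l3 == 0))
  expect_identical(attr(f12$history, "critic_updates"), 6L)
  # L2+L3: adversarial inactive, no critic updates
  f23 <- train(m, sl, train_config(max_batches = 3, batch_size = 6, seed = 7,
                                   loss_variant = "L2+L3"))
  expect_identical(attr(f23$history, "critic_updates"), 0L)
  expect_true(all(f23$history$l1_encoder == 0))
  expect_true(all(f23$history$l3 > 0))
  # L1+L3: pixel loss inactive
  f13 <- train(m, sl, train_config(max_batches = 3, batch_size = 6, seed = 7,
                                   loss_variant = "L1+L3"))
  expect_true(all(f13$history$l2 == 0))
})

test_that("evaluate() agrees with manual metric recomputation", {
  pop <- make_population(phantom_spec(n_subjects = 2, grid_shape = c(16, 16, 5),
                                      atrophy_fraction = 0, seed = 8))
  m <- build_model(tiny_arch(), seed = 8)
  fit <- train(m, pool_slices(pop, size = 16),
               train_config(max_batches = 5, batch_size = 5, seed = 8))
  ev <- evaluate(fit$model, pop)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$n_slices, c(5L, 5L))
  rec <- reconstruct_volume(fit$model, pop[[1]]$volume)
  manual <- subject_metrics(lapply(1:5, function(k) (rec$input_slices[, , k] + 1) / 2),
                            lapply(1:5, function(k) (rec$recon_slices[, , k] + 1) / 2))
  expect_equal(ev$ssim[1], manual$ssim)
  expect_equal(ev$mse[1], manual$mse)
  expect_equal(ev$psnr[1], manual$psnr)
  expect_warning(evaluate(build_model(tiny_arch(), seed = 9), pop), "untrained")
})

test_that("run_ablation produces one row of paired summaries per variant", {
  pop <- make_population(phantom_spec(n_subjects = 6, grid_shape = c(16, 16, 4),
                                      atrophy_fraction = 0, seed = 9))
  tab <- run_ablation(pop[1:4], pop[5:6], tiny_arch(),
                      train_config(max_batches = 4, batch_size = 6, seed = 9),
                      variants = c("full", "L1+L2"))
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$variant, c("full", "L1+L2"))
  metric_cols <- as.vector(outer(c("train", "test"),
    as.vector(outer(c("ssim", "psnr", "mse"), c("mean", "sd"), paste, sep = "_")),
    paste, sep = "_"))
  expect_true(all(metric_cols %in% names(tab)))
  expect_true(all(is.finite(unlist(tab[metric_cols]))))
  expect_length(attr(tab, "models"), 2L)
})

test_that("histories tidy and summarise into tibbles", {
  m <- build_model(tiny_arch(), seed = 10)
  fit <- train(m, tiny_slices(8), train_config(max_batches = 4, batch_size = 6,
                                               seed = 10))
  td <- tidy(fit$history)
  expect_true(all(c("step", "loss", "value") %in% names(td)))
  expect_true(all(td$loss %in% c("l1_critic", "gradient_penalty", "l1_encoder",
                                 "l2", "l3", "total")))
  gl <- glance(fit$history)
  expect_identical(gl$steps, 4L)
  expect_identical(gl$critic_updates, 8L)
  gm <- glance(fit$model)
  expect_identical(gm$latent_dim, 4L)
  expect_true(gm$trained)
  p <- autoplot(fit$history)
  expect_s3_class(p, "ggplot")
})
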