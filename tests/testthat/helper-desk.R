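# Shared desk-scale study: one seeded phantom population and one full
# training run reused by the training-contract and end-to-end tests.
# Conditions: default phantom population (64 x 64 x 24 grid, 48 subjects,
# a quarter anomalous, atrophy magnitude 0.5, radius 7), model input 32 x 32,
# base filters 4, latent 32, batch 32, 2,000 generator steps, seed 1.
.desk_cache <- new.env(parent = emptyenv())

desk_study <- function() {
  if (!is.null(.desk_cache$study)) return(.desk_cache$study)
  pop <- make_population(phantom_spec())
  normals <- Filter(function(s) !s$is_anomalous, pop)
  n_ref <- ceiling(length(normals) / 3)
  ref <- normals[seq_len(n_ref)]
  train_set <- normals[-seq_len(n_ref)]
  arch <- architecture_spec(input_size = 32, base_filters = 4, latent_dim = 32)
  slices <- pool_slices(train_set, size = 32)
  model0 <- build_model(arch, seed = 1)
  fit <- train(model0, slices, train_config(max_batches = 2000, seed = 1))
  maps <- lapply(pop, function(s) {
    rec <- reconstruct_volume(fit$model, s$volume)
    residual_map(rec$input, rec$reconstruction, s$subject_id)
  })
  .desk_cache$study <- list(
    pop = pop, ref = ref, train_set = train_set, arch = arch,
    model0 = model0, model = fit$model, history = fit$history,
    maps = maps,
    is_anom = vapply(pop, `[[`, logical(1), "is_anomalous"),
    support = pop[[1]]$support,
    # analyses run on the eroded tissue support (see erode_mask docs)
    analysis_mask = erode_mask(pop[[1]]$support, 3))
  .desk_cache$study
}
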