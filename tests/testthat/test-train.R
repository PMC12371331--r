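tiny_training_set <- function(n = 20L, seed = 31L) {
  syn <- generate_synthetic(synth_config(n_complexes = 2L,
                                         records_per_complex = n %/% 2L,
                                         bonus = 0, noise_sd = 0,
                                         seed = seed))
  syn$records
}

test_that("training reduces the training loss and is seed-deterministic", {
  recs <- tiny_training_set()
  spec <- embedder_spec(d = 8L, seed = 2L)
  cfg <- small_config()
  tc <- train_config(learning_rate = 3e-3, batch_size = 4L, max_epochs = 8L,
                     patience = 20L, seed = 9L)
  fit1 <- attnddg_fit(recs, spec, cfg, tc)
  h <- tidy(fit1)
  expect_lt(h$train_mse[nrow(h)], h$train_mse[1])
  expect_true(all(is.finite(h$train_mse)))
  # identical seeds and data give identical histories and predictions
  fit2 <- attnddg_fit(recs, spec, cfg, tc)
  expect_equal(tidy(fit2), h)
  expect_identical(predict(fit1, recs[1:3, ]), predict(fit2, recs[1:3, ]))
  # a different seed changes the trajectory
  tc2 <- tc; tc2$seed <- 10L
  expect_false(isTRUE(all.equal(tidy(attnddg_fit(recs, spec, cfg, tc2)), h)))
})

test_that("early stopping halts after `patience` non-improving epochs", {
  recs <- tiny_training_set()
  spec <- embedder_spec(d = 8L, seed = 2L)
  # a huge learning rate makes validation worsen immediately
  fit <- attnddg_fit(recs, spec, small_config(),
                     train_config(learning_rate = 5, batch_size = 4L,
                                  max_epochs = 50L, patience = 2L, seed = 3L))
  h <- tidy(fit)
  expect_lt(nrow(h), 50L)
  expect_equal(nrow(h), fit$best_epoch + 2L)
  # returned parameters are the best-validation ones
  expect_equal(fit$best_val_mse, min(h$val_mse))
})

test_that("the frozen embedder is untouched by training", {
  recs <- tiny_training_set()
  spec <- embedder_spec(d = 8L, seed = 2L)
  before <- embed_sequence(recs$ab_chains[[1]][["H"]], spec, cache = FALSE)
  digest_before <- digest::digest(lapply(seq_len(nrow(recs)), function(i)
    embed_complex(recs[i, ], spec)))
  fit <- attnddg_fit(recs, spec, small_config(),
                     train_config(learning_rate = 1e-3, max_epochs = 2L,
                                  patience = 5L, seed = 1L))
  after <- embed_sequence(recs$ab_chains[[1]][["H"]], spec, cache = FALSE)
  digest_after <- digest::digest(lapply(seq_len(nrow(recs)), function(i)
    embed_complex(recs[i, ], spec)))
  expect_identical(before, after)
  expect_identical(digest_before, digest_after)
  expect_identical(fit$embedder_digest, attnddg:::spec_digest(spec))
})

test_that("training aborts on divergence instead of returning garbage", {
  recs <- tiny_training_set()
  spec <- embedder_spec(d = 8L, seed = 2L)
  expect_error(
    attnddg_fit(recs, spec, small_config(),
                train_config(learning_rate = 1e9, batch_size = 4L,
                             max_epochs = 10L, patience = 10L,
                             weight_decay = 0.01, seed = 1L)),
    "non-finite")
})

test_that("fit accessors: tidy/glance/augment/predict are coherent", {
  recs <- tiny_training_set()
  fit <- attnddg_fit(recs, embedder_spec(d = 8L, seed = 2L), small_config(),
                     train_config(learning_rate = 1e-3, max_epochs = 3L,
                                  patience = 5L, seed = 4L))
  g <- glance(fit)
  expect_equal(g$epochs, nrow(tidy(fit)))
  expect_equal(g$n_params, fit$n_params)
  aug <- augment(fit, recs[1:4, ])
  expect_equal(aug$.pred, predict(fit, recs[1:4, ]))
  expect_equal(aug$.resid, aug$ddg - aug$.pred)
  ev <- evaluate_model(fit, recs)
  expect_equal(ev$n, nrow(recs))
  expect_gte(ev$rmse, 0)
  # plots build without evaluation errors
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_ddg_scatter(aug), "ggplot")
})

test_that("ablation harness pairs variants on a shared split with matched budgets", {
  syn <- generate_synthetic(synth_config(n_complexes = 3L,
                                         records_per_complex = 10L,
                                         seed = 17L))
  spec <- embedder_spec(d = 8L, seed = 2L)
  cfg <- small_config()
  tc <- train_config(learning_rate = 1e-3, max_epochs = 2L, patience = 3L,
                     batch_size = 8L, seed = 1L)
  out <- ablation_run(syn$records, "no_attention", spec, cfg, tc,
                      split_seed = 1L)
  expect_equal(out$variant, c("full", "no_attention"))
  expect_true(all(is.finite(out$rmse)))
  # the mlp replacement stays within 10% of the attention block's parameters
  out2 <- ablation_run(syn$records, "mlp", spec, cfg, tc, split_seed = 1L)
  ratio <- out2$block_params[2] / out2$block_params[1]
  expect_lt(abs(ratio - 1), 0.10)
  # an mlp width far off the attention budget is refused
  cfg_bad <- small_config(mlp_hidden = 64L)
  expect_error(ablation_run(syn$records, "mlp", spec, cfg_bad, tc),
               "within 10%")
})

test_that("cross-validation aggregates per-fold metrics", {
  recs <- tiny_training_set(n = 24L)
  cv <- cross_validate(recs, k = 3L, spec = embedder_spec(d = 8L, seed = 2L),
                       config = small_config(),
                       train = train_config(learning_rate = 1e-3,
                                            max_epochs = 2L, patience = 3L,
                                            batch_size = 8L, seed = 1L),
                       seed = 5L)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_equal(cv$summary$metric, c("rmse", "r2", "pcc", "spearman"))
  expect_equal(cv$summary$mean[1], mean(cv$per_fold$rmse))
})
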