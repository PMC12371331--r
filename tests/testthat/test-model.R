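test_that("model configuration validates its invariants", {
  expect_error(attention_config(d_model = 7L), "even")
  expect_error(attention_config(d_model = 8L, n_heads = 3L), "divide")
  expect_error(attention_config(conv_kernel = 2L), "odd")
  expect_error(attention_config(dropout = 1), "dropout")
  cfg <- attention_config(d_model = 16L, n_heads = 4L)
  expect_equal(cfg$mlp_hidden, 32L)
})

test_that("the forward pass produces finite predictions with coherent shapes", {
  rec <- random_record(6L, 9L, seed = 1)
  spec <- embedder_spec(d = 12L, seed = 2L)
  cfg <- small_config()
  p <- init_model_params(12L, cfg, seed = 3L)
  E <- embed_complex(rec, spec)
  r <- model_forward(E, p, cfg)
  expect_true(is.finite(r$y))
  # attention maps: (L_ab x L_ag) for ab queries, transposed for ag queries
  expect_equal(dim(r$state$attention$ab_wt[[1]]), c(6L, 9L))
  expect_equal(dim(r$state$attention$ag_mt[[1]]), c(9L, 6L))
  expect_length(r$state$attention$ab_wt, cfg$n_heads)
  # pooled vectors carry d_model width; joint feature twice that
  expect_length(r$state$pooled$ab_wt, cfg$d_model)
  expect_length(r$state$joint, 2L * cfg$d_model)
  # every normalised weight vector sums to 1
  for (k in names(r$state$gate_weights)) {
    expect_equal(sum(r$state$gate_weights[[k]]), 1, tolerance = 1e-5)
    expect_equal(sum(r$state$pool_weights[[k]]), 1, tolerance = 1e-5)
  }
})

test_that("a record whose mutant equals its wild type collapses the streams", {
  # antigen untouched: its wt/mt pooled vectors are identical
  rec <- toy_record(codes = "H:R3K")
  spec <- embedder_spec(d = 8L, seed = 4L)
  cfg <- small_config()
  p <- init_model_params(8L, cfg, seed = 5L)
  r <- model_forward(embed_complex(rec, spec), p, cfg)
  expect_true(is.finite(r$y))
  expect_false(identical(r$state$pooled$ab_wt, r$state$pooled$ab_mt))
  # the antigen stream still differs between wt and mt because its keys and
  # values come from the mutated antibody
  expect_false(identical(r$state$pooled$ag_wt, r$state$pooled$ag_mt))
  # fully identical complex (mutation on ab, then compare ag-only embeddings):
  E <- embed_complex(rec, spec)
  E_same <- list(ab_wt = E$ab_wt, ag_wt = E$ag_wt,
                 ab_mt = E$ab_wt, ag_mt = E$ag_wt)
  r2 <- model_forward(E_same, p, cfg)
  expect_identical(r2$state$pooled$ab_wt, r2$state$pooled$ab_mt)
  expect_identical(r2$state$pooled$ag_wt, r2$state$pooled$ag_mt)
})

test_that("padding plus masking reproduces the unpadded forward pass", {
  spec <- embedder_spec(d = 10L, seed = 6L)
  cfg <- small_config(conv_kernel = 3L)
  p <- init_model_params(10L, cfg, seed = 7L)
  withr::with_seed(77, {
    for (trial in 1:10) {
      rec <- random_record(sample(4:8, 1), sample(4:8, 1), seed = trial + 100)
      E <- embed_complex(rec, spec)
      base <- model_forward(E, p, cfg)
      pad <- function(M, extra) rbind(M, matrix(rnorm(extra * ncol(M)),
                                                extra, ncol(M)))
      extra <- 10L
      E_pad <- list(ab_wt = pad(E$ab_wt, extra), ag_wt = pad(E$ag_wt, extra),
                    ab_mt = pad(E$ab_mt, extra), ag_mt = pad(E$ag_mt, extra))
      masks <- lapply(E[c("ab_wt", "ag_wt", "ab_mt", "ag_mt")],
                      function(M) c(rep(TRUE, nrow(M)), rep(FALSE, extra)))
      positions <- lapply(E_pad, function(M) seq_len(nrow(M)) - 1)
      padded <- model_forward(E_pad, p, cfg, masks = masks,
                              positions = positions)
      expect_equal(padded$y, base$y, tolerance = 1e-5)
    }
  })
})

test_that("batched evaluation equals one-by-one evaluation", {
  # the batch path pads records to a common length under masks; predictions
  # must match the per-record unpadded forward pass
  spec <- embedder_spec(d = 8L, seed = 8L)
  cfg <- small_config()
  p <- init_model_params(8L, cfg, seed = 9L)
  recs <- dplyr::bind_rows(lapply(1:4, function(i)
    random_record(3L + i, 9L - i, seed = 200 + i)))
  singles <- vapply(seq_len(nrow(recs)), function(i) {
    model_forward(embed_complex(recs[i, ], spec), p, cfg)$y
  }, numeric(1))
  E_list <- lapply(seq_len(nrow(recs)), function(i) embed_complex(recs[i, ], spec))
  L_max <- max(unlist(lapply(E_list, function(E) vapply(
    E[c("ab_wt", "ag_wt", "ab_mt", "ag_mt")], nrow, integer(1)))))
  batched <- vapply(E_list, function(E) {
    keys <- c("ab_wt", "ag_wt", "ab_mt", "ag_mt")
    E_pad <- lapply(E[keys], function(M)
      rbind(M, matrix(0, L_max - nrow(M), ncol(M))))
    masks <- lapply(E[keys], function(M)
      c(rep(TRUE, nrow(M)), rep(FALSE, L_max - nrow(M))))
    positions <- lapply(E_pad, function(M) seq_len(nrow(M)) - 1)
    model_forward(E_pad, p, cfg, masks = masks, positions = positions)$y
  }, numeric(1))
  expect_equal(batched, singles, tolerance = 1e-5)
})

test_that("the fused forward equals the straight-line oracle on toy complexes", {
  spec <- embedder_spec(d = 12L, seed = 10L)
  cfg <- attention_config(d_model = 16L, n_heads = 2L, dropout = 0,
                          hidden = c(8L, 4L))
  withr::with_seed(55, {
    for (trial in 1:5) {
      rec <- random_record(sample(3:8, 1), sample(3:8, 1), seed = 300 + trial)
      p <- init_model_params(12L, cfg, seed = trial)
      E <- embed_complex(rec, spec)
      expect_equal(model_forward(E, p, cfg)$y, oracle_forward(E, p, cfg),
                   tolerance = 1e-5)
    }
  })
})

test_that("parameter flattening round-trips and counts are exact", {
  cfg <- small_config()
  p <- init_model_params(10L, cfg, seed = 11L)
  v <- attnddg:::flatten_params(p)
  p2 <- attnddg:::unflatten_params(v, p)
  expect_identical(p, p2)
  expect_equal(count_params(p), length(v))
  # hand count of one piece: input projection is d_in x d_model + bias
  expect_equal(length(attnddg:::flatten_params(p$proj)), 10L * 8L + 8L)
})
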