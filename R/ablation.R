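# Attention-ablation harness: train the full model and a variant on the
# same split and seed, and compare held-out performance.

attention_block_params <- function(config) {
  # per stream: Wq, Wk, Wv, Wo
  2L * 4L * config$d_model^2
}

mlp_block_params <- function(config) {
  d <- config$d_model; h <- config$mlp_hidden
  2L * (d * h + h + h * d + d)
}

variant_config <- function(config, variant) {
  cfg <- config
  cfg$variant <- variant
  if (variant == "mlp") {
    ratio <- mlp_block_params(cfg) / attention_block_params(cfg)
    if (abs(ratio - 1) > 0.10) {
      abort(glue(
        "mlp replacement has {round(100 * ratio)}% of the attention block's ",
        "parameters; adjust mlp_hidden to stay within 10%"))
    }
  }
  cfg
}

#' Train and compare the full model against an ablated variant
#'
#' Both models share the same seeded 80/20 record split, the same embedder
#' and the same training configuration; only the attention block differs.
#' `"no_attention"` removes the cross-attention entirely (pooling applies
#' directly to the gated streams); `"mlp"` replaces it with a position-wise
#' multi-layer perceptron whose parameter count is enforced to be within
#' 10% of the attention block's.
#'
#' @param records Record tibble.
#' @param variant `"no_attention"` or `"mlp"`.
#' @param spec,config,train Passed to [attnddg_fit()].
#' @param split_seed Seed of the shared train/test split.
#' @return Tibble with one row per model (`variant`, held-out metrics,
#'   `block_params`, `total_params`).
#' @export
ablation_run <- function(records, variant = c("no_attention", "mlp"),
                         spec = embedder_spec(), config = attention_config(),
                         train = train_config(), split_seed = 1L) {
  variant <- match.arg(variant)
  n <- nrow(records)
  te_idx <- with_local_seed(mix_seed(split_seed, 17L),
                            sample.int(n, max(1L, round(0.2 * n))))
  tr <- records[-te_idx, , drop = FALSE]
  te <- records[te_idx, , drop = FALSE]
  run_one <- function(v) {
    cfg <- variant_config(config, v)
    fit <- attnddg_fit(tr, spec, cfg, train)
    dplyr::mutate(
      evaluate_model(fit, te),
      variant = v,
      block_params = switch(v, full = attention_block_params(cfg),
                            mlp = mlp_block_params(cfg), 0L),
      total_params = fit$n_params,
      .before = 1L
    )
  }
  dplyr::bind_rows(run_one("full"), run_one(variant))
}

#' Repeat an ablation comparison over several seeds
#'
#' @param records Record tibble.
#' @param variant Ablated variant, as in [ablation_run()].
#' @param seeds Integer vector; each seed controls one repetition's split
#'   and training randomness.
#' @param spec,config,train Passed through.
#' @return Tibble of per-seed paired results (column `seed` added).
#' @export
ablation_repeat <- function(records, variant = c("no_attention", "mlp"),
                            seeds = 1:5, spec = embedder_spec(),
                            config = attention_config(),
                            train = train_config()) {
  variant <- match.arg(variant)
  dplyr::bind_rows(lapply(seeds, function(s) {
    tr_cfg <- train
    tr_cfg$seed <- as.integer(s)
    dplyr::mutate(
      ablation_run(records, variant, spec, config, tr_cfg, split_seed = s),
      seed = s, .before = 1L)
  }))
}
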