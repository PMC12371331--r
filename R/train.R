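# Training (AdamW on the mean-squared error, early stopping on a held-out
# validation fraction, embedder frozen throughout) and model evaluation.

#' Training configuration
#'
#' @param learning_rate AdamW learning rate.  The default follows the
#'   fine-tuning protocol used with large frozen language-model embedders;
#'   small from-scratch models at desk scale typically want `1e-3`.
#' @param batch_size Records per gradient step.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early stopping: stop after this many epochs without
#'   validation-loss improvement, returning the best-validation parameters.
#' @param validation_fraction Fraction of the training records held out to
#'   monitor early stopping.
#' @param weight_decay AdamW decoupled weight decay.  The default is 0: the
#'   wild-type/mutant difference signal reaching the regression head is
#'   small, and decay erodes the weights that carry it faster than the
#'   gradient builds them; enable decay only for models large enough to
#'   overfit badly.
#' @param seed Integer seed controlling the train/validation split, the
#'   parameter initialisation, shuffling and dropout.
#' @return An `attnddg_train_config` list.  The loss is fixed to mean
#'   squared error.
#' @export
train_config <- function(learning_rate = 3e-5, batch_size = 16L,
                         max_epochs = 200L, patience = 10L,
                         validation_fraction = 0.1, weight_decay = 0,
                         seed = 1L) {
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (patience < 1L) abort("patience must be at least 1")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         validation_fraction = validation_fraction,
         weight_decay = weight_decay, seed = as.integer(seed)),
    class = "attnddg_train_config"
  )
}

adamw_step <- function(theta, grad, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + wd * theta)
  list(theta = theta, state = state)
}

#' Fit the cross-attention ddG model
#'
#' Embeds every record once with the frozen embedder, holds out a seeded
#' validation fraction, and minimises the mean squared error with AdamW.
#' Training stops when the validation MSE fails to improve for `patience`
#' epochs (or at `max_epochs`); the parameters with the best validation
#' loss are returned.  The run is deterministic for a fixed seed.
#'
#' @param records Record tibble with `ddg` labels (at least two records).
#' @param spec An [embedder_spec()]; the embedder is never updated.
#' @param config An [attention_config()].
#' @param train An [train_config()].
#' @return An `attnddg_fit` object with elements `params`, `config`, `spec`,
#'   `train`, `history` (per-epoch train/validation MSE), `best_epoch`,
#'   `n_params`.  Works with [tidy()], [glance()], [augment()],
#'   [autoplot()] and [predict()].
#' @export
attnddg_fit <- function(records, spec = embedder_spec(),
                        config = attention_config(), train = train_config()) {
  n <- nrow(records)
  if (n < 2L) abort("need at least 2 records to fit")
  E_all <- lapply(seq_len(n), function(i) embed_complex(records[i, ], spec))
  d_in <- ncol(E_all[[1L]]$ab_wt)
  y <- records$ddg
  embedder_digest <- spec_digest(spec)

  with_local_seed(mix_seed(train$seed, 7L), {
    n_val <- max(1L, round(train$validation_fraction * n))
    if (n_val >= n) abort("validation fraction leaves no training records")
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)

    params <- init_model_params(d_in, config, seed = train$seed)
    template <- params
    theta <- flatten_params(params)
    opt <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)

    best_val <- Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
    history <- vector("list", train$max_epochs)

    eval_mse <- function(theta, idx) {
      params <- unflatten_params(theta, template)
      mean(vapply(idx, function(i) {
        (forward_complex(E_all[[i]], params, config)$y - y[i])^2
      }, numeric(1L)))
    }

    for (epoch in seq_len(train$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
      epoch_loss <- 0
      for (bt in batches) {
        params <- unflatten_params(theta, template)
        grads <- zero_like(params)
        for (i in bt) {
          r <- forward_complex(E_all[[i]], params, config, training = TRUE)
          err <- r$y - y[i]
          epoch_loss <- epoch_loss + err^2
          grads <- add_grads(grads,
                             backward_complex(2 * err / length(bt), r$cache,
                                              params, config))
        }
        gvec <- flatten_params(grads)
        if (!all(is.finite(gvec))) {
          abort(glue("non-finite gradient at epoch {epoch}; aborting"))
        }
        st <- adamw_step(theta, gvec, opt, train$learning_rate,
                         train$weight_decay)
        theta <- st$theta; opt <- st$state
      }
      train_mse <- epoch_loss / length(tr_idx)
      if (!is.finite(train_mse)) abort(glue("non-finite loss at epoch {epoch}"))
      val_mse <- eval_mse(theta, val_idx)
      improved <- val_mse < best_val - 1e-12
      if (improved) {
        best_val <- val_mse; best_theta <- theta
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
      }
      history[[epoch]] <- tibble(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse, best = improved)
      if (wait >= train$patience) break
    }

    structure(
      list(params = unflatten_params(best_theta, template),
           config = config, spec = spec, train = train,
           history = dplyr::bind_rows(history),
           best_epoch = best_epoch, best_val_mse = best_val,
           n_params = length(theta), d_in = d_in,
           embedder_digest = embedder_digest,
           val_idx = val_idx),
      class = "attnddg_fit"
    )
  })
}

#' @export
print.attnddg_fit <- function(x, ...) {
  cat("<attnddg_fit>\n")
  cat(glue("  variant: {x$config$variant}, d_model = {x$config$d_model}, ",
           "{x$config$n_heads} heads, {x$n_params} parameters"), "\n")
  cat(glue("  trained {nrow(x$history)} epochs; best epoch {x$best_epoch} ",
           "(validation MSE {signif(x$best_val_mse, 4)})"), "\n")
  invisible(x)
}

#' Predict ddG for new records
#'
#' @param object An `attnddg_fit`.
#' @param newdata Record tibble.
#' @param ... Unused.
#' @return Numeric vector of predicted ddG (kcal/mol).
#' @export
predict.attnddg_fit <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i) {
    E <- embed_complex(newdata[i, ], object$spec)
    forward_complex(E, object$params, object$config)$y
  }, numeric(1L))
}

#' Evaluate a fitted model on labelled records
#'
#' @param fit An `attnddg_fit`.
#' @param records Record tibble with `ddg` labels.
#' @return One-row metrics tibble from [regression_metrics()].
#' @export
evaluate_model <- function(fit, records) {
  regression_metrics(records$ddg, predict(fit, records))
}

#' K-fold cross-validation of the model
#'
#' Fits one model per fold (training on the other folds) and evaluates on
#' the held-out fold; reports per-fold metrics and their mean and standard
#' deviation.
#'
#' @param records Record tibble.
#' @param k Number of folds.
#' @param spec,config,train Passed to [attnddg_fit()].
#' @param seed Seed for the fold assignment.
#' @return List with `per_fold` (metrics tibble with a `fold` column) and
#'   `summary` (mean and sd per metric).
#' @export
cross_validate <- function(records, k, spec = embedder_spec(),
                           config = attention_config(),
                           train = train_config(), seed = 1L) {
  folded <- kfold_split(records, k, seed)
  per_fold <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
    tr <- folded[folded$.fold != f, , drop = FALSE]
    te <- folded[folded$.fold == f, , drop = FALSE]
    fit <- attnddg_fit(tr, spec, config, train)
    dplyr::mutate(evaluate_model(fit, te), fold = f, .before = 1L)
  }))
  num <- c("rmse", "r2", "pcc", "spearman")
  summary <- tibble(
    metric = num,
    mean = vapply(num, function(m) mean(per_fold[[m]]), numeric(1L),
                  USE.NAMES = FALSE),
    sd = vapply(num, function(m) sd(per_fold[[m]]), numeric(1L),
                USE.NAMES = FALSE)
  )
  list(per_fold = per_fold, summary = summary)
}
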