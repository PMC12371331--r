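# Evaluation metrics and the three data-split protocols: k-fold
# cross-validation, sequence-identity clustering split, and mutation-depth
# extrapolation split.

#' Regression metrics for ddG prediction
#'
#' Computes RMSE (kcal/mol), the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (which can be negative for predictors worse
#' than the label mean), the Pearson correlation and the Spearman rank
#' correlation (average ranks on ties).  With fewer than two observations or
#' zero-variance inputs the correlations are undefined and returned as `NA`
#' with the reason in `note`.
#'
#' @param truth Numeric vector of observed ddG.
#' @param estimate Numeric vector of predictions.
#' @return One-row tibble: `n`, `rmse`, `r2`, `pcc`, `spearman`, `note`.
#' @export
regression_metrics <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  n <- length(truth)
  if (n < 2L) {
    return(tibble(n = n, rmse = if (n == 1L) abs(truth - estimate) else NA_real_,
                  r2 = NA_real_, pcc = NA_real_, spearman = NA_real_,
                  note = "fewer than 2 observations: correlations undefined"))
  }
  res <- truth - estimate
  rmse <- sqrt(mean(res^2))
  ss_res <- sum(res^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  note <- NA_character_
  if (sd(estimate) == 0 || sd(truth) == 0) {
    pcc <- NA_real_; rho <- NA_real_
    note <- "zero-variance input: correlations undefined"
  } else {
    pcc <- cor(truth, estimate)
    rho <- cor(truth, estimate, method = "spearman")
  }
  tibble(n = n, rmse = rmse, r2 = r2, pcc = pcc, spearman = rho, note = note)
}

#' Assign k-fold cross-validation folds
#'
#' Randomly partitions the records into `k` folds whose sizes differ by at
#' most one; deterministic for a fixed seed.
#'
#' @param records Record tibble.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return `records` with an integer `.fold` column.
#' @export
kfold_split <- function(records, k, seed = 1L) {
  n <- nrow(records)
  k <- as.integer(k)
  if (k < 2L) abort("k must be at least 2")
  if (k > n) abort(glue("k = {k} exceeds the number of records ({n})"))
  fold <- integer(n)
  with_local_seed(mix_seed(seed, 11L), {
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  })
  dplyr::mutate(records, .fold = fold)
}

# Global-alignment fractional identity between two amino-acid sequences.
# Fixed scoring: match +2, mismatch -1, gap opening 10, gap extension 0.5;
# identity is computed over the alignment (PID1).
seq_identity <- function(a, b) {
  letters <- aa_letters_ok
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = m,
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

# Greedy single-linkage clustering: sequences joined whenever their pairwise
# identity reaches the threshold (union-find over the identity graph).
cluster_sequences <- function(seqs, threshold) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (seq_identity(seqs[i], seqs[j]) >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

record_split_sequence <- function(records, on) {
  vapply(seq_len(nrow(records)), function(i) {
    mt <- mutant_chains(records[i, ])
    switch(on,
      complex = paste0(concat_chains(mt$ab), concat_chains(mt$ag)),
      antibody = concat_chains(mt$ab),
      antigen = concat_chains(mt$ag)
    )
  }, character(1L))
}

#' Sequence-identity train/test split
#'
#' Clusters the records' mutated-complex sequences by greedy single-linkage
#' over global-alignment identity at `threshold`, then assigns whole
#' clusters to train or test, filling the train quota largest-first
#' (seeded shuffle among equal sizes) to approach the requested record
#' ratio.  No test record ever shares a cluster with a train record, which
#' is what makes this split a low-homology extrapolation test.
#'
#' @param records Record tibble.
#' @param threshold Identity threshold in (0, 1); default 0.30.
#' @param ratio Target train fraction of records (default 0.8).
#' @param seed Integer seed.
#' @param on Cluster on the `"complex"` (concatenated mutant antibody +
#'   antigen, the default), `"antibody"` or `"antigen"` sequence.
#' @return `records` with `.cluster` (integer) and `.split`
#'   (`"train"`/`"test"`) columns.
#' @export
identity_split <- function(records, threshold = 0.30, ratio = 0.8, seed = 1L,
                           on = c("complex", "antibody", "antigen")) {
  on <- match.arg(on)
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  seqs <- record_split_sequence(records, on)
  uniq <- unique(seqs)
  cl_uniq <- cluster_sequences(uniq, threshold)
  cluster <- cl_uniq[match(seqs, uniq)]
  n_cl <- length(unique(cluster))
  if (n_cl < 2L) {
    abort("identity split needs at least 2 sequence clusters")
  }
  sizes <- table(cluster)
  quota <- ratio * nrow(records)
  ord <- with_local_seed(mix_seed(seed, 13L), {
    ids <- as.integer(names(sizes))
    ids[order(-as.integer(sizes), sample.int(length(sizes)))]
  })
  train_clusters <- integer(0)
  n_train <- 0
  for (id in ord) {
    if (n_train >= quota) break
    train_clusters <- c(train_clusters, id)
    n_train <- n_train + sizes[[as.character(id)]]
  }
  if (length(train_clusters) == length(sizes)) {
    # never leave the test side empty
    train_clusters <- train_clusters[-length(train_clusters)]
  }
  dplyr::mutate(records,
                .cluster = cluster,
                .split = ifelse(cluster %in% train_clusters, "train", "test"))
}

#' Mutation-depth extrapolation split
#'
#' Single-point mutations form the training set; multi-point mutations
#' (depth >= 2) form the test set.
#'
#' @param records Record tibble.
#' @return `records` with a `.split` column.
#' @export
mutation_depth_split <- function(records) {
  depth <- mutation_depth(records)
  if (!any(depth == 1L)) abort("mutation depth split: no single-point records")
  if (!any(depth >= 2L)) abort("mutation depth split: no multi-point records")
  dplyr::mutate(records, .split = ifelse(depth == 1L, "train", "test"))
}
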