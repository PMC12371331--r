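# Shared fixtures: tiny records, random embeddings and parameter sets used
# across the unit tests.  Everything is generated in code under fixed seeds.

toy_record <- function(ab = c(H = "MARKSV"), ag = c(A = "TWENDY"),
                       codes = "H:R3K", ddg = 1.0, id = "TOY1") {
  complex_records(id, list(ab), list(ag), codes, ddg)
}

random_chain_fix <- function(len, seed) {
  withr::with_seed(seed, paste(sample(aa_alphabet, len, replace = TRUE),
                               collapse = ""))
}

# A random small complex record whose chains have the given lengths and one
# antibody point substitution (guaranteed to change the letter).
random_record <- function(l_ab, l_ag, seed) {
  withr::with_seed(seed, {
    ab_seq <- paste(sample(aa_alphabet, l_ab, replace = TRUE), collapse = "")
    ag_seq <- paste(sample(aa_alphabet, l_ag, replace = TRUE), collapse = "")
    pos <- sample.int(l_ab, 1L)
    wt <- substr(ab_seq, pos, pos)
    mut <- sample(setdiff(aa_alphabet, wt), 1L)
    complex_records(
      paste0("RND", seed), list(c(H = ab_seq)), list(c(A = ag_seq)),
      paste0("H:", wt, pos, mut), rnorm(1)
    )
  })
}

small_config <- function(...) {
  attention_config(d_model = 8L, n_heads = 2L, dropout = 0,
                   hidden = c(6L, 4L), ...)
}

rand_norm_params <- function(d, seed, kernel = 1L) {
  withr::with_seed(seed, list(
    gamma = runif(d, 0.5, 1.5), beta = rnorm(d, sd = 0.1),
    w = matrix(rnorm(kernel * d), kernel, d), b = rnorm(1)
  ))
}

rand_pool_params <- function(d, seed) {
  withr::with_seed(seed, list(
    gamma = runif(d, 0.5, 1.5), beta = rnorm(d, sd = 0.1),
    w = rnorm(d), b = rnorm(1)
  ))
}

rand_matrix <- function(nr, nc, seed) {
  withr::with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
}

# Random attention-map object over annotated residues (for interpretability
# tests); heads are random row-stochastic matrices.
random_attention_map <- function(lq, lk, n_heads, seed) {
  withr::with_seed(seed, {
    q_ann <- residue_annotations(c(H = paste(
      sample(aa_alphabet, lq, replace = TRUE), collapse = "")))
    k_ann <- residue_annotations(c(A = paste(
      sample(aa_alphabet, lk, replace = TRUE), collapse = "")))
    heads <- lapply(seq_len(n_heads), function(h) {
      m <- matrix(rexp(lq * lk), lq, lk)
      m / rowSums(m)
    })
    attnddg:::new_attention_map("ab_to_ag", "mt", heads, q_ann, k_ann)
  })
}
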