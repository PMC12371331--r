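# Synthetic antibody-antigen mutation datasets with a known ground truth:
# an additive per-substitution effect table plus optional cross-sequence
# interaction bonuses at designated interface pairs, and Gaussian label
# noise.  The generator emulates the shape of curated ddG benchmarks (a
# few dozen complexes, many variants per complex, mutation depths 1-7,
# a substitution alphabet biased the way alanine-scanning panels are)
# without claiming biophysical realism.

#' Frozen substitution-effect table
#'
#' A seeded draw of one additive effect `s(wt, mut)` in [-2, 2] kcal/mol
#' per ordered amino-acid pair (0 on the diagonal).  The default seed is
#' fixed so the table is identical across platforms and sessions.
#'
#' @param seed Integer seed of the draw.
#' @return 20 x 20 numeric matrix with amino-acid dimnames.
#' @export
effect_table <- function(seed = 20240901L) {
  with_local_seed(mix_seed(seed, 3L), {
    m <- matrix(runif(400, -2, 2), 20L, 20L,
                dimnames = list(aa_alphabet, aa_alphabet))
    diag(m) <- 0
    m
  })
}

#' Configure the synthetic-data generator
#'
#' @param n_complexes Number of distinct wild-type complexes.
#' @param records_per_complex Labelled variants per complex.
#' @param ab_len_range,ag_len_range Integer ranges (min, max) of antibody
#'   and antigen chain lengths; minimum 5.
#' @param depth_probs Named numeric vector over mutation depths (names in
#'   `"1"`..`"7"`), the probability of each depth.
#' @param mut_alphabet Mutant residues to draw from; the restricted default
#'   mirrors the substitution bias of alanine-scanning style panels.
#' @param p_ab Probability that a substitution falls on the antibody (the
#'   remainder land on the antigen, as general interface mutations do).
#' @param interface_size Number of antibody positions coupled to antigen
#'   partner positions.
#' @param bonus Interaction bonus b (kcal/mol): added when a mutated
#'   antibody interface position's designated antigen partner carries its
#'   trigger residue in the mutant antigen.  This cross-sequence AND is the
#'   signal purely additive models cannot fully capture.
#' @param noise_sd Gaussian label noise, kcal/mol.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @param effect_seed Seed of the frozen [effect_table()].
#' @return An `attnddg_synth_config` list.
#' @export
synth_config <- function(n_complexes = 10L, records_per_complex = 50L,
                         ab_len_range = c(15L, 25L),
                         ag_len_range = c(15L, 25L),
                         depth_probs = c(`1` = 0.8, `2` = 0.15, `3` = 0.05),
                         mut_alphabet = c("A", "G", "S", "F", "K", "E"),
                         p_ab = 0.8, interface_size = 4L, bonus = 1.5,
                         noise_sd = 0.2, seed = 1L,
                         effect_seed = 20240901L) {
  if (min(ab_len_range, ag_len_range) < 5L) abort("chain lengths must be >= 5")
  depths <- as.integer(names(depth_probs))
  if (any(is.na(depths)) || any(depths < 1L) || any(depths > 7L)) {
    abort("depth_probs names must be depths in 1..7")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (max(depths) > min(ab_len_range, ag_len_range)) {
    abort("maximum mutation depth exceeds the minimum chain length")
  }
  if (!all(mut_alphabet %in% aa_alphabet)) abort("mut_alphabet must be canonical")
  structure(
    list(n_complexes = as.integer(n_complexes),
         records_per_complex = as.integer(records_per_complex),
         ab_len_range = as.integer(ab_len_range),
         ag_len_range = as.integer(ag_len_range),
         depth_probs = depth_probs / sum(depth_probs),
         mut_alphabet = mut_alphabet, p_ab = p_ab,
         interface_size = as.integer(interface_size), bonus = bonus,
         noise_sd = noise_sd, seed = as.integer(seed),
         effect_seed = as.integer(effect_seed)),
    class = "attnddg_synth_config"
  )
}

random_chain <- function(len) paste(sample(aa_alphabet, len, replace = TRUE),
                                    collapse = "")

#' Generate a synthetic mutation dataset with known ground truth
#'
#' Labels follow `ddg = sum_m s(wt_m, mut_m) + sum_{interface} b + noise`:
#' the additive substitution effects from the frozen [effect_table()], the
#' interaction bonus for every mutated antibody interface position whose
#' antigen partner carries its trigger residue in the mutant antigen, and
#' `Normal(0, noise_sd^2)` noise.  The full decomposition is returned so
#' labels are exactly recomputable.
#'
#' @param config An [synth_config()].
#' @return List with `records` (valid record tibble) and `truth` (tibble:
#'   `record`, `additive`, `interaction`, `noise`, `ddg_true`), plus the
#'   per-complex `interface` definitions as an attribute of `truth`.
#' @export
generate_synthetic <- function(config = synth_config()) {
  eff <- effect_table(config$effect_seed)
  with_local_seed(mix_seed(config$seed, 5L), {
    rows <- list(); truths <- list(); interfaces <- list()
    rec <- 0L
    for (cx in seq_len(config$n_complexes)) {
      id <- sprintf("SYN%03d", cx)
      ab_len <- sample(config$ab_len_range[1L]:config$ab_len_range[2L], 1L)
      ag_len <- sample(config$ag_len_range[1L]:config$ag_len_range[2L], 1L)
      ab <- c(H = random_chain(ab_len))
      ag <- c(A = random_chain(ag_len))
      ag_letters <- strsplit(ag[["A"]], "", fixed = TRUE)[[1L]]
      iface <- tibble(
        ab_pos = sample.int(ab_len, config$interface_size),
        ag_pos = sample.int(ag_len, config$interface_size)
      )
      # triggers fire for about half of the wild-type complexes
      iface$trigger <- ifelse(
        runif(config$interface_size) < 0.5,
        ag_letters[iface$ag_pos],
        sample(aa_alphabet, config$interface_size, replace = TRUE)
      )
      interfaces[[id]] <- iface
      for (r in seq_len(config$records_per_complex)) {
        rec <- rec + 1L
        depth <- as.integer(sample(names(config$depth_probs), 1L,
                                   prob = config$depth_probs))
        on_ab <- runif(depth) < config$p_ab
        n_ab <- sum(on_ab); n_ag <- depth - n_ab
        ab_pos <- if (n_ab > 0L) sample.int(ab_len, n_ab) else integer(0)
        ag_pos <- if (n_ag > 0L) sample.int(ag_len, n_ag) else integer(0)
        muts <- dplyr::bind_rows(
          if (n_ab > 0L) tibble(chain = "H", pos = ab_pos) else NULL,
          if (n_ag > 0L) tibble(chain = "A", pos = ag_pos) else NULL
        )
        muts$wt <- vapply(seq_len(nrow(muts)), function(j) {
          s <- if (muts$chain[j] == "H") ab[["H"]] else ag[["A"]]
          substr(s, muts$pos[j], muts$pos[j])
        }, character(1L))
        muts$mut <- vapply(muts$wt, function(w) {
          pool <- setdiff(config$mut_alphabet, w)
          sample(pool, 1L)
        }, character(1L), USE.NAMES = FALSE)
        muts <- muts[, c("chain", "wt", "pos", "mut")]
        additive <- sum(eff[cbind(muts$wt, muts$mut)])
        mt_ag <- apply_mutations(ag, muts[muts$chain == "A", , drop = FALSE])
        mt_ag_letters <- strsplit(mt_ag[["A"]], "", fixed = TRUE)[[1L]]
        hit <- iface$ab_pos %in% muts$pos[muts$chain == "H"] &
          mt_ag_letters[iface$ag_pos] == iface$trigger
        interaction <- config$bonus * sum(hit)
        noise <- rnorm(1L, 0, config$noise_sd)
        rows[[rec]] <- complex_records(
          complex_id = id, ab_chains = list(ab), ag_chains = list(ag),
          mutations = list(muts), ddg = additive + interaction + noise
        )
        truths[[rec]] <- tibble(record = rec, additive = additive,
                                interaction = interaction, noise = noise,
                                ddg_true = additive + interaction)
      }
    }
    truth <- dplyr::bind_rows(truths)
    attr(truth, "interfaces") <- interfaces
    list(records = dplyr::bind_rows(rows), truth = truth)
  })
}

#' Generate records with built-in sequence-identity cluster structure
#'
#' Draws `n_clusters` unrelated prototype complexes and, within each
#' cluster, copies whose sequences differ from the prototype at no more
#' than a `divergence` fraction of positions; each member carries one
#' random labelled substitution.  Used to exercise the identity split:
#' within-cluster identity stays near `1 - divergence`, across-cluster
#' identity stays near the ~5% background of unrelated sequences.
#'
#' @param n_clusters Number of clusters (>= 2).
#' @param members_per_cluster Records per cluster.
#' @param chain_len Length of the (single) antibody and antigen chains.
#' @param divergence Maximum fraction of positions mutated away from the
#'   prototype, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Record tibble with a `.cluster_truth` column.
#' @export
make_identity_clusters <- function(n_clusters = 4L, members_per_cluster = 5L,
                                   chain_len = 60L, divergence = 0.1,
                                   seed = 1L) {
  if (n_clusters < 2L) abort("need at least 2 clusters")
  if (divergence < 0 || divergence >= 1) abort("divergence must be in [0, 1)")
  diverge <- function(seq) {
    n_mut <- floor(divergence * nchar(seq))
    if (n_mut == 0L) return(seq)
    pos <- sample.int(nchar(seq), n_mut)
    for (p in pos) substr(seq, p, p) <- sample(aa_alphabet, 1L)
    seq
  }
  with_local_seed(mix_seed(seed, 23L), {
    rows <- list(); k <- 0L
    for (cl in seq_len(n_clusters)) {
      proto_ab <- random_chain(chain_len)
      proto_ag <- random_chain(chain_len)
      for (m in seq_len(members_per_cluster)) {
        k <- k + 1L
        ab <- c(H = diverge(proto_ab))
        ag <- c(A = diverge(proto_ag))
        pos <- sample.int(chain_len, 1L)
        wt <- substr(ab[["H"]], pos, pos)
        mut <- sample(setdiff(aa_alphabet, wt), 1L)
        rows[[k]] <- dplyr::mutate(
          complex_records(
            complex_id = sprintf("CL%02d_%02d", cl, m),
            ab_chains = list(ab), ag_chains = list(ag),
            mutations = list(tibble(chain = "H", wt = wt, pos = pos,
                                    mut = mut)),
            ddg = rnorm(1L)
          ),
          .cluster_truth = cl)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the CSV dialect [read_mutation_dataset()] reads plus the ground
#' truth as JSON.
#'
#' @param synth Result of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mutation_dataset(synth$records, file.path(dir, "records.csv"))
  jsonlite::write_json(synth$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
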