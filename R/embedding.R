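# Frozen per-residue embeddings behind a pluggable embedder contract.
#
# The mock embedder makes the whole pipeline testable offline: each row is
# v(letter) + position_scale * u(position), seeded pseudo-random vectors, so
# a point substitution perturbs exactly one row while the substitution
# signal itself (v(mut) - v(wt)) is identical wherever the substitution
# occurs.  The default position_scale of 0 keeps rows position-independent,
# mirroring how real protein-language-model states are dominated by residue
# identity; positions still enter the model through the rotary embedding of
# queries and keys.  It is a test double, not a scientific claim.
# Pre-trained protein-language-model backends plug in through `kind = "plm"`
# with a user-supplied encoder function.

.embed_cache <- new.env(parent = emptyenv())
.embed_stats <- new.env(parent = emptyenv())
.embed_stats$calls <- 0L

#' Specify an embedder
#'
#' @param kind `"mock"` (deterministic offline embedder) or `"plm"`
#'   (pre-trained protein language model adapter; supply `fun`).
#' @param d Output embedding dimension; must be even (rotary position
#'   embedding pairs dimensions) and at least 2.
#' @param seed Integer seed for the mock embedder.
#' @param position_scale Mock embedder only: relative amplitude of an
#'   additive per-position pseudo-random component.  The default 0 keeps
#'   rows position-independent (per-residue identity only), which is what
#'   makes substitution effects transferable across positions; raise it to
#'   give every (residue, position) cell a distinct embedding.
#' @param model_id Identifier of the pre-trained backend (plm kind only).
#' @param fun For `kind = "plm"`: a function `(sequence_string) -> L x d
#'   matrix` of per-residue states with any special tokens already stripped.
#' @param max_len Context limit of the backend; longer sequences raise an
#'   explicit length error (no silent truncation).
#' @return An `attnddg_embedder_spec` object.  The embedder is always
#'   frozen: no gradient ever flows into it during training.
#' @export
embedder_spec <- function(kind = c("mock", "plm"), d = 32L, seed = 1L,
                          position_scale = 0, model_id = NULL, fun = NULL,
                          max_len = Inf) {
  kind <- match.arg(kind)
  d <- as.integer(d)
  if (d < 2L || d %% 2L != 0L) abort("embedding dimension d must be even and >= 2")
  if (position_scale < 0) abort("position_scale must be non-negative")
  if (kind == "plm" && !is.function(fun)) {
    abort(glue("no encoder registered for pre-trained backend ",
               "'{model_id %||% '<unnamed>'}': supply `fun`"))
  }
  structure(
    list(kind = kind, d = d, seed = as.integer(seed),
         position_scale = position_scale, model_id = model_id,
         fun = fun, max_len = max_len, frozen = TRUE),
    class = "attnddg_embedder_spec"
  )
}

spec_digest <- function(spec) {
  digest::digest(list(spec$kind, spec$d, spec$seed, spec$position_scale,
                      spec$model_id))
}

# Deterministic per-cell RNG that leaves the caller's RNG state untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

mix_seed <- function(...) {
  v <- c(...)
  h <- 104729
  for (x in v) h <- (h * 69069 + as.numeric(x) * 2654435761) %% 2147483647
  as.integer(h)
}

mock_letter_vectors <- function(spec) {
  with_local_seed(mix_seed(spec$seed, 1L), {
    m <- matrix(rnorm(length(aa_letters_ok) * spec$d), nrow = length(aa_letters_ok))
    rownames(m) <- aa_letters_ok
    m
  })
}

mock_position_vector <- function(spec, pos) {
  with_local_seed(mix_seed(spec$seed, 2L, pos), rnorm(spec$d))
}

mock_embed <- function(residues, spec) {
  letters <- strsplit(residues, "", fixed = TRUE)[[1L]]
  V <- mock_letter_vectors(spec)
  H <- unname(V[letters, , drop = FALSE])
  if (spec$position_scale > 0) {
    U <- t(vapply(seq_along(letters),
                  function(p) mock_position_vector(spec, p),
                  numeric(spec$d)))
    H <- H + spec$position_scale * U
  }
  H
}

#' Embed one protein sequence
#'
#' Returns the L x d per-residue embedding matrix for the sequence under the
#' given spec.  Results are a pure function of `(residues, spec)`; repeated
#' calls with caching enabled perform a single backend call.
#'
#' @param seq Residue string (validated with [validate_sequence()]).
#' @param spec An [embedder_spec()].
#' @param cache Use the in-memory embedding cache (default `TRUE`).
#' @param cache_dir Optional directory for an on-disk cache (content-addressed
#'   by the digest of sequence and spec); corrupted entries are recomputed
#'   with a warning.
#' @return L x d numeric matrix.
#' @export
embed_sequence <- function(seq, spec, cache = TRUE, cache_dir = NULL) {
  stopifnot(inherits(spec, "attnddg_embedder_spec"))
  seq <- validate_sequence(seq)
  L <- nchar(seq)
  if (L > spec$max_len) {
    abort(glue("sequence of length {L} exceeds the backend context limit ",
               "({spec$max_len}); refusing to truncate"))
  }
  key <- digest::digest(list(seq, spec_digest(spec)))
  if (cache && !is.null(.embed_cache[[key]])) return(.embed_cache[[key]])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      hit <- tryCatch(readRDS(f), error = function(e) NULL)
      if (is.matrix(hit) && nrow(hit) == L && ncol(hit) == spec$d &&
          all(is.finite(hit))) {
        if (cache) .embed_cache[[key]] <- hit
        return(hit)
      }
      warn(glue("corrupted embedding cache entry {basename(f)}; recomputing"))
    }
  }
  .embed_stats$calls <- .embed_stats$calls + 1L
  H <- switch(spec$kind,
    mock = mock_embed(seq, spec),
    plm = {
      out <- spec$fun(seq)
      if (!is.matrix(out) || nrow(out) != L) {
        abort(glue("backend returned {NROW(out)} rows for a {L}-residue ",
                   "sequence; strip special tokens in the adapter"))
      }
      unname(out)
    }
  )
  if (!all(is.finite(H))) abort("embedder produced non-finite values")
  if (cache) .embed_cache[[key]] <- H
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache_dir, paste0(key, ".rds"))
    saveRDS(H, f)
    jsonlite::write_json(
      list(sequence_length = L, d = spec$d, kind = spec$kind,
           digest = key),
      file.path(cache_dir, paste0(key, ".json")), auto_unbox = TRUE)
  }
  H
}

#' Reset the in-memory embedding cache and call counter
#' @export
clear_embedding_cache <- function() {
  rm(list = ls(.embed_cache), envir = .embed_cache)
  .embed_stats$calls <- 0L
  invisible(NULL)
}

#' Number of backend embedding computations since the last cache reset
#' @export
embedding_call_count <- function() .embed_stats$calls

#' Embed the four sequences of one mutation record
#'
#' Serialises each side by concatenating its chains in listed order, applies
#' the record's substitutions to obtain the mutant sequences, and embeds
#' wild-type and mutant antibody and antigen.  A side without mutations
#' yields identical wild-type and mutant matrices (the same object).
#'
#' @param record One-row record tibble.
#' @param spec An [embedder_spec()].
#' @param cache,cache_dir Passed to [embed_sequence()].
#' @return List with matrices `ab_wt`, `ag_wt`, `ab_mt`, `ag_mt`, plus
#'   `ab_annot`/`ag_annot` residue annotation tibbles.
#' @export
embed_complex <- function(record, spec, cache = TRUE, cache_dir = NULL) {
  ab <- record$ab_chains[[1L]]; ag <- record$ag_chains[[1L]]
  mt <- mutant_chains(record)
  ab_wt_seq <- concat_chains(ab); ag_wt_seq <- concat_chains(ag)
  ab_mt_seq <- concat_chains(mt$ab); ag_mt_seq <- concat_chains(mt$ag)
  H_ab_wt <- embed_sequence(ab_wt_seq, spec, cache, cache_dir)
  H_ag_wt <- embed_sequence(ag_wt_seq, spec, cache, cache_dir)
  H_ab_mt <- if (identical(ab_mt_seq, ab_wt_seq)) H_ab_wt else
    embed_sequence(ab_mt_seq, spec, cache, cache_dir)
  H_ag_mt <- if (identical(ag_mt_seq, ag_wt_seq)) H_ag_wt else
    embed_sequence(ag_mt_seq, spec, cache, cache_dir)
  list(
    ab_wt = H_ab_wt, ag_wt = H_ag_wt, ab_mt = H_ab_mt, ag_mt = H_ag_mt,
    ab_annot = residue_annotations(ab),
    ag_annot = residue_annotations(ag)
  )
}
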