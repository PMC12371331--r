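# AB-bind / SKEMPI style mutation tables: the in-memory record container,
# validation with a rejection report, and CSV round-tripping.

#' Build a table of labelled mutation records
#'
#' The central container is an ordinary tibble with one row per labelled
#' variant:
#' \describe{
#'   \item{complex_id}{character, e.g. a PDB code.}
#'   \item{ab_chains}{list column of named character vectors: antibody
#'     chain id -> wild-type sequence, in listed order.}
#'   \item{ag_chains}{list column, likewise for the antigen.}
#'   \item{mutations}{list column of tibbles (`chain`, `wt`, `pos`, `mut`),
#'     1-7 substitutions per record.}
#'   \item{ddg}{numeric ddG label, kcal/mol (positive = weakened binding).}
#' }
#'
#' @param complex_id Character vector.
#' @param ab_chains,ag_chains Lists of named character vectors (or a single
#'   named vector recycled).
#' @param mutations List of mutation tibbles, or character vector of
#'   `;`-separated mutation codes.
#' @param ddg Numeric labels, kcal/mol.
#' @return A tibble of records (unvalidated; see [validate_records()]).
#' @export
complex_records <- function(complex_id, ab_chains, ag_chains, mutations, ddg) {
  n <- length(complex_id)
  if (!is.list(ab_chains) || !is.null(names(ab_chains)) && is.character(ab_chains[[1]]) && length(ab_chains) != n) {
    # allow a single named vector for all rows
  }
  norm_chains <- function(x) {
    if (is.character(x)) x <- list(x)
    if (length(x) == 1L && n > 1L) x <- rep(x, n)
    x
  }
  ab_chains <- norm_chains(ab_chains)
  ag_chains <- norm_chains(ag_chains)
  if (is.character(mutations)) mutations <- lapply(mutations, parse_mutation_codes)
  if (length(mutations) == 1L && n > 1L) mutations <- rep(mutations, n)
  tibble(
    complex_id = as.character(complex_id),
    ab_chains = ab_chains,
    ag_chains = ag_chains,
    mutations = mutations,
    ddg = as.numeric(ddg)
  )
}

validate_one_record <- function(row) {
  ab <- row$ab_chains[[1L]]; ag <- row$ag_chains[[1L]]
  muts <- row$mutations[[1L]]
  tryCatch({
    if (length(intersect(names(ab), names(ag))) > 0L) {
      abort("antibody and antigen share a chain id")
    }
    for (s in c(ab, ag)) validate_sequence(s)
    if (nrow(muts) < 1L) abort("record has no mutations")
    all_chains <- c(ab, ag)
    apply_mutations(all_chains, muts)  # errors on wt mismatch / range
    NA_character_
  }, error = function(e) conditionMessage(e))
}

#' Validate mutation records, collecting rejections
#'
#' Checks every record against the container invariants: valid sequences,
#' disjoint chain ids, mutation depth >= 1, every mutation matching an
#' existing chain with the stated wild-type residue at the stated position.
#' Failing records are not dropped silently: they are returned in a
#' rejection report with the failure reason.
#'
#' @param records A record tibble (see [complex_records()]).
#' @return A list with `records` (the valid rows) and `rejections`
#'   (tibble: `row`, `complex_id`, `reason`).
#' @export
validate_records <- function(records) {
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    validate_one_record(records[i, ])
  }, character(1L))
  bad <- !is.na(reasons)
  list(
    records = records[!bad, , drop = FALSE],
    rejections = tibble(
      row = which(bad),
      complex_id = records$complex_id[bad],
      reason = reasons[bad]
    )
  )
}

#' Mutation depth of each record
#'
#' @param records A record tibble.
#' @return Integer vector: number of substitutions per record.
#' @export
mutation_depth <- function(records) {
  vapply(records$mutations, nrow, integer(1L))
}

#' Mutant chains of one record
#'
#' Applies the record's substitutions to its wild-type chains.
#'
#' @param record One-row record tibble (or a row extracted with `[i, ]`).
#' @return List with `ab` and `ag` named chain vectors after mutation.
#' @export
mutant_chains <- function(record) {
  ab <- record$ab_chains[[1L]]; ag <- record$ag_chains[[1L]]
  muts <- record$mutations[[1L]]
  all_mut <- apply_mutations(c(ab, ag), muts)
  list(
    ab = all_mut[seq_along(ab)],
    ag = all_mut[length(ab) + seq_along(ag)]
  )
}

# Serialise a multi-chain side as one sequence (concatenation in listed
# order); offsets let per-chain mutation positions map to global positions.
chain_offsets <- function(chains) {
  lens <- nchar(chains)
  setNames(cumsum(c(0L, lens[-length(lens)])), names(chains))
}

concat_chains <- function(chains) paste(chains, collapse = "")

# Residue annotations (chain, within-chain position, aa) for a concatenated
# side; used by the interpretability module.
residue_annotations <- function(chains) {
  dplyr::bind_rows(lapply(names(chains), function(id) {
    letters <- strsplit(chains[[id]], "", fixed = TRUE)[[1L]]
    tibble(chain = id, pos = seq_along(letters), aa = letters,
           label = paste0(id, ":", seq_along(letters), letters))
  }))
}

default_col_map <- function() {
  list(
    complex_id = "complex_id",
    ab_chain_ids = "ab_chain_ids", ab_seqs = "ab_seqs",
    ag_chain_ids = "ag_chain_ids", ag_seqs = "ag_seqs",
    mutations = "mutations", ddg = "ddg"
  )
}

split_fields <- function(ids, seqs) {
  id_v <- trimws(strsplit(ids, ";", fixed = TRUE)[[1L]])
  seq_v <- trimws(strsplit(seqs, ";", fixed = TRUE)[[1L]])
  if (length(id_v) != length(seq_v)) {
    abort("chain id list and sequence list have different lengths")
  }
  setNames(seq_v, id_v)
}

#' Read an AB-bind/SKEMPI-style mutation CSV
#'
#' Expected columns (remappable through `col_map`): `complex_id`,
#' `ab_chain_ids` / `ab_seqs` and `ag_chain_ids` / `ag_seqs`
#' (`;`-separated for multi-chain sides), `mutations` (`;`-separated
#' `CHAIN:WposM` codes) and `ddg` (kcal/mol, `.` decimal separator).
#' Rows that fail parsing or record validation are collected into the
#' rejection report rather than dropped.
#'
#' @param path CSV file path (UTF-8).
#' @param col_map Named list mapping the canonical column roles to the
#'   file's column names; defaults to the canonical names.
#' @return List with `records` (valid record tibble) and `rejections`.
#' @export
read_mutation_dataset <- function(path, col_map = NULL) {
  col_map <- modifyList(default_col_map(), col_map %||% list())
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unlist(col_map), names(raw))
  if (length(missing) > 0L) {
    abort(glue("dataset is missing required column(s): {paste(missing, collapse = ', ')}"))
  }
  rows <- vector("list", nrow(raw))
  rej <- list()
  for (i in seq_len(nrow(raw))) {
    rows[[i]] <- tryCatch({
      ddg_val <- suppressWarnings(as.numeric(raw[[col_map$ddg]][i]))
      if (is.na(ddg_val)) abort("unreadable ddG label")
      complex_records(
        complex_id = raw[[col_map$complex_id]][i],
        ab_chains = list(split_fields(raw[[col_map$ab_chain_ids]][i],
                                      raw[[col_map$ab_seqs]][i])),
        ag_chains = list(split_fields(raw[[col_map$ag_chain_ids]][i],
                                      raw[[col_map$ag_seqs]][i])),
        mutations = list(parse_mutation_codes(raw[[col_map$mutations]][i])),
        ddg = ddg_val
      )
    }, error = function(e) {
      rej[[length(rej) + 1L]] <<- tibble(
        row = i, complex_id = raw[[col_map$complex_id]][i],
        reason = conditionMessage(e))
      NULL
    })
  }
  parsed <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1L))])
  checked <- if (nrow(parsed) > 0L) validate_records(parsed) else
    list(records = parsed, rejections = tibble(row = integer(),
                                               complex_id = character(),
                                               reason = character()))
  # validate_records() reports row indices within the parsed subset; map back
  if (nrow(checked$rejections) > 0L) {
    kept_rows <- which(vapply(rows, Negate(is.null), logical(1L)))
    checked$rejections$row <- kept_rows[checked$rejections$row]
  }
  list(records = checked$records,
       rejections = dplyr::bind_rows(rej, checked$rejections))
}

#' Write mutation records to the CSV dialect read_mutation_dataset() reads
#'
#' @param records Valid record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_dataset <- function(records, path) {
  out <- tibble(
    complex_id = records$complex_id,
    ab_chain_ids = vapply(records$ab_chains, function(x) paste(names(x), collapse = ";"), character(1L)),
    ab_seqs = vapply(records$ab_chains, function(x) paste(x, collapse = ";"), character(1L)),
    ag_chain_ids = vapply(records$ag_chains, function(x) paste(names(x), collapse = ";"), character(1L)),
    ag_seqs = vapply(records$ag_chains, function(x) paste(x, collapse = ";"), character(1L)),
    mutations = vapply(records$mutations, format_mutation_codes, character(1L)),
    ddg = records$ddg
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a rejection report as JSON
#'
#' @param rejections Rejection tibble from [read_mutation_dataset()] or
#'   [validate_records()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejections, path) {
  jsonlite::write_json(rejections, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings for named amino-acid sequence sets.
#'
#' @param path FASTA file path.
#' @return `read_fasta_chains()` returns a named character vector.
#' @export
read_fasta_chains <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta_chains
#' @param chains Named character vector of sequences.
#' @export
write_fasta_chains <- function(chains, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(chains), path)
  invisible(path)
}
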