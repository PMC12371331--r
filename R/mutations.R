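# Sequence handling, mutation codes and the thermodynamic identities that
# define the ddG label.

#' The 20 canonical amino-acid one-letter codes
#'
#' `X` is additionally accepted in sequences as an unknown-residue
#' placeholder, but never as a wild-type or mutant letter in a mutation code.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

aa_letters_ok <- c(aa_alphabet, "X")

#' Validate and normalise a protein sequence
#'
#' Upper-cases the sequence and checks that it only contains the 20 canonical
#' amino-acid letters plus `X`, and that it is non-empty.
#'
#' @param x Character scalar, the residue string.
#' @param what Label used in error messages.
#' @return The normalised (upper-case) sequence, invisibly classified.
#' @export
validate_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(glue("{what} must be a single character string"))
  }
  x <- toupper(x)
  if (nchar(x) < 1L) abort(glue("{what} must contain at least one residue"))
  letters <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters), aa_letters_ok)
  if (length(bad) > 0L) {
    abort(glue(
      "{what} contains non-amino-acid letters: {paste(bad, collapse = ', ')}"
    ))
  }
  x
}

empty_mutation_table <- function() {
  tibble(
    chain = character(), wt = character(),
    pos = integer(), mut = character()
  )
}

#' Parse a single mutation code
#'
#' Mutation codes use the `CHAIN:WposM` dialect, e.g. `"A:R53Q"` for an
#' arginine-to-glutamine substitution at position 53 of chain A.  Positions
#' are 1-based indices into the chain sequence as supplied; no structure-based
#' renumbering is performed.
#'
#' @param code Character scalar, e.g. `"A:R53Q"`.
#' @return A one-row tibble with columns `chain`, `wt`, `pos`, `mut`.
#' @examples
#' parse_mutation_code("A:R53Q")
#' @export
parse_mutation_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    abort("mutation code must be a single character string")
  }
  m <- regmatches(code, regexec("^([A-Za-z0-9]+):([A-Z])([0-9]+)([A-Z])$",
                                toupper(trimws(code))))[[1L]]
  if (length(m) != 5L) {
    abort(glue("malformed mutation code: '{code}' (expected CHAIN:WposM)"))
  }
  wt <- m[3L]; pos <- suppressWarnings(as.integer(m[4L])); mut <- m[5L]
  if (!wt %in% aa_alphabet) {
    abort(glue("mutation code '{code}': unknown wild-type residue '{wt}'"))
  }
  if (!mut %in% aa_alphabet) {
    abort(glue("mutation code '{code}': unknown mutant residue '{mut}'"))
  }
  if (is.na(pos) || pos < 1L) {
    abort(glue("mutation code '{code}': position must be a positive integer"))
  }
  if (wt == mut) {
    abort(glue("mutation code '{code}': wild-type and mutant residue are identical"))
  }
  tibble(chain = m[2L], wt = wt, pos = pos, mut = mut)
}

#' Parse a semicolon-separated list of mutation codes
#'
#' @param codes Character scalar such as `"A:R53Q;A:S91A"`, or `""`/`NA` for
#'   no mutations.
#' @return A tibble with one row per substitution (columns `chain`, `wt`,
#'   `pos`, `mut`).
#' @export
parse_mutation_codes <- function(codes) {
  if (length(codes) != 1L) abort("parse_mutation_codes() takes one string")
  if (is.na(codes) || !nzchar(trimws(codes))) return(empty_mutation_table())
  parts <- strsplit(codes, ";", fixed = TRUE)[[1L]]
  dplyr::bind_rows(lapply(trimws(parts), parse_mutation_code))
}

#' Format a mutation table back into its code string
#'
#' Inverse of [parse_mutation_codes()]: `format_mutation_codes(parse_mutation_codes(x))`
#' returns `x` up to whitespace.
#'
#' @param mutations Tibble with columns `chain`, `wt`, `pos`, `mut`.
#' @return A single `;`-separated code string (empty string for no rows).
#' @export
format_mutation_codes <- function(mutations) {
  if (nrow(mutations) == 0L) return("")
  paste0(mutations$chain, ":", mutations$wt, mutations$pos, mutations$mut,
         collapse = ";")
}

#' Apply substitutions to a set of chains
#'
#' Chains are a named character vector (names are chain ids, values residue
#' strings).  Every mutation must name an existing chain, fall inside the
#' chain, and agree with the wild-type residue found there; otherwise a
#' validation error reports the chain, the position and the expected versus
#' found residue.  Input chains are not modified; an empty mutation table
#' returns the input unchanged.
#'
#' @param chains Named character vector of chain sequences.
#' @param mutations Tibble as returned by [parse_mutation_codes()].
#' @return Named character vector of mutated chains, same order and names.
#' @examples
#' apply_mutations(c(A = "MARKS"), parse_mutation_code("A:R3K"))
#' @export
apply_mutations <- function(chains, mutations) {
  if (is.null(names(chains)) || any(!nzchar(names(chains)))) {
    abort("chains must be a named character vector")
  }
  out <- vapply(chains, validate_sequence, character(1L))
  if (nrow(mutations) == 0L) return(out)
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chain[i]; pos <- mutations$pos[i]
    wt <- mutations$wt[i]; mut <- mutations$mut[i]
    hit <- which(names(out) == ch)
    if (length(hit) == 0L) abort(glue("mutation chain '{ch}' not found"))
    if (length(hit) > 1L) abort(glue("mutation chain '{ch}' is ambiguous"))
    seq <- out[[hit]]
    if (pos > nchar(seq)) {
      abort(glue("mutation {ch}:{wt}{pos}{mut}: position {pos} is out of range ",
                 "(chain '{ch}' has {nchar(seq)} residues)"))
    }
    found <- substr(seq, pos, pos)
    if (found != wt) {
      abort(glue("wt mismatch at chain '{ch}' position {pos}: ",
                 "expected '{wt}', found '{found}'"))
    }
    substr(seq, pos, pos) <- mut
    out[[hit]] <- seq
  }
  out
}

#' Thermodynamic constants for free-energy conversion
#'
#' Defaults are the gas constant in kcal mol^-1 K^-1 and 25 degrees C in
#' Kelvin; both can be overridden.
#'
#' @param R Gas constant, kcal mol^-1 K^-1 (> 0).
#' @param T Absolute temperature, Kelvin (> 0).
#' @return A list with elements `R` and `T`.
#' @export
thermo_constants <- function(R = 0.0019872, T = 298.15) {
  if (!is.numeric(R) || R <= 0) abort("R must be positive")
  if (!is.numeric(T) || T <= 0) abort("T must be positive")
  list(R = R, T = T)
}

#' Binding free energy from a dissociation constant
#'
#' Computes `dG = -RT * log(1 / Kd) = RT * log(Kd)` in kcal/mol.  Lower Kd
#' (tighter binding) gives a more negative dG.
#'
#' @param kd Dissociation constant(s), must be > 0 (same molar units as the
#'   standard state implicit in the label source).
#' @param const Constants from [thermo_constants()].
#' @return Numeric vector of free energies, kcal/mol.
#' @examples
#' delta_g(1e-9)  # about -12.3 kcal/mol at 298.15 K
#' @export
delta_g <- function(kd, const = thermo_constants()) {
  if (!is.numeric(kd) || any(is.na(kd)) || any(kd <= 0)) {
    abort("kd must be positive")
  }
  const$R * const$T * log(kd)
}

#' Binding free-energy change upon mutation
#'
#' `ddG = dG_mut - dG_wild`; positive values indicate weakened binding.
#'
#' @param dg_mut,dg_wild Free energies of the mutant and wild-type complex,
#'   kcal/mol.
#' @return `dg_mut - dg_wild`.
#' @export
ddg <- function(dg_mut, dg_wild) dg_mut - dg_wild
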