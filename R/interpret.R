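# Attention-weight interpretability: extract cross-attention maps for a
# record, rank the antigen residues most attended from a mutated antibody
# position (and vice versa), and serialise heatmap tables.

new_attention_map <- function(direction, variant, heads, query_annot,
                              key_annot) {
  mean_mat <- Reduce(`+`, heads) / length(heads)
  rownames(mean_mat) <- query_annot$label
  colnames(mean_mat) <- key_annot$label
  structure(
    list(direction = direction, variant = variant, heads = heads,
         mean = mean_mat, query_annot = query_annot, key_annot = key_annot),
    class = "attnddg_attention_map"
  )
}

#' @export
print.attnddg_attention_map <- function(x, ...) {
  cat(glue("<attention map {x$direction}, {x$variant}: ",
           "{nrow(x$mean)} x {ncol(x$mean)}, {length(x$heads)} heads>"), "\n")
  invisible(x)
}

#' Extract cross-attention maps for one record
#'
#' Runs the fitted model on the record and returns the four attention maps
#' (antibody-to-antigen and antigen-to-antibody, each for the wild-type and
#' the mutant complex), annotated with chain/position/residue labels.  The
#' head-averaged matrix is row-stochastic like each per-head matrix.
#'
#' @param fit An `attnddg_fit` with `variant = "full"` (ablated variants
#'   carry no attention weights and raise a capability error).
#' @param record One-row record tibble.
#' @return Named list of `attnddg_attention_map` objects:
#'   `ab_to_ag_wt`, `ag_to_ab_wt`, `ab_to_ag_mt`, `ag_to_ab_mt`.
#' @export
extract_attention <- function(fit, record) {
  if (fit$config$variant != "full") {
    abort(glue("model variant '{fit$config$variant}' has no attention ",
               "weights to extract"))
  }
  E <- embed_complex(record, fit$spec)
  state <- forward_complex(E, fit$params, fit$config)$state
  mt <- mutant_chains(record)
  ann <- list(
    ab_wt = residue_annotations(record$ab_chains[[1L]]),
    ag_wt = residue_annotations(record$ag_chains[[1L]]),
    ab_mt = residue_annotations(mt$ab),
    ag_mt = residue_annotations(mt$ag)
  )
  list(
    ab_to_ag_wt = new_attention_map("ab_to_ag", "wt", state$attention$ab_wt,
                                    ann$ab_wt, ann$ag_wt),
    ag_to_ab_wt = new_attention_map("ag_to_ab", "wt", state$attention$ag_wt,
                                    ann$ag_wt, ann$ab_wt),
    ab_to_ag_mt = new_attention_map("ab_to_ag", "mt", state$attention$ab_mt,
                                    ann$ab_mt, ann$ag_mt),
    ag_to_ab_mt = new_attention_map("ag_to_ab", "mt", state$attention$ag_mt,
                                    ann$ag_mt, ann$ab_mt)
  )
}

resolve_focal <- function(map, focal) {
  if (is.numeric(focal) && length(focal) == 1L) {
    idx <- as.integer(focal)
  } else if (is.list(focal)) {
    idx <- which(map$query_annot$chain == focal$chain &
                   map$query_annot$pos == focal$pos)
  } else {
    abort("focal must be a row index or list(chain =, pos =)")
  }
  if (length(idx) != 1L || is.na(idx) || idx < 1L ||
      idx > nrow(map$query_annot)) {
    abort("focal position not found on the map's query axis")
  }
  idx
}

#' Rank the partner residues most attended from a focal position
#'
#' Reads the focal row of the head-averaged attention matrix and returns
#' the `k` partner residues with the highest weights.  When a contrast map
#' (typically the wild-type map for a mutant-complex focal row) is
#' supplied, the per-partner weight difference (map minus contrast) is
#' reported as `delta`.
#'
#' @param map An `attnddg_attention_map`.
#' @param focal Query-row locator: integer index or `list(chain =, pos =)`.
#' @param k Number of partners to report; clamped to the key length.
#' @param contrast Optional second map on the same axes.
#' @return Tibble: `rank`, `chain`, `pos`, `aa`, `label`, `score`, `delta`.
#' @export
top_interactions <- function(map, focal, k = 5L, contrast = NULL) {
  if (k < 1L) abort("k must be at least 1")
  idx <- resolve_focal(map, focal)
  row <- map$mean[idx, ]
  delta <- if (!is.null(contrast)) {
    if (!all(dim(contrast$mean) == dim(map$mean))) {
      abort("contrast map has different axes")
    }
    row - contrast$mean[idx, ]
  } else rep(NA_real_, length(row))
  ord <- order(row, decreasing = TRUE)
  k <- min(as.integer(k), length(row))
  take <- ord[seq_len(k)]
  tibble(
    rank = seq_len(k),
    chain = map$key_annot$chain[take],
    pos = map$key_annot$pos[take],
    aa = map$key_annot$aa[take],
    label = map$key_annot$label[take],
    score = unname(row[take]),
    delta = unname(delta[take])
  )
}

#' Export an attention map as a TSV heatmap table
#'
#' Writes the head-averaged matrix with query labels as the first column
#' and key labels as the header; [read_heatmap_table()] restores it
#' losslessly to numeric precision.
#'
#' @param map An `attnddg_attention_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(map, path) {
  df <- as.data.frame(map$mean)
  out <- dplyr::bind_cols(tibble(query = rownames(map$mean)), df)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_heatmap_table
#' @export
read_heatmap_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    query = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$query
  m
}

#' Interaction report for a record's mutation sites
#'
#' For each mutated antibody (or antigen) position, ranks the partner
#' residues by mutant-complex attention and reports the mutant-minus-wild
#' weight shift, mirroring case-study analyses of attended antigen
#' positions around a mutated antibody site.
#'
#' @param fit A fitted full-variant model.
#' @param record One-row record tibble.
#' @param k Partners per mutation site.
#' @return Tibble with one block of rows per mutation
#'   (`mutation`, then the [top_interactions()] columns).
#' @export
interaction_report <- function(fit, record, k = 5L) {
  maps <- extract_attention(fit, record)
  muts <- record$mutations[[1L]]
  ab_ids <- names(record$ab_chains[[1L]])
  dplyr::bind_rows(lapply(seq_len(nrow(muts)), function(i) {
    m <- muts[i, ]
    on_ab <- m$chain %in% ab_ids
    mt_map <- if (on_ab) maps$ab_to_ag_mt else maps$ag_to_ab_mt
    wt_map <- if (on_ab) maps$ab_to_ag_wt else maps$ag_to_ab_wt
    contrast <- if (all(dim(wt_map$mean) == dim(mt_map$mean))) wt_map
    rep_i <- top_interactions(mt_map, list(chain = m$chain, pos = m$pos), k,
                              contrast = contrast)
    dplyr::mutate(rep_i,
                  mutation = paste0(m$chain, ":", m$wt, m$pos, m$mut),
                  .before = 1L)
  }))
}
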