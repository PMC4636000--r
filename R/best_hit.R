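#' @title Best-hit taxonomic classification
#' @description Percent-identity best-hit assignment of each metagenomic
#'   homolog against the HMM's reference homolog subset, computed on
#'   match-state columns.
#' @name best_hit
NULL

row_chars <- function(row) strsplit(row, "")[[1]]

#' Percent identity between two match-state alignment rows
#'
#' `100 * (identical residue columns) / (columns where both rows are
#' non-gap)`; 0 when the overlap is empty. Both rows must come from the
#' same profile's match-state alignment (equal width).
#'
#' @param query_row,reference_row Width-M alignment row strings (`-` = gap).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(query_row, reference_row) {
  a <- row_chars(query_row); b <- row_chars(reference_row)
  stopifnot(length(a) == length(b))
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (!n) return(0)
  100 * sum(a[both] == b[both]) / n
}

#' Classify a query by its best reference hit
#'
#' The best reference maximizes match-column percent identity; ties are
#' broken by the reference's own bit score against the HMM (higher first),
#' then lexicographic reference id. Queries whose best identity falls below
#' `identity_floor` are Unclassified — mirroring the failure mode of
#' similarity-search classification for reads that are too dissimilar from
#' the database.
#'
#' @param query_row Width-M alignment row of the query.
#' @param ref_rows Named character vector of reference rows (same HMM).
#' @param ref_taxa Named character vector: reference id -> taxon id.
#' @param tax A `"taxonomy"` index.
#' @param identity_floor Minimum percent identity (default 40).
#' @param ref_scores Optional named numeric: reference id -> bit score,
#'   used only for tie-breaking.
#' @return List: `ref_id` (NA if unclassified), `identity`, `lineage`
#'   (data.frame, zero rows if unclassified), `classified` (logical).
#' @export
classify_best_hit <- function(query_row, ref_rows, ref_taxa, tax,
                              identity_floor = 40, ref_scores = NULL) {
  empty <- list(ref_id = NA_character_, identity = NA_real_,
                lineage = data.frame(rank = character(0),
                                     taxon_id = character(0),
                                     name = character(0)),
                classified = FALSE)
  if (!length(ref_rows)) {
    warning("empty reference subset; query Unclassified")
    return(empty)
  }
  ids <- vapply(ref_rows, pairwise_identity, numeric(1),
                query_row = query_row)
  sc <- if (is.null(ref_scores)) rep(0, length(ids))
        else unname(ref_scores[names(ref_rows)])
  ord <- order(-ids, -sc, names(ref_rows))
  best <- ord[1L]
  if (ids[best] < identity_floor) {
    empty$identity <- unname(ids[best])
    return(empty)
  }
  rid <- names(ref_rows)[best]
  list(ref_id = rid, identity = unname(ids[best]),
       lineage = lineage_of(tax, ref_taxa[[rid]]),
       classified = TRUE)
}
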