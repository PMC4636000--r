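#' @title Homology search orchestration
#' @description Per-HMM searches over the reference protein set and the
#'   translated metagenome ORF sets, with E-value filtering, per-read
#'   deduplication, and the reduced-reference-database heuristic.
#' @name homology_search
NULL

#' Parse taxon identifiers from reference FASTA headers
#'
#' Default convention: a `taxid=<id>` token anywhere in the header, or
#' failing that the second `|`-delimited field of the id. A custom capture
#' regex (first group = taxon id) can be supplied instead.
#'
#' @param headers Character vector of full FASTA headers.
#' @param regex Optional regex whose first capture group is the taxon id.
#' @return Character vector of taxon ids (`NA` where none found).
#' @export
parse_ref_taxa <- function(headers, regex = NULL) {
  if (!is.null(regex)) {
    out <- rep(NA_character_, length(headers))
    hit <- grepl(regex, headers)
    out[hit] <- sub(paste0(".*?", regex, ".*"), "\\1", headers[hit])
    return(out)
  }
  out <- rep(NA_character_, length(headers))
  hit <- grepl("taxid=(\\S+)", headers)
  out[hit] <- sub(".*taxid=(\\S+).*", "\\1", headers[hit])
  pipey <- is.na(out) & grepl("\\|", headers)
  if (any(pipey)) {
    id1 <- vapply(strsplit(headers[pipey], "\\s+"), `[`, character(1), 1L)
    out[pipey] <- vapply(strsplit(id1, "|", fixed = TRUE), `[`,
                         character(1), 2L)
  }
  out
}

score_set <- function(profile, seqs) {
  # best local hit per target: bit score, envelope, match row
  res <- lapply(seqs, function(s) viterbi_score(profile, s))
  data.frame(
    target_id = names(seqs),
    bit_score = vapply(res, `[[`, numeric(1), "score"),
    k_start = vapply(res, function(r) if (is.null(r$envelope)) NA_integer_ else as.integer(r$envelope[["k_start"]]), integer(1)),
    k_end   = vapply(res, function(r) if (is.null(r$envelope)) NA_integer_ else as.integer(r$envelope[["k_end"]]), integer(1)),
    i_start = vapply(res, function(r) if (is.null(r$envelope)) NA_integer_ else as.integer(r$envelope[["i_start"]]), integer(1)),
    i_end   = vapply(res, function(r) if (is.null(r$envelope)) NA_integer_ else as.integer(r$envelope[["i_end"]]), integer(1)),
    match_row = vapply(res, `[[`, character(1), "match_row"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Collect reference homologs for every HMM in one pass
#'
#' Scores all profiles against the full reference protein set once, keeps
#' per HMM the references with `E <= cutoff`, and returns each HMM's
#' reduced reference subset. Downstream classification searches only these
#' subsets, which is what makes per-family profiling fast: the full
#' reference database is touched exactly once.
#'
#' @param profiles Named list of calibrated `profile_hmm` objects.
#' @param reference Named character vector / AAStringSet of reference
#'   proteins; names (or the `description` attribute from [read_fasta()])
#'   must yield taxon ids via [parse_ref_taxa()].
#' @param cutoff E-value cutoff (default `1e-6`); hits with `E <= cutoff`
#'   are kept.
#' @param taxa Optional character vector of taxon ids, parallel to
#'   `reference` (overrides header parsing).
#' @return List: `hits` (data.frame: hmm, dataset="reference", target_id,
#'   taxon_id, bit_score, e_value, envelope columns, match_row) and
#'   `subsets` (per-HMM named character vectors of reference sequences).
#' @export
collect_reference_homologs <- function(profiles, reference, cutoff = 1e-6,
                                       taxa = NULL) {
  headers <- attr(reference, "description")
  seqs <- stats::setNames(as.character(reference), names(reference))
  if (!length(seqs)) stop("empty reference protein set")
  if (is.null(names(seqs))) stop("reference sequences must be named")
  if (is.null(taxa)) {
    taxa <- parse_ref_taxa(if (is.null(headers)) names(seqs) else unname(headers))
  }
  names(taxa) <- names(seqs)
  hits <- list(); subsets <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    sc <- score_set(pr, seqs)
    sc$e_value <- evalue_of_score(pr, sc$bit_score, length(seqs))
    keep <- sc$e_value <= cutoff
    if (!any(keep)) {
      warning("HMM '", nm, "' has no reference homologs at E <= ", cutoff,
              "; it will be skipped downstream")
      subsets[[nm]] <- character(0)
      next
    }
    sub <- sc[keep, , drop = FALSE]
    sub <- sub[order(sub$target_id), , drop = FALSE]
    hits[[nm]] <- data.frame(hmm = nm, dataset = "reference",
                             target_id = sub$target_id,
                             read_id = sub$target_id,
                             taxon_id = unname(taxa[sub$target_id]),
                             bit_score = sub$bit_score,
                             e_value = sub$e_value,
                             k_start = sub$k_start, k_end = sub$k_end,
                             i_start = sub$i_start, i_end = sub$i_end,
                             match_row = sub$match_row,
                             stringsAsFactors = FALSE)
    subsets[[nm]] <- seqs[sub$target_id]
  }
  list(hits = if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE))
       else NULL,
       subsets = subsets)
}

#' Search metagenome ORF sets with every HMM
#'
#' Scores each dataset's peptide fragments against each profile, keeps
#' fragments with `E <= cutoff` (E-values use the dataset's fragment count
#' as database size), and retains a single fragment per read per HMM — the
#' lowest E-value, with ties broken by frame order (+1,+2,+3,-1,-2,-3) then
#' start coordinate — so each read votes once.
#'
#' @param profiles Named list of calibrated `profile_hmm` objects.
#' @param orf_sets Named list of ORF tables from [orf_set()] (or, for
#'   pre-translated protein inputs, data.frames with `orf_id`, `read_id`,
#'   `seq`; `frame`/`start` default to +1/1).
#' @param cutoff E-value cutoff (default `1e-6`).
#' @return HitTable data.frame (hmm, dataset, target_id, read_id,
#'   bit_score, e_value, envelope columns, match_row), ordered by
#'   (hmm, dataset, read_id).
#' @export
search_metagenomes <- function(profiles, orf_sets, cutoff = 1e-6) {
  stopifnot(is.list(orf_sets), !is.null(names(orf_sets)))
  out <- list()
  for (ds in names(orf_sets)) {
    orfs <- orf_sets[[ds]]
    if (!nrow(orfs)) next
    if (is.null(orfs$frame)) orfs$frame <- 1L
    if (is.null(orfs$start)) orfs$start <- 1L
    seqs <- stats::setNames(orfs$seq, orfs$orf_id)
    for (nm in names(profiles)) {
      pr <- profiles[[nm]]
      sc <- score_set(pr, seqs)
      sc$e_value <- evalue_of_score(pr, sc$bit_score, nrow(orfs))
      keep <- which(sc$e_value <= cutoff)
      if (!length(keep)) next
      sub <- cbind(sc[keep, , drop = FALSE],
                   orfs[keep, c("read_id", "frame", "start"), drop = FALSE])
      # one vote per read: lowest E, then frame order, then coordinate
      ford <- match(sub$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
      ord <- order(sub$read_id, sub$e_value, ford, sub$start)
      sub <- sub[ord, , drop = FALSE]
      sub <- sub[!duplicated(sub$read_id), , drop = FALSE]
      out[[paste(nm, ds)]] <- data.frame(
        hmm = nm, dataset = ds, target_id = sub$target_id,
        read_id = sub$read_id, bit_score = sub$bit_score,
        e_value = sub$e_value,
        k_start = sub$k_start, k_end = sub$k_end,
        i_start = sub$i_start, i_end = sub$i_end,
        match_row = sub$match_row, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(hmm = character(0), dataset = character(0),
                      target_id = character(0), read_id = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      k_start = integer(0), k_end = integer(0),
                      i_start = integer(0), i_end = integer(0),
                      match_row = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  res <- res[order(res$hmm, res$dataset, res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a hit table as TSV
#' @param hits HitTable data.frame.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
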