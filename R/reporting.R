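#' @title Reporting
#' @description Per-read annotation tables, Krona text exports, taxon x
#'   (dataset x HMM) heatmap tables and cross-HMM averaged profiles.
#' @name reporting
NULL

rank_cols <- function(prefix) paste0(prefix, "_", CANONICAL_RANKS)

lineage_to_cols <- function(lineage, prefix) {
  v <- stats::setNames(rep(UNCLASSIFIED, length(CANONICAL_RANKS)),
                       rank_cols(prefix))
  if (!is.null(lineage) && nrow(lineage)) {
    v[paste0(prefix, "_", lineage$rank)] <- lineage$name
  }
  as.list(v)
}

consensus_to_cols <- function(cons, prefix) {
  v <- stats::setNames(rep(UNCLASSIFIED, length(CANONICAL_RANKS)),
                       rank_cols(prefix))
  if (!is.null(cons) && !is.na(cons$assigned_rank)) {
    upto <- match(cons$assigned_rank, CANONICAL_RANKS)
    tb <- cons$table
    for (ri in seq_len(upto)) {
      if (!is.na(tb$name[ri])) v[ri] <- tb$name[ri]
    }
  }
  as.list(v)
}

#' Assemble the per-read annotation table
#'
#' One row per retained (dataset, hmm, read), with both classification
#' routes side by side: the best-hit assignment (reference id, percent
#' identity, lineage) and the placement assignment (consensus taxon per
#' rank, assigned rank, support). Rows are sorted by dataset, hmm, then
#' E-value. A read classified by neither route is marked Unclassified in
#' both column blocks.
#'
#' @param hits HitTable from [search_metagenomes()].
#' @param best_hits Named list keyed `"<dataset>|<hmm>|<read_id>"` of
#'   [classify_best_hit()] results.
#' @param placements Same keying, of [classify_by_placement()] results (or
#'   `NULL` for unplaced reads).
#' @return data.frame (AnnotationRow layout).
#' @export
build_annotation_table <- function(hits, best_hits, placements) {
  if (!nrow(hits)) {
    stop("build_annotation_table: empty hit table")
  }
  keys <- paste(hits$dataset, hits$hmm, hits$read_id, sep = "|")
  missing_bh <- setdiff(keys, names(best_hits))
  missing_pl <- setdiff(keys, names(placements))
  if (length(missing_bh) || length(missing_pl)) {
    stop("classifier outputs are missing for some hits (pipeline bug): ",
         paste(utils::head(c(missing_bh, missing_pl), 3), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(hits)), function(r) {
    key <- keys[r]
    bh <- best_hits[[key]]
    pl <- placements[[key]]
    c(list(dataset = hits$dataset[r], hmm = hits$hmm[r],
           read_id = hits$read_id[r], orf_id = hits$target_id[r],
           e_value = hits$e_value[r], bit_score = hits$bit_score[r],
           besthit_ref = if (bh$classified) bh$ref_id else UNCLASSIFIED,
           besthit_identity = if (is.null(bh$identity)) NA_real_ else bh$identity),
      lineage_to_cols(if (bh$classified) bh$lineage else NULL, "besthit"),
      consensus_to_cols(pl, "placement"),
      list(placement_rank = if (is.null(pl) || is.na(pl$assigned_rank))
             UNCLASSIFIED else pl$assigned_rank,
           placement_support = if (is.null(pl) || is.na(pl$assigned_rank))
             NA_real_ else
             pl$table$support[match(pl$assigned_rank, pl$table$rank)]))
  })
  ann <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  ann <- ann[order(ann$dataset, ann$hmm, ann$e_value, ann$read_id), ,
             drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write / read the annotation table as TSV
#' @param ann Annotation data.frame.
#' @param path TSV path.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

route_prefix <- function(route = c("placement", "besthit")) {
  match.arg(route)
}

#' Export Krona text-import files
#'
#' One file per (dataset, hmm): tab-separated lines
#' `count<TAB>superkingdom<TAB>...` over full lineage paths of the chosen
#' classifier route. Unclassified reads appear as their own single-field
#' path, so counts always sum to the number of annotated reads.
#'
#' @param ann Annotation table from [build_annotation_table()].
#' @param dir Output directory (created if needed).
#' @param route `"placement"` (default) or `"besthit"`.
#' @return Invisibly, a named character vector of written paths.
#' @export
export_krona_text <- function(ann, dir, route = "placement") {
  route <- route_prefix(route)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- rank_cols(route)
  paths <- character(0)
  for (ds in sort(unique(ann$dataset))) {
    for (hm in sort(unique(ann$hmm[ann$dataset == ds]))) {
      sub <- ann[ann$dataset == ds & ann$hmm == hm, , drop = FALSE]
      path_strs <- apply(sub[, cols, drop = FALSE], 1L, function(v) {
        v <- v[v != UNCLASSIFIED]
        if (!length(v)) UNCLASSIFIED else paste(v, collapse = "\t")
      })
      tb <- table(path_strs)
      fn <- file.path(dir, paste0("krona_", ds, "_", hm, ".txt"))
      writeLines(paste0(as.integer(tb), "\t", names(tb)), fn)
      paths[paste(ds, hm, sep = "|")] <- fn
    }
  }
  invisible(paths)
}

#' Taxon-by-(dataset x HMM) proportion table
#'
#' Rows are the taxa observed at the chosen rank (plus an explicit
#' Unclassified row); columns are `(dataset, hmm)` pairs. Each column holds
#' the proportions of that pair's retained reads and sums to 1.
#'
#' @param ann Annotation table.
#' @param rank One of the canonical ranks (default `"genus"`).
#' @param route `"placement"` (default) or `"besthit"`.
#' @return List of class `"heatmap_table"`: `matrix` (proportions),
#'   `counts`, `rank`, `route`.
#' @export
build_heatmap <- function(ann, rank = "genus", route = "placement") {
  stopifnot(rank %in% CANONICAL_RANKS)
  route <- route_prefix(route)
  col <- paste0(route, "_", rank)
  ann$taxon <- ann[[col]]
  combos <- unique(ann[, c("dataset", "hmm")])
  combos <- combos[order(combos$dataset, combos$hmm), , drop = FALSE]
  taxa <- sort(setdiff(unique(ann$taxon), UNCLASSIFIED))
  taxa <- c(taxa, UNCLASSIFIED)
  cnt <- matrix(0L, length(taxa), nrow(combos),
                dimnames = list(taxa, paste(combos$dataset, combos$hmm,
                                            sep = "|")))
  for (ci in seq_len(nrow(combos))) {
    sub <- ann$taxon[ann$dataset == combos$dataset[ci] &
                     ann$hmm == combos$hmm[ci]]
    tb <- table(sub)
    cnt[names(tb), ci] <- as.integer(tb)
  }
  tot <- colSums(cnt)
  if (any(tot == 0)) {
    warning("empty (dataset, hmm) cell(s): ",
            paste(colnames(cnt)[tot == 0], collapse = ", "))
  }
  prop <- sweep(cnt, 2L, pmax(tot, 1L), `/`)
  structure(list(matrix = prop, counts = cnt, rank = rank, route = route,
                 datasets = combos$dataset, hmms = combos$hmm),
            class = "heatmap_table")
}

#' @export
print.heatmap_table <- function(x, ...) {
  cat("heatmap table at rank", x$rank, "(", x$route, "route ):",
      nrow(x$matrix), "taxa x", ncol(x$matrix), "columns\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Average a dataset's per-HMM taxonomic profiles
#'
#' Unweighted arithmetic mean of the dataset's per-HMM proportion columns:
#' each marker family is treated as an independent estimator of community
#' composition, so a deeply sampled family does not dominate the profile.
#'
#' @param heatmap A `"heatmap_table"`.
#' @param dataset Dataset name (must have >= 1 HMM column).
#' @return Named numeric vector of taxon proportions (sums to 1).
#' @export
average_profiles <- function(heatmap, dataset) {
  sel <- heatmap$datasets == dataset
  if (!any(sel)) stop("no columns for dataset '", dataset, "'")
  rowMeans(heatmap$matrix[, sel, drop = FALSE])
}

#' Write a heatmap table (per-HMM columns plus per-dataset averages) as TSV
#' @param heatmap A `"heatmap_table"`.
#' @param path Output path.
#' @export
write_heatmap <- function(heatmap, path) {
  m <- heatmap$matrix
  for (ds in unique(heatmap$datasets)) {
    m <- cbind(m, average_profiles(heatmap, ds))
    colnames(m)[ncol(m)] <- paste0(ds, "|average")
  }
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
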