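#' @useDynLib hmmtax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical taxonomic ranks
#'
#' The seven Linnaean ranks used throughout the package, ordered from the
#' shallowest (superkingdom) to the deepest (species). Any other rank label
#' found in a taxonomy source is collapsed to `"no_rank"` and skipped when
#' lineages are materialized.
#'
#' @format Character vector of length 7.
#' @export
CANONICAL_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Label used for reads that cannot be assigned
#' @export
UNCLASSIFIED <- "Unclassified"

norm_rank <- function(rank) {
  rank <- tolower(trimws(rank))
  ifelse(rank %in% CANONICAL_RANKS, rank, "no_rank")
}

#' Load a ranked taxonomy
#'
#' Reads either the NCBI taxdump dialect (`nodes.dmp`, fields separated by
#' `"\t|\t"`, optionally with a separate `names.dmp`) or a headerless
#' 4-column TSV (`taxon_id`, `parent_id`, `rank`, `name`). The result is an
#' index supporting [lineage_of()], [lowest_common_ancestor()] and
#' [rank_consensus()].
#'
#' The root is the unique node whose parent is itself. Dangling parent
#' references and cycles are fatal.
#'
#' @param nodes_source Path to the node table (TSV or nodes.dmp dialect).
#' @param names_source Optional path to a names.dmp-dialect table supplying
#'   display names (rows whose fourth field is `"scientific name"` win).
#' @return An object of class `"taxonomy"`.
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  lines <- readLines(nodes_source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("taxonomy source is empty: ", nodes_source)
  dmp <- grepl("\t|\t", lines[1], fixed = TRUE)
  split_row <- function(x) {
    if (dmp) {
      x <- sub("\t\\|$", "", x)
      strsplit(x, "\t|\t", fixed = TRUE)[[1]]
    } else {
      strsplit(x, "\t", fixed = TRUE)[[1]]
    }
  }
  rows <- lapply(lines, split_row)
  id     <- vapply(rows, function(r) trimws(r[[1]]), character(1))
  parent <- vapply(rows, function(r) trimws(r[[2]]), character(1))
  rank   <- vapply(rows, function(r) trimws(r[[3]]), character(1))
  name   <- vapply(rows, function(r) {
    if (length(r) >= 4 && !dmp) trimws(r[[4]]) else trimws(r[[1]])
  }, character(1))
  if (anyDuplicated(id)) {
    stop("duplicate taxon_id in taxonomy: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (!is.null(names_source)) {
    nl <- readLines(names_source)
    nl <- nl[nzchar(trimws(nl))]
    nrows <- lapply(nl, function(x) {
      x <- sub("\t\\|$", "", x)
      strsplit(x, "\t|\t", fixed = TRUE)[[1]]
    }
    )
    nid <- vapply(nrows, function(r) trimws(r[[1]]), character(1))
    nnm <- vapply(nrows, function(r) trimws(r[[2]]), character(1))
    cls <- vapply(nrows, function(r) {
      if (length(r) >= 4) trimws(r[[4]]) else "scientific name"
    }, character(1))
    keep <- cls == "scientific name"
    nm_map <- nnm[keep]
    names(nm_map) <- nid[keep]
    hit <- id %in% names(nm_map)
    name[hit] <- nm_map[id[hit]]
  }
  missing_parent <- setdiff(parent, id)
  if (length(missing_parent)) {
    stop("taxonomy parent_id not found: ",
         paste(missing_parent, collapse = ", "))
  }
  root <- id[parent == id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (parent_id == taxon_id); found ",
         length(root))
  }
  rank <- norm_rank(rank)
  names(parent) <- id
  names(rank) <- id
  names(name) <- id

  # depth by walking parents; doubles as a cycle check
  depth <- rep(NA_integer_, length(id)); names(depth) <- id
  depth[root] <- 0L
  for (i in id) {
    chain <- character(0)
    j <- i
    while (is.na(depth[j])) {
      if (j %in% chain) stop("cycle detected in taxonomy at taxon_id ", j)
      chain <- c(chain, j)
      j <- parent[[j]]
    }
    d <- depth[[j]]
    for (k in rev(chain)) {
      d <- d + 1L
      depth[k] <- d
    }
  }
  structure(list(ids = id, parent = parent, rank = rank, name = name,
                 depth = depth, root = root),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy index:", length(x$ids), "nodes, root =", x$root, "\n")
  tb <- table(x$rank)
  cat("  ranks:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  invisible(x)
}

ancestors_of <- function(tax, taxon_id) {
  # node first, root last
  out <- character(0)
  j <- taxon_id
  repeat {
    out <- c(out, j)
    p <- tax$parent[[j]]
    if (p == j) break
    j <- p
  }
  out
}

#' Materialize the ranked lineage of a taxon
#'
#' Walks parent pointers from `taxon_id` to the root and keeps nodes at the
#' canonical ranks, in canonical (shallow to deep) order. `no_rank` clades
#' are skipped. The root itself carries `no_rank`, so the root's lineage is
#' empty.
#'
#' @param tax A `"taxonomy"` index from [load_taxonomy()].
#' @param taxon_id Taxon identifier present in the index.
#' @return data.frame with columns `rank`, `taxon_id`, `name`.
#' @export
lineage_of <- function(tax, taxon_id) {
  if (!taxon_id %in% tax$ids) {
    stop("unknown taxon_id '", taxon_id, "'; hit cannot be annotated",
         call. = FALSE)
  }
  anc <- ancestors_of(tax, taxon_id)
  rk <- tax$rank[anc]
  keep <- rk %in% CANONICAL_RANKS
  anc <- anc[keep]; rk <- rk[keep]
  ord <- order(match(rk, CANONICAL_RANKS))
  data.frame(rank = unname(rk[ord]), taxon_id = unname(anc[ord]),
             name = unname(tax$name[anc[ord]]), stringsAsFactors = FALSE)
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node ancestral to (or equal to) every input taxon;
#' `lowest_common_ancestor(tax, x)` of a single taxon is that taxon.
#'
#' @param tax A `"taxonomy"` index.
#' @param taxon_ids Non-empty character vector of taxon identifiers.
#' @return A single taxon_id.
#' @export
lowest_common_ancestor <- function(tax, taxon_ids) {
  taxon_ids <- unique(as.character(taxon_ids))
  if (!length(taxon_ids)) stop("lowest_common_ancestor: empty taxon set")
  unknown <- setdiff(taxon_ids, tax$ids)
  if (length(unknown)) {
    stop("unknown taxon_id(s): ", paste(unknown, collapse = ", "))
  }
  common <- ancestors_of(tax, taxon_ids[1])
  for (t in taxon_ids[-1]) {
    common <- intersect(common, ancestors_of(tax, t))
  }
  common[which.max(tax$depth[common])]
}

#' Rank-wise consensus over a set of lineages
#'
#' At each canonical rank the modal taxon and its support fraction are
#' computed over the lineages that carry that rank. The assignment descends
#' rank by rank and stops before the first rank whose support falls below
#' `threshold` (or that is tied between two modal taxa); ranks carried by no
#' lineage are skipped without blocking deeper ranks but are never assigned
#' themselves. If no rank qualifies the result is `Unclassified`.
#'
#' @param lineages Non-empty list of lineage data.frames (see [lineage_of()]).
#' @param threshold Support fraction required, in (0, 1]; default 0.8.
#' @return List with `table` (per-rank modal taxon, support, n), and the
#'   assignment: `assigned_rank`, `assigned_taxon`, `assigned_name`.
#' @export
rank_consensus <- function(lineages, threshold = 0.8) {
  if (!length(lineages)) stop("rank_consensus: empty lineage list")
  stopifnot(threshold > 0, threshold <= 1)
  tab <- data.frame(rank = CANONICAL_RANKS, taxon_id = NA_character_,
                    name = NA_character_, support = NA_real_,
                    n = 0L, stringsAsFactors = FALSE)
  assigned_rank <- NA_character_
  assigned_taxon <- UNCLASSIFIED
  assigned_name <- UNCLASSIFIED
  blocked <- FALSE
  for (ri in seq_along(CANONICAL_RANKS)) {
    rk <- CANONICAL_RANKS[ri]
    vals <- vapply(lineages, function(ln) {
      i <- match(rk, ln$rank)
      if (is.na(i)) NA_character_ else ln$taxon_id[i]
    }, character(1))
    nms <- vapply(lineages, function(ln) {
      i <- match(rk, ln$rank)
      if (is.na(i)) NA_character_ else ln$name[i]
    }, character(1))
    vals_ok <- vals[!is.na(vals)]
    n <- length(vals_ok)
    tab$n[ri] <- n
    if (n == 0L) next  # rank absent from every lineage: skip, do not block
    cnt <- sort(table(vals_ok), decreasing = TRUE)
    top <- names(cnt)[1]
    frac <- as.numeric(cnt[1]) / n
    tied <- length(cnt) > 1L && cnt[2] == cnt[1]
    tab$taxon_id[ri] <- top
    tab$name[ri] <- nms[match(top, vals)]
    tab$support[ri] <- frac
    if (!blocked && !tied && frac >= threshold) {
      assigned_rank <- rk
      assigned_taxon <- top
      assigned_name <- tab$name[ri]
    } else {
      blocked <- TRUE  # all deeper ranks disqualified
    }
  }
  list(table = tab, assigned_rank = assigned_rank,
       assigned_taxon = assigned_taxon, assigned_name = assigned_name,
       threshold = threshold)
}
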