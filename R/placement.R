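#' @title Phylogenetic placement classification
#' @description Kimura-corrected protein distances over match-state
#'   columns, neighbor-joining reference trees, least-squares placement of
#'   query reads onto tree edges, and subtree consensus classification.
#' @name placement
NULL

kimura_correct <- function(p) {
  # Kimura's empirical correction for protein p-distances; saturating
  # distances are clamped
  ifelse(p >= 0.85, 5.0, -log(1 - p - 0.2 * p * p))
}

pair_pdist <- function(a, b) {
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (!n) return(NULL)
  list(p = sum(a[both] != b[both]) / n, overlap = n)
}

#' Kimura-corrected distance matrix over match-state alignment rows
#'
#' Per pair, the mismatch fraction `p` over columns where both rows are
#' non-gap, corrected as `d = -ln(1 - p - p^2/5)` and clamped to 5.0 when
#' `p >= 0.85`. A pair with no overlapping columns is an error.
#'
#' @param alignment Named character vector of width-M rows
#'   (a `"match_alignment"` or plain vector).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row
#'   names.
#' @export
protein_distance_matrix <- function(alignment) {
  rows <- as.character(alignment)
  nms <- names(alignment)
  n <- length(rows)
  stopifnot(n >= 2L)
  ch <- lapply(rows, function(r) strsplit(r, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pp <- pair_pdist(ch[[i]], ch[[j]])
      if (is.null(pp)) {
        stop("no overlapping alignment columns between '", nms[i],
             "' and '", nms[j], "'")
      }
      D[i, j] <- D[j, i] <- kimura_correct(pp$p)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in Q are
#' resolved by the smallest (row, column) index pair, making the topology
#' deterministic. A negative branch length at a join is clamped to zero
#' with the deficit moved to its sibling edge, preserving the pair's total.
#' On an additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D Symmetric distance matrix with dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor_joining needs at least 3 taxa")
  labs <- rownames(D)
  stopifnot(!is.null(labs), !anyDuplicated(labs))
  nodes <- labs  # newick fragment per active node
  while (length(nodes) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest Q; tie -> smallest (i, j), i < j
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- D[i, j]; vi <- 0 }
    if (vj < 0) { vi <- D[i, j]; vj <- 0 }
    new_node <- sprintf("(%s:%.17g,%s:%.17g)", nodes[i], vi, nodes[j], vj)
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    nodes <- c(nodes[others], new_node)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  # final star join of the last three nodes
  va <- pmax(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- pmax(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- pmax(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 nodes[1], va, nodes[2], vb, nodes[3], vc)
  ape::read.tree(text = nwk)
}

edge_tip_partition <- function(tree) {
  # for each edge (row of tree$edge): tip indices on the child side
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) below[[t]] <- t
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}

#' Least-squares placement of a query onto a reference tree
#'
#' Attaches the query to the edge, distal position and pendant branch that
#' minimize the sum of squared differences between tree path distances and
#' the observed query-to-leaf distances. For each edge the optimal
#' `(distal, pendant)` is found in closed form (a 2x2 normal system with
#' box constraints `0 <= distal <= edge length`, `pendant >= 0`); the
#' global argmin over edges wins, ties going to the lower edge index.
#'
#' @param tree An `ape::phylo` reference tree.
#' @param query_dists Named numeric vector: observed distance from the
#'   query to every tip of `tree` (names = tip labels).
#' @return List: `edge` (row index into `tree$edge`), `child` (node id
#'   subtending the edge), `child_label` (tip label if the edge is
#'   pendant, else `NA`), `distal` (distance from the child node),
#'   `pendant`, `fit` (residual sum of squares).
#' @export
place_on_tree <- function(tree, query_dists) {
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(query_dists)))
  d_obs <- unname(query_dists[tips])
  nd <- ape::dist.nodes(tree)
  parts <- edge_tip_partition(tree)
  ntip <- length(tips)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_len <- tree$edge.length[e]
    s1 <- parts[[e]]                       # tip indices, child side
    eps <- rep(-1, ntip); eps[s1] <- 1
    cc <- ifelse(eps == 1, nd[ch, seq_len(ntip)],
                 t_len + nd[par, seq_len(ntip)])
    y <- d_obs - cc
    n <- ntip; Sy <- sum(y); Se <- sum(eps); Sey <- sum(eps * y)
    f <- function(p, x) sum((p + eps * x - y)^2)
    cand <- list()
    det <- n * n - Se * Se
    if (det > 0) {
      p0 <- (n * Sy - Se * Sey) / det
      x0 <- (n * Sey - Se * Sy) / det
      if (p0 >= 0 && x0 >= 0 && x0 <= t_len) cand <- list(c(p0, x0))
    }
    cand <- c(cand,
              list(c(max(0, Sy / n), 0),
                   c(max(0, (Sy - Se * t_len) / n), t_len),
                   c(0, min(max(Sey / n, 0), t_len))))
    vals <- vapply(cand, function(z) f(z[1], z[2]), numeric(1))
    b <- which.min(vals)
    fit <- vals[b]
    if (is.null(best) || fit < best$fit - 1e-12) {
      best <- list(edge = e, child = ch,
                   child_label = if (ch <= ntip) tips[ch] else NA_character_,
                   distal = cand[[b]][2], pendant = cand[[b]][1], fit = fit)
    }
  }
  best
}

#' Place a query alignment row onto the reference tree
#'
#' Convenience wrapper: derives the query-to-leaf distance vector from
#' match-state rows with the Kimura correction (using only the query's
#' non-gap columns) and calls [place_on_tree()]. Queries covering fewer
#' than `min_overlap` match columns, or lacking overlap with some leaf,
#' are not placed (returns `NULL`; the read is reported Unclassified).
#'
#' @param tree Reference `phylo` tree (tip labels = reference ids).
#' @param query_row Width-M match-state row of the query.
#' @param ref_rows Named width-M rows of the reference leaves.
#' @param min_overlap Minimum non-gap match columns (default 10).
#' @return A placement list (see [place_on_tree()]) or `NULL`.
#' @export
place_query <- function(tree, query_row, ref_rows, min_overlap = 10L) {
  qc <- strsplit(query_row, "")[[1]]
  if (sum(qc != "-") < min_overlap) return(NULL)
  tips <- tree$tip.label
  d <- numeric(length(tips)); names(d) <- tips
  for (tp in tips) {
    pp <- pair_pdist(qc, strsplit(ref_rows[[tp]], "")[[1]])
    if (is.null(pp)) {
      warning("query has no aligned overlap with reference '", tp,
              "'; not placed")
      return(NULL)
    }
    d[tp] <- kimura_correct(pp$p)
  }
  place_on_tree(tree, d)
}

#' Classify a placed read by subtree consensus
#'
#' The read inherits the rank-wise consensus of the smaller-leaf-count
#' side of its attachment edge (ties go to the side holding the
#' lexicographically smallest tip label). A placement on a pendant edge
#' therefore inherits that single leaf's full lineage.
#'
#' @param tree Reference `phylo` tree.
#' @param placement A placement from [place_on_tree()]/[place_query()].
#' @param leaf_taxa Named character vector: tip label -> taxon id.
#' @param tax A `"taxonomy"` index.
#' @param threshold Consensus support threshold (default 0.8).
#' @return A [rank_consensus()] result, plus `subtree_leaves`.
#' @export
classify_by_placement <- function(tree, placement, leaf_taxa, tax,
                                  threshold = 0.8) {
  parts <- edge_tip_partition(tree)
  tips <- tree$tip.label
  s1 <- tips[parts[[placement$edge]]]
  s2 <- setdiff(tips, s1)
  side <- if (length(s1) < length(s2)) s1
          else if (length(s2) < length(s1)) s2
          else if (min(s1) < min(s2)) s1 else s2
  lins <- lapply(side, function(tp) lineage_of(tax, leaf_taxa[[tp]]))
  res <- rank_consensus(lins, threshold = threshold)
  res$subtree_leaves <- side
  res
}
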