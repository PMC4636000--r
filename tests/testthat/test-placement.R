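test_that("Kimura-corrected distances follow the closed form", {
  expect_equal(protein_distance_matrix(c(a = "ACDEF", b = "ACDEF"))["a", "b"],
               0)
  # p = 0.1 over 10 overlapping columns
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHIKV"
  d <- protein_distance_matrix(c(a = a, b = b))["a", "b"]
  expect_equal(d, -log(1 - 0.1 - 0.002), tolerance = 1e-12)
  # saturation clamp
  x <- strrep("A", 20); y <- strrep("W", 20)
  expect_equal(protein_distance_matrix(c(x = x, y = y))["x", "y"], 5.0)
  # symmetry, zero diagonal
  set.seed(3)
  rows <- vapply(1:5, function(i) random_peptide(30), character(1))
  names(rows) <- letters[1:5]
  D <- protein_distance_matrix(rows)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  # zero overlap is an error naming the pair
  expect_error(protein_distance_matrix(c(p = "AC---", q = "---DE")),
               "p.*q|no overlapping")
})

test_that("neighbor joining exactly recovers random additive trees", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  for (rep in 1:50) {
    tr <- ape::rtree(8, br = function(n) stats::runif(n, 0.05, 1))
    tru <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tru)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    est <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(est, tru), 0)
    # additive lengths recovered: path distances agree to 1e-9
    De <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(De - D)), 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  run <- main_run()
  D <- protein_distance_matrix(run$ref_alignments$marker1)
  mine <- neighbor_joining(D)
  apes <- ape::nj(D)
  expect_equal(phangorn::RF.dist(mine, ape::unroot(apes)), 0)
})

test_that("NJ recovers the quartet split and handles stars", {
  # additive ((a,b),(c,d)) signal
  tru <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  D <- ape::cophenetic.phylo(tru)
  est <- neighbor_joining(D)
  part <- hmmtax:::edge_tip_partition(est)
  sides <- lapply(part, function(s) sort(est$tip.label[s]))
  expect_true(any(vapply(sides, function(s)
    identical(s, c("a", "b")) || identical(s, c("c", "d")), logical(1))))
  # star: equal distances resolve with zero internal lengths
  Ds <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Ds) <- 0
  star <- neighbor_joining(Ds)
  internal <- star$edge[, 2] > length(star$tip.label)
  expect_true(all(star$edge.length[internal] < 1e-12))
  expect_error(neighbor_joining(Ds[1:2, 1:2]), "at least 3")
})

test_that("tree-realizable query distances place exactly", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- ape::unroot(ape::rtree(8, br = function(n) stats::runif(n, .1, 1)))
    nd <- ape::dist.nodes(tr)
    ntip <- length(tr$tip.label)
    # a query identical to each leaf: distance vector = that leaf's tree
    # path distances
    for (leaf in seq_len(ntip)) {
      d <- stats::setNames(nd[leaf, seq_len(ntip)], tr$tip.label)
      pl <- place_on_tree(tr, d)
      expect_identical(pl$child_label, tr$tip.label[leaf])
      expect_equal(pl$pendant, 0, tolerance = 1e-9)
      expect_equal(pl$distal, 0, tolerance = 1e-9)
      expect_equal(pl$fit, 0, tolerance = 1e-12)
    }
    # a query grafted onto a random edge midpoint with a known pendant
    e <- sample(nrow(tr$edge), 1)
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t_len <- tr$edge.length[e]
    x0 <- 0.4 * t_len; p0 <- 0.3
    below <- hmmtax:::edge_tip_partition(tr)[[e]]
    d <- vapply(seq_len(ntip), function(tp) {
      if (tp %in% below) p0 + x0 + nd[ch, tp]
      else p0 + (t_len - x0) + nd[par, tp]
    }, numeric(1))
    names(d) <- tr$tip.label
    pl <- place_on_tree(tr, d)
    expect_identical(pl$edge, e)
    expect_equal(pl$distal, x0, tolerance = 1e-8)
    expect_equal(pl$pendant, p0, tolerance = 1e-8)
    expect_lt(pl$fit, 1e-12)
  }
})

test_that("an identical-row query lands on its leaf's pendant edge", {
  run <- main_run()
  tr <- run$trees$marker1
  rows <- run$ref_alignments$marker1
  for (leaf in names(rows)[c(1, 4, 8)]) {
    pl <- place_query(tr, rows[[leaf]], rows)
    expect_identical(pl$child_label, leaf)
  }
})

test_that("short or non-overlapping queries are not placed", {
  run <- main_run()
  tr <- run$trees$marker2
  rows <- run$ref_alignments$marker2
  M <- nchar(rows[[1]])
  sparse <- paste0(substr(rows[[1]], 1, 5), strrep("-", M - 5))
  expect_null(place_query(tr, sparse, rows, min_overlap = 10))
  expect_null(place_query(tr, strrep("-", M), rows))
})

test_that("subtree consensus matches composing extraction with counting", {
  run <- main_run(); w <- main_world()
  tr <- run$trees$marker3
  rows <- run$ref_alignments$marker3
  taxa <- run$leaf_taxa$marker3
  set.seed(33)
  queries <- run$hits[run$hits$hmm == "marker3", ]
  for (r in sample(nrow(queries), 20)) {
    pl <- place_query(tr, queries$match_row[r], rows)
    res <- classify_by_placement(tr, pl, taxa, w$taxonomy, threshold = 0.8)
    # independent subtree extraction: the smaller side of the edge
    part <- hmmtax:::edge_tip_partition(tr)[[pl$edge]]
    s1 <- tr$tip.label[part]; s2 <- setdiff(tr$tip.label, s1)
    side <- if (length(s1) < length(s2)) s1
            else if (length(s2) < length(s1)) s2
            else if (min(s1) < min(s2)) s1 else s2
    expect_setequal(res$subtree_leaves, side)
    lins <- lapply(side, function(tp) lineage_of(w$taxonomy, taxa[[tp]]))
    for (rk in c("genus", "species")) {
      o <- consensus_count_oracle(lins, rk)
      if (!is.null(o) && !o$tied) {
        row <- res$table[res$table$rank == rk, ]
        expect_identical(row$taxon_id, o$taxon)
        expect_equal(row$support, o$support)
      }
    }
  }
})

test_that("pendant placements inherit the leaf lineage (classifier accord)", {
  run <- main_run(); w <- main_world()
  tr <- run$trees$marker1
  rows <- run$ref_alignments$marker1
  taxa <- run$leaf_taxa$marker1
  leaf <- names(rows)[2]
  pl <- place_query(tr, rows[[leaf]], rows)
  pc <- classify_by_placement(tr, pl, taxa, w$taxonomy)
  bh <- classify_best_hit(rows[[leaf]], rows, taxa, w$taxonomy)
  expect_identical(pc$assigned_rank, "species")
  expect_identical(pc$assigned_taxon,
                   bh$lineage$taxon_id[bh$lineage$rank == "species"])
  expect_equal(bh$identity, 100)
})
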