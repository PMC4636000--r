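test_that("the same seed reproduces the world and reads bit for bit", {
  w1 <- simulate_world(n_families = 2, leaves_per_family = 4, seed = 7)
  w2 <- simulate_world(n_families = 2, leaves_per_family = 4, seed = 7)
  expect_identical(w1$reference, w2$reference)
  expect_identical(w1$tax_table, w2$tax_table)
  expect_identical(lapply(w1$families, `[[`, "tree"),
                   lapply(w2$families, `[[`, "tree"))
  r1 <- simulate_reads(w1, 150, 0.1, n_reads = 25, seed = 3)
  r2 <- simulate_reads(w2, 150, 0.1, n_reads = 25, seed = 3)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  w3 <- simulate_world(n_families = 2, leaves_per_family = 4, seed = 8)
  expect_false(identical(w1$reference, w3$reference))
})

test_that("zero-length branches leave leaves identical to the root", {
  w <- simulate_world(n_families = 1, leaves_per_family = 4, seed = 5,
                      pendant_mean = 1e-12, internal_mean = 1e-12)
  fam <- w$families$marker1
  expect_true(all(fam$leaf_seqs == fam$root_seq))
})

test_that("each family's HMM prefers its own leaves by a wide margin", {
  w <- main_world()
  margins <- c()
  for (fam in names(w$families)) {
    own <- vapply(w$families[[fam]]$leaf_seqs, function(s)
      viterbi_score(w$profiles[[fam]], s)$score, numeric(1))
    other_fams <- setdiff(names(w$families), fam)
    foreign <- vapply(other_fams, function(of)
      max(vapply(w$families[[of]]$leaf_seqs, function(s)
        viterbi_score(w$profiles[[fam]], s)$score, numeric(1))),
      numeric(1))
    margins <- c(margins, min(own) - max(foreign))
  }
  expect_gt(stats::median(margins), 10)
})

test_that("undiverged reads carry an exact substring of the source protein", {
  w <- main_world()
  rs <- simulate_reads(w, 300, divergence = 0, n_reads = 30, seed = 9)
  for (i in seq_len(30)) {
    orfs <- six_frame_orfs(rs$reads[[i]], "r", min_aa = 10)
    src <- w$families[[rs$truth$family[i]]]$leaf_seqs[[rs$truth$leaf[i]]]
    # the true-frame fragment spans the whole 100-codon window and is an
    # exact substring of the source protein
    expect_true(any(vapply(orfs$seq, function(s)
      nchar(s) >= 99 && grepl(s, src, fixed = TRUE), logical(1))))
  }
})

test_that("strands are randomized roughly half and half", {
  w <- main_world()
  rs <- simulate_reads(w, 150, 0.05, n_reads = 200, seed = 13)
  n_minus <- sum(rs$truth$strand == "-")
  expect_gt(n_minus, 60)
  expect_lt(n_minus, 140)
})

test_that("300-nt reads at 5% divergence always yield usable ORFs", {
  w <- main_world()
  rs <- main_reads()
  for (i in seq_along(rs$reads)) {
    orfs <- six_frame_orfs(rs$reads[[i]], "r", min_aa = 10)
    expect_gte(nrow(orfs), 1)
  }
})

test_that("precision scoring matches an independent per-read loop", {
  run <- main_run(); w <- main_world(); rs <- main_reads()
  rep <- evaluate_precision(run$annotations, rs$truth, w$taxonomy,
                            route = "besthit")
  ann <- run$annotations
  for (rk in c("species", "genus", "phylum")) {
    correct <- 0
    for (r in seq_len(nrow(ann))) {
      tid <- rs$truth$taxon_id[rs$truth$read_id == ann$read_id[r]]
      lin <- lineage_of(w$taxonomy, tid)
      want <- lin$name[lin$rank == rk]
      if (length(want) && ann[[paste0("besthit_", rk)]][r] == want) {
        correct <- correct + 1
      }
    }
    row <- rep[rep$rank == rk & rep$stratum == "all", ]
    expect_equal(row$correct, correct)
    expect_equal(row$precision, correct / nrow(ann))
  }
  # degenerate cases: all correct; half unclassified
  perfect <- data.frame(dataset = "d", hmm = "h",
                        read_id = rs$truth$read_id[1:10],
                        besthit_species = vapply(rs$truth$taxon_id[1:10],
                          function(t) {
                            l <- lineage_of(w$taxonomy, t)
                            l$name[l$rank == "species"]
                          }, character(1)),
                        stringsAsFactors = FALSE)
  pr <- evaluate_precision(perfect, rs$truth, w$taxonomy,
                           route = "besthit", ranks = "species")
  expect_equal(pr$precision, 1)
  half <- perfect
  half$besthit_species[1:5] <- UNCLASSIFIED
  ph <- evaluate_precision(half, rs$truth, w$taxonomy,
                           route = "besthit", ranks = "species")
  expect_equal(ph$precision, 0.5)
  # a read missing from the truth map is fatal
  rogue <- perfect
  rogue$read_id[1] <- "readXXXXX"
  expect_error(evaluate_precision(rogue, rs$truth, w$taxonomy,
                                  route = "besthit", ranks = "species"),
               "absent from truth")
})

test_that("worlds serialize to standard formats that reload cleanly", {
  w <- simulate_world(n_families = 2, leaves_per_family = 4, seed = 21)
  dir <- tempfile()
  paths <- write_world(w, dir)
  tax <- load_taxonomy(paths$taxonomy)
  expect_setequal(tax$ids, w$taxonomy$ids)
  ref <- read_fasta(paths$reference, "protein")
  expect_identical(unname(as.character(ref)), unname(w$reference))
  expect_identical(unname(parse_ref_taxa(unname(attr(ref, "description")))),
                   unname(w$ref_taxa[names(ref)]))
  p <- parse_hmmer3_profile(paths$hmms[["marker1"]])
  expect_identical(p$M, w$families$marker1$prob_profile$M)
  tr <- ape::read.tree(paths$trees[["marker2"]])
  expect_setequal(tr$tip.label, names(w$families$marker2$leaf_seqs))
})
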