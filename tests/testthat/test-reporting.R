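test_that("annotation table has one sorted row per retained hit", {
  run <- main_run()
  ann <- run$annotations
  expect_identical(nrow(ann), nrow(run$hits))
  for (ds in unique(ann$dataset)) {
    for (hm in unique(ann$hmm)) {
      ev <- ann$e_value[ann$dataset == ds & ann$hmm == hm]
      expect_true(all(diff(ev) >= 0))
    }
  }
  # at least one classifier column populated per row, or both Unclassified
  expect_true(all(ann$besthit_ref != UNCLASSIFIED |
                    ann$placement_rank != UNCLASSIFIED |
                    (ann$besthit_species == UNCLASSIFIED &
                       ann$placement_species == UNCLASSIFIED)))
  # a key mismatch between classifier maps is fatal
  expect_error(build_annotation_table(run$hits, run$best_hits[-1],
                                      run$placements),
               "missing")
})

test_that("annotation TSV round-trips", {
  run <- main_run()
  tf <- tempfile(fileext = ".tsv")
  write_annotation_table(run$annotations, tf)
  back <- read_annotation_table(tf)
  expect_identical(dim(back), dim(run$annotations))
  expect_identical(back$read_id, run$annotations$read_id)
  expect_equal(back$e_value, run$annotations$e_value, tolerance = 1e-12)
  expect_identical(back$placement_genus, run$annotations$placement_genus)
})

test_that("Krona exports conserve read counts over lineage paths", {
  run <- main_run()
  ann <- run$annotations
  dir <- tempfile()
  paths <- export_krona_text(ann, dir, route = "placement")
  for (key in names(paths)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    lines <- readLines(paths[[key]])
    counts <- as.integer(vapply(strsplit(lines, "\t"), `[`, character(1), 1))
    expect_identical(sum(counts),
                     sum(ann$dataset == parts[1] & ann$hmm == parts[2]))
  }
  # single-lineage case collapses to one line
  mini <- ann[ann$placement_genus == ann$placement_genus[1] &
                ann$hmm == ann$hmm[1], ][1:3, ]
  mini$placement_species <- mini$placement_species[1]
  d2 <- tempfile()
  p2 <- export_krona_text(mini, d2, route = "placement")
  l2 <- readLines(p2[[1]])
  expect_length(l2, 1)
  expect_match(l2, "^3\t")
})

test_that("heatmap columns are proportions that sum to one", {
  run <- main_run()
  hm <- build_heatmap(run$annotations, rank = "genus", route = "besthit")
  expect_true(all(abs(colSums(hm$matrix) - 1) < 1e-9))
  expect_true(UNCLASSIFIED %in% rownames(hm$matrix))
  # counts match annotation rows per (dataset, hmm)
  for (ci in seq_len(ncol(hm$counts))) {
    expect_identical(sum(hm$counts[, ci]),
                     sum(run$annotations$dataset == hm$datasets[ci] &
                           run$annotations$hmm == hm$hmms[ci]))
  }
  # worked micro-example: 4 reads {A, A, B, Unclassified} at genus
  ann <- data.frame(dataset = "d", hmm = "h",
                    read_id = sprintf("r%d", 1:4),
                    besthit_genus = c("A", "A", "B", UNCLASSIFIED),
                    stringsAsFactors = FALSE)
  h <- build_heatmap(ann, rank = "genus", route = "besthit")
  expect_equal(unname(h$matrix[c("A", "B", UNCLASSIFIED), 1]),
               c(0.5, 0.25, 0.25))
})

test_that("profiles from markers of one community are concordant", {
  run <- main_run()
  hm <- build_heatmap(run$annotations, rank = "genus", route = "besthit")
  # the markers sample the same community, so their genus profiles agree
  # up to multinomial noise (~40 reads per marker here; the tighter bound
  # at the full benchmark depth lives in the acceptance suite)
  tv <- function(a, b) 0.5 * sum(abs(a - b))
  cols <- which(hm$datasets == "meta1")
  for (i in cols) for (j in cols) {
    if (i < j) expect_lt(tv(hm$matrix[, i], hm$matrix[, j]), 0.25)
  }
})

test_that("averaging marker profiles is an unweighted row-wise mean", {
  run <- main_run()
  hm <- build_heatmap(run$annotations, rank = "genus", route = "besthit")
  avg <- average_profiles(hm, "meta1")
  expect_equal(sum(avg), 1, tolerance = 1e-9)
  sel <- hm$datasets == "meta1"
  expect_equal(avg, rowMeans(hm$matrix[, sel, drop = FALSE]))
  # idempotence on identical columns
  m2 <- hm
  m2$matrix <- cbind(hm$matrix[, 1], hm$matrix[, 1])
  m2$datasets <- c("x", "x"); m2$hmms <- c("a", "b")
  colnames(m2$matrix) <- c("x|a", "x|b")
  expect_equal(average_profiles(m2, "x"), hm$matrix[, 1])
  # two orthogonal columns average to (0.5, 0.5)
  m3 <- hm
  m3$matrix <- matrix(c(1, 0, 0, 1), 2, 2,
                      dimnames = list(c("A", "B"), c("x|a", "x|b")))
  m3$datasets <- c("x", "x"); m3$hmms <- c("a", "b")
  expect_equal(unname(average_profiles(m3, "x")), c(0.5, 0.5))
})

test_that("permuting dataset input order only permutes heatmap columns", {
  w <- main_world()
  rs <- main_reads()
  r1 <- rs$reads[1:40]; r2 <- rs$reads[41:80]
  a <- suppressMessages(run_pipeline(w$profiles, w$reference,
                                     list(d1 = r1, d2 = r2), w$taxonomy,
                                     ref_taxa = w$ref_taxa))
  b <- suppressMessages(run_pipeline(w$profiles, w$reference,
                                     list(d2 = r2, d1 = r1), w$taxonomy,
                                     ref_taxa = w$ref_taxa))
  ha <- build_heatmap(a$annotations, "genus")
  hb <- build_heatmap(b$annotations, "genus")
  common <- intersect(colnames(ha$matrix), colnames(hb$matrix))
  expect_identical(sort(colnames(ha$matrix)), sort(colnames(hb$matrix)))
  common_taxa <- intersect(rownames(ha$matrix), rownames(hb$matrix))
  expect_equal(ha$matrix[common_taxa, common],
               hb$matrix[common_taxa, common])
})
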