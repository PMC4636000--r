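#' @title Synthetic benchmark worlds
#' @description Self-contained test worlds: a ranked taxonomy, reference
#'   protein families evolved on known trees, profile HMMs derived from the
#'   family alignments, and read sets fragmented from the references at
#'   controlled lengths and divergences, with ground-truth labels and
#'   precision scoring.
#' @name synthetic_fixtures
NULL

# reverse genetic code: amino acid -> codons (stops excluded)
codons_by_aa <- function(code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

mutate_protein <- function(seq_chars, branch_len) {
  # Poisson(L * t) substitutions at uniform sites, uniform replacement
  # over the 19 alternatives
  L <- length(seq_chars)
  nsub <- stats::rpois(1L, L * branch_len)
  if (nsub > 0L) {
    sites <- sample.int(L, nsub, replace = TRUE)
    for (s in sites) {
      seq_chars[s] <- sample(setdiff(AMINO_ALPHABET, seq_chars[s]), 1L)
    }
  }
  seq_chars
}

# balanced topology over species indices lo..hi, consistent with the
# taxonomy's nested bisection; returns newick fragment
balanced_newick <- function(ids, pendant_mean, internal_mean) {
  n <- length(ids)
  if (n == 1L) {
    return(sprintf("%s:%.8f", ids, stats::rexp(1L, 1 / pendant_mean)))
  }
  half <- ceiling(n / 2)
  left <- balanced_newick(ids[seq_len(half)], pendant_mean, internal_mean)
  right <- balanced_newick(ids[seq(half + 1L, n)], pendant_mean,
                           internal_mean)
  sprintf("(%s,%s):%.8f", left, right, stats::rexp(1L, 1 / internal_mean))
}

build_family_profile <- function(name, leaf_seqs, pseudocount = 1) {
  chars <- do.call(rbind, strsplit(unname(leaf_seqs), ""))
  M <- ncol(chars)
  n <- nrow(chars)
  mat_p <- t(vapply(seq_len(M), function(k) {
    cnt <- table(factor(chars[, k], levels = AMINO_ALPHABET))
    (as.numeric(cnt) + pseudocount * AMINO_BACKGROUND) / (n + pseudocount)
  }, numeric(20)))
  ins_p <- matrix(AMINO_BACKGROUND, M, 20, byrow = TRUE)
  tr_p <- matrix(rep(c(0.98, 0.01, 0.01, 0.5, 0.5, 0.5, 0.5), each = M),
                 M, 7, dimnames = list(NULL, TRANS_COLS))
  tr_p[M, ] <- c(1, 0, 0, 0.5, 0.5, 1, 0)
  list(name = name, acc = NA_character_, M = M,
       mat_p = mat_p, ins_p = ins_p, tr_p = tr_p,
       mu = NA_real_, lambda = NA_real_)
}

prob_to_profile <- function(pp) {
  bg <- matrix(AMINO_BACKGROUND, pp$M, 20, byrow = TRUE)
  with_neg <- function(x) ifelse(x <= 0, -Inf, log2(x))
  new_profile_hmm(pp$name, pp$acc, pp$M,
                  mat = log2(pp$mat_p / bg),
                  ins = log2(pp$ins_p / bg),
                  tr = with_neg(pp$tr_p),
                  mu = pp$mu, lambda = pp$lambda)
}

#' Simulate a benchmark world
#'
#' Builds a ranked taxonomy by nested bisection of a species set (one
#' superkingdom, two phyla, then families/genera of nested pairs down to
#' one species per leaf), then for each marker family draws a balanced
#' species tree with exponential branch lengths, evolves a random root
#' protein along it by Poisson substitution (uniform replacement kernel),
#' and derives a calibrated profile HMM from the resulting leaf alignment
#' (match emissions = column frequencies with background pseudocounts).
#'
#' All randomness flows from `seed`: the taxonomy, trees, root proteins,
#' leaf sequences and profile calibrations are drawn in a fixed order, so
#' the same seed reproduces the world byte for byte.
#'
#' @param n_families Number of marker families (default 3).
#' @param leaves_per_family Species count, >= 2 (default 8); every family
#'   covers the same species set, as marker genes sampled from one
#'   community would.
#' @param seed World seed.
#' @param aa_length Root protein length in residues (default 120).
#' @param pendant_mean,internal_mean Mean exponential branch lengths
#'   (substitutions/site) for pendant and internal edges.
#' @return A `"sim_world"` list: `taxonomy`, `tax_table`, `species`,
#'   `families` (per family: `tree`, `leaf_seqs`, `root_seq`, `prob_profile`),
#'   `profiles` (calibrated `profile_hmm`s), `reference` (named protein
#'   vector), `ref_taxa`, `leaf_species`.
#' @export
simulate_world <- function(n_families = 3L, leaves_per_family = 8L,
                           seed = 1L, aa_length = 120L,
                           pendant_mean = 0.06, internal_mean = 0.10) {
  stopifnot(n_families >= 1L, leaves_per_family >= 2L, aa_length >= 30L)
  old <- .Random.seed_exists(); on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  n <- leaves_per_family
  sp <- sprintf("sp%02d", seq_len(n))
  gen <- sprintf("gen%02d", ceiling(seq_len(n) / 2))
  famt <- sprintf("famt%02d", ceiling(seq_len(n) / 4))
  ordt <- sprintf("ord%02d", ceiling(seq_len(n) / 4))
  clst <- sprintf("cls%02d", ceiling(seq_len(n) / 4))
  phy <- sprintf("phy%02d", ceiling(seq_len(n) / ceiling(n / 2)))
  rows <- unique(rbind(
    data.frame(id = "root", parent = "root", rank = "no_rank",
               name = "root"),
    data.frame(id = "sk01", parent = "root", rank = "superkingdom",
               name = "Bacteria"),
    data.frame(id = unique(phy), parent = "sk01", rank = "phylum",
               name = unique(phy)),
    data.frame(id = unique(clst),
               parent = phy[match(unique(clst), clst)], rank = "class",
               name = unique(clst)),
    data.frame(id = unique(ordt),
               parent = clst[match(unique(ordt), ordt)], rank = "order",
               name = unique(ordt)),
    data.frame(id = unique(famt),
               parent = ordt[match(unique(famt), famt)], rank = "family",
               name = unique(famt)),
    data.frame(id = unique(gen),
               parent = famt[match(unique(gen), gen)], rank = "genus",
               name = unique(gen)),
    data.frame(id = sp, parent = gen, rank = "species", name = sp)))
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(rows, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tax <- load_taxonomy(tf)
  unlink(tf)

  families <- list(); profiles <- list()
  reference <- character(0); ref_taxa <- character(0)
  leaf_species <- character(0)
  fam_names <- sprintf("marker%d", seq_len(n_families))
  for (fi in seq_len(n_families)) {
    fam <- fam_names[fi]
    leaf_ids <- paste0(fam, "_", sp)
    nwk <- paste0("(",
                  balanced_newick(leaf_ids[seq_len(ceiling(n / 2))],
                                  pendant_mean, internal_mean),
                  ",",
                  balanced_newick(leaf_ids[seq(ceiling(n / 2) + 1L, n)],
                                  pendant_mean, internal_mean),
                  ");")
    tree <- ape::read.tree(text = nwk)
    root_seq <- sample(AMINO_ALPHABET, aa_length, replace = TRUE,
                       prob = AMINO_BACKGROUND)
    # evolve along the tree; reversed postorder visits every edge with its
    # parent sequence already drawn
    seqs_at <- vector("list", length(tree$tip.label) + tree$Nnode)
    seqs_at[[length(tree$tip.label) + 1L]] <- root_seq
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(po$edge)))) {
      seqs_at[[po$edge[e, 2]]] <-
        mutate_protein(seqs_at[[po$edge[e, 1]]], po$edge.length[e])
    }
    leaf_seqs <- vapply(seq_along(tree$tip.label),
                        function(t) paste0(seqs_at[[t]], collapse = ""),
                        character(1))
    names(leaf_seqs) <- tree$tip.label
    leaf_seqs <- leaf_seqs[leaf_ids]  # stable order sp01..spNN

    pp <- build_family_profile(fam, leaf_seqs)
    pr <- calibrate_profile(prob_to_profile(pp),
                            seed = seed + 1000L + fi)
    pp$mu <- pr$mu; pp$lambda <- pr$lambda

    families[[fam]] <- list(tree = tree, leaf_seqs = leaf_seqs,
                            root_seq = paste0(root_seq, collapse = ""),
                            prob_profile = pp)
    profiles[[fam]] <- pr
    reference <- c(reference, leaf_seqs)
    ref_taxa <- c(ref_taxa, stats::setNames(sp, leaf_ids))
    leaf_species <- c(leaf_species, stats::setNames(sp, leaf_ids))
  }
  structure(list(taxonomy = tax, tax_table = rows, species = sp,
                 families = families, profiles = profiles,
                 reference = reference, ref_taxa = ref_taxa,
                 leaf_species = leaf_species, seed = seed),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("simulated world (seed", x$seed, "):", length(x$families),
      "families x", length(x$species), "species,",
      length(x$taxonomy$ids), "taxonomy nodes\n")
  invisible(x)
}

#' Write a simulated world to standard-format files
#'
#' Emits `taxonomy.tsv`, `reference.fasta` (headers with `taxid=` tokens),
#' one HMMER3 `.hmm` per family, one Newick per family, and returns the
#' paths.
#'
#' @param world A `"sim_world"`.
#' @param dir Output directory.
#' @return Named list of paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxp <- file.path(dir, "taxonomy.tsv")
  utils::write.table(world$tax_table, taxp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  refp <- file.path(dir, "reference.fasta")
  hdrs <- paste0(names(world$reference), " taxid=",
                 world$ref_taxa[names(world$reference)])
  write_fasta(stats::setNames(world$reference, hdrs), refp)
  hmms <- character(0); trees <- character(0)
  for (fam in names(world$families)) {
    hp <- file.path(dir, paste0(fam, ".hmm"))
    write_hmmer3(world$families[[fam]]$prob_profile, hp)
    hmms[fam] <- hp
    tp <- file.path(dir, paste0(fam, ".nwk"))
    ape::write.tree(world$families[[fam]]$tree, tp)
    trees[fam] <- tp
  }
  list(taxonomy = taxp, reference = refp, hmms = hmms, trees = trees)
}

#' Simulate metagenomic reads from a world
#'
#' Each read takes a random window of a random reference leaf protein,
#' reverse-translates it (uniform synonymous codon choice under the chosen
#' code), applies per-base substitutions at the given divergence rate, and
#' lands on a random strand. The truth map records the source leaf and its
#' species.
#'
#' @param world A `"sim_world"`.
#' @param read_length_nt Read length in nt (>= 60; default 300).
#' @param divergence Per-base substitution probability in `[0, 1)`.
#' @param n_reads Number of reads (default 500).
#' @param seed Read-set seed.
#' @param code Genetic code id (default "11").
#' @return List: `reads` (named character vector of DNA sequences),
#'   `truth` (data.frame: read_id, family, leaf, taxon_id, strand).
#' @export
simulate_reads <- function(world, read_length_nt = 300L, divergence = 0.05,
                           n_reads = 500L, seed = 1L, code = "11") {
  stopifnot(read_length_nt >= 60L, divergence >= 0, divergence < 1)
  old <- .Random.seed_exists(); on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  rev_code <- codons_by_aa(code)
  fams <- names(world$families)
  bases <- c("A", "C", "G", "T")
  reads <- character(n_reads); truth <- vector("list", n_reads)
  n_codon_req <- read_length_nt %/% 3L
  for (i in seq_len(n_reads)) {
    fam <- fams[sample.int(length(fams), 1L)]
    leafs <- world$families[[fam]]$leaf_seqs
    li <- sample.int(length(leafs), 1L)
    prot <- strsplit(leafs[[li]], "")[[1]]
    n_codon <- n_codon_req
    if (n_codon > length(prot)) {
      warning("read window longer than protein; truncated")
      n_codon <- length(prot)
    }
    start <- sample.int(length(prot) - n_codon + 1L, 1L)
    window <- prot[seq(start, start + n_codon - 1L)]
    nt <- unlist(lapply(window, function(a) {
      cs <- rev_code[[a]]
      strsplit(cs[sample.int(length(cs), 1L)], "")[[1]]
    }))
    mut <- stats::runif(length(nt)) < divergence
    if (any(mut)) {
      nt[mut] <- vapply(nt[mut],
                        function(b) sample(setdiff(bases, b), 1L),
                        character(1))
    }
    s <- paste0(nt, collapse = "")
    strand <- if (stats::runif(1L) < 0.5) "+" else "-"
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    rid <- sprintf("read%05d", i)
    reads[i] <- s; names(reads)[i] <- rid
    truth[[i]] <- data.frame(read_id = rid, family = fam,
                             leaf = names(leafs)[li],
                             taxon_id = world$leaf_species[[names(leafs)[li]]],
                             strand = strand, stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Score classification precision against the truth map
#'
#' Per rank (and optionally per stratum), the fraction of annotation rows
#' whose assigned taxon name matches the truth lineage at that rank.
#' Unclassified rows count as incorrect; every row's read must be in the
#' truth map. Denominators are all evaluated rows.
#'
#' @param ann Annotation table from [build_annotation_table()].
#' @param truth Truth data.frame from [simulate_reads()].
#' @param tax A `"taxonomy"` index.
#' @param route `"besthit"` or `"placement"`.
#' @param ranks Ranks to score (default species, genus, phylum).
#' @param strata Optional named vector read_id -> stratum label.
#' @return data.frame: route, rank, stratum, n, correct, precision.
#' @export
evaluate_precision <- function(ann, truth, tax, route = "besthit",
                               ranks = c("species", "genus", "phylum"),
                               strata = NULL) {
  stopifnot(all(ranks %in% CANONICAL_RANKS))
  bad <- setdiff(ann$read_id, truth$read_id)
  if (length(bad)) {
    stop("annotated read(s) absent from truth map: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  true_lin <- lapply(stats::setNames(unique(truth$taxon_id),
                                     unique(truth$taxon_id)),
                     function(tid) lineage_of(tax, tid))
  truth_tax <- stats::setNames(truth$taxon_id, truth$read_id)
  out <- list()
  strat_of <- if (is.null(strata)) {
    stats::setNames(rep("all", nrow(ann)), ann$read_id)
  } else strata
  groups <- c("all", setdiff(unique(strat_of), "all"))
  for (rk in ranks) {
    assigned <- ann[[paste0(route, "_", rk)]]
    expected <- vapply(ann$read_id, function(rid) {
      lin <- true_lin[[truth_tax[[rid]]]]
      i <- match(rk, lin$rank)
      if (is.na(i)) NA_character_ else lin$name[i]
    }, character(1))
    ok <- !is.na(expected) & assigned == expected
    for (g in groups) {
      sel <- if (g == "all") rep(TRUE, nrow(ann))
             else strat_of[ann$read_id] == g
      out[[paste(rk, g)]] <- data.frame(
        route = route, rank = rk, stratum = g,
        n = sum(sel), correct = sum(ok & sel),
        precision = if (sum(sel)) sum(ok & sel) / sum(sel) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(unname(out), make.row.names = FALSE))
  rownames(res) <- NULL
  res
}
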