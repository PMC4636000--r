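# Independent brute-force oracles. These deliberately re-derive results by
# enumeration/counting and never call the code paths they check.

# exhaustive enumeration of all local uni-hit state paths, mirroring the
# model definition (uniform local entry over match states, free exit from
# any match state) but not the dynamic program
enumerate_viterbi <- function(profile, target) {
  x <- match(strsplit(toupper(target), "")[[1]], profile$alphabet)
  L <- length(x); M <- profile$M
  tr <- profile$tr
  em <- function(mt, k, i) if (is.na(x[i])) 0 else mt[k, x[i]]
  best <- -Inf
  recurse <- function(state, k, i, sc) {
    sc <- unname(sc)
    if (state == "M" && sc > best) best <<- sc
    if (state == "M") {
      if (k < M && i < L)
        recurse("M", k + 1, i + 1, sc + tr[k, "mm"] + em(profile$mat, k + 1, i + 1))
      if (i < L)
        recurse("I", k, i + 1, sc + tr[k, "mi"] + em(profile$ins, k, i + 1))
      if (k < M)
        recurse("D", k + 1, i, sc + tr[k, "md"])
    } else if (state == "I") {
      if (k < M && i < L)
        recurse("M", k + 1, i + 1, sc + tr[k, "im"] + em(profile$mat, k + 1, i + 1))
      if (i < L)
        recurse("I", k, i + 1, sc + tr[k, "ii"] + em(profile$ins, k, i + 1))
    } else {
      if (k < M && i < L)
        recurse("M", k + 1, i + 1, sc + tr[k, "dm"] + em(profile$mat, k + 1, i + 1))
      if (k < M)
        recurse("D", k + 1, i, sc + tr[k, "dd"])
    }
  }
  for (i0 in seq_len(L)) {
    for (k0 in seq_len(M)) {
      recurse("M", k0, i0, -log2(M) + em(profile$mat, k0, i0))
    }
  }
  best
}

# random probability-space profile of M match states, as a profile_hmm
random_tiny_profile <- function(M) {
  rdir <- function(n) { x <- stats::rexp(n) + 0.05; x / sum(x) }
  mat_p <- t(vapply(seq_len(M), function(k) rdir(20), numeric(20)))
  ins_p <- t(vapply(seq_len(M), function(k) rdir(20), numeric(20)))
  tr_p <- t(vapply(seq_len(M), function(k) {
    m3 <- rdir(3); i2 <- rdir(2); d2 <- rdir(2)
    c(m3, i2, d2)
  }, numeric(7)))
  colnames(tr_p) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  pp <- list(name = paste0("tiny", M), acc = NA, M = M, mat_p = mat_p,
             ins_p = ins_p, tr_p = tr_p, mu = NA_real_, lambda = NA_real_)
  hmmtax:::prob_to_profile(pp)
}

random_peptide <- function(len) {
  paste0(sample(hmmtax:::AMINO_ALPHABET, len, replace = TRUE), collapse = "")
}

# ancestor-path-intersection LCA oracle
lca_oracle <- function(tax, ids) {
  paths <- lapply(ids, function(i) hmmtax:::ancestors_of(tax, i))
  common <- Reduce(intersect, paths)
  common[which.max(tax$depth[common])]
}

# counting oracle for rank consensus: modal taxon and support at one rank
consensus_count_oracle <- function(lineages, rank) {
  vals <- unlist(lapply(lineages, function(ln) {
    i <- match(rank, ln$rank)
    if (is.na(i)) NULL else ln$taxon_id[i]
  }))
  if (!length(vals)) return(NULL)
  tb <- sort(table(vals), decreasing = TRUE)
  list(taxon = names(tb)[1], support = as.numeric(tb[1]) / length(vals),
       tied = length(tb) > 1 && tb[2] == tb[1])
}

# random small taxonomy: a chain-of-ranks tree with branching factor 2
random_taxonomy <- function(n_leaves = 64) {
  n <- n_leaves
  rows <- data.frame(id = "root", parent = "root", rank = "no_rank",
                     name = "root", stringsAsFactors = FALSE)
  prev <- "root"
  make_level <- function(rank, count, parents) {
    ids <- sprintf("%s%03d", substr(rank, 1, 3), seq_len(count))
    data.frame(id = ids,
               parent = parents[((seq_len(count) - 1) %% length(parents)) + 1],
               rank = rank, name = ids, stringsAsFactors = FALSE)
  }
  counts <- pmin(2 ^ seq_len(7), n)
  levels_df <- list()
  parents <- "root"
  for (ri in seq_along(hmmtax::CANONICAL_RANKS)) {
    df <- make_level(hmmtax::CANONICAL_RANKS[ri], counts[ri], parents)
    levels_df[[ri]] <- df
    parents <- df$id
  }
  rows <- rbind(rows, do.call(rbind, levels_df))
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(rows, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  on.exit(unlink(tf))
  hmmtax::load_taxonomy(tf)
}
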