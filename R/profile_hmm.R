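#' @title Profile HMM machinery
#' @description Parsing of HMMER3 ASCII profiles, local Viterbi alignment,
#'   Gumbel E-values, and projection of hits onto match-state columns.
#' @name profile_hmm
NULL

# HMMER alphabet order for amino profiles
AMINO_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# i.i.d. amino-acid background frequencies (Swiss-Prot derived, as used by
# standard profile-HMM null models), in alphabet order
AMINO_BACKGROUND <- c(
  0.0787945, 0.0151600, 0.0535222, 0.0668298, 0.0397062,
  0.0695071, 0.0229198, 0.0590092, 0.0594422, 0.0963728,
  0.0237718, 0.0414386, 0.0482904, 0.0395639, 0.0540978,
  0.0683364, 0.0540687, 0.0673417, 0.0114135, 0.0304133)
names(AMINO_BACKGROUND) <- AMINO_ALPHABET

TRANS_COLS <- c("mm", "mi", "md", "im", "ii", "dm", "dd")

new_profile_hmm <- function(name, acc, M, mat, ins, tr,
                            mu = NA_real_, lambda = NA_real_) {
  structure(list(name = name, acc = acc, M = M,
                 alphabet = AMINO_ALPHABET,
                 mat = mat, ins = ins, tr = tr,
                 mu = mu, lambda = lambda),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM", x$name, "- ", x$M, "match states",
      if (!is.na(x$mu)) sprintf("(Gumbel mu=%.4f lambda=%.4f)", x$mu, x$lambda)
      else "(uncalibrated)", "\n")
  invisible(x)
}

# "*" encodes probability zero (-ln p = Inf)
parse_hmm_val <- function(v) ifelse(v == "*", Inf, suppressWarnings(as.numeric(v)))

#' Read profile HMMs from a HMMER3 ASCII file
#'
#' Parses single- or multi-model `.hmm` files. Match and insert emission
#' scores are converted from the file's negative natural-log probabilities
#' to log-odds in bits against a fixed amino-acid background; transitions
#' become log2 probabilities. `STATS LOCAL VITERBI mu lambda` lines are
#' captured as the Gumbel calibration used for E-values.
#'
#' @param source Path to a HMMER3 ASCII file (must start with `HMMER3/`).
#' @return A named list of `profile_hmm` objects (one per model).
#' @seealso [parse_hmmer3_profile()] for the single-model convenience form.
#' @export
read_hmmer3 <- function(source) {
  lines <- readLines(source)
  if (!length(lines) || !startsWith(lines[1], "HMMER3/")) {
    stop("not a HMMER3 ASCII file (missing 'HMMER3/' header): ", source)
  }
  profiles <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !startsWith(lines[i], "HMMER3/")) i <- i + 1L
    if (i > n) break
    i <- i + 1L
    name <- NULL; acc <- NA_character_; leng <- NULL; alph <- NULL
    mu <- NA_real_; lambda <- NA_real_
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      key <- sub("^(\\S+).*$", "\\1", lines[i])
      val <- trimws(sub("^\\S+\\s*", "", lines[i]))
      if (key == "NAME") name <- val
      if (key == "ACC") acc <- val
      if (key == "LENG") leng <- as.integer(val)
      if (key == "ALPH") alph <- tolower(val)
      if (key == "STATS") {
        f <- strsplit(val, "\\s+")[[1]]
        if (length(f) >= 4 && f[1] == "LOCAL" && f[2] == "VITERBI") {
          mu <- as.numeric(f[3]); lambda <- as.numeric(f[4])
        }
      }
      i <- i + 1L
    }
    if (i > n) stop("truncated HMMER3 model (no HMM table): ", source)
    if (is.null(leng)) stop("HMMER3 model missing LENG: ", source)
    if (!identical(alph, "amino")) {
      stop("unsupported alphabet '", alph, "' (only amino profiles)")
    }
    i <- i + 2L  # skip "HMM ..." header and transition-order line
    tok <- function(j) strsplit(trimws(lines[j]), "\\s+")[[1]]
    if (i <= n && tok(i)[1] == "COMPO") i <- i + 1L
    i <- i + 2L  # node-0 insert emission and begin-transition lines
    M <- leng
    mat <- matrix(NA_real_, M, 20)
    ins <- matrix(NA_real_, M, 20)
    trn <- matrix(NA_real_, M, 7, dimnames = list(NULL, TRANS_COLS))
    for (k in seq_len(M)) {
      if (i + 2L > n || grepl("^//", lines[i])) {
        stop("truncated HMMER3 model '", name, "': expected ", M,
             " match rows, got ", k - 1L)
      }
      f <- tok(i)
      if (as.integer(f[1]) != k) {
        stop("HMMER3 model '", name, "': match row ", k,
             " has node index ", f[1])
      }
      mat[k, ] <- parse_hmm_val(f[2:21])
      ins[k, ] <- parse_hmm_val(tok(i + 1L)[1:20])
      trn[k, ] <- parse_hmm_val(tok(i + 2L)[1:7])
      i <- i + 3L
    }
    if (i > n || !grepl("^//", lines[i])) {
      stop("HMMER3 model '", name, "': missing terminating '//'")
    }
    i <- i + 1L
    # probability sanity on transitions (last node exits to E via mm)
    psum <- exp(-trn[, "mm"]) + exp(-trn[, "mi"]) + exp(-trn[, "md"])
    if (any(abs(psum - 1) > 1e-2)) {
      stop("HMMER3 model '", name, "': match transitions do not sum to 1")
    }
    # convert: emissions to bits of log-odds, transitions to log2 prob
    bg <- matrix(log(AMINO_BACKGROUND), M, 20, byrow = TRUE)
    p <- new_profile_hmm(
      name = if (is.null(name)) "unnamed" else name, acc = acc, M = M,
      mat = (-mat - bg) / log(2),
      ins = (-ins - bg) / log(2),
      tr = -trn / log(2),
      mu = mu, lambda = lambda)
    profiles[[p$name]] <- p
  }
  if (!length(profiles)) stop("no models found in ", source)
  profiles
}

#' Parse a single-model HMMER3 file
#'
#' @inheritParams read_hmmer3
#' @return One `profile_hmm` object.
#' @export
parse_hmmer3_profile <- function(source) {
  p <- read_hmmer3(source)
  if (length(p) != 1L) {
    stop(source, " contains ", length(p),
         " models; use read_hmmer3() for multi-model files")
  }
  p[[1L]]
}

#' Score a peptide against a profile HMM (local Viterbi)
#'
#' Best uni-hit local alignment of `target` to the profile, scored in bits
#' against the i.i.d. background null model. Local entry is uniform over
#' match states; exit from any match state is free. Residues outside the
#' 20-letter alphabet (e.g. `X`) emit the background (log-odds 0). The
#' traceback is deterministic: ties prefer match over delete over insert.
#'
#' @param profile A `profile_hmm`.
#' @param target Peptide sequence (character scalar), non-empty.
#' @return List: `score` (bits), `path` (data.frame `state` in M/D/I, `k`
#'   match-state index, `i` target position), `envelope`
#'   (`k_start`,`k_end`,`i_start`,`i_end`), `match_row` (width-M character
#'   string: residue per match state, `-` for delete/uncovered).
#' @export
viterbi_score <- function(profile, target) {
  stopifnot(inherits(profile, "profile_hmm"))
  target <- toupper(as.character(target))
  if (!nchar(target)) stop("viterbi_score: empty target")
  x <- match(strsplit(target, "")[[1]], profile$alphabet)
  x[is.na(x)] <- 0L          # X and friends -> background
  res <- viterbi_c(profile$mat, profile$ins, profile$tr,
                   as.integer(x - 1L), -log2(profile$M))
  if (!is.finite(res$score) || !length(res$k)) {
    return(list(score = -Inf, path = NULL, envelope = NULL,
                match_row = strrep("-", profile$M)))
  }
  st <- c("M", "D", "I")[res$state]
  path <- data.frame(state = st, k = res$k, i = res$i,
                     stringsAsFactors = FALSE)
  m <- st == "M"
  row <- rep("-", profile$M)
  row[res$k[m]] <- strsplit(target, "")[[1]][res$i[m]]
  list(score = res$score,
       path = path,
       envelope = c(k_start = min(res$k[m]), k_end = max(res$k[m]),
                    i_start = min(res$i[m]), i_end = max(res$i[m])),
       match_row = paste0(row, collapse = ""))
}

#' E-value of a bit score under the profile's Gumbel calibration
#'
#' `E = N * P(S >= s)` with `P(S >= s) = 1 - exp(-exp(-lambda * (s - mu)))`,
#' the survival function of the Gumbel law fitted to null (non-homologous)
#' Viterbi scores. `N` is the number of target sequences searched.
#'
#' @param profile A calibrated `profile_hmm` (from a `STATS LOCAL VITERBI`
#'   line or [calibrate_profile()]).
#' @param bit_score Numeric vector of Viterbi bit scores.
#' @param database_size Number of sequences searched (>= 1).
#' @return E-values (same length as `bit_score`).
#' @export
evalue_of_score <- function(profile, bit_score, database_size) {
  stopifnot(database_size >= 1)
  if (is.na(profile$mu) || is.na(profile$lambda)) {
    stop("profile '", profile$name, "' has no Gumbel calibration; ",
         "supply STATS LOCAL VITERBI lines in the .hmm file or run ",
         "calibrate_profile() first")
  }
  p <- -expm1(-exp(-profile$lambda * (bit_score - profile$mu)))
  database_size * p
}

#' Calibrate a profile's Gumbel location from shuffled background sequences
#'
#' When a profile file carries no `STATS` line the Gumbel slope is fixed at
#' `lambda = log(2)` and the location `mu` is estimated by maximum
#' likelihood from the Viterbi scores of `n` i.i.d. background sequences of
#' the profile's own length, drawn under a fixed seed.
#'
#' @param profile A `profile_hmm`.
#' @param n Number of null sequences (default 200).
#' @param seed RNG seed for the null sample (default 7).
#' @param lambda Gumbel slope (default `log(2)`).
#' @return The profile with `mu` and `lambda` filled in.
#' @export
calibrate_profile <- function(profile, n = 200L, seed = 7L, lambda = log(2)) {
  len <- max(profile$M, 30L)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  sc <- vapply(seq_len(n), function(i) {
    s <- paste0(sample(AMINO_ALPHABET, len, replace = TRUE,
                       prob = AMINO_BACKGROUND), collapse = "")
    viterbi_score(profile, s)$score
  }, numeric(1))
  # ML location for fixed slope: mu = -log(mean(exp(-lambda s))) / lambda
  m <- max(-lambda * sc)
  mu <- -(m + log(mean(exp(-lambda * sc - m)))) / lambda
  profile$mu <- mu
  profile$lambda <- lambda
  profile
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Project sequences onto a profile's match-state columns
#'
#' Runs the Viterbi traceback for each sequence and keeps, per match state,
#' the aligned residue (insert-state residues are dropped; delete states and
#' uncovered states become gaps). This is the fixed-width coordinate system
#' shared by the best-hit and placement classifiers. Sequences whose best
#' local alignment scores <= 0 bits get an all-gap row with a warning.
#'
#' @param profile A `profile_hmm`.
#' @param seqs Named character vector (or AAStringSet) of peptides.
#' @return Named character vector of width-`M` rows (`-` = gap); class
#'   `"match_alignment"` with attribute `M`.
#' @export
align_to_match_states <- function(profile, seqs) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  stopifnot(!is.null(names(seqs)))
  rows <- vapply(seq_along(seqs), function(j) {
    v <- viterbi_score(profile, seqs[[j]])
    if (!is.finite(v$score) || v$score <= 0) {
      warning("no positive-scoring alignment for '", names(seqs)[j],
              "'; emitting all-gap row")
      strrep("-", profile$M)
    } else v$match_row
  }, character(1))
  names(rows) <- names(seqs)
  structure(rows, M = profile$M, class = "match_alignment")
}

#' Write a match-state alignment as aligned FASTA
#'
#' @param alignment A `"match_alignment"` (named width-M rows).
#' @param path Output path.
#' @export
write_match_alignment <- function(alignment, path) {
  write_fasta(unclass(alignment), path)
}
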