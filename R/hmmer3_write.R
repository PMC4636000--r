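#' Write a probability-space profile as HMMER3 ASCII
#'
#' Serializes a profile given in probability space (as produced by
#' [simulate_world()]'s family-profile builder) to the HMMER3/f ASCII
#' layout that [read_hmmer3()] parses: emissions and transitions as
#' negative natural-log probabilities, zero probabilities as `*`, and a
#' `STATS LOCAL VITERBI` line when the profile carries a Gumbel
#' calibration.
#'
#' @param prob_profile List with `name`, optional `acc`, `M`, `mat_p`
#'   (M x 20 match emission probabilities in alphabet order), `ins_p`
#'   (M x 20 insert emissions), `tr_p` (M x 7 transition probabilities,
#'   columns mm, mi, md, im, ii, dm, dd), optional `mu`, `lambda`.
#' @param path Output path.
#' @param append Append to an existing file (multi-model output).
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(prob_profile, path, append = FALSE) {
  p <- prob_profile
  stopifnot(nrow(p$mat_p) == p$M, ncol(p$mat_p) == 20L,
            all(abs(rowSums(p$mat_p) - 1) < 1e-6))
  fmt <- function(x) ifelse(x <= 0, "*", sprintf("%.5f", -log(x)))
  pad <- function(v) paste(sprintf("%8s", v), collapse = " ")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("HMMER3/f [hmmtax]")
  w("NAME  ", p$name)
  if (!is.null(p$acc) && !is.na(p$acc)) w("ACC   ", p$acc)
  w("LENG  ", p$M)
  w("ALPH  amino")
  if (!is.null(p$mu) && !is.na(p$mu)) {
    w(sprintf("STATS LOCAL VITERBI %9.4f %9.5f", p$mu, p$lambda))
  }
  w("HMM      ", pad(AMINO_ALPHABET))
  w("         ", pad(c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")))
  avg <- colMeans(p$mat_p)
  w("  COMPO  ", pad(sprintf("%.5f", -log(avg))))
  w("         ", pad(fmt(AMINO_BACKGROUND)))
  # begin transitions: B->M1 dominant, tiny B->I0/B->D1 (unused by the
  # local-entry model but kept for format fidelity)
  w("         ", pad(c(fmt(c(0.98, 0.01, 0.01, 0.5, 0.5, 1)), "*")))
  for (k in seq_len(p$M)) {
    w(sprintf("%7d  ", k), pad(fmt(p$mat_p[k, ])),
      sprintf("%7d %s - - -", k, "x"))
    w("         ", pad(fmt(p$ins_p[k, ])))
    w("         ", pad(fmt(p$tr_p[k, ])))
  }
  w("//")
  invisible(path)
}
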