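#' Read a FASTA file
#'
#' Thin wrapper over Biostrings readers that enforces the package's id
#' conventions: the record id is the first whitespace-delimited token of the
#' header, ids must be unique within a file, and sequences are upper-cased.
#' The full header line is kept as the `description` attribute so that
#' taxonomy tokens (e.g. `taxid=562`) survive.
#'
#' @param source Path to a FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A `DNAStringSet` or `AAStringSet` named by record id, with a
#'   character vector attribute `"description"` holding full headers.
#' @export
read_fasta <- function(source, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(source, format = "fasta")
  } else {
    Biostrings::readAAStringSet(source, format = "fasta")
  }
  if (!length(set)) {
    warning("empty FASTA file: ", source)
    return(set)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", source, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- toupper(as.character(set))
  set <- if (type == "dna") Biostrings::DNAStringSet(chars) else Biostrings::AAStringSet(chars)
  names(set) <- ids
  attr(set, "description") <- stats::setNames(headers, ids)
  set
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or XStringSet.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Six-frame ORF extraction
#'
#' Translates a nucleotide read in all six frames under a chosen genetic
#' code, splits each frame's translation at stop codons, and emits every
#' stop-free segment of at least `min_aa` residues as a candidate peptide
#' fragment. Open reading frames are stop-to-stop: no start codon is
#' required, because metagenomic reads are arbitrary gene fragments.
#'
#' Coordinates are always 1-based inclusive on the forward strand of the
#' source read, for any frame, so `length(peptide) * 3 == end - start + 1`.
#' Codons containing any non-ACGT base translate to `X`; `X` never ends a
#' segment. Fragment ids follow `<read_id>|f<frame>|<start>-<end>`.
#'
#' @param sequence Nucleotide sequence (character or DNAString).
#' @param read_id Source read identifier used in fragment ids.
#' @param min_aa Minimum fragment length in residues (default 10).
#' @param code Genetic code id as in [Biostrings::getGeneticCode()]
#'   (default `"11"`, bacterial/archaeal).
#' @return data.frame with columns `orf_id`, `read_id`, `frame`, `start`,
#'   `end`, `seq`.
#' @export
six_frame_orfs <- function(sequence, read_id = "read", min_aa = 10L,
                           code = "11") {
  stopifnot(min_aa >= 1L)
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  empty <- data.frame(orf_id = character(0), read_id = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  gc <- Biostrings::getGeneticCode(code)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  out <- vector("list", 6L)
  n_out <- 0L
  for (strand in c(1L, -1L)) {
    tpl <- if (strand == 1L) s else rc
    for (off in 0:2) {
      n_codon <- (L - off) %/% 3L
      if (n_codon < 1L) next
      sub <- substr(tpl, off + 1L, off + 3L * n_codon)
      aa <- translate_string(sub, gc)
      frame <- strand * (off + 1L)
      # split at stops; record codon index ranges of stop-free runs
      segs <- stopfree_segments(aa, min_aa)
      if (!nrow(segs)) next
      # codon i (1-based) covers template positions off+3i-2 .. off+3i
      t_start <- off + 3L * segs$first - 2L
      t_end <- off + 3L * segs$last
      if (strand == 1L) {
        fstart <- t_start; fend <- t_end
      } else {
        fstart <- L + 1L - t_end; fend <- L + 1L - t_start
      }
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        orf_id = sprintf("%s|f%+d|%d-%d", read_id, frame, fstart, fend),
        read_id = read_id, frame = frame, start = fstart, end = fend,
        seq = segs$seq, stringsAsFactors = FALSE)
    }
  }
  if (!n_out) return(empty)
  res <- do.call(rbind, out[seq_len(n_out)])
  ford <- c(1L, 2L, 3L, -1L, -2L, -3L)
  res <- res[order(match(res$frame, ford), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# translate a length-multiple-of-3 string; fuzzy codons -> X
translate_string <- function(nt, gc) {
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

stopfree_segments <- function(aa, min_aa) {
  runs <- strsplit(aa, "*", fixed = TRUE)[[1]]
  first <- integer(0); last <- integer(0); seqs <- character(0)
  pos <- 1L
  for (r in runs) {
    n <- nchar(r)
    if (n >= min_aa) {
      first <- c(first, pos); last <- c(last, pos + n - 1L)
      seqs <- c(seqs, r)
    }
    pos <- pos + n + 1L  # skip the stop
  }
  data.frame(first = first, last = last, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Six-frame ORFs for a whole read set
#'
#' @param reads Named DNAStringSet or named character vector of reads.
#' @inheritParams six_frame_orfs
#' @return One data.frame of fragments for all reads (see [six_frame_orfs()]).
#' @export
orf_set <- function(reads, min_aa = 10L, code = "11") {
  ids <- names(reads)
  stopifnot(!is.null(ids))
  chars <- as.character(reads)
  parts <- lapply(seq_along(chars),
                  function(i) six_frame_orfs(chars[[i]], ids[[i]],
                                             min_aa = min_aa, code = code))
  out <- do.call(rbind, parts)
  if (is.null(out)) return(six_frame_orfs("", "x", min_aa = min_aa))
  rownames(out) <- NULL
  out
}
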