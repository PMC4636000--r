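#' Default pipeline parameters
#'
#' E-value cutoff `1e-6`, subtree consensus threshold `0.8`, best-hit
#' identity floor `40` percent, reporting rank `"genus"`.
#'
#' @return Named list of defaults.
#' @export
hmmtax_defaults <- function() {
  list(evalue = 1e-6, consensus = 0.8, identity_floor = 40,
       rank = "genus", min_aa = 10L, code = "11", min_overlap = 10L)
}

load_profiles <- function(hmms) {
  if (is.character(hmms)) {
    profiles <- list()
    for (f in hmms) profiles <- c(profiles, read_hmmer3(f))
  } else {
    profiles <- hmms
  }
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  for (nm in names(profiles)) {
    if (is.na(profiles[[nm]]$mu)) {
      profiles[[nm]] <- calibrate_profile(profiles[[nm]])
    }
  }
  profiles
}

#' Run the full profiling pipeline
#'
#' End-to-end: parse profile HMMs, collect reference homologs once (the
#' reduced per-HMM reference databases), six-frame translate each
#' metagenome, search every (HMM, dataset) pair with the E-value cutoff,
#' classify every retained read by both routes (best hit over match-state
#' identity; least-squares placement on a neighbor-joining reference tree
#' with subtree consensus), and assemble the reports.
#'
#' The run is fully deterministic for fixed inputs: the only randomness is
#' the Gumbel calibration of uncalibrated profiles, which uses a fixed
#' internal seed.
#'
#' @param hmms Path(s) to HMMER3 files, or a named list of `profile_hmm`.
#' @param reference Path to a protein FASTA (headers carrying
#'   `taxid=<id>`), or a named vector/AAStringSet.
#' @param datasets Named list of metagenomes: nucleotide FASTA paths,
#'   DNAStringSets, or pre-built ORF tables (data.frames).
#' @param taxonomy Path to a taxonomy table or a `"taxonomy"` object.
#' @param evalue E-value cutoff (default 1e-6).
#' @param consensus Subtree consensus threshold (default 0.8).
#' @param identity_floor Best-hit identity floor in percent (default 40).
#' @param rank Reporting rank for the heatmap (default "genus").
#' @param min_aa Minimum ORF length in residues (default 10).
#' @param code Genetic code id (default "11").
#' @param min_overlap Minimum query match columns for placement.
#' @param ref_taxa Optional named taxon ids for the reference sequences.
#' @param out_dir Optional directory; when given, all artifacts (hit
#'   tables, annotation TSV, per-HMM Newick trees and aligned FASTA,
#'   Krona text files, heatmap TSV) are written there.
#' @return List: `annotations`, `heatmap`, `hits`, `ref_hits`, `trees`,
#'   `alignments`, `profiles`, `params`.
#' @export
run_pipeline <- function(hmms, reference, datasets, taxonomy,
                         evalue = 1e-6, consensus = 0.8,
                         identity_floor = 40, rank = "genus",
                         min_aa = 10L, code = "11", min_overlap = 10L,
                         ref_taxa = NULL, out_dir = NULL) {
  profiles <- load_profiles(hmms)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_fasta(reference, "protein")
  }
  tax <- if (inherits(taxonomy, "taxonomy")) taxonomy
         else load_taxonomy(taxonomy)

  message("stage=reference_search profiles=", length(profiles),
          " references=", length(reference))
  ref <- collect_reference_homologs(profiles, reference, cutoff = evalue,
                                    taxa = ref_taxa)
  profiles <- profiles[names(profiles) %in%
                         names(which(lengths(ref$subsets) > 0))]
  if (!length(profiles)) stop("no HMM retained any reference homolog")

  orf_sets <- lapply(datasets, function(d) {
    if (is.data.frame(d)) d
    else {
      if (is.character(d) && length(d) == 1L && file.exists(d)) {
        d <- read_fasta(d, "dna")
      }
      orf_set(d, min_aa = min_aa, code = code)
    }
  })
  message("stage=translate datasets=", length(orf_sets), " orfs=",
          sum(vapply(orf_sets, nrow, integer(1))))

  hits <- search_metagenomes(profiles, orf_sets, cutoff = evalue)
  message("stage=metagenome_search hits=", nrow(hits))

  # per-HMM reference machinery: match rows, taxa, NJ tree
  trees <- list(); ref_rows_all <- list(); leaf_taxa_all <- list()
  ref_scores_all <- list()
  for (nm in names(profiles)) {
    rh <- ref$hits[ref$hits$hmm == nm, , drop = FALSE]
    rows <- stats::setNames(rh$match_row, rh$target_id)
    ref_rows_all[[nm]] <- rows
    leaf_taxa_all[[nm]] <- stats::setNames(rh$taxon_id, rh$target_id)
    ref_scores_all[[nm]] <- stats::setNames(rh$bit_score, rh$target_id)
    trees[[nm]] <- if (length(rows) >= 3L) {
      neighbor_joining(protein_distance_matrix(rows))
    } else NULL
  }

  best_hits <- list(); placements <- list()
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits))) {
      nm <- hits$hmm[r]
      key <- paste(hits$dataset[r], nm, hits$read_id[r], sep = "|")
      best_hits[[key]] <- classify_best_hit(
        hits$match_row[r], ref_rows_all[[nm]], leaf_taxa_all[[nm]], tax,
        identity_floor = identity_floor, ref_scores = ref_scores_all[[nm]])
      placements[[key]] <- if (is.null(trees[[nm]])) NULL else {
        pl <- place_query(trees[[nm]], hits$match_row[r],
                          ref_rows_all[[nm]], min_overlap = min_overlap)
        if (is.null(pl)) NULL else {
          cl <- classify_by_placement(trees[[nm]], pl, leaf_taxa_all[[nm]],
                                      tax, threshold = consensus)
          cl$placement <- pl
          cl
        }
      }
    }
  }
  ann <- if (nrow(hits)) build_annotation_table(hits, best_hits, placements)
         else NULL
  message("stage=classify annotated=", if (is.null(ann)) 0 else nrow(ann))
  hm <- if (!is.null(ann)) build_heatmap(ann, rank = rank) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hit_table(hits, file.path(out_dir, "hits.tsv"))
    write_hit_table(ref$hits, file.path(out_dir, "reference_hits.tsv"))
    if (!is.null(ann)) {
      write_annotation_table(ann, file.path(out_dir, "annotations.tsv"))
      export_krona_text(ann, file.path(out_dir, "krona"))
      write_heatmap(hm, file.path(out_dir, paste0("heatmap_", rank, ".tsv")))
    }
    for (nm in names(profiles)) {
      if (!is.null(trees[[nm]])) {
        ape::write.tree(trees[[nm]],
                        file.path(out_dir, paste0("tree_", nm, ".nwk")))
      }
      write_fasta(ref_rows_all[[nm]],
                  file.path(out_dir, paste0("refaln_", nm, ".fasta")))
    }
  }

  list(annotations = ann, heatmap = hm, hits = hits, ref_hits = ref$hits,
       ref_subsets = ref$subsets, trees = trees,
       ref_alignments = ref_rows_all, leaf_taxa = leaf_taxa_all,
       profiles = profiles, placements = placements,
       best_hits = best_hits, taxonomy = tax,
       params = list(evalue = evalue, consensus = consensus,
                     identity_floor = identity_floor, rank = rank,
                     min_aa = min_aa, code = code,
                     min_overlap = min_overlap))
}
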