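---
title: "Function-specific taxonomic profiling with hmmtax: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-specific taxonomic profiling with hmmtax: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmtax)
```

## The problem

Whole-community taxonomic profilers answer "who is there" for an entire
metagenome. Many questions are narrower: who carries *this* function —
which organisms contribute the nitrogenase, the hydrogenase, the cobalamin
synthesis genes in a sample? `hmmtax` answers that question by restricting
taxonomic profiling to the reads that match one or more user-chosen protein
families, each described by a profile hidden Markov model (HMM), and
classifying only those reads. When the chosen families are single-copy
taxonomic markers the same machinery estimates overall community
composition; when they are pathway markers it yields a function-specific
profile, and markers of both kinds can be compared side by side across
many metagenomes.

The package implements the whole backend in R: HMMER3 profile parsing and
local Viterbi alignment, six-frame ORF translation, E-value filtering,
two taxonomic classifiers (similarity best-hit and phylogenetic placement
with subtree consensus), comparative reports, and a synthetic benchmark
generator so that every stage is testable without external databases.

## Pipeline overview

For each profile HMM and each metagenome:

1. **Reference homolog collection.** Every profile is scored against the
   full reference protein set exactly once. References with E-value at or
   below the cutoff become that family's *reduced reference database*; all
   downstream classification searches only this subset. This one-pass
   design is what keeps per-family profiling cheap: the full database is
   never touched again.
2. **Translation.** Nucleotide reads are translated in all six frames;
   each stop-free segment of at least `min_aa` residues (default 10)
   becomes a candidate peptide fragment. ORFs are stop-to-stop, with no
   start-codon requirement: metagenomic reads are arbitrary gene
   fragments, and demanding a start codon would discard most true
   homologs. The default genetic code is the bacterial/archaeal table 11.
3. **Homology search.** Each fragment is scored by local Viterbi
   alignment; fragments with E-value at or below the cutoff (default
   `1e-6`) are kept, and each read votes at most once per family — only
   its lowest-E fragment is retained, with deterministic tie-breaking by
   frame order (+1,+2,+3,−1,−2,−3) and then coordinate.
4. **Classification** by two routes, reported side by side (below).
5. **Reporting.** A per-read annotation table (TSV), Krona text-import
   files, a taxon × (dataset × HMM) proportion heatmap with an explicit
   Unclassified row, and cross-marker averaged profiles.

## The profile HMM model

A profile of `M` match states carries per-state match-emission and
insert-emission probabilities plus transitions (M→M, M→I, M→D, I→M, I→I,
D→M, D→D). On parsing, the HMMER3 file's negative natural-log
probabilities are converted to log-odds in bits against a fixed i.i.d.
amino-acid background (the Swiss-Prot-derived frequencies used by standard
profile-HMM null models).

Alignment is **uni-hit local**: one envelope per target, which is the
right granularity for classifying short reads (a read votes once). Local
entry is uniform over match states (probability `1/M`) and exit from any
match state is free. This is simpler than a full multi-hit architecture
with begin/end length modelling — the calibration step absorbs the
difference at the scale this package targets, and the simpler model is
exactly enumerable, so the dynamic program is verified against brute-force
path enumeration over all local alignments on small cases. Residues
outside the 20-letter alphabet (`X` from ambiguous codons) emit the
background in every state, i.e. contribute 0 bits. Traceback ties prefer
match over delete over insert, making alignments fully deterministic.

**E-values.** Viterbi bit scores of non-homologous sequences follow a
Gumbel law; with calibration `(mu, lambda)` the E-value in a database of
`N` sequences is `E = N * (1 - exp(-exp(-lambda * (s - mu))))`. `N` is the
number of sequences actually searched per (profile, dataset) pair.
Calibration is read from `STATS LOCAL VITERBI` lines when present; for
profiles lacking them the slope is fixed at `lambda = log 2` (the
theoretical value for bit scores) and the location `mu` is fitted by
maximum likelihood to the scores of 200 background sequences drawn under a
fixed internal seed, so calibration — and hence the whole pipeline — is
reproducible run to run. The null model omits a target-length correction;
at fixture scale the location fit absorbs it, and the E-value cutoff of
`1e-6` sits far from the regime where the correction matters.

## Match-state coordinates

Both classifiers work in the profile's match-state coordinate system: each
retained sequence is projected onto the `M` match columns of its Viterbi
traceback (insert residues dropped, deletions as gaps). This fixed-width
alignment is what an `hmmalign`-style re-alignment would give, reuses the
alignment already computed during search, and makes downstream identity
and distance computations deterministic. Rows are written as aligned FASTA
for offline use.

## Best-hit classification

The query's percent identity to each reference in the family subset is
`100 * (identical columns) / (columns where both are non-gap)`. The best
reference wins (ties: higher reference bit score, then lexicographic id)
and donates its full lineage. If the best identity falls below the
**identity floor** (default 40%) the read is Unclassified — this mirrors
the failure mode of similarity-search classifiers, which stop working when
reads are too dissimilar from the database, and 40% is the permissive end
of the commonly cited 40–50% twilight range. Identity is computed on match
columns rather than from a fresh pairwise alignment: it is deterministic
and reuses the HMM's column homology.

## Phylogenetic classification

1. **Distances.** Pairwise distances over match columns use the p-distance
   with Kimura's empirical protein correction
   `d = -ln(1 - p - p^2/5)`, clamped to `d = 5` when `p >= 0.85` where the
   correction saturates.
2. **Reference tree.** Neighbor joining (Saitou–Nei Q criterion) on the
   reference subset. Ties in Q resolve to the smallest index pair;
   negative branch lengths are clamped to zero with the deficit moved to
   the sibling edge so the joined pair's total is preserved. On an
   additive matrix NJ provably recovers the generating topology and branch
   lengths, which the tests exercise against an independent
   implementation. Trees are written as Newick and can be re-used.
3. **Placement.** Each query is attached to the edge, distal position
   `x` and pendant length `p >= 0` minimizing the sum of squared
   differences between tree path distances and the query's observed
   distances to every leaf. Writing `eps_i = +1` for leaves on the child
   side of an edge and `-1` otherwise, the model distance to leaf `i` is
   `p + eps_i x + c_i` with a per-leaf constant `c_i`, so each edge's
   optimum is a 2×2 linear solve with box constraints, evaluated in closed
   form; the global argmin over edges wins, ties to the lower edge index.
   When the query's distance vector is exactly realizable on the tree the
   optimum has zero residual — in particular a query identical to a leaf
   places on that leaf's pendant edge with pendant length 0. With noisy
   (non-additive) distances the identical-row query still lands on its
   leaf's pendant edge, but its fitted pendant is of the order of the NJ
   fit residual rather than exactly zero; the exact-zero property is
   therefore tested with tree-realizable distance vectors, and the noisy
   case is covered by a stochastic true-or-adjacent-edge bound. Queries
   covering fewer than 10 match columns are left unplaced (distances from
   a handful of columns are unstable), as are queries with no overlap with
   some leaf.
4. **Subtree consensus.** "The subtree containing the placed read" is
   ambiguous on an unrooted tree; `hmmtax` defines it as the
   smaller-leaf-count side of the attachment edge (ties to the side
   holding the lexicographically smallest leaf), which is bounded and
   deterministic. At each canonical rank the modal taxon and its support
   fraction over that side's lineages are computed; the read is assigned
   at the deepest rank whose support reaches the **consensus threshold**
   (default 80%) with every shallower rank also qualifying. A tie between
   two modal taxa disqualifies the rank regardless of threshold
   (conservative), and lineages lacking a rank are excluded from that
   rank's denominator so sparsely annotated references do not penalize
   the ranks they do carry; a rank carried by no lineage is skipped
   without blocking deeper ranks. A placement on a pendant edge therefore
   inherits the leaf's full lineage, which keeps the two classifiers
   consistent on exact matches.

## Taxonomy handling

The taxonomy reader accepts the NCBI taxdump dialect (`nodes.dmp` /
`names.dmp`, `\t|\t` separators) and a plain 4-column TSV. Ranks are
normalized to the seven Linnaean ranks (superkingdom … species); anything
else, including the root, becomes `no_rank` and is skipped in lineages.
The index supports lineage materialization, lowest common ancestors
(verified against ancestor-set intersection), and the rank-wise consensus
above. The LCA of disjoint superkingdoms is the unranked root, which
yields Unclassified at every canonical rank.

## Reporting conventions

Each (dataset, HMM) pair conserves counts across reports: Krona line
counts, annotation rows and heatmap column numerators are identical by
construction, and the tests assert it. Heatmap columns are proportions
over retained reads with an explicit Unclassified row, so columns sum
to 1. Per-dataset profiles averaged across markers use an **unweighted**
mean of the per-HMM columns: each marker family is treated as an
independent estimator of composition, so a deeply sampled family does not
dominate. The benchmark harness, by contrast, scores Unclassified reads
as *incorrect* — an explicit category in displays, a penalty in
evaluation. All outputs are byte-identical across repeated runs on the
same inputs.

## The synthetic benchmark

`simulate_world()` builds a self-contained test world emulating a
simulated-community benchmark at desk scale:

* a ranked taxonomy by nested bisection of a species set (two phyla,
  nested genera of two species each, one superkingdom);
* per marker family, a balanced species tree with independent exponential
  branch lengths (pendant mean 0.06, internal mean 0.10
  substitutions/site — within-genus identity around 90%, cross-phylum
  around 50–60%, spanning the informative range for both classifiers);
* leaf proteins evolved from a random 120-residue root by Poisson
  substitution with a **uniform replacement kernel** over the 19
  alternatives. Uniform (rather than an empirical matrix such as LG/WAG)
  keeps the generator dependency-free and consistent with the simple
  mismatch-fraction distances used downstream;
* a profile HMM per family, with match emissions from column frequencies
  plus background pseudocounts, and Gumbel calibration computed at build
  time and embedded as `STATS` lines.

`simulate_reads()` fragments the leaf proteins: a random window is
reverse-translated with uniform synonymous codon choice (table 11),
per-base substitutions are applied at the requested divergence, and the
read lands on a random strand. The truth map records each read's source
leaf and species. Every draw flows from one seed in a fixed order, so
worlds and read sets are reproducible bit for bit.

What the generator deliberately does **not** model: indels (so ORFs never
frameshift), codon usage bias, sequencing error profiles, chimeras,
contamination, paralogy and horizontal transfer, and a reference database
that is a biased subsample of the community. Passing tests on this world
therefore demonstrate the correctness and internal consistency of the
algorithms — recovery of planted homologs, calibration of the E-value
filter, exactness of NJ and placement on realizable inputs, conservation
across reports — not field accuracy on real metagenomes, where divergence
from the reference universe is the dominant error source.

## Problem sizes and defaults

The packaged benchmark uses 3 marker families over 8 species with
500 reads of 300 nt at 5% divergence, plus 150-read sets at the three
divergence bins 0–5%, 10–15% and 25–30% used for the
accuracy-versus-similarity stratification; these sizes give stable
statistics while keeping a full run in the order of a minute or two on
one core. Defaults: E-value cutoff `1e-6` (boundary kept, `E <= cutoff`),
consensus threshold `0.8`, identity floor `40`%, reporting rank `genus`,
`min_aa = 10`, minimum placement overlap 10 columns. On the benchmark
world the expected behavior, which the acceptance checks recompute, is:
best-hit precision near-perfect at 5% divergence and monotonically
degrading with divergence; precision ordered phylum ≥ genus ≥ species;
and the placement route classifying at least as large a fraction of reads
as the best-hit route at the highest divergence bin, where best-hit
identities start falling under the floor.

## Known limitations

* The Viterbi engine is uni-hit and unaccelerated (no MSV/forward
  filters); it is built for per-family read sets and small reference
  subsets, not for whole-database scans.
* Only per-target best-domain E-values are filtered; there is no
  multi-domain envelope logic.
* NJ with least-squares placement replaces likelihood-based tree building
  and placement; the classification semantics (subtree consensus over an
  edge attachment) are preserved and externally built Newick trees can be
  supplied, but posterior placement uncertainty is not modelled.
* The Kimura correction saturates at p ≥ 0.85; distances between very
  remote homologs are all clamped to 5, which flattens deep tree
  structure.
* Protein-space FASTA inputs bypass translation entirely; quality-aware
  FASTQ handling is out of scope.
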