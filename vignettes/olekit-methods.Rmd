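---
title: "Methods: detecting ole clusters and modelling olefin profiles"
author: "olekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting ole clusters and modelling olefin profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Certain bacteria synthesize long-chain internal olefins through the ole
pathway: the thiolase OleA condenses two fatty-acyl-CoA substrates
head-to-head into a β-keto acid, OleD reduces it, OleC forms a β-lactone,
and OleB decarboxylates the lactone to a cis olefin. Because one carbon is
lost at decarboxylation, an olefin built from precursors of `n1` and `n2`
carbons has `n1 + n2 - 1` carbons, and each of its two ends inherits the
branch state (iso, anteiso, or straight) of one precursor.

`olekit` implements, as testable desk-scale components, the computational
steps of a survey of this pathway in bacterial genomes: motif-based OleA
discovery, gene-neighborhood verification of the full `oleABCD` cluster,
a sequence similarity network (SSN) over OleA proteins, mapping of cluster
presence onto a species phylogeny, internal-standard quantification of
GC/MS olefin and fatty-acid peak tables, and a generative condensation
model that links precursor pools and OleA substrate specificity to olefin
chain-length × branch-isomer distributions. Every stage can be exercised
without downloads through seeded synthetic-data generators that emit
machine-readable ground truth.

# Motif screen

Putative OleA thiolases are found with the compact PROSITE-style pattern
`EPxx[AS]x(14,18)DxxNACL` (13 elements; any match spans 26–30 residues).
The scanner reports every sequence position at which a match can start,
one match per start using the shortest admissible span (lazy gap). The
pipeline only consumes "has at least one hit", so the choice of span
convention does not affect downstream results; shortest-span was chosen
because it is deterministic and cheap to verify. Three conventions are
worth stating:

* **Ambiguity codes.** `B`, `Z`, `X` in input proteins satisfy wildcard
  elements but never literal, choice, or exclusion elements — a
  conservative reading that can only lose borderline candidates, never
  invent them.
* **Coordinates** are 0-based half-open internally and converted to
  1-based inclusive only at export boundaries.
* **Exclusion sets** `{..}` are supported for completeness even though
  the OleA screen does not use them. N-/C-terminal anchors and
  profile/PSSM scanning are out of scope.

Correctness is established against an exhaustive enumerator that tries
every (start, repeat-assignment) combination; the suite checks equality of
hit-start sets and spans on hundreds of random and planted proteins.

# Homology and E-values

Neighborhood verification needs pairwise protein homology calls. The
package implements Smith–Waterman local alignment with affine gaps
(BLOSUM62, gap open 11, extend 1; a gap of length L costs `11 + L`),
with a deterministic traceback (diagonal preferred over up over left,
earliest optimal end cell in row-major order). Percent identity divides
identities by the alignment length including gap columns — a convention
that must be fixed for the 75% collapse below to be deterministic.

Significance uses the Karlin–Altschul form `E = K·m·n·exp(-λ·S)` on the
raw score with the standard gapped constants for BLOSUM62 11/1
(λ = 0.267, K = 0.041). No bit-score conversion is applied: for a fixed
scheme the map score → E is monotone, so thresholding at `E ≤ 1e-5` is
unaffected. Heuristic seeding and composition-based statistics are
deliberately absent; at desk scale the exact quadratic algorithm (in
Rcpp) is fast enough for every analysis the package performs.

The aligner is validated two ways: against exhaustive enumeration of all
gapped local alignments on short sequences, and against an independent
dynamic-programming implementation (`Biostrings::pairwiseAlignment`) on
both tiny and realistic-length pairs.

# Cluster detection

A genome is called positive when a motif-bearing oleA candidate has, on
the same contig, neighbors homologous to both query proteins (an OleBC
fusion and OleD) with `E ≤ 1e-5`, each gene's span intersecting the oleA
span extended by ±5000 bp. Design choices, all configurable:

* The window is anchored to the oleA **gene span**, extended by ±5000 bp,
  with any-overlap inclusion — the most permissive deterministic reading
  of "close vicinity"; the reported `distance_bp` is the gap between
  closest gene boundaries (0 when spans overlap).
* Hits to the oleA gene itself never count as oleBCD evidence.
* Clusters never span contigs.
* Multiple oleA candidates are verified independently; the genome-level
  call is their OR.

GenBank flat files (single-interval CDS with `/locus_tag` and
`/translation`) and GFF3+FASTA are both supported and produce identical
internal records; proteins without provided translations are translated
with genetic code table 11, minus-strand features from the reverse
complement. Compound/join locations and pseudogenes are out of scope.

# Sequence similarity network

Nodes collapse proteins connected by single-linkage chains of pairwise
identity **strictly greater than** 75%; single linkage was chosen over
greedy centroid clustering because it is order-independent and
reproducible. The representative is the longest member (ties by
lexicographic id). Edges join distinct nodes when some member pair aligns
with `E < 1e-5` (strict, matching the network threshold's wording as
opposed to the neighborhood cutoff's `≤`), weighted by the best
member-pair score. Edges between nodes labelled with different phyla are
flagged as lateral-transfer candidates.

The all-vs-all step is exact. A k-mer prefilter was considered for
larger inputs and rejected: at the problem sizes this package analyses
(tens of sequences; hundreds of pairs) the exact all-vs-all completes in
seconds, and a prefilter would add a losslessness proof obligation
without measurable benefit here.

# Phylogenetic mapping

Presence/absence is mapped onto a species tree by leaf name; table rows
missing from the tree are reported, not fatal, and are excluded from
cluster counting but kept in genus-level statistics (the two statistics
have different domains). Two statistics are computed:

* **Genus ubiquity**: per-genus fraction of trait-positive species and
  the share of genera that are all-or-none.
* **Presence clusters**: visual cluster counting on a circular tree is
  operationalized as the number of maximal runs of present leaves in a
  canonical ladderized leaf order (children sorted by subtree size, ties
  by smallest contained leaf name), with runs separated by at most
  `gap_tolerance` non-present leaves merged. `gap_tolerance` defaults to
  0 and is exposed rather than guessed, because the rank at which a
  human reader ignores gaps is not derivable; leaves of unknown status
  count as gaps.

# GC/MS quantification

Peak identity is taken from the input table's labels; spectral
deconvolution is upstream of this package. Olefins are quantified by
direct area comparison with the triacontane internal standard (default
40 µg: 4 mL hexane × 10 µg/mL), FAMEs against eicosanoic acid (default
50 µg: 0.5 mL × 100 µg/mL). Response factors default to 1 for every
analyte — the "direct comparison" reading — and are configurable
per analyte. Amounts are reported in µg per mL of culture per OD600
unit, dividing linearly by the measured OD600:

`amount_i = (area_i / area_IS) · amount_IS / volume_mL / OD600`

so the worked example — equal areas, 40 µg standard, 10 mL culture,
OD 2 — gives 2 µg·mL⁻¹·OD⁻¹. Quantification is invariant under a global
rescaling of all areas. Each olefin's two chain ends map to one of six
unordered branch-pair classes (`isoiso`, `isoai`, `aiai`, `isosc`,
`aisc`, `scsc`); marginal distributions over chain length and isomer
class, and total-variation distances between joint profiles, summarize
and compare profiles.

# Condensation model

The generative model is the minimal quantitative formalization of the
pathway chemistry plus the observation that OleA substrate specificity
and precursor availability jointly determine the product profile. Each
product draws two precursors **independently** from the pool, species
`s` with probability proportional to `f_s · w_s` (abundance ×
specificity weight); the unordered pair `{i, j}` has probability
`u_i u_j (2 − [i = j])` and maps to chain length `n_i + n_j − 1` and the
isomer class of its branch pair. Independence of the two draws is the
simplest assumption that reproduces the observed swap behaviour and
keeps the model identifiable; any dimerization cooperativity is beyond
what profile data alone can constrain.

Because the multinomial likelihood is scale-free in `w`, weights are
anchored by `Σ f_s w_s = 1`. Fitting maximizes the multinomial
likelihood by expectation–maximization over latent precursor pairs
(allocate each observed cell's count to its compatible pairs, then
re-estimate draw probabilities); from the uniform start the procedure is
deterministic, the log-likelihood provably never decreases, and the
suite asserts monotonicity per iteration. Convergence uses a `1e-12`
tolerance on draw probabilities with a 5000-iteration cap; fitting the
exact expectation of a known model recovers its weights to < 1e-6
relative error, and 10^5-draw samples recover them within 10% (median
over 20 replicates). Observed cells unreachable from the pool are an
error by default (`allow_slack = TRUE` drops them with a warning).
Weights are per (chain length, branch) class; unsaturated and cyclic
fatty-acid species are excluded from pools by default because olefin
tables report only branch classes. Absolute flux is deliberately not
modelled — only the product distribution — since profile data carry no
expression or activity information.

The in-silico swap experiment predicts the same host pool under host and
donor weights. Its direction-level expectations: an
anteiso-C15-dominated host peaks at C29 (15+15−1); donor weights
favouring short iso precursors shift the mode down and raise
iso-containing classes; and a host pool without straight-chain
precursors can never yield `scsc` products regardless of donor weights —
a pure support constraint.

# Synthetic data

The generators define the study conditions; their defaults are fixed and
not tuned per test:

* **Genome benchmark**: 30 positives and 10 genomes per decoy class
  (motif broken by one forbidden residue; homologs displaced beyond
  5000 bp; oleD neighbor residue-scrambled; homologs on another contig).
  Planted OleBC/OleD homologs sit at 85% identity to the synthetic query
  proteins — comfortably inside the E-cutoff — while scrambled neighbors
  score near the random background (empirically E ≥ ~1e-2, three orders
  of magnitude above the cutoff). Proteins are drawn uniformly over the
  20 residues; every non-planted protein is resampled until motif-free,
  so a generated dataset provably contains exactly the planted hits and
  the zero-noise benchmark must separate perfectly — which is what the
  sensitivity/specificity check verifies.
* **Families**: blocks mutated from a common ancestor with substitutions
  on disjoint position sets, so positional pairwise identities equal the
  within/between targets exactly; local-alignment identities may deviate
  by ±2 points through end trimming. Infeasible targets (not enough
  positions) are refused.
* **Trees**: coalescent-shaped, genus-monophyletic; exactly `k` whole
  genera are positive, placed at alternating positions of the canonical
  leaf order so the planted cluster count is exactly `k` (hence
  `k ≤ ⌈genera/2⌉`), and genus ubiquity is 1 by construction.
* **Peak tables**: multinomial molecule counts from the model, optional
  per-class response factors, multiplicative lognormal noise with mean 1
  and chosen CV, and an internal-standard row on the same area scale.

What the generators do **not** emulate — realistic codon usage and GC
content, chromatographic peak shapes, co-eluting analytes,
response-factor drift, non-uniform residue composition, paralogs at
intermediate identity — bounds what green tests mean: they demonstrate
correctness of the algorithms under their stated models, not performance
on real survey data, where motif sensitivity and the 75%/E-value
conventions of third-party tools dominate.

# Problem sizes and numerical choices

The suite and the acceptance script run on fixture sizes chosen to make
every check exact or statistically stable on one CPU in minutes: 70
genomes with ~5 genes each; 10–12 sequence families of length 120–200;
42-leaf trees; 10^5-molecule peak tables (10^6 for the tightest
convergence check); 20 fitting replicates. Determinism throughout comes
from explicit seeds: generators take a seed, restore the caller's RNG
state, and regenerate byte-identical files from the same seed.

Degenerate inputs are defined errors, not silent results: empty
sequences for alignment, missing/zero-area internal standards, observed
cells unreachable from a pool, repeat ranges with min > max, out-of-bounds
CDS coordinates.

# Known limitations

* GenBank support covers single-interval CDS features only.
* E-values use fixed scheme constants; they are calibrated for
  thresholding, not for reproducing BLAST report numbers.
* The 75% collapse convention of third-party SSN servers is not fully
  documented upstream; single-linkage over alignment-length identity is
  one defensible reading, so external node counts should be treated as
  approximate cross-checks.
* The condensation model treats draws as independent and ignores
  OleBCD-step selectivity and absolute flux.
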