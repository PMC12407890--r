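---
title: "Methods: barcoded Kras G12D clonal tracing from targeted single-cell amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded Kras G12D clonal tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotracer)
```

# The experimental system and what the package computes

In the autochthonous pancreatic-cancer model this package supports, tumour
initiation is driven by homology-directed repair that knocks an engineered
*Kras* allele into the endogenous locus. The engineered allele carries three
kinds of changes inside the codon 2–31 window: the oncogenic G12D
substitution, six fixed synonymous substitutions at codons 3–8 that destroy
the sgKras protospacer (so the repaired allele is not re-cut), and a
combination of synonymous changes — mostly at wobble bases — that acts as a
heritable clone barcode. Because HDR is rare, essentially every malignant
cell carries exactly one barcoded G12D allele plus an untouched wildtype
allele; reading the barcode from the 10x cDNA pool by targeted resequencing
(KrasBC-Seq) therefore assigns each cell to its clone of origin, and the
G12D:WT transcript ratio reports the allelic conformation of the locus. A
companion targeted library (Kdm8-Seq) reads the *Kdm8* transcript in the
same cells to infer which carry inactivating edits.

The package implements that computational pipeline end to end — library
design, ground-truthed simulation, molecule-level barcode calling, per-cell
quantification, Kdm8 genotyping, and clone-by-state analytics — with the
wet-lab stages, transcriptome clustering, and trajectory inference
explicitly out of scope (state labels and transcriptome UMI totals are
consumed as annotations).

# Barcode library design

A `barcode_design` is a codon window plus disjoint sets of fixed and
variable codons. Variable codons carry their allowed synonymous codon sets;
under the default wobble-only policy these are the third-position variants
encoding the same amino acid. The predicted diversity is the product of the
allowed-set sizes.

The construct this design emulates fixes only the total diversity
(2,359,296) and the fixed substitutions, not which codons vary. The default design ships the
unique decomposition of that number into standard degeneracy classes within
the window: nine four-fold-degenerate codons and the two isoleucine codons
(21 and 24; three wobble options each), since 4^9 × 3^2 = 2,359,296 and no
other combination of wobble families in this window reproduces it. Among
the eleven four-fold candidates in the window we take the nine closest to
the G12D codon (2, 9, 10, 11, 13, 14, 15, 18, 20); which nine are chosen
does not affect diversity, synonymy, or any downstream computation.

```{r diversity}
design <- kras_default_design()
compute_diversity(design)
```

The bundled wildtype window is a synthetic stand-in for the murine Kras CDS
segment: it encodes the correct residues 2–31, contains the documented codon
3–8 segment and the sgKras protospacer context, and uses GGT at codon 12 so
that G12D is the canonical single-base GGT→GAT change; wobble bases outside
the documented segments are representative rather than transcript-verified.
Every quantity the package computes depends only on the designed structure,
not on those free wobble choices. The two oligo pools flanking G12D are
modelled as a single design; pool partitioning does not change the barcode
space.

# The synthetic-data generator

`simulate_truth()` draws, per cell: a clone (power-law sizes, exponent
`clone_alpha = 1`), a transcriptomic state (per-clone Dirichlet mixing over
three labels), an allelic mode, per-allele UMI counts, Kdm8 status, and a
log-normal transcriptome depth. `emit_fastqs()` expands every true molecule
into `1 + Pois(reads_per_umi − 1)` duplicate reads (so each UMI is seen at
least once), with substitution errors applied to read 2 at
`per_base_error`. Read 1 is the 16 + 10 nt cellBC/UMI of 10x 5' chemistry,
kept error-free; barcode-whitelist correction is still implemented and
tested, but the simulator's difficulty lives in read 2, where calling
actually happens.

Two generator choices deserve emphasis:

* **Classes are drawn conditioned on the classification rule.** A
  "balanced" cell, for example, draws its G12D and WT counts from iid
  shifted Poissons conditioned on the event `1 ≤ WT ≤ G12D`; an
  "imbalanced" cell has WT fixed at 0 and G12D ≥ 2. This makes the true
  class identical to the rule applied to the true counts *and* makes class
  frequencies match the configured probabilities exactly in distribution —
  so truth-recovery tests are sharp, at the cost of mild truncation bias in
  the marginal count distributions.
* **Defaults are the study conditions where stated, desk-scale choices
  elsewhere.** `p_kdm8_positive = 0.114` is the observed positive fraction;
  class rates, sequencing depths and error rates of the targeted libraries
  are not fixed by the assay, so the remaining defaults (imbalanced 0.15, WT-dominant 0.05,
  somatic 0.10, ~4 UMIs per expressed allele, 3 reads per UMI) were chosen
  once for a realistic shallow targeted library and are not tuned.

What the generator does **not** emulate: PCR chimeras, ambient-RNA soup,
indel sequencing errors (substitution-only by default, so the edit-distance
merge test stays interpretable), quality-score structure (constant 'I'),
spike-in cells, and UMI collisions across alleles (UMIs are drawn distinct
within a cell so molecule conservation is exact). Passing tests on this
generator demonstrate the pipeline's logic, not robustness to every
artefact of real droplet data.

# Read processing and allele calling

KrasBC read 2 is trimmed with a linked, both-optional flank pair, each
tolerating up to `floor(0.2 × flank length)` mismatches; the best occurrence
is minimal-mismatch with ties resolved leftmost (5') / rightmost-start (3'),
and the 3' flank is only searched downstream of the 5' trim point. Matching
is substitution-only, consistent with the error model. Kdm8 read 2 drops a
fixed 26-bp primer-derived prefix.

Inserts are matched to the allele reference by **semi-global edit
distance** — insert aligned globally, reference locally, unit costs — via
`Biostrings::pairwiseAlignment(type = "global-local")`, a deliberate
replacement of the genome-scale short-read aligner a production pipeline
would use: at desk scale (dozens of
~90-nt alleles) exact edit-distance semantics make every call decidable and
testable against a dynamic-programming oracle, which the suite does on
randomized references. The call is the unique minimum if it is within
`max_edit_distance = 3`; tied minima are `AMBIGUOUS` and excess distance is
`UNMAPPED`, both discarded from quantification but counted in QC. The
threshold mirrors the barcode-merge radius so that a sequencing error within
one merge class still maps. Designs whose minimum pairwise allele distance
is ≤ 2 × `max_edit_distance` trigger a warning, since equidistant ties then
become possible; randomly sampled wobble barcodes routinely sit near this
bound, which in practice costs only the rare discarded ambiguous read.

# Per-cell quantification

Molecules are collapsed on the exact (cellBC, allele, UMI) triplet. Within
each cell, barcode counts are then merged **directionally**: a barcode
within edit distance 2 (the "distance < 3" rule) of a strictly
higher-count barcode is absorbed into it, lower into higher, ties among
candidate parents broken by count then lexicographic allele id, chains
resolved to their root. Directional merging (as in UMI-tools) matches the
generative model — error barcodes are low-count satellites of a real
parent — and is order-stable; whether the assay's merge was directional or
clique-based is not specified, and the merge is applied per cell, the reading
consistent with per-cell dominant assignment. Counts are conserved exactly;
the wildtype allele never participates.

Classification follows the assay's cell-class definitions, with two points
they leave open resolved as follows:

* `MALIGNANT`: unique maximum among merged barcode counts (the dominant
  barcode). A **tied** maximum leaves no dominant barcode; such cells are
  `EXCLUDED` regardless of wildtype count, because a detected barcode
  violates the somatic "no detectable barcode" definition.
* `SOMATIC`: no barcode and more than one wildtype UMI.
* `EXCLUDED` otherwise — including the no-barcode, exactly-one-WT-UMI cell,
  which fails both definitions under a strict reading; the count is
  carried in QC.

Allelic state of malignant cells (default rule): `IMBALANCED` when no
wildtype UMI is seen and the dominant barcode has ≥ 2 UMIs (the
`min_g12d_umis` floor guards against calling imbalance on a single
molecule); `WT_DOMINANT` when wildtype exceeds the dominant count;
otherwise `BALANCED`. The assay fixes no numeric
balanced/imbalanced rule; this threshold rule is the package's default, with an exact-binomial alternative (test of the G12D
fraction against 0.5 at α = 0.05) exposed alongside it. Kras abundance is
(dominant + wildtype UMIs) / transcriptome total × 10,000; depth scaling
names no constant in the assay, so counts-per-10k is fixed as the package
convention.

# Kdm8 genotyping

Kdm8 molecules are unique (cellBC, UMI) pairs on the transcript reference;
every annotated cell appears in the output with absentees imputed to zero.
The default positivity rule is detected-vs-zero, consistent with the
imputation language; the alternative `"antimode"` rule thresholds at the
kernel-density minimum between the two most prominent modes and falls back
(with a warning) when the distribution is not bimodal. A failed library can
be marked as such, yielding `NA` statuses rather than imputed negatives —
a different epistemic state than dropout within a working library. The
summary formatter reports the positive percentage at one decimal (797 of
6,999 → 11.4).

# Clone-by-state analytics

The clone-state table joins malignant profiles with annotations and Kdm8
status and counts cells per (clonotype, sample, state, allelic state, Kdm8
status); marginals are conserved and unannotated called cells are dropped
with a QC count. Sankey export emits clone→sample and sample→state links
with conserved flow. Clone sharing ranks primary clonotypes by cell count
(ties lexicographic) and reports the fraction of metastatic cells in the
top *k*.

`fisher_exact_two_sided()` is authored in-package: the exact conditional
hypergeometric test, two-sided by the probability-ordering convention, with
a relative tolerance of 1 + 1e-7 on the probability comparison so that
floating-point noise cannot flip a boundary table; degenerate margins
return 1. It agrees with `stats::fisher.test` and with full enumeration
over every 2×2 table of total ≤ 40 (the suite checks all 135,750 of
them). The imbalance-enrichment report builds one 2×2 per sample
(state-group × imbalance), using the Haldane–Anscombe correction for the
odds ratio only — the p-value is always computed on raw counts.

A note on calibration: exact conditional p-values are discrete and
conservative, so at small per-table counts their null distribution is
visibly super-uniform — a property of the test, shared by any correct
implementation, not an artefact. The calibration suite therefore checks
strict validity (P(p ≤ α) ≤ α) at generator scale, and checks approximate
uniformity (Kolmogorov–Smirnov over 500 independent-null replicates) at
5,000 cells per table, where the hypergeometric support is dense enough for
the asymptotic claim to be testable.

# Problem sizes and determinism

The test and acceptance suites run at the following sizes, chosen as the
package's own desk-scale conditions: zero-noise end-to-end at 500 cells /
20 clones (recovery must be exact); noisy recovery at 2,000 cells, 1%
per-base error, 3 reads per UMI (dominant-barcode accuracy ≥ 95%);
frequency recovery at 20,000 simulated cells (3-binomial-SD bands); caller
oracle equivalence on randomized references up to 50 alleles × 120 nt;
diversity-enumeration cross-checks on designs up to 10^5 barcodes. All
randomness flows through explicit integer seeds: `simulate_truth()` seeds
the stream and `emit_fastqs()` continues it, so a (params, seed) pair
reproduces a dataset bit-identically at the sequence level, and
`run_pipeline()` is deterministic given its inputs.

# Known limitations

* Double-HDR cells are assumed absent; doublets are modelled (union of two
  clones' molecules) but off by default, and doublet detection is not
  attempted.
* Cell-barcode correction handles one mismatch against a provided
  whitelist; there is no frequency-aware correction and no indel-tolerant
  read-1 parsing.
* The caller is exact but quadratic per (insert, allele) pair; it is sized
  for targeted references, not transcriptome-scale alignment.
* The antimode rule assumes a genuinely bimodal abundance mixture; with
  overlapping modes its threshold is noisy, which is why detected-vs-zero
  is the default.
* The synthetic wildtype window and Kdm8 fragment are labelled stand-ins;
  analyses that would depend on transcript-exact wobble bases outside the
  documented segments should substitute verified references via
  `write_reference()`/`read_reference()`.
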