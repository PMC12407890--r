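# clonotracer

Clonal barcode calling and allelic-imbalance analysis for single-cell
lineage tracing with synonymous-mutation barcodes engineered into the
*Kras*<sup>G12D</sup> allele.

## The problem

In barcoded autochthonous cancer models, tumour initiation installs an
engineered *Kras* allele carrying (i) the oncogenic G12D substitution,
(ii) fixed synonymous substitutions at codons 3–8 that confer sgRNA
resistance, and (iii) a clone-specific combination of synonymous wobble-base
changes drawn from a library of millions. Because homology-directed repair
is rare, each malignant cell carries exactly one barcoded G12D allele next
to an intact wildtype allele. Targeted resequencing of the 10x 5' cDNA pool
(KrasBC-Seq) then recovers, per cell, the clone of origin and the
G12D:WT transcript ratio; a companion targeted library (Kdm8-Seq) genotypes
loss of *Kdm8* expression in the same cells. This package is the analysis
side of that design, for researchers running or evaluating such tracing
experiments:

1. **Library design** — enumerate/sample the synonymous barcode space over a
   codon window. The default design (nine four-fold-degenerate codons plus
   the two isoleucine codons, wobble-only) has diversity
   4<sup>9</sup> × 3<sup>2</sup> = 2,359,296.
2. **Simulation** — ground-truthed paired FASTQs (clone structure, allelic
   classes, bimodal Kdm8 signal with 11.4% positive cells, PCR duplicates,
   substitution errors) plus the companion cell-annotation table.
3. **Barcode calling** — cellBC/UMI parsing, linked-flank trimming (20%
   error tolerance, both flanks optional), semi-global edit-distance
   matching to the allele reference (unique minimum ≤ 3, ties ambiguous).
4. **Per-cell quantification** — UMI collapsing on the (cellBC, allele,
   UMI) triplet; directional merging of error barcodes within edit
   distance 2; dominant-barcode assignment; `MALIGNANT` / `SOMATIC` /
   `EXCLUDED` classes; `BALANCED` / `IMBALANCED` / `WT_DOMINANT` allelic
   states; counts-per-10k Kras abundance.
5. **Kdm8 genotyping** — 26-bp prefix trimming, unique (cellBC, UMI)
   counting with zero imputation over the annotated cell universe,
   detected-vs-zero (or KDE-antimode) positivity.
6. **Analytics** — clone × sample × state tables, Sankey link export,
   primary→metastasis clone sharing, and an exact two-sided Fisher test
   (probability-ordering convention) for enrichment of allelic imbalance in
   chosen cell states.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated tumour
(1,000 cells, 20 clones, a metastasis seeded by the two largest clones,
0.5% per-base error):

```sh
Rscript analysis/01_design_library.R
Rscript analysis/02_simulate_reads.R
Rscript analysis/03_call_barcodes.R
Rscript analysis/04_genotype_kdm8.R
Rscript analysis/05_clonal_analysis.R
```

Output of the calling and analytics steps (abridged):

```
QC: 19841/19860 reads called (19 unmapped, 0 ambiguous)
Cell classes:
MALIGNANT   SOMATIC
      908        92
Allelic states (malignant cells):
   BALANCED  IMBALANCED WT_DOMINANT
        637         223          48
Dominant-barcode accuracy vs truth: 1

Kdm8 positivity: 84/1000 cells (8.4%)
Status agreement with truth: 1

Fraction of metastatic cells from the top-2 primary clonotypes: 1
Allelic-imbalance enrichment in hypoxic cells:
   sample_id odds_ratio  p_value
1:   primary       4.94 5.62e-17
2:       met       4.03 2.16e-03
Liver-metastasis contingency (0/13 vs 6/9): two-sided Fisher p = 0.001
```

Reading this: every read that survives QC is assigned to a reference allele
at most 3 edits away; all 908 malignant cells get the correct dominant
barcode; the Kdm8 detected-vs-zero rule reproduces the simulated positive
set exactly; all metastatic cells trace back to the two seeding clones; and
the planted hypoxia/imbalance association is recovered with odds ratios ~4
in both samples. The final line is the worked contingency example: 0 of 13
control mice versus 6 of 9 knockout mice with liver metastases gives
p = 0.001 by the package's exact two-sided Fisher test.

The same pipeline is available as a single call on any config
(`run_pipeline()` over a YAML or `pipeline_config()` object), writing stage
TSVs, a QC JSON and a run log.

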