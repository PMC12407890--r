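#!/usr/bin/env Rscript

# Step 1 — design the synonymous Kras G12D barcode library.
#
# Builds the default design (codons 2-31; nine four-fold variable codons plus
# the two isoleucine codons under the wobble-only policy), verifies that the
# fixed substitutions destroy the sgKras protospacer, samples a working
# reference of barcoded alleles, and writes it as FASTA.

suppressMessages(library(clonotracer))

dir.create("results", showWarnings = FALSE)

design <- kras_default_design()
message("Barcode design over Kras codons 2-31:")
message("  variable codons: ",
        paste(names(design$variable_codons), collapse = ", "))
message("  predicted diversity: ",
        format(compute_diversity(design), big.mark = ","))

engineered <- apply_fixed_substitutions(design$window, design$fixed)
wt_context <- paste0("ATG", design$window$cds_segment)
stopifnot(
  !check_protospacer_disruption(wt_context, kras_protospacer()),     # WT is cut
  check_protospacer_disruption(paste0("ATG", engineered), kras_protospacer())
)
message("sgKras protospacer: present in wildtype, disrupted in the engineered allele")

reference <- build_reference(design, n_barcodes = 50, seed = 20260922)
write_reference(reference, "results/reference.fa")
message("Wrote results/reference.fa (", nrow(reference), " alleles incl. Kras_WT)")
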