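## Bundled Kras locus constants and the default library design.
##
## The wildtype codon 2-31 window below is a synthetic stand-in for the murine
## Kras CDS (offline build; no sequence download). It encodes the correct
## Kras residues 2-31 (TEYKLVVVGAGGVGKSALTIQLIQNHFVDE), carries the documented
## codon 3-8 segment GAGTATAAACTTGTGGTG targeted by the sgKras protospacer,
## uses GGT at codon 12 so that G12D is the canonical single-base GGT->GAT
## change, and has isoleucine codons at positions 21 and 24. Analyses that
## depend only on the documented segments (sgRNA resistance, fixed-substitution
## arithmetic, library diversity) are exact; wobble bases elsewhere are
## representative, not RefSeq-verified.

## codons:         2   3   4   5   6   7   8   9  10  11  12  13  14  15
##                ACT GAG TAT AAA CTT GTG GTG GTT GGA GCT GGT GGC GTA GGC
##                16  17  18  19  20  21  22  23  24  25  26  27  28  29  30  31
##                AAG AGT GCC TTG ACG ATA CAG CTA ATT CAG AAT CAT TTT GTG GAC GAA
.KRAS_WINDOW_SEQ <- paste0(
  "ACTGAGTATAAACTTGTGGTGGTTGGAGCTGGTGGCGTAGGC",
  "AAGAGTGCCTTGACGATACAGCTAATTCAGAATCATTTTGTGGACGAA"
)

#' The bundled Kras codon 2-31 wildtype window
#'
#' A synthetic stand-in for the murine Kras CDS segment spanning codons 2-31
#' (see the package vignette): the encoded protein and the documented codon 3-8
#' and protospacer segments are exact, remaining wobble bases representative.
#'
#' @return a [codon_window()] with `first_codon_index = 2`.
#' @export
kras_window <- function() {
  codon_window(.KRAS_WINDOW_SEQ, first_codon_index = 2L)
}

#' The sgKras protospacer
#'
#' The guide target spanning Kras codons 2-8; the fixed sgRNA-resistance
#' substitutions of the engineered allele destroy this site.
#'
#' @return protospacer DNA string (20 nt).
#' @export
kras_protospacer <- function() "GACTGAGTATAAACTTGTGG"

#' Fixed substitutions of the engineered Kras G12D allele
#'
#' Six synonymous sgRNA-resistance substitutions at codons 3-8
#' (GAGTATAAACTTGTGGTG -> GAATACAAGCTAGTAGTC) plus the oncogenic G12D codon
#' (GGT -> GAT at codon 12), the single permitted non-synonymous change.
#'
#' @param g12d_codon replacement codon at position 12 (default `"GAT"`).
#' @return list of [fixed_substitution()] objects.
#' @export
kras_fixed_substitutions <- function(g12d_codon = "GAT") {
  c(
    Map(function(i, codon) fixed_substitution(i, codon, synonymous_required = TRUE),
        3:8, c("GAA", "TAC", "AAG", "CTA", "GTA", "GTC")),
    list(fixed_substitution(12L, g12d_codon, synonymous_required = FALSE))
  )
}

#' Default barcoded Kras G12D library design
#'
#' Nine four-fold-degenerate variable codons (2, 9, 10, 11, 13, 14, 15, 18,
#' 20) plus the two isoleucine codons (21, 24; three wobble options each),
#' under the wobble-only policy, giving a predicted diversity of
#' 4^9 x 3^2 = 2,359,296 barcodes. Fixed substitutions per
#' [kras_fixed_substitutions()].
#'
#' @param wobble_only wobble-only synonymy policy (default `TRUE`).
#' @return a [barcode_design()].
#' @examples
#' compute_diversity(kras_default_design())  # 2359296
#' @export
kras_default_design <- function(wobble_only = TRUE) {
  barcode_design(
    window = kras_window(),
    fixed = kras_fixed_substitutions(),
    variable_codons = c(2L, 9L, 10L, 11L, 13L, 14L, 15L, 18L, 20L, 21L, 24L),
    wobble_only = wobble_only
  )
}

## Amplicon flanks of the KrasBC-Seq read-2 insert (the linked-adapter pair
## used for trimming, from the targeted-library primer design).
.KRASBC_FLANK5 <- "CTCTATCGTAGGGTCATA"
.KRASBC_FLANK3 <- "CATTTTCAGCAGGCCT"

#' KrasBC-Seq amplicon flanks
#'
#' The 5' and 3' sequences flanking the barcode window in KrasBC-Seq read 2;
#' both are trimmed (each optional, up to a 20% error rate) before allele
#' matching.
#'
#' @return named character vector with elements `five_prime`, `three_prime`.
#' @export
krasbc_flanks <- function() {
  c(five_prime = .KRASBC_FLANK5, three_prime = .KRASBC_FLANK3)
}

## Kdm8-Seq read-2 layout: a fixed 26-nt primer-derived prefix followed by the
## transcript fragment. The fragment below is a synthetic stand-in for the
## Kdm8 transcript (offline build), used consistently by the simulator and
## the genotyper.
.KDM8_PREFIX <- "AGCTCCTCCTCTTTGTCAGGCTGACA"  # 26 nt
.KDM8_FRAGMENT <- paste0(
  "ATGGCGGACTTCCTGAAGCGATACGTTCAGGAATGGCTCCGT",
  "GACCTTGGAAGCCAATCGTTTACCAGACTGGAGCATCCGTAC",
  "GGATTCAACGTGCTGAAGTCCTACGACCTGATTGCAG"
)

#' Kdm8 targeted-sequencing constants
#'
#' `kdm8_prefix_length()` is the fixed number of primer-derived bases trimmed
#' from the start of every Kdm8-Seq read 2 (26 bp). `kdm8_reference()` returns
#' the transcript-fragment reference the trimmed inserts are matched against —
#' a synthetic stand-in fragment, single entry with id `Kdm8`.
#'
#' @return see above.
#' @export
kdm8_prefix_length <- function() 26L

#' @rdname kdm8_prefix_length
#' @export
kdm8_reference <- function() {
  data.frame(allele_id = "Kdm8", sequence = .KDM8_FRAGMENT,
             stringsAsFactors = FALSE)
}

.kdm8_read_prefix <- function() .KDM8_PREFIX
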