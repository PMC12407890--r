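test_that("synonymous codon enumeration respects the genetic code and the wobble policy", {
  expect_setequal(enumerate_synonymous_options("GTG"), c("GTA", "GTC", "GTG", "GTT"))
  expect_setequal(enumerate_synonymous_options("ATT"), c("ATA", "ATC", "ATT"))
  expect_identical(enumerate_synonymous_options("TGG"), "TGG")
  # six-fold leucine collapses to the CTN four under wobble-only
  expect_setequal(enumerate_synonymous_options("CTT"), c("CTA", "CTC", "CTG", "CTT"))
  expect_length(enumerate_synonymous_options("CTT", wobble_only = FALSE), 6L)
  # lowercase accepted, result always contains the input
  for (codon in c("aaa", "GGC", "atg")) {
    expect_true(toupper(codon) %in% enumerate_synonymous_options(codon))
  }
  expect_error(enumerate_synonymous_options("AX"), "length|triplet|non-DNA")
  expect_error(enumerate_synonymous_options("AXG"), "non-DNA")
})

test_that("diversity is the product of allowed-set sizes and matches full enumeration", {
  expect_identical(compute_diversity(toy_design()), 12)  # 4 * 3
  no_var <- barcode_design(codon_window("GTTATT"), variable_codons = integer())
  expect_identical(compute_diversity(no_var), 1)         # empty product

  # explicit option sizes {2, 3} -> 6
  d23 <- barcode_design(
    codon_window("AAATTG"),
    variable_codons = list(`1` = c("AAA", "AAG"), `2` = c("TTA", "TTG", "CTG"))
  )
  expect_identical(compute_diversity(d23), 6)

  # enumeration oracle + permutation invariance on designs up to 10^5
  win <- kras_window()
  sets <- list(c(2L, 9L, 10L), c(14L, 21L, 24L, 29L), c(2L, 9L, 10L, 11L, 13L, 14L, 20L, 21L))
  for (vc in sets) {
    des <- barcode_design(win, kras_fixed_substitutions(), vc)
    bcs <- enumerate_barcodes(des)
    expect_identical(length(bcs), as.integer(compute_diversity(des)))
    expect_false(anyDuplicated(bcs) > 0L)
    des_perm <- barcode_design(win, kras_fixed_substitutions(), rev(vc))
    expect_identical(compute_diversity(des_perm), compute_diversity(des))
  }
})

test_that("design invariants are enforced", {
  win <- kras_window()
  # variable set must include the wildtype codon and stay synonymous
  expect_error(barcode_design(win, variable_codons = list(`9` = c("GTA", "GTC"))),
               "wildtype")
  expect_error(barcode_design(win, variable_codons = list(`9` = c("GTT", "GCT"))),
               "non-synonymous")
  # fixed/variable overlap forbidden
  expect_error(barcode_design(win, kras_fixed_substitutions(),
                              variable_codons = 12L), "disjoint")
  # only one non-synonymous fixed substitution allowed
  two_onco <- c(kras_fixed_substitutions(),
                list(fixed_substitution(13L, "TGT", synonymous_required = FALSE)))
  expect_error(barcode_design(win, two_onco), "non-synonymous")
  # synonymous_required is checked against the window
  expect_error(
    barcode_design(win, list(fixed_substitution(12L, "GAT", synonymous_required = TRUE))),
    "synonymous"
  )
})

test_that("fixed substitutions reproduce the sgRNA-resistance segment and G12D changes one residue", {
  seg <- codon_window("GAGTATAAACTTGTGGTG", first_codon_index = 3L)
  res <- apply_fixed_substitutions(
    seg, Map(function(i, codon) fixed_substitution(i, codon),
             3:8, c("GAA", "TAC", "AAG", "CTA", "GTA", "GTC"))
  )
  expect_identical(res, "GAATACAAGCTAGTAGTC")
  # synonymy preserved across the whole segment
  aa <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x)))
  expect_identical(aa(res), aa(seg$cds_segment))

  # identity on the empty list
  expect_identical(apply_fixed_substitutions(kras_window(), list()),
                   kras_window()$cds_segment)

  # the oncogenic substitution changes exactly one residue
  wt <- kras_window()
  mut <- apply_fixed_substitutions(wt, kras_fixed_substitutions())
  diffs <- which(strsplit(aa(mut), "")[[1]] != strsplit(aa(wt$cds_segment), "")[[1]])
  expect_length(diffs, 1L)
  expect_identical(wt$codon_indices[diffs], 12L)  # glycine 12 -> aspartate

  expect_error(apply_fixed_substitutions(wt, list(fixed_substitution(99L, "AAA"))),
               "outside window")
})

test_that("barcode sampling is uniform without replacement, deterministic, and synonymous", {
  des <- toy_design()
  full <- sample_barcodes(des, n = 12, seed = 3)
  expect_identical(nrow(full), 12L)
  expect_false(anyDuplicated(full$sequence) > 0L)
  expect_setequal(full$sequence, enumerate_barcodes(des))

  expect_identical(sample_barcodes(des, 5, seed = 42),
                   sample_barcodes(des, 5, seed = 42))
  expect_error(sample_barcodes(des, 13, seed = 1), "exceeds")

  # every sampled barcode from the default design translates like the
  # fixed-substituted wildtype window
  dd <- kras_default_design()
  bcs <- sample_barcodes(dd, 50, seed = 9)
  aa <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x)))
  target <- aa(apply_fixed_substitutions(dd$window, dd$fixed))
  expect_true(all(vapply(bcs$sequence, aa, character(1)) == target))
})

test_that("protospacer disruption distinguishes wildtype from the engineered allele", {
  proto <- kras_protospacer()
  wt_context <- paste0("ATG", kras_window()$cds_segment)
  expect_false(check_protospacer_disruption(wt_context, proto))
  engineered <- paste0("ATG", apply_fixed_substitutions(kras_window(),
                                                        kras_fixed_substitutions()))
  expect_true(check_protospacer_disruption(engineered, proto))
  expect_false(check_protospacer_disruption(proto, proto))
  expect_error(check_protospacer_disruption("ACGT", "ACGTACGT"), ">= 10")
})

test_that("reference FASTA round-trips at the sequence level", {
  entries <- build_reference(toy_design(), n_barcodes = 3, seed = 2)
  expect_identical(entries$allele_id[1], "Kras_WT")
  path <- tempfile(fileext = ".fa")
  write_reference(entries, path)
  back <- read_reference(path)
  expect_identical(back$allele_id, entries$allele_id)
  expect_identical(back$sequence, entries$sequence)
  expect_identical(nrow(back), 4L)

  expect_error(write_reference(entries[0, ], tempfile()), "empty")
  dup <- rbind(entries, entries[2, ])
  expect_error(write_reference(dup, tempfile()), "duplicate")
})
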