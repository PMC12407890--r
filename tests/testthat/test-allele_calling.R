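test_that("molecule collapsing deduplicates the cellBC/allele/UMI triplet", {
  mols <- data.table::data.table(
    cell_barcode = c(rep("CELL1", 5), "CELL1", "CELL1", "CELL2"),
    allele_id = c(rep("BC_A", 5), "BC_A", "BC_A", "BC_A"),
    umi = c(rep("UMI1", 5), "UMI2", "UMI2", "UMI1")
  )
  out <- collapse_molecules(mols)
  expect_identical(nrow(out), 3L)                      # (C1,A,U1) (C1,A,U2) (C2,A,U1)
  expect_identical(out, collapse_molecules(mols[sample(nrow(mols))]))
  expect_identical(nrow(collapse_molecules(mols[0])), 0L)
})

test_that("directional barcode merging absorbs error barcodes and conserves counts", {
  seqs <- c(BC_A = "AAAACCCCGGGG", BC_Aerr = "AAAACCCCGGGT",   # d = 1
            BC_B = "TTTTGGGGCCCC", Kras_WT = "ACGTACGTACGT")

  merged <- merge_barcodes(c(BC_A = 10, BC_Aerr = 1), seqs)
  expect_identical(merged, c(BC_A = 11))

  # beyond the radius: unchanged
  expect_identical(sort(merge_barcodes(c(BC_A = 5, BC_B = 5), seqs)),
                   sort(c(BC_A = 5, BC_B = 5)))
  # radius 0: identity
  expect_identical(sort(merge_barcodes(c(BC_A = 10, BC_Aerr = 1), seqs, radius = 0L)),
                   sort(c(BC_A = 10, BC_Aerr = 1)))
  # wildtype never participates even when within radius of a barcode
  wt_close <- c(BC_X = "ACGTACGTACGA", Kras_WT = "ACGTACGTACGT")
  m <- merge_barcodes(c(BC_X = 3, Kras_WT = 20), wt_close)
  expect_identical(sort(m), sort(c(BC_X = 3, Kras_WT = 20)))
  # equal counts never absorb each other (strictly-higher rule)
  expect_length(merge_barcodes(c(BC_A = 4, BC_Aerr = 4), seqs), 2L)

  expect_error(merge_barcodes(c(BC_missing = 2, BC_A = 5), seqs), "no sequence")
  expect_error(merge_barcodes(c(BC_A = 1), seqs, radius = -1L), ">= 0")
})

test_that("merging resolves chains, is order-independent, and conserves totals", {
  # chain: C (1) -> B (3) -> A (9); d(A,B) = d(B,C) = 1, d(A,C) = 2
  seqs <- c(BC_A = "AAAAAAAAAA", BC_B = "AAAAAAAAAT", BC_C = "AAAAAAAATT")
  merged <- merge_barcodes(c(BC_C = 1, BC_B = 3, BC_A = 9), seqs, radius = 1L)
  expect_identical(merged, c(BC_A = 13))

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    ids <- sprintf("BC_%02d", 1:n)
    sq <- stats::setNames(random_dna(n, 12), ids)
    cnt <- stats::setNames(sample(1:20, n, replace = TRUE), ids)
    m1 <- merge_barcodes(cnt, sq)
    perm <- sample(n)
    m2 <- merge_barcodes(cnt[perm], sq[perm])
    expect_identical(m1[order(names(m1))], m2[order(names(m2))])
    expect_equal(sum(m1), sum(cnt))                   # conservation
  }
})

test_that("dominant assignment implements the malignant/somatic/excluded definitions", {
  d <- assign_dominant(c(BC_A = 11), wt_umi_count = 4)
  expect_identical(d$dominant_bc, "BC_A")
  expect_identical(d$cell_class, "MALIGNANT")

  s <- assign_dominant(numeric(0), wt_umi_count = 3)   # WT > 1, no barcode
  expect_identical(s$cell_class, "SOMATIC")
  expect_true(is.na(s$dominant_bc))

  expect_identical(assign_dominant(numeric(0), 0)$cell_class, "EXCLUDED")
  expect_identical(assign_dominant(numeric(0), 1)$cell_class, "EXCLUDED")  # single WT UMI
  # unmergeable tie at the maximum: no dominant
  tie <- assign_dominant(c(BC_A = 5, BC_B = 5), 0)
  expect_identical(tie$cell_class, "EXCLUDED")
  expect_true(is.na(tie$dominant_bc))
  expect_identical(assign_dominant(c(BC_A = 5, BC_B = 5), 4)$cell_class, "EXCLUDED")
})

test_that("allelic-state classification follows the threshold rule (with binomial alternative)", {
  cls <- classify_allelic_state(
    rep("MALIGNANT", 4),
    dominant_count = c(8, 4, 1, 1),
    wt_umi_count = c(0, 3, 5, 0)
  )
  expect_identical(cls, c("IMBALANCED", "BALANCED", "WT_DOMINANT", "BALANCED"))
  # last case: WT = 0 but G12D below min_g12d_umis -> not called imbalanced
  expect_identical(classify_allelic_state("SOMATIC", 0, 5), NA_character_)

  bin <- classify_allelic_state(
    rep("MALIGNANT", 3),
    dominant_count = c(30, 6, 2),
    wt_umi_count = c(5, 5, 0),
    rule = "binomial"
  )
  # 30 vs 5 is significantly G12D-skewed; 6 vs 5 is not; 2 vs 0 too few
  expect_identical(bin[1], "IMBALANCED")
  expect_identical(bin[2], "BALANCED")
  expect_identical(bin[3], "BALANCED")
})

test_that("normalized Kras abundance is counts-per-scale with NA on missing totals", {
  expect_identical(normalize_kras_abundance(3, 2, 10000), 5.0)
  expect_true(is.na(normalize_kras_abundance(3, 2, 0)))
  expect_true(is.na(normalize_kras_abundance(3, 2, NA)))
  # homogeneity: doubling the total halves the abundance
  expect_identical(normalize_kras_abundance(4, 1, 20000),
                   normalize_kras_abundance(4, 1, 10000) / 2)
  expect_identical(normalize_kras_abundance(2, 0, 20000, scale = 10000), 1.0)
})

test_that("per-cell profiles recover zero-noise truth and conserve merged counts", {
  sim <- simulate_dataset(
    sim_params(n_cells = 150, n_clones = 12, per_base_error = 0, seed = 21),
    tempfile("prof")
  )
  ann <- data.table::fread(sim$paths$annotations)
  res <- suppressWarnings(process_krasbc_fastqs(
    sim$paths$krasbc_r1, sim$paths$krasbc_r2, sim$reference,
    whitelist = ann$cell_barcode
  ))
  prof <- build_cell_profiles(res$molecules, sim$reference, ann)
  m <- merge(prof, sim$truth, by = "cell_barcode")
  expect_identical(nrow(m), 150L)

  expect_identical(m$cell_class, m$true_class)
  mal <- m[m$cell_class == "MALIGNANT", ]
  expect_identical(mal$dominant_bc, mal$true_barcode)
  expect_identical(mal$allelic_state, mal$true_allelic_state)
  expect_identical(as.integer(m$g12d_umis.x), m$g12d_umis.y)
  expect_identical(as.integer(m$wt_umis.x), m$wt_umis.y)
  expect_equal(m$kras_abundance,
               (m$g12d_umis.y + m$wt_umis.y) / m$total_umis * 1e4)

  # clonotype summary marginals match the profile table
  cs <- clonotype_summary(prof, ann)
  expect_identical(sum(cs$n_cells), sum(prof$cell_class == "MALIGNANT"))
})
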