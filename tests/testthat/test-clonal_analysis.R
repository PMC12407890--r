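test_that("two-sided Fisher matches stats::fisher.test across random and edge tables", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1.0)
  expect_identical(fisher_exact_two_sided(0, 0, 3, 5), 1.0)   # degenerate row
  expect_identical(fisher_exact_two_sided(0, 4, 0, 6), 1.0)   # degenerate column
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "positive")

  # full-enumeration worked example: [[5,0],[0,5]] -> 2 / C(10,5)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / choose(10, 5))

  set.seed(13)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2, 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("the clone-state table conserves marginals and drops unannotated cells", {
  profiles <- data.table::data.table(
    cell_barcode = sprintf("C%02d", 1:6),
    dominant_bc = c("BC_A", "BC_A", "BC_A", "BC_B", NA, "BC_C"),
    cell_class = c(rep("MALIGNANT", 4), "SOMATIC", "MALIGNANT"),
    allelic_state = c("BALANCED", "BALANCED", "IMBALANCED", "BALANCED", NA, "BALANCED")
  )
  ann <- data.table::data.table(
    cell_barcode = sprintf("C%02d", 1:5),              # C06 unannotated
    sample_id = "primary",
    state = c("EMT", "EMT", "hypoxia", "classical", "EMT"),
    total_umis = 5000L
  )
  kd <- data.table::data.table(cell_barcode = sprintf("C%02d", 1:6),
                               kdm8_status = "NEGATIVE")
  tab <- build_clone_state_table(profiles, kd, ann)
  expect_identical(sum(tab$n_cells), 4L)               # malignant ∩ annotated
  expect_identical(attr(tab, "dropped_unannotated"), 1L)
  # 3 cells of clone BC_A across two states -> two rows summing to 3
  a_rows <- tab[tab$clonotype == "BC_A", ]
  expect_identical(nrow(a_rows), 2L)
  expect_identical(sum(a_rows$n_cells), 3L)

  empty <- build_clone_state_table(profiles[0], kd, ann)
  expect_identical(nrow(empty), 0L)
})

test_that("clone sharing ranks primary clonotypes and scores metastatic membership", {
  prim <- data.table::data.table(clonotype = c("BC_A", "BC_B", "BC_C"),
                                 n_cells = c(50L, 30L, 5L))
  met_top <- data.table::data.table(clonotype = "BC_A", n_cells = 12L)
  expect_identical(clone_sharing(prim, met_top, top_k = 1L), 1.0)
  met_absent <- data.table::data.table(clonotype = "BC_Z", n_cells = 7L)
  expect_identical(clone_sharing(prim, met_absent, top_k = 2L), 0.0)
  mixed <- data.table::data.table(clonotype = c("BC_A", "BC_C"), n_cells = c(6L, 2L))
  expect_equal(clone_sharing(prim, mixed, top_k = 2L), 6 / 8)
  expect_true(is.na(clone_sharing(prim, met_top[0], top_k = 1L)))
})

test_that("the simulated seeding clones are recovered by clone sharing", {
  sim <- simulate_dataset(
    sim_params(n_cells = 600, n_clones = 12, met_fraction = 0.25,
               met_seed_clones = 2L, per_base_error = 0, seed = 41),
    tempfile("seed")
  )
  ann <- data.table::fread(sim$paths$annotations)
  res <- suppressWarnings(process_krasbc_fastqs(
    sim$paths$krasbc_r1, sim$paths$krasbc_r2, sim$reference,
    whitelist = ann$cell_barcode
  ))
  prof <- build_cell_profiles(res$molecules, sim$reference, ann)
  cs <- clonotype_summary(prof, ann)
  prim <- cs[sample_id == "primary", list(clonotype = dominant_bc, n_cells)]
  met <- cs[sample_id == "met", list(clonotype = dominant_bc, n_cells)]
  # every metastatic cell descends from one of the two largest primary clones
  expect_identical(clone_sharing(prim, met, top_k = 2L), 1.0)
})

test_that("imbalance enrichment recovers a planted state association and handles degeneracy", {
  set.seed(61)
  ref <- build_reference(kras_default_design(), 10, seed = 1)
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    tr <- simulate_truth(
      sim_params(n_cells = 800, n_clones = 10, seed = 6000 + s,
                 imbalance_state_logor = c(hypoxia = 1.5)),
      ref
    )
    cells <- tr[true_class == "MALIGNANT",
                list(sample_id, state, allelic_state = true_allelic_state)]
    enr <- imbalance_enrichment(cells, "hypoxia")
    hits <- hits + (enr$odds_ratio > 1)
  }
  expect_gte(hits / n_rep, 0.95)

  # all cells imbalanced in-group: odds ratio finite via Haldane-Anscombe
  cells <- data.table::data.table(
    sample_id = "s1",
    state = c(rep("hypoxia", 5), rep("classical", 5)),
    allelic_state = c(rep("IMBALANCED", 5), rep("BALANCED", 5))
  )
  enr <- imbalance_enrichment(cells, "hypoxia")
  expect_true(is.finite(enr$odds_ratio))
  expect_gt(enr$odds_ratio, 1)

  expect_error(imbalance_enrichment(cells[state == "hypoxia"], "hypoxia"),
               "single group")
})

test_that("Sankey export links clone -> sample -> state with conserved flow", {
  tab <- data.table::data.table(
    clonotype = "BC_A", sample_id = "primary", state = "EMT",
    allelic_state = "BALANCED", kdm8_status = "NEGATIVE", n_cells = 10L
  )
  links <- export_sankey(tab)
  expect_identical(nrow(links), 2L)
  expect_true(all(links$value == 10L))

  sim_tab <- data.table::data.table(
    clonotype = rep(c("BC_A", "BC_B"), each = 3),
    sample_id = rep(c("primary", "met"), 3),
    state = c("EMT", "EMT", "hypoxia", "classical", "EMT", "hypoxia"),
    allelic_state = "BALANCED", kdm8_status = "NEGATIVE",
    n_cells = c(4L, 2L, 7L, 1L, 3L, 5L)
  )
  links <- export_sankey(sim_tab)
  samples <- unique(sim_tab$sample_id)
  inflow <- vapply(samples, function(s) sum(links$value[links$target_node == s]),
                   numeric(1))
  outflow <- vapply(samples, function(s) sum(links$value[links$source_node == s]),
                    numeric(1))
  expect_equal(inflow, outflow)

  path <- tempfile(fileext = ".tsv")
  export_sankey(sim_tab, path)
  back <- data.table::fread(path)
  expect_identical(names(back), c("source_node", "target_node", "value"))
  expect_identical(sum(back$value), 2L * sum(sim_tab$n_cells))

  expect_error(export_sankey(sim_tab[0]), "empty")
})
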