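## Clone-by-state analytics: joined clone/state/genotype tables, Sankey link
## export, clone sharing between lesions, and exact Fisher enrichment tests.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution with both
#' margins fixed: the two-sided p-value sums the probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (probability-ordering convention, with a relative tolerance
#' of 1e-7 on the comparison to avoid floating-point boundary
#' misclassification). Degenerate tables — a row or column summing to zero —
#' return exactly 1.
#'
#' @param table 2x2 matrix of non-negative counts, or the count `a` with
#'   `b`, `c`, `d` supplied.
#' @param b,c,d remaining cells when `table` is given as a scalar (row-wise:
#'   `a b / c d`).
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(0, 13, 6, 3), 2, 2, byrow = TRUE))  # 0.001
#' @export
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(cells) == 0) stop("at least one cell must be positive", call. = FALSE)

  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)

  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1.0)
}

#' Join per-cell tables into a clone-by-state count table
#'
#' Inner-joins the malignant cells of the allele profiles with their Kdm8
#' status and annotation (sample, state), then counts cells per unique
#' (clonotype, sample, state, allelic state, Kdm8 status) combination.
#' Called cells missing from the annotation table are dropped and counted in
#' the `dropped_unannotated` attribute.
#'
#' @param profiles output of [build_cell_profiles()].
#' @param kdm8_profiles per-cell Kdm8 table (`cell_barcode`, `kdm8_status`),
#'   or `NULL` (status recorded as `"NA"`).
#' @param annotations annotation table (`cell_barcode`, `sample_id`, `state`).
#' @return `data.table` with columns `clonotype`, `sample_id`, `state`,
#'   `allelic_state`, `kdm8_status`, `n_cells`.
#' @export
build_clone_state_table <- function(profiles, kdm8_profiles, annotations) {
  prof <- data.table::as.data.table(profiles)[cell_class == "MALIGNANT"]
  ann <- data.table::as.data.table(annotations)
  joined <- merge(prof, ann[, list(cell_barcode, sample_id, state)],
                  by = "cell_barcode")
  dropped <- nrow(prof) - nrow(joined)
  if (!is.null(kdm8_profiles)) {
    kd <- data.table::as.data.table(kdm8_profiles)
    joined <- merge(joined, kd[, list(cell_barcode, kdm8_status)],
                    by = "cell_barcode", all.x = TRUE)
  } else {
    joined[, kdm8_status := NA_character_]
  }
  out <- joined[, list(n_cells = .N),
                by = list(clonotype = dominant_bc, sample_id, state,
                          allelic_state, kdm8_status)]
  data.table::setorder(out, sample_id, -n_cells, clonotype)
  data.table::setattr(out, "dropped_unannotated", dropped)
  out[]
}

#' Fraction of metastatic cells derived from the top primary clonotypes
#'
#' Ranks the primary clonotypes by cell count (ties broken lexicographically)
#' and returns the fraction of metastatic cells whose clonotype is among the
#' top `top_k`.
#'
#' @param primary_table,met_table clone tables for the primary tumour and the
#'   metastasis — any table with `clonotype` and `n_cells` columns (e.g.
#'   [build_clone_state_table()] output, or [clonotype_summary()] renamed).
#' @param top_k number of top primary clonotypes considered.
#' @return fraction in `[0, 1]`; `NA` for an empty metastasis table.
#' @export
clone_sharing <- function(primary_table, met_table, top_k = 1L) {
  prim <- data.table::as.data.table(primary_table)[, list(n_cells = sum(n_cells)),
                                                   by = clonotype]
  met <- data.table::as.data.table(met_table)
  if (nrow(met) == 0L || sum(met$n_cells) == 0L) return(NA_real_)
  data.table::setorder(prim, -n_cells, clonotype)
  top <- head(prim$clonotype, top_k)
  sum(met$n_cells[met$clonotype %in% top]) / sum(met$n_cells)
}

#' Per-sample enrichment of allelic imbalance in a state group
#'
#' For each sample, forms the 2x2 table of state-group membership (cell state
#' in `group_states` vs not) against allelic imbalance (`IMBALANCED` vs other
#' malignant states) and reports the odds ratio and the exact two-sided
#' Fisher p-value. When any cell of the table is zero the odds ratio uses the
#' Haldane–Anscombe correction (0.5 added to every cell); the p-value is
#' always computed on the uncorrected counts.
#'
#' @param cells per-cell `data.table`/`data.frame` with columns `sample_id`,
#'   `state`, `allelic_state` (malignant cells).
#' @param group_states character vector of state labels defining the group
#'   (e.g. the advanced-state set).
#' @return `data.table` with `sample_id`, the four cell counts
#'   (`in_imb`, `in_bal`, `out_imb`, `out_bal`), `odds_ratio`, `p_value`.
#' @export
imbalance_enrichment <- function(cells, group_states) {
  dt <- data.table::as.data.table(cells)
  stopifnot(all(c("sample_id", "state", "allelic_state") %in% names(dt)))
  dt <- dt[!is.na(allelic_state)]
  in_group <- dt$state %in% group_states
  if (length(unique(in_group)) < 2L) {
    stop("state grouping yields a single group; need cells both inside and ",
         "outside `group_states`", call. = FALSE)
  }
  dt[, `:=`(grp = state %in% group_states, imb = allelic_state == "IMBALANCED")]
  out <- dt[, {
    a <- sum(grp & imb); b <- sum(grp & !imb)
    cc <- sum(!grp & imb); dd <- sum(!grp & !imb)
    or <- if (min(a, b, cc, dd) == 0) {
      ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * dd) / (b * cc)
    }
    list(in_imb = a, in_bal = b, out_imb = cc, out_bal = dd,
         odds_ratio = or,
         p_value = fisher_exact_two_sided(a, b, cc, dd))
  }, by = sample_id]
  out[]
}

#' Export a two-layer Sankey link table
#'
#' Links clone -> sample and sample -> state with cell-count values, suitable
#' for standard Sankey plotting tools. Middle-layer (sample) inflow equals
#' outflow by construction.
#'
#' @param clone_state_table output of [build_clone_state_table()].
#' @param path optional TSV output path.
#' @return `data.table` with `source_node`, `target_node`, `value`
#'   (invisibly when `path` is given).
#' @export
export_sankey <- function(clone_state_table, path = NULL) {
  dt <- data.table::as.data.table(clone_state_table)
  if (nrow(dt) == 0L) stop("empty clone-state table", call. = FALSE)
  l1 <- dt[, list(value = sum(n_cells)),
           by = list(source_node = clonotype, target_node = sample_id)]
  l2 <- dt[, list(value = sum(n_cells)),
           by = list(source_node = sample_id, target_node = state)]
  links <- data.table::rbindlist(list(l1, l2))
  if (!is.null(path)) {
    data.table::fwrite(links, path, sep = "\t")
    return(invisible(links[]))
  }
  links[]
}
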