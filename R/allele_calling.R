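## Per-cell KrasBC-Seq quantification: UMI collapsing, directional
## edit-distance barcode merging, dominant-barcode assignment, cell
## classification, and depth-normalized Kras abundance.

#' Collapse duplicate molecules
#'
#' Exact deduplication on the (cell barcode, allele, UMI) triplet: PCR
#' duplicates of one original transcript collapse to a single molecule. The
#' result is sorted and therefore independent of input order.
#'
#' @param records `data.table`/`data.frame` with columns `cell_barcode`,
#'   `allele_id`, `umi` (extra columns dropped).
#' @return deduplicated `data.table`, keyed by the triplet.
#' @export
collapse_molecules <- function(records) {
  dt <- data.table::as.data.table(records)[, list(cell_barcode, allele_id, umi)]
  out <- unique(dt, by = c("cell_barcode", "allele_id", "umi"))
  data.table::setkey(out, cell_barcode, allele_id, umi)
  out[]
}

#' Directionally merge error barcodes into their parents
#'
#' Each barcode whose sequence lies within edit distance `radius` of a
#' strictly higher-count barcode is absorbed into it (lower into higher;
#' among equally counted candidate parents the lexicographically smallest
#' allele id wins). Absorption chains resolve to the final representative.
#' The wildtype allele (`Kras_WT`) never participates. Total counts are
#' conserved, and the result does not depend on the input order.
#'
#' @param raw_counts named numeric vector, allele id -> UMI count.
#' @param barcode_sequences named character vector supplying a sequence for
#'   every counted allele.
#' @param radius maximum edit distance absorbed (default 2, i.e. the
#'   "distance < 3" merge rule).
#' @return named numeric vector of merged counts, representative -> count.
#' @export
merge_barcodes <- function(raw_counts, barcode_sequences, radius = 2L) {
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  if (length(raw_counts) == 0L) return(raw_counts)

  wt <- raw_counts[names(raw_counts) == "Kras_WT"]
  bc <- raw_counts[names(raw_counts) != "Kras_WT"]
  if (length(bc) <= 1L || radius == 0L) return(c(bc, wt))

  missing_seq <- setdiff(names(bc), names(barcode_sequences))
  if (length(missing_seq) > 0L) {
    stop("no sequence for counted allele(s): ",
         paste(missing_seq, collapse = ","), call. = FALSE)
  }

  ## canonical order: count descending, then allele id — makes parent choice
  ## and chain resolution order-independent
  ord <- order(-bc, names(bc))
  bc <- bc[ord]
  ids <- names(bc)
  dmat <- utils::adist(barcode_sequences[ids])

  parent <- seq_along(bc)   # index into ids, identity = unabsorbed
  for (i in seq_along(bc)) {
    cand <- which(bc > bc[i] & dmat[i, ] <= radius)
    if (length(cand) > 0L) parent[i] <- cand[1L]  # ord puts best parent first
  }
  ## resolve chains (child -> parent -> grandparent ...)
  root <- parent
  repeat {
    nxt <- parent[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  merged <- tapply(bc, ids[root], sum)
  merged <- stats::setNames(as.numeric(merged), names(merged))
  c(merged, wt)
}

#' Assign the dominant barcode and classify the cell
#'
#' The dominant barcode is the unique maximum of the merged barcode counts;
#' a cell with one is `MALIGNANT`. A cell with no detectable barcode and more
#' than one wildtype UMI is `SOMATIC` (presumed non-malignant). Cells with no
#' dominant barcode otherwise — zero barcodes with at most one wildtype UMI,
#' or an unmergeable tie at the maximum — are `EXCLUDED` from lineage
#' analyses.
#'
#' @param merged_counts named numeric vector of merged barcode counts
#'   (wildtype excluded; an entry named `Kras_WT` is ignored).
#' @param wt_umi_count wildtype UMI count of the cell.
#' @return list with `dominant_bc` (allele id or `NA`), `dominant_count`,
#'   and `cell_class` (`MALIGNANT`/`SOMATIC`/`EXCLUDED`).
#' @export
assign_dominant <- function(merged_counts, wt_umi_count) {
  merged_counts <- merged_counts[names(merged_counts) != "Kras_WT"]
  if (length(merged_counts) == 0L) {
    cls <- if (wt_umi_count > 1) "SOMATIC" else "EXCLUDED"
    return(list(dominant_bc = NA_character_, dominant_count = 0,
                cell_class = cls))
  }
  mx <- max(merged_counts)
  top <- names(merged_counts)[merged_counts == mx]
  if (length(top) == 1L) {
    list(dominant_bc = top, dominant_count = mx, cell_class = "MALIGNANT")
  } else {
    ## tied maximum: no dominant barcode, and a detected barcode rules out
    ## the somatic definition
    list(dominant_bc = NA_character_, dominant_count = 0,
         cell_class = "EXCLUDED")
  }
}

#' Classify the Kras allelic state of a malignant cell
#'
#' Default threshold rule: `IMBALANCED` when no wildtype UMI is detected and
#' the dominant barcode has at least `min_g12d_umis` UMIs (G12D-dominant
#' imbalance); `WT_DOMINANT` when wildtype exceeds the dominant barcode
#' count; otherwise `BALANCED`. The alternative `"binomial"` rule calls
#' imbalance by an exact binomial test of the G12D fraction against 0.5 at
#' `alpha` (G12D side only). Non-malignant cells get `NA`.
#'
#' @param cell_class cell class from [assign_dominant()].
#' @param dominant_count merged UMI count of the dominant barcode.
#' @param wt_umi_count wildtype UMI count.
#' @param min_g12d_umis minimum dominant count for the threshold rule
#'   (default 2).
#' @param rule `"threshold"` (default) or `"binomial"`.
#' @param alpha significance level for the binomial rule.
#' @return character scalar (vectorized over equal-length inputs).
#' @export
classify_allelic_state <- function(cell_class, dominant_count, wt_umi_count,
                                   min_g12d_umis = 2L,
                                   rule = c("threshold", "binomial"),
                                   alpha = 0.05) {
  rule <- match.arg(rule)
  n <- length(cell_class)
  out <- rep(NA_character_, n)
  mal <- which(cell_class == "MALIGNANT")
  for (i in mal) {
    g <- dominant_count[i]
    w <- wt_umi_count[i]
    imb <- if (rule == "threshold") {
      w == 0 && g >= min_g12d_umis
    } else {
      g > w && stats::binom.test(g, g + w, p = 0.5)$p.value < alpha
    }
    out[i] <- if (imb) "IMBALANCED" else if (w > g) "WT_DOMINANT" else "BALANCED"
  }
  out
}

#' Depth-normalized Kras abundance
#'
#' (dominant G12D UMIs + wildtype UMIs) divided by the cell's total
#' transcriptome UMI count, scaled to counts-per-`scale` (default 10,000).
#' Cells with a missing or non-positive transcriptome total get `NA`.
#'
#' @param dominant_count,wt_umi_count per-cell UMI counts (vectorized).
#' @param total_transcriptome_umis per-cell transcriptome totals.
#' @param scale scaling constant (default 1e4).
#' @return numeric vector.
#' @export
normalize_kras_abundance <- function(dominant_count, wt_umi_count,
                                     total_transcriptome_umis, scale = 1e4) {
  total <- as.numeric(total_transcriptome_umis)
  bad <- is.na(total) | total <= 0
  out <- (dominant_count + wt_umi_count) / total * scale
  out[bad] <- NA_real_
  out
}

#' Build per-cell allele profiles from molecule-level calls
#'
#' Runs the whole per-cell quantification: UMI collapsing, directional
#' barcode merging within each cell, dominant assignment, cell
#' classification, allelic-state classification, and (when annotations are
#' supplied) depth-normalized Kras abundance.
#'
#' @param molecules molecule table (`cell_barcode`, `allele_id`, `umi`);
#'   ambiguous/unmapped records must already be removed.
#' @param reference allele reference `data.frame` (sequences for merging).
#' @param annotations optional annotation table with `cell_barcode` and
#'   `total_umis`; adds `kras_abundance`.
#' @param merge_radius directional merge radius (default 2).
#' @param min_g12d_umis threshold for the imbalance rule (default 2).
#' @param allelic_rule `"threshold"` or `"binomial"`.
#' @param scale normalization scale (default 1e4).
#' @return `data.table`, one row per cell: `cell_barcode`, `dominant_bc`,
#'   `g12d_umis`, `wt_umis`, `n_barcodes`, `cell_class`, `allelic_state`,
#'   `kras_abundance` (NA without annotations).
#' @export
build_cell_profiles <- function(molecules, reference, annotations = NULL,
                                merge_radius = 2L, min_g12d_umis = 2L,
                                allelic_rule = "threshold", scale = 1e4) {
  mols <- collapse_molecules(molecules)
  if (nrow(mols) == 0L) {
    return(data.table::data.table(
      cell_barcode = character(0), dominant_bc = character(0),
      g12d_umis = numeric(0), wt_umis = numeric(0), n_barcodes = integer(0),
      cell_class = character(0), allelic_state = character(0),
      kras_abundance = numeric(0)
    ))
  }
  counts <- mols[, list(count = .N), by = list(cell_barcode, allele_id)]
  seqs <- stats::setNames(reference$sequence, reference$allele_id)

  prof <- counts[, {
    raw <- stats::setNames(as.numeric(count), allele_id)
    wt_n <- sum(raw[names(raw) == "Kras_WT"])
    merged <- merge_barcodes(raw, seqs, radius = merge_radius)
    dom <- assign_dominant(merged, wt_n)
    list(
      dominant_bc = dom$dominant_bc,
      g12d_umis = dom$dominant_count,
      wt_umis = wt_n,
      n_barcodes = sum(names(merged) != "Kras_WT"),
      cell_class = dom$cell_class
    )
  }, by = cell_barcode]

  prof[, allelic_state := classify_allelic_state(
    cell_class, g12d_umis, wt_umis,
    min_g12d_umis = min_g12d_umis, rule = allelic_rule
  )]

  if (!is.null(annotations)) {
    ann <- data.table::as.data.table(annotations)
    prof <- merge(prof, ann[, list(cell_barcode, total_umis)],
                  by = "cell_barcode", all.x = TRUE)
    prof[, kras_abundance := normalize_kras_abundance(g12d_umis, wt_umis,
                                                      total_umis, scale)]
    prof[, total_umis := NULL]
  } else {
    prof[, kras_abundance := NA_real_]
  }
  data.table::setkey(prof, cell_barcode)
  prof[]
}

#' Clonotype summary: cells per dominant barcode and sample
#'
#' @param profiles output of [build_cell_profiles()].
#' @param annotations annotation table with `cell_barcode`, `sample_id`.
#' @return `data.table` with `dominant_bc`, `sample_id`, `n_cells`, sorted by
#'   descending clone size (malignant cells only).
#' @export
clonotype_summary <- function(profiles, annotations) {
  ann <- data.table::as.data.table(annotations)
  dt <- merge(profiles[cell_class == "MALIGNANT"],
              ann[, list(cell_barcode, sample_id)], by = "cell_barcode")
  out <- dt[, list(n_cells = .N), by = list(dominant_bc, sample_id)]
  data.table::setorder(out, -n_cells, dominant_bc)
  out[]
}
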