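## Kdm8-Seq: per-cell transcript UMI counting with zero imputation,
## depth-normalized abundance, and bimodal positive/negative classification.

#' Count Kdm8 molecules per cell with zero imputation
#'
#' Unique (cell, UMI) pairs among reads mapped to the Kdm8 reference. Every
#' cell of the annotation universe appears in the output; cells without
#' detectable signal are imputed as zero — distinguishing dropout within a
#' good library from cells missing upstream.
#'
#' @param molecules Kdm8 molecule table (`cell_barcode`, `umi`).
#' @param cell_universe character vector of all annotated cell barcodes for
#'   the sample.
#' @return `data.table` with `cell_barcode`, `kdm8_umis`, one row per cell in
#'   the universe (input order preserved).
#' @export
count_kdm8_molecules <- function(molecules, cell_universe) {
  dt <- data.table::as.data.table(molecules)
  if (nrow(dt) > 0L) {
    dt <- unique(dt[, list(cell_barcode, umi)], by = c("cell_barcode", "umi"))
    counts <- dt[, list(kdm8_umis = .N), by = cell_barcode]
  } else {
    counts <- data.table::data.table(cell_barcode = character(0),
                                     kdm8_umis = integer(0))
  }
  hit <- counts$kdm8_umis[match(cell_universe, counts$cell_barcode)]
  data.table::data.table(
    cell_barcode = cell_universe,
    kdm8_umis = data.table::fifelse(is.na(hit), 0L, hit)
  )
}

#' Depth-normalized Kdm8 abundance
#'
#' Unique UMI count over the cell's transcriptome total, scaled to
#' counts-per-`scale`; same contract as [normalize_kras_abundance()].
#'
#' @param count per-cell Kdm8 UMI counts.
#' @param total_transcriptome_umis per-cell transcriptome totals.
#' @param scale scaling constant (default 1e4).
#' @return numeric vector (NA where the total is missing or non-positive).
#' @export
normalize_kdm8_abundance <- function(count, total_transcriptome_umis,
                                     scale = 1e4) {
  total <- as.numeric(total_transcriptome_umis)
  bad <- is.na(total) | total <= 0
  out <- count / total * scale
  out[bad] <- NA_real_
  out
}

#' Positivity summary formatter
#'
#' @param n_positive,n_total integer counts.
#' @return list with `n_positive`, `n_total`, `percent_positive` (one
#'   decimal, e.g. `11.4` for 797 of 6,999).
#' @export
kdm8_positivity_summary <- function(n_positive, n_total) {
  list(
    n_positive = as.integer(n_positive),
    n_total = as.integer(n_total),
    percent_positive = if (n_total > 0) round(100 * n_positive / n_total, 1) else 0.0
  )
}

## Antimode of a (bimodal) abundance distribution: the KDE minimum between
## the two most prominent modes. Returns NA when fewer than two modes exist.
.kde_antimode <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 3L) return(NA_real_)
  d <- stats::density(x)
  y <- d$y
  ## interior local maxima / minima of the density grid
  up <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(up) < 2L) return(NA_real_)
  top2 <- sort(up[order(y[up], decreasing = TRUE)][1:2])
  seg <- seq(top2[1], top2[2])
  d$x[seg[which.min(y[seg])]]
}

#' Classify per-cell Kdm8 status
#'
#' Default rule: a cell is `POSITIVE` iff its abundance exceeds zero —
#' consistent with zero imputation of undetected cells. The `"antimode"`
#' rule instead thresholds at the kernel-density minimum between the two
#' modes of the (bimodal) abundance distribution; on effectively unimodal
#' data it falls back to the default rule with a warning. A failed library
#' (`library_failed = TRUE`) yields all-`NA` statuses rather than imputed
#' negatives.
#'
#' @param abundances numeric vector of per-cell abundances (or raw counts).
#' @param rule `"detected"` (default) or `"antimode"`.
#' @param library_failed mark the whole library as failed.
#' @return list with `status` (character vector `POSITIVE`/`NEGATIVE`/`NA`),
#'   `threshold` (abundance cut used), and `summary` per
#'   [kdm8_positivity_summary()].
#' @export
classify_kdm8_status <- function(abundances, rule = c("detected", "antimode"),
                                 library_failed = FALSE) {
  rule <- match.arg(rule)
  if (length(abundances) == 0L) stop("empty abundance vector", call. = FALSE)
  if (library_failed) {
    return(list(status = rep(NA_character_, length(abundances)),
                threshold = NA_real_,
                summary = kdm8_positivity_summary(0L, 0L)))
  }
  threshold <- 0
  if (rule == "antimode") {
    am <- .kde_antimode(abundances)
    if (is.na(am)) {
      warning("abundance distribution not bimodal; falling back to the ",
              "detected-vs-zero rule", call. = FALSE)
    } else {
      threshold <- am
    }
  }
  status <- ifelse(abundances > threshold, "POSITIVE", "NEGATIVE")
  list(
    status = status,
    threshold = threshold,
    summary = kdm8_positivity_summary(sum(status == "POSITIVE", na.rm = TRUE),
                                      sum(!is.na(status)))
  )
}

#' Per-cell Kdm8 profiles over an annotation universe
#'
#' Convenience wrapper joining [count_kdm8_molecules()],
#' [normalize_kdm8_abundance()] and [classify_kdm8_status()].
#'
#' @param molecules Kdm8 molecule table.
#' @param annotations annotation table (`cell_barcode`, `total_umis`).
#' @param rule positivity rule (see [classify_kdm8_status()]).
#' @param scale normalization scale.
#' @param library_failed see [classify_kdm8_status()].
#' @return list with `profiles` (`data.table`: `cell_barcode`, `kdm8_umis`,
#'   `kdm8_abundance`, `kdm8_status`) and `summary`.
#' @export
build_kdm8_profiles <- function(molecules, annotations, rule = "detected",
                                scale = 1e4, library_failed = FALSE) {
  ann <- data.table::as.data.table(annotations)
  prof <- count_kdm8_molecules(molecules, ann$cell_barcode)
  prof[, kdm8_abundance := normalize_kdm8_abundance(kdm8_umis, ann$total_umis,
                                                    scale)]
  cls <- classify_kdm8_status(prof$kdm8_abundance, rule = rule,
                              library_failed = library_failed)
  prof[, kdm8_status := cls$status]
  list(profiles = prof[], summary = cls$summary, threshold = cls$threshold)
}
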