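## Configuration and the end-to-end driver binding the pipeline stages:
## call (KrasBC) -> genotype (Kdm8) -> analyze (clone-by-state).

#' Build a run configuration
#'
#' Collects the paths, chemistry and thresholds of one pipeline run. The
#' same structure round-trips through a YAML file via [read_config()] /
#' [write_config()].
#'
#' @param reference_fasta barcode reference FASTA (wildtype + barcoded
#'   alleles).
#' @param krasbc_r1,krasbc_r2 paired KrasBC-Seq FASTQs.
#' @param kdm8_r1,kdm8_r2 paired Kdm8-Seq FASTQs (optional; `NULL` skips the
#'   genotyping stage).
#' @param annotations cell-annotation TSV (`cell_barcode`, `sample_id`,
#'   `state`, `total_umis`).
#' @param out_dir output directory.
#' @param bc_len,umi_len read-1 geometry (defaults 16 + 10).
#' @param merge_radius directional barcode-merge radius (default 2).
#' @param max_edit_distance allele-call threshold (default 3).
#' @param min_g12d_umis imbalance-rule threshold (default 2).
#' @param allelic_rule `"threshold"` or `"binomial"`.
#' @param kdm8_rule `"detected"` or `"antimode"`.
#' @param kdm8_library_failed mark the Kdm8 library failed (statuses NA).
#' @param scale normalization scale (default 1e4).
#' @param whitelist_correction correct cell barcodes against the annotation
#'   cell list (default TRUE).
#' @param seed integer seed recorded with the run.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(reference_fasta, krasbc_r1, krasbc_r2, annotations,
                            out_dir, kdm8_r1 = NULL, kdm8_r2 = NULL,
                            bc_len = 16L, umi_len = 10L, merge_radius = 2L,
                            max_edit_distance = 3L, min_g12d_umis = 2L,
                            allelic_rule = "threshold", kdm8_rule = "detected",
                            kdm8_library_failed = FALSE, scale = 1e4,
                            whitelist_correction = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks threshold ranges and the existence of every referenced input file
#' before any I/O. Errors name the offending field.
#'
#' @param config a `run_config`.
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  num_ok <- function(x, lo) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo
  if (!num_ok(config$merge_radius, 0)) stop("invalid merge_radius", call. = FALSE)
  if (!num_ok(config$max_edit_distance, 0)) stop("invalid max_edit_distance", call. = FALSE)
  if (!num_ok(config$min_g12d_umis, 1)) stop("invalid min_g12d_umis", call. = FALSE)
  if (!num_ok(config$scale, 1)) stop("invalid scale", call. = FALSE)
  if (!num_ok(config$bc_len, 1) || !num_ok(config$umi_len, 1)) {
    stop("invalid read-1 geometry", call. = FALSE)
  }
  if (!config$allelic_rule %in% c("threshold", "binomial")) {
    stop("invalid allelic_rule", call. = FALSE)
  }
  if (!config$kdm8_rule %in% c("detected", "antimode")) {
    stop("invalid kdm8_rule", call. = FALSE)
  }
  for (f in c("reference_fasta", "krasbc_r1", "krasbc_r2", "annotations",
              "kdm8_r1", "kdm8_r2")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("missing input file for ", f, ": ", p, call. = FALSE)
    }
  }
  invisible(config)
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(log, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log(sprintf("stage %-10s ok", name))
  res
}

#' Run the full pipeline
#'
#' Executes call -> genotype -> analyze on the configured inputs and writes
#' every stage table under `out_dir`: molecule TSVs, per-cell profile TSVs,
#' the clone-by-state table, the Sankey link table, a QC JSON and a run log
#' (versions, config hash, per-stage record counts). Outputs are
#' reproducible bit-identically for the same config and inputs.
#'
#' @param config a `run_config` (validated first).
#' @return list with the in-memory stage outputs (`profiles`,
#'   `kdm8_profiles`, `clone_state`, `qc`, `paths`), invisibly.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(msg, log_con)

  log(sprintf("clonotracer %s | R %s",
              as.character(utils::packageVersion("clonotracer")),
              paste(R.version$major, R.version$minor, sep = ".")))
  log(sprintf("config digest: %s", digest_config(config)))
  log(sprintf("seed: %d", config$seed))

  reference <- .stage(log, "reference", read_reference(config$reference_fasta))
  annotations <- .stage(log, "annotations", {
    ann <- data.table::fread(config$annotations)
    stopifnot(all(c("cell_barcode", "sample_id", "state", "total_umis") %in% names(ann)))
    ann
  })
  whitelist <- if (isTRUE(config$whitelist_correction)) annotations$cell_barcode else NULL

  kras <- .stage(log, "call", process_krasbc_fastqs(
    config$krasbc_r1, config$krasbc_r2, reference,
    max_edit_distance = config$max_edit_distance, whitelist = whitelist,
    bc_len = config$bc_len, umi_len = config$umi_len
  ))
  log(sprintf("  krasbc reads in/called: %d/%d", kras$qc$reads_in, kras$qc$reads_called))

  profiles <- .stage(log, "profiles", build_cell_profiles(
    kras$molecules, reference, annotations,
    merge_radius = config$merge_radius, min_g12d_umis = config$min_g12d_umis,
    allelic_rule = config$allelic_rule, scale = config$scale
  ))
  log(sprintf("  cells profiled: %d", nrow(profiles)))

  kdm8 <- NULL
  if (!is.null(config$kdm8_r1)) {
    kd_raw <- .stage(log, "genotype", process_kdm8_fastqs(
      config$kdm8_r1, config$kdm8_r2, kdm8_reference(),
      max_edit_distance = config$max_edit_distance, whitelist = whitelist,
      bc_len = config$bc_len, umi_len = config$umi_len
    ))
    kdm8 <- build_kdm8_profiles(kd_raw$molecules, annotations,
                                rule = config$kdm8_rule, scale = config$scale,
                                library_failed = config$kdm8_library_failed)
    log(sprintf("  kdm8 positive: %d/%d (%.1f%%)", kdm8$summary$n_positive,
                kdm8$summary$n_total, kdm8$summary$percent_positive))
  }

  clone_state <- .stage(log, "analyze", build_clone_state_table(
    profiles, if (is.null(kdm8)) NULL else kdm8$profiles, annotations
  ))

  paths <- list(
    molecules = file.path(config$out_dir, "krasbc_molecules.tsv"),
    profiles = file.path(config$out_dir, "cell_profiles.tsv"),
    clone_state = file.path(config$out_dir, "clone_state.tsv"),
    clonotypes = file.path(config$out_dir, "clonotype_summary.tsv"),
    sankey = file.path(config$out_dir, "sankey_links.tsv"),
    qc = file.path(config$out_dir, "qc.json"),
    log = log_path
  )
  data.table::fwrite(kras$molecules, paths$molecules, sep = "\t")
  data.table::fwrite(profiles, paths$profiles, sep = "\t")
  data.table::fwrite(clone_state, paths$clone_state, sep = "\t")
  data.table::fwrite(clonotype_summary(profiles, annotations), paths$clonotypes,
                     sep = "\t")
  if (nrow(clone_state) > 0L) {
    export_sankey(clone_state, paths$sankey)
  } else {
    data.table::fwrite(data.table::data.table(source_node = character(0),
                                              target_node = character(0),
                                              value = integer(0)),
                       paths$sankey, sep = "\t")
  }

  qc <- list(krasbc = kras$qc)
  if (!is.null(kdm8)) {
    paths$kdm8_profiles <- file.path(config$out_dir, "kdm8_profiles.tsv")
    data.table::fwrite(kdm8$profiles, paths$kdm8_profiles, sep = "\t")
    qc$kdm8 <- list(summary = kdm8$summary)
  }
  qc$dropped_unannotated <- attr(clone_state, "dropped_unannotated")
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, pretty = TRUE)
  log("pipeline complete")

  invisible(list(profiles = profiles,
                 kdm8_profiles = if (is.null(kdm8)) NULL else kdm8$profiles,
                 kdm8_summary = if (is.null(kdm8)) NULL else kdm8$summary,
                 clone_state = clone_state, qc = qc, paths = paths))
}

#' Stable digest of a run configuration
#'
#' Deterministic fingerprint of the configuration values (md5 of their
#' serialized form), recorded in the run log.
#'
#' @param config a `run_config`.
#' @return character digest.
#' @export
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(unclass(config))), tmp)
  unname(tools::md5sum(tmp))
}
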