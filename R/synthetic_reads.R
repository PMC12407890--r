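## Ground-truthed synthetic inputs: clone structure, per-cell allele UMI
## counts, Kdm8 status, paired FASTQs for both targeted libraries, and the
## companion cell-annotation table.

#' Simulation parameters
#'
#' Defaults describe a desk-scale tumour: a modest number of clones with
#' power-law size decay, three transcriptomic states mixed per clone, a
#' bimodal Kdm8 signal with 11.4% positive cells, and shallow targeted
#' sequencing. All randomness is governed by `seed`.
#'
#' @param n_cells number of cells.
#' @param n_clones number of barcoded clones (requires at least this many
#'   barcoded alleles in the reference).
#' @param clone_alpha power-law exponent for clone sizes (weights
#'   proportional to `rank^-clone_alpha`); 0 = uniform.
#' @param states character vector of transcriptomic state labels.
#' @param state_concentration Dirichlet concentration of per-clone state
#'   mixing weights (1 = uniform simplex).
#' @param p_imbalanced probability a cell is a G12D-dominant imbalanced
#'   malignant cell (wildtype allele silent).
#' @param p_wt_dominant probability a cell is a WT-dominant malignant cell.
#' @param p_somatic probability a cell is somatic (no engineered barcode).
#'   The remaining mass is balanced malignant cells.
#' @param p_kdm8_positive probability a cell expresses Kdm8 (default 0.114,
#'   the observed positive fraction).
#' @param imbalance_state_logor optional named numeric: additive log-odds on
#'   the imbalanced class for cells in the named state(s); used to plant a
#'   state/imbalance association (default none — independence).
#' @param mean_umis_per_allele expected UMI count per expressed allele.
#' @param reads_per_umi expected read duplicates per UMI (mean of the shifted
#'   Poisson `1 + Pois(reads_per_umi - 1)`, so every UMI yields >= 1 read).
#' @param per_base_error substitution error rate applied to read 2.
#' @param doublet_rate fraction of cell barcodes carrying two clones'
#'   molecules.
#' @param umi_meanlog,umi_sdlog log-normal parameters of the per-cell total
#'   transcriptome UMI count.
#' @param met_fraction fraction of cells assigned to a metastasis sample
#'   (`"met"`) instead of `"primary"`; 0 = single sample.
#' @param met_seed_clones number of largest primary clones seeding the
#'   metastasis.
#' @param seed integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cells = 500L,
                       n_clones = 20L,
                       clone_alpha = 1,
                       states = c("classical", "EMT", "hypoxia"),
                       state_concentration = 1,
                       p_imbalanced = 0.15,
                       p_wt_dominant = 0.05,
                       p_somatic = 0.10,
                       p_kdm8_positive = 0.114,
                       imbalance_state_logor = NULL,
                       mean_umis_per_allele = 4,
                       reads_per_umi = 3,
                       per_base_error = 0,
                       doublet_rate = 0,
                       umi_meanlog = log(5000),
                       umi_sdlog = 0.3,
                       met_fraction = 0,
                       met_seed_clones = 2L,
                       seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_imbalanced, p$p_wt_dominant, p$p_somatic, p$p_kdm8_positive,
             p$per_base_error, p$doublet_rate, p$met_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  if (p$p_imbalanced + p$p_wt_dominant + p$p_somatic > 1) {
    stop("p_imbalanced + p_wt_dominant + p_somatic must be <= 1", call. = FALSE)
  }
  if (p$n_cells < 1L || p$n_clones < 1L) stop("counts must be positive", call. = FALSE)
  if (p$mean_umis_per_allele <= 0 || p$reads_per_umi < 1) {
    stop("UMI depth parameters out of range", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

## distinct random k-mers: sample integer codes without replacement, decode
.random_kmers <- function(n, k) {
  codes <- sample.int(4^k, n, replace = FALSE) - 1
  out <- matrix("", nrow = k, ncol = n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(k)) {
    out[i, ] <- bases[codes %% 4 + 1]
    codes <- codes %/% 4
  }
  apply(out, 2, paste, collapse = "")
}

.rdirichlet1 <- function(k, conc) {
  g <- rgamma(k, shape = conc)
  g / sum(g)
}

## shifted Poisson >= lo with mean approximately m
.rpois_min <- function(n, m, lo) {
  lo + rpois(n, max(m - lo, 0.5))
}

#' Simulate cell-level ground truth
#'
#' Draws clone membership, transcriptomic state, allelic class, per-allele UMI
#' counts, Kdm8 status and transcriptome depth for every cell. Counts for each
#' allelic mode are drawn from that mode's base distribution conditioned on
#' the classification rule mapping the draw back to the same mode, so the true
#' class always equals the class implied by the true counts and class
#' frequencies match the configured probabilities.
#'
#' @param params a [sim_params()].
#' @param reference allele reference `data.frame` (`allele_id`, `sequence`)
#'   containing `Kras_WT` plus at least `n_clones` barcoded alleles.
#' @return `data.table`, one row per cell: `cell_barcode`, `sample_id`,
#'   `clone_id`, `true_barcode` (NA for somatic), `second_barcode` (doublets),
#'   `true_class`, `true_allelic_state`, `true_kdm8`, `state`, `g12d_umis`,
#'   `wt_umis`, `kdm8_umis`, `total_umis`.
#' @export
simulate_truth <- function(params, reference) {
  stopifnot(inherits(params, "sim_params"))
  bc_ids <- setdiff(reference$allele_id, "Kras_WT")
  if (length(bc_ids) < params$n_clones) {
    stop("reference has ", length(bc_ids), " barcoded alleles; need ",
         params$n_clones, call. = FALSE)
  }
  set.seed(as.integer(params$seed))
  n <- as.integer(params$n_cells)

  cell_barcode <- .random_kmers(n, 16L)

  ## clone structure: power-law weights over n_clones barcodes
  clone_ids <- bc_ids[seq_len(params$n_clones)]
  w <- seq_len(params$n_clones)^(-params$clone_alpha)
  w <- w / sum(w)

  ## sample assignment and clone draw (metastasis seeded by the largest clones)
  sample_id <- ifelse(runif(n) < params$met_fraction, "met", "primary")
  seed_set <- order(w, decreasing = TRUE)[seq_len(min(params$met_seed_clones,
                                                      params$n_clones))]
  clone_idx <- integer(n)
  is_met <- sample_id == "met"
  clone_idx[!is_met] <- sample.int(params$n_clones, sum(!is_met), replace = TRUE, prob = w)
  if (any(is_met)) {
    wm <- w[seed_set] / sum(w[seed_set])
    clone_idx[is_met] <- seed_set[sample.int(length(seed_set), sum(is_met),
                                             replace = TRUE, prob = wm)]
  }

  ## per-clone state mixing
  state_w <- t(vapply(seq_len(params$n_clones),
                      function(i) .rdirichlet1(length(params$states),
                                               params$state_concentration),
                      numeric(length(params$states))))
  state <- vapply(clone_idx, function(i) {
    sample(params$states, 1L, prob = state_w[i, ])
  }, character(1))

  ## allelic class, optionally state-linked on the imbalanced component
  p_imb <- rep(params$p_imbalanced, n)
  if (!is.null(params$imbalance_state_logor) && params$p_imbalanced > 0) {
    for (s in names(params$imbalance_state_logor)) {
      hit <- state == s
      lo <- log(p_imb[hit] / (1 - p_imb[hit])) + params$imbalance_state_logor[[s]]
      p_imb[hit] <- 1 / (1 + exp(-lo))
    }
  }
  u <- runif(n)
  true_class_mode <- ifelse(
    u < p_imb, "IMBALANCED",
    ifelse(u < p_imb + params$p_wt_dominant, "WT_DOMINANT",
           ifelse(u < p_imb + params$p_wt_dominant + params$p_somatic,
                  "SOMATIC", "BALANCED"))
  )

  m <- params$mean_umis_per_allele
  g12d <- integer(n)
  wt <- integer(n)

  idx <- which(true_class_mode == "SOMATIC")
  wt[idx] <- .rpois_min(length(idx), m, 2L)          # somatic: WT > 1, no barcode

  idx <- which(true_class_mode == "IMBALANCED")
  g12d[idx] <- .rpois_min(length(idx), m, 2L)        # WT silent, G12D >= 2

  ## balanced / WT-dominant: iid shifted-Poisson pair conditioned on the class rule
  for (mode in c("BALANCED", "WT_DOMINANT")) {
    idx <- which(true_class_mode == mode)
    todo <- idx
    while (length(todo) > 0L) {
      a <- .rpois_min(length(todo), m, 1L)
      b <- .rpois_min(length(todo), m, 1L)
      ok <- if (mode == "BALANCED") b <= a else b > a
      g12d[todo[ok]] <- a[ok]
      wt[todo[ok]] <- b[ok]
      todo <- todo[!ok]
    }
  }

  true_barcode <- ifelse(true_class_mode == "SOMATIC", NA_character_,
                         clone_ids[clone_idx])
  clone_id <- ifelse(true_class_mode == "SOMATIC", NA_character_,
                     clone_ids[clone_idx])

  ## doublets: a second clone's molecules under the same cell barcode
  second_barcode <- rep(NA_character_, n)
  if (params$doublet_rate > 0 && params$n_clones > 1L) {
    dbl <- which(runif(n) < params$doublet_rate & true_class_mode != "SOMATIC")
    for (i in dbl) {
      other <- sample(setdiff(seq_len(params$n_clones), clone_idx[i]), 1L)
      second_barcode[i] <- clone_ids[other]
    }
  }

  kdm8_pos <- runif(n) < params$p_kdm8_positive
  kdm8_umis <- integer(n)
  kdm8_umis[kdm8_pos] <- .rpois_min(sum(kdm8_pos), m, 1L)

  total_umis <- pmax(100L, as.integer(round(rlnorm(n, params$umi_meanlog,
                                                   params$umi_sdlog))))

  truth <- data.table::data.table(
    cell_barcode = cell_barcode,
    sample_id = sample_id,
    clone_id = clone_id,
    true_barcode = true_barcode,
    second_barcode = second_barcode,
    true_class = ifelse(true_class_mode == "SOMATIC", "SOMATIC", "MALIGNANT"),
    true_allelic_state = ifelse(true_class_mode == "SOMATIC", NA_character_,
                                true_class_mode),
    true_kdm8 = ifelse(kdm8_pos, "POSITIVE", "NEGATIVE"),
    state = state,
    g12d_umis = g12d,
    wt_umis = wt,
    kdm8_umis = kdm8_umis,
    total_umis = total_umis
  )
  truth[]
}

#' Inject substitution errors into DNA strings
#'
#' Each base is substituted independently with probability `rate`, always to a
#' different base. Vectorized over sequences.
#'
#' @param seqs character vector of DNA strings.
#' @param rate per-base substitution probability.
#' @return character vector with errors applied.
#' @export
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit) > 0L) {
    ## substitute to one of the three other bases
    cur <- match(flat[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    flat[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  starts <- cumsum(c(1L, lens[-length(lens)]))
  vapply(seq_along(seqs), function(i) {
    paste(flat[starts[i]:(starts[i] + lens[i] - 1L)], collapse = "")
  }, character(1))
}

.write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs) == 0L) {
    return(invisible(path))
  }
  quals <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

## Expand one library's molecule table into duplicated, error-bearing reads.
.emit_library <- function(mols, r2_of_allele, params, out_prefix, lib) {
  if (nrow(mols) > 0L) {
    dup <- 1L + rpois(nrow(mols), params$reads_per_umi - 1)
    rd <- mols[rep(seq_len(nrow(mols)), dup)]
    ## shuffle so file order carries no truth signal
    rd <- rd[sample.int(nrow(rd))]
    r1 <- paste0(rd$cell_barcode, rd$umi)
    r2 <- add_substitution_errors(r2_of_allele[rd$allele_id], params$per_base_error)
    ids <- sprintf("%s_%07d", lib, seq_len(nrow(rd)))
  } else {
    r1 <- r2 <- ids <- character(0)
  }
  p1 <- paste0(out_prefix, "_", lib, "_R1.fastq.gz")
  p2 <- paste0(out_prefix, "_", lib, "_R2.fastq.gz")
  .write_fastq(ids, r1, p1)
  .write_fastq(ids, r2, p2)
  c(p1, p2)
}

#' Emit paired FASTQs for the KrasBC and Kdm8 targeted libraries
#'
#' Read 1 is the 16-nt cell barcode followed by the 10-nt UMI (10x 5'-style
#' geometry). KrasBC read 2 is the 5' flank + allele sequence + 3' flank;
#' Kdm8 read 2 is the fixed 26-nt prefix + transcript fragment. Each true UMI
#' yields `1 + Pois(reads_per_umi - 1)` duplicate reads; substitution errors
#' at `per_base_error` are applied to read 2. UMIs are distinct within a cell,
#' and Kdm8-negative cells emit no Kdm8 reads.
#'
#' Continues the RNG stream from [simulate_truth()]; call it immediately after
#' for a reproducible end-to-end dataset (or use [simulate_dataset()]).
#'
#' @param truth output of [simulate_truth()].
#' @param reference allele reference `data.frame` used to simulate `truth`.
#' @param params the same [sim_params()].
#' @param out_prefix path prefix for the four FASTQ files.
#' @return named character vector of the four file paths, invisibly.
#' @export
emit_fastqs <- function(truth, reference, params, out_prefix) {
  stopifnot(inherits(params, "sim_params"))
  ref_seq <- stats::setNames(reference$sequence, reference$allele_id)
  missing_ref <- setdiff(stats::na.omit(unique(c(truth$true_barcode,
                                                 truth$second_barcode))),
                         names(ref_seq))
  if (length(missing_ref) > 0L) {
    stop("truth references alleles absent from the reference: ",
         paste(head(missing_ref, 3), collapse = ","), call. = FALSE)
  }

  ## molecule tables: one row per true UMI
  per_cell <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i]
    alleles <- c(
      rep(row$true_barcode, row$g12d_umis * !is.na(row$true_barcode)),
      rep(row$second_barcode, row$g12d_umis * !is.na(row$second_barcode)),
      rep("Kras_WT", row$wt_umis),
      rep("Kdm8", row$kdm8_umis)
    )
    if (length(alleles) == 0L) return(NULL)
    umis <- .random_kmers(length(alleles), 10L)
    data.table::data.table(cell_barcode = row$cell_barcode, umi = umis,
                           allele_id = alleles)
  })
  mols <- data.table::rbindlist(per_cell)
  if (nrow(mols) == 0L) {
    mols <- data.table::data.table(cell_barcode = character(0),
                                   umi = character(0), allele_id = character(0))
  }

  flanks <- krasbc_flanks()
  kras_r2 <- paste0(flanks[["five_prime"]], ref_seq, flanks[["three_prime"]])
  names(kras_r2) <- names(ref_seq)
  kdm8_r2 <- c(Kdm8 = paste0(.kdm8_read_prefix(), kdm8_reference()$sequence))

  paths <- c(
    .emit_library(mols[allele_id != "Kdm8"], kras_r2, params, out_prefix, "krasbc"),
    .emit_library(mols[allele_id == "Kdm8"], kdm8_r2, params, out_prefix, "kdm8")
  )
  names(paths) <- c("krasbc_r1", "krasbc_r2", "kdm8_r1", "kdm8_r2")
  invisible(paths)
}

#' Write the companion cell-annotation table
#'
#' One row per cell with the columns the downstream analytics consume:
#' `cell_barcode`, `sample_id`, `state`, `total_umis` (tab-separated, header
#' line, in that order).
#'
#' @param truth output of [simulate_truth()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
emit_cell_annotations <- function(truth, path) {
  ann <- truth[, list(cell_barcode, sample_id, state, total_umis)]
  data.table::fwrite(ann, path, sep = "\t")
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Convenience wrapper: samples a barcode reference from the default design,
#' simulates truth, and writes reference FASTA, truth TSV, annotation TSV and
#' the four FASTQs under `out_dir`.
#'
#' @param params a [sim_params()].
#' @param out_dir output directory (created if needed).
#' @param design a [barcode_design()]; default [kras_default_design()].
#' @param n_barcodes barcoded alleles to sample for the reference (default
#'   `n_clones`).
#' @return list with `reference`, `truth`, and all file `paths`.
#' @export
simulate_dataset <- function(params, out_dir, design = kras_default_design(),
                             n_barcodes = params$n_clones) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- build_reference(design, n_barcodes, seed = params$seed)
  truth <- simulate_truth(params, reference)

  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    truth = file.path(out_dir, "truth.tsv"),
    annotations = file.path(out_dir, "annotations.tsv")
  )
  write_reference(reference, paths$reference)
  data.table::fwrite(truth, paths$truth, sep = "\t")
  emit_cell_annotations(truth, paths$annotations)
  fq <- emit_fastqs(truth, reference, params, file.path(out_dir, "sim"))
  paths <- c(paths, as.list(fq))

  list(reference = reference, truth = truth, paths = paths)
}
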