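## Raw paired reads -> per-molecule allele calls.
##
## Read 1 carries the cell barcode and UMI at fixed offsets; read 2 carries
## the amplicon insert between optional flanks (KrasBC) or after a fixed
## primer prefix (Kdm8). Inserts are matched to the allele reference by
## semi-global edit distance (insert aligned globally, reference locally).

#' Parse cell barcode and UMI from read 1
#'
#' 10x 5'-style geometry: the first `bc_len` bases are the cell barcode, the
#' next `umi_len` the UMI. Reads shorter than `bc_len + umi_len` are rejected
#' (`ok = FALSE`) and counted by the caller's QC.
#'
#' @param seqs character vector of read-1 sequences.
#' @param bc_len cell-barcode length (default 16).
#' @param umi_len UMI length (default 10).
#' @return `data.table` with columns `cell_barcode`, `umi`, `ok`.
#' @export
parse_r1 <- function(seqs, bc_len = 16L, umi_len = 10L) {
  need <- bc_len + umi_len
  ok <- !is.na(seqs) & nchar(seqs) >= need
  data.table::data.table(
    cell_barcode = ifelse(ok, substr(seqs, 1L, bc_len), NA_character_),
    umi = ifelse(ok, substr(seqs, bc_len + 1L, need), NA_character_),
    ok = ok
  )
}

## Locate the minimal-mismatch occurrence of `flank` in each read.
## Returns start positions (NA if no occurrence within max_mm mismatches).
## Tie-breaking among equal-mismatch hits: leftmost if side = "5p",
## rightmost start if side = "3p". Substitution-only matching (no indels),
## consistent with the short fixed flanks it is applied to.
.locate_flank <- function(reads, flank, max_mm, side = c("5p", "3p")) {
  side <- match.arg(side)
  n <- length(reads)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  subj <- Biostrings::DNAStringSet(reads)
  todo <- rep(TRUE, n)
  for (k in 0:max_mm) {
    if (!any(todo)) break
    hits <- Biostrings::vmatchPattern(flank, subj[todo], max.mismatch = k,
                                      with.indels = FALSE)
    starts <- Biostrings::startIndex(hits)
    found <- lengths(starts) > 0L
    idx <- which(todo)[found]
    if (length(idx) > 0L) {
      pick <- vapply(starts[found], function(s) {
        if (side == "5p") min(s) else max(s)
      }, integer(1))
      pos[idx] <- pick
      todo[idx] <- FALSE
    }
  }
  pos
}

#' Trim linked amplicon flanks from read 2
#'
#' Removes everything up to and including the best occurrence of the 5'
#' flank, and everything from the best occurrence of the 3' flank onward.
#' Each flank tolerates up to `floor(max_error_rate * nchar(flank))`
#' mismatches and is optional: a flank with no acceptable occurrence leaves
#' that side untrimmed. The best occurrence is minimal-mismatch; ties go to
#' the leftmost start for the 5' flank and the rightmost start for the 3'
#' flank. The 3' flank is searched only downstream of the 5' trim point.
#'
#' @param seqs character vector of read-2 sequences.
#' @param five_prime_flank,three_prime_flank flank sequences (non-empty).
#' @param max_error_rate tolerated mismatch fraction per flank (default 0.2).
#' @return character vector of inserts.
#' @export
trim_linked_flanks <- function(seqs,
                               five_prime_flank = krasbc_flanks()[["five_prime"]],
                               three_prime_flank = krasbc_flanks()[["three_prime"]],
                               max_error_rate = 0.2) {
  stopifnot(nchar(five_prime_flank) > 0L, nchar(three_prime_flank) > 0L)
  if (length(seqs) == 0L) return(character(0))
  seqs <- toupper(seqs)
  out <- seqs

  mm5 <- floor(max_error_rate * nchar(five_prime_flank))
  ok_len <- nchar(seqs) >= nchar(five_prime_flank)
  p5 <- rep(NA_integer_, length(seqs))
  p5[ok_len] <- .locate_flank(seqs[ok_len], five_prime_flank, mm5, "5p")
  has5 <- !is.na(p5)
  out[has5] <- substr(seqs[has5], p5[has5] + nchar(five_prime_flank),
                      nchar(seqs[has5]))

  mm3 <- floor(max_error_rate * nchar(three_prime_flank))
  ok_len <- nchar(out) >= nchar(three_prime_flank)
  p3 <- rep(NA_integer_, length(out))
  p3[ok_len] <- .locate_flank(out[ok_len], three_prime_flank, mm3, "3p")
  has3 <- !is.na(p3)
  out[has3] <- substr(out[has3], 1L, p3[has3] - 1L)
  out
}

#' Trim a fixed-length prefix from read 2
#'
#' Drops the first `min(n, length)` bases of each read — the Kdm8-Seq
#' primer-derived 26 bp by default.
#'
#' @param seqs character vector of read-2 sequences.
#' @param n prefix length (default [kdm8_prefix_length()]).
#' @return character vector of inserts (possibly empty strings).
#' @export
trim_fixed_prefix <- function(seqs, n = kdm8_prefix_length()) {
  if (n <= 0L) return(seqs)
  substr(seqs, n + 1L, nchar(seqs))
}

## Semi-global edit distances of one insert set against one allele sequence:
## the insert is aligned end-to-end, the allele locally (free ends), with
## unit mismatch/indel costs. Exact, via Biostrings' alignment engine.
.semiglobal_distances <- function(inserts, allele_seq) {
  ## plain unit-cost matrix over A/C/G/T/N: N mismatches everything but
  ## itself (the IUPAC-aware matrix would score ambiguity codes fractionally)
  letters5 <- c("A", "C", "G", "T", "N")
  submat <- matrix(-1, 5L, 5L, dimnames = list(letters5, letters5))
  diag(submat) <- 0
  -Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(inserts),
    subject = Biostrings::DNAString(allele_seq),
    type = "global-local",
    substitutionMatrix = submat,
    gapOpening = 0, gapExtension = -1,
    scoreOnly = TRUE
  )
}

#' Match inserts to the allele reference by semi-global edit distance
#'
#' For every insert the edit distance to each reference allele is computed
#' with the insert aligned globally and the allele locally (so an insert that
#' is an exact substring of an allele has distance 0). The call is the unique
#' minimum-distance allele if its distance is at most `max_edit_distance`;
#' `AMBIGUOUS` if the minimum is tied between alleles; `UNMAPPED` if the
#' minimum exceeds the threshold or the insert is empty.
#'
#' Designs whose minimum pairwise allele distance is `<= 2 * max_edit_distance`
#' risk systematic ambiguity and trigger a warning.
#'
#' @param inserts character vector of insert sequences.
#' @param reference allele reference `data.frame` (`allele_id`, `sequence`).
#' @param max_edit_distance maximum accepted distance (default 3).
#' @param warn_close_alleles check reference pairwise distances (default
#'   TRUE; skipped for references with > 200 alleles).
#' @return `data.table` with columns `insert`, `allele_id`, `edit_distance`
#'   (NA when unmapped), aligned with the input order.
#' @export
call_alleles <- function(inserts, reference, max_edit_distance = 3L,
                         warn_close_alleles = TRUE) {
  stopifnot(nrow(reference) > 0L)
  if (warn_close_alleles && nrow(reference) > 1L && nrow(reference) <= 200L) {
    dmat <- utils::adist(reference$sequence)
    if (min(dmat[upper.tri(dmat)]) <= 2L * max_edit_distance) {
      warning("minimum pairwise allele distance <= 2 * max_edit_distance; ",
              "calls may be systematically ambiguous", call. = FALSE)
    }
  }
  out <- data.table::data.table(insert = inserts)
  uq <- unique(inserts)
  nonempty <- uq[!is.na(uq) & nchar(uq) > 0L]

  call_id <- rep("UNMAPPED", length(uq))
  call_d <- rep(NA_integer_, length(uq))
  names(call_id) <- names(call_d) <- uq

  if (length(nonempty) > 0L) {
    d <- matrix(NA_real_, nrow = length(nonempty), ncol = nrow(reference))
    ## exact-equality fast path: distance 0, provably minimal
    eq <- match(nonempty, reference$sequence)
    for (a in seq_len(nrow(reference))) {
      need <- which(is.na(eq) | eq != a)
      hit <- which(!is.na(eq) & eq == a)
      d[hit, a] <- 0
      if (length(need) > 0L) {
        d[need, a] <- .semiglobal_distances(nonempty[need],
                                            reference$sequence[a])
      }
    }
    dmin <- apply(d, 1L, min)
    nmin <- rowSums(d == dmin)
    best <- max.col(-d, ties.method = "first")
    id <- ifelse(dmin > max_edit_distance, "UNMAPPED",
                 ifelse(nmin > 1L, "AMBIGUOUS", reference$allele_id[best]))
    dd <- ifelse(dmin > max_edit_distance, NA_integer_, as.integer(dmin))
    call_id[nonempty] <- id
    call_d[nonempty] <- dd
  }
  out[, allele_id := call_id[insert]]
  out[, edit_distance := call_d[insert]]
  out[is.na(insert) | insert == "", allele_id := "UNMAPPED"]
  out[]
}

#' Correct cell barcodes against a whitelist
#'
#' Exact matches pass through; a non-matching barcode within Hamming distance
#' 1 of exactly one whitelist entry is corrected to it; anything else becomes
#' `NA`. Mirrors droplet pipelines' one-mismatch correction.
#'
#' @param bcs character vector of observed cell barcodes.
#' @param whitelist character vector of valid barcodes.
#' @return character vector of corrected barcodes (NA where uncorrectable).
#' @export
correct_cell_barcodes <- function(bcs, whitelist) {
  out <- ifelse(bcs %in% whitelist, bcs, NA_character_)
  bad <- unique(bcs[is.na(out) & !is.na(bcs)])
  if (length(bad) == 0L) return(out)
  wl <- new.env(hash = TRUE, parent = emptyenv())
  for (w in whitelist) assign(w, TRUE, envir = wl)
  bases <- c("A", "C", "G", "T")
  fix <- vapply(bad, function(b) {
    n <- nchar(b)
    hit <- character(0)
    for (i in seq_len(n)) {
      cur <- substr(b, i, i)
      for (nt in bases[bases != cur]) {
        cand <- paste0(substr(b, 1L, i - 1L), nt, substr(b, i + 1L, n))
        if (!is.null(wl[[cand]])) {
          hit <- c(hit, cand)
          if (length(hit) > 1L) return(NA_character_)
        }
      }
    }
    if (length(hit) == 1L) hit else NA_character_
  }, character(1))
  idx <- is.na(out) & !is.na(bcs)
  out[idx] <- fix[bcs[idx]]
  out
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ path, optionally gzipped.
#' @return character vector of read sequences, in file order.
#' @export
read_fastq_sequences <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

## Shared R1/R2 -> molecule-table core for both targeted libraries.
.process_paired_fastqs <- function(r1_path, r2_path, reference, trim_fun,
                                   max_edit_distance, whitelist, bc_len, umi_len) {
  r1 <- read_fastq_sequences(r1_path)
  r2 <- read_fastq_sequences(r2_path)
  if (length(r1) != length(r2)) {
    stop("R1/R2 read counts differ (", length(r1), " vs ", length(r2), ")",
         call. = FALSE)
  }
  qc <- list(reads_in = length(r1))

  parsed <- parse_r1(r1, bc_len = bc_len, umi_len = umi_len)
  qc$reads_parsed <- sum(parsed$ok)
  qc$reads_rejected_short <- sum(!parsed$ok)

  inserts <- trim_fun(r2)
  calls <- call_alleles(inserts, reference, max_edit_distance = max_edit_distance)

  mols <- data.table::data.table(
    cell_barcode = parsed$cell_barcode,
    umi = parsed$umi,
    allele_id = calls$allele_id,
    edit_distance = calls$edit_distance
  )[parsed$ok]

  qc$reads_ambiguous <- sum(mols$allele_id == "AMBIGUOUS")
  qc$reads_unmapped <- sum(mols$allele_id == "UNMAPPED")
  mols <- mols[!allele_id %in% c("AMBIGUOUS", "UNMAPPED")]
  qc$reads_called <- nrow(mols)

  if (!is.null(whitelist)) {
    corrected <- correct_cell_barcodes(mols$cell_barcode, whitelist)
    qc$reads_bc_corrected <- sum(!is.na(corrected) & corrected != mols$cell_barcode)
    qc$reads_bc_dropped <- sum(is.na(corrected))
    mols[, cell_barcode := corrected]
    mols <- mols[!is.na(cell_barcode)]
  }
  list(molecules = mols[], qc = qc)
}

#' Process KrasBC-Seq paired FASTQs into molecule-level calls
#'
#' Parses cellBC/UMI from read 1, trims the linked flanks from read 2, calls
#' each insert against the allele reference, optionally corrects cell
#' barcodes against a whitelist, and drops ambiguous/unmapped reads (counted
#' in the QC report).
#'
#' @param r1_path,r2_path paired FASTQ paths (optionally gzipped).
#' @param reference allele reference `data.frame` containing `Kras_WT` and
#'   the barcoded alleles.
#' @param max_edit_distance allele-call threshold (default 3).
#' @param whitelist optional cell-barcode whitelist (e.g. the annotation
#'   table's cells); `NULL` disables correction.
#' @param max_flank_error_rate linked-flank mismatch tolerance (default 0.2).
#' @param bc_len,umi_len read-1 geometry.
#' @return list with `molecules` (`data.table`: `cell_barcode`, `umi`,
#'   `allele_id`, `edit_distance`) and `qc` (named counts).
#' @export
process_krasbc_fastqs <- function(r1_path, r2_path, reference,
                                  max_edit_distance = 3L, whitelist = NULL,
                                  max_flank_error_rate = 0.2,
                                  bc_len = 16L, umi_len = 10L) {
  flanks <- krasbc_flanks()
  .process_paired_fastqs(
    r1_path, r2_path, reference,
    trim_fun = function(x) trim_linked_flanks(x, flanks[["five_prime"]],
                                              flanks[["three_prime"]],
                                              max_flank_error_rate),
    max_edit_distance = max_edit_distance, whitelist = whitelist,
    bc_len = bc_len, umi_len = umi_len
  )
}

#' Process Kdm8-Seq paired FASTQs into molecule-level calls
#'
#' Same contract as [process_krasbc_fastqs()] but read 2 is trimmed by
#' removing the fixed primer-derived prefix and matched against the Kdm8
#' transcript reference.
#'
#' @inheritParams process_krasbc_fastqs
#' @param reference Kdm8 reference (default [kdm8_reference()]).
#' @param prefix_length bases removed from the start of read 2 (default 26).
#' @export
process_kdm8_fastqs <- function(r1_path, r2_path, reference = kdm8_reference(),
                                max_edit_distance = 3L, whitelist = NULL,
                                prefix_length = kdm8_prefix_length(),
                                bc_len = 16L, umi_len = 10L) {
  .process_paired_fastqs(
    r1_path, r2_path, reference,
    trim_fun = function(x) trim_fixed_prefix(x, prefix_length),
    max_edit_distance = max_edit_distance, whitelist = whitelist,
    bc_len = bc_len, umi_len = umi_len
  )
}
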