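## Design of the synonymous Kras G12D barcode library.
##
## Barcodes live in a codon window of the Kras CDS. A small set of codons is
## fixed (the sgRNA-resistance substitutions and the oncogenic G12D codon);
## a disjoint set of codons varies over synonymous alternatives, mostly at the
## wobble base. The library is the Cartesian product of the allowed codon sets.

#' Normalize and validate a DNA string
#'
#' Uppercases the input and checks the alphabet. Used by every constructor in
#' the design module; lowercase input is accepted and normalized.
#'
#' @param x character scalar.
#' @param allow_n also allow `N`.
#' @return uppercase DNA string.
#' @keywords internal
.normalize_dna <- function(x, allow_n = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x)) {
    stop("non-DNA characters in sequence: ", substr(x, 1, 30), call. = FALSE)
  }
  x
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon, call. = FALSE)
  aa
}

.translate <- function(seq) {
  paste(vapply(.split_codons(seq), .translate_codon, character(1)), collapse = "")
}

#' Codon window of a coding sequence
#'
#' A contiguous stretch of codons within a CDS, addressed by 1-based codon
#' number on the protein (codon 1 is the start codon). The barcoded Kras
#' library uses codons 2–31.
#'
#' @param cds_segment DNA string, length divisible by 3; lowercase accepted.
#' @param first_codon_index 1-based codon number of the first codon in the
#'   segment within the full CDS.
#' @return an object of class `codon_window` with elements `cds_segment`,
#'   `first_codon_index`, `codons` (character vector) and `codon_indices`.
#' @export
codon_window <- function(cds_segment, first_codon_index = 1L) {
  cds_segment <- .normalize_dna(cds_segment)
  first_codon_index <- as.integer(first_codon_index)
  if (nchar(cds_segment) %% 3L != 0L) {
    stop("cds_segment length must be divisible by 3", call. = FALSE)
  }
  if (is.na(first_codon_index) || first_codon_index < 1L) {
    stop("first_codon_index must be >= 1", call. = FALSE)
  }
  codons <- .split_codons(cds_segment)
  structure(
    list(
      cds_segment = cds_segment,
      first_codon_index = first_codon_index,
      codons = codons,
      codon_indices = seq.int(first_codon_index, length.out = length(codons))
    ),
    class = "codon_window"
  )
}

.window_codon <- function(window, codon_index) {
  pos <- match(codon_index, window$codon_indices)
  if (anyNA(pos)) {
    stop("codon index ", paste(codon_index[is.na(pos)], collapse = ","),
         " outside window", call. = FALSE)
  }
  window$codons[pos]
}

#' A fixed codon substitution within a barcode design
#'
#' @param codon_index 1-based codon number.
#' @param replacement_codon DNA triplet replacing the wildtype codon.
#' @param synonymous_required must the replacement encode the same amino acid?
#'   The single oncogenic substitution (G12D) sets this to `FALSE`; at most one
#'   non-synonymous fixed substitution is permitted per design.
#' @export
fixed_substitution <- function(codon_index, replacement_codon,
                               synonymous_required = TRUE) {
  replacement_codon <- .normalize_dna(replacement_codon)
  if (nchar(replacement_codon) != 3L) stop("replacement must be a triplet", call. = FALSE)
  structure(
    list(
      codon_index = as.integer(codon_index),
      replacement_codon = replacement_codon,
      synonymous_required = isTRUE(synonymous_required)
    ),
    class = "fixed_substitution"
  )
}

#' Enumerate synonymous codon alternatives
#'
#' All triplets encoding the same amino acid as the input under the standard
#' genetic code. With `wobble_only = TRUE` (the library's default policy,
#' "mostly at wobble bases") only triplets differing from the input at the
#' third position are returned. The input codon is always included.
#'
#' @param codon DNA triplet.
#' @param wobble_only restrict to third-position variants.
#' @return character vector of triplets, sorted, containing `codon`.
#' @examples
#' enumerate_synonymous_options("GTG")          # four-fold valine family
#' enumerate_synonymous_options("ATT")          # ATT/ATC/ATA, ATG excluded
#' enumerate_synonymous_options("TGG")          # tryptophan: only itself
#' @export
enumerate_synonymous_options <- function(codon, wobble_only = TRUE) {
  codon <- .normalize_dna(codon)
  if (nchar(codon) != 3L) stop("codon must be a triplet", call. = FALSE)
  aa <- .translate_codon(codon)
  code <- Biostrings::GENETIC_CODE
  if (wobble_only) {
    candidates <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  } else {
    candidates <- names(code)
  }
  sort(candidates[code[candidates] == aa])
}

#' Barcode design over a codon window
#'
#' Combines the wildtype window, the fixed substitutions, and the variable
#' codon sets into one validated design. Variable codons may be given as a
#' bare integer vector of codon indices — allowed sets are then derived with
#' [enumerate_synonymous_options()] under the design's wobble policy — or as a
#' named list mapping codon index to an explicit codon set.
#'
#' Invariants enforced: fixed and variable indices are disjoint; every allowed
#' codon is synonymous with the wildtype codon at its position and the set
#' contains the wildtype codon; at most one fixed substitution is
#' non-synonymous.
#'
#' @param window a [codon_window()].
#' @param fixed list of [fixed_substitution()] objects.
#' @param variable_codons integer vector of codon indices, or named list of
#'   codon sets keyed by codon index.
#' @param wobble_only policy used when deriving allowed sets from indices.
#' @return object of class `barcode_design`.
#' @export
barcode_design <- function(window, fixed = list(), variable_codons = integer(),
                           wobble_only = TRUE) {
  stopifnot(inherits(window, "codon_window"))
  if (inherits(fixed, "fixed_substitution")) fixed <- list(fixed)
  fixed_idx <- vapply(fixed, function(f) f$codon_index, integer(1))
  if (anyDuplicated(fixed_idx)) stop("duplicate fixed codon indices", call. = FALSE)

  n_nonsyn <- 0L
  for (f in fixed) {
    wt <- .window_codon(window, f$codon_index)
    same_aa <- .translate_codon(wt) == .translate_codon(f$replacement_codon)
    if (f$synonymous_required && !same_aa) {
      stop("fixed substitution at codon ", f$codon_index,
           " marked synonymous but changes the amino acid", call. = FALSE)
    }
    if (!same_aa) n_nonsyn <- n_nonsyn + 1L
  }
  if (n_nonsyn > 1L) {
    stop("at most one non-synonymous fixed substitution (the oncogenic codon) ",
         "is permitted", call. = FALSE)
  }

  if (is.list(variable_codons)) {
    var_idx <- as.integer(names(variable_codons))
    var_sets <- lapply(variable_codons, function(s) {
      sort(vapply(s, .normalize_dna, character(1), USE.NAMES = FALSE))
    })
  } else {
    var_idx <- as.integer(variable_codons)
    var_sets <- lapply(var_idx, function(i) {
      enumerate_synonymous_options(.window_codon(window, i), wobble_only)
    })
  }
  if (anyDuplicated(var_idx)) stop("duplicate variable codon indices", call. = FALSE)
  if (length(intersect(var_idx, fixed_idx)) > 0L) {
    stop("variable and fixed codon indices must be disjoint", call. = FALSE)
  }
  for (k in seq_along(var_idx)) {
    wt <- .window_codon(window, var_idx[k])
    set <- var_sets[[k]]
    if (length(set) == 0L) stop("empty allowed set at codon ", var_idx[k], call. = FALSE)
    if (!(wt %in% set)) {
      stop("allowed set at codon ", var_idx[k], " must include the wildtype codon ",
           wt, call. = FALSE)
    }
    aa_wt <- .translate_codon(wt)
    ok <- vapply(set, .translate_codon, character(1)) == aa_wt
    if (!all(ok)) {
      stop("non-synonymous codon ", set[!ok][1], " in allowed set at codon ",
           var_idx[k], call. = FALSE)
    }
  }
  names(var_sets) <- var_idx
  structure(
    list(
      window = window,
      fixed = fixed,
      variable_codons = var_sets,
      wobble_only = isTRUE(wobble_only)
    ),
    class = "barcode_design"
  )
}

#' @export
print.barcode_design <- function(x, ...) {
  cat("barcode_design: codons ", min(x$window$codon_indices), "-",
      max(x$window$codon_indices), "; ", length(x$fixed), " fixed, ",
      length(x$variable_codons), " variable codons; diversity ",
      format(compute_diversity(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Predicted diversity of a barcode design
#'
#' The number of distinct barcodes: the product over variable codons of the
#' allowed-set sizes. Fixed substitutions contribute a factor of 1; a design
#' with no variable codons has diversity 1 (the empty product).
#'
#' @param design a [barcode_design()].
#' @return the barcode count as a (integer-valued) numeric.
#' @export
compute_diversity <- function(design) {
  stopifnot(inherits(design, "barcode_design"))
  prod(vapply(design$variable_codons, length, integer(1)))
}

#' Apply fixed codon substitutions to a window
#'
#' @param window a [codon_window()].
#' @param fixed list of [fixed_substitution()] objects.
#' @return the substituted window as an uppercase DNA string.
#' @export
apply_fixed_substitutions <- function(window, fixed = list()) {
  stopifnot(inherits(window, "codon_window"))
  if (inherits(fixed, "fixed_substitution")) fixed <- list(fixed)
  codons <- window$codons
  for (f in fixed) {
    pos <- match(f$codon_index, window$codon_indices)
    if (is.na(pos)) stop("codon index ", f$codon_index, " outside window", call. = FALSE)
    same_aa <- .translate_codon(codons[pos]) == .translate_codon(f$replacement_codon)
    if (f$synonymous_required && !same_aa) {
      stop("substitution at codon ", f$codon_index, " violates synonymy", call. = FALSE)
    }
    codons[pos] <- f$replacement_codon
  }
  paste(codons, collapse = "")
}

## Decode a 1-based index into the mixed-radix product space of allowed sets.
.decode_barcode_index <- function(idx, var_sets, base_codons, var_pos) {
  codons <- base_codons
  rem <- idx - 1
  for (k in seq_along(var_sets)) {
    size <- length(var_sets[[k]])
    choice <- rem %% size
    rem <- rem %/% size
    codons[var_pos[k]] <- var_sets[[k]][choice + 1L]
  }
  paste(codons, collapse = "")
}

#' Sample barcodes uniformly without replacement from a design
#'
#' Draws `n` distinct barcode sequences from the designed space. Each drawn
#' barcode has the fixed substitutions applied, so every sequence translates
#' identically to the fixed-substituted wildtype window. Deterministic for a
#' given seed.
#'
#' @param design a [barcode_design()].
#' @param n number of barcodes; must not exceed [compute_diversity()].
#' @param seed integer seed.
#' @param prefix allele-id prefix; ids are `BC_0001`, `BC_0002`, ...
#' @return `data.frame` with columns `allele_id`, `sequence`.
#' @export
sample_barcodes <- function(design, n, seed = 1L, prefix = "BC_") {
  stopifnot(inherits(design, "barcode_design"))
  D <- compute_diversity(design)
  if (n > D) stop("n (", n, ") exceeds design diversity (", D, ")", call. = FALSE)
  if (D > .Machine$integer.max) {
    stop("design space too large to index exactly", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(as.integer(D), size = n, replace = FALSE)

  base <- .split_codons(apply_fixed_substitutions(design$window, design$fixed))
  var_idx <- as.integer(names(design$variable_codons))
  var_pos <- match(var_idx, design$window$codon_indices)
  seqs <- vapply(idx, .decode_barcode_index, character(1),
                 var_sets = design$variable_codons, base_codons = base,
                 var_pos = var_pos)
  data.frame(
    allele_id = sprintf("%s%04d", prefix, seq_len(n)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' Enumerate the full barcode space of a design
#'
#' Intended for small designs (used to cross-check [compute_diversity()]).
#'
#' @param design a [barcode_design()].
#' @param max_diversity refuse to enumerate larger spaces.
#' @return character vector of all barcode sequences (fixed substitutions
#'   applied), in mixed-radix order.
#' @export
enumerate_barcodes <- function(design, max_diversity = 1e5) {
  D <- compute_diversity(design)
  if (D > max_diversity) {
    stop("diversity ", D, " exceeds max_diversity = ", max_diversity, call. = FALSE)
  }
  base <- .split_codons(apply_fixed_substitutions(design$window, design$fixed))
  var_idx <- as.integer(names(design$variable_codons))
  var_pos <- match(var_idx, design$window$codon_indices)
  vapply(seq_len(D), .decode_barcode_index, character(1),
         var_sets = design$variable_codons, base_codons = base,
         var_pos = var_pos)
}

#' Does a sequence disrupt a CRISPR protospacer?
#'
#' `TRUE` iff the exact protospacer does not occur as a substring of the
#' sequence — the criterion for sgRNA resistance of the engineered allele.
#'
#' @param sequence DNA string to scan.
#' @param protospacer protospacer sequence (>= 10 nt).
#' @export
check_protospacer_disruption <- function(sequence, protospacer) {
  sequence <- .normalize_dna(sequence, allow_n = TRUE)
  protospacer <- .normalize_dna(protospacer)
  if (nchar(protospacer) < 10L) stop("protospacer must be >= 10 nt", call. = FALSE)
  !grepl(protospacer, sequence, fixed = TRUE)
}

#' Write / read a barcode allele reference FASTA
#'
#' The reference holds the wildtype allele (id `Kras_WT`) plus the engineered
#' barcoded alleles, one record per allele. Sequences round-trip bit-identically
#' through [read_reference()].
#'
#' @param entries `data.frame` with columns `allele_id`, `sequence`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(entries, path) {
  stopifnot(is.data.frame(entries), all(c("allele_id", "sequence") %in% names(entries)))
  if (nrow(entries) == 0L) stop("empty entry list", call. = FALSE)
  if (anyDuplicated(entries$allele_id)) stop("duplicate allele ids", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(entries$sequence, .normalize_dna,
                                          character(1), USE.NAMES = FALSE))
  names(seqs) <- entries$allele_id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(
    allele_id = names(seqs),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Assemble a full barcode reference (wildtype + sampled barcodes)
#'
#' @param design a [barcode_design()].
#' @param n_barcodes number of barcoded alleles to sample.
#' @param seed integer seed passed to [sample_barcodes()].
#' @return `data.frame` with the `Kras_WT` entry first, then the barcodes.
#' @export
build_reference <- function(design, n_barcodes, seed = 1L) {
  bcs <- sample_barcodes(design, n_barcodes, seed = seed)
  rbind(
    data.frame(allele_id = "Kras_WT", sequence = design$window$cds_segment,
               stringsAsFactors = FALSE),
    bcs
  )
}
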