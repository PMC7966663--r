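## Alignment-based analysis of disordered C-terminal tails: reference-
## anchored numbering, tail classification at the anchor motif (positions
## 183-185 in NCS-1 numbering), partitioned conservation, motif census,
## position frequency matrices and tail physicochemistry.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a reference-anchored multiple sequence alignment
#'
#' Wraps an aligned set of amino-acid sequences together with a column map
#' derived from the reference row, so that alignment columns can be addressed
#' by reference residue number (NCS-1 numbering 1-190 when the reference is
#' the full-length sensor).
#'
#' @param sequences Named character vector of equal-length aligned sequences
#'   (gap character `-`; `.` is accepted and normalised to `-`).
#' @param reference_id Id of the reference row; defaults to the first
#'   sequence.
#' @return An `anchored_msa` list with `sequences`, `ids`, `reference_id` and
#'   `column_map` (named integer vector: reference residue number -> column).
#' @export
anchored_msa <- function(sequences, reference_id = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- toupper(gsub(".", "-", sequences, fixed = TRUE))
  w <- unique(nchar(sequences))
  if (length(w) != 1L)
    stop("all aligned rows must have equal length", call. = FALSE)
  if (is.null(reference_id)) reference_id <- names(sequences)[1L]
  if (!reference_id %in% names(sequences))
    stop("reference id '", reference_id, "' not found in the alignment",
         call. = FALSE)
  ref <- strsplit(sequences[[reference_id]], "")[[1L]]
  cols <- which(ref != "-")
  if (length(cols) == 0L)
    stop("reference row is all gaps", call. = FALSE)
  column_map <- stats::setNames(cols, seq_along(cols))
  structure(list(sequences = sequences, ids = names(sequences),
                 reference_id = reference_id, column_map = column_map),
            class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat(sprintf("Anchored MSA: %d sequences x %d columns, reference '%s' (%d residues)\n",
              length(x$sequences), nchar(x$sequences[[1L]]), x$reference_id,
              length(x$column_map)))
  invisible(x)
}

#' Read a reference-anchored alignment from disk
#'
#' Aligned FASTA and Stockholm are read with Biostrings; A3M is converted by
#' dropping lowercase insert-state columns relative to the reference columns.
#'
#' @param path File path.
#' @param reference_id Reference sequence id (default: first row).
#' @param format `"fasta"`, `"stockholm"` or `"a3m"`; guessed from the file
#'   extension by default.
#' @return An [anchored_msa()].
#' @export
read_anchored_msa <- function(path, reference_id = NULL,
                              format = c("auto", "fasta", "stockholm", "a3m")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, a3m = "a3m", sto = "stockholm",
                     stk = "stockholm", stockholm = "stockholm", "fasta")
  }
  if (format == "a3m") {
    seqs <- .read_fasta_raw(path)
    seqs <- vapply(seqs, function(s) gsub("[a-z]", "", s), character(1))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    ss <- as.character(Biostrings::unmasked(aln))
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  anchored_msa(seqs, reference_id)
}

## minimal FASTA-record reader used only for the A3M shim
.read_fasta_raw <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  ends <- c(hdr[-1L] - 1L, length(lines))
  stats::setNames(vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1)), ids)
}

.msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$sequences, ""))
  rownames(m) <- msa$ids
  m
}

.anchor_cols <- function(msa, positions) {
  pos <- as.character(positions)
  if (!all(pos %in% names(msa$column_map)))
    stop("reference lacks residues ", paste(positions, collapse = ", "),
         call. = FALSE)
  msa$column_map[pos]
}

#' Classify homologs by presence of a C-terminal tail
#'
#' A homolog "has a tail" when non-gap residues align with the anchor motif
#' positions (183-185 in reference numbering).  By default all three mapped
#' columns must be occupied (`mode = "all"`); `mode = "any"` gives the
#' permissive reading (any one occupied).
#'
#' @param msa An [anchored_msa()].
#' @param positions Reference anchor positions, default `183:185`.
#' @param mode `"all"` (default) or `"any"`.
#' @return Named logical vector over sequence ids.
#' @export
classify_tail <- function(msa, positions = 183:185, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(msa, "anchored_msa"))
  cols <- .anchor_cols(msa, positions)
  m <- .msa_matrix(msa)[, cols, drop = FALSE] != "-"
  if (mode == "all") apply(m, 1, all) else apply(m, 1, any)
}

.partition_ids <- function(msa, partition, ...) {
  partition <- match.arg(partition, c("all", "tailed", "untailed"))
  if (partition == "all") return(msa$ids)
  tl <- classify_tail(msa, ...)
  ids <- if (partition == "tailed") names(tl)[tl] else names(tl)[!tl]
  if (length(ids) == 0L)
    stop("empty partition: no ", partition, " sequences", call. = FALSE)
  ids
}

## per-column residue counts over a set of rows; rows = 20 amino acids + gap
.column_counts <- function(msa, ids) {
  seqs <- Biostrings::AAStringSet(msa$sequences[ids])
  cm <- Biostrings::consensusMatrix(seqs)
  counts <- matrix(0, nrow = length(.AA20) + 1L, ncol = ncol(cm),
                   dimnames = list(c(.AA20, "-"), NULL))
  for (ch in intersect(rownames(cm), rownames(counts)))
    counts[ch, ] <- cm[ch, ]
  counts
}

#' Per-position conservation profile
#'
#' For each reference position, the modal (consensus) residue and its
#' frequency among non-gap rows of the chosen partition, plus the gap
#' fraction.  Frequencies deliberately exclude gaps from the denominator; the
#' gap fraction is reported alongside so the alternative convention is
#' recoverable.  Ties on the modal residue are broken alphabetically and
#' flagged.
#'
#' @param msa An [anchored_msa()].
#' @param partition `"all"`, `"tailed"` or `"untailed"`.
#' @param ... Passed to [classify_tail()] (anchor `positions`, `mode`).
#' @return Data frame `position`, `consensus`, `frequency`, `gap_fraction`,
#'   `tie`.
#' @export
conservation <- function(msa, partition = "all", ...) {
  stopifnot(inherits(msa, "anchored_msa"))
  ids <- .partition_ids(msa, partition, ...)
  counts <- .column_counts(msa, ids)[, msa$column_map, drop = FALSE]
  n <- length(ids)
  aa <- counts[.AA20, , drop = FALSE]
  nongap <- colSums(aa)
  top <- apply(aa, 2, max)
  cons <- apply(aa, 2, function(col) .AA20[which.max(col)])  # alphabetical tie-break
  tie <- apply(aa, 2, function(col) sum(col == max(col)) > 1L & max(col) > 0)
  data.frame(position = as.integer(names(msa$column_map)),
             consensus = ifelse(nongap > 0, cons, NA_character_),
             frequency = ifelse(nongap > 0, top / nongap, NA_real_),
             gap_fraction = 1 - nongap / n,
             tie = tie)
}

#' Tail-specific conservation ranking
#'
#' Per reference position, the conservation in the tailed partition and its
#' difference from the untailed partition, ranked by the difference.  This is
#' the screen that surfaces positions co-conserved with tail presence
#' (position 100 in the calcium-sensor family).
#'
#' @inheritParams conservation
#' @return Data frame `position`, `consensus_tailed`, `cons_tailed`,
#'   `cons_untailed`, `difference`, `rank` (1 = most tail-specific), ordered
#'   by decreasing difference.
#' @export
tail_specific_conservation <- function(msa, ...) {
  ct <- conservation(msa, "tailed", ...)
  cu <- conservation(msa, "untailed", ...)
  out <- data.frame(position = ct$position,
                    consensus_tailed = ct$consensus,
                    cons_tailed = ct$frequency,
                    cons_untailed = cu$frequency,
                    difference = ct$frequency - cu$frequency)
  out <- out[order(-out$difference, out$position), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Census of residue classes at the tail anchor motif
#'
#' Counts, over tailed homologs only, the residue classes observed at the
#' anchor positions: aliphatic \[ILVM\] or aromatic \[FWY\] at 183; Ser or Thr
#' at 184; \[AVILM\] or aromatic at 185; and the complete L-S-L motif.  The
#' tailed set is additionally split into aliphatic-183 and aromatic-183
#' branches with a position frequency matrix per branch over the tail region.
#'
#' @param msa An [anchored_msa()].
#' @param positions Anchor positions, default `183:185`.
#' @param branch_region Reference positions for the per-branch PFMs; defaults
#'   to the available tail positions 176-190.
#' @param ... Passed to [classify_tail()].
#' @return A `motif_census` list: `counts` (named integer vector incl.
#'   `total_tailed`), `branches` (ids per 183-branch), `branch_pfms`.
#' @export
motif_census <- function(msa, positions = 183:185,
                         branch_region = 176:190, ...) {
  stopifnot(inherits(msa, "anchored_msa"), length(positions) == 3L)
  tl <- classify_tail(msa, positions = positions, ...)
  # the census is over homologs; the anchoring reference row is not counted
  tailed_ids <- setdiff(names(tl)[tl], msa$reference_id)
  if (length(tailed_ids) == 0L) {
    warning("no tailed sequences: census is empty")
    return(structure(list(counts = c(aliphatic_183 = 0L, aromatic_183 = 0L,
                                     ser_184 = 0L, thr_184 = 0L,
                                     aliphatic_185 = 0L, aromatic_185 = 0L,
                                     lsl_complete = 0L, total_tailed = 0L),
                          branches = list(), branch_pfms = list()),
                     class = "motif_census"))
  }
  cols <- .anchor_cols(msa, positions)
  m <- .msa_matrix(msa)[tailed_ids, cols, drop = FALSE]
  aliph <- c("I", "L", "V", "M"); arom <- c("F", "W", "Y")
  counts <- c(
    aliphatic_183 = sum(m[, 1L] %in% aliph),
    aromatic_183 = sum(m[, 1L] %in% arom),
    ser_184 = sum(m[, 2L] == "S"),
    thr_184 = sum(m[, 2L] == "T"),
    aliphatic_185 = sum(m[, 3L] %in% c("A", aliph)),
    aromatic_185 = sum(m[, 3L] %in% arom),
    lsl_complete = sum(m[, 1L] == "L" & m[, 2L] == "S" & m[, 3L] == "L"),
    total_tailed = length(tailed_ids))
  branches <- list(aliphatic_183 = tailed_ids[m[, 1L] %in% aliph],
                   aromatic_183 = tailed_ids[m[, 1L] %in% arom])
  region <- intersect(branch_region, as.integer(names(msa$column_map)))
  branch_pfms <- lapply(branches, function(ids) {
    if (length(ids) == 0L) return(NULL)
    sub <- msa; sub$sequences <- msa$sequences[ids]; sub$ids <- ids
    # keep the reference anchoring of the parent alignment
    sub$reference_id <- msa$reference_id
    sub$column_map <- msa$column_map
    .pfm_counts(sub, region, ids)
  })
  structure(list(counts = counts, branches = branches,
                 branch_pfms = branch_pfms),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("Tail anchor-motif census (tailed homologs only):\n")
  print(x$counts)
  invisible(x)
}

.pfm_counts <- function(msa, positions, ids) {
  cols <- .anchor_cols(msa, positions)
  counts <- .column_counts(msa, ids)[, cols, drop = FALSE]
  aa <- counts[.AA20, , drop = FALSE]
  nongap <- colSums(aa)
  freq <- sweep(aa, 2, pmax(nongap, 1), "/")
  freq[, nongap == 0] <- NA_real_
  colnames(freq) <- as.character(positions)
  attr(freq, "gap_fraction") <- stats::setNames(
    counts["-", ] / length(ids), as.character(positions))
  attr(freq, "flagged_all_gap") <- as.integer(positions)[nongap == 0]
  freq
}

#' Position frequency matrix for a logo
#'
#' 20-row frequency matrix over the requested reference positions, columns
#' normalised over non-gap counts (suitable for sequence-logo tools).  The
#' per-column gap fraction travels as an attribute; all-gap columns are NA
#' and flagged.
#'
#' @param msa An [anchored_msa()].
#' @param positions Reference positions.
#' @param partition `"all"`, `"tailed"` or `"untailed"`.
#' @param ... Passed to [classify_tail()].
#' @return Matrix (20 x positions) with attributes `gap_fraction` and
#'   `flagged_all_gap`.
#' @export
pfm <- function(msa, positions, partition = "all", ...) {
  stopifnot(inherits(msa, "anchored_msa"))
  ids <- .partition_ids(msa, partition, ...)
  .pfm_counts(msa, positions, ids)
}

## Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Physicochemical properties of a tail sequence
#'
#' Formal net side-chain charge at pH 7 ((K + R) - (D + E), His neutral,
#' termini ignored), Kyte-Doolittle hydropathy as sliding-window means
#' (odd window, edges truncated), and length.
#'
#' @param sequence Single string of standard one-letter amino acids.
#' @param window Odd hydropathy window size, default 5.
#' @return A `tail_properties` list: `net_charge`, `hydropathy` (per-position
#'   window means), `length`.  Optional `helicity`/`disorder` slots are
#'   reserved for user-supplied external predictor scores.
#' @export
tail_properties <- function(sequence, window = 5L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window %% 2L != 1L || window < 1L)
    stop("'window' must be a positive odd integer", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(aa, .AA20)
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  charge <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  h <- .KD_SCALE[aa]
  half <- (window - 1L) %/% 2L
  hyd <- vapply(seq_along(aa), function(i)
    mean(h[max(1L, i - half):min(length(aa), i + half)]), numeric(1))
  structure(list(net_charge = charge,
                 hydropathy = stats::setNames(hyd, seq_along(aa)),
                 length = length(aa),
                 helicity = NULL, disorder = NULL),
            class = "tail_properties")
}
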