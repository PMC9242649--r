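# Aligned multiple-sequence-alignment container and per-column conservation
# statistics.  The alignment is held as an N x L character matrix over the
# 20 amino acids, 'X' (unknown) and '-' (gap), with sequence ids as rownames
# and an optional subfamily label per sequence.

#' Standard amino-acid alphabet (20 letters)
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Phe/Tyr six-carbon-aromatic class; Trp is deliberately excluded.
phi_class <- function() c("F", "Y")

# Display symbol for the Phe/Tyr class (capital phi).
phi_symbol <- function() "\u03a6"

msa_gap <- "-"
msa_unknown <- "X"

#' Construct an aligned MSA object
#'
#' @param rows Character vector of aligned sequences (equal length, gaps `-`).
#' @param seq_ids Unique sequence identifiers, one per row.
#' @param labels Optional named character vector mapping `seq_ids` to
#'   subfamily tags (e.g. `"TRPV"`).  Names must be a subset of `seq_ids`.
#' @return An object of class `msa`: an N x L character matrix with sequence
#'   ids as rownames and a `labels` attribute.
#' @export
msa <- function(rows, seq_ids = NULL, labels = NULL) {
  if (length(rows) < 1L) stop("an MSA needs at least one sequence")
  if (is.null(seq_ids)) seq_ids <- paste0("seq", seq_along(rows))
  seq_ids <- as.character(seq_ids)
  if (anyDuplicated(seq_ids)) stop("sequence ids must be unique")
  if (length(seq_ids) != length(rows)) stop("one id per sequence required")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- seq_ids[which(lens != lens[1L])[1L]]
    stop("ragged alignment: record '", bad, "' has length ", nchar(rows[bad]),
         ", expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  m <- matrix(unlist(strsplit(toupper(rows), "", fixed = TRUE), use.names = FALSE),
              nrow = length(rows), byrow = TRUE)
  m[m == "."] <- msa_gap
  ok <- m %in% c(aa_alphabet(), msa_gap, msa_unknown)
  if (!all(ok)) {
    n_bad <- sum(!ok)
    warning(n_bad, " character(s) outside the amino-acid alphabet mapped to 'X'")
    m[!ok] <- msa_unknown
  }
  rownames(m) <- seq_ids
  if (!is.null(labels)) {
    labels <- stats::setNames(as.character(labels), names(labels))
    if (is.null(names(labels)) || !all(names(labels) %in% seq_ids)) {
      stop("labels must be named by existing sequence ids")
    }
  }
  structure(m, class = c("msa", class(m)), labels = labels)
}

#' @export
print.msa <- function(x, ...) {
  cat("Aligned MSA: ", nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  lab <- attr(x, "labels")
  if (!is.null(lab)) {
    tab <- table(lab)
    cat("Subfamily labels: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

msa_labels <- function(msa) attr(msa, "labels")

#' Read an aligned FASTA file into an `msa` object
#'
#' Characters outside the 20-letter alphabet (other than `-` and `.`) are
#' mapped to `'X'` with a warning.  All records must have the same aligned
#' length.
#'
#' @param path Path to an aligned FASTA file.
#' @param labels Optional path to a two-column TSV (seq_id, subfamily) or a
#'   named character vector of subfamily tags.
#' @return An [msa] object.
#' @export
read_msa <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  rows <- as.character(aa)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  msa(rows, seq_ids = ids, labels = labels)
}

#' Read a sequence-to-subfamily label sidecar (TSV: seq_id, subfamily)
#' @param path Path to a two-column tab-separated file, no header required.
#' @return Named character vector (names = seq ids).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("seq_id", "subfamily"))
  stats::setNames(df$subfamily, df$seq_id)
}

#' Write an `msa` object to aligned FASTA
#' @param msa An [msa] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  rows <- apply(unclass(msa), 1L, paste, collapse = "")
  x <- Biostrings::AAStringSet(rows)
  names(x) <- rownames(msa)
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

# Residue count matrix: (20 aa + X + gap) x L integer counts.
column_counts <- function(msa) {
  states <- c(aa_alphabet(), msa_unknown, msa_gap)
  m <- unclass(msa)
  out <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = states), nbins = length(states))
  }, integer(length(states)))
  rownames(out) <- states
  out
}

#' Per-column residue statistics of an alignment
#'
#' For every alignment column, counts residues and reports the gap fraction,
#' consensus residue, identity (fraction of the most common residue) and
#' `phi_identity`, the combined Phe+Tyr fraction.  By default the identity
#' denominator is the full number of sequences N, so gaps count against
#' conservation; set `gap_denominator = FALSE` to divide by the non-gap count
#' instead (sensitivity analysis).
#'
#' `'X'` counts in the denominator but is never reported as consensus; ties
#' for consensus are broken alphabetically.
#'
#' @param msa An [msa] object.
#' @param gap_denominator Logical; include gapped sequences in the identity
#'   denominator (default `TRUE`).
#' @return A data.frame with one row per column: `column`, `gap_fraction`,
#'   `consensus`, `identity`, `phi_identity`, `n_nongap`.  The full residue
#'   count matrix (states x columns) is attached as attribute `"counts"`.
#' @export
column_profiles <- function(msa, gap_denominator = TRUE) {
  counts <- column_counts(msa)
  n <- nrow(msa)
  gap_n <- counts[msa_gap, ]
  nongap <- n - gap_n
  denom <- if (gap_denominator) rep(n, ncol(msa)) else pmax(nongap, 1L)
  res_counts <- counts[aa_alphabet(), , drop = FALSE]  # X never consensus
  top <- apply(res_counts, 2L, max)
  consensus <- rownames(res_counts)[apply(res_counts, 2L, which.max)]
  consensus[top == 0L] <- NA_character_
  identity <- top / denom
  phi <- colSums(counts[phi_class(), , drop = FALSE]) / denom
  out <- data.frame(
    column = seq_len(ncol(msa)),
    gap_fraction = gap_n / n,
    consensus = consensus,
    identity = identity,
    phi_identity = phi,
    n_nongap = as.integer(nongap),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- counts
  out
}

#' Scan an alignment for highly conserved columns
#'
#' Returns every column whose identity strictly exceeds `threshold`; with
#' `use_phi = TRUE` a column also qualifies when its combined Phe+Tyr fraction
#' strictly exceeds the threshold, in which case the consensus is reported as
#' the aromatic-class symbol and `class_used` is `"phi"`.  When both criteria
#' fire, the exact-identity classification takes precedence.
#'
#' @param msa An [msa] object.
#' @param threshold Conservation threshold in (0, 1]; strict inequality
#'   (default 0.90, i.e. identity > 90\%).
#' @param use_phi Also accept columns conserved as the \{F, Y\} class.
#' @param gap_denominator Passed to [column_profiles()].
#' @return data.frame: `column`, `consensus`, `identity_pct`, `class_used`
#'   (`"exact"` or `"phi"`).
#' @export
conservation_scan <- function(msa, threshold = 0.90, use_phi = TRUE,
                              gap_denominator = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  prof <- column_profiles(msa, gap_denominator = gap_denominator)
  exact <- prof$identity > threshold & !is.na(prof$consensus)
  phi <- if (use_phi) prof$phi_identity > threshold else rep(FALSE, nrow(prof))
  hit <- exact | phi
  cls <- ifelse(exact, "exact", "phi")  # exact wins when both fire
  out <- data.frame(
    column = prof$column[hit],
    consensus = ifelse(cls[hit] == "exact", prof$consensus[hit], phi_symbol()),
    identity_pct = 100 * ifelse(cls[hit] == "exact",
                                prof$identity[hit], prof$phi_identity[hit]),
    class_used = cls[hit],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-subfamily gap-fraction profile
#'
#' One row per subfamily label, one column per alignment column; each entry is
#' that subfamily's gap fraction at that column.  Used to profile
#' subfamily-specific indel blocks in loop regions.
#'
#' @param msa An [msa] object with sequence labels.
#' @return Numeric matrix, subfamilies x columns, values in \[0, 1\].
#' @export
gap_pattern_profile <- function(msa) {
  lab <- msa_labels(msa)
  if (is.null(lab)) stop("gap_pattern_profile requires subfamily labels")
  m <- unclass(msa) == msa_gap
  fams <- sort(unique(lab))
  out <- t(vapply(fams, function(f) {
    ids <- names(lab)[lab == f]
    colMeans(m[rownames(msa) %in% ids, , drop = FALSE])
  }, numeric(ncol(msa))))
  rownames(out) <- fams
  out
}

#' Shannon entropy of a discrete distribution
#'
#' @param p Non-negative weights (normalised internally); `0 * log 0 = 0`.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return Entropy, a single non-negative number.
#' @export
shannon_entropy <- function(p, base = 2) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("entropy of an empty distribution is undefined")
  p <- p[p > 0] / s
  -sum(p * log(p, base = base))
}

#' Per-column letter frequencies and information content (sequence-logo data)
#'
#' Frequencies are over the 20 standard residues among non-gap, non-`X`
#' characters; information content is `log2(20)` minus the Shannon entropy of
#' that distribution.  All-gap (or all-unknown) columns yield a flagged row of
#' zero frequencies and zero information.
#'
#' @param msa An [msa] object.
#' @param columns Integer vector of 1-based columns (default: all).
#' @return Long-format data.frame: `column`, `residue`, `frequency`,
#'   `bits` (per-column information content, repeated across its residues),
#'   `all_gap` flag.
#' @export
export_logo_data <- function(msa, columns = seq_len(ncol(msa))) {
  if (any(columns < 1L | columns > ncol(msa))) {
    stop("columns out of range 1..", ncol(msa))
  }
  counts <- column_counts(msa)[aa_alphabet(), columns, drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(columns), function(k) {
    cnt <- counts[, k]
    tot <- sum(cnt)
    if (tot == 0L) {
      return(data.frame(column = columns[k], residue = NA_character_,
                        frequency = 0, bits = 0, all_gap = TRUE,
                        stringsAsFactors = FALSE))
    }
    freq <- cnt / tot
    ic <- log2(20) - shannon_entropy(freq, base = 2)
    keep <- freq > 0
    data.frame(column = columns[k], residue = names(freq)[keep],
               frequency = unname(freq[keep]), bits = ic, all_gap = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
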