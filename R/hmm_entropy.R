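# Profile-emission corroboration of the conservation scan: pick match columns
# by gap content, estimate per-column emission probabilities with a single
# pseudocount, and rank columns by Shannon entropy.  This deliberately does
# not replicate hmmbuild's Dirichlet-mixture priors: the entropy ranking is
# what matters and it is robust to the prior.

#' Select profile match columns by gap content
#'
#' @param msa An [msa] object.
#' @param max_gap Columns with gap fraction strictly below this value are
#'   kept (default 0.5, the "less than 50\% gaps" match-state rule).
#' @return Ascending integer vector of 1-based column indices.
#' @export
select_match_columns <- function(msa, max_gap = 0.5) {
  stopifnot(max_gap > 0, max_gap <= 1)
  gap_frac <- colMeans(unclass(msa) == msa_gap)
  which(gap_frac < max_gap)
}

#' Per-column emission probabilities over the 20 residues
#'
#' For each selected column, `p(a) = (weighted count of a + pseudocount *
#' background(a)) / (weighted non-gap total + pseudocount)`.  Gaps and
#' unknown residues are excluded from the counts (match-state convention).
#' With `pseudocount = 0` and unit weights the emissions are the empirical
#' non-gap frequencies.
#'
#' @param msa An [msa] object.
#' @param columns Columns to profile (default: [select_match_columns()]).
#' @param pseudocount Total pseudocount mass (>= 0, default 1).
#' @param weights Optional per-sequence weights (default: 1 each), e.g. from
#'   [sequence_weights()].
#' @param background Background distribution over the 20 residues
#'   (default uniform 1/20); must sum to 1.
#' @return An `emission_profile`: list with `match_columns`, `emissions`
#'   (columns x 20 matrix, rows summing to 1) and `entropy_bits`.
#' @export
emission_probabilities <- function(msa, columns = select_match_columns(msa),
                                   pseudocount = 1.0, weights = NULL,
                                   background = rep(1 / 20, 20)) {
  stopifnot(pseudocount >= 0, length(background) == 20,
            abs(sum(background) - 1) < 1e-9)
  m <- unclass(msa)
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights > 0))
  alpha <- aa_alphabet()
  emis <- t(vapply(columns, function(j) {
    col <- m[, j]
    keep <- col %in% alpha
    cnt <- vapply(alpha, function(a) sum(weights[keep][col[keep] == a]),
                  numeric(1))
    tot <- sum(cnt)
    if (tot == 0 && pseudocount == 0) {
      stop("column ", j, " has no countable residues and pseudocount is 0")
    }
    (cnt + pseudocount * background) / (tot + pseudocount)
  }, numeric(20)))
  rownames(emis) <- as.character(columns)
  colnames(emis) <- alpha
  ent <- apply(emis, 1L, shannon_entropy, base = 2)
  structure(list(match_columns = as.integer(columns), emissions = emis,
                 entropy_bits = unname(ent)),
            class = "emission_profile")
}

#' @export
print.emission_profile <- function(x, ...) {
  cat("Emission profile over ", length(x$match_columns), " match columns\n",
      sep = "")
  cat("Entropy (bits): min ", round(min(x$entropy_bits), 3), ", median ",
      round(stats::median(x$entropy_bits), 3), ", max ",
      round(max(x$entropy_bits), 3), "\n", sep = "")
  invisible(x)
}

#' Rank profile columns by emission entropy
#'
#' @param profile An `emission_profile`.
#' @return data.frame `column`, `entropy_bits`, ascending by entropy (most
#'   conserved first); ties keep column order.
#' @export
entropy_scan <- function(profile) {
  ord <- order(profile$entropy_bits, profile$match_columns)
  data.frame(column = profile$match_columns[ord],
             entropy_bits = profile$entropy_bits[ord])
}

#' Where do fingerprint columns rank in the entropy scan?
#'
#' Reports, for each fingerprint slot, its emission entropy and percentile
#' among all match columns (0 = most conserved).  Fingerprint columns that
#' are not match columns are flagged rather than fatal.
#'
#' @param scan Result of [entropy_scan()].
#' @param fp A `fingerprint_def` (default [fingerprint_default()]).
#' @return data.frame: `slot`, `label`, `align_col`, `entropy_bits`,
#'   `rank`, `percentile` (in \[0, 100\]), `in_match_columns`.
#' @export
fingerprint_rank_check <- function(scan, fp = fingerprint_default()) {
  n <- nrow(scan)
  idx <- match(fp$align_col, scan$column)
  out <- data.frame(
    slot = fp$slot, label = fp$label, align_col = fp$align_col,
    entropy_bits = scan$entropy_bits[idx],
    rank = idx,
    percentile = 100 * (idx - 1) / max(n - 1, 1),
    in_match_columns = !is.na(idx),
    stringsAsFactors = FALSE
  )
  if (any(!out$in_match_columns)) {
    warning("fingerprint column(s) ",
            paste(out$align_col[!out$in_match_columns], collapse = ", "),
            " are not match columns")
  }
  rownames(out) <- NULL
  out
}
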