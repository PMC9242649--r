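# The twelve-slot Group-I TRP residue fingerprint (W F Φ G Φ Φ Φ N L I A W)
# and scoring of residue tuples / whole alignments against it.

#' Default Group-I TRP fingerprint definition
#'
#' Twelve ordered slots, each with an allowed residue set, a display label, a
#' 1-based alignment column in the primary TRP alignment, and the equivalent
#' rat TRPV1 position.  Slots labelled with the aromatic-class symbol allow
#' \{F, Y\}; all other slots allow a single residue.
#'
#' @param slot2_phi Treat slot 2 (Phe434 in rat TRPV1) as the \{F, Y\} class
#'   instead of strict F (default `FALSE`).
#' @return A `fingerprint_def`: data.frame with columns `slot`, `label`,
#'   `allowed` (list of character vectors), `align_col`, `rtrpv1_pos`.
#' @export
fingerprint_default <- function(slot2_phi = FALSE) {
  labels <- c("W", "F", phi_symbol(), "G", phi_symbol(), phi_symbol(),
              phi_symbol(), "N", "L", "I", "A", "W")
  allowed <- lapply(labels, function(l) {
    if (l == phi_symbol()) phi_class() else l
  })
  if (slot2_phi) allowed[[2L]] <- phi_class()
  new_fingerprint_def(
    labels = labels, allowed = allowed,
    align_col = c(81L, 320L, 331L, 633L, 662L, 755L, 852L, 862L, 864L, 865L,
                  866L, 883L),
    rtrpv1_pos = c(426L, 434L, 441L, 563L, 591L, 638L, 666L, 676L, 678L,
                   679L, 680L, 697L)
  )
}

new_fingerprint_def <- function(labels, allowed, align_col, rtrpv1_pos) {
  if (length(labels) != 12L) stop("a fingerprint has exactly 12 slots")
  stopifnot(length(allowed) == 12L, length(align_col) == 12L,
            length(rtrpv1_pos) == 12L)
  if (any(diff(align_col) <= 0L)) {
    stop("alignment columns must be strictly increasing")
  }
  df <- data.frame(slot = 1:12, label = labels,
                   align_col = as.integer(align_col),
                   rtrpv1_pos = as.integer(rtrpv1_pos),
                   stringsAsFactors = FALSE)
  df$allowed <- allowed
  structure(df, class = c("fingerprint_def", "data.frame"))
}

#' @export
print.fingerprint_def <- function(x, ...) {
  cat("TRP fingerprint definition (12 slots):\n")
  cat("  ", paste(x$label, collapse = " "), "\n", sep = "")
  cat("  alignment columns: ", paste(x$align_col, collapse = ", "), "\n",
      sep = "")
  cat("  rTRPV1 positions:  ", paste(x$rtrpv1_pos, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read / write a fingerprint definition as JSON
#'
#' The file is a JSON list of 12 objects with keys `allowed` (array of
#' residues), `label`, `align_col`, `rtrpv1_pos`.  A copy of the default
#' definition ships with the package under
#' `system.file("extdata", "fingerprint_gi_trp.json", package = "trpfinger")`.
#'
#' @param path JSON file path.
#' @return [read_fingerprint()]: a `fingerprint_def`.
#' @export
read_fingerprint <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(js) != 12L) stop("fingerprint JSON must contain 12 slots")
  new_fingerprint_def(
    labels = vapply(js, function(s) s$label, character(1)),
    allowed = lapply(js, function(s) unlist(s$allowed)),
    align_col = vapply(js, function(s) as.integer(s$align_col), integer(1)),
    rtrpv1_pos = vapply(js, function(s) as.integer(s$rtrpv1_pos), integer(1))
  )
}

#' @rdname read_fingerprint
#' @param fp A `fingerprint_def`.
#' @export
write_fingerprint <- function(fp, path) {
  js <- lapply(seq_len(12L), function(i) {
    list(label = fp$label[i], allowed = as.list(fp$allowed[[i]]),
         align_col = fp$align_col[i], rtrpv1_pos = fp$rtrpv1_pos[i])
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Score a 12-residue tuple against a fingerprint
#'
#' A slot matches iff the character is in the slot's allowed set; the
#' aromatic-class symbol is accepted as an input character and matches
#' class slots only.  Gaps (`-`) never match.
#'
#' @param residues Character vector of exactly 12 one-letter codes (gap `-`
#'   and the class symbol allowed).
#' @param fp A `fingerprint_def` (default [fingerprint_default()]).
#' @param seq_id Optional identifier carried into the result.
#' @return A `fingerprint_score`: list with `seq_id`, `residues`,
#'   `match_mask` (12 logicals) and `count` (0-12).
#' @export
score_residues <- function(residues, fp = fingerprint_default(),
                           seq_id = NA_character_) {
  residues <- as.character(residues)
  if (length(residues) != 12L) {
    stop("exactly 12 residues required, got ", length(residues))
  }
  is_phi_slot <- vapply(fp$allowed, function(a) setequal(a, phi_class()),
                        logical(1))
  mask <- vapply(seq_len(12L), function(i) {
    r <- residues[i]
    if (r == msa_gap) return(FALSE)
    if (r == phi_symbol()) return(is_phi_slot[i])
    r %in% fp$allowed[[i]]
  }, logical(1))
  structure(list(seq_id = seq_id, residues = residues, match_mask = mask,
                 count = sum(mask)),
            class = "fingerprint_score")
}

#' @export
print.fingerprint_score <- function(x, ...) {
  cat("Fingerprint score", if (!is.na(x$seq_id)) paste0(" [", x$seq_id, "]"),
      ": ", x$count, "/12\n", sep = "")
  cat("  ", paste(x$residues, collapse = " "), "\n", sep = "")
  cat("  ", paste(ifelse(x$match_mask, "+", "."), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Score every sequence of an alignment against a fingerprint
#'
#' Extracts the residue at each fingerprint alignment column and applies
#' [score_residues()].
#'
#' @param msa An [msa] object whose length covers all fingerprint columns.
#' @param fp A `fingerprint_def`.
#' @return data.frame with `seq_id`, `residues` (12-character string) and
#'   `count`; the 12-column logical match matrix is attached as attribute
#'   `"match_mask"`, and per-slot residues as attribute `"slot_residues"`.
#' @export
score_msa <- function(msa, fp = fingerprint_default()) {
  if (max(fp$align_col) > ncol(msa)) {
    stop("fingerprint column ", max(fp$align_col),
         " exceeds alignment length ", ncol(msa))
  }
  m <- unclass(msa)[, fp$align_col, drop = FALSE]
  scores <- lapply(seq_len(nrow(m)), function(i) {
    score_residues(m[i, ], fp, seq_id = rownames(msa)[i])
  })
  out <- data.frame(
    seq_id = rownames(msa),
    residues = apply(m, 1L, paste, collapse = ""),
    count = vapply(scores, function(s) s$count, integer(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "match_mask") <- t(vapply(scores, function(s) s$match_mask,
                                      logical(12)))
  attr(out, "slot_residues") <- m
  rownames(out) <- NULL
  out
}

#' Fingerprint census over a set of scores
#'
#' For k = 0..12, the fraction of sequences with exactly k and with at least
#' k fingerprint matches.
#'
#' @param scores Result of [score_msa()], or an integer vector of counts.
#' @return data.frame: `k`, `n`, `fraction_eq`, `fraction_ge` (non-increasing
#'   in k).
#' @export
fingerprint_census <- function(scores) {
  counts <- if (is.data.frame(scores)) scores$count else as.integer(scores)
  if (length(counts) == 0L) stop("census of an empty score set")
  if (any(counts < 0L | counts > 12L)) stop("counts must lie in 0..12")
  n_k <- tabulate(factor(counts, levels = 0:12), nbins = 13L)
  data.frame(
    k = 0:12,
    n = n_k,
    fraction_eq = n_k / length(counts),
    fraction_ge = rev(cumsum(rev(n_k))) / length(counts)
  )
}
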