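# Shared fixtures and independent oracles for the suite.

# Tiny alignment from explicit rows.
tiny_msa <- function(rows, labels = NULL) {
  trpfinger::msa(rows, seq_ids = paste0("s", seq_along(rows)),
                 labels = labels)
}

# An MSA whose columns are given explicitly (vector of column strings).
msa_from_columns <- function(cols, labels = NULL) {
  n <- nchar(cols[1L])
  rows <- vapply(seq_len(n), function(i) {
    paste(substr(cols, i, i), collapse = "")
  }, character(1))
  tiny_msa(rows, labels = labels)
}

# Brute-force fingerprint scoring oracle: slot-by-slot membership check,
# written independently of score_residues.
oracle_fingerprint_count <- function(residues, fp) {
  n <- 0L
  for (i in 1:12) {
    allowed <- fp$allowed[[i]]
    r <- residues[i]
    is_phi_slot <- length(allowed) == 2L && all(sort(allowed) == c("F", "Y"))
    ok <- if (r == "-") FALSE
      else if (r == "Φ") is_phi_slot
      else any(r == allowed)
    if (ok) n <- n + 1L
  }
  n
}

# Hand-written minimal PDB text: three residues (GLY, ALA, PHE) on chain A.
minimal_pdb_text <- function() {
  c(
    "ATOM      1  N   GLY A  10      0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A  10      1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A  10      2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A  11      3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A  11      4.000   2.800   0.000  1.00  0.00           C",
    "ATOM      6  CB  ALA A  11      4.500   3.200   1.400  1.00  0.00           C",
    "ATOM      7  N   PHE A  12      5.000   3.000  -1.000  1.00  0.00           N",
    "ATOM      8  CA  PHE A  12      6.200   3.700  -0.600  1.00  0.00           C",
    "ATOM      9  CB  PHE A  12      7.100   4.000  -1.800  1.00  0.00           C",
    "ATOM     10  CG  PHE A  12      8.200   4.900  -1.400  1.00  0.00           C",
    "END")
}

write_minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(minimal_pdb_text(), path)
  path
}

# Brute-force connected components via repeated neighbourhood expansion
# (independent of the union-find implementation under test).
oracle_components <- function(nodes, edges) {
  comp <- as.list(nodes)
  names(comp) <- nodes
  assign_of <- stats::setNames(nodes, nodes)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- assign_of[[edges$from[k]]]
      b <- assign_of[[edges$to[k]]]
      if (a != b) {
        assign_of[assign_of == b] <- a
        changed <- TRUE
      }
    }
  }
  unname(lapply(split(nodes, assign_of[nodes]), sort))
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Empirical mutual information between two encoded columns.
column_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  mi
}
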