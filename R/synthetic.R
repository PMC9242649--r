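# Synthetic-data generators with planted ground truth: structured MSAs
# (near-invariant columns, subfamily indel blocks, controllable gap rates),
# Potts-sampled MSAs with planted couplings, and ideal helix-bundle
# coordinate ensembles with inward/outward-pointing side chains.  All
# generators are pure functions of their arguments and seed.

#' Simulate a structured alignment with planted conserved columns
#'
#' Background columns draw i.i.d. from `background`; each planted column
#' carries its designated residue with probability `p` and a background draw
#' otherwise.  A planted aromatic-class column draws from \{F, Y\} with
#' proportions `phi_split`.  Subfamilies may carry indel blocks (columns
#' forced to gap for all members) and an extra uniform gap rate.
#'
#' @param n_seqs Number of sequences.
#' @param length Alignment length.
#' @param conserved Optional data.frame with `column`, `residue` (one-letter
#'   code or the aromatic-class symbol) and `p` (conservation level).
#' @param subfamilies Optional list of lists with fields `label`, `size`,
#'   optional `indel` (list of `c(start, end)` column ranges gapped for the
#'   whole subfamily) and optional `gap_level` (per-position gap rate).
#'   Sizes must sum to `n_seqs`.
#' @param background Probability vector over the 20 residues (default
#'   uniform).
#' @param phi_split Named probabilities for class draws
#'   (default `c(Y = 0.75, F = 0.25)`, mimicking a Tyr-dominated aromatic
#'   column).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List: `msa` (an [msa] with subfamily labels when given) and
#'   `truth` (the planted design: conserved table, subfamily table, indel
#'   blocks).
#' @export
simulate_msa <- function(n_seqs, length, conserved = NULL,
                         subfamilies = NULL,
                         background = rep(1 / 20, 20),
                         phi_split = c(Y = 0.75, F = 0.25), seed = 1L) {
  stopifnot(n_seqs >= 1, length >= 1, abs(sum(background) - 1) < 1e-9)
  if (!is.null(conserved)) {
    if (any(conserved$column < 1L | conserved$column > length)) {
      stop("conserved columns outside 1..", length)
    }
    if (any(conserved$p < 0 | conserved$p > 1)) stop("p must lie in [0, 1]")
    if (anyDuplicated(conserved$column)) stop("duplicate conserved columns")
  }
  if (!is.null(subfamilies)) {
    sizes <- vapply(subfamilies, function(s) s$size, numeric(1))
    if (sum(sizes) != n_seqs) stop("subfamily sizes must sum to n_seqs")
    for (s in subfamilies) {
      for (blk in s$indel) {
        if (blk[1L] < 1L || blk[2L] > length || blk[1L] > blk[2L]) {
          stop("invalid indel block in subfamily ", s$label)
        }
      }
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alpha <- aa_alphabet()
  m <- matrix(sample(alpha, n_seqs * length, replace = TRUE,
                     prob = background), n_seqs, length)
  if (!is.null(conserved)) {
    for (k in seq_len(nrow(conserved))) {
      j <- conserved$column[k]
      hit <- stats::runif(n_seqs) < conserved$p[k]
      res <- conserved$residue[k]
      if (res == phi_symbol()) {
        m[hit, j] <- sample(names(phi_split), sum(hit), replace = TRUE,
                            prob = phi_split)
      } else {
        m[hit, j] <- res
      }
    }
  }
  labels <- NULL
  if (!is.null(subfamilies)) {
    fam <- rep(vapply(subfamilies, function(s) s$label, character(1)),
               times = vapply(subfamilies, function(s) s$size, numeric(1)))
    row0 <- 0L
    for (s in subfamilies) {
      rows <- row0 + seq_len(s$size)
      for (blk in s$indel) m[rows, blk[1L]:blk[2L]] <- "-"
      if (!is.null(s$gap_level) && s$gap_level > 0) {
        drop <- matrix(stats::runif(s$size * length) < s$gap_level,
                       s$size, length)
        # planted indels stay gaps; extra gaps sprinkle everywhere else
        m[rows, ][drop] <- "-"
      }
      row0 <- row0 + s$size
    }
    ids <- paste0("seq", seq_len(n_seqs))
    labels <- stats::setNames(fam, ids)
  }
  rows <- apply(m, 1L, paste, collapse = "")
  out <- msa(rows, seq_ids = paste0("seq", seq_len(n_seqs)), labels = labels)
  truth <- list(conserved = conserved,
                subfamilies = if (is.null(subfamilies)) NULL else
                  data.frame(
                    label = vapply(subfamilies, function(s) s$label,
                                   character(1)),
                    size = vapply(subfamilies, function(s) s$size,
                                  numeric(1))),
                indel_blocks = if (is.null(subfamilies)) NULL else
                  stats::setNames(lapply(subfamilies, function(s) s$indel),
                                  vapply(subfamilies, function(s) s$label,
                                         character(1))),
                seed = seed)
  list(msa = out, truth = truth)
}

# Save/restore the global RNG state so generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct a same-state-favouring coupling block
#' @param q Alphabet size.
#' @param strength Coupling strength placed on the diagonal.
#' @return q x q matrix `strength * diag(q)`.
#' @export
potts_diagonal_block <- function(q, strength) diag(q) * strength

#' Gibbs-sample an alignment from a pairwise Potts model
#'
#' Samples `P(x)` proportional to `exp(sum_i h_i(x_i) + sum_(i<j)
#' J_ij(x_i, x_j))` by single-site Gibbs sweeps from one chain with burn-in
#' and thinning.  States are emitted as the first `q` letters of the
#' amino-acid alphabet (no gaps).
#'
#' @param L Number of columns.
#' @param q Number of states (<= 21).
#' @param couplings data.frame with `i`, `j`, `strength`: each planted pair
#'   gets the block [potts_diagonal_block()] of that strength.
#'   Alternatively a list with `i`, `j`, `block` entries for arbitrary
#'   blocks.
#' @param N Number of sequences to emit.
#' @param h Optional L x q field matrix (default zero).
#' @param burn_in Sweeps discarded before the first sample (default 500).
#' @param thin Sweeps between consecutive samples (default 5).
#' @param seed Integer seed.
#' @return List: `msa` and `truth` (planted pairs, blocks, fields, seed).
#' @export
simulate_potts_msa <- function(L, q, couplings, N, h = NULL,
                               burn_in = 500L, thin = 5L, seed = 1L) {
  stopifnot(L >= 2, q >= 2, q <= 21, N >= 1)
  if (is.data.frame(couplings)) {
    pairs <- lapply(seq_len(nrow(couplings)), function(k) {
      list(i = couplings$i[k], j = couplings$j[k],
           block = potts_diagonal_block(q, couplings$strength[k]))
    })
  } else {
    pairs <- couplings
  }
  for (p in pairs) {
    if (p$i < 1 || p$j < 1 || p$i > L || p$j > L || p$i == p$j) {
      stop("coupling pair out of range: (", p$i, ", ", p$j, ")")
    }
  }
  if (is.null(h)) h <- matrix(0, L, q)
  # neighbour lists: site -> list of (other site, oriented block)
  nb <- vector("list", L)
  for (p in pairs) {
    nb[[p$i]] <- c(nb[[p$i]], list(list(j = p$j, B = p$block)))
    nb[[p$j]] <- c(nb[[p$j]], list(list(j = p$i, B = t(p$block))))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- sample.int(q, L, replace = TRUE)
  sweep_once <- function(x) {
    for (i in seq_len(L)) {
      e <- h[i, ]
      for (nbk in nb[[i]]) e <- e + nbk$B[, x[nbk$j]]
      pr <- exp(e - max(e))
      x[i] <- sample.int(q, 1L, prob = pr)
    }
    x
  }
  for (s in seq_len(burn_in)) x <- sweep_once(x)
  out <- matrix(0L, N, L)
  for (n in seq_len(N)) {
    for (s in seq_len(thin)) x <- sweep_once(x)
    out[n, ] <- x
  }
  letters20 <- aa_alphabet()
  rows <- apply(out, 1L, function(v) paste(letters20[v], collapse = ""))
  truth <- list(pairs = data.frame(
                  i = vapply(pairs, function(p) as.integer(p$i), integer(1)),
                  j = vapply(pairs, function(p) as.integer(p$j), integer(1))),
                blocks = lapply(pairs, function(p) p$block),
                h = h, q = q, seed = seed)
  list(msa = msa(rows, paste0("s", seq_len(N))), truth = truth)
}

# --- helix-bundle coordinate ensembles ------------------------------------

# Ideal alpha-helix CA trace along +z: rise 1.5 A/residue, 100 deg/residue,
# helix radius 2.3 A, centred on the given axis position.
helix_ca_trace <- function(n_res, center_xy, phase = 0, helix_radius = 2.3,
                           rise = 1.5, twist_deg = 100) {
  i <- seq_len(n_res) - 1L
  ang <- phase + i * twist_deg * pi / 180
  cbind(x = center_xy[1L] + helix_radius * cos(ang),
        y = center_xy[2L] + helix_radius * sin(ang),
        z = i * rise)
}

# Hexagonal aromatic ring template: CG plus 5 ring carbons in the plane
# spanned by unit vectors d (outward) and t, bond length 1.4 A.
ring_atoms <- function(cg, d, t) {
  ang <- seq(0, by = pi / 3, length.out = 6)[-1L]
  centre <- cg + 1.4 * d
  xyz <- t(vapply(ang, function(a) {
    centre + 1.4 * (cos(a) * d + sin(a) * t)
  }, numeric(3)))
  rownames(xyz) <- c("CD1", "CD2", "CE1", "CE2", "CZ")
  xyz
}

#' Simulate an ideal helix-bundle structure ensemble
#'
#' Builds `n_helices` parallel ideal alpha-helices on a circle of radius
#' `bundle_radius`, residues mostly alanine (CA + CB), with planted
#' aromatic side chains whose gamma atom points toward (`"in"`) or away
#' from (`"out"`) the bundle axis.  Conformers optionally displace one
#' helix rigidly in steps and add isotropic coordinate noise; a tetramer
#' option replicates the protomer by exact 4-fold rotation into chains
#' A-D.  Helix k residues are numbered `k * 100 + (1..n_res)`.
#'
#' @param n_helices 4 or 6 helices (labelled TM1..TMn).
#' @param n_res Residues per helix (default 18).
#' @param bundle_radius Distance of each helix axis from the bundle axis
#'   (Angstrom, default 8.5).
#' @param aromatics Optional data.frame with `helix` (1-based index),
#'   `pos` (1..n_res), `resname` (PHE/TYR/TRP) and `orientation`
#'   (`"in"`/`"out"`).
#' @param n_conformers Number of ensemble members (default 1).
#' @param moved_helix Optional helix index displaced across conformers.
#' @param move_step Displacement added per conformer index (length-3,
#'   default `c(1, 0, 0)`).
#' @param noise_sd Isotropic coordinate noise per conformer (default 0).
#' @param tetramer Replicate the protomer by 4-fold rotation (chains A-D).
#' @param tetramer_gap Nearest-atom gap aimed for between adjacent
#'   protomers (Angstrom, default 3.5).
#' @param seed Integer seed.
#' @return List: `structures` (list of `structure_model`), `helices`
#'   (label -> residue numbers), and `truth` (facing table with planted
#'   orientations, moved helix, per-conformer displacements, seed).
#' @export
simulate_bundle_ensemble <- function(n_helices = 4L, n_res = 18L,
                                     bundle_radius = 8.5,
                                     aromatics = NULL,
                                     n_conformers = 1L,
                                     moved_helix = NULL,
                                     move_step = c(1, 0, 0),
                                     noise_sd = 0,
                                     tetramer = FALSE,
                                     tetramer_gap = 3.5,
                                     seed = 1L) {
  stopifnot(n_helices %in% c(4L, 6L), n_res >= 4L, n_conformers >= 1L)
  if (!is.null(aromatics)) {
    stopifnot(all(aromatics$helix %in% seq_len(n_helices)),
              all(aromatics$pos %in% seq_len(n_res)),
              all(aromatics$orientation %in% c("in", "out")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  helix_angles <- 2 * pi * (seq_len(n_helices) - 1L) / n_helices
  centers <- cbind(bundle_radius * cos(helix_angles),
                   bundle_radius * sin(helix_angles))
  build_protomer <- function(helix_shift = NULL) {
    atoms <- list()
    for (k in seq_len(n_helices)) {
      ca <- helix_ca_trace(n_res, centers[k, ])
      if (!is.null(helix_shift) && !is.null(moved_helix) &&
          k == moved_helix) {
        ca <- ca + matrix(helix_shift, n_res, 3L, byrow = TRUE)
      }
      for (i in seq_len(n_res)) {
        resno <- k * 100L + i
        p <- ca[i, ]
        arom <- NULL
        if (!is.null(aromatics)) {
          hit <- aromatics$helix == k & aromatics$pos == i
          if (any(hit)) arom <- aromatics[which(hit)[1L], ]
        }
        # side-chain direction: radially away from this helix's own axis,
        # or forced toward/away from the bundle axis for planted residues
        axis_pt <- c(if (!is.null(helix_shift) && !is.null(moved_helix) &&
                         k == moved_helix) {
                       centers[k, ] + helix_shift[1:2]
                     } else centers[k, ], p[3L])
        d_local <- p - axis_pt
        d_local[3L] <- 0
        d_local <- d_local / sqrt(sum(d_local^2))
        if (!is.null(arom)) {
          d_core <- c(-p[1L], -p[2L], 0)
          d_core <- d_core / sqrt(sum(d_core^2))
          d <- if (arom$orientation == "in") d_core else -d_core
          resname <- arom$resname
        } else {
          d <- d_local
          resname <- "ALA"
        }
        cb <- p + 1.5 * d
        rows <- list(c("CA", p), c("CB", cb))
        if (!is.null(arom)) {
          cg <- p + 2.5 * d   # gamma carbon 1 A beyond CB along d
          tvec <- c(0, 0, 1)
          ring <- ring_atoms(cg, d, tvec)
          rows <- c(rows, list(c("CG", cg)),
                    lapply(rownames(ring), function(nm) c(nm, ring[nm, ])))
        }
        for (rw in rows) {
          atoms[[length(atoms) + 1L]] <- data.frame(
            chain = "A", resno = resno, icode = "", resname = resname,
            atom = rw[[1L]][1L],
            altloc = " ",
            x = as.numeric(rw[2L]), y = as.numeric(rw[3L]),
            z = as.numeric(rw[4L]),
            occupancy = 1, element = substr(rw[[1L]][1L], 1L, 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, atoms)
  }
  structures <- vector("list", n_conformers)
  displacements <- matrix(0, n_conformers, 3L)
  for (c_i in seq_len(n_conformers)) {
    shift <- if (is.null(moved_helix)) NULL else move_step * (c_i - 1L)
    if (!is.null(shift)) displacements[c_i, ] <- shift
    at <- build_protomer(shift)
    if (noise_sd > 0) {
      at[c("x", "y", "z")] <- at[c("x", "y", "z")] +
        matrix(stats::rnorm(nrow(at) * 3L, sd = noise_sd), nrow(at), 3L)
    }
    if (tetramer) {
      build_tet <- function(D) {
        prot <- at
        prot$x <- prot$x + D
        chains <- lapply(0:3, function(m_i) {
          ang <- m_i * pi / 2
          rot <- prot
          rot$x <- cos(ang) * prot$x - sin(ang) * prot$y
          rot$y <- sin(ang) * prot$x + cos(ang) * prot$y
          rot$chain <- LETTERS[m_i + 1L]
          rot
        })
        do.call(rbind, chains)
      }
      min_ab <- function(tet) {
        xa <- as.matrix(tet[tet$chain == "A", c("x", "y", "z")])
        xb <- as.matrix(tet[tet$chain == "B", c("x", "y", "z")])
        sqrt(min(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                 2 * xa %*% t(xb)))
      }
      # place protomers so adjacent subunits approach the requested gap
      r_max <- max(sqrt(at$x^2 + at$y^2))
      D <- (2 * r_max + tetramer_gap) / sqrt(2)
      tet <- build_tet(D)
      for (it in 1:6) {
        m0 <- min_ab(tet)
        if (abs(m0 - tetramer_gap) < 0.05) break
        D <- D - (m0 - tetramer_gap) / sqrt(2)
        tet <- build_tet(D)
      }
      at <- tet
    }
    # clash guard on the CA trace
    ca <- at[at$atom == "CA", , drop = FALSE]
    helix_of <- ca$resno %/% 100L
    xyz <- as.matrix(ca[c("x", "y", "z")])
    dd <- as.matrix(stats::dist(xyz))
    other <- outer(paste(ca$chain, helix_of),
                   paste(ca$chain, helix_of), "!=")
    if (min(dd[other]) <= 3) {
      stop("clash check failed: inter-helix CA distance ",
           round(min(dd[other]), 2), " A <= 3 A")
    }
    structures[[c_i]] <- new_structure_model(
      paste0("bundle_conf", c_i), at)
  }
  helices <- stats::setNames(
    lapply(seq_len(n_helices), function(k) k * 100L + seq_len(n_res)),
    paste0("TM", seq_len(n_helices)))
  facing_truth <- if (is.null(aromatics)) NULL else data.frame(
    chain = "A", helix = paste0("TM", aromatics$helix),
    resno = aromatics$helix * 100L + aromatics$pos,
    resname = aromatics$resname, orientation = aromatics$orientation,
    stringsAsFactors = FALSE)
  list(structures = structures, helices = helices,
       truth = list(facing = facing_truth, moved_helix = moved_helix,
                    displacements = displacements, noise_sd = noise_sd,
                    seed = seed))
}

#' Write a `structure_model` as a PDB-format file
#'
#' Emits single-model, single-altloc ATOM records (plus END).
#'
#' @param structure A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    name <- a$atom[i]
    # PDB atom-name column convention: 1-letter elements start in column 14
    name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_fmt, " ", a$resname[i], a$chain[i], a$resno[i],
            ifelse(a$icode[i] == "", " ", a$icode[i]),
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0,
            a$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
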