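# Aromatic-core detection inside the TM1-TM4 helix bundle: the alpha/gamma
# carbon facing rule, minimal all-atom pair distances between facing
# aromatics, single-linkage clustering at a distance threshold, and general /
# pi-pi residue contact detection (optionally across subunits).

# Gamma-position heavy atom per residue type; NA = no gamma (never facing).
gamma_atom_name <- function(resname) {
  map <- c(PHE = "CG", TYR = "CG", TRP = "CG", HIS = "CG", LEU = "CG",
           ARG = "CG", GLN = "CG", GLU = "CG", LYS = "CG", MET = "CG",
           PRO = "CG", ASN = "CG", ASP = "CG",
           ILE = "CG1", VAL = "CG1",
           THR = "OG1", SER = "OG", CYS = "SG")
  unname(map[resname])
}

# Three-letter codes of the aromatic residue set (His configurable off).
aromatic_resnames <- function(include_his = TRUE) {
  c("PHE", "TYR", "TRP", if (include_his) "HIS")
}

res_key <- function(chain, resno) paste(chain, resno, sep = ":")

#' Residues facing the TM1-TM4 core (alpha/gamma carbon rule)
#'
#' For every residue `r` of a helix, the opposing-helix residue `o`
#' minimising the Calpha-Calpha distance is found; `r` faces the core when
#' that distance strictly exceeds the distance from `o`'s Calpha to `r`'s
#' gamma atom, i.e. when the side chain points inward.  Both orderings of
#' each helix pair are evaluated and the union reported.  Residues without a
#' gamma-position atom (Gly, Ala, or truncated side chains) are never facing
#' and are flagged.
#'
#' @param structure A `structure_model`.
#' @param helices Named list mapping helix labels to integer residue-number
#'   vectors on `chain` (e.g. `list(TM1 = 433:460, ...)`).
#' @param chain Chain id of the protomer analysed (default: first chain).
#' @param pairs List of opposing-helix label pairs
#'   (default `list(c("TM1","TM3"), c("TM2","TM4"))`).
#' @return data.frame: `chain`, `resno`, `resname`, `helix`, `opp_helix`,
#'   `opp_resno`, `d_alpha_alpha`, `d_alpha_gamma`, `has_gamma`, `facing`.
#' @export
core_facing_residues <- function(structure, helices, chain = NULL,
                                 pairs = list(c("TM1", "TM3"),
                                              c("TM2", "TM4"))) {
  if (is.null(chain)) chain <- sort(unique(structure$atoms$chain))[1L]
  need <- unique(unlist(pairs))
  if (!all(need %in% names(helices))) {
    stop("missing helix annotation(s): ",
         paste(setdiff(need, names(helices)), collapse = ", "))
  }
  res <- structure_residues(structure, chain)
  ca <- structure$atoms[structure$atoms$chain == chain &
                        structure$atoms$atom == "CA", , drop = FALSE]
  ca_xyz <- function(resno) {
    i <- match(resno, ca$resno)
    if (is.na(i)) c(NA_real_, NA_real_, NA_real_) else
      as.numeric(ca[i, c("x", "y", "z")])
  }
  rows <- list()
  for (pr in pairs) {
    for (ord in list(pr, rev(pr))) {
      ha <- helices[[ord[1L]]]
      hb <- helices[[ord[2L]]]
      hb_ca <- t(vapply(hb, ca_xyz, numeric(3)))
      ok_b <- !is.na(hb_ca[, 1L])
      if (!any(ok_b)) next
      for (r in ha) {
        p_r <- ca_xyz(r)
        if (anyNA(p_r)) next
        dd <- sqrt(colSums((t(hb_ca[ok_b, , drop = FALSE]) - p_r)^2))
        k <- which.min(dd)
        o <- hb[ok_b][k]
        d_aa <- dd[k]
        resname <- res$resname[match(r, res$resno)]
        gname <- gamma_atom_name(resname)
        if (is.na(resname) || is.na(gname)) {
          g <- c(NA_real_, NA_real_, NA_real_)
        } else {
          g <- atom_coord(structure, chain, r, gname)
        }
        has_gamma <- !anyNA(g)
        d_ag <- if (has_gamma) sqrt(sum((ca_xyz(o) - g)^2)) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resno = r, resname = resname,
          helix = ord[1L], opp_helix = ord[2L], opp_resno = o,
          d_alpha_alpha = d_aa, d_alpha_gamma = d_ag,
          has_gamma = has_gamma,
          facing = has_gamma && d_aa > d_ag,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  # union over orderings: a residue is facing if any evaluation says so
  agg <- !duplicated(out$resno)
  facing_any <- tapply(out$facing, out$resno, any)
  keep <- out[agg, , drop = FALSE]
  keep$facing <- as.logical(facing_any[as.character(keep$resno)])
  keep <- keep[order(keep$resno), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

# Heavy atoms of one residue (side-chain only optionally).
residue_heavy_atoms <- function(structure, chain, resno, side_chain_only = FALSE) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno
  a <- a[sel, , drop = FALSE]
  is_h <- a$element %in% c("H", "D") |
    (a$element == "" & grepl("^[0-9]*H", a$atom))
  a <- a[!is_h, , drop = FALSE]
  if (side_chain_only) {
    a <- a[!a$atom %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  }
  as.matrix(a[c("x", "y", "z")])
}

min_atom_distance <- function(xyz_a, xyz_b) {
  if (nrow(xyz_a) == 0L || nrow(xyz_b) == 0L) return(NA_real_)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * (xyz_a %*% t(xyz_b))
  sqrt(max(0, min(d2)))
}

#' Minimal heavy-atom distances between pairs of residues
#'
#' For each unordered pair of the given residues, the minimum distance over
#' all heavy-atom pairs (hydrogens excluded; backbone included by default,
#' per the all-atom convention).
#'
#' @param structure A `structure_model`.
#' @param residues data.frame with `chain` and `resno` columns (e.g. the
#'   facing aromatics).
#' @param side_chain_only Exclude backbone atoms (default `FALSE`).
#' @return data.frame: `key_i`, `key_j` (`chain:resno`), `min_dist`.
#' @export
aromatic_pair_min_distances <- function(structure, residues,
                                        side_chain_only = FALSE) {
  n <- nrow(residues)
  if (n < 2L) {
    return(data.frame(key_i = character(0), key_j = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  }
  xyz <- lapply(seq_len(n), function(i) {
    residue_heavy_atoms(structure, residues$chain[i], residues$resno[i],
                        side_chain_only)
  })
  keys <- res_key(residues$chain, residues$resno)
  idx <- utils::combn(n, 2L)
  data.frame(
    key_i = keys[idx[1L, ]], key_j = keys[idx[2L, ]],
    min_dist = vapply(seq_len(ncol(idx)), function(k) {
      min_atom_distance(xyz[[idx[1L, k]]], xyz[[idx[2L, k]]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Single-linkage clustering of residues at a distance threshold
#'
#' Builds the graph whose edges are residue pairs with minimal distance
#' strictly below `threshold` and returns its connected components
#' (single-linkage clusters).  Residues with no sub-threshold partner are
#' reported as singletons.
#'
#' @param pair_distances data.frame from [aromatic_pair_min_distances()].
#' @param threshold Linkage threshold in Angstrom (default 5.0).
#' @return An `aromatic_clusters` object: list with `clusters` (list of
#'   member-key vectors, largest first), `singletons`, `threshold` and
#'   `pair_distances`.
#' @export
cluster_aromatics <- function(pair_distances, threshold = 5.0) {
  stopifnot(threshold > 0)
  keys <- sort(unique(c(pair_distances$key_i, pair_distances$key_j)))
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- pair_distances[!is.na(pair_distances$min_dist) &
                          pair_distances$min_dist < threshold, , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    ri <- find(match(edges$key_i[k], keys))
    rj <- find(match(edges$key_j[k], keys))
    if (ri != rj) parent[ri] <- rj
  }
  comp <- vapply(seq_along(keys), find, numeric(1))
  groups <- split(keys, comp)
  sizes <- lengths(groups)
  clusters <- groups[sizes > 1L]
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, character(1)))]
  structure(list(clusters = unname(clusters),
                 singletons = sort(unlist(groups[sizes == 1L],
                                          use.names = FALSE)),
                 threshold = threshold,
                 pair_distances = pair_distances),
            class = "aromatic_clusters")
}

#' @export
print.aromatic_clusters <- function(x, ...) {
  cat("Aromatic clusters at < ", x$threshold, " Angstrom: ",
      length(x$clusters), " cluster(s), ", length(x$singletons),
      " singleton(s)\n", sep = "")
  for (i in seq_along(x$clusters)) {
    cat("  [", i, "] n=", length(x$clusters[[i]]), ": ",
        paste(x$clusters[[i]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Full aromatic-core detection for one protomer
#'
#' Convenience pipeline: facing detection on the TM1-TM4 bundle, restriction
#' to aromatic residues, minimal all-atom pair distances, and single-linkage
#' clustering at `threshold`.
#'
#' @inheritParams core_facing_residues
#' @param threshold Cluster linkage threshold (Angstrom, default 5.0).
#' @param include_his Count histidine as aromatic (default `FALSE`; the
#'   core definition uses the Phe/Tyr/Trp set).
#' @return List with `facing` (full facing table), `aromatics` (facing
#'   aromatic residues), `pair_distances`, `clusters`
#'   (an `aromatic_clusters`), and `core_size` (size of the largest cluster,
#'   0 if none).
#' @export
aromatic_core <- function(structure, helices, chain = NULL, threshold = 5.0,
                          include_his = FALSE,
                          pairs = list(c("TM1", "TM3"), c("TM2", "TM4"))) {
  facing <- core_facing_residues(structure, helices, chain, pairs)
  arom <- facing[facing$facing &
                 facing$resname %in% aromatic_resnames(include_his), ,
                 drop = FALSE]
  pd <- aromatic_pair_min_distances(structure, arom)
  cl <- cluster_aromatics(pd, threshold)
  core_size <- if (length(cl$clusters)) length(cl$clusters[[1L]]) else
    as.integer(nrow(arom) > 0L)
  list(facing = facing, aromatics = arom, pair_distances = pd,
       clusters = cl, core_size = core_size)
}

#' Residue contact detection (general 4 A, pi-pi 5 A)
#'
#' Lists residue pairs whose minimal heavy-atom distance is strictly below
#' the general threshold, plus aromatic-aromatic pairs below the (laxer)
#' pi-pi threshold.  With `cross_chain = TRUE` only inter-chain pairs are
#' considered (inter-subunit contacts); otherwise only pairs within each
#' chain.
#'
#' @param structure A `structure_model`.
#' @param threshold_general General contact threshold (Angstrom, default 4).
#' @param threshold_pipi Aromatic-aromatic threshold (default 5).
#' @param cross_chain Detect inter-chain contacts instead of intra-chain.
#' @param include_his Count histidine as aromatic for the pi-pi rule.
#' @param residues Optional data.frame (`chain`, `resno`) restricting the
#'   residues considered.
#' @return data.frame: `chain_i`, `resno_i`, `resname_i`, `chain_j`,
#'   `resno_j`, `resname_j`, `min_dist`, `rule` (`"general"` or `"pipi"`).
#' @export
residue_contacts <- function(structure, threshold_general = 4.0,
                             threshold_pipi = 5.0, cross_chain = FALSE,
                             include_his = FALSE, residues = NULL) {
  stopifnot(threshold_general > 0, threshold_pipi > 0)
  res <- structure_residues(structure)
  if (!is.null(residues)) {
    res <- res[res_key(res$chain, res$resno) %in%
               res_key(residues$chain, residues$resno), , drop = FALSE]
  }
  n <- nrow(res)
  if (n < 2L) return(empty_contacts())
  aromatic <- res$resname %in% aromatic_resnames(include_his)
  # coarse prefilter on CA distance before exact atom-pair minimisation
  ca <- t(vapply(seq_len(n), function(i) {
    atom_coord(structure, res$chain[i], res$resno[i], "CA", res$icode[i])
  }, numeric(3)))
  lim <- max(threshold_general, threshold_pipi) + 12
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_chain <- res$chain[i] == res$chain[j]
      if (cross_chain == same_chain) next
      if (!anyNA(ca[i, ]) && !anyNA(ca[j, ]) &&
          sqrt(sum((ca[i, ] - ca[j, ])^2)) > lim) next
      d <- min_atom_distance(
        residue_heavy_atoms(structure, res$chain[i], res$resno[i]),
        residue_heavy_atoms(structure, res$chain[j], res$resno[j])
      )
      if (is.na(d)) next
      rule <- if (d < threshold_general) "general"
        else if (aromatic[i] && aromatic[j] && d < threshold_pipi) "pipi"
        else NA_character_
      if (is.na(rule)) next
      out[[length(out) + 1L]] <- data.frame(
        chain_i = res$chain[i], resno_i = res$resno[i],
        resname_i = res$resname[i],
        chain_j = res$chain[j], resno_j = res$resno[j],
        resname_j = res$resname[j],
        min_dist = d, rule = rule, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty_contacts())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(chain_i = character(0), resno_i = integer(0),
             resname_i = character(0), chain_j = character(0),
             resno_j = integer(0), resname_j = character(0),
             min_dist = numeric(0), rule = character(0),
             stringsAsFactors = FALSE)
}
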