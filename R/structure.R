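# Structure handling: a minimal fixed-width PDB ATOM reader (no R-side PDB
# parser is available as a dependency), representative side-chain coordinates
# (CB, CA for glycine), alignment-column feature selection, per-structure
# distance matrices and ensemble distogram statistics.

#' Read a PDB-format structure
#'
#' Parses ATOM records of one model into a flat atom table.  HETATM records
#' are excluded; alternate locations are resolved to the highest-occupancy
#' conformer (ties go to altloc `A`).
#'
#' @param path Path to a PDB-format file.
#' @param model 1-based model index to extract (default: first model).
#' @param structure_id Identifier stored with the model (default: file stem).
#' @param regions Optional named list of residue ranges (see [read_regions()]).
#' @return A `structure_model`: list with `structure_id`, `atoms`
#'   (data.frame: chain, resno, icode, resname, atom, altloc, x, y, z,
#'   occupancy, element) and `regions`.
#' @export
read_structure <- function(path, model = 1L, structure_id = NULL,
                           regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_breaks <- which(trimws(rec) == "MODEL")
  if (length(model_breaks) >= 1L) {
    if (model > length(model_breaks)) {
      stop("model ", model, " requested but file has ",
           length(model_breaks), " models")
    }
    start <- model_breaks[model]
    ends <- which(trimws(rec) == "ENDMDL")
    end <- ends[ends > start][1L]
    if (is.na(end)) end <- length(lines)
    lines <- lines[start:end]
    rec <- substr(lines, 1, 6)
  }
  at <- lines[rec == "ATOM  "]
  if (length(at) == 0L) stop("no ATOM records parsed from ", path)
  atoms <- data.frame(
    chain = substr(at, 22, 22),
    resno = as.integer(substr(at, 23, 26)),
    icode = trimws(substr(at, 27, 27)),
    resname = trimws(substr(at, 18, 20)),
    atom = trimws(substr(at, 13, 16)),
    altloc = substr(at, 17, 17),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(at, 55, 60))),
    element = trimws(substr(at, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("unparseable coordinates in ", path)
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # altloc policy: highest occupancy wins; ties resolved toward 'A'/blank
  if (any(atoms$altloc != " ")) {
    pref <- ifelse(atoms$altloc == " ", 0L, match(atoms$altloc, LETTERS))
    ord <- order(-atoms$occupancy, pref)
    atoms <- atoms[ord, , drop = FALSE]
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
    atoms <- atoms[!duplicated(key), , drop = FALSE]
    atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_structure_model(structure_id, atoms, regions)
}

new_structure_model <- function(structure_id, atoms, regions = NULL) {
  structure(list(structure_id = structure_id, atoms = atoms,
                 regions = regions),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(x$atoms[c("chain", "resno", "icode")])
  cat("Structure ", x$structure_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(res), " residues, chains ",
      paste(sort(unique(x$atoms$chain)), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' List the residues of a structure (optionally one chain)
#' @param structure A `structure_model`.
#' @param chain Optional chain id filter.
#' @return data.frame: chain, resno, icode, resname.
#' @export
structure_residues <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  out <- unique(a[c("chain", "resno", "icode", "resname")])
  rownames(out) <- NULL
  out
}

# Coordinate of one named atom of a residue, or c(NA,NA,NA).
atom_coord <- function(structure, chain, resno, atom, icode = "") {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resno == resno & a$icode == icode &
             a$atom == atom)
  if (length(i) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Representative coordinate of a residue (CB; CA for glycine)
#'
#' Returns the beta-carbon coordinate; the alpha carbon for glycine; and the
#' alpha carbon (with a warning) for non-glycine residues whose side chain is
#' truncated.  Residues lacking both atoms yield `NA` coordinates and are
#' masked out of distance matrices.
#'
#' @param structure A `structure_model`.
#' @param chain,resno,icode Residue address.
#' @return Numeric length-3 coordinate (possibly `NA`).
#' @export
representative_coordinate <- function(structure, chain, resno, icode = "") {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno & a$icode == icode
  if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
  resname <- a$resname[sel][1L]
  if (resname == "GLY") return(atom_coord(structure, chain, resno, "CA", icode))
  cb <- atom_coord(structure, chain, resno, "CB", icode)
  if (!anyNA(cb)) return(cb)
  ca <- atom_coord(structure, chain, resno, "CA", icode)
  if (!anyNA(ca)) {
    warning("residue ", chain, resno, " (", resname,
            ") lacks CB; falling back to CA")
  }
  ca
}

#' Select alignment columns by sequence presence
#'
#' Keeps columns whose non-gap fraction strictly exceeds `min_presence`
#' (default 0.96, i.e. tolerating < 4\% gaps), optionally intersected with a
#' knowledge-based region restriction (e.g. the transmembrane helices,
#' linker, pore and TRP-domain helix).
#'
#' @param msa An [msa] object.
#' @param min_presence Presence threshold in (0, 1]; strict inequality.
#' @param region_columns Optional integer vector of admissible columns.
#' @return Ascending integer vector of selected 1-based columns.
#' @export
feature_select_positions <- function(msa, min_presence = 0.96,
                                     region_columns = NULL) {
  stopifnot(min_presence > 0, min_presence <= 1)
  presence <- colMeans(unclass(msa) != msa_gap)
  keep <- which(presence > min_presence)
  if (!is.null(region_columns)) keep <- intersect(keep, region_columns)
  sort(keep)
}

#' Read a sequence-structure residue map sidecar
#'
#' TSV with a header and columns `column` (1-based alignment column),
#' `chain`, `resno` (author residue number).  The map must be injective in
#' both directions over mapped entries.
#'
#' @param path TSV path.
#' @return data.frame of class `seqstruct_map`.
#' @export
read_seqstruct_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  seqstruct_map(df$column, df$chain, df$resno)
}

#' Construct a sequence-structure residue map
#' @param column 1-based alignment columns.
#' @param chain Chain id per entry.
#' @param resno Author residue number per entry.
#' @return data.frame of class `seqstruct_map`.
#' @export
seqstruct_map <- function(column, chain, resno) {
  df <- data.frame(column = as.integer(column), chain = as.character(chain),
                   resno = as.integer(resno), stringsAsFactors = FALSE)
  if (anyDuplicated(df$column)) stop("map not injective: duplicate columns")
  if (anyDuplicated(paste(df$chain, df$resno))) {
    stop("map not injective: duplicate residues")
  }
  structure(df, class = c("seqstruct_map", "data.frame"))
}

#' Pairwise residue distance matrix on alignment positions
#'
#' Euclidean distances between representative coordinates (CB, CA for
#' glycine) of the residues mapped to the requested alignment positions.
#' Unmapped positions, or positions whose residue lacks usable atoms, give
#' fully masked (`NA`) rows/columns.
#'
#' @param structure A `structure_model`.
#' @param map A `seqstruct_map`.
#' @param positions Alignment columns to include (default: all mapped).
#' @return P x P symmetric numeric matrix (Angstrom) with zero diagonal and
#'   `NA` where data are missing; dimnames are the positions.
#' @export
distance_matrix <- function(structure, map, positions = map$column) {
  positions <- as.integer(positions)
  idx <- match(positions, map$column)
  coords <- t(vapply(seq_along(positions), function(k) {
    if (is.na(idx[k])) return(c(NA_real_, NA_real_, NA_real_))
    representative_coordinate(structure, map$chain[idx[k]], map$resno[idx[k]])
  }, numeric(3)))
  d <- as.matrix(stats::dist(coords))
  # dist() silently yields NA rows for NA coords; enforce zero diagonal
  diag(d) <- ifelse(is.na(coords[, 1L]), NA_real_, 0)
  dimnames(d) <- list(positions, positions)
  d
}

#' Ensemble distogram: mean, variance and normalized variance of distances
#'
#' Aggregates per-structure distance matrices elementwise over the ensemble.
#' A cell uses every structure where both positions are present; cells seen
#' in fewer than two structures have masked variance.  The default variance
#' is the population (divide-by-n) variance, treating the ensemble as the
#' object of study; set `sample_variance = TRUE` for divide-by-(n-1).
#' Normalized variance is variance divided by squared mean distance
#' (dimensionless; defined 0 on the diagonal), which removes the bias toward
#' large variances at large separations and highlights variable short-range
#' pairs.
#'
#' @param matrices List of P x P matrices from [distance_matrix()] with
#'   identical position sets.
#' @param sample_variance Use the n-1 denominator (default `FALSE`).
#' @return A `distogram`: list with `positions`, `mean`, `variance`,
#'   `norm_variance`, `n` (per-cell observation counts) and `n_structures`.
#' @export
distogram_stats <- function(matrices, sample_variance = FALSE) {
  if (length(matrices) < 2L) stop("an ensemble needs at least 2 structures")
  dims <- vapply(matrices, function(m) dim(m)[1L], integer(1))
  if (length(unique(dims)) != 1L) stop("inconsistent matrix sizes")
  p <- dims[1L]
  pos <- dimnames(matrices[[1L]])[[1L]]
  arr <- array(unlist(matrices, use.names = FALSE),
               dim = c(p, p, length(matrices)))
  obs <- !is.na(arr)
  n <- apply(obs, c(1, 2), sum)
  s1 <- apply(arr, c(1, 2), function(v) sum(v, na.rm = TRUE))
  mu <- ifelse(n > 0, s1 / n, NA_real_)
  # two-pass variance; constant cells (replicate ensembles) are exactly 0
  dev2 <- sweep(arr, c(1, 2), mu)^2
  ss <- apply(dev2, c(1, 2), function(v) sum(v, na.rm = TRUE))
  v <- ifelse(n > 0, ss / n, NA_real_)
  spread <- apply(arr, c(1, 2), function(vv) {
    vv <- vv[!is.na(vv)]
    if (length(vv)) max(vv) - min(vv) else NA_real_
  })
  v[!is.na(spread) & spread == 0] <- 0
  if (sample_variance) v <- ifelse(n > 1, v * n / (n - 1), NA_real_)
  v[n < 2L] <- NA_real_
  nv <- ifelse(!is.na(mu) & mu > 0, v / mu^2, NA_real_)
  diag(nv) <- ifelse(is.na(diag(mu)), NA_real_, 0)
  dv <- diag(v)
  dv[!is.na(dv)] <- 0
  diag(v) <- dv
  out <- list(positions = if (is.null(pos)) as.character(seq_len(p)) else pos,
              mean = mu, variance = v, norm_variance = nv, n = n,
              n_structures = length(matrices))
  for (nm in c("mean", "variance", "norm_variance", "n")) {
    dimnames(out[[nm]]) <- list(out$positions, out$positions)
  }
  structure(out, class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat("Distogram over ", length(x$positions), " positions, ",
      x$n_structures, " structures\n", sep = "")
  cat("Mean distance range: ",
      paste(round(range(x$mean[upper.tri(x$mean)], na.rm = TRUE), 2),
            collapse = " - "), " Angstrom\n", sep = "")
  invisible(x)
}

#' @export
plot.distogram <- function(x, what = c("mean", "variance", "norm_variance"),
                           ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(seq_along(x$positions), seq_along(x$positions),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  xlab = "position", ylab = "position",
                  main = paste("distogram:", what),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Write distogram matrices as long-format TSV
#' @param x A `distogram`.
#' @param path Output TSV path (`pos_i`, `pos_j`, `mean`, `variance`,
#'   `norm_variance`, `n`).
#' @return `path`, invisibly.
#' @export
write_distogram <- function(x, path) {
  p <- length(x$positions)
  idx <- which(upper.tri(x$mean, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(pos_i = x$positions[idx[, 1L]],
                   pos_j = x$positions[idx[, 2L]],
                   mean = x$mean[idx], variance = x$variance[idx],
                   norm_variance = x$norm_variance[idx], n = x$n[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a named-region configuration (JSON)
#'
#' JSON object mapping region labels (e.g. `"TM1"`) to one `[start, end]`
#' pair or a list of pairs (inclusive ranges of residue numbers or alignment
#' columns).
#'
#' @param path JSON path.
#' @return Named list of two-column integer matrices (start, end).
#' @export
read_regions <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js <- js[!startsWith(names(js), "_")]   # "_comment" and friends
  lapply(js, function(r) {
    m <- matrix(as.integer(unlist(r)), ncol = 2L, byrow = !is.matrix(r))
    if (is.matrix(r)) m <- matrix(as.integer(r), ncol = 2L)
    colnames(m) <- c("start", "end")
    m
  })
}

#' Expand region ranges to a sorted vector of positions
#' @param regions Named list from [read_regions()] (or of numeric
#'   `c(start, end)` pairs).
#' @param which Optional subset of region labels.
#' @return Sorted unique integer positions.
#' @export
regions_to_positions <- function(regions, which = NULL) {
  if (is.null(which)) {
    which <- if (is.null(names(regions))) seq_along(regions) else
      names(regions)
  }
  out <- unlist(lapply(regions[which], function(m) {
    m <- matrix(as.integer(unlist(m)), ncol = 2L)
    unlist(apply(m, 1L, function(r) seq.int(r[1L], r[2L]), simplify = FALSE))
  }), use.names = FALSE)
  sort(unique(out))
}

#' Apply a rigid (or general affine) transform to all coordinates
#' @param structure A `structure_model`.
#' @param rotation 3 x 3 matrix (default identity).
#' @param translation Length-3 vector (default zero).
#' @param scale Scalar multiplier applied after rotation (default 1).
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), scale = 1) {
  xyz <- as.matrix(structure$atoms[c("x", "y", "z")])
  xyz <- scale * (xyz %*% t(rotation)) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  structure$atoms[c("x", "y", "z")] <- xyz
  structure
}
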