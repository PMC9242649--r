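# Asymmetric pseudo-likelihood direct coupling analysis (Potts model) with
# sequence reweighting, per-column L2-regularised conditional fits, coupling
# symmetrisation, and zero-sum-gauge Frobenius scores with average-product
# correction.  The fit is the package's own implementation; scores are
# intended for ranking putatively coevolving column pairs.

#' Default 21-state DCA alphabet (20 residues + gap)
#' @return Character vector of states; the gap `-` is the last state.
#' @export
dca_alphabet <- function() c(aa_alphabet(), "-")

# Integer-encode an MSA over the given state alphabet; unknowns ('X' or any
# character outside the alphabet) are mapped to the gap state.
encode_msa <- function(msa, alphabet = dca_alphabet()) {
  m <- unclass(msa)
  x <- match(m, alphabet)
  gap_state <- match("-", alphabet)
  if (anyNA(x)) {
    if (is.na(gap_state)) stop("alphabet lacks the gap state needed for ",
                               "unknown characters")
    x[is.na(x)] <- gap_state
  }
  matrix(as.integer(x), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Similarity-based sequence weights
#'
#' The weight of a sequence is 1 over the number of sequences (itself
#' included) within fractional Hamming distance `theta` of it; the effective
#' alignment size is `M_eff = sum(weights)`.  With `theta = 0` all weights
#' are 1.
#'
#' @param msa An [msa] object (gaps count as a 21st state).
#' @param theta Distance threshold in \[0, 1) (default 0.1, i.e. sequences
#'   more than 90\% identical share weight).
#' @return Numeric weight vector with attribute `M_eff`.
#' @export
sequence_weights <- function(msa, theta = 0.1) {
  stopifnot(theta >= 0, theta < 1)
  x <- encode_msa(msa)
  n <- nrow(x)
  if (theta == 0 || n == 1L) {
    w <- rep(1, n)
    attr(w, "M_eff") <- n
    return(w)
  }
  L <- ncol(x)
  q <- max(x)
  matches <- matrix(0, n, n)
  for (a in seq_len(q)) {
    ind <- (x == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  similar <- (1 - matches / L) < theta   # fractional Hamming < theta
  w <- 1 / rowSums(similar)
  attr(w, "M_eff") <- sum(w)
  w
}

# Pseudo-likelihood objective and gradient for one column's conditional
# model.  par = c(h (q), J (q x q x (L-1))), J[a, b, j] couples state a at
# the focal column with state b at the j-th other column.
plm_column_objective <- function(par, xr, X_other, w, q, lambda_h, lambda_J,
                                 M_eff) {
  n <- length(xr)
  n_other <- ncol(X_other)
  h <- par[seq_len(q)]
  J <- array(par[-seq_len(q)], dim = c(q, q, n_other))
  E <- matrix(h, n, q, byrow = TRUE)
  for (j in seq_len(n_other)) {
    E <- E + t(J[, X_other[, j], j])
  }
  Emax <- apply(E, 1L, max)
  logZ <- Emax + log(rowSums(exp(E - Emax)))
  nll <- sum(w * (logZ - E[cbind(seq_len(n), xr)])) / M_eff
  nll + lambda_h * sum(h^2) + lambda_J * sum(J^2)
}

plm_column_gradient <- function(par, xr, X_other, w, q, lambda_h, lambda_J,
                                M_eff) {
  n <- length(xr)
  n_other <- ncol(X_other)
  h <- par[seq_len(q)]
  J <- array(par[-seq_len(q)], dim = c(q, q, n_other))
  E <- matrix(h, n, q, byrow = TRUE)
  for (j in seq_len(n_other)) {
    E <- E + t(J[, X_other[, j], j])
  }
  Emax <- apply(E, 1L, max)
  P <- exp(E - Emax)
  P <- P / rowSums(P)
  D <- P
  D[cbind(seq_len(n), xr)] <- D[cbind(seq_len(n), xr)] - 1
  D <- D * (w / M_eff)
  g_h <- colSums(D) + 2 * lambda_h * h
  g_J <- array(0, dim = c(q, q, n_other))
  for (j in seq_len(n_other)) {
    acc <- rowsum(D, group = X_other[, j])
    g_J[, as.integer(rownames(acc)), j] <- t(acc)
  }
  c(g_h, as.numeric(g_J)) + c(numeric(q), 2 * lambda_J * as.numeric(J))
}

#' Fit a Potts sequence model by asymmetric pseudo-likelihood maximisation
#'
#' Each alignment column's conditional distribution given all other columns
#' is fit independently (a multiclass logistic model over the state
#' alphabet) with L2 penalties `lambda_h * ||h||^2 + lambda_J * ||J||^2`;
#' sequence terms are weighted by [sequence_weights()] and the
#' log-pseudo-likelihood is normalised by `M_eff`.  The asymmetric coupling
#' estimates are then symmetrised, `J_ij <- (J_ij + t(J_ji)) / 2`.
#'
#' @param msa An [msa] object.
#' @param lambda_h,lambda_J L2 regularisation weights (default 0.01 each).
#' @param theta Reweighting similarity threshold (default 0.1).
#' @param alphabet State alphabet; default the 21 states of
#'   [dca_alphabet()].  Pass a reduced alphabet for reduced-state data.
#' @param weights Optional precomputed sequence weights.
#' @param maxit Maximum L-BFGS iterations per column (default 500).
#' @param tol Projected-gradient tolerance for convergence (default 1e-5).
#' @param allow_large Override the desk-scale guard refusing L > 400 or
#'   N > 20000.
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @return A `plmdca` model: fields `L`, `q`, `alphabet`, `h` (L x q),
#'   `J` (list of q x q blocks keyed `"i|j"`, i < j), `lambda_h`,
#'   `lambda_J`, `theta`, `weights`, `M_eff` and per-column `diagnostics`
#'   (initial/final objective, convergence code, gradient norm).
#' @seealso [coupling_scores()], [sequence_weights()]
#' @export
plmdca <- function(msa, lambda_h = 0.01, lambda_J = 0.01, theta = 0.1,
                   alphabet = dca_alphabet(), weights = NULL, maxit = 500L,
                   tol = 1e-5, allow_large = FALSE,
                   on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (nrow(msa) < 2L || ncol(msa) < 2L) stop("plmdca needs N >= 2, L >= 2")
  if (!allow_large && (ncol(msa) > 400L || nrow(msa) > 20000L)) {
    stop("alignment exceeds the desk-scale guard (L > 400 or N > 20000); ",
         "pass allow_large = TRUE to override")
  }
  X <- encode_msa(msa, alphabet)
  q <- length(alphabet)
  L <- ncol(X)
  n <- nrow(X)
  if (is.null(weights)) weights <- sequence_weights(msa, theta)
  M_eff <- sum(weights)
  h <- matrix(0, L, q)
  J_asym <- vector("list", L)   # per focal column: q x q x (L-1)
  diag_rows <- vector("list", L)
  for (r in seq_len(L)) {
    others <- setdiff(seq_len(L), r)
    X_other <- X[, others, drop = FALSE]
    xr <- X[, r]
    par0 <- numeric(q + q * q * (L - 1L))
    f0 <- plm_column_objective(par0, xr, X_other, weights, q,
                               lambda_h, lambda_J, M_eff)
    fit <- stats::optim(
      par0, plm_column_objective, plm_column_gradient,
      xr = xr, X_other = X_other, w = weights, q = q,
      lambda_h = lambda_h, lambda_J = lambda_J, M_eff = M_eff,
      method = "L-BFGS-B",
      control = list(maxit = maxit, pgtol = tol, factr = 1e4)
    )
    h[r, ] <- fit$par[seq_len(q)]
    J_asym[[r]] <- array(fit$par[-seq_len(q)], dim = c(q, q, L - 1L))
    gnorm <- sqrt(sum(plm_column_gradient(fit$par, xr, X_other, weights, q,
                                          lambda_h, lambda_J, M_eff)^2))
    diag_rows[[r]] <- data.frame(column = r, initial = f0, final = fit$value,
                                 convergence = fit$convergence,
                                 grad_norm = gnorm)
  }
  diagnostics <- do.call(rbind, diag_rows)
  bad <- diagnostics$column[diagnostics$convergence != 0]
  if (length(bad)) {
    msg <- paste0("plmdca did not converge for column(s) ",
                  paste(bad, collapse = ", "), " within ", maxit,
                  " iterations (max |grad| norm ",
                  signif(max(diagnostics$grad_norm[bad]), 3), ")")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  # symmetrise: J_ij[a, b] couples state a at i with state b at j
  J <- list()
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      Jij_from_i <- J_asym[[i]][, , j - 1L]       # j's index among i's others
      Jji_from_j <- J_asym[[j]][, , i]            # i's index among j's others
      J[[paste(i, j, sep = "|")]] <- (Jij_from_i + t(Jji_from_j)) / 2
    }
  }
  structure(list(L = L, q = q, alphabet = alphabet, h = h, J = J,
                 lambda_h = lambda_h, lambda_J = lambda_J, theta = theta,
                 weights = as.numeric(weights), M_eff = M_eff,
                 diagnostics = diagnostics, call = match.call()),
            class = "plmdca")
}

#' @export
print.plmdca <- function(x, ...) {
  cat("Pseudo-likelihood DCA model\n")
  cat("  L = ", x$L, " columns, q = ", x$q, " states, M_eff = ",
      round(x$M_eff, 1), " (of ", length(x$weights), " sequences)\n",
      sep = "")
  cat("  lambda_h = ", x$lambda_h, ", lambda_J = ", x$lambda_J,
      ", theta = ", x$theta, "\n", sep = "")
  invisible(x)
}

#' @export
summary.plmdca <- function(object, ...) {
  sc <- coupling_scores(object)
  top <- utils::head(sc$pairs, 10L)
  out <- list(model = object, top_pairs = top,
              converged = all(object$diagnostics$convergence == 0))
  class(out) <- "summary.plmdca"
  out
}

#' @export
print.summary.plmdca <- function(x, ...) {
  print(x$model)
  cat("  all columns converged: ", x$converged, "\n", sep = "")
  cat("Top coupled pairs (APC-corrected):\n")
  print(x$top_pairs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.plmdca <- function(object, ...) {
  list(h = object$h, J = object$J)
}

#' @export
plot.plmdca <- function(x, ...) {
  sc <- coupling_scores(x)
  m <- sc$apc
  graphics::image(seq_len(x$L), seq_len(x$L),
                  t(m[rev(seq_len(x$L)), , drop = FALSE]),
                  xlab = "column", ylab = "column",
                  main = "APC-corrected coupling scores",
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE), ...)
  invisible(x)
}

# q x q coupling block of a fitted model for columns i < j.
coupling_block <- function(model, i, j) {
  if (i == j) return(matrix(0, model$q, model$q))
  if (i < j) model$J[[paste(i, j, sep = "|")]] else
    t(model$J[[paste(j, i, sep = "|")]])
}

# Zero-sum (Ising) gauge of a q x q block.
zero_sum_block <- function(B) {
  B - outer(rowMeans(B), rep(1, ncol(B))) -
    outer(rep(1, nrow(B)), colMeans(B)) + mean(B)
}

#' Average-product correction of a symmetric score matrix
#'
#' Subtracts the separable background `rowmean_i * rowmean_j / grandmean`
#' from each entry (means taken over full rows/columns).  A rank-one matrix
#' maps exactly to zero.
#'
#' @param F Symmetric numeric matrix.
#' @return Corrected matrix of the same shape.
#' @export
apc_correction <- function(F) {
  g <- mean(F)
  if (g == 0) return(F)
  F - outer(rowMeans(F), colMeans(F)) / g
}

#' Coupling scores of a fitted DCA model
#'
#' For each column pair, the Frobenius norm of the coupling block after
#' restriction to non-gap states and shift to the zero-sum gauge, followed
#' by the average-product correction.
#'
#' @param model A fitted `plmdca` model.
#' @param exclude_gap Drop the gap state from the block before scoring
#'   (default `TRUE`).
#' @param apc Apply the average-product correction (default `TRUE`).
#' @return A `coupling_scores` object: list with `frobenius` (L x L),
#'   `apc` (L x L; equals `frobenius` if `apc = FALSE`) and `pairs`
#'   (data.frame `i`, `j`, `frobenius`, `apc_score`, ranked by `apc_score`
#'   descending).
#' @export
coupling_scores <- function(model, exclude_gap = TRUE, apc = TRUE) {
  L <- model$L
  keep <- if (exclude_gap) which(model$alphabet != "-") else
    seq_len(model$q)
  Fm <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- coupling_block(model, i, j)[keep, keep, drop = FALSE]
      B <- zero_sum_block(B)
      Fm[i, j] <- Fm[j, i] <- sqrt(sum(B^2))
    }
  }
  S <- if (apc) apc_correction(Fm) else Fm
  diag(S) <- 0
  idx <- which(upper.tri(Fm), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1L], j = idx[, 2L],
                      frobenius = Fm[idx], apc_score = S[idx])
  pairs <- pairs[order(-pairs$apc_score), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(frobenius = Fm, apc = S, pairs = pairs),
            class = "coupling_scores")
}

#' @export
print.coupling_scores <- function(x, ...) {
  cat("Coupling scores over ", nrow(x$frobenius), " columns; top pairs:\n",
      sep = "")
  print(utils::head(x$pairs, 10L), row.names = FALSE)
  invisible(x)
}

#' Write coupling scores as long-format TSV (i, j, frobenius, apc_score)
#' @param x A `coupling_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_scores <- function(x, path) {
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
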