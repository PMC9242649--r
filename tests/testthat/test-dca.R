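test_that("sequence reweighting counts similarity neighbourhoods", {
  # all-distinct sequences get weight 1
  m <- tiny_msa(c("ACDEFGHIKL", "WWWWWWWWWW", "YYYYYYYYYY"))
  w <- sequence_weights(m, theta = 0.1)
  expect_equal(as.numeric(w), c(1, 1, 1))
  expect_equal(attr(w, "M_eff"), 3)
  # two identical, one distant: weights (1/2, 1/2, 1), M_eff = 2
  m2 <- tiny_msa(c("ACDEFGHIKL", "ACDEFGHIKL", "WWWWWWWWWW"))
  w2 <- sequence_weights(m2, theta = 0.1)
  expect_equal(as.numeric(w2), c(0.5, 0.5, 1))
  expect_equal(attr(w2, "M_eff"), 2)
  # k-fold duplication leaves M_eff unchanged
  rows <- c("ACDEFGHIKL", "LKIHGFEDCA", "WWWWWWWWWW")
  m3 <- tiny_msa(rows)
  m3x <- msa(rep(rows, 3), seq_ids = paste0("s", 1:9))
  expect_equal(attr(sequence_weights(m3, 0.2), "M_eff"),
               attr(sequence_weights(m3x, 0.2), "M_eff"))
  # theta = 0 disables reweighting
  expect_equal(as.numeric(sequence_weights(m2, 0)), rep(1, 3))
})

test_that("two perfectly covarying columns dominate the coupling scores", {
  set.seed(3)
  n <- 240
  s <- sample(c("A", "C", "D", "E"), n, replace = TRUE)
  noise <- function() sample(c("A", "C", "D", "E"), n, replace = TRUE)
  rows <- paste0(noise(), s, noise(), noise(), s, noise())
  m <- msa(rows, paste0("q", seq_len(n)))
  fit <- plmdca(m, alphabet = c("A", "C", "D", "E"), theta = 0)
  sc <- coupling_scores(fit)
  expect_equal(sort(unlist(sc$pairs[1, c("i", "j")])), c(i = 2, j = 5),
               ignore_attr = TRUE)
  # clear margin over the best background pair
  expect_gt(sc$pairs$apc_score[1], 2 * sc$pairs$apc_score[2])
})

test_that("uniform i.i.d. columns yield no coupling above a permutation null", {
  set.seed(8)
  n <- 300; L <- 8
  q4 <- c("A", "C", "D", "E")
  base <- matrix(sample(q4, n * L, replace = TRUE), n, L)
  m <- msa(apply(base, 1, paste, collapse = ""), paste0("r", 1:n))
  fit <- plmdca(m, alphabet = q4, theta = 0)
  max_obs <- max(coupling_scores(fit)$pairs$apc_score)
  # permutation null: independently shuffle each column, refit
  nulls <- vapply(1:3, function(k) {
    shuf <- apply(base, 2, sample)
    mN <- msa(apply(shuf, 1, paste, collapse = ""), paste0("r", 1:n))
    max(coupling_scores(plmdca(mN, alphabet = q4, theta = 0))$pairs$apc_score)
  }, numeric(1))
  expect_lt(max_obs, 3 * max(nulls))
})

test_that("pseudo-likelihood optimisation decreases the objective", {
  set.seed(5)
  sim <- simulate_potts_msa(L = 6, q = 4,
                            couplings = data.frame(i = 1, j = 4,
                                                   strength = 2),
                            N = 150, seed = 5)
  fit <- plmdca(sim$msa, alphabet = aa_alphabet()[1:4])
  d <- fit$diagnostics
  expect_true(all(d$final <= d$initial))
  expect_true(all(d$convergence == 0))
  # symmetrised couplings: block (i,j) is the transpose of block (j,i)
  B12 <- trpfinger:::coupling_block(fit, 1, 2)
  B21 <- trpfinger:::coupling_block(fit, 2, 1)
  expect_equal(B12, t(B21))
})

test_that("desk-scale guard and degenerate inputs are refused", {
  wide <- msa(rep(paste(rep("A", 401), collapse = ""), 2),
              seq_ids = c("a", "b"))
  expect_error(plmdca(wide), "desk-scale guard")
  expect_error(plmdca(msa("AC")), "N >= 2")
})

test_that("APC maps rank-one matrices to zero and scores stay symmetric", {
  set.seed(11)
  u <- stats::runif(9, 0.5, 2)
  F1 <- outer(u, u)
  expect_equal(apc_correction(F1), matrix(0, 9, 9), tolerance = 1e-12)
  # zero couplings give zero scores
  zero_model <- structure(list(
    L = 4, q = 3, alphabet = c("A", "C", "-"),
    h = matrix(0, 4, 3),
    J = stats::setNames(
      lapply(1:6, function(i) matrix(0, 3, 3)),
      apply(utils::combn(4, 2), 2, paste, collapse = "|")),
    lambda_h = 0.01, lambda_J = 0.01, theta = 0.1,
    weights = rep(1, 5), M_eff = 5), class = "plmdca")
  sc0 <- coupling_scores(zero_model)
  expect_true(all(sc0$frobenius == 0))
  expect_true(all(sc0$apc == 0))
  # symmetry and zero diagonal on a fitted model
  sim <- simulate_potts_msa(L = 5, q = 3,
                            couplings = data.frame(i = 2, j = 4,
                                                   strength = 1.5),
                            N = 120, seed = 2)
  sc <- coupling_scores(plmdca(sim$msa, alphabet = aa_alphabet()[1:3]))
  expect_equal(sc$apc, t(sc$apc))
  expect_equal(unname(diag(sc$apc)), rep(0, 5))
  expect_true(all(is.finite(sc$apc)))
})

test_that("scores are invariant under gauge shifts of the couplings", {
  sim <- simulate_potts_msa(L = 5, q = 4,
                            couplings = data.frame(i = 1, j = 3,
                                                   strength = 2),
                            N = 150, seed = 6)
  fit <- plmdca(sim$msa, alphabet = aa_alphabet()[1:4])
  sc <- coupling_scores(fit, exclude_gap = FALSE)
  # add arbitrary row/column patterns phi_i(a) + psi_j(b) to each block:
  # a pure gauge change that must not move the reported scores
  set.seed(14)
  fit2 <- fit
  for (k in names(fit2$J)) {
    q <- fit2$q
    fit2$J[[k]] <- fit2$J[[k]] +
      outer(stats::rnorm(q), rep(1, q)) + outer(rep(1, q), stats::rnorm(q))
  }
  sc2 <- coupling_scores(fit2, exclude_gap = FALSE)
  expect_equal(sc2$apc, sc$apc, tolerance = 1e-6)
})

test_that("column permutation permutes the score matrix identically", {
  sim <- simulate_potts_msa(L = 6, q = 3,
                            couplings = data.frame(i = 2, j = 5,
                                                   strength = 2),
                            N = 150, seed = 4)
  alpha3 <- aa_alphabet()[1:3]
  sc <- coupling_scores(plmdca(sim$msa, alphabet = alpha3, theta = 0))
  perm <- c(3, 1, 6, 2, 5, 4)
  m_perm <- msa(apply(unclass(sim$msa)[, perm], 1, paste, collapse = ""),
                rownames(sim$msa))
  sc_p <- coupling_scores(plmdca(m_perm, alphabet = alpha3, theta = 0))
  expect_equal(sc_p$apc, sc$apc[perm, perm], tolerance = 1e-4)
})

test_that("coupling recovery improves with sample size", {
  couplings <- data.frame(i = c(2, 5, 9), j = c(7, 11, 12), strength = 0.8)
  rank_cor <- vapply(c(150, 1200), function(N) {
    sim <- simulate_potts_msa(L = 12, q = 4, couplings = couplings, N = N,
                              seed = 20)
    sc <- coupling_scores(plmdca(sim$msa, alphabet = aa_alphabet()[1:4],
                                 theta = 0))
    truth <- rep(0, nrow(sc$pairs))
    key <- paste(sc$pairs$i, sc$pairs$j)
    truth[key %in% paste(couplings$i, couplings$j)] <- 1
    stats::cor(truth, sc$pairs$apc_score, method = "spearman")
  }, numeric(1))
  expect_true(all(rank_cor > 0))
  expect_gt(rank_cor[2], rank_cor[1])
})
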