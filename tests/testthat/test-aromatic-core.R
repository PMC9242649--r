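planted_bundle <- function(seed = 4) {
  simulate_bundle_ensemble(
    n_helices = 4, n_res = 14,
    aromatics = data.frame(
      helix = c(1, 1, 2, 3, 3, 4), pos = c(4, 8, 6, 5, 9, 7),
      resname = c("PHE", "TYR", "TRP", "PHE", "PHE", "TYR"),
      orientation = c("in", "in", "in", "out", "in", "out")),
    seed = seed)
}

test_that("facing detection recovers planted orientations exactly", {
  b <- planted_bundle()
  st <- b$structures[[1L]]
  facing <- core_facing_residues(st, b$helices)
  truth <- b$truth$facing
  planted_in <- truth$resno[truth$orientation == "in"]
  detected <- facing$resno[facing$facing &
                           facing$resname %in% c("PHE", "TYR", "TRP")]
  # precision = recall = 1 on the planted set
  expect_setequal(detected, planted_in)
  # the facing relation is exactly d_alpha_alpha > d_alpha_gamma
  ok <- facing$has_gamma
  expect_equal(facing$facing[ok],
               facing$d_alpha_alpha[ok] > facing$d_alpha_gamma[ok])
  # residues without a gamma atom (here Ala background) are never facing
  expect_false(any(facing$facing[!facing$has_gamma]))
  expect_error(core_facing_residues(st, b$helices["TM1"]), "missing helix")
})

test_that("facing classification is rigid-motion invariant", {
  b <- planted_bundle()
  st <- b$structures[[1L]]
  f0 <- core_facing_residues(st, b$helices)
  set.seed(6)
  st2 <- transform_structure(st, rotation = random_rotation(),
                             translation = stats::rnorm(3, sd = 30))
  f1 <- core_facing_residues(st2, b$helices)
  expect_equal(f1$facing, f0$facing)
  expect_equal(f1$d_alpha_alpha, f0$d_alpha_alpha, tolerance = 1e-9)
  expect_equal(f1$d_alpha_gamma, f0$d_alpha_gamma, tolerance = 1e-9)
})

test_that("minimal pair distances are true minima over heavy atoms", {
  b <- planted_bundle()
  st <- b$structures[[1L]]
  arom <- structure_residues(st)
  arom <- arom[arom$resname %in% c("PHE", "TYR", "TRP"), ]
  pd <- aromatic_pair_min_distances(st, arom)
  expect_equal(nrow(pd), choose(nrow(arom), 2))
  # min distance never exceeds the CB-CB distance of the same pair
  for (k in seq_len(nrow(pd))) {
    pi_ <- strsplit(pd$key_i[k], ":")[[1]]
    pj_ <- strsplit(pd$key_j[k], ":")[[1]]
    cb_i <- trpfinger:::atom_coord(st, pi_[1], as.integer(pi_[2]), "CB")
    cb_j <- trpfinger:::atom_coord(st, pj_[1], as.integer(pj_[2]), "CB")
    expect_lte(pd$min_dist[k], sqrt(sum((cb_i - cb_j)^2)) + 1e-12)
  }
  # constructed pair with closest atoms at exactly 4.2 A
  at <- data.frame(chain = "A", resno = c(1L, 1L, 2L, 2L), icode = "",
                   resname = "PHE",
                   atom = c("CA", "CG", "CA", "CG"), altloc = " ",
                   x = c(0, 1, 10, 5.2), y = 0, z = 0, occupancy = 1,
                   element = "C", stringsAsFactors = FALSE)
  st_pair <- trpfinger:::new_structure_model("pair", at)
  pd2 <- aromatic_pair_min_distances(
    st_pair, data.frame(chain = "A", resno = c(1L, 2L)))
  expect_equal(pd2$min_dist, 4.2, tolerance = 1e-9)
})

test_that("single-linkage clustering equals a connected-components oracle", {
  # the worked triangle: A-B 4.0, B-C 4.5, A-C 9.0 -> one cluster
  pd <- data.frame(key_i = c("A:1", "A:2", "A:1"),
                   key_j = c("A:2", "A:3", "A:3"),
                   min_dist = c(4.0, 4.5, 9.0), stringsAsFactors = FALSE)
  cl <- cluster_aromatics(pd, threshold = 5.0)
  expect_equal(length(cl$clusters), 1L)
  expect_setequal(cl$clusters[[1L]], c("A:1", "A:2", "A:3"))
  # all pairs at or above threshold: no multi-residue cluster
  cl2 <- cluster_aromatics(transform(pd, min_dist = c(5.0, 6, 9)), 5.0)
  expect_equal(length(cl2$clusters), 0L)
  expect_setequal(cl2$singletons, c("A:1", "A:2", "A:3"))

  # randomized graphs against the brute-force oracle
  set.seed(123)
  for (trial in 1:1000) {
    n <- sample(3:10, 1)
    keys <- paste0("A:", seq_len(n))
    idx <- utils::combn(n, 2)
    pd_r <- data.frame(key_i = keys[idx[1, ]], key_j = keys[idx[2, ]],
                       min_dist = stats::runif(ncol(idx), 0, 10),
                       stringsAsFactors = FALSE)
    thr <- stats::runif(1, 2, 8)
    cl_r <- cluster_aromatics(pd_r, thr)
    got <- c(lapply(cl_r$clusters, sort),
             as.list(cl_r$singletons))
    edges <- pd_r[pd_r$min_dist < thr, ]
    want <- oracle_components(keys, data.frame(from = edges$key_i,
                                               to = edges$key_j))
    canon <- function(l) {
      l <- lapply(l, sort)
      l[order(vapply(l, `[`, character(1), 1L))]
    }
    expect_identical(canon(got), canon(want))
  }
})

test_that("raising the cluster threshold never splits a cluster", {
  set.seed(77)
  n <- 12
  keys <- paste0("A:", 1:n)
  idx <- utils::combn(n, 2)
  pd <- data.frame(key_i = keys[idx[1, ]], key_j = keys[idx[2, ]],
                   min_dist = stats::runif(ncol(idx), 0, 10),
                   stringsAsFactors = FALSE)
  thresholds <- c(2, 4, 6, 8)
  prev <- NULL
  for (thr in thresholds) {
    cl <- cluster_aromatics(pd, thr)
    groups <- c(cl$clusters, as.list(cl$singletons))
    if (!is.null(prev)) {
      # each earlier cluster is contained in one current cluster
      for (g in prev) {
        containing <- vapply(groups, function(h) all(g %in% h), logical(1))
        expect_equal(sum(containing), 1L)
      }
    }
    prev <- groups
  }
})

test_that("clustering is invariant to pair enumeration order", {
  set.seed(42)
  n <- 9
  keys <- paste0("A:", 1:n)
  idx <- utils::combn(n, 2)
  pd <- data.frame(key_i = keys[idx[1, ]], key_j = keys[idx[2, ]],
                   min_dist = stats::runif(ncol(idx), 0, 10),
                   stringsAsFactors = FALSE)
  cl1 <- cluster_aromatics(pd, 5)
  cl2 <- cluster_aromatics(pd[sample(nrow(pd)), ], 5)
  canon <- function(cl) {
    l <- lapply(cl$clusters, sort)
    l[order(vapply(l, `[`, character(1), 1L))]
  }
  expect_identical(canon(cl1), canon(cl2))
})

test_that("aromatic_core pipeline groups inward aromatics", {
  # plant a tight inward aromatic set on neighbouring rungs of TM1/TM2
  b <- simulate_bundle_ensemble(
    n_helices = 4, n_res = 14,
    aromatics = data.frame(
      helix = c(1, 1, 2, 2), pos = c(7, 8, 7, 8),
      resname = c("PHE", "TYR", "PHE", "TRP"),
      orientation = "in"),
    seed = 10)
  ac <- aromatic_core(b$structures[[1L]], b$helices)
  expect_equal(nrow(ac$aromatics), 4L)
  expect_gte(ac$core_size, 2L)
})

test_that("contact rules bracket thresholds and respect chain selection", {
  # two aromatic residues with minimal distance 4.6 A
  at <- data.frame(chain = "A", resno = c(1L, 2L), icode = "",
                   resname = c("PHE", "TYR"), atom = "CG", altloc = " ",
                   x = c(0, 4.6), y = 0, z = 0, occupancy = 1,
                   element = "C", stringsAsFactors = FALSE)
  at <- rbind(at, within(at, { atom <- "CA"; x <- x + c(-1, 1) }))
  st <- trpfinger:::new_structure_model("pair", at)
  ct <- residue_contacts(st)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$rule, "pipi")
  expect_equal(ct$min_dist, 4.6, tolerance = 1e-9)
  # a non-aromatic pair at 4.6 A is not a contact
  st_nonarom <- st
  st_nonarom$atoms$resname <- "LEU"
  expect_equal(nrow(residue_contacts(st_nonarom)), 0L)
  # at 3.5 A the general rule fires
  st_close <- st
  st_close$atoms$x[st_close$atoms$atom == "CG"] <- c(0, 3.5)
  expect_equal(residue_contacts(st_close)$rule, "general")
  # cross-chain mode reports only inter-chain pairs
  expect_equal(nrow(residue_contacts(st, cross_chain = TRUE)), 0L)
})

test_that("4-fold symmetric tetramer yields contacts in orbits of 4", {
  b <- simulate_bundle_ensemble(
    n_helices = 4, n_res = 10,
    aromatics = data.frame(helix = 1, pos = 5, resname = "PHE",
                           orientation = "out"),
    tetramer = TRUE, tetramer_gap = 3.0, seed = 12)
  st <- b$structures[[1L]]
  ct <- residue_contacts(st, cross_chain = TRUE, threshold_general = 4.5)
  expect_gt(nrow(ct), 0L)
  # group by residue pair irrespective of which chains carry it
  sig <- paste(pmin(ct$resno_i, ct$resno_j), pmax(ct$resno_i, ct$resno_j))
  expect_true(all(table(sig) %% 4 == 0))
  expect_equal(nrow(ct) %% 4, 0)
})
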