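test_that("PDB parsing: atoms, altloc policy, model selection", {
  path <- write_minimal_pdb()
  st <- read_structure(path)
  res <- structure_residues(st)
  expect_equal(nrow(res), 3L)
  expect_equal(res$resname, c("GLY", "ALA", "PHE"))
  expect_equal(st$atoms$x[st$atoms$atom == "CA" & st$atoms$resno == 10], 1.458)

  # altloc: keep the highest-occupancy conformer, ties -> A
  alt <- c(
    "ATOM      1  CA AALA A   1      0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1      9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1      1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1      8.000   0.000   0.000  0.50  0.00           C",
    "END")
  p2 <- tempfile(fileext = ".pdb")
  writeLines(alt, p2)
  st2 <- read_structure(p2)
  expect_equal(nrow(st2$atoms), 2L)
  expect_equal(st2$atoms$x[st2$atoms$atom == "CA"], 9.000)  # occupancy wins
  expect_equal(st2$atoms$x[st2$atoms$atom == "CB"], 1.000)  # tie -> altloc A

  # HETATM excluded; missing file and empty models are errors
  expect_error(read_structure(tempfile()), "no such file")
  p3 <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1      0.0     0.0     0.0", "END"),
             p3)
  expect_error(read_structure(p3), "no ATOM records")
})

test_that("synthetic bundle writer round-trips through the reader", {
  b <- simulate_bundle_ensemble(
    n_helices = 4, n_res = 10,
    aromatics = data.frame(helix = 1, pos = 5, resname = "TYR",
                           orientation = "in"),
    seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_pdb(b$structures[[1L]], path)
  st <- read_structure(path)
  a0 <- b$structures[[1L]]$atoms
  a1 <- st$atoms
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$atom, a0$atom)
  expect_equal(a1$x, a0$x, tolerance = 1e-3)  # PDB fixed precision
  expect_equal(a1$z, a0$z, tolerance = 1e-3)
})

test_that("representative coordinates: CB, CA for glycine, CA fallback", {
  st <- read_structure(write_minimal_pdb())
  # glycine -> CA
  expect_equal(representative_coordinate(st, "A", 10), c(1.458, 0, 0))
  # alanine with CB -> CB
  expect_equal(representative_coordinate(st, "A", 11), c(4.5, 3.2, 1.4))
  # truncated side chain (drop PHE's CB/CG) -> CA with a warning
  st2 <- st
  st2$atoms <- st2$atoms[!(st2$atoms$resno == 12 &
                           st2$atoms$atom %in% c("CB", "CG")), ]
  expect_warning(xyz <- representative_coordinate(st2, "A", 12), "CB")
  expect_equal(xyz, c(6.2, 3.7, -0.6))
})

test_that("feature selection by presence is strict and region-aware", {
  gapless <- tiny_msa(c("ACDEF", "ACDEF"))
  expect_equal(feature_select_positions(gapless), 1:5)
  # a column with presence exactly at the threshold is excluded
  cols <- c(paste(rep("A", 100), collapse = ""),
            paste(c(rep("A", 96), rep("-", 4)), collapse = ""),
            paste(c(rep("A", 97), rep("-", 3)), collapse = ""))
  m <- msa_from_columns(cols)
  expect_equal(feature_select_positions(m, min_presence = 0.96), c(1L, 3L))
  expect_equal(feature_select_positions(m, 0.96, region_columns = 3:9), 3L)
  # engineered selection count from the generator ground truth
  sim <- simulate_msa(
    n_seqs = 200, length = 80,
    subfamilies = list(list(label = "A", size = 20,
                            indel = list(c(61, 80)), gap_level = 0),
                       list(label = "B", size = 180, indel = list(),
                            gap_level = 0)),
    seed = 17)
  expect_equal(length(feature_select_positions(sim$msa, 0.96)), 60L)
})

test_that("distance matrices: 3-4-5 check, masking, rigid invariance", {
  b <- simulate_bundle_ensemble(n_helices = 4, n_res = 8, seed = 5)
  st <- b$structures[[1L]]
  # hand-placed two-residue check
  at <- data.frame(chain = "A", resno = c(1L, 2L), icode = "",
                   resname = "ALA", atom = "CB", altloc = " ",
                   x = c(0, 3), y = c(0, 4), z = c(0, 0), occupancy = 1,
                   element = "C", stringsAsFactors = FALSE)
  st345 <- st
  st345$atoms <- at
  map <- seqstruct_map(column = c(10L, 20L), chain = "A", resno = c(1L, 2L))
  d <- distance_matrix(st345, map)
  expect_equal(d["10", "20"], 5.0)
  expect_equal(diag(d), c(`10` = 0, `20` = 0))

  # unmapped position is fully masked
  d2 <- distance_matrix(st345, map, positions = c(10L, 20L, 30L))
  expect_true(all(is.na(d2["30", ])))
  expect_true(all(is.na(d2[, "30"])))

  # rigid motion leaves distances unchanged to 1e-9
  res <- structure_residues(st)
  map_full <- seqstruct_map(seq_len(nrow(res)), res$chain, res$resno)
  d_ref <- distance_matrix(st, map_full)
  set.seed(2)
  for (k in 1:5) {
    st_t <- transform_structure(st, rotation = random_rotation(),
                                translation = stats::rnorm(3, sd = 20))
    expect_equal(distance_matrix(st_t, map_full), d_ref, tolerance = 1e-9)
  }
})

test_that("distogram statistics match a brute-force oracle", {
  set.seed(13)
  p <- 6; n_st <- 5
  mats <- lapply(seq_len(n_st), function(s) {
    xyz <- matrix(stats::rnorm(p * 3, sd = 8), p)
    d <- as.matrix(stats::dist(xyz))
    if (s <= 2) d[1, 2] <- d[2, 1] <- NA  # missing cell in two structures
    dimnames(d) <- list(1:p, 1:p)
    d
  })
  dg <- distogram_stats(mats)
  # brute-force per-cell loop
  for (i in 1:p) for (j in 1:p) {
    v <- vapply(mats, function(m) m[i, j], numeric(1))
    v <- v[!is.na(v)]
    expect_equal(dg$n[i, j], length(v))
    expect_equal(dg$mean[i, j], mean(v), tolerance = 1e-12)
    expect_equal(dg$variance[i, j], mean((v - mean(v))^2), tolerance = 1e-12)
    if (i != j) {
      expect_equal(dg$norm_variance[i, j],
                   mean((v - mean(v))^2) / mean(v)^2, tolerance = 1e-12)
    }
  }
  # symmetry, zero diagonal, non-negative variance
  expect_equal(dg$mean, t(dg$mean))
  expect_equal(unname(diag(dg$mean)), rep(0, p))
  expect_true(all(dg$variance >= 0))
  # the {4, 6} hand case: mean 5, variance 1, normalized variance 0.04
  m46 <- lapply(c(4, 6), function(v) {
    m <- matrix(c(0, v, v, 0), 2)
    dimnames(m) <- list(1:2, 1:2)
    m
  })
  dg46 <- distogram_stats(m46)
  expect_equal(dg46$mean[1, 2], 5)
  expect_equal(dg46$variance[1, 2], 1)
  expect_equal(dg46$norm_variance[1, 2], 0.04)
  # sample-variance flag uses n-1
  expect_equal(distogram_stats(m46, sample_variance = TRUE)$variance[1, 2], 2)
})

test_that("replicate ensembles have zero variance; scaling leaves norm_variance", {
  b <- simulate_bundle_ensemble(n_helices = 4, n_res = 8, n_conformers = 3,
                                noise_sd = 0, seed = 9)
  res <- structure_residues(b$structures[[1L]])
  map <- seqstruct_map(seq_len(nrow(res)), res$chain, res$resno)
  mats <- lapply(b$structures, distance_matrix, map = map)
  dg <- distogram_stats(mats)
  expect_true(all(dg$variance == 0))

  # a moving helix among static ones: cross cells dominate norm_variance
  bm <- simulate_bundle_ensemble(n_helices = 4, n_res = 8, n_conformers = 4,
                                 moved_helix = 3, move_step = c(1.5, 0, 0),
                                 seed = 9)
  mats_m <- lapply(bm$structures, distance_matrix, map = map)
  dg_m <- distogram_stats(mats_m)
  helix_of <- res$resno %/% 100L
  static <- helix_of != 3
  within_static <- dg_m$norm_variance[static, static]
  cross <- dg_m$norm_variance[static, !static]
  expect_lt(max(within_static), 1e-12)
  expect_gt(min(cross), max(within_static))
  mx <- which(dg_m$norm_variance == max(dg_m$norm_variance),
              arr.ind = TRUE)[1, ]
  expect_true(any(!static[mx]))  # the extreme cell involves the moved helix

  # scale invariance of normalized variance
  mats_s <- lapply(bm$structures, function(s) {
    distance_matrix(transform_structure(s, scale = 2.7), map = map)
  })
  dg_s <- distogram_stats(mats_s)
  expect_equal(dg_s$norm_variance, dg_m$norm_variance, tolerance = 1e-9)
  expect_error(distogram_stats(mats_m[1]), "at least 2")
})
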