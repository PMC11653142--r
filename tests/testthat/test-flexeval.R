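test_that("superposition recovers rigid-motion copies exactly", {
  ref <- withr::with_seed(1, matrix(rnorm(30, sd = 4), 10, 3))
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- ref %*% R + matrix(c(4, -7, 2), 10, 3, byrow = TRUE)
  tr <- trajectory_from_frames(list(ref, moved))
  sup <- kabsch_superpose(tr, ref)
  expect_lt(sqrt(mean(rowSums((frame_coords(sup, 2) - ref)^2))), 1e-8)
  # an already-aligned frame is left unchanged
  expect_lt(max(abs(frame_coords(sup, 1) - ref)), 1e-10)
  # collinear reference is rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(trajectory_from_frames(list(line)), line),
               class = "degenerate_input")
})

test_that("mirror images are fit with proper rotations only", {
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0, 0, 4))
  mirror <- P %*% diag(c(-1, 1, 1))
  tr <- trajectory_from_frames(list(mirror))
  sup <- kabsch_superpose(tr, P)
  Pc <- sweep(P, 2, colMeans(P))
  Mc <- sweep(mirror, 2, colMeans(mirror))
  U <- flexrestrain:::kabsch_rotation(Mc, Pc)
  expect_equal(det(U), 1, tolerance = 1e-10)
  rmsd <- sqrt(mean(rowSums((frame_coords(sup, 1) - P)^2)))
  expect_gt(rmsd, 0.1)  # a mirror image cannot be matched by rotation
  # exhaustive rotation-grid oracle: the SVD fit is at least as good
  oracle <- grid_best_rmsd(Mc, Pc, step_deg = 10)
  expect_lte(rmsd, oracle + 1e-9)
})

test_that("RMSF follows its definition and matches a brute-force reference", {
  # identical frames: all zeros
  fr <- straight_chain(5)
  same <- trajectory_from_frames(list(fr, fr, fr))
  expect_equal(compute_rmsf(same, superpose = FALSE)$values, rep(0, 5))
  # two frames, residue displaced +/- 1 A in x: RMSF exactly 1
  a <- straight_chain(5); b <- straight_chain(5)
  a[3, 1] <- a[3, 1] + 1; b[3, 1] <- b[3, 1] - 1
  p <- compute_rmsf(trajectory_from_frames(list(a, b)), superpose = FALSE)
  expect_equal(p$values[3], 1.0)
  expect_error(compute_rmsf(trajectory_from_frames(list(a))),
               class = "too_few_frames")
  # random small ensembles match the per-coordinate loop reference exactly
  withr::with_seed(7, {
    for (rep in 1:5) {
      arr <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
      tr <- flexrestrain:::new_trajectory(arr)
      expect_equal(compute_rmsf(tr, superpose = FALSE)$values,
                   brute_force_rmsf(arr), tolerance = 1e-12)
    }
  })
})

test_that("isotropic Gaussian displacements give the sigma*sqrt(3) law", {
  s <- structure_from_coords(straight_chain(20), plddt = 90, ss = "COIL")
  tr <- make_planted_trajectory(s, sigma = 0.5 * sqrt(3), n_frames = 10000,
                                seed = 123)
  p <- compute_rmsf(tr, superpose = FALSE)
  expect_lt(max(abs(p$values - 0.866)) / 0.866, 0.02)
})

test_that("RMSF is invariant under rigid motion when superposition is on", {
  s <- helix_coil_helix(seed = 11)
  base <- make_planted_trajectory(s, planted_sigma(s), n_frames = 60, seed = 5)
  p0 <- compute_rmsf(base, superpose = TRUE)
  moved <- base
  withr::with_seed(9, for (f in seq_len(n_frames(base))) {
    R <- flexrestrain:::kabsch_rotation(matrix(rnorm(9), 3), diag(3))
    moved$coords[f, , ] <- frame_coords(base, f) %*% R +
      matrix(rnorm(3, sd = 8), dim(base$coords)[2], 3, byrow = TRUE)
  })
  p1 <- compute_rmsf(moved, superpose = TRUE)
  expect_equal(p1$values, p0$values, tolerance = 1e-8)
})

test_that("pearson_r matches the textbook formula and its invariances", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 100)
  expect_equal(pearson_r(a, b), textbook_pearson(a, b), tolerance = 1e-12)
  x <- withr::with_seed(2, runif(25)); y <- withr::with_seed(3, runif(25))
  expect_equal(pearson_r(x, y), textbook_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x + 10), -1.0)
  # invariant under positive affine rescaling
  expect_equal(pearson_r(2.5 * x + 1, y), pearson_r(x, y), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 25)), class = "constant_profile")
  expect_error(pearson_r(x, y[1:10]), class = "length_mismatch")
  expect_equal(pearson_r(x, y, method = "spearman"),
               cor(x, y, method = "spearman"))
})

test_that("best-of-replicas takes the maximum and never drops when refs grow", {
  pred <- c(1, 3, 2, 5, 4, 6)
  refs <- list(c(6, 5, 4, 3, 2, 1), c(1, 2, 3, 4, 5, 7), pred)
  ev <- best_replica_correlation(pred, refs)
  expect_equal(length(ev$per_replica_r), 3L)
  expect_equal(ev$best_r, max(ev$per_replica_r))
  expect_equal(ev$best_r, 1.0)
  expect_equal(ev$mean_pred_rmsf, mean(pred))
  one <- best_replica_correlation(pred, refs[1])
  expect_equal(one$best_r, one$per_replica_r[1])
  expect_gte(best_replica_correlation(pred, refs)$best_r,
             best_replica_correlation(pred, refs[1:2])$best_r)
  expect_error(best_replica_correlation(pred, list(c(1, 2, 3))),
               class = "length_mismatch")
})

test_that("paired comparison handles identical, constant-shift and normal cases", {
  rs <- c(0.4, 0.5, 0.6, 0.7, 0.55)
  same <- paired_comparison(rs, rs)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shift <- paired_comparison(rs + 0.1, rs)
  expect_lt(shift$p_value, 0.05)
  # ordinary case agrees with stats::t.test
  a <- withr::with_seed(4, rnorm(8)); b <- withr::with_seed(5, rnorm(8))
  got <- paired_comparison(a, b)
  want <- t.test(a, b, paired = TRUE)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)
  expect_error(paired_comparison(a, b[1:3]), class = "length_mismatch")
})

test_that("RMSF profile text round-trips", {
  s <- helix_coil_helix(seed = 12)
  p <- compute_rmsf(make_planted_trajectory(s, planted_sigma(s), 50, seed = 1))
  back <- read_rmsf_profile(write_rmsf_profile(p))
  expect_equal(back$values, round(p$values, 4), tolerance = 1e-9)
  expect_error(read_rmsf_profile("1 0.5\n2 -0.2"), class = "range_error")
})
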