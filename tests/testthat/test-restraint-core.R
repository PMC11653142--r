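test_that("category assignment follows base-plus-confidence-bump with clamping", {
  expect_equal(assign_category("COIL", 40), 0L)    # base 0, bump -1, clamped
  expect_equal(assign_category("HELIX", 95), 3L)   # base 2, bump +1
  expect_equal(assign_category("TURN", 60), 1L)    # base 1, no bump
  expect_equal(assign_category("SHEET", 45), 1L)   # base 2, bump -1
  expect_equal(assign_category("COIL", 90), 1L)    # cutoff inclusive at 90
  expect_equal(assign_category("TURN", 50), 1L)    # 50 is not below the low cutoff
  expect_error(assign_category("HELIX", NA_real_), class = "missing_score")
  expect_error(assign_category("HELIX", 130), class = "range_error")

  # monotone in pLDDT for each fixed class
  for (ss in c("HELIX", "SHEET", "TURN", "COIL")) {
    cats <- assign_category(rep(ss, 201), seq(0, 100, by = 0.5))
    expect_true(all(diff(cats) >= 0))
  }
})

test_that("pair strength is the symmetric category-matrix lookup", {
  expect_equal(pair_strength(0L, 3L), 0.0)
  expect_equal(pair_strength(2L, 3L), 1.0)
  expect_equal(pair_strength(1L, 2L), 0.5)
  expect_equal(pair_strength(1L, 1L), 0.5)
  grid <- expand.grid(a = 0:3, b = 0:3)
  expect_equal(pair_strength(grid$a, grid$b), pair_strength(grid$b, grid$a))
  expect_error(pair_strength(0L, 1L, matrix(runif(16), 4)), class = "spec_error")
})

test_that("mode weight rules match their definitions on hand-built pairs", {
  # two residues 7.2 A apart, 10 apart in sequence, helix/helix
  xyz <- rbind(straight_chain(10, 0.5), c(0, 7.2, 4.5))
  mk <- function(pl) {
    s <- structure_from_coords(xyz, plddt = pl, ss = "HELIX")
    s$residues$x[2:10] <- 1000 + 10 * (2:10)  # park intermediates far away
    s
  }
  gen <- function(s, mode) generate_restraints(s, restraint_config(mode = mode))
  s <- mk(c(80, rep(70, 9), 60))
  r_min <- gen(s, "min")$restraints
  expect_equal(nrow(r_min), 1L)
  expect_equal(r_min$weight, 0.60)            # min(80, 60)/100
  expect_equal(r_min$d0, sqrt(7.2^2 + 4.5^2))
  expect_equal(r_min$slope_min, 0.60 * 3.5)
  expect_equal(r_min$slope_max, 0.60 * 0.5)
  expect_equal(gen(s, "max")$restraints$weight, 0.80)
  expect_equal(gen(s, "mean")$restraints$weight, 0.70)

  # the 0.5 floor drops a low-confidence pair in min mode
  low <- mk(c(45, rep(70, 9), 90))
  expect_equal(nrow(gen(low, "min")$restraints), 0L)
  expect_equal(gen(low, "max")$restraints$weight, 0.90)
  # a weight exactly at the floor is kept ("below 0.5" is strict)
  at_floor <- mk(c(50, rep(70, 9), 90))
  expect_equal(gen(at_floor, "min")$restraints$weight, 0.50)

  # plddt1 needs one score above 50, plddt2 needs both (strictly)
  p <- mk(c(49, rep(70, 9), 90))
  expect_equal(nrow(gen(p, "plddt2")$restraints), 0L)
  expect_equal(nrow(gen(p, "plddt1")$restraints), 1L)
  edge <- mk(c(50, rep(70, 9), 90))
  expect_equal(nrow(gen(edge, "plddt2")$restraints), 0L)  # 50 is not > 50
})

test_that("SS2 restrains within regular structure but not across to coil", {
  # residues 0-9 helix, 10-19 coil, geometry compact enough for contacts
  th <- 100 * pi / 180; t <- 0:19
  xyz <- cbind(2.3 * cos(th * t), 2.3 * sin(th * t), 1.5 * t)
  s <- structure_from_coords(xyz, plddt = 90,
                             ss = rep(c("HELIX", "COIL"), each = 10))
  rs <- generate_restraints(s, restraint_config(mode = "ss2"))$restraints
  expect_true(any(rs$i == 2 & rs$j == 7))
  expect_false(any(rs$i == 2 & rs$j == 14))
  expect_false(any(rs$i >= 10))  # no coil-coil pairs either
})

test_that("the sequence-gap rule excludes close pairs", {
  s <- structure_from_coords(straight_chain(8, 2.0), plddt = 90, ss = "HELIX")
  for (mode in c("all", "ss2", "min", "category")) {
    rs <- generate_restraints(s, restraint_config(mode = mode))$restraints
    expect_true(all(rs$j - rs$i >= 3), info = mode)
    expect_true(any(rs$j - rs$i == 3), info = mode)  # >= is inclusive
  }
})

test_that("generated sets match the brute-force oracle on random toys", {
  for (seed in 1:12) {
    s <- random_toy(seed)
    for (mode in c("ss2", "ss1", "all", "min", "max", "mean",
                   "plddt1", "plddt2", "category")) {
      cfg <- restraint_config(mode = mode)
      got <- generate_restraints(s, cfg)$restraints
      want <- brute_force_restraints(s, cfg)
      expect_equal(nrow(got), nrow(want), info = paste(seed, mode))
      if (nrow(want)) {
        expect_identical(got$i, want$i, info = paste(seed, mode))
        expect_identical(got$j, want$j, info = paste(seed, mode))
        expect_equal(got$d0, want$d0, info = paste(seed, mode))
        expect_equal(got$weight, want$weight, info = paste(seed, mode))
      }
    }
  }
})

test_that("mode subset laws hold as pair sets", {
  for (seed in 13:18) {
    s <- random_toy(seed)
    key <- function(mode) pair_key(
      generate_restraints(s, restraint_config(mode = mode))$restraints)
    expect_true(all(key("ss2") %in% key("ss1")))
    expect_true(all(key("ss1") %in% key("all")))
    expect_true(all(key("plddt2") %in% key("plddt1")))
    expect_true(all(key("plddt1") %in% key("all")))
  }
})

test_that("raising one residue's pLDDT never weakens its restraints", {
  s0 <- random_toy(21)
  n <- n_residues(s0)
  withr::with_seed(99, {
    for (rep in 1:60) {
      k <- sample.int(n, 1)
      s1 <- s0
      bump <- runif(1, 0, 100 - s1$residues$plddt[k])
      s1$residues$plddt[k] <- s1$residues$plddt[k] + bump
      expect_gte(assign_category(s1$residues$ss[k], s1$residues$plddt[k]),
                 assign_category(s0$residues$ss[k], s0$residues$plddt[k]))
      for (mode in c("min", "max", "mean")) {
        cfg <- restraint_config(mode = mode, plddt_strength_floor = 0)
        r0 <- generate_restraints(s0, cfg)$restraints
        r1 <- generate_restraints(s1, cfg)$restraints
        m <- match(pair_key(r0), pair_key(r1))
        expect_false(anyNA(m))
        expect_true(all(r1$weight[m] - r0$weight >= -1e-12))
      }
      for (mode in c("plddt1", "plddt2")) {
        cfg <- restraint_config(mode = mode)
        k0 <- pair_key(generate_restraints(s0, cfg)$restraints)
        k1 <- pair_key(generate_restraints(s1, cfg)$restraints)
        expect_true(all(k0 %in% k1))
      }
    }
  })
})

test_that("the flat-bottom energy is zero inside, linear outside, continuous", {
  e <- function(d) restraint_energy(d, d0 = 7, slope_min = 3.5, slope_max = 0.5)
  expect_equal(e(7), 0)
  expect_equal(e(8), 0)                       # boundary of the flat bottom
  expect_equal(e(6), 0)
  expect_equal(e(7 + 2.5), 0.5 * 1.5)         # max_force side
  expect_equal(e(7 - 2.0), 3.5 * 1.0)         # min_force side
  # continuity at both kinks
  eps <- 1e-10
  expect_lt(abs(e(8 + eps) - e(8 - eps)), 1e-9)
  expect_lt(abs(e(6 - eps) - e(6 + eps)), 1e-9)
  # non-negative and non-decreasing in |d - d0| outside the flat bottom
  d <- seq(0.5, 20, by = 0.01)
  v <- e(d)
  expect_true(all(v >= 0))
  expect_true(all(diff(v[d > 8]) >= 0))
  expect_true(all(diff(v[d < 6]) <= 0))
  # weight scaling enters through the slopes
  expect_equal(restraint_energy(9.5, 7, 0.5 * 3.5, 0.5 * 0.5), 0.5 * 0.75)
  # quadratic variant agrees at the kink and grows faster beyond it
  eq <- function(d) restraint_energy(d, 7, 3.5, 0.5, shape = "quadratic")
  expect_equal(eq(8), 0)
  expect_equal(eq(9.5), 0.5 * 1.5^2)
})

test_that("total restraint energy is zero on the input and additive", {
  s <- helix_coil_helix(seed = 3)
  set <- generate_restraints(s)
  xyz <- ca_coords(s)
  expect_identical(total_restraint_energy(xyz, set), 0)
  expect_gt(total_restraint_energy(xyz * 1.5, set), 0)
  # additivity over a partition of the set
  half <- set; rest <- set
  n <- n_restraints(set)
  half$restraints <- set$restraints[seq_len(floor(n / 2)), ]
  rest$restraints <- set$restraints[seq(floor(n / 2) + 1, n), ]
  probe <- xyz + withr::with_seed(4, matrix(rnorm(length(xyz), sd = 1.2), nrow(xyz)))
  expect_equal(total_restraint_energy(probe, set),
               total_restraint_energy(probe, half) +
                 total_restraint_energy(probe, rest))
  expect_error(total_restraint_energy(xyz[1:3, ], set), class = "index_error")
})

test_that("every emitted restraint respects the distance and gap filters", {
  for (seed in 31:40) {
    s <- random_toy(seed)
    cfg <- restraint_config(mode = "all",
                            max_distance = runif(1, 6, 14),
                            min_seq_gap = sample(1:5, 1))
    rs <- generate_restraints(s, cfg)$restraints
    if (!nrow(rs)) next
    expect_true(all(rs$d0 <= cfg$max_distance))
    expect_true(all(rs$j - rs$i >= cfg$min_seq_gap))
    xyz <- ca_coords(s, drop_missing = FALSE)
    d <- sqrt(rowSums((xyz[rs$i + 1, , drop = FALSE] -
                         xyz[rs$j + 1, , drop = FALSE])^2))
    expect_equal(rs$d0, d)
  }
})

test_that("subsampling removes the exact count, deterministically, in order", {
  s <- structure_from_coords(straight_chain(60, 1.1), plddt = 90, ss = "HELIX")
  set <- generate_restraints(s, restraint_config(mode = "all", max_distance = 20,
                                                 min_seq_gap = 5))
  expect_gte(n_restraints(set), 100)
  base <- set
  base$restraints <- base$restraints[1:100, ]
  thinned <- subsample_restraints(base, 0.05, seed = 11)
  expect_equal(n_restraints(thinned), 95L)
  expect_identical(subsample_restraints(base, 0.05, seed = 11), thinned)
  expect_false(identical(subsample_restraints(base, 0.05, seed = 12), thinned))
  # survivors keep their relative order
  keys <- pair_key(thinned$restraints)
  expect_identical(keys, pair_key(base$restraints)[pair_key(base$restraints) %in% keys])
  expect_identical(subsample_restraints(base, 0), base)
  expect_equal(n_restraints(subsample_restraints(base, 1)), 0L)
})

test_that("restraint files round-trip and report malformed lines", {
  s <- helix_coil_helix(seed = 5)
  set <- generate_restraints(s)
  txt <- write_restraints(set)
  back <- read_restraints(txt, structure = s, config = set$config)
  expect_equal(back$restraints$i, set$restraints$i)
  expect_equal(back$restraints$j, set$restraints$j)
  expect_equal(back$restraints$d0, set$restraints$d0, tolerance = 1e-3)
  expect_equal(back$restraints$weight, set$restraints$weight, tolerance = 1e-3)
  expect_identical(back$restraints$chain_i, set$restraints$chain_i)
  expect_identical(back$restraints$res_i, set$restraints$res_i)

  one <- read_restraints("A:12 A:40 9.135 1.000")
  expect_equal(n_restraints(one), 1L)
  expect_equal(one$restraints$d0, 9.135)
  expect_equal(one$restraints$res_j, 40L)
  err <- tryCatch(read_restraints("A:12 A:40 9.1 1.0\nA:12 A:40 abc 1.0"),
                  error = function(e) e)
  expect_s3_class(err, "malformed_input")
  expect_match(conditionMessage(err), "line 2")
})

test_that("identical inputs give byte-identical restraint files", {
  for (seed in c(2, 9)) {
    a <- write_restraints(generate_restraints(helix_coil_helix(seed),
                                              restraint_config(drop_fraction = 0.05)))
    b <- write_restraints(generate_restraints(helix_coil_helix(seed),
                                              restraint_config(drop_fraction = 0.05)))
    expect_identical(a, b)
  }
})
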