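test_that("site_pi matches its closed form and handles edge cases", {
  expect_equal(site_pi(2, 4), 2 / 3, tolerance = 1e-12)
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_true(is.na(site_pi(1, 1)))
})

test_that("windows tile chromosomes per spec and carry member-site ranges", {
  gm <- make_gm(matrix(0:2, 3, 6), pos = c(10L, 40L, 60L, 90L, 120L, 150L),
                chrom_lengths = c(chr1 = 150L))
  w <- make_windows(gm, window_spec(size = 50L, step = 20L))
  expect_equal(w$start, seq(1L, 150L, by = 20L))
  expect_equal(w$end, pmin(w$start + 49L, 150L))
  # membership: window [1,50] holds sites at 10, 40; [21,70] holds 40, 60
  expect_equal(w$i2[1] - w$i1[1] + 1L, 2L)
  expect_equal(w$i2[2] - w$i1[2] + 1L, 2L)
})

test_that("window_pi equals the brute-force pairwise-difference oracle", {
  set.seed(67)
  calls <- matrix(sample(c(0:2, NA), 50, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 5, 10)
  pos <- sort(sample(1:50000, 10))
  gm <- make_gm(calls, pos = pos, chrom_lengths = c(chr1 = 50000L))
  spec <- window_spec(size = 50000L, step = 50000L)
  got <- window_pi(gm, 1:5, spec)
  want <- oracle_window_pi(calls, pos, 1, 50000, 50000)
  expect_equal(got$pi[1], want, tolerance = 1e-12)
  # arithmetic example: one singleton among 4 alleles has pi_site = 0.5,
  # so a 50 kb window holding only that site gives 1e-5 per bp scaled
  calls3 <- matrix(c(1L, 0L), 2, 1)
  gm3 <- make_gm(calls3, pos = 100L, chrom_lengths = c(chr1 = 50000L))
  w3 <- window_pi(gm3, 1:2, window_spec(50000L, 50000L))
  expect_equal(w3$pi[1], 0.5 / 50000, tolerance = 1e-15)
  # no segregating sites -> 0
  gm0 <- make_gm(matrix(0L, 3, 2), pos = c(10L, 20L),
                 chrom_lengths = c(chr1 = 1000L))
  expect_equal(window_pi(gm0, 1:3, window_spec(1000L, 1000L))$pi, 0)
})

test_that("weir_fst matches hand-computed components and the scalar oracle", {
  # fixed difference, equal n, no heterozygotes: a = 0.5, b = c = 0
  gm <- make_gm(rbind(matrix(2L, 4, 1), matrix(0L, 4, 1)),
                chrom_lengths = c(chr1 = 1000L))
  res <- weir_fst(gm, 1:4, 5:8, window_spec(1000L, 1000L))
  expect_equal(res$site$a, 0.5, tolerance = 1e-12)
  expect_equal(res$site$b, 0, tolerance = 1e-12)
  expect_equal(res$site$c, 0, tolerance = 1e-12)
  expect_identical(res$site$theta, 1)
  expect_identical(res$windows$fst[1], 1)
  # random fixtures against the straight-from-formula scalar oracle
  set.seed(71)
  for (rep in 1:10) {
    calls <- matrix(sample(c(0:2, NA), 20 * 12, replace = TRUE,
                           prob = c(.3, .3, .3, .1)), 12, 20)
    gmr <- make_gm(calls)
    resr <- weir_fst(gmr, 1:6, 7:12)
    for (j in sample(20, 5)) {
      want <- oracle_wc_from_calls(calls[1:6, , drop = FALSE],
                                   calls[7:12, , drop = FALSE], j)
      expect_equal(resr$site$a[j], unname(want["a"]), tolerance = 1e-12)
      expect_equal(resr$site$b[j], unname(want["b"]), tolerance = 1e-12)
      expect_equal(resr$site$c[j], unname(want["c"]), tolerance = 1e-12)
    }
  }
})

test_that("theta is non-positive when cohorts match in frequency and heterozygosity", {
  # both cohorts: same p and same observed het -> s2 = 0 forces a <= 0
  block <- rbind(c(0L, 1L), c(1L, 2L), c(2L, 0L))
  gm <- make_gm(rbind(block, block))
  res <- weir_fst(gm, 1:3, 4:6)
  expect_true(all(res$site$theta <= 1e-12, na.rm = TRUE))
})

test_that("windowed theta on one duplicated population stays near zero", {
  set.seed(73)
  p <- runif(1000, 0.1, 0.9)
  calls <- t(replicate(20, hwe_ind(p)))
  gm <- make_gm(calls, pos = seq_len(1000L) * 10L,
                chrom_lengths = c(chr1 = 10000L))
  res <- weir_fst(gm, 1:10, 11:20, window_spec(10000L, 10000L))
  expect_lte(abs(res$windows$fst[1]), 0.05)
})

test_that("theta is label-symmetric and delta statistics antisymmetric", {
  set.seed(79)
  calls <- matrix(sample(0:2, 12 * 30, replace = TRUE), 12, 30)
  gm <- make_gm(calls, chrom_lengths = c(chr1 = 3100L))
  ab <- weir_fst(gm, 1:6, 7:12)
  ba <- weir_fst(gm, 7:12, 1:6)
  expect_equal(ab$site$theta, ba$site$theta, tolerance = 1e-12)
  spec <- window_spec(3100L, 3100L)
  d_ab <- window_pi(gm, 1:6, spec)$pi - window_pi(gm, 7:12, spec)$pi
  d_ba <- window_pi(gm, 7:12, spec)$pi - window_pi(gm, 1:6, spec)$pi
  expect_equal(d_ab, -d_ba, tolerance = 1e-15)
})

test_that("tajimas_d matches the straight-formula oracle", {
  set.seed(83)
  for (rep in 1:10) {
    n_ind <- sample(3:8, 1)
    calls <- matrix(sample(0:2, n_ind * 15, replace = TRUE), n_ind, 15)
    pos <- sort(sample(1:2000, 15))
    gm <- make_gm(calls, pos = pos, chrom_lengths = c(chr1 = 2000L))
    got <- tajimas_d(gm, seq_len(n_ind), window_spec(2000L, 2000L))
    want <- oracle_tajd(colSums(calls), 2L * n_ind)
    expect_equal(got$tajd[1], want, tolerance = 1e-12)
  }
})

test_that("tajimas_d is zero when pi_hat equals S/a1 and negative for all-singletons", {
  # n = 4 alleles: 8 singletons + 3 doubletons give pi_hat == S/a1 exactly
  singleton <- c(1L, 0L)
  doubleton <- c(1L, 1L)
  calls <- cbind(matrix(rep(singleton, 8), nrow = 2),
                 matrix(rep(doubleton, 3), nrow = 2))
  gm <- make_gm(calls, pos = seq_len(11L) * 10L,
                chrom_lengths = c(chr1 = 200L))
  got <- tajimas_d(gm, 1:2, window_spec(200L, 200L))
  expect_equal(got$tajd[1], 0, tolerance = 1e-12)
  # all singletons: excess of rare variants, D < 0
  calls2 <- matrix(rep(c(1L, 0L, 0L, 0L), 12), nrow = 4)
  gm2 <- make_gm(calls2, pos = seq_len(12L) * 10L,
                 chrom_lengths = c(chr1 = 200L))
  expect_lt(tajimas_d(gm2, 1:4, window_spec(200L, 200L))$tajd[1], 0)
  # S = 0 -> missing value
  gm0 <- make_gm(matrix(0L, 4, 3), chrom_lengths = c(chr1 = 1000L))
  expect_true(is.na(tajimas_d(gm0, 1:4, window_spec(1000L, 1000L))$tajd[1]))
})

test_that("z_transform standardizes and rejects degenerate input", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(z_transform(c(2, 2, 2)), "zero standard deviation")
  expect_error(z_transform(3), "finite")
  set.seed(89)
  z <- z_transform(c(rnorm(100), NA, Inf))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(is.na(z[101:102])))
})

test_that("scan_table populates both window scales with unit z-scores", {
  st <- simulate_study(sim_config(n_sites = 3000L, n_chrom = 1L,
                                  chrom_length = 1000000L, seed = 97L))
  for (spec in list(window_spec(100000L, 10000L), window_spec(50000L, 1000L))) {
    sc <- scan_table(st$gm, st$design, spec)
    expect_s3_class(sc, "window_scan")
    expect_equal(sc$delta_pi, sc$pi_control - sc$pi_case, tolerance = 1e-15)
    expect_equal(sc$delta_tajd, sc$tajd_control - sc$tajd_case,
                 tolerance = 1e-15)
    for (col in c("z_fst", "z_delta_pi", "z_delta_tajd")) {
      expect_equal(mean(sc[[col]], na.rm = TRUE), 0, tolerance = 1e-10)
      expect_equal(sd(sc[[col]], na.rm = TRUE), 1, tolerance = 1e-10)
    }
  }
  expect_error(scan_table(st$gm, st$design, case = "nope"), "no samples")
})

test_that("a planted strong locus attains the genome-wide maximum FST z-score", {
  st <- simulate_study(sim_config(n_sites = 20000L, n_chrom = 2L,
                                  chrom_length = 5000000L,
                                  island_divergence = 0.1, n_causal = 1L,
                                  causal_delta = 0.6, seed = 3L))
  sc <- scan_table(st$gm, st$design, window_spec(50000L, 1000L))
  best <- sc[which.max(sc$z_fst), ]
  tc <- st$truth$causal
  expect_equal(best$chrom, tc$chrom)
  expect_lte(best$start, tc$pos)
  expect_gte(best$end, tc$pos)
})
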