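# a genotype track that is heterozygous-rich outside any planted tract,
# so background windows never classify homozygous
het_track <- function(n) rep(c(1L, 0L, 1L, 2L), length.out = n)

test_that("detect_roh calls a long homozygous stretch and honors min length", {
  # SNVs every 2.5 kb; tract of 61 SNVs spans 150 kb
  n <- 300
  pos <- seq_len(n) * 2500L
  g <- het_track(n)
  tract <- 100:160
  g[tract] <- 2L
  gm <- make_gm(matrix(g, 1), pos = pos, ids = "s1")
  runs <- detect_roh(gm, "s1")
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, runs$end - runs$start + 1L)
  expect_gte(runs$length, 100000L)
  # recovered span covers most of the tract
  tr_start <- pos[min(tract)]; tr_end <- pos[max(tract)]
  ov <- min(runs$end, tr_end) - max(runs$start, tr_start) + 1L
  expect_gt(ov / (tr_end - tr_start + 1L), 0.85)
  # a 37-SNV stretch spanning 90 kb fails the 100 kb minimum
  g2 <- het_track(n)
  g2[100:136] <- 0L
  gm2 <- make_gm(matrix(g2, 1), pos = pos, ids = "s1")
  expect_equal(nrow(detect_roh(gm2, "s1")), 0L)
})

test_that("runs split at gaps larger than 100 kb", {
  # homozygous SNVs every 2.5 kb with a 150 kb hole in the middle
  pos <- c(seq_len(60) * 2500L, 300000L + seq_len(60) * 2500L)
  g <- c(rep(2L, 60), rep(0L, 60))
  # flank with het background so the runs end where the tracts do
  pos <- c(pos, 600000L + seq_len(120) * 2500L)
  g <- c(g, het_track(120))
  gm <- make_gm(matrix(g, 1), pos = pos, ids = "s1")
  runs <- detect_roh(gm, "s1")
  expect_equal(nrow(runs), 2L)
  expect_true(all(runs$length >= 100000L))
  expect_lt(runs$end[1L], 300000L)
  expect_gte(runs$start[2L], 300000L)
})

test_that("detect_roh equals the exhaustive oracle on random instances", {
  set.seed(103)
  for (rep in 1:8) {
    n <- sample(120:400, 1)
    pos <- sort(sample.int(n * 3000L, n))
    # mosaic of homozygous stretches and noisy background
    g <- het_track(n)
    n_tracts <- sample(1:3, 1)
    for (k in seq_len(n_tracts)) {
      a <- sample.int(n - 50L, 1)
      len <- sample(30:80, 1)
      g[a:min(n, a + len)] <- sample(c(0L, 2L), 1)
    }
    g[sample.int(n, round(0.03 * n))] <- NA  # sprinkle missingness
    params <- roh_params(window_snv = sample(c(20L, 50L), 1),
                         min_length_bp = sample(c(50000L, 100000L), 1))
    gm <- make_gm(matrix(g, 1), pos = pos, ids = "s1")
    got <- suppressWarnings(detect_roh(gm, "s1", params))
    want <- oracle_roh(g, pos, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, unname(want[, "start"]))
      expect_equal(got$end, unname(want[, "end"]))
      expect_equal(got$n_snv, unname(want[, "n_snv"]))
    }
  }
})

test_that("chromosomes with fewer SNVs than the window are skipped with a warning", {
  gm <- make_gm(matrix(rep(2L, 10), 1), pos = seq_len(10L) * 1000L, ids = "s1")
  expect_warning(runs <- detect_roh(gm, "s1"), "fewer than")
  expect_equal(nrow(runs), 0L)
})

test_that("planted simulator tracts are recovered; short tracts are not", {
  roh <- data.frame(cohort = c("case", "case"), chrom = c("chr1", "chr2"),
                    start = c(500000L, 500000L),
                    end = c(680000L, 550000L),  # 180 kb and 50 kb
                    carrier_frac = c(1, 1))
  st <- simulate_study(sim_config(n_sites = 8000L, n_chrom = 2L,
                                  chrom_length = 2000000L,
                                  roh_planted = roh, missing_rate = 0.01,
                                  seed = 107L))
  carriers <- strsplit(st$truth$roh$carriers[1L], ",")[[1L]]
  runs <- detect_roh(st$gm, carriers[1L])
  long_hit <- runs$chrom == "chr1" & runs$start <= 520000L &
    runs$end >= 660000L
  expect_true(any(long_hit))
  # the 50 kb tract must not be called (min length 100 kb)
  short_hit <- runs$chrom == "chr2" & runs$start >= 450000L &
    runs$end <= 600000L & runs$length < 100000L
  expect_false(any(short_hit))
  expect_true(all(runs$length >= 100000L))
})

test_that("froh is the run-covered fraction of the SNV map", {
  gm <- make_gm(matrix(0L, 1, 4), pos = c(1L, 4000000L, 5000000L, 11000000L),
                chrom = c("chr1", "chr1", "chr2", "chr2"), ids = "s1")
  # map length = 4e6 + 6000001
  runs <- data.frame(sample_id = "s1", chrom = "chr1", start = 1L,
                     end = 1000000L, n_snv = 10L, length = 1000000L)
  expect_equal(froh(runs, gm), 1000000 / 10000001, tolerance = 1e-12)
  expect_equal(froh(runs[0, ], gm), 0)
  # runs covering the whole map give 1
  runs_all <- data.frame(sample_id = "s1", chrom = c("chr1", "chr2"),
                         start = c(1L, 5000000L),
                         end = c(4000000L, 11000000L), n_snv = 5L,
                         length = c(4000000L, 6000001L))
  expect_equal(froh(runs_all, gm), 1, tolerance = 1e-12)
})

test_that("froh grows with planted tract length", {
  lens <- c(200000L, 600000L, 1200000L)
  f <- vapply(lens, function(L) {
    roh <- data.frame(cohort = "case", chrom = "chr1", start = 300000L,
                      end = 300000L + L, carrier_frac = 1)
    st <- simulate_study(sim_config(n_sites = 4000L, n_chrom = 1L,
                                    chrom_length = 2000000L,
                                    roh_planted = roh, seed = 109L))
    carrier <- strsplit(st$truth$roh$carriers, ",")[[1L]][1L]
    froh(detect_roh(st$gm, carrier), st$gm)
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("roh_sharing reports per-cohort coverage proportions", {
  design <- cohort_design(c(paste0("ca", 1:12), paste0("cb", 1:11)),
                          c(rep("case", 12), rep("control_a", 11)))
  gm <- make_gm(matrix(0L, 23, 3), pos = c(100L, 5000L, 9000L),
                ids = design$sample_id)
  runs <- rbind(
    data.frame(sample_id = paste0("ca", 1:10), chrom = "chr1", start = 1L,
               end = 6000L, n_snv = 2L, length = 6000L),
    data.frame(sample_id = paste0("cb", 1:7), chrom = "chr1", start = 4000L,
               end = 9500L, n_snv = 2L, length = 5501L))
  track <- roh_sharing(runs, gm, design)
  expect_equal(track$share_case, c(10, 10, 0) / 12)
  expect_equal(track$share_control_a, c(0, 7, 7) / 11)
  # no runs at all: zero track
  track0 <- roh_sharing(runs[0, ], gm, design)
  expect_true(all(track0$share_case == 0 & track0$share_control_a == 0))
})

test_that("candidate_roh applies case-high / control-low thresholds", {
  track <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    share_case = c(0.83, 0.83, 0.83, 0.5),
    share_control_a = c(0.64, 0.64, 0.80, 0.64),
    share_control_b = c(0.44, 0.44, 0.44, 0.44))
  got <- candidate_roh(track)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(100L, 200L))
  # control_a at 0.80 >= 0.75 breaks the stretch at pos 300
  # permissive thresholds admit everything with any case sharing
  all_in <- candidate_roh(track, hi = 0, lo = 1.01)
  expect_equal(sum(all_in$n_snv), 4L)
})
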