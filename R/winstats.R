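#' Sliding window specification
#'
#' Windows are 1-based inclusive intervals starting at 1, 1 + step,
#' 1 + 2*step, ... while the start lies within the chromosome; the last
#' window is truncated at the chromosome end. A site at position p belongs
#' to window `[start, start + size - 1]` when `start <= p <= end`. The
#' scan scales used throughout are 100 kb windows / 10 kb step for the
#' coarse genome scan and 50 kb / 1 kb for the fine scan.
#'
#' @param size window size in bp.
#' @param step step between window starts in bp (`0 < step <= size`).
#' @return a list of class `window_spec`.
#' @export
window_spec <- function(size = 50000L, step = 1000L) {
  stopifnot(size > 0, step > 0, step <= size)
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "window_spec")
}

# chromosome lengths used for tiling: declared lengths if carried by the
# matrix, else the last observed site position
chrom_lengths_of <- function(gm) {
  chroms <- unique(gm$chrom)
  if (!is.null(gm$chrom_lengths) && all(chroms %in% names(gm$chrom_lengths)))
    return(gm$chrom_lengths[chroms])
  vapply(chroms, function(ch) max(gm$pos[gm$chrom == ch]), integer(1))
}

#' Tile chromosomes into sliding windows
#'
#' @param gm a [geno_matrix()].
#' @param spec a [window_spec()].
#' @return a `data.frame` with `chrom`, `start`, `end` (1-based inclusive)
#'   and the site-index range `i1`, `i2` of member sites (`i1 > i2` for an
#'   empty window).
#' @export
make_windows <- function(gm, spec) {
  lens <- chrom_lengths_of(gm)
  out <- vector("list", length(lens))
  for (k in seq_along(lens)) {
    ch <- names(lens)[k]
    L <- lens[[k]]
    starts <- seq.int(1L, L, by = spec$step)
    ends <- pmin(starts + spec$size - 1L, L)
    sidx <- which(gm$chrom == ch)
    pos <- gm$pos[sidx]
    i1 <- findInterval(starts - 1L, pos) + 1L
    i2 <- findInterval(ends, pos)
    off <- if (length(sidx)) sidx[1L] - 1L else 0L
    out[[k]] <- data.frame(chrom = ch, start = starts, end = ends,
                           i1 = i1 + off, i2 = i2 + off)
  }
  do.call(rbind, out)
}

# sum `values` (one per site) over each window's member-site index range
window_sum <- function(values, windows) {
  cs <- c(0, cumsum(ifelse(is.na(values), 0, values)))
  cs[windows$i2 + 1L] - cs[windows$i1]
}

#' Per-site nucleotide diversity
#'
#' Expected heterozygosity with the unbiased (n-1) denominator: the
#' fraction of the `n*(n-1)/2` allele pairs that differ,
#' `2 c (n - c) / (n (n - 1))` for alternate count `c` among `n` called
#' alleles.
#'
#' @param alt_count alternate-allele count(s) `c`.
#' @param n_alleles called allele count(s) `n` (must be >= 2).
#' @return per-site pi; `NA` where `n < 2`.
#' @export
site_pi <- function(alt_count, n_alleles) {
  ifelse(n_alleles >= 2,
         2 * alt_count * (n_alleles - alt_count) /
           (n_alleles * (n_alleles - 1)),
         NA_real_)
}

#' Windowed nucleotide diversity for one cohort
#'
#' Sums [site_pi()] over member sites and divides by the window length in
#' bp (the truncated length for a chromosome-end window), giving diversity
#' per base pair. Sites with fewer than 2 called alleles in the cohort are
#' skipped.
#'
#' @param gm a [geno_matrix()].
#' @param cohort_samples character IDs or indices of the cohort members.
#' @param spec a [window_spec()].
#' @param windows optional precomputed [make_windows()] table.
#' @return the windows table with a `pi` column added.
#' @export
window_pi <- function(gm, cohort_samples, spec = window_spec(),
                      windows = make_windows(gm, spec)) {
  ac <- allele_counts(gm, samples = cohort_samples)
  pi_site <- site_pi(ac$alt_count, ac$n_called)
  windows$pi <- window_sum(pi_site, windows) /
    (windows$end - windows$start + 1)
  windows
}

# Weir & Cockerham (1984) variance components for two populations at every
# site: a (among populations), b (among individuals within populations),
# c (within individuals), from per-population sample sizes, allele
# frequencies and observed heterozygote frequencies.
wc_components <- function(gm, samples_a, samples_b) {
  stats_of <- function(samples) {
    si <- if (is.character(samples)) match(samples, gm$sample_ids) else samples
    calls <- gm$calls[si, , drop = FALSE]
    n <- colSums(!is.na(calls))
    p <- colSums(calls, na.rm = TRUE) / (2 * n)
    h <- colSums(calls == 1L, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  }
  A <- stats_of(samples_a)
  B <- stats_of(samples_b)
  r <- 2
  nbar <- (A$n + B$n) / r
  ok <- A$n >= 1 & B$n >= 1 & nbar > 1
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # degenerate sites (empty cohort or nc = 0) contribute nothing
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0; cc[!is.finite(cc)] <- 0
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST per site and per window
#'
#' Per-site theta is `a / (a + b + c)` from the 1984 variance components
#' with two populations; the windowed estimate is the ratio-of-sums
#' ("weighted") estimator `sum(a) / sum(a + b + c)` over member sites.
#' Sites with a zero total component are skipped for per-site theta and
#' contribute zeros to the window sums. Per-site theta can be negative at
#' undifferentiated sites (its expectation is zero without structure).
#'
#' @param gm a [geno_matrix()].
#' @param samples_a,samples_b the two cohorts' sample IDs or indices.
#' @param spec a [window_spec()].
#' @param windows optional precomputed [make_windows()] table.
#' @return a list with `site` (a `data.frame` of `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta`) and `windows` (the windows table with `fst` added; `NA`
#'   where no site contributes).
#' @export
weir_fst <- function(gm, samples_a, samples_b, spec = window_spec(),
                     windows = make_windows(gm, spec)) {
  comp <- wc_components(gm, samples_a, samples_b)
  tot <- comp$a + comp$b + comp$c
  theta <- ifelse(tot != 0, comp$a / tot, NA_real_)
  sum_a <- window_sum(comp$a, windows)
  sum_tot <- window_sum(tot, windows)
  windows$fst <- ifelse(sum_tot != 0, sum_a / sum_tot, NA_real_)
  list(
    site = data.frame(chrom = gm$chrom, pos = gm$pos,
                      a = comp$a, b = comp$b, c = comp$c, theta = theta),
    windows = windows
  )
}

# Tajima's D normalizing constants for n sampled alleles
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D for one cohort
#'
#' `D = (pi_hat - S / a1) / sqrt(e1 S + e2 S (S - 1))` where `S` is the
#' number of segregating sites in the window and `pi_hat` the mean number
#' of pairwise differences, both over a fixed allele count
#' `n = 2 * cohort size`. Negative D indicates an excess of rare variants
#' relative to the neutral equilibrium expectation. With an upstream
#' call-rate filter of 0.95 the per-site called count is nearly constant;
#' by default a site with missing calls contributes through its allele
#' frequency scaled to the fixed `n` (set `fully_called_only = TRUE` to
#' restrict to fully-called sites instead).
#'
#' @param gm a [geno_matrix()].
#' @param cohort_samples cohort sample IDs or indices.
#' @param spec a [window_spec()].
#' @param windows optional precomputed [make_windows()] table.
#' @param fully_called_only drop sites with any missing cohort call.
#' @return the windows table with `S` and `tajd` columns added (`tajd` is
#'   `NA` where `S = 0` or the variance term is non-positive).
#' @export
tajimas_d <- function(gm, cohort_samples, spec = window_spec(),
                      windows = make_windows(gm, spec),
                      fully_called_only = FALSE) {
  si <- if (is.character(cohort_samples))
    match(cohort_samples, gm$sample_ids) else cohort_samples
  n_ind <- length(si)
  n <- 2L * n_ind
  if (n < 4L) stop("Tajima's D needs a cohort of >= 2 individuals")
  ac <- allele_counts(gm, samples = si)
  usable <- ac$n_called >= 2
  if (fully_called_only) usable <- ac$n_called == n
  p <- ifelse(usable, ac$af, NA_real_)
  seg <- !is.na(p) & p > 0 & p < 1
  chat <- p * n
  khat_site <- ifelse(seg, 2 * chat * (n - chat) / (n * (n - 1)), 0)
  konst <- tajima_constants(n)
  S <- window_sum(as.numeric(seg), windows)
  khat <- window_sum(khat_site, windows)
  varD <- konst$e1 * S + konst$e2 * S * (S - 1)
  windows$S <- S
  windows$tajd <- ifelse(S > 0 & varD > 0,
                         (khat - S / konst$a1) / sqrt(varD), NA_real_)
  windows
}

#' Z-score standardization
#'
#' Centers and scales by the mean and sample (n-1) standard deviation over
#' finite values; non-finite entries stay `NA`. Used to place windowed
#' statistics on a common scale before empirical-percentile outlier calls.
#'
#' @param values numeric vector.
#' @return z-scores, same length as `values`.
#' @export
z_transform <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2L) stop("need >= 2 finite values")
  s <- stats::sd(values[fin])
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  out <- (values - mean(values[fin])) / s
  out[!fin] <- NA_real_
  out
}

#' Assemble the full window scan for a comparison pair
#'
#' Computes, per window: case and control nucleotide diversity and their
#' difference `delta_pi = pi_control - pi_case`, the weighted
#' Weir-Cockerham FST between the cohorts, per-cohort Tajima's D and
#' `delta_tajd = D_control - D_case`, and genome-wide z-scores of `fst`,
#' `delta_pi` and `delta_tajd`. The control-minus-case orientation puts
#' the expected disease-susceptibility signals (reduced diversity and an
#' excess of rare variants in cases) in the upper tail of each statistic.
#'
#' Only full-length windows enter the z-standardization: a truncated
#' chromosome-end window rests on a fraction of the evidence of the rest
#' of the genome, so its statistics are reported but its z-scores are
#' `NA`. Without this, the high-variance end windows dominate all three
#' upper tails simultaneously and generate spurious outlier
#' intersections at chromosome ends.
#'
#' @param gm a [geno_matrix()].
#' @param design a [cohort_design()].
#' @param spec a [window_spec()].
#' @param case,control cohort labels; `control` may name several cohorts,
#'   which are pooled.
#' @return a `data.frame` of class `window_scan` with one row per window.
#' @export
scan_table <- function(gm, design, spec = window_spec(),
                       case = "case", control = "control_a") {
  case_s <- design_samples(design, case)
  ctrl_s <- design_samples(design, control)
  windows <- make_windows(gm, spec)
  tab <- windows[, c("chrom", "start", "end")]
  tab$n_sites <- windows$i2 - windows$i1 + 1L
  tab$pi_case <- window_pi(gm, case_s, spec, windows)$pi
  tab$pi_control <- window_pi(gm, ctrl_s, spec, windows)$pi
  tab$delta_pi <- tab$pi_control - tab$pi_case
  tab$fst <- weir_fst(gm, case_s, ctrl_s, spec, windows)$windows$fst
  tab$tajd_case <- tajimas_d(gm, case_s, spec, windows)$tajd
  tab$tajd_control <- tajimas_d(gm, ctrl_s, spec, windows)$tajd
  tab$delta_tajd <- tab$tajd_control - tab$tajd_case
  full <- (tab$end - tab$start + 1L) == spec$size
  z_full <- function(x) {
    z <- rep(NA_real_, length(x))
    z[full] <- z_transform(ifelse(full, x, NA_real_)[full])
    z
  }
  tab$z_fst <- z_full(tab$fst)
  tab$z_delta_pi <- z_full(tab$delta_pi)
  tab$z_delta_tajd <- z_full(tab$delta_tajd)
  class(tab) <- c("window_scan", "data.frame")
  tab
}

#' @rdname scan_table
#' @param scan a `window_scan`.
#' @param path output TSV path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
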