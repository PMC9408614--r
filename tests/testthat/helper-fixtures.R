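# Small fixture builders and independent oracles. The oracles are written
# as plain, loop-based transcriptions of the defining formulas so they
# share no code path with the package implementations they check.

make_gm <- function(calls, pos = NULL, chrom = NULL, ids = NULL,
                    depth = NULL, gq = NULL, chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  ns <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(calls)))
  geno_matrix(calls, chrom, pos, ref = rep("A", ns), alt = rep("G", ns),
              sample_ids = ids, depth = depth, gq = gq,
              chrom_lengths = chrom_lengths)
}

# brute-force window pi: explicit pairwise allele comparisons per site
oracle_window_pi <- function(calls, pos, start, end, win_len) {
  total <- 0
  for (j in seq_along(pos)) {
    if (pos[j] < start || pos[j] > end) next
    g <- calls[, j]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) c(as.integer(x >= 1),
                                              as.integer(x >= 2))))
    n <- length(alleles)
    if (n < 2) next
    diff_pairs <- 0; n_pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      n_pairs <- n_pairs + 1
      if (alleles[a] != alleles[b]) diff_pairs <- diff_pairs + 1
    }
    total <- total + diff_pairs / n_pairs
  }
  total / win_len
}

# Weir & Cockerham (1984) components, scalar, straight from the printed
# formulas for r populations (used with r = 2)
oracle_wc_site <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_from_calls <- function(calls_a, calls_b, j) {
  stat <- function(g) {
    g <- g[!is.na(g)]
    c(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
  }
  A <- stat(calls_a[, j]); B <- stat(calls_b[, j])
  oracle_wc_site(c(A["n"], B["n"]), c(A["p"], B["p"]), c(A["h"], B["h"]))
}

# Tajima's D, straight from the defining formulas, for a window of sites
# given as alt-allele counts among a fixed n alleles (fully-called data)
oracle_tajd <- function(alt_counts, n) {
  seg <- alt_counts > 0 & alt_counts < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  khat <- 0
  for (c in alt_counts[seg]) khat <- khat + c * (n - c) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exhaustive sliding-window ROH oracle for one genotype track
oracle_roh <- function(g, pos, params) {
  n <- length(g)
  w <- params$window_snv
  if (n < w) return(NULL)
  nw <- n - w + 1
  hom_win <- logical(nw)
  for (s in seq_len(nw)) {
    win <- g[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_miss_per_window
  }
  in_run <- logical(n)
  for (i in seq_len(n)) {
    cov <- max(1, i - w + 1):min(i, nw)
    in_run[i] <- mean(hom_win[cov]) >= params$min_prop_hom_windows
  }
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!in_run[i]) { i <- i + 1; next }
    j <- i
    while (j < n && in_run[j + 1] && pos[j + 1] - pos[j] <= params$max_gap_bp)
      j <- j + 1
    len <- pos[j] - pos[i] + 1
    nsnv <- j - i + 1
    if (nsnv >= params$min_snv_in_run && len >= params$min_length_bp &&
        nsnv / len >= 1 / params$density_bp)
      runs[[length(runs) + 1]] <- c(start = pos[i], end = pos[j],
                                    n_snv = nsnv)
    i <- j + 1
  }
  if (length(runs)) do.call(rbind, runs) else NULL
}

# exhaustive maximum independent set: all subsets, lexicographically
# smallest among the maximum-cardinality independent ones
oracle_mis <- function(adj, ids) {
  ids <- sort(ids)
  n <- length(ids)
  best <- character(0)
  for (mask in 0:(2^n - 1)) {
    members <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(members) <= length(best)) next
    ok <- TRUE
    if (length(members) > 1) {
      for (a in seq_len(length(members) - 1))
        for (b in (a + 1):length(members))
          if (adj[members[a], members[b]]) { ok <- FALSE; break }
    }
    if (ok && length(members) > length(best)) best <- members
  }
  # re-scan for lexicographic tie-break at the optimum size
  k <- length(best)
  cands <- list()
  for (mask in 0:(2^n - 1)) {
    members <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(members) != k) next
    ok <- TRUE
    if (length(members) > 1) {
      for (a in seq_len(length(members) - 1))
        for (b in (a + 1):length(members))
          if (adj[members[a], members[b]]) { ok <- FALSE; break }
    }
    if (ok) cands[[length(cands) + 1]] <- sort(members)
  }
  keys <- vapply(cands, paste, "", collapse = "|")
  cands[[order(keys)[1]]]
}

# fabricate a kinship_matrix from an explicit phi matrix
fake_km <- function(phi, ids) {
  dimnames(phi) <- list(ids, ids)
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  structure(list(sample_ids = ids, phi = phi,
                 pairs = data.frame(sample_i = ids[idx[, 1]],
                                    sample_j = ids[idx[, 2]],
                                    kinship = phi[idx])),
            class = "kinship_matrix")
}

# diploid HWE genotype draws and a Mendelian child, for pedigree oracles
hwe_ind <- function(p) stats::rbinom(length(p), 2, p)
mendel_child <- function(a, b) {
  ta <- ifelse(a == 2, 1, ifelse(a == 0, 0, stats::rbinom(length(a), 1, 0.5)))
  tb <- ifelse(b == 2, 1, ifelse(b == 0, 0, stats::rbinom(length(b), 1, 0.5)))
  ta + tb
}

# mean silhouette width for a 2-group labelling of a score matrix
silhouette_mean <- function(scores, labels) {
  d <- as.matrix(stats::dist(scores))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
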