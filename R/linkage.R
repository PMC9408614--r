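#' Genotypic r-squared between two sites
#'
#' Squared Pearson correlation of alternate-allele dosages (0/1/2) over
#' samples called at both sites — the "genotypic" LD measure used by PLINK
#' when haplotype phase is unknown. Symmetric in its arguments.
#'
#' @param gm a [geno_matrix()].
#' @param site_i,site_j site indices (columns of `gm$calls`).
#' @return r-squared in `[0, 1]`, or `NA` when fewer than 2 jointly-called
#'   samples remain or either site has zero dosage variance among them.
#' @export
pairwise_r2 <- function(gm, site_i, site_j) {
  x <- gm$calls[, site_i]
  y <- gm$calls[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r2 matrix for a block of site indices (pairwise-complete samples)
r2_block <- function(calls, idx) {
  m <- calls[, idx, drop = FALSE]
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))^2
}

#' Window-based LD pruning
#'
#' Greedy within-window pruning after PLINK's `--indep-pairwise`: within
#' each `window_snv`-SNV window (slid by `step_snv` SNVs per chromosome),
#' while any pair of still-retained sites has r-squared above `r2_max`, the
#' later site of the offending pair (in position order) is dropped. Setting
#' `r2_max = 0.90` gives the "strong" prune used to remove redundant
#' markers in SNV-dense regions before autozygosity calling.
#'
#' @param gm a [geno_matrix()] with sites ordered per chromosome.
#' @param window_snv window width in SNVs (default 50).
#' @param step_snv slide in SNVs (default 5).
#' @param r2_max maximum tolerated r-squared (default 0.2).
#' @return integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(gm, window_snv = 50L, step_snv = 5L, r2_max = 0.2) {
  stopifnot(window_snv >= 2L, step_snv >= 1L, r2_max >= 0)
  keep <- rep(TRUE, n_sites(gm))
  for (ch in unique(gm$chrom)) {
    sites <- which(gm$chrom == ch)
    nc <- length(sites)
    starts <- seq(1L, max(1L, nc), by = step_snv)
    for (s in starts) {
      win <- sites[s:min(s + window_snv - 1L, nc)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- r2_block(gm$calls, win)
      repeat {
        r2u <- r2
        r2u[lower.tri(r2u, diag = TRUE)] <- NA
        bad <- which(r2u > r2_max, arr.ind = TRUE)
        if (nrow(bad) == 0L) break
        # first offending pair in (i, j) order; drop the later site j
        bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
        j <- bad[1L, 2L]
        keep[win[j]] <- FALSE
        r2[j, ] <- NA; r2[, j] <- NA
      }
      if (s + window_snv - 1L >= nc) break
    }
  }
  which(keep)
}

#' LD decay with physical distance
#'
#' Mean genotypic r-squared in distance bins over all intra-chromosomal
#' site pairs up to `max_dist` apart. The decay distance is the midpoint of
#' the first bin whose mean drops below `threshold` with all later bins
#' also below it (`NA` when LD never decays within range).
#'
#' @param gm a [geno_matrix()].
#' @param max_dist maximum pair separation in bp (default 500 kb).
#' @param bin bin width in bp (default 5 kb).
#' @param threshold r-squared decay threshold (default 0.2).
#' @param max_pairs_per_bin optional cap on pairs per bin for speed; `Inf`
#'   (default) uses all pairs.
#' @return a list of class `ld_decay` with a `data.frame` `curve`
#'   (`dist_lo`, `dist_hi`, `mid`, `mean_r2`, `n_pairs`) and
#'   `crossing_dist`, the r-squared = `threshold` decay distance in bp.
#' @export
ld_decay <- function(gm, max_dist = 500000L, bin = 5000L, threshold = 0.2,
                     max_pairs_per_bin = Inf) {
  n_bins <- ceiling(max_dist / bin)
  sum_r2 <- numeric(n_bins)
  n_pair <- integer(n_bins)
  for (ch in unique(gm$chrom)) {
    sites <- which(gm$chrom == ch)
    if (length(sites) < 2L) next
    pos <- gm$pos[sites]
    for (a in seq_len(length(sites) - 1L)) {
      b <- a + 1L
      while (b <= length(sites) && pos[b] - pos[a] <= max_dist) {
        d <- pos[b] - pos[a]
        k <- min(n_bins, (d - 1L) %/% bin + 1L)
        if (n_pair[k] < max_pairs_per_bin) {
          r2 <- pairwise_r2(gm, sites[a], sites[b])
          if (!is.na(r2)) {
            sum_r2[k] <- sum_r2[k] + r2
            n_pair[k] <- n_pair[k] + 1L
          }
        }
        b <- b + 1L
      }
    }
  }
  if (sum(n_pair) == 0L) stop("no intra-chromosomal pairs within max_dist")
  mean_r2 <- ifelse(n_pair > 0L, sum_r2 / n_pair, NA_real_)
  lo <- (seq_len(n_bins) - 1L) * bin
  curve <- data.frame(dist_lo = lo, dist_hi = lo + bin, mid = lo + bin / 2,
                      mean_r2 = mean_r2, n_pairs = n_pair)
  # first bin below threshold such that every subsequent informative bin
  # is also below threshold
  below <- is.na(mean_r2) | mean_r2 < threshold
  informative_below <- !is.na(mean_r2) & mean_r2 < threshold
  crossing <- NA_real_
  suffix_ok <- rev(cumprod(rev(below))) == 1
  cand <- which(suffix_ok & informative_below)
  if (length(cand) > 0L) crossing <- curve$mid[cand[1L]]
  structure(list(curve = curve, crossing_dist = crossing,
                 threshold = threshold),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("ld_decay: %d bins, %d pairs\n",
              nrow(x$curve), sum(x$curve$n_pairs)))
  cat(sprintf("  r2 = %.2f decay distance: %s bp\n", x$threshold,
              format(x$crossing_dist)))
  invisible(x)
}
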