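#' PCA on pruned, putatively neutral SNVs
#'
#' Restricts the dosage matrix to the requested sites (typically the
#' intersection of a neutral-region track with an LD-pruned site set),
#' drops monomorphic sites, centers each site by twice its allele
#' frequency and scales by `sqrt(2 p (1 - p))` (the PLINK
#' variance-standardized convention), mean-imputes missing dosages (zero
#' after centering), and eigendecomposes the sample covariance. Sign
#' convention: within each component the loading-vector entry of largest
#' magnitude is positive, so output is deterministic and invariant to
#' sample order up to that convention.
#'
#' @param gm a [geno_matrix()].
#' @param k number of components (default 10, capped at n samples - 1).
#' @param neutral optional interval track from [read_bed()]; sites outside
#'   it are excluded.
#' @param pruned_sites optional integer site indices (e.g. from
#'   [ld_prune()]); sites outside are excluded.
#' @return a list of class `pca_result`: `sample_ids`, `scores`
#'   (samples x k), `var_frac` (variance fraction per component),
#'   `n_sites_used`.
#' @export
pca_genotypes <- function(gm, k = 10L, neutral = NULL, pruned_sites = NULL) {
  if (n_samples(gm) < 2L) stop("need >= 2 samples")
  keep <- rep(TRUE, n_sites(gm))
  if (!is.null(pruned_sites)) {
    keep <- rep(FALSE, n_sites(gm))
    keep[pruned_sites] <- TRUE
  }
  if (!is.null(neutral)) {
    snv <- GenomicRanges::GRanges(gm$chrom,
                                  IRanges::IRanges(gm$pos, gm$pos))
    ov <- GenomicRanges::findOverlaps(snv, track_to_granges(neutral))
    inside <- rep(FALSE, n_sites(gm))
    inside[unique(S4Vectors::queryHits(ov))] <- TRUE
    keep <- keep & inside
  }
  X <- gm$calls[, keep, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(X)
  k <- min(k, n_samples(gm) - 1L)
  if (m < k) stop("fewer informative sites (", m, ") than components (", k, ")")
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  cov <- tcrossprod(Z) / m
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(eig$vectors[, j]))
    if (eig$vectors[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(gm$sample_ids, paste0("PC", seq_len(k)))
  structure(list(sample_ids = gm$sample_ids, scores = scores,
                 var_frac = ev[seq_len(k)] / sum(ev),
                 n_sites_used = m),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d sites, %d components\n",
              length(x$sample_ids), x$n_sites_used, ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}
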