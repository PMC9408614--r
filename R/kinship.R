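#' KING-robust pairwise kinship
#'
#' Estimates the kinship coefficient for every sample pair from shared
#' heterozygosity and opposing-homozygote counts, using only sites called
#' in both members of a pair:
#' \deqn{\hat\phi_{ij} = \frac12 - \frac{N^{(i)}_{het} + N^{(j)}_{het}
#'   - 2 N_{het,het} + 4 N_{opp.hom}}{4\,\min(N^{(i)}_{het}, N^{(j)}_{het})}}
#' The min-heterozygosity denominator makes the estimator robust to
#' population structure, which matters for cohorts drawn from diverged
#' islands. A self-comparison (or duplicated sample) gives exactly 0.5;
#' parent-offspring pairs concentrate near 0.25; unrelated pairs near 0.
#'
#' A pair in which either member has zero heterozygous calls (over the
#' jointly-called sites) has an undefined estimate; it is reported `NA`
#' with a warning and ignored by [max_unrelated()].
#'
#' @param gm a [geno_matrix()] with at least 2 samples.
#' @return a list of class `kinship_matrix` with elements `sample_ids`,
#'   `phi` (symmetric matrix, diagonal 0.5) and `pairs`, a `data.frame` of
#'   per-pair counts (`n_het_i`, `n_het_j`, `n_het_het`, `n_opp_hom`,
#'   `kinship`).
#' @export
king_kinship <- function(gm) {
  n <- n_samples(gm)
  if (n < 2L) stop("need at least 2 samples")
  calls <- gm$calls
  het <- calls == 1L; het[is.na(het)] <- FALSE
  aa <- calls == 0L; aa[is.na(aa)] <- FALSE
  bb <- calls == 2L; bb[is.na(bb)] <- FALSE
  called <- !is.na(calls)
  mode(het) <- "numeric"; mode(aa) <- "numeric"; mode(bb) <- "numeric"
  mode(called) <- "numeric"
  # all pairwise counts via cross-products over sites
  n_het_het <- tcrossprod(het)
  n_opp_hom <- tcrossprod(aa, bb); n_opp_hom <- n_opp_hom + t(n_opp_hom)
  n_het_i <- tcrossprod(het, called)   # [i, j] = het in i among sites called in both
  phi <- matrix(NA_real_, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  pairs <- NULL
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  hi <- n_het_i[idx]; hj <- t(n_het_i)[idx]
  hh <- n_het_het[idx]; oh <- n_opp_hom[idx]
  denom <- 4 * pmin(hi, hj)
  k <- ifelse(denom > 0, 0.5 - (hi + hj - 2 * hh + 4 * oh) / denom, NA_real_)
  if (anyNA(k))
    warning(sum(is.na(k)), " pair(s) with zero heterozygous calls: ",
            "kinship undefined")
  phi[idx] <- k
  phi[idx[, c(2L, 1L), drop = FALSE]] <- k
  diag(phi) <- 0.5
  pairs <- data.frame(
    sample_i = gm$sample_ids[idx[, 1L]],
    sample_j = gm$sample_ids[idx[, 2L]],
    n_het_i = hi, n_het_j = hj, n_het_het = hh, n_opp_hom = oh,
    kinship = k
  )
  structure(list(sample_ids = gm$sample_ids, phi = phi, pairs = pairs),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d samples, %d pairs\n",
              length(x$sample_ids), nrow(x$pairs)))
  cat(sprintf("  kinship range: [%.4f, %.4f]\n",
              min(x$pairs$kinship, na.rm = TRUE),
              max(x$pairs$kinship, na.rm = TRUE)))
  invisible(x)
}

#' @rdname king_kinship
#' @param km a `kinship_matrix`.
#' @param path output TSV path.
#' @export
write_kinship <- function(km, path) {
  utils::write.table(km$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Maximum set of mutually unrelated samples
#'
#' Finds a maximum-cardinality subset of samples in which every pairwise
#' kinship estimate is at or below `threshold` (default 0.0884, the
#' conventional 2nd-degree cutoff at \eqn{1/2^{4.5}}). The "related" graph
#' connects pairs above the threshold and an exact maximum independent set
#' is computed by branch and bound, which is feasible and deterministic at
#' cohort scale (tested to 64 samples). Pairs with undefined kinship impose
#' no constraint. Ties between equally large sets are broken in favor of
#' the lexicographically smallest set of sample IDs, so the result does not
#' depend on input order.
#'
#' @param km a `kinship_matrix` from [king_kinship()].
#' @param threshold kinship above which a pair is considered related.
#' @return character vector of retained sample IDs (sorted).
#' @export
max_unrelated <- function(km, threshold = 0.0884) {
  ids <- sort(km$sample_ids)
  n <- length(ids)
  if (n > 64L) stop("exact search supported for <= 64 samples")
  phi <- km$phi[ids, ids, drop = FALSE]
  adj <- !is.na(phi) & phi > threshold
  diag(adj) <- FALSE
  # branch and bound over vertices in lexicographic order, include-first:
  # the first maximum found is the lexicographically smallest maximum set
  best <- character(0)
  recurse <- function(cand, chosen) {
    if (length(chosen) + length(cand) <= length(best)) return()
    if (length(cand) == 0L) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    v <- cand[1L]
    rest <- cand[-1L]
    recurse(rest[!adj[v, rest]], c(chosen, v))   # include v
    recurse(rest, chosen)                        # exclude v
  }
  recurse(ids, character(0))
  sort(best)
}
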