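#' Genotype and site filtration thresholds
#'
#' Defaults reproduce a conservative short-read filtration scheme for
#' cross-species alignments: per-call depth must lie within 60--250% of the
#' individual's mean depth (calls outside that band often reflect paralogy
#' or copy-number differences against the reference genome), genotype
#' quality must be at least 20, and sites must be called in at least 95% of
#' individuals with minor allele frequency at least 0.01.
#'
#' @param depth_lo_frac lower depth bound as a fraction of the individual
#'   mean depth (default 0.60; calls exactly at the bound are retained).
#' @param depth_hi_frac upper depth bound fraction (default 2.50, retained
#'   at the bound).
#' @param min_gq minimum genotype quality; calls with GQ strictly below are
#'   set missing (default 20).
#' @param min_call_rate minimum fraction of samples called at a site
#'   (default 0.95).
#' @param min_maf minimum minor allele frequency over surviving calls
#'   (default 0.01).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(depth_lo_frac = 0.60, depth_hi_frac = 2.50,
                          min_gq = 20, min_call_rate = 0.95, min_maf = 0.01) {
  stopifnot(depth_lo_frac >= 0, depth_hi_frac > depth_lo_frac,
            min_gq >= 0, min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(depth_lo_frac = depth_lo_frac, depth_hi_frac = depth_hi_frac,
                 min_gq = min_gq, min_call_rate = min_call_rate,
                 min_maf = min_maf),
            class = "filter_config")
}

#' Apply per-call and per-site filters
#'
#' Rules are applied in a fixed order:
#' \enumerate{
#'   \item per call, set missing when `DP < depth_lo_frac * meanDP(sample)`
#'     or `DP > depth_hi_frac * meanDP(sample)`, where `meanDP(sample)` is
#'     that sample's mean depth over all input sites (computed once, before
#'     any masking);
#'   \item per call, set missing when `GQ < min_gq`;
#'   \item per site, drop when the call rate over surviving calls falls
#'     below `min_call_rate` or the minor allele frequency over surviving
#'     called alleles falls below `min_maf`.
#' }
#' A site where every call has been masked is dropped by the call-rate rule.
#'
#' @param gm a [geno_matrix()] with `depth` and `gq` populated (absent
#'   matrices skip the corresponding rules).
#' @param cfg a [filter_config()].
#' @return a list with elements `gm` (the filtered matrix) and `report`, a
#'   `filter_report` tallying calls masked and sites dropped per rule.
#' @export
filter_genotypes <- function(gm, cfg = filter_config()) {
  calls <- gm$calls
  called0 <- !is.na(calls)
  masked_depth <- 0L
  masked_gq <- 0L
  mean_dp <- attr(gm, "mean_depth_ref")
  if (!is.null(gm$depth)) {
    # the per-sample reference depth is computed once, over all sites of
    # the original input, and carried on the result so that re-filtering
    # is idempotent
    if (is.null(mean_dp)) mean_dp <- rowMeans(gm$depth)
    lo <- cfg$depth_lo_frac * mean_dp
    hi <- cfg$depth_hi_frac * mean_dp
    bad <- (gm$depth < lo | gm$depth > hi) & called0
    masked_depth <- sum(bad)
    calls[bad] <- NA_integer_
  }
  if (!is.null(gm$gq)) {
    bad <- gm$gq < cfg$min_gq & !is.na(calls)
    masked_gq <- sum(bad)
    calls[bad] <- NA_integer_
  }
  n_samp <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  call_rate <- n_called / n_samp
  af <- colSums(calls, na.rm = TRUE) / (2L * n_called)
  maf <- pmin(af, 1 - af)
  drop_rate <- call_rate < cfg$min_call_rate
  # a site with zero surviving calls has undefined MAF: it fails the MAF
  # rule whenever a positive threshold is in force, else is kept as-is
  drop_maf <- !drop_rate &
    ifelse(is.nan(maf), cfg$min_maf > 0, maf < cfg$min_maf)
  keep <- !(drop_rate | drop_maf)
  gm2 <- gm
  gm2$calls <- calls
  gm2 <- gm_subset(gm2, sites = keep)
  attr(gm2, "mean_depth_ref") <- mean_dp
  report <- structure(list(
    n_sites_in = n_sites(gm),
    calls_masked_depth = masked_depth,
    calls_masked_gq = masked_gq,
    sites_dropped_call_rate = sum(drop_rate),
    sites_dropped_maf = sum(drop_maf),
    sites_retained = sum(keep)
  ), class = "filter_report")
  list(gm = gm2, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  cat(sprintf("  input sites:              %d\n", x$n_sites_in))
  cat(sprintf("  calls masked (depth):     %d\n", x$calls_masked_depth))
  cat(sprintf("  calls masked (GQ):        %d\n", x$calls_masked_gq))
  cat(sprintf("  sites dropped (call rate):%d\n", x$sites_dropped_call_rate))
  cat(sprintf("  sites dropped (MAF):      %d\n", x$sites_dropped_maf))
  cat(sprintf("  sites retained:           %d\n", x$sites_retained))
  invisible(x)
}

#' @rdname filter_genotypes
#' @param report a `filter_report`.
#' @param path output TSV path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transition/transversion ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' A<->G and C<->T; everything else is a transversion. Under random
#' substitution the expected ratio is 0.5; genuine SNV call sets in mammals
#' typically exceed 2, so the ratio is a standard quality diagnostic.
#'
#' @param gm a [geno_matrix()].
#' @return ratio of transition to transversion site counts.
#' @export
ts_tv_ratio <- function(gm) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  pair <- paste0(pmin(gm$ref, gm$alt), pmax(gm$ref, gm$alt))
  is_ts <- pair %in% c("AG", "CT")
  tv <- sum(!is_ts)
  if (tv == 0L) stop("no transversions: Ts/Tv undefined")
  sum(is_ts) / tv
}

#' Polarize alleles as ancestral or derived
#'
#' For alignments against an outgroup reference genome (here, the domestic
#' dog standing in as the outgroup for island fox data), the reference base
#' is taken as the ancestral allele at every site, so the derived allele
#' frequency equals the alternate-allele frequency. Idempotent.
#'
#' @param gm a [geno_matrix()].
#' @return `gm` with `ancestral_is_ref` set `TRUE` at every site.
#' @export
polarize <- function(gm) {
  gm$ancestral_is_ref <- rep(TRUE, n_sites(gm))
  gm
}

#' @rdname polarize
#' @return `derived_af`: per-site derived allele frequency over called
#'   alleles (requires a polarized matrix).
#' @export
derived_af <- function(gm) {
  if (!isTRUE(all(gm$ancestral_is_ref)))
    stop("matrix is not polarized; call polarize() first")
  allele_counts(gm)$af
}
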