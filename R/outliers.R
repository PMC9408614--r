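#' Top-percentile outlier windows
#'
#' Windows whose statistic reaches the empirical `q`-quantile of the
#' finite genome-wide values (upper tail of the signed statistic; ties at
#' the quantile are included). With `q = 0.99` this is the top-1% rule.
#'
#' @param scan a `window_scan` from [scan_table()].
#' @param statistic column name, e.g. `"z_fst"`, `"z_delta_pi"`,
#'   `"z_delta_tajd"`.
#' @param q quantile in `[0, 1)` (default 0.99).
#' @param min_finite minimum finite windows required (default 100).
#' @return the subset of `scan` rows at or above the quantile.
#' @export
top_windows <- function(scan, statistic, q = 0.99, min_finite = 100L) {
  x <- scan[[statistic]]
  if (is.null(x)) stop("no such statistic column: ", statistic)
  fin <- is.finite(x)
  if (sum(fin) < min_finite)
    stop("too few finite windows (", sum(fin), ") for quantile selection")
  cut <- stats::quantile(x[fin], probs = q, names = FALSE, type = 7)
  scan[fin & x >= cut, , drop = FALSE]
}

#' Merge outlier windows into peaks
#'
#' Maximal unions of outlier windows that overlap or abut (zero gap) on
#' the same chromosome; a 1 bp gap separates peaks. Stepped sliding
#' windows make a contiguous outlier stretch appear as many overlapping
#' windows, which collapse to a single peak here.
#'
#' @param outliers a subset of `window_scan` rows (one statistic).
#' @param statistic the z-score column used to record each peak's maximum.
#' @return a `data.frame` of peaks: `chrom`, `start`, `end`, `max_z`,
#'   `n_windows`.
#' @export
merge_peaks <- function(outliers, statistic = NULL) {
  if (nrow(outliers) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), max_z = numeric(),
                      n_windows = integer()))
  gr <- GenomicRanges::GRanges(outliers$chrom,
                               IRanges::IRanges(outliers$start, outliers$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  z <- if (!is.null(statistic)) outliers[[statistic]] else rep(NA_real_, nrow(outliers))
  peak_of <- S4Vectors::subjectHits(hit)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    max_z = as.numeric(tapply(z[S4Vectors::queryHits(hit)], peak_of, max)),
    n_windows = as.integer(tabulate(peak_of, nbins = length(red)))
  )
}

#' Intersect outlier peaks of three statistics into candidate regions
#'
#' A candidate region is the intersection interval of a triple of mutually
#' overlapping peaks, one from each statistic (FST, delta-pi, delta-
#' Tajima's D). Overlapping candidate intervals are merged, and regions are
#' ranked by the sum of the member peaks' z-maxima (rank 1 = strongest).
#'
#' @param peaks_fst,peaks_dpi,peaks_dtajd peak tables from [merge_peaks()].
#' @return a `data.frame`: `chrom`, `start`, `end`, `score` (summed peak
#'   z-maxima, maximal over contributing triples), `rank`.
#' @export
intersect_peaks <- function(peaks_fst, peaks_dpi, peaks_dtajd) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(), rank = integer())
  if (nrow(peaks_fst) == 0L || nrow(peaks_dpi) == 0L ||
      nrow(peaks_dtajd) == 0L) return(empty)
  gr <- function(p) GenomicRanges::GRanges(p$chrom,
                                           IRanges::IRanges(p$start, p$end))
  g1 <- gr(peaks_fst); g2 <- gr(peaks_dpi); g3 <- gr(peaks_dtajd)
  h12 <- GenomicRanges::findOverlaps(g1, g2)
  if (length(h12) == 0L) return(empty)
  i12 <- IRanges::pintersect(g1[S4Vectors::queryHits(h12)],
                             g2[S4Vectors::subjectHits(h12)])
  h123 <- GenomicRanges::findOverlaps(i12, g3)
  if (length(h123) == 0L) return(empty)
  core <- IRanges::pintersect(i12[S4Vectors::queryHits(h123)],
                              g3[S4Vectors::subjectHits(h123)])
  score <- peaks_fst$max_z[S4Vectors::queryHits(h12)][S4Vectors::queryHits(h123)] +
    peaks_dpi$max_z[S4Vectors::subjectHits(h12)][S4Vectors::queryHits(h123)] +
    peaks_dtajd$max_z[S4Vectors::subjectHits(h123)]
  merged <- GenomicRanges::reduce(core, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(core, merged)
  agg <- tapply(score[S4Vectors::queryHits(hit)],
                S4Vectors::subjectHits(hit), max)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    score = as.numeric(agg)
  )
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-SNV differentiation within a flanked region
#'
#' For every SNV within `flank` bp of the region, computes the single-site
#' Weir-Cockerham theta ("allelic FST") between cases and controls and the
#' absolute case-control allele-frequency difference.
#'
#' @param gm a [geno_matrix()].
#' @param design a [cohort_design()].
#' @param region a one-row region (`chrom`, `start`, `end`, 1-based
#'   inclusive) or a list with those elements.
#' @param flank flanking distance in bp either side (default 150 kb).
#' @param case,control cohort labels (control may pool several).
#' @return a `data.frame`: `chrom`, `pos`, `fst`, `daf` (absolute
#'   frequency difference), `af_case`, `af_control`.
#' @export
per_snv_diff <- function(gm, design, region, flank = 150000L,
                         case = "case", control = "control_a") {
  lo <- max(1L, region$start - flank)
  hi <- region$end + flank
  sel <- gm$chrom == region$chrom & gm$pos >= lo & gm$pos <= hi
  if (!any(sel))
    return(data.frame(chrom = character(), pos = integer(), fst = numeric(),
                      daf = numeric(), af_case = numeric(),
                      af_control = numeric()))
  sub <- gm_subset(gm, sites = sel)
  case_s <- design_samples(design, case)
  ctrl_s <- design_samples(design, control)
  comp <- wc_components(sub, case_s, ctrl_s)
  tot <- comp$a + comp$b + comp$c
  af_c <- allele_counts(sub, samples = case_s)$af
  af_k <- allele_counts(sub, samples = ctrl_s)$af
  data.frame(
    chrom = sub$chrom, pos = sub$pos,
    fst = ifelse(tot != 0, comp$a / tot, NA_real_),
    daf = abs(af_c - af_k),
    af_case = af_c, af_control = af_k
  )
}

#' Select strongly differentiated SNVs
#'
#' Keeps records with allele-frequency difference strictly greater than
#' `min_daf` (default 0.45; a record exactly at the threshold is excluded).
#'
#' @param records output of [per_snv_diff()].
#' @param min_daf threshold on the absolute frequency difference.
#' @return the selected subset of `records`.
#' @export
select_differentiated <- function(records, min_daf = 0.45) {
  records[!is.na(records$daf) & records$daf > min_daf, , drop = FALSE]
}

#' Annotate SNV records with nearest gene and TFBS membership
#'
#' Nearest gene by minimal distance (0 when the SNV lies inside the gene
#' interval); ties are broken toward the lexicographically smaller gene
#' name. TFBS membership is interval containment under BED half-open
#' semantics, as loaded by [read_bed()].
#'
#' @param records a `data.frame` with `chrom` and `pos`.
#' @param genes,tfbs tracks from [read_bed()] (1-based inclusive), or
#'   `NULL` to skip.
#' @return `records` with `gene`, `gene_dist` and `in_tfbs` columns.
#' @export
annotate_snvs <- function(records, genes = NULL, tfbs = NULL) {
  records$gene <- NA_character_
  records$gene_dist <- NA_integer_
  records$in_tfbs <- NA
  if (nrow(records) == 0L) return(records)
  snv <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos, records$pos))
  if (!is.null(genes) && nrow(genes) > 0L) {
    ggr <- track_to_granges(genes)
    d <- GenomicRanges::distanceToNearest(snv, ggr, select = "all")
    if (length(d) > 0L) {
      dd <- data.frame(q = S4Vectors::queryHits(d),
                       s = S4Vectors::subjectHits(d),
                       dist = S4Vectors::mcols(d)$distance)
      dd$name <- genes$name[dd$s]
      dd <- dd[order(dd$q, dd$dist, dd$name), , drop = FALSE]
      dd <- dd[!duplicated(dd$q), , drop = FALSE]
      records$gene[dd$q] <- dd$name
      # report basepair distance (0 inside the gene), not the IRanges
      # between-gap convention
      records$gene_dist[dd$q] <- as.integer(pmax(
        0L,
        genes$start[dd$s] - records$pos[dd$q],
        records$pos[dd$q] - genes$end[dd$s]))
    }
  }
  if (!is.null(tfbs)) {
    records$in_tfbs <- FALSE
    if (nrow(tfbs) > 0L) {
      tgr <- track_to_granges(tfbs)
      ov <- GenomicRanges::findOverlaps(snv, tgr)
      records$in_tfbs[unique(S4Vectors::queryHits(ov))] <- TRUE
    }
  }
  records
}
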