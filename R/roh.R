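#' ROH detection parameters
#'
#' Sliding-window autozygosity parameters in the detectRUNS style: a
#' 50-SNV window scans each chromosome one SNV at a time; a window is
#' classified homozygous when it contains at most `max_het_per_window`
#' heterozygous and `max_miss_per_window` missing calls; a SNV is inside a
#' run when at least `min_prop_hom_windows` of the windows covering it are
#' homozygous-classified. Runs are then split at inter-SNV gaps above
#' `max_gap_bp` and discarded unless they contain `min_snv_in_run` SNVs,
#' span `min_length_bp`, and have at least one SNV per `density_bp`.
#' Defaults reproduce a permissive small-population configuration run on
#' an LD-pruned call set: window 50 SNVs, proportion 0.05, 1 het / 2
#' missing per window, >= 2 SNVs, >= 100 kb, 1 SNV per 50 kb, gaps
#' <= 100 kb.
#'
#' @param window_snv sliding window width in SNVs.
#' @param min_prop_hom_windows minimum fraction of covering windows that
#'   are homozygous-classified for a SNV to be in-run.
#' @param max_het_per_window,max_miss_per_window window classification
#'   allowances.
#' @param min_snv_in_run,min_length_bp,density_bp,max_gap_bp run-level
#'   constraints.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(window_snv = 50L, min_prop_hom_windows = 0.05,
                       max_het_per_window = 1L, max_miss_per_window = 2L,
                       min_snv_in_run = 2L, min_length_bp = 100000L,
                       density_bp = 50000L, max_gap_bp = 100000L) {
  stopifnot(window_snv >= 1L, min_prop_hom_windows > 0,
            min_prop_hom_windows <= 1, max_het_per_window >= 0L,
            max_miss_per_window >= 0L, min_snv_in_run >= 1L,
            min_length_bp >= 1L, density_bp >= 1L, max_gap_bp >= 1L)
  structure(list(window_snv = as.integer(window_snv),
                 min_prop_hom_windows = min_prop_hom_windows,
                 max_het_per_window = as.integer(max_het_per_window),
                 max_miss_per_window = as.integer(max_miss_per_window),
                 min_snv_in_run = as.integer(min_snv_in_run),
                 min_length_bp = as.integer(min_length_bp),
                 density_bp = as.integer(density_bp),
                 max_gap_bp = as.integer(max_gap_bp)),
            class = "roh_params")
}

# rolling sum of x over windows of width w: out[k] = sum(x[k:(k+w-1)])
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Detect runs of homozygosity for one sample
#'
#' Applies the sliding-window procedure of [roh_params()] to one sample's
#' genotype track (which should be LD-pruned). Run coordinates are
#' SNV-delimited: span = first to last member SNV position. Chromosomes
#' with fewer SNVs than the window width cannot form windows and are
#' skipped with a warning.
#'
#' @param gm a [geno_matrix()] (typically subset to pruned sites).
#' @param sample a sample ID or index.
#' @param params a [roh_params()].
#' @return a `data.frame` of runs: `sample_id`, `chrom`, `start`, `end`,
#'   `n_snv`, `length` (= `end - start + 1`).
#' @export
detect_roh <- function(gm, sample, params = roh_params()) {
  si <- if (is.character(sample)) match(sample, gm$sample_ids) else sample
  if (is.na(si)) stop("unknown sample: ", sample)
  id <- gm$sample_ids[si]
  out <- list()
  for (ch in unique(gm$chrom)) {
    sel <- which(gm$chrom == ch)
    w <- params$window_snv
    if (length(sel) < w) {
      warning("chromosome ", ch, " has fewer than ", w, " SNVs; skipped")
      next
    }
    g <- gm$calls[si, sel]
    pos <- gm$pos[sel]
    nsnv <- length(g)
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    hom_win <- roll_sum(het, w) <= params$max_het_per_window &
      roll_sum(mis, w) <= params$max_miss_per_window
    # SNV i is covered by windows max(1, i-w+1) .. min(i, n_windows)
    n_win <- nsnv - w + 1L
    cw <- c(0, cumsum(as.integer(hom_win)))
    lo <- pmax(1L, seq_len(nsnv) - w + 1L)
    hi <- pmin(seq_len(nsnv), n_win)
    n_cov <- hi - lo + 1L
    n_hom <- cw[hi + 1L] - cw[lo]
    in_run <- n_hom / n_cov >= params$min_prop_hom_windows
    out[[ch]] <- segment_runs(id, ch, pos, in_run, params)
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(res))
    res <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snv = integer(), length = integer())
  rownames(res) <- NULL
  res
}

# split maximal in-run SNV stretches at gaps > max_gap_bp and apply the
# run-level count/length/density constraints
segment_runs <- function(id, ch, pos, in_run, params) {
  runs <- list()
  r <- rle(in_run)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts_i[k]:ends_i[k]
    p <- pos[idx]
    brk <- which(diff(p) > params$max_gap_bp)
    seg_start <- c(1L, brk + 1L)
    seg_end <- c(brk, length(p))
    for (s in seq_along(seg_start)) {
      pp <- p[seg_start[s]:seg_end[s]]
      n_snv <- length(pp)
      len <- pp[n_snv] - pp[1L] + 1L
      if (n_snv < params$min_snv_in_run) next
      if (len < params$min_length_bp) next
      if (n_snv / len < 1 / params$density_bp) next
      runs[[length(runs) + 1L]] <- data.frame(
        sample_id = id, chrom = ch, start = pp[1L], end = pp[n_snv],
        n_snv = n_snv, length = len)
    }
  }
  if (length(runs)) do.call(rbind, runs) else NULL
}

#' Detect ROH for every sample
#'
#' @param gm a [geno_matrix()].
#' @param params a [roh_params()].
#' @return a combined run `data.frame` (see [detect_roh()]).
#' @export
detect_roh_all <- function(gm, params = roh_params()) {
  res <- lapply(seq_len(n_samples(gm)), function(i)
    detect_roh(gm, i, params))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient FROH
#'
#' Fraction of the surveyed map covered by one individual's runs, where
#' the surveyed map length is the sum over chromosomes of (last SNV
#' position - first SNV position + 1) in the call set used for detection.
#'
#' @param runs run table for one sample (from [detect_roh()]).
#' @param gm the [geno_matrix()] the runs were detected on (defines the
#'   map).
#' @return FROH in `[0, 1]`.
#' @export
froh <- function(runs, gm) {
  if (n_sites(gm) == 0L) stop("empty SNV map")
  map_len <- sum(vapply(unique(gm$chrom), function(ch) {
    p <- gm$pos[gm$chrom == ch]
    max(p) - min(p) + 1L
  }, integer(1)))
  if (nrow(runs) == 0L) return(0)
  sum(as.numeric(runs$length)) / map_len
}

#' Per-SNV ROH sharing per cohort
#'
#' For each SNV and cohort, the proportion of cohort members whose
#' detected run covers the SNV position.
#'
#' @param runs combined run table (from [detect_roh_all()]).
#' @param gm the [geno_matrix()] defining SNV positions.
#' @param design a [cohort_design()].
#' @return a `data.frame`: `chrom`, `pos`, one proportion column per
#'   cohort label (`share_<label>`).
#' @export
roh_sharing <- function(runs, gm, design) {
  snv <- GenomicRanges::GRanges(gm$chrom,
                                IRanges::IRanges(gm$pos, gm$pos))
  out <- data.frame(chrom = gm$chrom, pos = gm$pos)
  for (lab in unique(design$cohort)) {
    members <- design_samples(design, lab)
    count <- integer(n_sites(gm))
    mruns <- runs[runs$sample_id %in% members, , drop = FALSE]
    if (nrow(mruns) > 0L) {
      rgr <- GenomicRanges::GRanges(mruns$chrom,
                                    IRanges::IRanges(mruns$start, mruns$end))
      ov <- GenomicRanges::findOverlaps(snv, rgr)
      # one individual may in principle contribute overlapping runs; count
      # distinct individuals per SNV
      q <- S4Vectors::queryHits(ov)
      s <- mruns$sample_id[S4Vectors::subjectHits(ov)]
      tab <- unique(data.frame(q = q, s = s))
      count <- tabulate(tab$q, nbins = n_sites(gm))
    }
    out[[paste0("share_", lab)]] <- count / length(members)
  }
  out
}

#' Cohort-differential candidate ROH regions
#'
#' Maximal stretches of consecutive SNVs whose case sharing exceeds `hi`
#' while every control cohort's sharing stays below `lo`. The design
#' default is 75%/75%; a separate, more permissive reporting threshold
#' (e.g. 70%) can be passed explicitly.
#'
#' @param track sharing track from [roh_sharing()].
#' @param case,controls cohort labels.
#' @param hi case-sharing threshold (strict `>`).
#' @param lo control-sharing threshold (strict `<`).
#' @return a `data.frame` of candidate intervals: `chrom`, `start`, `end`,
#'   `n_snv`, plus the mean sharing of each cohort over the stretch.
#' @export
candidate_roh <- function(track, case = "case",
                          controls = c("control_a", "control_b"),
                          hi = 0.75, lo = 0.75) {
  ok <- track[[paste0("share_", case)]] > hi
  for (ctl in controls)
    ok <- ok & track[[paste0("share_", ctl)]] < lo
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    flag <- ok[sel]
    pos <- track$pos[sel]
    r <- rle(flag)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- which(sel)[starts_i[k]:ends_i[k]]
      row <- data.frame(chrom = ch, start = pos[starts_i[k]],
                        end = pos[ends_i[k]],
                        n_snv = ends_i[k] - starts_i[k] + 1L)
      row[[paste0("share_", case)]] <-
        mean(track[[paste0("share_", case)]][idx])
      for (ctl in controls)
        row[[paste0("share_", ctl)]] <-
          mean(track[[paste0("share_", ctl)]][idx])
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snv = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
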