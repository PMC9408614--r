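#' Synthetic cohort configuration
#'
#' Describes a two-island case/control study to simulate. Defaults emulate
#' the motivating design: 12 carcinoma cases and 11 tumor-free controls
#' from one island, 9 controls from a second, diverged island, sequenced
#' to ~10x with genotype-quality fields, with a handful of planted
#' case-differentiated loci and planted autozygous tracts.
#'
#' Island allele frequencies derive from a shared ancestral frequency via
#' the Balding-Nichols beta model with drift parameter `island_divergence`
#' (F): island frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F). Cases and
#' same-island controls share island-A frequencies except at the
#' `n_causal` planted loci, where the case frequency is shifted so that
#' `|p_case - p_control_a| = causal_delta`; the second island follows its
#' own frequencies everywhere.
#'
#' @param n_case,n_control_a,n_control_b cohort sizes (12 / 11 / 9).
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_sites total SNV count, split evenly across chromosomes.
#' @param island_divergence Balding-Nichols F >= 0 (0 = panmixia).
#' @param n_causal number of planted case-vs-control differentiated loci.
#' @param causal_delta target case-minus-control frequency shift in [0,1].
#' @param causal_width_bp footprint of a planted locus in bp (default
#'   50 kb, on the order of the LD decay scale of small island
#'   populations): all sites within `causal_width_bp / 2` of the focal SNV
#'   are shifted in the same direction, clamped to [0, 1], emulating the
#'   hitchhiking footprint a selected haplotype leaves; the focal SNV
#'   itself attains `causal_delta` exactly. Set to 0 to shift single SNVs
#'   only.
#' @param roh_planted `data.frame` with columns `cohort`, `chrom`, `start`,
#'   `end`, `carrier_frac` describing autozygous tracts to plant, or `NULL`.
#' @param missing_rate per-call missingness probability.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param seed integer seed; fixed seed gives byte-identical artifacts.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_case = 12L, n_control_a = 11L, n_control_b = 9L,
                       n_chrom = 2L, chrom_length = 5000000L,
                       n_sites = 5000L, island_divergence = 0.1,
                       n_causal = 0L, causal_delta = 0.6,
                       causal_width_bp = 50000L,
                       roh_planted = NULL, missing_rate = 0.02,
                       mean_depth = 10, seed = 1L) {
  stopifnot(n_case > 0, n_control_a > 0, n_control_b > 0, n_chrom > 0,
            chrom_length > 0, n_sites > 0, island_divergence >= 0,
            n_causal >= 0, causal_delta >= 0, causal_delta <= 1,
            causal_width_bp >= 0,
            missing_rate >= 0, missing_rate < 1, mean_depth > 0)
  if (!is.null(roh_planted)) {
    stopifnot(all(c("cohort", "chrom", "start", "end", "carrier_frac") %in%
                    names(roh_planted)),
              all(roh_planted$start >= 1),
              all(roh_planted$end <= chrom_length),
              all(roh_planted$start < roh_planted$end))
  }
  structure(list(n_case = as.integer(n_case),
                 n_control_a = as.integer(n_control_a),
                 n_control_b = as.integer(n_control_b),
                 n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 n_sites = as.integer(n_sites),
                 island_divergence = island_divergence,
                 n_causal = as.integer(n_causal),
                 causal_delta = causal_delta,
                 causal_width_bp = as.integer(causal_width_bp),
                 roh_planted = roh_planted,
                 missing_rate = missing_rate,
                 mean_depth = mean_depth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_bn <- function(n, p, F) {
  if (F <= 0) return(rep(p, length.out = n))
  stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a two-island case/control cohort study
#'
#' Draws ancestral allele frequencies from Uniform(0.05, 0.95), island
#' frequencies via Balding-Nichols drift, genotypes as Binomial(2, p) per
#' cohort frequency, plants causal frequency shifts and autozygous tracts,
#' then overlays per-call depth (Poisson) and genotype quality
#' (`GQ = min(99, round(10 DP / 3))`, monotone in depth) and injects
#' missingness. Deterministic given `config$seed`.
#'
#' Causal loci are chosen among island-A sites where the `causal_delta`
#' shift is feasible (shifted frequency within [0, 1]); ancestral
#' frequencies are redrawn a bounded number of times otherwise.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_study`: `gm` (a [geno_matrix()]), `design`
#'   (a [cohort_design()]), `truth` (list with `causal` and `roh`
#'   tables), and `tracks` (list of `genes`, `tfbs`, `neutral` interval
#'   tracks, 1-based inclusive).
#' @export
simulate_study <- function(config) {
  set.seed(config$seed)
  nA <- config$n_case + config$n_control_a
  n_all <- nA + config$n_control_b
  ids <- sprintf("F%02d", seq_len(n_all))
  design <- cohort_design(ids, c(rep("case", config$n_case),
                                 rep("control_a", config$n_control_a),
                                 rep("control_b", config$n_control_b)))
  # site positions: uniform without replacement per chromosome, sorted
  per_chrom <- rep(config$n_sites %/% config$n_chrom, config$n_chrom)
  extra <- config$n_sites %% config$n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  chrom <- rep(chroms, per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    sort(sample.int(config$chrom_length, m))), use.names = FALSE)
  n_sites <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  # allele frequencies
  F <- config$island_divergence
  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  pA <- rbeta_bn(n_sites, p_anc, F)
  pB <- rbeta_bn(n_sites, p_anc, F)
  p_case <- pA
  causal <- NULL
  if (config$n_causal > 0) {
    d <- config$causal_delta
    feasible <- pA + d <= 1 | pA - d >= 0
    for (tries in 1:50) {
      if (sum(feasible) >= config$n_causal) break
      redraw <- which(!feasible)
      p_anc[redraw] <- stats::runif(length(redraw), 0.05, 0.95)
      pA[redraw] <- rbeta_bn(length(redraw), p_anc[redraw], F)
      p_case[redraw] <- pA[redraw]
      feasible <- pA + d <= 1 | pA - d >= 0
    }
    if (sum(feasible) < config$n_causal)
      stop("causal_delta infeasible at too many sites after bounded retries")
    loci <- sort(sample(which(feasible), config$n_causal))
    up <- pA[loci] + d <= 1
    # where both directions fit, shift away from the nearer boundary
    both <- up & (pA[loci] - d >= 0)
    up[both] <- pA[loci][both] <= 0.5
    p_case[loci] <- ifelse(up, pA[loci] + d, pA[loci] - d)
    # hitchhiking footprint: neighbors within the causal width shift in
    # the focal direction, clamped to [0, 1]; the focal SNV is exact
    half <- config$causal_width_bp / 2
    if (half > 0) {
      for (k in seq_along(loci)) {
        nb <- which(chrom == chrom[loci[k]] &
                      abs(pos - pos[loci[k]]) <= half)
        nb <- setdiff(nb, loci)
        p_case[nb] <- if (up[k]) pmin(1, pA[nb] + d) else pmax(0, pA[nb] - d)
      }
    }
    causal <- data.frame(chrom = chrom[loci], pos = pos[loci],
                         p_case = p_case[loci], p_control_a = pA[loci],
                         p_control_b = pB[loci])
  }
  # genotypes: Binomial(2, p) by cohort
  draw <- function(n_ind, p) matrix(stats::rbinom(n_ind * n_sites, 2L,
                                                  rep(p, each = n_ind)),
                                    nrow = n_ind)
  calls <- rbind(draw(config$n_case, p_case),
                 draw(config$n_control_a, pA),
                 draw(config$n_control_b, pB))
  # plant autozygous tracts: carriers become homozygous across the tract,
  # drawing the homozygous allele from the island frequency so tracts look
  # autozygous, not artificially fixed
  roh_truth <- NULL
  if (!is.null(config$roh_planted)) {
    rows <- list()
    for (k in seq_len(nrow(config$roh_planted))) {
      tr <- config$roh_planted[k, ]
      members <- design_samples(design, tr$cohort)
      n_car <- max(1L, round(tr$carrier_frac * length(members)))
      carriers <- sort(sample(members, n_car))
      sel <- which(chrom == tr$chrom & pos >= tr$start & pos <= tr$end)
      p_isl <- if (tr$cohort == "control_b") pB[sel] else pA[sel]
      for (cid in carriers) {
        i <- match(cid, ids)
        calls[i, sel] <- 2L * stats::rbinom(length(sel), 1L, p_isl)
      }
      rows[[k]] <- data.frame(cohort = tr$cohort, chrom = tr$chrom,
                              start = tr$start, end = tr$end,
                              carriers = paste(carriers, collapse = ","))
    }
    roh_truth <- do.call(rbind, rows)
  }
  # sequencing overlay
  depth <- matrix(stats::rpois(n_all * n_sites, config$mean_depth),
                  nrow = n_all)
  gq <- depth
  gq[] <- pmin(99L, as.integer(round(10 * depth / 3)))
  miss <- matrix(stats::runif(n_all * n_sites) < config$missing_rate,
                 nrow = n_all)
  calls[miss] <- NA_integer_
  clen <- stats::setNames(rep(config$chrom_length, config$n_chrom), chroms)
  gm <- geno_matrix(calls, chrom, pos, ref, alt, sample_ids = ids,
                    depth = depth, gq = gq, chrom_lengths = clen)
  tracks <- sim_tracks(config, chroms)
  structure(list(gm = gm, design = design,
                 truth = list(causal = causal, roh = roh_truth),
                 tracks = tracks),
            class = "sim_study")
}

# simple seeded interval tracks: non-overlapping "genes" tiling ~30% of
# each chromosome, short "TFBS" intervals near gene starts, and "neutral"
# intergenic intervals
sim_tracks <- function(config, chroms) {
  genes <- list(); tfbs <- list(); neutral <- list()
  L <- config$chrom_length
  gene_len <- 20000L
  gap <- 50000L
  for (ch in chroms) {
    starts <- seq.int(gap, L - gene_len, by = gene_len + gap)
    g <- data.frame(chrom = ch, start = starts, end = starts + gene_len - 1L,
                    name = sprintf("%s_gene%03d", ch, seq_along(starts)))
    t <- data.frame(chrom = ch, start = pmax(1L, starts - 500L),
                    end = pmax(1L, starts - 500L) + 99L,
                    name = sprintf("%s_tfbs%03d", ch, seq_along(starts)))
    nstart <- g$end[-nrow(g)] + 10000L
    nend <- g$start[-1L] - 10000L
    n <- data.frame(chrom = ch, start = nstart, end = nend,
                    name = sprintf("%s_neut%03d", ch,
                                   seq_along(nstart)))
    genes[[ch]] <- g; tfbs[[ch]] <- t; neutral[[ch]] <- n[n$end > n$start, ]
  }
  list(genes = do.call(rbind, genes), tfbs = do.call(rbind, tfbs),
       neutral = do.call(rbind, neutral))
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:\n  ")
  print(x$gm)
  cat(sprintf("  cohorts: %s\n",
              paste(names(table(x$design$cohort)),
                    table(x$design$cohort), sep = "=", collapse = ", ")))
  cat(sprintf("  planted causal loci: %d; planted ROH tracts: %d\n",
              if (is.null(x$truth$causal)) 0L else nrow(x$truth$causal),
              if (is.null(x$truth$roh)) 0L else nrow(x$truth$roh)))
  invisible(x)
}

#' Write/read the simulation truth table
#'
#' Two-section TSV: causal-locus rows (`type = "causal"`) with cohort-wise
#' generating frequencies, and planted-ROH rows (`type = "roh"`) with the
#' interval and comma-separated carrier list. Round-trips exactly.
#'
#' @param truth the `truth` element of a `sim_study`.
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("type", "cohort", "chrom", "pos", "start", "end",
            "p_case", "p_control_a", "p_control_b", "carriers")
  empty <- function() {
    d <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                       cols))
    d
  }
  rows <- empty()
  if (!is.null(truth$causal) && nrow(truth$causal) > 0) {
    c <- truth$causal
    rows <- rbind(rows, data.frame(
      type = "causal", cohort = NA, chrom = c$chrom, pos = c$pos,
      start = NA, end = NA, p_case = c$p_case,
      p_control_a = c$p_control_a, p_control_b = c$p_control_b,
      carriers = NA))
  }
  if (!is.null(truth$roh) && nrow(truth$roh) > 0) {
    r <- truth$roh
    rows <- rbind(rows, data.frame(
      type = "roh", cohort = r$cohort, chrom = r$chrom, pos = NA,
      start = r$start, end = r$end, p_case = NA, p_control_a = NA,
      p_control_b = NA, carriers = r$carriers))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth`: a list with `causal` and `roh` tables (`NULL`
#'   when absent).
#' @export
read_truth <- function(path) {
  d <- utils::read.delim(path, colClasses = c(
    type = "character", cohort = "character", chrom = "character",
    pos = "integer", start = "integer", end = "integer",
    p_case = "numeric", p_control_a = "numeric", p_control_b = "numeric",
    carriers = "character"))
  causal <- d[d$type == "causal",
              c("chrom", "pos", "p_case", "p_control_a", "p_control_b")]
  roh <- d[d$type == "roh", c("cohort", "chrom", "start", "end", "carriers")]
  rownames(causal) <- NULL; rownames(roh) <- NULL
  list(causal = if (nrow(causal)) causal else NULL,
       roh = if (nrow(roh)) roh else NULL)
}

#' Write all simulation artifacts to a directory
#'
#' Emits `cohort.vcf`, `design.tsv`, `truth.tsv`, and `genes.bed`,
#' `tfbs.bed`, `neutral.bed` under `dir`.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(study$gm, file.path(dir, "cohort.vcf"))
  write_design(study$design, file.path(dir, "design.tsv"))
  write_truth(study$truth, file.path(dir, "truth.tsv"))
  write_bed(study$tracks$genes, file.path(dir, "genes.bed"))
  write_bed(study$tracks$tfbs, file.path(dir, "tfbs.bed"))
  write_bed(study$tracks$neutral, file.path(dir, "neutral.bed"))
  invisible(dir)
}
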