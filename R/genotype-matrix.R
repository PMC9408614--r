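#' Genotype matrix container
#'
#' `geno_matrix` holds diploid genotype calls for biallelic SNVs as a
#' samples-by-sites integer matrix of alternate-allele dosages (0, 1, 2, or
#' `NA` for missing), together with per-site metadata (chromosome, 1-based
#' position, reference and alternate base) and optional per-call depth and
#' genotype-quality matrices of the same shape.
#'
#' Sites must be strictly increasing in position within each chromosome and
#' ref must differ from alt at every site. Chromosome lengths, when known
#' (e.g. from a simulation), are carried in `chrom_lengths` and used to tile
#' windows; otherwise the last site position per chromosome is used.
#'
#' @param calls integer matrix, samples x sites, values in `c(0:2, NA)`.
#' @param chrom character vector of site chromosomes (length = n sites).
#' @param pos integer vector of 1-based site positions.
#' @param ref,alt single-character ref/alt bases per site.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   rownames of `calls`.
#' @param depth,gq optional integer matrices, same shape as `calls`.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @param ancestral_is_ref logical per-site flag set by [polarize()].
#' @return an object of class `geno_matrix`.
#' @seealso [read_vcf()], [filter_genotypes()], [polarize()]
#' @export
geno_matrix <- function(calls, chrom, pos, ref, alt,
                        sample_ids = rownames(calls),
                        depth = NULL, gq = NULL,
                        chrom_lengths = NULL,
                        ancestral_is_ref = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_samp <- nrow(calls)
  n_site <- ncol(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samp))
  stopifnot(
    length(sample_ids) == n_samp,
    length(chrom) == n_site, length(pos) == n_site,
    length(ref) == n_site, length(alt) == n_site
  )
  if (any(!is.na(calls) & (calls < 0L | calls > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  if (n_site > 1L) {
    same <- chrom[-1L] == chrom[-n_site]
    if (any(same & pos[-1L] <= pos[-n_site]))
      stop("positions must be strictly increasing within each chromosome")
  }
  if (any(ref == alt)) stop("ref must differ from alt at every site")
  chk_mat <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (!identical(dim(m), dim(calls)))
      stop(what, " must have the same dimensions as calls")
    if (any(m < 0L, na.rm = TRUE)) stop(what, " must be non-negative")
    m
  }
  if (is.null(ancestral_is_ref)) ancestral_is_ref <- rep(NA, n_site)
  dimnames(calls) <- NULL
  structure(list(
    sample_ids = as.character(sample_ids),
    chrom = chrom, pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    calls = calls,
    depth = chk_mat(depth, "depth"),
    gq = chk_mat(gq, "gq"),
    chrom_lengths = chrom_lengths,
    ancestral_is_ref = as.logical(ancestral_is_ref)
  ), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %d chromosome(s)\n",
              n_samples(x), n_sites(x), length(unique(x$chrom))))
  cat(sprintf("  missing calls: %.2f%%", 100 * mean(is.na(x$calls))))
  if (!is.null(x$depth)) cat(sprintf(" | mean depth: %.1f", mean(x$depth, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm a `geno_matrix`.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname geno_matrix
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix
#'
#' @param gm a `geno_matrix`.
#' @param samples sample index, logical mask, or character IDs.
#' @param sites site index or logical mask (site order is preserved).
#' @return a `geno_matrix` restricted to the requested samples/sites.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  si <- seq_len(n_samples(gm))
  vi <- seq_len(n_sites(gm))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  if (!is.null(sites)) vi <- vi[sites]
  geno_matrix(
    calls = gm$calls[si, vi, drop = FALSE],
    chrom = gm$chrom[vi], pos = gm$pos[vi],
    ref = gm$ref[vi], alt = gm$alt[vi],
    sample_ids = gm$sample_ids[si],
    depth = if (!is.null(gm$depth)) gm$depth[si, vi, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[si, vi, drop = FALSE],
    chrom_lengths = gm$chrom_lengths,
    ancestral_is_ref = gm$ancestral_is_ref[vi]
  )
}

#' Per-site alternate-allele counts and frequencies
#'
#' Counts are over called alleles only: a site with `k` called diploid
#' genotypes contributes `2k` alleles.
#'
#' @param gm a `geno_matrix`.
#' @param samples optional sample subset (passed to [gm_subset()] semantics).
#' @return a `data.frame` with columns `chrom`, `pos`, `alt_count`
#'   (alternate-allele count), `n_called` (called alleles) and `af`
#'   (alternate-allele frequency, `NaN` where nothing is called).
#' @export
allele_counts <- function(gm, samples = NULL) {
  calls <- gm$calls
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$sample_ids) else samples
    calls <- calls[si, , drop = FALSE]
  }
  alt_count <- colSums(calls, na.rm = TRUE)
  n_called <- 2L * colSums(!is.na(calls))
  data.frame(
    chrom = gm$chrom, pos = gm$pos,
    alt_count = alt_count, n_called = n_called,
    af = alt_count / n_called
  )
}

#' Cohort design: sample-to-cohort mapping
#'
#' @param sample_ids character vector of sample IDs.
#' @param cohort character vector of cohort labels, conventionally
#'   `"case"`, `"control_a"` (same-island controls) and `"control_b"`
#'   (second-island controls).
#' @return a `data.frame` of class `cohort_design`.
#' @export
cohort_design <- function(sample_ids, cohort) {
  stopifnot(length(sample_ids) == length(cohort), !anyDuplicated(sample_ids))
  structure(
    data.frame(sample_id = as.character(sample_ids),
               cohort = as.character(cohort),
               stringsAsFactors = FALSE),
    class = c("cohort_design", "data.frame")
  )
}

#' @rdname cohort_design
#' @param design a `cohort_design`.
#' @param label a cohort label (or vector of labels, pooled).
#' @return `design_samples`: the sample IDs belonging to `label`.
#' @export
design_samples <- function(design, label) {
  out <- design$sample_id[design$cohort %in% label]
  if (length(out) == 0L) stop("no samples with cohort label: ",
                              paste(label, collapse = ", "))
  out
}

#' Read/write a cohort design TSV (columns sample_id, cohort)
#' @param path file path.
#' @return `read_design`: a `cohort_design`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  cohort_design(d$sample_id, d$cohort)
}

#' @rdname read_design
#' @param design a `cohort_design`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
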