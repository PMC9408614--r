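#' Read a VCF into a genotype matrix
#'
#' Reads a VCF 4.x file (plain text or bgzipped) of biallelic SNVs with a
#' `GT` FORMAT field and optional `DP` and `GQ` fields. Records that are not
#' biallelic SNVs (multi-allelic sites, indels, symbolic alleles) are skipped
#' and counted. Half-missing diploid genotypes (e.g. `./1`) are treated as
#' missing, as are any ploidy other than 2.
#'
#' @param path path to a VCF file.
#' @return a [geno_matrix()]; the number of skipped non-SNV records is
#'   attached as attribute `"skipped"`.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  keep <- lengths(altl) == 1L & nchar(ref) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[keep] <- vapply(altl[keep], function(a) as.character(a[1L]), "")
  keep <- keep & !is.na(alt) & nchar(alt) == 1L & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  if (skipped > 0L)
    message("read_vcf: skipped ", skipped, " non-biallelic-SNV record(s)")
  vcf <- vcf[keep]
  rr <- rr[keep]
  gt <- VariantAnnotation::geno(vcf)$GT  # sites x samples, character
  calls <- gt_to_dosage(gt)              # sites x samples, integer
  g <- VariantAnnotation::geno(vcf)
  grab <- function(field) {
    if (!field %in% names(g)) return(NULL)
    m <- g[[field]]
    storage.mode(m) <- "integer"
    m[is.na(m)] <- 0L
    t(m)
  }
  gm <- geno_matrix(
    calls = t(calls),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref[keep], alt = alt[keep],
    sample_ids = colnames(gt),
    depth = grab("DP"), gq = grab("GQ")
  )
  attr(gm, "skipped") <- skipped
  gm
}

# "0/0"-style diploid GT strings -> dosage; anything not two called alleles -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]", perl = TRUE)[[1L]]
    if (length(al) != 2L || any(al == ".") || anyNA(suppressWarnings(as.integer(al))))
      return(NA_integer_)
    sum(as.integer(al) > 0L)
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic SNV record per site with FORMAT `GT:DP:GQ` (or just
#' `GT` when depth/quality are absent). Missing calls are written `./.` with
#' missing DP/GQ. Output is deterministic given the same matrix, so repeated
#' simulation under one seed yields byte-identical files.
#'
#' @param gm a [geno_matrix()].
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n_site <- n_sites(gm)
  gt_str <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
  gt_str[is.na(gt_str)] <- "./."
  dim(gt_str) <- dim(gm$calls)
  fmt_int <- function(m) {
    s <- as.character(m)
    s[is.na(m) | is.na(gm$calls)] <- "."
    dim(s) <- dim(m)
    s
  }
  if (!is.null(gm$depth) && !is.null(gm$gq)) {
    format_id <- "GT:DP:GQ"
    body <- matrix(paste(t(gt_str), t(fmt_int(gm$depth)), t(fmt_int(gm$gq)),
                         sep = ":"),
                   nrow = n_site)
  } else {
    format_id <- "GT"
    body <- t(gt_str)
  }
  chroms <- unique(gm$chrom)
  clen <- gm$chrom_lengths
  contig <- if (is.null(clen)) {
    sprintf("##contig=<ID=%s>", chroms)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(clen[chroms]))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ccscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (format_id != "GT") c(
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
    contig,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  fixed <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", ".", ".",
                 format_id, sep = "\t")
  lines <- c(header, paste(fixed, apply(body, 1L, paste, collapse = "\t"),
                           sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write BED interval tracks
#'
#' BED uses 0-based half-open coordinates; these helpers centralize the
#' conversion to the 1-based inclusive convention used everywhere else in
#' the package.
#'
#' @param path BED file path (3+ columns; column 4, when present, is the
#'   feature name).
#' @return `read_bed`: a `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) and `name`.
#' @export
read_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(b) < 3L) stop("BED file needs at least 3 columns")
  data.frame(
    chrom = as.character(b[[1L]]),
    start = as.integer(b[[2L]]) + 1L,
    end = as.integer(b[[3L]]),
    name = if (ncol(b) >= 4L) as.character(b[[4L]]) else
      paste0("feature", seq_len(nrow(b))),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_bed
#' @param track a `data.frame` with 1-based inclusive `chrom`, `start`,
#'   `end` and optionally `name`.
#' @export
write_bed <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(track)))
  out <- data.frame(track$chrom, as.integer(track$start) - 1L,
                    as.integer(track$end))
  if (!is.null(track$name)) out$name <- track$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 1-based inclusive data.frame track -> GRanges
track_to_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start, end = track$end),
    name = if (!is.null(track$name)) track$name else NA_character_
  )
}
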