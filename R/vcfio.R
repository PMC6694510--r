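#' Read founder genotypes from a VCF
#'
#' Reads diploid GT calls for the pedigree founders from a (multi-sample)
#' VCF. Only biallelic SNPs are kept; multi-allelic records and records
#' whose REF/ALT are not single nucleotides are dropped with a counter.
#' Genotypes are converted to alternative-allele dose irrespective of
#' phasing separator. Per-site `AC` is taken from INFO when present,
#' otherwise computed from the genotypes.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param founder_ids optional character vector restricting/ordering the
#'   sample columns; an id absent from the file is an error.
#' @return A [founder_set()] with attribute `n_dropped_multiallelic`.
#' @export
read_founder_vcf <- function(path, founder_ids = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(founder_ids)) {
    absent <- setdiff(founder_ids, colnames(gt))
    if (length(absent)) {
      stop("founder id(s) absent from VCF: ", paste(absent, collapse = ", "))
    }
    gt <- gt[, founder_ids, drop = FALSE]
  }
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(!biallelic)
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]

  dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  core <- sub(":.*", "", gt)
  dose[core %in% c("0/0", "0|0")] <- 0L
  dose[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[core %in% c("1/1", "1|1")] <- 2L

  info_ac <- suppressWarnings(
    as.integer(sub(".*AC=([0-9]+).*", "\\1", fix$INFO)))
  info_ac[!grepl("AC=", fix$INFO)] <- NA_integer_
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      stringsAsFactors = FALSE)
  if (any(!is.na(info_ac))) {
    sites$ac <- ifelse(is.na(info_ac),
                       rowSums(dose, na.rm = TRUE), info_ac)
  }
  out <- founder_set(sites, dose)
  attr(out, "n_dropped_multiallelic") <- n_dropped
  out
}

#' Write founder genotypes as an uncompressed VCF
#'
#' Emits a minimal VCFv4.2 file with QUAL, `INFO AC;AN` and per-founder GT
#' fields -- the dialect [read_founder_vcf()] consumes.
#'
#' @param fs a [founder_set()].
#' @param path output path.
#' @param header_lines optional extra `##` header lines (without `##`).
#' @export
write_founder_vcf <- function(fs, path, header_lines = NULL) {
  stopifnot(inherits(fs, "founder_set"))
  s <- fs$sites
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(fs$geno), ncol(fs$geno))
  ok <- !is.na(fs$geno)
  gt[ok] <- gt_code[as.character(fs$geno[ok])]
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                format(s$qual, trim = TRUE, scientific = FALSE),
                "PASS", paste0("AC=", s$ac, ";AN=", s$an), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(header_lines)) paste0("##", header_lines),
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(fs$geno)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-sample allele depths for offspring from a VCF
#'
#' Extracts the per-sample allele-depth (`AD`) field from a multi-sample
#' VCF into the long depth table consumed by [extract_depths()]. Records
#' with a malformed AD entry for a sample are skipped for that sample and
#' counted.
#'
#' @param path path to a VCF carrying a FORMAT `AD` field.
#' @return data.frame `chrom pos sample n_ref n_alt` with attributes
#'   `samples` and `n_malformed`.
#' @export
read_offspring_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  n <- nrow(ad)
  long <- data.frame(
    chrom = rep(fix$CHROM, times = length(samples)),
    pos = rep(as.integer(fix$POS), times = length(samples)),
    sample = rep(samples, each = n),
    ad = as.vector(ad), stringsAsFactors = FALSE)
  parts <- strsplit(long$ad, ",", fixed = TRUE)
  two <- lengths(parts) == 2
  long$n_ref <- suppressWarnings(
    as.integer(vapply(parts, `[`, "", 1)))
  long$n_alt <- suppressWarnings(
    as.integer(ifelse(two, vapply(parts, function(p) p[2], ""), NA)))
  missing_ad <- is.na(long$ad) | long$ad %in% c(".", "./.")
  ok <- !missing_ad & !is.na(long$n_ref) & !is.na(long$n_alt)
  n_malformed <- sum(!ok & !missing_ad)
  out <- long[ok, c("chrom", "pos", "sample", "n_ref", "n_alt")]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Write offspring allele depths as an uncompressed multi-sample VCF
#'
#' Sites form the union over samples; a sample without data at a site is
#' emitted as `.` (no depth information).
#'
#' @param depths data.frame `chrom pos ref alt sample n_ref n_alt`.
#' @param path output path.
#' @param samples optional sample ordering (default: sorted unique).
#' @param header_lines optional extra `##` header lines (without `##`).
#' @export
write_offspring_vcf <- function(depths, path, samples = NULL,
                                header_lines = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample",
                  "n_ref", "n_alt") %in% names(depths)))
  if (is.null(samples)) samples <- sort(unique(depths$sample))
  sites <- unique(depths[, c("chrom", "pos", "ref", "alt")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  key <- paste(sites$chrom, sites$pos)
  ad <- matrix(".", nrow(sites), length(samples),
               dimnames = list(NULL, samples))
  i <- match(paste(depths$chrom, depths$pos), key)
  j <- match(depths$sample, samples)
  ad[cbind(i, j)] <- paste0(depths$n_ref, ",", depths$n_alt)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "AD",
                apply(ad, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(header_lines)) paste0("##", header_lines),
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plain site-by-individual depth table
#'
#' TSV dialect `chrom pos sample n_ref n_alt`, the tabular alternative to
#' a VCF with AD fields.
#'
#' @param path file path.
#' @return data.frame with attribute `samples`.
#' @export
read_depth_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("chrom", "pos", "sample", "n_ref", "n_alt") %in% names(x)))
  x$chrom <- as.character(x$chrom)
  x$sample <- as.character(x$sample)
  attr(x, "samples") <- unique(x$sample)
  x
}
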