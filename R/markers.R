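#' Founder genotype set
#'
#' Container for biallelic founder variant sites and diploid genotype
#' calls. Genotypes are stored as alternative-allele dose (0 = hom ref,
#' 1 = het, 2 = hom alt, `NA` = missing), one column per founder.
#'
#' Per-site `AC` (alternative allele count), `AN` (called allele number)
#' and `MAF` are computed jointly across all founders in the set unless
#' already supplied (e.g. from VCF INFO).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual` and optionally `ac`, `an`.
#' @param geno integer matrix, sites x founders, with founder ids as
#'   column names; values in `{0, 1, 2, NA}`.
#' @return A `founder_set` list with `sites` (including `ac`, `an`, `maf`)
#'   and `geno`.
#' @export
founder_set <- function(sites, geno) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites),
            !is.null(colnames(geno)))
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotype doses must be 0, 1, 2 or NA")
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in founder sites")
  }
  an_obs <- 2L * rowSums(!is.na(geno))
  ac_obs <- rowSums(geno, na.rm = TRUE)
  if (is.null(sites$ac)) sites$ac <- ac_obs
  if (is.null(sites$an)) sites$an <- an_obs
  p <- ifelse(an_obs > 0, ac_obs / an_obs, NA_real_)
  sites$maf <- pmin(p, 1 - p)
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno), class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("founder_set: ", nrow(x$sites), " sites x ", ncol(x$geno),
      " founders\n", sep = "")
  invisible(x)
}

#' Founder variant filter thresholds
#'
#' Defaults keep a site only when its minor allele frequency, alternative
#' allele count and variant quality all clear the strict thresholds
#' MAF > 0.043, AC > 5 and QUAL > 30 used for the founder call set.
#'
#' @param min_maf exclusive MAF threshold in `[0, 0.5]`.
#' @param min_ac exclusive alternative-allele-count threshold.
#' @param min_qual exclusive QUAL threshold.
#' @return A `founder_filter_config` list.
#' @export
founder_filter_config <- function(min_maf = 0.043, min_ac = 5,
                                  min_qual = 30) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  structure(list(min_maf = min_maf, min_ac = min_ac, min_qual = min_qual),
            class = "founder_filter_config")
}

#' Filter founder variants on MAF, AC and QUAL
#'
#' Retains exactly the sites with `MAF > min_maf` and `AC > min_ac` and
#' `QUAL > min_qual` (all strict inequalities). Sites with all founder
#' genotypes missing are excluded and counted, not an error.
#'
#' @param fs a [founder_set()].
#' @param cfg a [founder_filter_config()].
#' @return The filtered `founder_set`, with attribute `filter_log`: counts
#'   of input sites, sites failing each criterion, all-missing sites, and
#'   sites kept.
#' @export
filter_founder_variants <- function(fs, cfg = founder_filter_config()) {
  stopifnot(inherits(fs, "founder_set"))
  s <- fs$sites
  all_missing <- s$an == 0 | is.na(s$maf)
  fail_maf <- !all_missing & !(s$maf > cfg$min_maf)
  fail_ac <- !(s$ac > cfg$min_ac)
  fail_qual <- !(s$qual > cfg$min_qual)
  keep <- !all_missing & !fail_maf & !fail_ac & !fail_qual
  out <- founder_set(s[keep, setdiff(names(s), "maf"), drop = FALSE],
                     fs$geno[keep, , drop = FALSE])
  attr(out, "filter_log") <- c(
    n_input = nrow(s), n_all_missing = sum(all_missing),
    n_fail_maf = sum(fail_maf), n_fail_ac = sum(fail_ac),
    n_fail_qual = sum(fail_qual), n_kept = sum(keep))
  out
}

#' Select markers informative for line origin within one family
#'
#' A site is informative for a family when its four F0 grandparents are
#' fixed for alternative alleles between the lines: both H founders share
#' one homozygous genotype, both L founders share the homozygous genotype
#' for the other allele, and none of the four calls is missing or
#' heterozygous. Any read from the F2 at such a marker reveals founder-line
#' origin. The allele carried by the H line (`h_allele`, `"ref"` or
#' `"alt"`) is recorded so that downstream read counts can be polarized.
#'
#' @param fs a [founder_set()] holding genotypes for (at least) the four
#'   founders of the family.
#' @param family a [nuclear_family()].
#' @return A `marker_set`: data.frame `chrom pos ref alt h_allele`, sorted
#'   by `chrom` then `pos`, with attribute `family_id`.
#' @export
select_family_informative <- function(fs, family) {
  stopifnot(inherits(fs, "founder_set"), inherits(family, "nuclear_family"))
  ids <- c(family$f0_h, family$f0_l)
  absent <- setdiff(ids, colnames(fs$geno))
  if (length(absent)) {
    stop("no genotype data for founder(s): ", paste(absent, collapse = ", "))
  }
  g <- fs$geno[, ids, drop = FALSE]
  h1 <- g[, 1]; h2 <- g[, 2]; l1 <- g[, 3]; l2 <- g[, 4]
  complete <- !is.na(h1) & !is.na(h2) & !is.na(l1) & !is.na(l2)
  h_ref <- complete & h1 == 0 & h2 == 0 & l1 == 2 & l2 == 2
  h_alt <- complete & h1 == 2 & h2 == 2 & l1 == 0 & l2 == 0
  keep <- h_ref | h_alt
  m <- fs$sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  m$h_allele <- ifelse(h_ref[keep], "ref", "alt")
  rownames(m) <- NULL
  structure(m, class = c("marker_set", "data.frame"),
            family_id = family$family_id)
}

#' Select line-level informative markers from pooled founders
#'
#' Alternative selection mode for the pooled-founder sequencing strategy:
#' a site is informative at the line level when one allele has frequency
#' at least `1 - delta` among the H-line founders and at most `delta`
#' among the L-line founders. With the default `delta = 0` the two lines
#' must be strictly fixed for alternative alleles. Sites where either line
#' has no called genotype are skipped.
#'
#' @param fs a [founder_set()].
#' @param h_ids,l_ids founder ids belonging to the H and L line.
#' @param delta tolerated departure from fixation in `[0, 0.5)`.
#' @return A `marker_set` with attribute `family_id = "pooled"`.
#' @export
select_pooled_informative <- function(fs, h_ids, l_ids, delta = 0) {
  stopifnot(inherits(fs, "founder_set"), delta >= 0, delta < 0.5)
  if (!length(h_ids) || !length(l_ids)) {
    stop("need at least one genotyped founder per line")
  }
  absent <- setdiff(c(h_ids, l_ids), colnames(fs$geno))
  if (length(absent)) {
    stop("no genotype data for founder(s): ", paste(absent, collapse = ", "))
  }
  gh <- fs$geno[, h_ids, drop = FALSE]
  gl <- fs$geno[, l_ids, drop = FALSE]
  nh <- rowSums(!is.na(gh)); nl <- rowSums(!is.na(gl))
  p_h <- rowSums(gh, na.rm = TRUE) / (2 * nh)  # alt freq in H line
  p_l <- rowSums(gl, na.rm = TRUE) / (2 * nl)
  ok <- nh > 0 & nl > 0
  h_alt <- ok & p_h >= 1 - delta & p_l <= delta
  h_ref <- ok & (1 - p_h) >= 1 - delta & (1 - p_l) <= delta
  keep <- h_alt | h_ref
  m <- fs$sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  m$h_allele <- ifelse(h_alt[keep], "alt", "ref")
  rownames(m) <- NULL
  structure(m, class = c("marker_set", "data.frame"), family_id = "pooled")
}

#' Write / read a per-family informative marker table
#'
#' TSV dialect `chrom pos ref alt h_allele`, optionally preceded by `#`
#' comment lines.
#'
#' @param markers a `marker_set`.
#' @param path file path.
#' @param header_lines optional comment lines (without leading `#`).
#' @export
write_marker_table <- function(markers, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(markers), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @param family_id family id to attach on read.
#' @export
read_marker_table <- function(path, family_id = NA_character_) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("chrom", "pos", "ref", "alt", "h_allele") %in% names(m)))
  m$chrom <- as.character(m$chrom)
  structure(m[order(m$chrom, m$pos), , drop = FALSE],
            class = c("marker_set", "data.frame"), family_id = family_id)
}
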