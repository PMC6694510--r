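#' Read validation genotypes
#'
#' TSV dialect `chrom pos individual code`, codes in
#' `{HH, HL, LL, missing}`.
#'
#' @param path file path.
#' @return data.frame sorted by `chrom`, `pos`.
#' @export
read_validation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("chrom", "pos", "individual", "code") %in% names(x)))
  if (!all(x$code %in% c("HH", "HL", "LL", "missing"))) {
    stop("validation codes must be HH, HL, LL or missing")
  }
  x$chrom <- as.character(x$chrom)
  x[order(x$chrom, x$pos), , drop = FALSE]
}

#' Agreement between binned mosaic genotypes and validation genotypes
#'
#' Each validation locus is mapped into its bin of the binned genotypes.
#' A locus is comparable for an individual when both sources carry a
#' decided code (HH/HL/LL); loci falling in masked bins (including bins
#' excluded for inferred recombination events) are dropped and counted.
#' Agreement fractions are reported across loci per individual and across
#' individuals per locus; an individual (or locus) with zero comparable
#' entries is reported as `NA`, not 0.
#'
#' @param binned a `binned_genotypes` table (see [bin_genotypes()]).
#' @param validation data.frame `chrom pos individual code`.
#' @return list `per_individual` (`individual n_comparable agreement`),
#'   `per_locus` (`chrom pos n_comparable agreement`), `overall`
#'   (mean of per-individual and of per-locus fractions), `n_dropped`
#'   (validation entries without a comparable bin).
#' @export
agreement <- function(binned, validation) {
  v <- validation
  b <- as.data.frame(binned)
  bkey <- paste(b$individual, b$chrom)
  # locate the bin containing each validation locus
  code <- rep(NA_character_, nrow(v))
  vkey <- paste(v$individual, v$chrom)
  for (grp in unique(vkey)) {
    sel <- which(vkey == grp)
    bb <- b[bkey == grp, , drop = FALSE]
    if (!nrow(bb)) next
    bb <- bb[order(bb$start), , drop = FALSE]
    i <- findInterval(v$pos[sel], bb$start)
    ok <- i >= 1 & v$pos[sel] <= bb$end[pmax(i, 1)]
    code[sel[ok]] <- bb$code[i[ok]]
  }
  comparable <- !is.na(code) & code %in% DECIDED &
    v$code %in% DECIDED
  agree <- comparable & code == v$code
  frac <- function(keys) {
    u <- unique(keys)
    n <- vapply(u, function(k) sum(comparable[keys == k]), 0)
    a <- vapply(u, function(k) {
      if (n[match(k, u)] == 0) NA_real_ else
        sum(agree[keys == k]) / sum(comparable[keys == k])
    }, 0)
    list(u = u, n = n, a = a)
  }
  fi <- frac(v$individual)
  per_individual <- data.frame(individual = fi$u, n_comparable = fi$n,
                               agreement = fi$a, stringsAsFactors = FALSE)
  fl <- frac(paste(v$chrom, v$pos))
  lp <- do.call(rbind, strsplit(fl$u, " ", fixed = TRUE))
  per_locus <- data.frame(chrom = lp[, 1], pos = as.numeric(lp[, 2]),
                          n_comparable = fl$n, agreement = fl$a,
                          stringsAsFactors = FALSE)
  list(per_individual = per_individual, per_locus = per_locus,
       overall = list(
         mean_individual = mean(per_individual$agreement, na.rm = TRUE),
         mean_locus = mean(per_locus$agreement, na.rm = TRUE)),
       n_dropped = sum(!comparable))
}

#' Export a truth mosaic as validation genotypes at given loci
#'
#' Utility for cross-checking [truth_agreement()] against [agreement()]:
#' evaluates the true segment state of each individual at a set of loci.
#'
#' @param truth_segments data.frame `individual chrom start end state`.
#' @param loci data.frame `chrom pos`.
#' @return Validation table `chrom pos individual code`.
#' @export
truth_as_validation <- function(truth_segments, loci) {
  rows <- list()
  for (id in unique(truth_segments$individual)) {
    for (ch in unique(loci$chrom)) {
      s <- truth_segments[truth_segments$individual == id &
                            truth_segments$chrom == ch, , drop = FALSE]
      pos <- loci$pos[loci$chrom == ch]
      if (!nrow(s) || !length(pos)) next
      s <- s[order(s$start), , drop = FALSE]
      st <- s$state[findInterval(pos, s$start)]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = pos, individual = id, code = st,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Agreement of reconstructed mosaics with simulated truth
#'
#' The truth mosaic is binned exactly like the reconstruction (bins
#' containing a true crossover become `missing`), and the two binned
#' matrices are compared on bins where both are decided -- so bins
#' overlapping either a true or an inferred recombination event are
#' excluded. Additionally reports, per individual and overall, the
#' fraction of true crossovers lying inside an inferred breakpoint
#' interval of the same individual and chromosome.
#'
#' @param seg a `mosaic_seg` (reconstruction, post-QC).
#' @param truth a `sim_cross` or a list with `truth_segments` and
#'   `truth_crossovers`.
#' @param genome a [genome_spec()].
#' @param cfg a [qc_config()] (binning resolution).
#' @return list `per_individual`, `overall` (mean per-individual
#'   agreement), `binned`, `truth_binned`, `co_in_interval` (fraction of
#'   true crossovers inside an inferred breakpoint interval).
#' @export
truth_agreement <- function(seg, truth, genome, cfg = qc_config()) {
  binned <- bin_genotypes(seg, genome, cfg)
  truth_seg <- new_mosaic_seg(truth$truth_segments, bp_empty())
  truth_binned <- bin_genotypes(truth_seg, genome, cfg)
  key <- function(b) paste(b$individual, b$chrom, b$start)
  i <- match(key(binned), key(truth_binned))
  tb <- truth_binned$code[i]
  comparable <- binned$code %in% DECIDED & !is.na(tb) & tb %in% DECIDED
  agree <- comparable & binned$code == tb
  ids <- unique(binned$individual)
  per_individual <- data.frame(
    individual = ids,
    n_comparable = vapply(ids, function(k)
      sum(comparable[binned$individual == k]), 0),
    agreement = vapply(ids, function(k) {
      n <- sum(comparable[binned$individual == k])
      if (n == 0) NA_real_ else
        sum(agree[binned$individual == k]) / n
    }, 0), stringsAsFactors = FALSE)
  rownames(per_individual) <- NULL

  cx <- truth$truth_crossovers
  bp <- seg$breakpoints
  inside <- if (nrow(cx)) {
    vapply(seq_len(nrow(cx)), function(r) {
      bb <- bp[bp$individual == cx$individual[r] &
                 bp$chrom == cx$chrom[r], , drop = FALSE]
      any(cx$pos[r] >= bb$left_bp & cx$pos[r] <= bb$right_bp)
    }, TRUE)
  } else {
    logical(0)
  }
  list(per_individual = per_individual,
       overall = mean(per_individual$agreement, na.rm = TRUE),
       binned = binned, truth_binned = truth_binned,
       co_in_interval = if (length(inside)) mean(inside) else NA_real_)
}
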