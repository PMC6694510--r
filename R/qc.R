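#' Quality-control configuration
#'
#' @param min_double_co_span_bp internal decided segments flanked by two
#'   crossovers and shorter than this are biologically implausible double
#'   crossovers and are removed (default 3 Mb, motivated by absolute
#'   crossover interference over short distances).
#' @param min_call_rate individuals whose genome-wide decided call rate
#'   falls below this after double-crossover removal are flagged
#'   (default 0.90).
#' @param bin_size_bp resolution of genotype binning (default 1 Mb).
#' @param outlier_mode `"call_rate"` (default) or `"crossover_count"`;
#'   the two give very similar individual sets.
#' @param outlier_multiplier robust-scale multiplier for
#'   `crossover_count` mode (default 3).
#' @param double_co_action `"mask"` (default) turns a short
#'   disagreeing-flank segment into `UU`; `"merge_left"` assigns it to the
#'   left flank state instead.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_double_co_span_bp = 3e6, min_call_rate = 0.90,
                      bin_size_bp = 1e6,
                      outlier_mode = c("call_rate", "crossover_count"),
                      outlier_multiplier = 3,
                      double_co_action = c("mask", "merge_left")) {
  stopifnot(min_double_co_span_bp > 0, bin_size_bp > 0,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(min_double_co_span_bp = min_double_co_span_bp,
                 min_call_rate = min_call_rate, bin_size_bp = bin_size_bp,
                 outlier_mode = match.arg(outlier_mode),
                 outlier_multiplier = outlier_multiplier,
                 double_co_action = match.arg(double_co_action)),
            class = "qc_config")
}

DECIDED <- c("HH", "HL", "LL")
state_dose <- c(HH = 2, HL = 1, LL = 0, UU = NA)

coalesce_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep_run <- rle(seg$state)
  ends <- cumsum(keep_run$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- seg[starts, , drop = FALSE]
  out$end <- seg$end[ends]
  rownames(out) <- NULL
  out
}

#' Remove biologically implausible close double crossovers
#'
#' Every internal decided segment shorter than `min_double_co_span_bp`
#' whose two neighbours are both decided (i.e. the segment is flanked by
#' two crossovers) is removed: when the flanking segments share a state,
#' the three segments merge into one (eliminating both crossovers); when
#' they differ, the short segment is masked to `UU` (default) or merged
#' into the left flank. The rule is applied iteratively until no such
#' segment remains, so the operation is idempotent and never increases
#' the crossover count.
#'
#' @param seg a `mosaic_seg`.
#' @param cfg a [qc_config()].
#' @return The filtered `mosaic_seg` with attribute `removal_log`
#'   (data.frame `individual chrom start end state action`).
#' @export
remove_close_double_crossovers <- function(seg, cfg = qc_config()) {
  stopifnot(inherits(seg, "mosaic_seg"))
  log <- list()
  pieces <- split(seg$segments,
                  list(seg$segments$individual, seg$segments$chrom),
                  drop = TRUE)
  pieces <- lapply(pieces, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    repeat {
      n <- nrow(s)
      if (n < 3) break
      len <- s$end - s$start + 1
      decided <- s$state %in% DECIDED
      idx <- 2:(n - 1)
      bad <- idx[decided[idx] & decided[idx - 1] & decided[idx + 1] &
                   len[idx] < cfg$min_double_co_span_bp]
      if (!length(bad)) break
      i <- bad[which.min(len[bad])]
      entry <- s[i, c("individual", "chrom", "start", "end", "state")]
      if (s$state[i - 1] == s$state[i + 1]) {
        entry$action <- "merged"
        s$state[i] <- s$state[i - 1]
      } else if (cfg$double_co_action == "merge_left") {
        entry$action <- "merged_left"
        s$state[i] <- s$state[i - 1]
      } else {
        entry$action <- "masked"
        s$state[i] <- "UU"
      }
      log[[length(log) + 1]] <<- entry
      s <- coalesce_segments(s)
    }
    s
  })
  segments <- do.call(rbind, pieces)
  segments <- segments[order(segments$individual, segments$chrom,
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  # keep only breakpoints that still separate two different decided-or-UU
  # segments at the same position
  bp <- seg$breakpoints
  if (nrow(bp)) {
    keep <- vapply(seq_len(nrow(bp)), function(i) {
      s <- segments[segments$individual == bp$individual[i] &
                      segments$chrom == bp$chrom[i], , drop = FALSE]
      any(s$end == bp$point[i])
    }, TRUE)
    bp <- bp[keep, , drop = FALSE]
    rownames(bp) <- NULL
  }
  out <- new_mosaic_seg(segments, bp)
  attr(out, "removal_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(individual = character(), chrom = character(),
               start = numeric(), end = numeric(), state = character(),
               action = character(), stringsAsFactors = FALSE)
  out
}

#' Count genome-wide crossovers per individual
#'
#' A boundary between two adjacent decided segments counts as the number
#' of line-origin changes (`HH|HL` = 1, `HH|LL` = 2); boundaries touching
#' `UU` segments are not counted (the crossovers there are unplaced).
#'
#' @param seg a `mosaic_seg`.
#' @return Named numeric vector of crossover counts per individual.
#' @export
count_crossovers <- function(seg) {
  s <- seg$segments
  ids <- unique(s$individual)
  vapply(ids, function(id) {
    tot <- 0
    si <- s[s$individual == id, , drop = FALSE]
    for (ch in unique(si$chrom)) {
      sc <- si[si$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$start), , drop = FALSE]
      if (nrow(sc) < 2) next
      d <- state_dose[sc$state]
      steps <- abs(diff(d))
      tot <- tot + sum(steps, na.rm = TRUE)
    }
    tot
  }, 0)
}

#' Genome-wide genotype call rate of one individual
#'
#' Fraction of the assayed genome length assigned a decided state
#' (HH/HL/LL) by the (post-filter) segmentation.
#'
#' @param seg a `mosaic_seg` (one individual's segments).
#' @param genome a [genome_spec()].
#' @return Scalar in `[0, 1]`.
#' @export
call_rate <- function(seg, genome) {
  s <- seg$segments
  s <- s[s$chrom %in% assayed_chroms(genome), , drop = FALSE]
  decided <- s$state %in% DECIDED
  sum((s$end - s$start + 1)[decided]) / assayed_length(genome)
}

#' Flag outlier individuals after mosaic reconstruction
#'
#' Sample mix-ups, contamination and pedigree errors inflate the apparent
#' number of genome-wide recombination events. In `crossover_count` mode,
#' individuals whose count exceeds `median + multiplier * MAD` are
#' flagged; in `call_rate` mode (default), individuals whose post-filter
#' call rate falls below `min_call_rate` are flagged. Both statistics are
#' reported for every individual.
#'
#' @param seg a `mosaic_seg` holding all individuals (post
#'   [remove_close_double_crossovers()]).
#' @param genome a [genome_spec()].
#' @param cfg a [qc_config()].
#' @return data.frame `individual crossovers call_rate flagged`.
#' @export
crossover_outliers <- function(seg, genome, cfg = qc_config()) {
  ids <- unique(seg$segments$individual)
  co <- count_crossovers(seg)
  cr <- vapply(ids, function(id) {
    call_rate(new_mosaic_seg(
      seg$segments[seg$segments$individual == id, , drop = FALSE],
      bp_empty()), genome)
  }, 0)
  flagged <- if (cfg$outlier_mode == "crossover_count") {
    co > stats::median(co) + cfg$outlier_multiplier * stats::mad(co)
  } else {
    cr < cfg$min_call_rate
  }
  out <- data.frame(individual = ids, crossovers = as.numeric(co[ids]),
                    call_rate = as.numeric(cr[ids]),
                    flagged = as.logical(flagged[ids]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract binned genotypes from a mosaic segmentation
#'
#' Each chromosome is tiled with `bin_size_bp` bins (terminal partial bins
#' retained at their true span). A bin takes the state of the single
#' decided segment that covers it entirely; bins containing a crossover or
#' overlapping any `UU` segment are `missing`.
#'
#' @param seg a `mosaic_seg`.
#' @param genome a [genome_spec()].
#' @param cfg a [qc_config()].
#' @return A `binned_genotypes` data.frame
#'   `individual chrom start end code`.
#' @export
bin_genotypes <- function(seg, genome, cfg = qc_config()) {
  out <- list()
  for (id in unique(seg$segments$individual)) {
    for (ch in assayed_chroms(genome)) {
      s <- seg$segments[seg$segments$individual == id &
                          seg$segments$chrom == ch, , drop = FALSE]
      s <- coalesce_segments(s[order(s$start), , drop = FALSE])
      bins <- tile_bins(chrom_length(genome, ch), cfg$bin_size_bp)
      if (nrow(s) == 0) {
        code <- rep("missing", nrow(bins))
      } else {
        i <- findInterval(bins$start, s$start)
        covers <- i >= 1 & s$end[i] >= bins$end
        code <- ifelse(covers & s$state[i] %in% DECIDED, s$state[i],
                       "missing")
      }
      out[[length(out) + 1]] <- data.frame(
        individual = id, chrom = ch, start = bins$start, end = bins$end,
        code = code, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("binned_genotypes", "data.frame")
  res
}

#' Export binned genotypes in R/qtl "csv" format
#'
#' Markers are named `c<chrom>_<bin start>`; genetic positions are
#' approximated as physical Mb times a constant cM/Mb rate (no linkage map
#' is estimated here). Genotype codes: `HH -> A`, `HL -> H`, `LL -> B`,
#' `missing -> -`. The file has the standard three header rows (marker
#' ids, chromosome, position) over one row per individual, with the
#' individual id as the sole phenotype column.
#'
#' @param binned a `binned_genotypes` table.
#' @param path output file.
#' @param cm_per_mb map-rate used for the cM positions (default 3.0).
#' @return The path, invisibly.
#' @export
export_rqtl <- function(binned, path, cm_per_mb = 3.0) {
  ids <- unique(binned$individual)
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  bins <- unique(binned[, c("chrom", "start")])
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  marker <- paste0("c", bins$chrom, "_", bins$start)
  pos_cm <- (bins$start - 1) / 1e6 * cm_per_mb
  code_map <- c(HH = "A", HL = "H", LL = "B", missing = "-")
  key <- paste(bins$chrom, bins$start)
  geno <- matrix("-", length(ids), nrow(bins),
                 dimnames = list(ids, marker))
  i <- match(binned$individual, ids)
  j <- match(paste(binned$chrom, binned$start), key)
  geno[cbind(i, j)] <- code_map[binned$code]
  lines <- c(
    paste(c("id", marker), collapse = ","),
    paste(c("", bins$chrom), collapse = ","),
    paste(c("", format(pos_cm, trim = TRUE, scientific = FALSE)),
          collapse = ","),
    vapply(ids, function(id) paste(c(id, geno[id, ]), collapse = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read binned genotypes back from an R/qtl csv written by [export_rqtl()]
#'
#' @param path file path.
#' @param bin_size_bp bin width used at export (default 1 Mb).
#' @return A `binned_genotypes` data.frame (terminal bin ends are
#'   truncated to `start + bin_size_bp - 1`; pass the genome to recover
#'   exact terminal spans).
#' @param genome optional [genome_spec()] to restore exact terminal ends.
#' @export
read_rqtl <- function(path, bin_size_bp = 1e6, genome = NULL) {
  lines <- readLines(path)
  split1 <- strsplit(lines, ",", fixed = TRUE)
  marker <- split1[[1]][-1]
  chrom <- split1[[2]][-1]
  start <- as.numeric(sub(".*_", "", marker))
  inv_map <- c(A = "HH", H = "HL", B = "LL", `-` = "missing")
  rows <- lapply(split1[-(1:3)], function(p) {
    data.frame(individual = p[1], chrom = chrom, start = start,
               end = start + bin_size_bp - 1,
               code = unname(inv_map[p[-1]]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(genome)) {
    res$end <- pmin(res$end, genome$length[match(res$chrom, genome$chrom)])
  }
  res <- res[order(res$individual, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("binned_genotypes", "data.frame")
  res
}

#' Distribution of breakpoint-interval lengths
#'
#' Each inferred crossover is localised to the interval between its
#' flanking read-covered informative markers; the interval length measures
#' breakpoint resolution.
#'
#' @param seg a `mosaic_seg`.
#' @return list `lengths` (bp, one per breakpoint) and `summary`
#'   (data.frame with `n`, `median`, `q25`, `q75`, `q90`, in bp); both
#'   empty when there are no breakpoints.
#' @export
breakpoint_resolution <- function(seg) {
  bp <- seg$breakpoints
  len <- bp$right_bp - bp$left_bp
  if (!length(len)) {
    return(list(lengths = numeric(0),
                summary = data.frame(n = 0L, median = NA_real_,
                                     q25 = NA_real_, q75 = NA_real_,
                                     q90 = NA_real_)))
  }
  q <- stats::quantile(len, c(0.25, 0.5, 0.75, 0.9), names = FALSE)
  list(lengths = len,
       summary = data.frame(n = length(len), median = q[2], q25 = q[1],
                            q75 = q[3], q90 = q[4]))
}

#' Export segments as TSV (1-based inclusive) or BED (0-based half-open)
#'
#' @param seg a `mosaic_seg`.
#' @param path output file.
#' @param format `"tsv"` (default; columns `individual chrom start end
#'   state`) or `"bed"` (`chrom start0 end individual_state`).
#' @param header_lines optional comment lines (without leading `#`).
#' @export
write_segments <- function(seg, path, format = c("tsv", "bed"),
                           header_lines = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines) && format == "tsv") {
    writeLines(paste0("# ", header_lines), con)
  }
  if (format == "tsv") {
    utils::write.table(seg$segments, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = seg$segments$chrom,
                      start = seg$segments$start - 1,  # 0-based half-open
                      end = seg$segments$end,
                      name = paste0(seg$segments$individual, "_",
                                    seg$segments$state))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
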