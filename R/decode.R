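#' Decode one chromosome into a founder mosaic segmentation
#'
#' Runs Viterbi (default) or per-marker max-posterior decoding, merges
#' consecutive identical states into segments, and places each segment
#' boundary at the midpoint of its breakpoint interval. The breakpoint
#' interval spans from the last read-covered informative marker supporting
#' the left state to the first read-covered marker supporting the right
#' state; when a flanking segment contains no covered marker the boundary
#' marker position itself is used. Chromosome ends are extended to
#' `[1, length]`. A chromosome with no read-covered marker (or no markers
#' at all) yields a single `UU` segment.
#'
#' @param obs `site_obs` rows for one chromosome, position-sorted.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bp.
#' @param cfg an [hmm_config()].
#' @param individual individual id recorded in the output.
#' @return A `mosaic_seg` list with data.frames `segments`
#'   (`individual chrom start end state`) and `breakpoints`
#'   (`individual chrom left_bp right_bp point left_state right_state`).
#' @export
decode_chromosome <- function(obs, chrom, chrom_len, cfg = hmm_config(),
                              individual = NA_character_) {
  covered <- obs$n_H + obs$n_L >= 1
  if (nrow(obs) == 0 || !any(covered)) {
    if (nrow(obs) == 0) {
      warning("chromosome ", chrom, " has no informative markers; ",
              "returning a single UU segment")
    }
    return(new_mosaic_seg(
      segments = seg_row(individual, chrom, 1, chrom_len, "UU"),
      breakpoints = bp_empty()))
  }
  hmm <- build_hmm(obs, cfg)
  path <- if (cfg$decode_mode == "posterior") {
    g <- forward_backward(hmm)
    apply(g, 2, which.max)
  } else {
    viterbi_path(hmm)
  }
  states <- hmm$states[path]
  segmentation_from_path(states, obs, chrom, chrom_len, individual)
}

seg_row <- function(individual, chrom, start, end, state) {
  data.frame(individual = individual, chrom = chrom, start = start,
             end = end, state = state, stringsAsFactors = FALSE)
}

bp_empty <- function() {
  data.frame(individual = character(), chrom = character(),
             left_bp = numeric(), right_bp = numeric(), point = numeric(),
             left_state = character(), right_state = character(),
             stringsAsFactors = FALSE)
}

new_mosaic_seg <- function(segments, breakpoints) {
  structure(list(segments = segments, breakpoints = breakpoints),
            class = "mosaic_seg")
}

#' @export
print.mosaic_seg <- function(x, ...) {
  cat("mosaic_seg: ", nrow(x$segments), " segments, ",
      nrow(x$breakpoints), " breakpoints across ",
      length(unique(x$segments$individual)), " individual(s)\n", sep = "")
  invisible(x)
}

#' Combine mosaic segmentations (e.g. across chromosomes or individuals)
#' @param ... `mosaic_seg` objects.
#' @return A single `mosaic_seg`.
#' @export
bind_mosaics <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "mosaic_seg")) {
    xs <- xs[[1]]
  }
  new_mosaic_seg(
    segments = do.call(rbind, lapply(xs, `[[`, "segments")),
    breakpoints = do.call(rbind, lapply(xs, `[[`, "breakpoints")))
}

segmentation_from_path <- function(states, obs, chrom, chrom_len,
                                   individual) {
  n <- length(states)
  covered <- obs$n_H + obs$n_L >= 1
  runs <- rle(states)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  k <- length(runs$values)
  if (k == 1) {
    return(new_mosaic_seg(seg_row(individual, chrom, 1, chrom_len,
                                  runs$values), bp_empty()))
  }
  bps <- vector("list", k - 1)
  for (b in 1:(k - 1)) {
    li <- starts_idx[b]:ends_idx[b]          # marker indices, left run
    ri <- starts_idx[b + 1]:ends_idx[b + 1]  # right run
    lcov <- li[covered[li]]
    rcov <- ri[covered[ri]]
    left_bp <- if (length(lcov)) obs$pos[max(lcov)] else obs$pos[ends_idx[b]]
    right_bp <- if (length(rcov)) obs$pos[min(rcov)] else
      obs$pos[starts_idx[b + 1]]
    bps[[b]] <- data.frame(
      individual = individual, chrom = chrom, left_bp = left_bp,
      right_bp = right_bp, point = floor((left_bp + right_bp) / 2),
      left_state = runs$values[b], right_state = runs$values[b + 1],
      stringsAsFactors = FALSE)
  }
  bps <- do.call(rbind, bps)
  seg_start <- c(1, bps$point + 1)
  seg_end <- c(bps$point, chrom_len)
  segs <- seg_row(individual, chrom, seg_start, seg_end, runs$values)
  new_mosaic_seg(segs, bps)
}

#' Reconstruct the genome-wide founder mosaic of one individual
#'
#' Applies [decode_chromosome()] to every assayed chromosome of the
#' genome, using the individual's polarized observations.
#'
#' @param obs a `site_obs` table (all chromosomes) for the individual.
#' @param genome a [genome_spec()].
#' @param cfg an [hmm_config()].
#' @param individual id recorded in the output (defaults to the `site_obs`
#'   attribute).
#' @return A `mosaic_seg` covering all assayed chromosomes.
#' @export
reconstruct_mosaic <- function(obs, genome, cfg = hmm_config(),
                               individual = NULL) {
  if (is.null(individual)) individual <- attr(obs, "individual")
  if (is.null(individual)) individual <- NA_character_
  pieces <- lapply(assayed_chroms(genome), function(ch) {
    o <- obs[obs$chrom == ch, , drop = FALSE]
    o <- o[order(o$pos), , drop = FALSE]
    suppressWarnings(
      decode_chromosome(o, ch, chrom_length(genome, ch), cfg, individual))
  })
  bind_mosaics(pieces)
}
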