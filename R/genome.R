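#' Describe a genome assembly for mosaic imputation
#'
#' A genome specification is the shared coordinate frame of the pipeline:
#' an ordered set of chromosomes with their physical lengths and a flag
#' saying whether each chromosome is part of the assayed (imputed) genome.
#' Sex chromosomes and unplaced scaffolds can be carried along but are
#' excluded from imputation and from all genome-length denominators by
#' setting `assayed = FALSE`.
#'
#' All coordinates in the package are 1-based inclusive (VCF convention);
#' BED-style exports convert to 0-based half-open at write time.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive integer vector of chromosome lengths in bp.
#' @param assayed logical, recycled; whether the chromosome enters
#'   imputation and genome-wide denominators (default `TRUE`).
#' @return A `genome_spec` data.frame with columns `chrom`, `length`,
#'   `assayed`.
#' @examples
#' g <- genome_spec(c("1", "2"), c(50e6, 20e6))
#' assayed_length(g)
#' @export
genome_spec <- function(chrom, length, assayed = TRUE) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  assayed <- rep_len(as.logical(assayed), base::length(chrom))
  g <- data.frame(chrom = chrom, length = length, assayed = assayed,
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Read a genome specification from a two-column TSV
#'
#' Expected columns: `chrom`, `length` (header optional when exactly two
#' columns are present). An optional third logical column `assayed` is
#' honoured.
#'
#' @param path path to a tab-separated file.
#' @return A [genome_spec()].
#' @export
read_genome_spec <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("chrom", "length") %in% names(x))) {
    # headerless two-column file
    x <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(x) < 2) stop("genome file needs columns chrom, length")
    names(x)[1:2] <- c("chrom", "length")
  }
  assayed <- if ("assayed" %in% names(x)) as.logical(x$assayed) else TRUE
  genome_spec(x$chrom, x$length, assayed)
}

#' Total assayed genome length
#'
#' @param genome a [genome_spec()].
#' @return Total length in bp of chromosomes with `assayed = TRUE`.
#' @export
assayed_length <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  sum(genome$length[genome$assayed])
}

#' Chromosomes included in imputation
#' @param genome a [genome_spec()].
#' @return Character vector of assayed chromosome names, in genome order.
#' @export
assayed_chroms <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  genome$chrom[genome$assayed]
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  genome$length[i]
}

#' Tile a chromosome with physical bins
#'
#' Bins are `bin_size` bp, 1-based inclusive; the terminal bin is retained
#' at its true (possibly shorter) span.
#'
#' @param len chromosome length in bp.
#' @param bin_size bin width in bp.
#' @return data.frame with `start`, `end`.
#' @keywords internal
tile_bins <- function(len, bin_size) {
  starts <- seq.int(1L, len, by = bin_size)
  data.frame(start = starts, end = pmin(starts + bin_size - 1, len))
}
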