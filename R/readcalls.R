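#' Polarize offspring allele depths at informative markers
#'
#' Maps per-site (ref, alt) read depths of one low-coverage offspring to
#' line-polarized counts `(n_H, n_L)` using each marker's recorded H-line
#' allele: when `h_allele = "ref"`, `n_H = n_ref`; when `h_allele = "alt"`
#' the counts swap. Only sites present in the marker set are consulted;
#' marker sites absent from the depth input yield `(0, 0)` (no reads).
#'
#' @param depths long depth table `chrom pos sample n_ref n_alt` (from
#'   [read_offspring_vcf()], [read_depth_table()] or the simulator).
#' @param markers a `marker_set` for the offspring's family.
#' @param sample id of the offspring; must occur in the depth input's
#'   sample universe.
#' @return A `site_obs` data.frame `chrom pos n_H n_L`, one row per
#'   marker, position-sorted, with attribute `individual`.
#' @export
extract_depths <- function(depths, markers, sample) {
  stopifnot(inherits(markers, "marker_set"))
  universe <- attr(depths, "samples")
  if (is.null(universe)) universe <- unique(depths$sample)
  if (!sample %in% universe) {
    stop("sample absent from depth input: ", sample)
  }
  d <- depths[depths$sample == sample, , drop = FALSE]
  m <- as.data.frame(markers)
  i <- match(paste(m$chrom, m$pos), paste(d$chrom, d$pos))
  n_ref <- ifelse(is.na(i), 0L, d$n_ref[i])
  n_alt <- ifelse(is.na(i), 0L, d$n_alt[i])
  swap <- m$h_allele == "alt"
  obs <- data.frame(chrom = m$chrom, pos = m$pos,
                    n_H = ifelse(swap, n_alt, n_ref),
                    n_L = ifelse(swap, n_ref, n_alt),
                    stringsAsFactors = FALSE)
  obs <- obs[order(obs$chrom, obs$pos), , drop = FALSE]
  rownames(obs) <- NULL
  structure(obs, class = c("site_obs", "data.frame"), individual = sample)
}

#' Marker-density filter configuration
#'
#' @param min_snps_per_mb individuals whose genome-wide density of
#'   read-covered informative markers falls below this value are dropped
#'   (default 5 SNPs/Mb).
#' @return A `density_filter_config` list.
#' @export
density_filter_config <- function(min_snps_per_mb = 5) {
  stopifnot(min_snps_per_mb >= 0)
  structure(list(min_snps_per_mb = min_snps_per_mb),
            class = "density_filter_config")
}

#' Per-individual covered-marker density filter
#'
#' Accurate mosaic reconstruction needs a minimum density of informative
#' markers actually hit by reads. The density is the count of marker sites
#' with at least one read (`n_H + n_L >= 1`), divided by the assayed
#' genome length in Mb; an individual is dropped when it falls below
#' `min_snps_per_mb`.
#'
#' @param obs a `site_obs` table for one individual (all chromosomes).
#' @param genome a [genome_spec()].
#' @param cfg a [density_filter_config()].
#' @return list `keep` (logical), `density` (SNPs/Mb), `covered_sites`.
#' @export
density_filter <- function(obs, genome, cfg = density_filter_config()) {
  covered <- sum(obs$n_H + obs$n_L >= 1)
  dens <- covered / (assayed_length(genome) / 1e6)
  list(keep = dens >= cfg$min_snps_per_mb, density = dens,
       covered_sites = covered)
}

#' Coverage and density diagnostics across individuals
#'
#' @param obs_list named list of `site_obs` tables, one per individual.
#' @param genome a [genome_spec()].
#' @param cfg a [density_filter_config()].
#' @return data.frame `individual markers covered_sites mean_depth density
#'   keep`.
#' @export
coverage_report <- function(obs_list, genome,
                            cfg = density_filter_config()) {
  rows <- lapply(names(obs_list), function(id) {
    o <- obs_list[[id]]
    f <- density_filter(o, genome, cfg)
    data.frame(individual = id, markers = nrow(o),
               covered_sites = f$covered_sites,
               mean_depth = mean(o$n_H + o$n_L),
               density = f$density, keep = f$keep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
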