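#' Simulation configuration for a two-line F2 intercross
#'
#' The generator emulates the data-generating conditions of a divergent
#' two-line intercross genotyped by skim sequencing: a founder pool per
#' line drifted from a common base population, a controllable fraction of
#' sites strictly fixed between the lines, nuclear F0-F1-F2 families,
#' meioses with hard crossover interference, and Poisson read depths with
#' a per-read line-flip error at informative marker sites only.
#'
#' `informative_density_per_mb` is the target density of within-family
#' informative markers that survive the default founder variant filter;
#' the total simulated site density is calibrated internally (by a
#' seeded Monte Carlo estimate of the per-site informativeness rate) so
#' that the realized density matches the target in expectation.
#'
#' @param genome a [genome_spec()].
#' @param n_families number of nuclear families (one F2 each; default 10).
#' @param founders_per_line size of the F0 pool per line from which family
#'   grandparents are drawn (default 4; must be >= 2).
#' @param informative_density_per_mb target within-family informative
#'   marker density (default 791 markers/Mb).
#' @param fixed_fraction fraction of simulated sites strictly fixed for
#'   alternative alleles between the two lines (default 0.034).
#' @param within_line_het expected heterozygosity of segregating sites
#'   within a line (default 0.30); controls the Beta line-frequency model.
#' @param coverage mean sequencing depth per marker site per offspring
#'   (default 0.33x).
#' @param seq_error per-read probability that a read reports the wrong
#'   line allele (default 0.005).
#' @param interference_min_gap_bp hard minimum distance between two
#'   crossovers of one meiosis (default 5 Mb).
#' @param map_rate_cm_per_mb recombination rate (default 3.0 cM/Mb).
#' @param filter the [founder_filter_config()] assumed when calibrating
#'   the informative density.
#' @param seed integer RNG seed; all outputs are byte-identical under a
#'   fixed seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome, n_families = 10, founders_per_line = 4,
                       informative_density_per_mb = 791,
                       fixed_fraction = 0.034, within_line_het = 0.30,
                       coverage = 0.33, seq_error = 0.005,
                       interference_min_gap_bp = 5e6,
                       map_rate_cm_per_mb = 3.0,
                       filter = founder_filter_config(), seed = 1) {
  stopifnot(inherits(genome, "genome_spec"), n_families >= 1,
            founders_per_line >= 2,
            fixed_fraction >= 0, fixed_fraction <= 1,
            within_line_het >= 0, within_line_het < 0.5,
            informative_density_per_mb > 0, coverage >= 0,
            seq_error >= 0, seq_error <= 1, interference_min_gap_bp >= 0,
            map_rate_cm_per_mb >= 0)
  structure(list(genome = genome, n_families = n_families,
                 founders_per_line = founders_per_line,
                 informative_density_per_mb = informative_density_per_mb,
                 fixed_fraction = fixed_fraction,
                 within_line_het = within_line_het, coverage = coverage,
                 seq_error = seq_error,
                 interference_min_gap_bp = interference_min_gap_bp,
                 map_rate_cm_per_mb = map_rate_cm_per_mb,
                 filter = filter, seed = as.integer(seed)),
            class = "sim_config")
}

sim_founder_ids <- function(cfg) {
  list(h = paste0("H", seq_len(cfg$founders_per_line)),
       l = paste0("L", seq_len(cfg$founders_per_line)))
}

# Draw per-line alt-allele frequencies and founder doses for n sites.
# Fixed sites are alternate-fixed between lines; segregating sites drift
# independently per line from a symmetric Beta whose parameter is chosen
# so that E[2pq] = within_line_het.
sim_site_genotypes <- function(n, cfg) {
  fpl <- cfg$founders_per_line
  fixed <- stats::runif(n) < cfg$fixed_fraction
  h_is_alt <- stats::runif(n) < 0.5
  het <- cfg$within_line_het
  if (het > 0) {
    a <- het / (1 - 2 * het)
    p_h <- stats::rbeta(n, a, a)
    p_l <- stats::rbeta(n, a, a)
  } else {
    p_h <- stats::rbinom(n, 1, 0.5)
    p_l <- stats::rbinom(n, 1, 0.5)
  }
  p_h[fixed] <- as.numeric(h_is_alt[fixed])
  p_l[fixed] <- as.numeric(!h_is_alt[fixed])
  gh <- matrix(stats::rbinom(n * fpl, 2, rep(p_h, fpl)), n, fpl)
  gl <- matrix(stats::rbinom(n * fpl, 2, rep(p_l, fpl)), n, fpl)
  ids <- sim_founder_ids(cfg)
  geno <- cbind(gh, gl)
  colnames(geno) <- c(ids$h, ids$l)
  list(geno = geno, fixed = fixed)
}

# Monte Carlo estimate of the probability that a simulated site is
# within-family informative for a canonical family (H1,H2 x L1,L2) AND
# passes the founder variant filter computed on the whole founder pool.
informative_rate_mc <- function(cfg, n_mc = 200000) {
  g <- sim_site_genotypes(n_mc, cfg)$geno
  h1 <- g[, 1]; h2 <- g[, 2]
  l1 <- g[, cfg$founders_per_line + 1]; l2 <- g[, cfg$founders_per_line + 2]
  informative <- (h1 == 0 & h2 == 0 & l1 == 2 & l2 == 2) |
    (h1 == 2 & h2 == 2 & l1 == 0 & l2 == 0)
  ac <- rowSums(g)
  an <- 2 * ncol(g)
  p <- ac / an
  maf <- pmin(p, 1 - p)
  pass <- informative & maf > cfg$filter$min_maf & ac > cfg$filter$min_ac
  mean(pass)
}

#' Simulate founder genotypes and the genome-wide site list
#'
#' Sites are placed uniformly at random at a total density calibrated so
#' that the expected within-family informative density (after the default
#' founder filter) matches `informative_density_per_mb`. A
#' `fixed_fraction` subset is strictly fixed for alternative alleles
#' between the lines; the remaining sites segregate within lines under
#' the Beta drift model. QUAL values are drawn high (gamma with mean 200)
#' so that simulated sites represent confidently called variants.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream
#'   (used internally by [simulate_cross()]).
#' @return list with `founders` (a [founder_set()]), `founder_lines`
#'   (named character vector `H`/`L` per founder id), `site_class`
#'   (`"fixed"`/`"segregating"` per site, aligned with
#'   `founders$sites`), and `total_density_per_mb`.
#' @export
simulate_founders <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  rate <- informative_rate_mc(cfg)
  if (rate <= 0) {
    # no site can be informative (e.g. fixed_fraction 0 with degenerate
    # drift); fall back to the raw target density
    dens <- cfg$informative_density_per_mb
  } else {
    dens <- cfg$informative_density_per_mb / rate
  }
  nucs <- c("A", "C", "G", "T")
  pieces <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    len <- cfg$genome$length[i]
    n <- as.integer(round(dens * len / 1e6))
    n <- min(n, len)
    pos <- sort(sample.int(len, n))
    ref <- sample(nucs, n, replace = TRUE)
    alt_shift <- sample.int(3, n, replace = TRUE)
    alt <- nucs[(match(ref, nucs) - 1 + alt_shift) %% 4 + 1]
    pieces[[i]] <- data.frame(chrom = cfg$genome$chrom[i], pos = pos,
                              ref = ref, alt = alt,
                              qual = round(stats::rgamma(n, 10, scale = 20), 1),
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, pieces)
  gsim <- sim_site_genotypes(nrow(sites), cfg)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- gsim$geno[ord, , drop = FALSE]
  site_class <- ifelse(gsim$fixed[ord], "fixed", "segregating")
  ids <- sim_founder_ids(cfg)
  lines <- stats::setNames(rep(c("H", "L"), each = cfg$founders_per_line),
                           c(ids$h, ids$l))
  list(founders = founder_set(sites, geno), founder_lines = lines,
       site_class = site_class, total_density_per_mb = dens)
}

#' Simulate one meiosis with hard crossover interference
#'
#' The crossover count is Poisson with mean equal to the chromosome map
#' length in Morgans (`length * rate`); positions are uniform, subject to
#' all pairwise gaps being at least `interference_min_gap_bp` (rejection
#' sampling; an infeasible count is resampled with a warning). The gamete
#' alternates between the two parental haplotypes, starting from a random
#' one, switching after each crossover position.
#'
#' @param hap_a,hap_b labels of the two parental haplotypes.
#' @param chrom_len chromosome length in bp.
#' @param cfg a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list `segments` (data.frame `start end hap`) and `crossovers`
#'   (integer positions; the gamete switches between `pos` and `pos + 1`).
#' @export
simulate_meiosis <- function(hap_a, hap_b, chrom_len, cfg,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  morgans <- chrom_len * cfg$map_rate_cm_per_mb / 100 / 1e6
  gap <- cfg$interference_min_gap_bp
  max_feasible <- if (gap > 0) floor((chrom_len - 2) / gap) + 1 else Inf
  n <- stats::rpois(1, morgans)
  warned <- FALSE
  while (n > max_feasible) {
    if (!warned) {
      warning("crossover count ", n, " infeasible under ", gap,
              "-bp interference on a ", chrom_len, "-bp chromosome; ",
              "resampling")
      warned <- TRUE
    }
    n <- stats::rpois(1, morgans)
  }
  cx <- integer(0)
  if (n > 0) {
    repeat {
      cx <- sort(sample.int(chrom_len - 1, n))
      if (n == 1 || min(diff(cx)) >= gap) break
    }
  }
  haps <- c(hap_a, hap_b)
  first <- sample.int(2, 1)
  ord <- rep(haps[c(first, 3 - first)], length.out = n + 1)
  starts <- c(1, cx + 1)
  ends <- c(cx, chrom_len)
  list(segments = data.frame(start = starts, end = ends, hap = ord,
                             stringsAsFactors = FALSE),
       crossovers = cx)
}

# line origin ("H"/"L") of a gamete at integer positions
gamete_origin <- function(gamete, pos) {
  gamete$segments$hap[findInterval(pos, gamete$segments$start)]
}

# overlay two F1 gametes into a 3-state truth segmentation
overlay_gametes <- function(g1, g2, chrom_len) {
  cx <- sort(c(g1$crossovers, g2$crossovers))
  starts <- c(1, unique(cx) + 1)
  ends <- c(unique(cx), chrom_len)
  dose <- (gamete_origin(g1, starts) == "H") +
    (gamete_origin(g2, starts) == "H")
  state <- c("LL", "HL", "HH")[dose + 1]
  seg <- data.frame(start = starts, end = ends, state = state,
                    stringsAsFactors = FALSE)
  coalesce_segments(seg)
}

#' Simulate read depths at informative marker sites for one offspring
#'
#' Depth per site is Poisson(`coverage`); each read originates from one of
#' the two true haplotypes (equally likely) and reports the wrong line
#' with probability `seq_error`. Counts are returned polarized back to
#' (ref, alt) via each marker's H-line allele, i.e. in the orientation of
#' the sequencing output.
#'
#' @param dose true H-line allele dose per marker site (2 = HH, 1 = HL,
#'   0 = LL).
#' @param h_allele `"ref"`/`"alt"` per site.
#' @param cfg a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data.frame `n_ref n_alt`.
#' @export
simulate_reads <- function(dose, h_allele, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(dose)
  depth <- stats::rpois(n, cfg$coverage)
  p_h <- c(cfg$seq_error, 0.5, 1 - cfg$seq_error)[dose + 1]
  n_h <- stats::rbinom(n, depth, p_h)
  n_l <- depth - n_h
  swap <- h_allele == "alt"
  data.frame(n_ref = ifelse(swap, n_l, n_h),
             n_alt = ifelse(swap, n_h, n_l))
}

#' Simulate a complete two-line F2 cohort with ground truth
#'
#' Generates the founder pool, `n_families` nuclear families (each F2 has
#' two F1 parents bred from founders sampled from the pool), per-family
#' informative marker sets, F1 meioses with crossover interference, and
#' low-coverage read counts at each F2's informative markers. All stages
#' share one RNG stream seeded from `cfg$seed`, so the whole object is
#' reproducible byte-for-byte.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_cross` list: `cfg`, `genome`, `founders`,
#'   `founder_lines`, `site_class`, `families` (list of
#'   [nuclear_family()]), `pedigree` (individual table), `markers` (list
#'   of per-family `marker_set`s of all truly informative sites),
#'   `depths` (long table `chrom pos sample n_ref n_alt`, covered sites
#'   only), `truth_segments` (`individual chrom start end state`), and
#'   `truth_crossovers` (`individual chrom pos`).
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fdr <- simulate_founders(cfg, seed = NULL)
  ids <- sim_founder_ids(cfg)

  families <- list()
  ped_rows <- list()
  add_ind <- function(id, gen, line, sire, dam) {
    ped_rows[[id]] <<- data.frame(id = id, generation = gen, line = line,
                                  sire = sire, dam = dam,
                                  stringsAsFactors = FALSE)
  }
  for (h in ids$h) add_ind(h, "F0", "H", NA, NA)
  for (l in ids$l) add_ind(l, "F0", "L", NA, NA)
  for (i in seq_len(cfg$n_families)) {
    hp <- sample(ids$h, 2)
    lp <- sample(ids$l, 2)
    sire <- sprintf("S%02d", i); dam <- sprintf("D%02d", i)
    f2 <- sprintf("F2_%02d", i)
    add_ind(sire, "F1", NA, hp[1], lp[1])
    add_ind(dam, "F1", NA, hp[2], lp[2])
    add_ind(f2, "F2", NA, sire, dam)
    families[[f2]] <- nuclear_family(f2, sire, dam, f0_h = hp, f0_l = lp)
  }

  markers <- lapply(families, function(fam) {
    select_family_informative(fdr$founders, fam)
  })

  truth_segs <- list(); truth_cx <- list(); depth_rows <- list()
  assay <- cfg$genome[cfg$genome$assayed, , drop = FALSE]
  for (f2 in names(families)) {
    m <- markers[[f2]]
    for (i in seq_len(nrow(assay))) {
      ch <- assay$chrom[i]; len <- assay$length[i]
      g1 <- simulate_meiosis("H", "L", len, cfg)
      g2 <- simulate_meiosis("H", "L", len, cfg)
      seg <- overlay_gametes(g1, g2, len)
      truth_segs[[length(truth_segs) + 1]] <-
        cbind(individual = f2, chrom = ch, seg, stringsAsFactors = FALSE)
      cx <- c(g1$crossovers, g2$crossovers)
      if (length(cx)) {
        truth_cx[[length(truth_cx) + 1]] <-
          data.frame(individual = f2, chrom = ch, pos = sort(cx),
                     stringsAsFactors = FALSE)
      }
      mc <- m[m$chrom == ch, , drop = FALSE]
      if (!nrow(mc)) next
      dose <- state_dose[seg$state[findInterval(mc$pos, seg$start)]]
      rd <- simulate_reads(dose, mc$h_allele, cfg)
      cov <- rd$n_ref + rd$n_alt >= 1
      if (any(cov)) {
        depth_rows[[length(depth_rows) + 1]] <- data.frame(
          chrom = ch, pos = mc$pos[cov], sample = f2,
          n_ref = rd$n_ref[cov], n_alt = rd$n_alt[cov],
          stringsAsFactors = FALSE)
      }
    }
  }
  depths <- if (length(depth_rows)) do.call(rbind, depth_rows) else
    data.frame(chrom = character(), pos = integer(), sample = character(),
               n_ref = integer(), n_alt = integer(),
               stringsAsFactors = FALSE)
  rownames(depths) <- NULL
  attr(depths, "samples") <- names(families)
  structure(list(
    cfg = cfg, genome = cfg$genome, founders = fdr$founders,
    founder_lines = fdr$founder_lines, site_class = fdr$site_class,
    families = families, pedigree = do.call(rbind, ped_rows),
    markers = markers, depths = depths,
    truth_segments = do.call(rbind, truth_segs),
    truth_crossovers = if (length(truth_cx)) do.call(rbind, truth_cx) else
      data.frame(individual = character(), chrom = character(),
                 pos = integer(), stringsAsFactors = FALSE)),
    class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("sim_cross: ", length(x$families), " families, ",
      nrow(x$founders$sites), " founder sites on ",
      nrow(x$genome), " chromosomes (seed ", x$cfg$seed, ")\n", sep = "")
  invisible(x)
}

#' Binomially thin read depths to emulate lower sequencing coverage
#'
#' Every read is kept independently with probability `keep_prob`, so a
#' thinned dataset is a coupled subsample of the original: titrating
#' coverage downward through repeated thinning only removes information.
#'
#' @param depths long depth table (`n_ref`, `n_alt` columns).
#' @param keep_prob per-read retention probability in `[0, 1]`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return The thinned table (rows that lose all reads are dropped).
#' @export
thin_depths <- function(depths, keep_prob, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(keep_prob >= 0, keep_prob <= 1)
  out <- depths
  out$n_ref <- stats::rbinom(nrow(out), out$n_ref, keep_prob)
  out$n_alt <- stats::rbinom(nrow(out), out$n_alt, keep_prob)
  keep <- out$n_ref + out$n_alt >= 1
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "samples") <- attr(depths, "samples")
  res
}

#' Write a simulated dataset in the pipeline's input dialects
#'
#' Emits `genome.tsv`, `pedigree.tsv`, `founders.vcf`, `offspring.vcf`
#' (multi-sample, AD fields), per-family `markers_<family>.tsv` of the
#' truly informative sites, `truth_segments.tsv` and
#' `truth_crossovers.tsv`.
#'
#' @param sim a `sim_cross`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
sim_write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cross"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(sim$genome),
                     file.path(dir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  write_founder_vcf(sim$founders, file.path(dir, "founders.vcf"),
                    header_lines = paste0("mosaicimpute_sim seed=",
                                          sim$cfg$seed))
  sites <- sim$founders$sites
  d <- sim$depths
  i <- match(paste(d$chrom, d$pos), paste(sites$chrom, sites$pos))
  d$ref <- sites$ref[i]; d$alt <- sites$alt[i]
  write_offspring_vcf(d, file.path(dir, "offspring.vcf"),
                      samples = names(sim$families),
                      header_lines = paste0("mosaicimpute_sim seed=",
                                            sim$cfg$seed))
  for (f2 in names(sim$markers)) {
    write_marker_table(sim$markers[[f2]],
                       file.path(dir, paste0("markers_", f2, ".tsv")))
  }
  utils::write.table(sim$truth_segments,
                     file.path(dir, "truth_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_crossovers,
                     file.path(dir, "truth_crossovers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
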