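small_cfg <- function(...) {
  sim_config(genome_spec(c("1", "2"), c(8e6, 4e6)), n_families = 2,
             informative_density_per_mb = 200, seed = 99, ...)
}

test_that("founder simulation honours the fixation limits", {
  # all sites fixed between lines, no within-line variation:
  # every site is informative for every family
  cfg <- sim_config(genome_spec("1", 2e6), n_families = 1,
                    informative_density_per_mb = 100, fixed_fraction = 1,
                    within_line_het = 0, seed = 1)
  sim <- simulate_cross(cfg)
  expect_true(all(sim$site_class == "fixed"))
  expect_equal(nrow(sim$markers[[1]]), nrow(sim$founders$sites))
  ids <- mosaicimpute:::sim_founder_ids(cfg)
  pooled <- select_pooled_informative(sim$founders, ids$h, ids$l)
  expect_equal(nrow(pooled), nrow(sim$founders$sites))

  # no deliberately fixed sites: any pooled-informative site must come
  # from chance fixation of the sampled founder pools (line drift)
  cfg0 <- sim_config(genome_spec("1", 2e6), n_families = 1,
                     informative_density_per_mb = 50, fixed_fraction = 0,
                     within_line_het = 0.3, seed = 2)
  f0 <- simulate_founders(cfg0)
  expect_equal(sum(f0$site_class == "fixed"), 0)
  h_ids <- names(f0$founder_lines)[f0$founder_lines == "H"]
  l_ids <- names(f0$founder_lines)[f0$founder_lines == "L"]
  pooled0 <- select_pooled_informative(f0$founders, h_ids, l_ids)
  g <- f0$founders$geno
  fixed_by_chance <- (rowSums(g[, h_ids]) == 0 &
                        rowSums(g[, l_ids]) == 2 * length(l_ids)) |
    (rowSums(g[, h_ids]) == 2 * length(h_ids) & rowSums(g[, l_ids]) == 0)
  expect_equal(nrow(pooled0), sum(fixed_by_chance))
})

test_that("realized informative density is calibrated to the target", {
  dens <- vapply(1:6, function(s) {
    cfg <- sim_config(genome_spec("1", 10e6), n_families = 1,
                      informative_density_per_mb = 300, seed = s)
    sim <- simulate_cross(cfg)
    nrow(sim$markers[[1]]) / 10
  }, 0)
  # binomial sampling spread around the 300/Mb target over several seeds
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 300), 3 * max(se, 5))
})

test_that("meiosis respects the map length and hard interference", {
  cfg <- small_cfg()
  # zero map rate: no crossovers, gamete is a single parental haplotype
  cfg0 <- sim_config(genome_spec("1", 8e6), map_rate_cm_per_mb = 1e-9,
                     seed = 3)
  set.seed(3)
  m0 <- simulate_meiosis("H", "L", 8e6, cfg0)
  expect_length(m0$crossovers, 0)
  expect_equal(nrow(m0$segments), 1)
  expect_true(m0$segments$hap %in% c("H", "L"))

  # all crossover pairs at least the interference gap apart
  set.seed(4)
  gaps <- c()
  for (i in 1:1000) {
    m <- simulate_meiosis("H", "L", 40e6, sim_config(
      genome_spec("1", 40e6), interference_min_gap_bp = 5e6, seed = 1))
    if (length(m$crossovers) >= 2) gaps <- c(gaps, diff(m$crossovers))
  }
  expect_true(all(gaps >= 5e6))

  # mean crossover count matches the map length in Morgans
  set.seed(5)
  cfg_free <- sim_config(genome_spec("1", 50e6),
                         interference_min_gap_bp = 0, seed = 1)
  counts <- vapply(1:4000, function(i)
    length(simulate_meiosis("H", "L", 50e6, cfg_free)$crossovers), 0)
  morgans <- 50e6 * 3 / 100 / 1e6  # 1.5 M
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - morgans), 3 * se)
})

test_that("read simulation follows the Poisson/error model", {
  cfg <- small_cfg()
  dose <- rep(2L, 5000)
  # zero coverage: no reads at all
  cfg0 <- sim_config(genome_spec("1", 1e6), coverage = 0, seed = 1)
  rd0 <- simulate_reads(dose, rep("ref", 5000), cfg0, seed = 6)
  expect_true(all(rd0$n_ref + rd0$n_alt == 0))
  # zero error on HH truth: never a wrong-line read
  cfg_noerr <- sim_config(genome_spec("1", 1e6), coverage = 2,
                          seq_error = 0, seed = 1)
  rd1 <- simulate_reads(dose, rep("ref", 5000), cfg_noerr, seed = 7)
  expect_true(all(rd1$n_alt == 0))
  expect_gt(sum(rd1$n_ref), 0)
  # covered fraction approximates 1 - exp(-coverage)
  cfg_cov <- sim_config(genome_spec("1", 1e6), coverage = 0.33, seed = 1)
  rd2 <- simulate_reads(dose, rep("ref", 5000), cfg_cov, seed = 8)
  p <- mean(rd2$n_ref + rd2$n_alt >= 1)
  want <- 1 - exp(-0.33)
  expect_lt(abs(p - want), 3 * sqrt(want * (1 - want) / 5000))
})

test_that("the whole simulation is byte-identical under a fixed seed", {
  a <- simulate_cross(small_cfg())
  b <- simulate_cross(small_cfg())
  expect_identical(a, b)
  d <- simulate_cross(sim_config(genome_spec(c("1", "2"), c(8e6, 4e6)),
                                 n_families = 2,
                                 informative_density_per_mb = 200,
                                 seed = 100))
  expect_false(identical(a$truth_segments, d$truth_segments))
  # written dataset is byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_write_dataset(a, d1); sim_write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("truth segments tile chromosomes and depths only cover marker sites", {
  sim <- simulate_cross(small_cfg())
  for (f2 in names(sim$families)) {
    for (ch in c("1", "2")) {
      s <- sim$truth_segments[sim$truth_segments$individual == f2 &
                                sim$truth_segments$chrom == ch, ]
      expect_equal(s$start[1], 1)
      expect_equal(s$end[nrow(s)],
                   sim$genome$length[match(ch, sim$genome$chrom)])
      if (nrow(s) > 1) {
        expect_equal(s$start[-1], head(s$end, -1) + 1)
        expect_true(all(s$state[-1] != head(s$state, -1)))
      }
    }
    d <- sim$depths[sim$depths$sample == f2, ]
    m <- sim$markers[[f2]]
    expect_true(all(paste(d$chrom, d$pos) %in% paste(m$chrom, m$pos)))
  }
})

test_that("thinning reads is a coupled monotone subsample", {
  sim <- simulate_cross(small_cfg())
  thinned <- thin_depths(sim$depths, 0.5, seed = 9)
  expect_lt(sum(thinned$n_ref + thinned$n_alt),
            sum(sim$depths$n_ref + sim$depths$n_alt))
  key <- function(d) paste(d$chrom, d$pos, d$sample)
  expect_true(all(key(thinned) %in% key(sim$depths)))
  i <- match(key(thinned), key(sim$depths))
  expect_true(all(thinned$n_ref <= sim$depths$n_ref[i]))
  expect_true(all(thinned$n_alt <= sim$depths$n_alt[i]))
})

test_that("perfect data reconstructs truth segments away from breakpoints", {
  # deep coverage, zero error: decoded states must match truth at every
  # marker outside breakpoint intervals
  cfg <- sim_config(genome_spec("1", 20e6), n_families = 1,
                    informative_density_per_mb = 100, coverage = 5,
                    seq_error = 1e-6, seed = 12)
  sim <- simulate_cross(cfg)
  f2 <- names(sim$families)[1]
  obs <- extract_depths(sim$depths, sim$markers[[f2]], f2)
  seg <- reconstruct_mosaic(obs, sim$genome, hmm_config(), f2)
  truth <- sim$truth_segments[sim$truth_segments$individual == f2, ]
  st_truth <- truth$state[findInterval(obs$pos, truth$start)]
  st_hat <- rep(NA_character_, nrow(obs))
  s <- seg$segments
  st_hat <- s$state[findInterval(obs$pos, s$start)]
  in_bp <- rep(FALSE, nrow(obs))
  for (r in seq_len(nrow(seg$breakpoints))) {
    in_bp <- in_bp | (obs$pos >= seg$breakpoints$left_bp[r] &
                        obs$pos <= seg$breakpoints$right_bp[r])
  }
  tr_cx <- sim$truth_crossovers$pos[sim$truth_crossovers$individual == f2]
  for (cx in tr_cx) in_bp <- in_bp | abs(obs$pos - cx) < 1e5
  expect_true(all(st_hat[!in_bp] == st_truth[!in_bp]))
})
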