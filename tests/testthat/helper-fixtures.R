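# Shared fixtures and independent oracles, all built in code.

toy_genome <- function() genome_spec(c("1", "2"), c(10e6, 5e6))

# minimal conforming pedigree table: 4 F0, 2 F1, 1 F2
toy_pedigree <- function() {
  data.frame(
    id = c("H1", "H2", "L1", "L2", "S1", "D1", "X1"),
    generation = c("F0", "F0", "F0", "F0", "F1", "F1", "F2"),
    line = c("H", "H", "L", "L", NA, NA, NA),
    sire = c(NA, NA, NA, NA, "H1", "H2", "S1"),
    dam = c(NA, NA, NA, NA, "L1", "L2", "D1"),
    stringsAsFactors = FALSE)
}

toy_family <- function() {
  nuclear_family("X1", "S1", "D1", f0_h = c("H1", "H2"),
                 f0_l = c("L1", "L2"))
}

# founder_set with explicit doses; geno is a matrix with founder columns
make_founders <- function(geno, chrom = "1",
                          pos = seq_len(nrow(geno)) * 1000,
                          qual = 100) {
  n <- nrow(geno)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep("A", n), alt = rep("G", n),
                      qual = rep_len(qual, n), stringsAsFactors = FALSE)
  founder_set(sites, geno)
}

random_founder_geno <- function(n, ids = c("H1", "H2", "L1", "L2"),
                                p_missing = 0.05) {
  g <- matrix(sample(c(0L, 1L, 2L), n * length(ids), replace = TRUE),
              n, length(ids), dimnames = list(NULL, ids))
  g[runif(length(g)) < p_missing] <- NA
  g
}

# observation table for one chromosome
make_obs <- function(n_H, n_L, chrom = "1",
                     pos = seq_along(n_H) * 10000,
                     individual = "X1") {
  structure(data.frame(chrom = rep_len(chrom, length(n_H)), pos = pos,
                       n_H = n_H, n_L = n_L, stringsAsFactors = FALSE),
            class = c("site_obs", "data.frame"), individual = individual)
}

make_seg <- function(starts, ends, states, chrom = "1",
                     individual = "X1") {
  mosaicimpute:::new_mosaic_seg(
    data.frame(individual = individual, chrom = chrom, start = starts,
               end = ends, state = states, stringsAsFactors = FALSE),
    mosaicimpute:::bp_empty())
}

# ---- independent oracles ------------------------------------------------

# exhaustive-path likelihood and best path for a built HMM: sums/maximises
# over all 3^n state sequences using the model's initial, transition and
# emission terms directly (no dynamic programming).
enumerate_paths <- function(hmm) {
  n <- length(hmm$pos)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  ll <- hmm$log_pi[paths[, 1]] + hmm$log_emis[cbind(paths[, 1], 1)]
  if (n > 1) {
    for (t in 2:n) {
      m <- mosaicimpute:::step_matrix(hmm, t - 1)
      ll <- ll + m[cbind(paths[, t - 1], paths[, t])] +
        hmm$log_emis[cbind(paths[, t], t)]
    }
  }
  mx <- max(ll)
  list(loglik = mx + log(sum(exp(ll - mx))),
       best = paths[which.max(ll), ])
}

# per-bp recount of decided fraction on a toy genome
callrate_oracle <- function(seg, genome) {
  tot <- 0; dec <- 0
  for (ch in assayed_chroms(genome)) {
    len <- genome$length[match(ch, genome$chrom)]
    tot <- tot + len
    s <- seg$segments[seg$segments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      if (s$state[i] %in% c("HH", "HL", "LL")) {
        dec <- dec + s$end[i] - s$start[i] + 1
      }
    }
  }
  dec / tot
}

# per-bp scan: bin code is the state seen at every bp of the bin, else missing
bin_oracle <- function(seg, genome, bin_size) {
  out <- list()
  for (ch in assayed_chroms(genome)) {
    len <- genome$length[match(ch, genome$chrom)]
    s <- seg$segments[seg$segments$chrom == ch, , drop = FALSE]
    state_at <- function(bp) {
      hit <- s$state[s$start <= bp & s$end >= bp]
      if (length(hit) == 1) hit else NA_character_
    }
    starts <- seq(1, len, by = bin_size)
    for (st in starts) {
      en <- min(st + bin_size - 1, len)
      codes <- unique(vapply(st:en, state_at, ""))
      code <- if (length(codes) == 1 && codes %in% c("HH", "HL", "LL"))
        codes else "missing"
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = st, end = en, code = code,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
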