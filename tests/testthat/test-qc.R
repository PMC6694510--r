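mb <- 1e6

test_that("close double crossovers merge when flanks agree, mask when they differ", {
  # HH(0-10), HL(10-12), HH(12-20): 2 Mb < 3 Mb and flanks agree -> merge
  seg <- make_seg(c(1, 10 * mb + 1, 12 * mb + 1),
                  c(10 * mb, 12 * mb, 20 * mb), c("HH", "HL", "HH"))
  out <- remove_close_double_crossovers(seg)
  expect_equal(out$segments$state, "HH")
  expect_equal(out$segments$end, 20 * mb)
  expect_equal(attr(out, "removal_log")$action, "merged")

  # 4 Mb middle segment: untouched
  seg2 <- make_seg(c(1, 10 * mb + 1, 14 * mb + 1),
                   c(10 * mb, 14 * mb, 20 * mb), c("HH", "HL", "HH"))
  out2 <- remove_close_double_crossovers(seg2)
  expect_equal(out2$segments$state, c("HH", "HL", "HH"))

  # disagreeing flanks: HH, HL(2 Mb), LL -> HH, UU, LL; the two decided
  # crossovers disappear from the count
  seg3 <- make_seg(c(1, 10 * mb + 1, 12 * mb + 1),
                   c(10 * mb, 12 * mb, 20 * mb), c("HH", "HL", "LL"))
  expect_equal(unname(count_crossovers(seg3)), 2)
  out3 <- remove_close_double_crossovers(seg3)
  expect_equal(out3$segments$state, c("HH", "UU", "LL"))
  expect_equal(unname(count_crossovers(out3)), 0)
  # merge-to-left option
  out3b <- remove_close_double_crossovers(
    seg3, qc_config(double_co_action = "merge_left"))
  expect_equal(out3b$segments$state, c("HH", "LL"))
})

test_that("double-crossover removal is idempotent and never raises the count", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    cuts <- sort(sample.int(40 * mb - 1, n - 1))
    starts <- c(1, cuts + 1); ends <- c(cuts, 40 * mb)
    states <- character(n)
    states[1] <- sample(c("HH", "HL", "LL"), 1)
    for (i in 2:n) states[i] <- sample(
      setdiff(c("HH", "HL", "LL"), states[i - 1]), 1)
    seg <- make_seg(starts, ends, states)
    out1 <- remove_close_double_crossovers(seg)
    out2 <- remove_close_double_crossovers(out1)
    expect_identical(out1$segments, out2$segments)
    expect_lte(count_crossovers(out1), count_crossovers(seg))
    # no remaining decided internal segment flanked by crossovers is short
    s <- out1$segments
    if (nrow(s) >= 3) {
      for (i in 2:(nrow(s) - 1)) {
        if (all(s$state[(i - 1):(i + 1)] %in% c("HH", "HL", "LL"))) {
          expect_gte(s$end[i] - s$start[i] + 1, 3 * mb)
        }
      }
    }
    # masking can only lower the decided call rate
    g <- genome_spec("1", 40 * mb)
    expect_lte(call_rate(out1, g), call_rate(seg, g))
  }
})

test_that("call rate equals the per-bp recount", {
  g <- genome_spec("1", 100 * mb)
  seg <- make_seg(1, 100 * mb, "HL")
  expect_equal(call_rate(seg, g), 1.0)
  seg2 <- make_seg(c(1, 50 * mb + 1, 55 * mb + 1),
                   c(50 * mb, 55 * mb, 100 * mb), c("HH", "UU", "HL"))
  expect_equal(call_rate(seg2, g), 0.95)
  # toy per-bp oracle on a small genome
  gt <- genome_spec("1", 1000)
  seg3 <- make_seg(c(1, 301, 700), c(300, 699, 1000), c("HH", "UU", "LL"))
  expect_equal(call_rate(seg3, gt), callrate_oracle(seg3, gt))
})

test_that("crossover outliers are flagged robustly and order-invariantly", {
  set.seed(52)
  mk <- function(id, n_co) {
    cuts <- sort(sample(seq(5 * mb, 95 * mb, by = 5 * mb), n_co))
    starts <- c(1, cuts + 1); ends <- c(cuts, 100 * mb)
    states <- rep(c("HH", "HL"), length.out = n_co + 1)
    make_seg(starts, ends, states, individual = id)
  }
  ids <- sprintf("I%02d", 1:10)
  segs <- lapply(seq_along(ids), function(i)
    mk(ids[i], sample(3:5, 1)))
  segs[[10]] <- mk(ids[10], 15)
  seg <- bind_mosaics(segs)
  g <- genome_spec("1", 100 * mb)
  rep1 <- crossover_outliers(seg, g, qc_config(outlier_mode = "crossover_count"))
  expect_equal(rep1$individual[rep1$flagged], "I10")
  # identical counts: nobody flagged
  seg_same <- bind_mosaics(lapply(ids, function(id) mk(id, 4)))
  rep2 <- crossover_outliers(seg_same, g,
                             qc_config(outlier_mode = "crossover_count"))
  expect_false(any(rep2$flagged))
  # permutation of individuals leaves flags unchanged
  seg_perm <- bind_mosaics(segs[c(5:10, 1:4)])
  rep3 <- crossover_outliers(seg_perm, g,
                             qc_config(outlier_mode = "crossover_count"))
  expect_equal(rep3, rep1)
  # call-rate mode delegates to the call-rate threshold
  seg_cr <- bind_mosaics(list(
    make_seg(1, 100 * mb, "HH", individual = "A"),
    make_seg(c(1, 80 * mb + 1), c(80 * mb, 100 * mb), c("HH", "UU"),
             individual = "B")))
  rep4 <- crossover_outliers(seg_cr, g, qc_config(outlier_mode = "call_rate"))
  expect_equal(rep4$individual[rep4$flagged], "B")
})

test_that("binning assigns fully covered bins and masks crossover bins", {
  g <- genome_spec("1", 5 * mb)
  seg <- make_seg(1, 5 * mb, "HH")
  b <- bin_genotypes(seg, g)
  expect_equal(nrow(b), 5)
  expect_true(all(b$code == "HH"))
  # crossover at 1.5 Mb: bin 2 masked
  seg2 <- make_seg(c(1, 1.5 * mb + 1), c(1.5 * mb, 5 * mb), c("HH", "HL"))
  b2 <- bin_genotypes(seg2, g)
  expect_equal(b2$code, c("HH", "missing", "HL", "HL", "HL"))
  # per-bp oracle on random segmentations of a toy genome
  set.seed(53)
  gt <- genome_spec("1", 10000)
  for (rep in 1:10) {
    cuts <- sort(sample(2:9998, 3))
    seg3 <- make_seg(c(1, cuts + 1), c(cuts, 10000),
                     sample(c("HH", "HL", "LL", "UU"), 4, replace = TRUE))
    b3 <- bin_genotypes(seg3, gt, qc_config(bin_size_bp = 1000))
    oracle <- bin_oracle(seg3, gt, 1000)
    expect_equal(b3$code, oracle$code)
  }
  # terminal partial bin keeps its true span
  g4 <- genome_spec("1", 2.5 * mb)
  b4 <- bin_genotypes(make_seg(1, 2.5 * mb, "LL"), g4)
  expect_equal(b4$end[3] - b4$start[3] + 1, 0.5 * mb)
})

test_that("R/qtl export writes A/H/B/- codes and round-trips", {
  g <- genome_spec("1", 3 * mb)
  seg <- bind_mosaics(list(
    make_seg(c(1, 1.2 * mb), c(1.2 * mb - 1, 3 * mb), c("HH", "HL"),
             individual = "X1"),
    make_seg(1, 3 * mb, "LL", individual = "X2")))
  binned <- bin_genotypes(seg, g)
  path <- withr::local_tempfile(fileext = ".csv")
  export_rqtl(binned, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2 + 3)   # marker/chrom/pos headers + 2 rows
  expect_match(lines[1], "^id,c1_1,")
  x1 <- strsplit(lines[4], ",")[[1]]
  expect_equal(x1, c("X1", "A", "-", "H"))
  expect_equal(strsplit(lines[5], ",")[[1]], c("X2", "B", "B", "B"))
  back <- read_rqtl(path, bin_size_bp = 1e6, genome = g)
  expect_equal(back[order(back$individual, back$start), "code"],
               binned[order(binned$individual, binned$start), "code"])
})

test_that("breakpoint-interval summaries match a sort-based oracle", {
  bp <- data.frame(individual = "X1", chrom = "1",
                   left_bp = c(10000, 50000, 90000),
                   right_bp = c(14000, 58000, 110000),
                   point = 0, left_state = "HH", right_state = "HL",
                   stringsAsFactors = FALSE)
  seg <- mosaicimpute:::new_mosaic_seg(
    make_seg(1, 2e5, "HH")$segments, bp)
  res <- breakpoint_resolution(seg)
  expect_equal(res$lengths, c(4000, 8000, 20000))
  expect_equal(res$summary$median, sort(res$lengths)[2])
  empty <- breakpoint_resolution(make_seg(1, 1e6, "HH"))
  expect_equal(empty$summary$n, 0)
  expect_length(empty$lengths, 0)
})

test_that("segment export converts coordinates for BED", {
  seg <- make_seg(c(1, 1001), c(1000, 5000), c("HH", "HL"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segments(seg, tsv, header_lines = "demo")
  write_segments(seg, bed, format = "bed")
  x <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(x$start, c(1, 1001))
  y <- utils::read.delim(bed, header = FALSE)
  expect_equal(y$V2, c(0, 1000))  # 0-based half-open
  expect_equal(y$V3, c(1000, 5000))
})
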