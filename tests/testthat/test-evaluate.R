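mk_binned <- function(codes, individual = "X1", chrom = "1") {
  n <- length(codes)
  structure(data.frame(individual = individual, chrom = chrom,
                       start = seq(1, by = 1e6, length.out = n),
                       end = seq(1e6, by = 1e6, length.out = n),
                       code = codes, stringsAsFactors = FALSE),
            class = c("binned_genotypes", "data.frame"))
}

test_that("agreement fractions follow direct recounting", {
  codes <- rep(c("HH", "HL", "LL"), length.out = 10)
  binned <- mk_binned(codes)
  val <- data.frame(chrom = "1", pos = seq(5e5, by = 1e6, length.out = 10),
                    individual = "X1", code = codes,
                    stringsAsFactors = FALSE)
  res <- agreement(binned, val)
  expect_equal(res$per_individual$agreement, 1.0)
  expect_equal(res$overall$mean_locus, 1.0)

  val2 <- val
  val2$code[4] <- "LL"  # one mismatch in 10 comparable loci
  res2 <- agreement(binned, val2)
  expect_equal(res2$per_individual$agreement, 0.9)

  # masked bins are dropped from the comparison, zero comparable -> NA
  binned3 <- mk_binned(rep("missing", 10))
  res3 <- agreement(binned3, val)
  expect_true(is.na(res3$per_individual$agreement))
  expect_equal(res3$n_dropped, 10)
})

test_that("agreement equals a brute-force element-wise comparison", {
  set.seed(61)
  ids <- c("A", "B", "C")
  states <- c("HH", "HL", "LL", "missing")
  binned <- do.call(rbind, lapply(ids, function(id)
    mk_binned(sample(states, 12, replace = TRUE), individual = id)))
  class(binned) <- c("binned_genotypes", "data.frame")
  val <- expand.grid(pos = seq(3e5, by = 1e6, length.out = 12),
                     individual = ids, stringsAsFactors = FALSE)
  val$chrom <- "1"
  val$code <- sample(states, nrow(val), replace = TRUE)
  res <- agreement(binned, val)
  for (id in ids) {
    num <- 0; den <- 0
    for (r in which(val$individual == id)) {
      bin <- binned[binned$individual == id &
                      binned$start <= val$pos[r] &
                      binned$end >= val$pos[r], ]
      if (bin$code != "missing" && val$code[r] != "missing") {
        den <- den + 1
        if (bin$code == val$code[r]) num <- num + 1
      }
    }
    got <- res$per_individual$agreement[res$per_individual$individual == id]
    expect_equal(got, if (den == 0) NA_real_ else num / den)
  }
  # symmetry in the two matrices: swap roles via truth_as_validation
  # and invariance to locus order
  res_shuf <- agreement(binned, val[sample(nrow(val)), ])
  expect_equal(sort(res_shuf$per_individual$agreement),
               sort(res$per_individual$agreement))
})

test_that("truth agreement is exact for a perfect reconstruction and H/L symmetric", {
  g <- genome_spec("1", 10e6)
  truth_seg <- data.frame(individual = "X1", chrom = "1",
                          start = c(1, 4.5e6 + 1), end = c(4.5e6, 10e6),
                          state = c("HH", "HL"), stringsAsFactors = FALSE)
  truth <- list(truth_segments = truth_seg,
                truth_crossovers = data.frame(individual = "X1",
                                              chrom = "1", pos = 4.5e6))
  bp <- data.frame(individual = "X1", chrom = "1", left_bp = 4.4e6,
                   right_bp = 4.6e6, point = 4.5e6, left_state = "HH",
                   right_state = "HL", stringsAsFactors = FALSE)
  seg <- mosaicimpute:::new_mosaic_seg(truth_seg, bp)
  res <- truth_agreement(seg, truth, g)
  expect_equal(res$overall, 1.0)
  expect_equal(res$co_in_interval, 1.0)
  # bins holding the crossover are excluded on both sides
  expect_equal(sum(res$binned$code == "missing"), 1)

  # relabelling H and L everywhere leaves the metrics unchanged
  flip <- c(HH = "LL", HL = "HL", LL = "HH")
  seg_f <- seg; truth_f <- truth
  seg_f$segments$state <- unname(flip[seg$segments$state])
  truth_f$truth_segments$state <- unname(flip[truth_seg$state])
  res_f <- truth_agreement(seg_f, truth_f, g)
  expect_equal(res_f$overall, res$overall)
  expect_equal(res_f$per_individual, res$per_individual)
})

test_that("truth agreement cross-checks against agreement() on exported truth", {
  set.seed(62)
  g <- genome_spec("1", 12e6)
  cuts <- c(3.2e6, 7.8e6)
  truth_seg <- data.frame(individual = "X1", chrom = "1",
                          start = c(1, cuts + 1), end = c(cuts, 12e6),
                          state = c("HH", "HL", "LL"),
                          stringsAsFactors = FALSE)
  truth <- list(truth_segments = truth_seg,
                truth_crossovers = data.frame(individual = character(),
                                              chrom = character(),
                                              pos = numeric()))
  # an imperfect reconstruction with one shifted boundary
  rec_seg <- truth_seg
  rec_seg$end[1] <- 4.2e6; rec_seg$start[2] <- 4.2e6 + 1
  seg <- mosaicimpute:::new_mosaic_seg(rec_seg, mosaicimpute:::bp_empty())
  res <- truth_agreement(seg, truth, g)
  # evaluate the same comparison through the validation-set route,
  # at decided-bin midpoints
  b <- res$binned
  comp <- b[b$code != "missing", ]
  val <- truth_as_validation(truth_seg,
                             data.frame(chrom = comp$chrom,
                                        pos = (comp$start + comp$end) / 2))
  res2 <- agreement(res$binned, val)
  # drop loci in truth-masked bins like truth_agreement does
  tkey <- paste(res$truth_binned$chrom, res$truth_binned$start)
  decided_truth <- res$truth_binned$code != "missing"
  keep <- paste(val$chrom, floor((val$pos - 1) / 1e6) * 1e6 + 1) %in%
    tkey[decided_truth]
  res3 <- agreement(res$binned, val[keep, ])
  expect_equal(res3$per_individual$agreement,
               res$per_individual$agreement)
})

test_that("validation IO validates codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tindividual\tcode", "1\t100\tX1\tHH",
               "1\t200\tX1\tZZ"), path)
  expect_error(read_validation(path), "codes")
  writeLines(c("chrom\tpos\tindividual\tcode", "1\t300\tX1\tHL",
               "1\t100\tX1\tmissing"), path)
  v <- read_validation(path)
  expect_equal(v$pos, c(100, 300))  # sorted
})
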