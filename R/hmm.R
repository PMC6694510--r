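#' HMM configuration for mosaic reconstruction
#'
#' @param window_large,window_small number of consecutive markers averaged
#'   per window on large / small chromosomes (defaults 200 / 50).
#' @param small_chrom_marker_threshold a chromosome is treated as "small"
#'   (window `window_small`) when it carries fewer informative markers
#'   than this (default 2000), else "large".
#' @param recomb_rate_cm_per_mb genome-wide recombination rate used to
#'   turn physical distance into map distance (default 3.0 cM/Mb, a
#'   chicken-like genome average; configurable per analysis).
#' @param seq_error per-read probability `epsilon` that a read reports the
#'   wrong founder line (sequencing + mapping error; default 0.01).
#' @param min_hom_reads minimum reads `k` of a single line required to
#'   call a site-level homozygous state (default 2); below `k` the site is
#'   only "H or unknown" (HU) / "L or unknown" (LU).
#' @param decode_mode `"viterbi"` (default) or `"posterior"` (per-marker
#'   max-posterior).
#' @return An `hmm_config` list.
#' @export
hmm_config <- function(window_large = 200, window_small = 50,
                       small_chrom_marker_threshold = 2000,
                       recomb_rate_cm_per_mb = 3.0, seq_error = 0.01,
                       min_hom_reads = 2,
                       decode_mode = c("viterbi", "posterior")) {
  stopifnot(window_large >= 1, window_small >= 1,
            seq_error > 0, seq_error < 0.5, min_hom_reads >= 1,
            recomb_rate_cm_per_mb > 0)
  structure(list(window_large = window_large, window_small = window_small,
                 small_chrom_marker_threshold = small_chrom_marker_threshold,
                 recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
                 seq_error = seq_error, min_hom_reads = min_hom_reads,
                 decode_mode = match.arg(decode_mode)),
            class = "hmm_config")
}

#' Translate polarized read counts into site-level genotype states
#'
#' Each scored marker is translated into one of six states: `HH`, `HU`,
#' `HL`, `LU`, `LL`, `UU`, where H/L are the two founder lines and U is
#' unknown. Reads from both lines give `HL`; at least `k` reads from one
#' line and none from the other give the homozygous state; fewer than `k`
#' one-sided reads give the corresponding ambiguous state; no reads give
#' `UU`. The U-bearing states express read-level ambiguity only and never
#' appear in final segmentations.
#'
#' @param n_H,n_L non-negative integer read counts (vectorized).
#' @param min_hom_reads threshold `k` (default 2).
#' @return Character vector of states.
#' @export
translate_states <- function(n_H, n_L, min_hom_reads = 2) {
  stopifnot(length(n_H) == length(n_L), all(n_H >= 0), all(n_L >= 0))
  k <- min_hom_reads
  out <- rep("UU", length(n_H))
  out[n_H >= 1 & n_L >= 1] <- "HL"
  out[n_H >= k & n_L == 0] <- "HH"
  out[n_H >= 1 & n_H < k & n_L == 0] <- "HU"
  out[n_L >= k & n_H == 0] <- "LL"
  out[n_L >= 1 & n_L < k & n_H == 0] <- "LU"
  out
}

#' Window-averaged line-read ratios along a chromosome
#'
#' Read counts are averaged across non-overlapping windows of `window`
#' consecutive markers; the trailing partial window is merged into the
#' previous one. Per window the H-read fraction
#' `f = sum(n_H) / sum(n_H + n_L)` and the total depth are reported;
#' windows with zero reads are flagged (`f = NA`). A chromosome with fewer
#' markers than one window becomes a single whole-chromosome window, with
#' a warning.
#'
#' @param obs position-sorted `site_obs` rows of one chromosome.
#' @param window markers per window.
#' @return data.frame `window start_idx end_idx start_pos end_pos n_H
#'   depth f zero_reads`.
#' @export
window_ratios <- function(obs, window) {
  n <- nrow(obs)
  if (n == 0) stop("no observations")
  if (n < window) {
    warning("fewer markers (", n, ") than one window (", window,
            "); using a single whole-chromosome window")
    starts <- 1L
  } else {
    starts <- seq.int(1L, n - n %% window, by = window)
    starts <- starts[starts + window - 1 <= n]
  }
  ends <- c(starts[-1] - 1L, n)  # trailing partial merged into last window
  nh <- cumsum(obs$n_H); tot <- cumsum(obs$n_H + obs$n_L)
  wh <- diff(c(0, nh[ends])); wt <- diff(c(0, tot[ends]))
  data.frame(window = seq_along(starts), start_idx = starts,
             end_idx = ends, start_pos = obs$pos[starts],
             end_pos = obs$pos[ends], n_H = wh, depth = wt,
             f = ifelse(wt > 0, wh / wt, NA_real_),
             zero_reads = wt == 0)
}

#' Estimate the chromosome-level allele-ratio bias from window ratios
#'
#' Windows whose H-read fraction lies in `[0.25, 0.75]` are taken as
#' predominantly heterozygous (HL) territory; their mean deviation from
#' 0.5 estimates a systematic line-read bias `b` (reference bias, mapping
#' asymmetry). The bias magnitude is folded into the per-read error used
#' by the emission model.
#'
#' @param windows output of [window_ratios()].
#' @return Scalar bias `b` (0 when no informative window exists).
#' @export
estimate_read_bias <- function(windows) {
  f <- windows$f[!windows$zero_reads & !is.na(windows$f)]
  f <- f[f >= 0.25 & f <= 0.75]
  if (!length(f)) return(0)
  mean(f) - 0.5
}

haldane_r <- function(d_bp, rate_cm_per_mb) {
  d_morgan <- d_bp * rate_cm_per_mb / 100 / 1e6
  0.5 * (1 - exp(-2 * d_morgan))
}

#' Build the chromosome-specific mosaic HMM
#'
#' Hidden states are the three line-origin genotypes `HH`, `HL`, `LL`.
#' Between adjacent markers at physical distance `d`, the per-meiosis
#' recombination fraction is Haldane's `r = 0.5 (1 - exp(-2 d m))` with
#' map distance from the configured cM/Mb rate; transitions changing one
#' line origin (`HH <-> HL`, `HL <-> LL`) have probability `r`, the
#' double change `HH <-> LL` has `r^2`, and the remaining mass stays.
#' Emissions are binomial in the H-read count at each site with per-read
#' `P(H | HH) = 1 - eps'`, `P(H | HL) = 0.5`, `P(H | LL) = eps'`, where
#' `eps'` is the configured error inflated by the magnitude of the
#' window-estimated allele-ratio bias. The window size (200 or 50 markers)
#' follows the chromosome's marker count, making the HMM
#' chromosome-specific. The initial distribution is the F2 expectation
#' (1/4, 1/2, 1/4).
#'
#' @param obs position-sorted `site_obs` rows of one chromosome.
#' @param cfg an [hmm_config()].
#' @return An `lmosaic_hmm` list: `states`, `pos`, `n_H`, `n_L`, `log_pi`,
#'   `log_emis` (3 x n), `trans` (list of per-step 3 x 3 matrices is
#'   avoided: `r` vector of length n-1 plus `log_trans` 9 x (n-1)),
#'   `p_h`, `eps_eff`, `bias`, `windows`, `window_size`.
#' @export
build_hmm <- function(obs, cfg = hmm_config()) {
  n <- nrow(obs)
  if (n == 0) stop("cannot build an HMM for a chromosome with 0 markers")
  if (is.unsorted(obs$pos, strictly = FALSE)) stop("observations not sorted")
  window <- if (n < cfg$small_chrom_marker_threshold) cfg$window_small else
    cfg$window_large
  windows <- suppressWarnings(window_ratios(obs, window))
  bias <- estimate_read_bias(windows)
  eps_eff <- min(0.45, cfg$seq_error + abs(bias))
  p_h <- c(HH = 1 - eps_eff, HL = 0.5, LL = eps_eff)

  tot <- obs$n_H + obs$n_L
  log_emis <- rbind(
    HH = stats::dbinom(obs$n_H, tot, p_h[["HH"]], log = TRUE),
    HL = stats::dbinom(obs$n_H, tot, p_h[["HL"]], log = TRUE),
    LL = stats::dbinom(obs$n_H, tot, p_h[["LL"]], log = TRUE))

  r <- if (n > 1) haldane_r(diff(obs$pos), cfg$recomb_rate_cm_per_mb) else
    numeric(0)
  # rows of each step matrix: from-state HH, HL, LL; columns: to-state
  log_trans <- rbind(
    HH_HH = log(1 - r - r^2), HH_HL = log(r), HH_LL = log(r^2),
    HL_HH = log(r), HL_HL = log(1 - 2 * r), HL_LL = log(r),
    LL_HH = log(r^2), LL_HL = log(r), LL_LL = log(1 - r - r^2))

  structure(list(states = c("HH", "HL", "LL"), pos = obs$pos,
                 n_H = obs$n_H, n_L = obs$n_L,
                 log_pi = log(c(HH = 0.25, HL = 0.5, LL = 0.25)),
                 log_emis = log_emis, log_trans = log_trans, r = r,
                 p_h = p_h, eps_eff = eps_eff, bias = bias,
                 windows = windows, window_size = window),
            class = "lmosaic_hmm")
}

step_matrix <- function(hmm, t) {
  matrix(hmm$log_trans[, t], 3, 3, byrow = TRUE,
         dimnames = list(hmm$states, hmm$states))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Forward log-likelihood of the observations under the mosaic HMM
#'
#' @param hmm a model built by [build_hmm()].
#' @return Total log-likelihood (scalar).
#' @export
forward_loglik <- function(hmm) {
  n <- length(hmm$pos)
  a <- hmm$log_pi + hmm$log_emis[, 1]
  if (n > 1) {
    for (t in 2:n) {
      m <- step_matrix(hmm, t - 1)
      a <- vapply(1:3, function(j) logsumexp(a + m[, j]), 0) +
        hmm$log_emis[, t]
    }
  }
  logsumexp(a)
}

forward_backward <- function(hmm) {
  n <- length(hmm$pos)
  alpha <- matrix(NA_real_, 3, n)
  beta <- matrix(0, 3, n)
  alpha[, 1] <- hmm$log_pi + hmm$log_emis[, 1]
  if (n > 1) {
    for (t in 2:n) {
      m <- step_matrix(hmm, t - 1)
      alpha[, t] <- vapply(1:3, function(j) logsumexp(alpha[, t - 1] + m[, j]),
                           0) + hmm$log_emis[, t]
    }
    for (t in (n - 1):1) {
      m <- step_matrix(hmm, t)
      beta[, t] <- vapply(1:3, function(i) {
        logsumexp(m[i, ] + hmm$log_emis[, t + 1] + beta[, t + 1])
      }, 0)
    }
  }
  g <- alpha + beta
  g <- sweep(g, 2, apply(g, 2, logsumexp))
  exp(g)
}

#' Viterbi decoding of the mosaic HMM
#'
#' Ties in the dynamic program are broken toward the state of the
#' preceding marker (self-transition preferred), which favours fewer
#' crossovers; a residual tie takes the lower state index.
#'
#' @param hmm a model built by [build_hmm()].
#' @return Integer vector of state indices (1 = HH, 2 = HL, 3 = LL).
#' @export
viterbi_path <- function(hmm) {
  n <- length(hmm$pos)
  lt <- hmm$log_trans
  le <- hmm$log_emis
  delta <- hmm$log_pi + le[, 1]
  if (n == 1) return(which.max(delta))
  ptr <- matrix(1L, 3, n)
  for (t in 2:n) {
    s <- t - 1L
    for (j in 1:3) {
      cand <- delta + lt[c(j, j + 3L, j + 6L), s]
      best <- max(cand)
      arg <- which(cand == best)
      # prefer staying in the same state on ties
      arg <- if (j %in% arg) j else arg[1]
      ptr[j, t] <- arg
      if (j == 1) d1 <- best + le[1, t]
      else if (j == 2) d2 <- best + le[2, t]
      else d3 <- best + le[3, t]
    }
    delta <- c(d1, d2, d3)
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in n:2) path[t - 1] <- ptr[path[t], t]
  path
}
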