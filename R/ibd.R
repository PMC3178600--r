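# Windowed Bayesian IBD estimation -------------------------------------------
#
# For a sample pair, concordant-homozygote and missing loci are removed and
# two informative tracks are built:
#   d0 track : loci with state IBS0 or IBS2*; an IBS0 call is the "event".
#              Within IBD0 the event fraction is 1/3 (allele frequencies
#              cancel); within not-IBD0 it is only the genotyping error.
#   d12 track: loci with state IBS1 or IBS2*; an IBS1 call is the "event".
#              Within IBD1 the event fraction is the allele-frequency
#              integral c (default 0.518); within IBD2 only the error.
# Overlapping fixed-count windows are scanned along each chromosome; per
# window, binomial likelihoods give P(IBD0 | S) on the d0 track and the
# IBD1-vs-IBD2 split of the remaining mass on the d12 track.  The two window
# sets have different genomic spans, so they are reconciled on a per-base-pair
# profile (averaging overlapping windows) before genome-length weighting into
# the Cotterman coefficient estimates K0, K1, K2.

#' Parameters of the windowed IBD model
#'
#' @param window_size number of track SNPs per window (default 300; sizes in
#'   150-600 behave similarly, larger windows blur IBD-state boundaries).
#' @param step window advance in track SNPs (default `window_size / 3`).
#' @param error genotyping error rate used in the no-event likelihoods
#'   (default 0.01).
#' @param c expected IBS1 fraction among IBS1 + IBS2* loci within IBD1,
#'   integrated over allele frequency; default 0.518 from
#'   [compute_c()]`("empirical_bayes")`.  Must satisfy `error < c <= 2/3`.
#' @param prior_d0,prior_d1,prior_d2 prior IBD-state probabilities
#'   (non-informative 1/3 each).
#' @param prior_d1_given_not_d0 prior split of the not-IBD0 mass (1/2).
#' @return An object of class `ibd_params` (a list of the above).
#' @export
ibd_params <- function(window_size = 300L, step = NULL, error = 0.01,
                       c = 0.518, prior_d0 = 1 / 3, prior_d1 = 1 / 3,
                       prior_d2 = 1 / 3, prior_d1_given_not_d0 = 0.5) {
  if (is.null(step)) step <- max(1L, as.integer(round(window_size / 3)))
  stopifnot(window_size >= 2L, step >= 1L, step <= window_size)
  if (!(error > 0 && error < c && c <= 2 / 3))
    stop("require 0 < error < c <= 2/3 (got error = ", error, ", c = ", c, ")")
  pr <- c(prior_d0, prior_d1, prior_d2)
  if (abs(sum(pr) - 1) > 1e-9 || any(pr <= 0))
    stop("IBD-state priors must be positive and sum to 1")
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 error = error, c = c, prior_d0 = prior_d0,
                 prior_d1 = prior_d1, prior_d2 = prior_d2,
                 prior_d1_given_not_d0 = prior_d1_given_not_d0),
            class = "ibd_params")
}

#' @export
print.ibd_params <- function(x, ...) {
  cat(sprintf(
    "ibd_params: window %d SNPs, step %d, error %.4g, c %.4g, priors (%.3g, %.3g, %.3g)\n",
    x$window_size, x$step, x$error, x$c, x$prior_d0, x$prior_d1, x$prior_d2))
  invisible(x)
}

#' Informative-locus tracks for a pair
#'
#' Removes concordant-homozygote and missing loci and returns the two event
#' tracks used by the windowed estimator (IBS2* loci sit on both tracks).
#'
#' @param table an autosome-filtered `genotype_table`.
#' @param sample_a,sample_b sample ids.
#' @return An object of class `informative_tracks`: list with data.frames
#'   `d0` and `d12`, each holding `chromosome`, `position` and logical
#'   `event` (IBS0 on the d0 track, IBS1 on the d12 track), ordered by
#'   position within chromosome.
#' @export
build_tracks <- function(table, sample_a, sample_b) {
  s <- pair_state_codes(sample_column(table, sample_a),
                        sample_column(table, sample_b))
  chrom <- table$markers$chromosome
  pos <- table$markers$position
  d0 <- which(!is.na(s) & (s == 0L | s == 3L))
  d12 <- which(!is.na(s) & (s == 1L | s == 3L))
  if (length(d0) == 0L && length(d12) == 0L)
    warning("pair ", sample_a, "/", sample_b,
            " shares no informative polymorphism; tracks are empty")
  out <- list(
    d0 = data.frame(chromosome = chrom[d0], position = pos[d0],
                    event = s[d0] == 0L, stringsAsFactors = FALSE),
    d12 = data.frame(chromosome = chrom[d12], position = pos[d12],
                     event = s[d12] == 1L, stringsAsFactors = FALSE),
    sample_a = sample_a, sample_b = sample_b)
  class(out) <- "informative_tracks"
  out
}

#' @export
print.informative_tracks <- function(x, ...) {
  cat("informative_tracks: ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  d0 track: %d SNPs (%d IBS0 events)\n",
              nrow(x$d0), sum(x$d0$event)))
  cat(sprintf("  d12 track: %d SNPs (%d IBS1 events)\n",
              nrow(x$d12), sum(x$d12$event)))
  invisible(x)
}

# windows over one chromosome of one track: half-open [start, end) indices.
# Full windows advance by `step`; SNPs left uncovered beyond the last full
# window form a final partial window if there are >= window_size/2 of them,
# otherwise they are merged into the last window.  Chromosomes with
# < window_size/2 SNPs yield no windows.
window_bounds <- function(n, window_size, step) {
  half <- window_size / 2
  if (n < half) return(NULL)
  if (n <= window_size) return(cbind(start = 1L, end = n + 1L))
  starts <- seq.int(1L, n - window_size + 1L, by = step)
  ends <- starts + window_size
  leftover <- n - (ends[length(ends)] - 1L)
  if (leftover > 0L) {
    if (leftover >= half) {
      starts <- c(starts, ends[length(ends)])
      ends <- c(ends, n + 1L)
    } else ends[length(ends)] <- n + 1L
  }
  cbind(start = starts, end = ends)
}

#' Overlapping windows along the informative tracks
#'
#' Cuts each chromosome of each track into overlapping windows of
#' `window_size` track SNPs advanced by `step`.  A final partial window with
#' at least `window_size / 2` SNPs is emitted at each chromosome end
#' (shorter tails are merged into the preceding window); chromosomes with
#' fewer than `window_size / 2` track SNPs are skipped with a warning.
#' Windows never cross a chromosome boundary.
#'
#' @param tracks an `informative_tracks` object.
#' @param params an [ibd_params()] object.
#' @return data.frame with one row per window: `track` (`"d0"`/`"d12"`),
#'   `chromosome`, `start_idx`/`end_idx` (half-open, into that chromosome's
#'   track), `start_bp`/`end_bp` (first and last marker position),
#'   `span_bp` (= `end_bp - start_bp + 1`), `n_snps`, `n_events`.
#' @export
iter_windows <- function(tracks, params = ibd_params()) {
  stopifnot(inherits(tracks, "informative_tracks"),
            inherits(params, "ibd_params"))
  one_track <- function(df, label) {
    res <- lapply(split(df, df$chromosome), function(ch) {
      ch <- ch[order(ch$position), , drop = FALSE]
      b <- window_bounds(nrow(ch), params$window_size, params$step)
      if (is.null(b)) {
        warning("chromosome ", ch$chromosome[1], " has only ", nrow(ch), " ",
                label, "-track SNPs (< window_size/2); skipped")
        return(NULL)
      }
      cs <- c(0L, cumsum(ch$event))
      data.frame(track = label, chromosome = ch$chromosome[1],
                 start_idx = b[, "start"], end_idx = b[, "end"],
                 start_bp = ch$position[b[, "start"]],
                 end_bp = ch$position[b[, "end"] - 1L],
                 span_bp = ch$position[b[, "end"] - 1L] -
                   ch$position[b[, "start"]] + 1L,
                 n_snps = b[, "end"] - b[, "start"],
                 n_events = cs[b[, "end"]] - cs[b[, "start"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(one_track(tracks$d0, "d0"), one_track(tracks$d12, "d12"))
  rownames(out) <- NULL
  out
}

#' Posterior probability of IBD0 for d0-track windows
#'
#' Bayes' rule with binomial likelihoods on the window's IBS0 event count:
#' success probability 1/3 under IBD0 and `error` under not-IBD0, with prior
#' `prior_d0`.  Computed in log space.
#'
#' @param window data.frame of d0-track windows (needs `n_events`, `n_snps`);
#'   vectorized over rows.
#' @param params an [ibd_params()] object.
#' @return Numeric vector of P(IBD0 | S) in \[0, 1\].
#' @export
posterior_d0 <- function(window, params = ibd_params()) {
  l0 <- stats::dbinom(window$n_events, window$n_snps, 1 / 3, log = TRUE)
  ln <- stats::dbinom(window$n_events, window$n_snps, params$error, log = TRUE)
  p <- stats::plogis(l0 - ln + log(params$prior_d0 / (1 - params$prior_d0)))
  pmin(pmax(p, 0), 1)
}

#' Split the not-IBD0 mass into IBD1 and IBD2 for d12-track windows
#'
#' Binomial likelihoods on the window's IBS1 event count: success probability
#' `c` under IBD1 and `error` under IBD2, with the equal sub-priors
#' `prior_d1_given_not_d0`.  The conditional split is scaled by the supplied
#' not-IBD0 probability, so `p_d1 + p_d2 = p_not_d0`.
#'
#' @param window data.frame of d12-track windows; vectorized over rows.
#' @param params an [ibd_params()] object.
#' @param p_not_d0 probability mass to divide (scalar or per-window vector).
#' @return data.frame with columns `p_d1` and `p_d2`.
#' @export
posterior_split_d1_d2 <- function(window, params = ibd_params(), p_not_d0 = 1) {
  g <- split_fraction_d1(window, params)
  data.frame(p_d1 = p_not_d0 * g, p_d2 = p_not_d0 * (1 - g))
}

# conditional P(IBD1 | not IBD0, S) for d12 windows
split_fraction_d1 <- function(window, params) {
  l1 <- stats::dbinom(window$n_events, window$n_snps, params$c, log = TRUE)
  l2 <- stats::dbinom(window$n_events, window$n_snps, params$error, log = TRUE)
  pr <- params$prior_d1_given_not_d0
  g <- stats::plogis(l1 - l2 + log(pr / (1 - pr)))
  pmin(pmax(g, 0), 1)
}

# Reconcile d0 and d12 window posteriors on one chromosome into
# length-weighted sums of (p_d0, p_d1, p_d2).  Both window sets are piecewise
# constant over bp intervals; overlapping windows of the same track are
# averaged per position.  Only positions covered by the d0 track contribute
# length; where d12 coverage is absent there the prior split is used.
reconcile_chromosome <- function(w0, p0, w12, g12, prior_split) {
  if (nrow(w0) == 0L) return(c(0, 0, 0, 0))
  brk <- sort(unique(c(w0$start_bp, w0$end_bp + 1L,
                       w12$start_bp, w12$end_bp + 1L)))
  ns <- length(brk) - 1L
  seg_len <- diff(brk)
  acc <- function(wdf, val) {
    s <- numeric(ns); k <- numeric(ns)
    for (i in seq_len(nrow(wdf))) {
      i1 <- findInterval(wdf$start_bp[i], brk)
      i2 <- findInterval(wdf$end_bp[i], brk)   # segment containing last bp
      s[i1:i2] <- s[i1:i2] + val[i]
      k[i1:i2] <- k[i1:i2] + 1
    }
    list(sum = s, n = k)
  }
  a0 <- acc(w0, p0)
  cov0 <- a0$n > 0
  p_d0 <- ifelse(cov0, a0$sum / pmax(a0$n, 1), NA_real_)
  if (nrow(w12) > 0L) {
    a12 <- acc(w12, g12)
    g <- ifelse(a12$n > 0, a12$sum / pmax(a12$n, 1), prior_split)
  } else g <- rep(prior_split, ns)
  len <- seg_len[cov0]
  p0s <- p_d0[cov0]; gs <- g[cov0]
  c(sum(len * p0s), sum(len * (1 - p0s) * gs),
    sum(len * (1 - p0s) * (1 - gs)), sum(len))
}

#' Estimate Cotterman coefficients (K0, K1, K2) for a pair
#'
#' Runs the full windowed estimator: informative tracks, overlapping windows,
#' per-window posteriors, per-base-pair reconciliation of the two tracks, and
#' genome-length weighting `K_j = sum_w P_w(Dj | S) l_w / sum_w l_w`.
#'
#' @param table an autosome-filtered `genotype_table`.
#' @param sample_a,sample_b sample ids.
#' @param params an [ibd_params()] object.
#' @param windows logical; attach the per-window posterior table
#'   (BED-like: chromosome, 0-based half-open start/end, p_d0, p_d1, p_d2).
#' @return An object of class `k_coefficients`: list with `k0`, `k1`, `k2`
#'   (summing to 1), `n_d0_snps`, `n_d12_snps`, `n_windows`, `genome_bp`
#'   (total reconciled length), the sample ids and `params`; plus `windows`
#'   if requested.
#' @export
estimate_k <- function(table, sample_a, sample_b, params = ibd_params(),
                       windows = FALSE) {
  tracks <- build_tracks(table, sample_a, sample_b)
  win <- iter_windows(tracks, params)
  if (is.null(win) || nrow(win) == 0L || !any(win$track == "d0"))
    stop("no usable windows for pair ", sample_a, "/", sample_b,
         " (d0 track: ", nrow(tracks$d0), " SNPs, d12 track: ",
         nrow(tracks$d12), " SNPs)")
  w0 <- win[win$track == "d0", , drop = FALSE]
  w12 <- win[win$track == "d12", , drop = FALSE]
  p0 <- posterior_d0(w0, params)
  g12 <- if (nrow(w12)) split_fraction_d1(w12, params) else numeric(0)
  chroms <- unique(w0$chromosome)
  tot <- c(0, 0, 0, 0)
  for (ch in chroms) {
    i0 <- w0$chromosome == ch
    i12 <- w12$chromosome == ch
    tot <- tot + reconcile_chromosome(w0[i0, , drop = FALSE], p0[i0],
                                      w12[i12, , drop = FALSE], g12[i12],
                                      params$prior_d1_given_not_d0)
  }
  k <- tot[1:3] / tot[4]
  out <- list(sample_a = sample_a, sample_b = sample_b,
              k0 = k[1], k1 = k[2], k2 = k[3],
              n_d0_snps = nrow(tracks$d0), n_d12_snps = nrow(tracks$d12),
              n_windows = nrow(win), genome_bp = tot[4], params = params)
  if (windows) {
    split12 <- posterior_split_d1_d2(w12, params, 1)
    out$windows <- rbind(
      data.frame(track = "d0", chromosome = w0$chromosome,
                 start = w0$start_bp - 1L, end = w0$end_bp,
                 p_d0 = p0, p_d1 = NA_real_, p_d2 = NA_real_),
      data.frame(track = "d12", chromosome = w12$chromosome,
                 start = w12$start_bp - 1L, end = w12$end_bp,
                 p_d0 = NA_real_, p_d1 = split12$p_d1, p_d2 = split12$p_d2))
  }
  class(out) <- "k_coefficients"
  out
}

#' @export
print.k_coefficients <- function(x, ...) {
  cat("k_coefficients: ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  K0 = %.3f  K1 = %.3f  K2 = %.3f\n", x$k0, x$k1, x$k2))
  cat(sprintf("  %d d0-track SNPs, %d d12-track SNPs, %d windows, %.1f Mb\n",
              x$n_d0_snps, x$n_d12_snps, x$n_windows, x$genome_bp / 1e6))
  invisible(x)
}
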