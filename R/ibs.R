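# Identity-by-state core -----------------------------------------------------
#
# Per-locus IBS states for a sample pair.  IBS2 is split into IBS2* (both
# samples heterozygous, AB/AB) and concordant homozygotes (AA/AA, BB/BB).
# IBS0 (discordant homozygotes, AA/BB) and IBS2* are the "informative"
# states: under the null of four unrelated alleles in one Hardy-Weinberg
# population, IBS2* / (IBS0 + IBS2*) has expectation 2/3 at every marker,
# independent of the allele frequency.

IBS_LEVELS <- c("IBS0", "IBS1", "IBS2hom", "IBS2star", "missing")

# integer codes over genotype codes (0/1/2, NA): 0=IBS0, 1=IBS1, 2=IBS2hom,
# 3=IBS2star, NA=missing
pair_state_codes <- function(ga, gb) {
  d <- abs(ga - gb)
  s <- integer(length(ga))
  s[d == 2L] <- 0L
  s[d == 1L] <- 1L
  conc <- d == 0L
  s[conc & ga == 1L] <- 3L
  s[conc & ga != 1L] <- 2L
  s[is.na(d)] <- NA_integer_
  s
}

#' Per-locus IBS state of two genotype calls
#'
#' @param call_a,call_b character vectors of calls in `AA`, `AB`, `BB`, `NC`
#'   (recycled to a common length).
#' @return Factor with levels `IBS0`, `IBS1`, `IBS2hom`, `IBS2star`,
#'   `missing`.  Any pair involving `NC` is `missing`; `AB`/`AB` is
#'   `IBS2star`; `AA`/`AA` and `BB`/`BB` are `IBS2hom`; discordant
#'   homozygotes are `IBS0`; a homozygote against a heterozygote is `IBS1`.
#' @examples
#' ibs_state(c("AA", "AB", "AA"), c("BB", "AB", "NC"))
#' @export
ibs_state <- function(call_a, call_b) {
  code <- function(x) {
    i <- match(x, GENO_LEVELS)
    if (anyNA(i)) stop("invalid genotype call: ",
                       paste(unique(x[is.na(i)]), collapse = ", "))
    c(0L, 1L, 2L, NA_integer_)[i]
  }
  n <- max(length(call_a), length(call_b))
  s <- pair_state_codes(rep_len(code(call_a), n), rep_len(code(call_b), n))
  factor(IBS_LEVELS[ifelse(is.na(s), 5L, s + 1L)], levels = IBS_LEVELS)
}

#' Genome-wide IBS tallies for one sample pair
#'
#' @param table an autosome-filtered `genotype_table`.
#' @param sample_a,sample_b sample ids.
#' @return An object of class `pair_ibs_counts`: list with `n_ibs0`,
#'   `n_ibs1`, `n_ibs2_hom`, `n_ibs2_star`, `n_missing`, `n_total` (their
#'   sum equals the marker count) and the sample ids.
#' @export
count_pair <- function(table, sample_a, sample_b) {
  s <- pair_state_codes(sample_column(table, sample_a),
                        sample_column(table, sample_b))
  tab <- tabulate(s + 1L, nbins = 4L)
  out <- list(sample_a = sample_a, sample_b = sample_b,
              n_ibs0 = tab[1], n_ibs1 = tab[2], n_ibs2_hom = tab[3],
              n_ibs2_star = tab[4], n_missing = sum(is.na(s)),
              n_total = length(s))
  class(out) <- "pair_ibs_counts"
  out
}

#' @export
print.pair_ibs_counts <- function(x, ...) {
  cat("pair_ibs_counts: ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  IBS0 %d  IBS1 %d  IBS2hom %d  IBS2* %d  missing %d  (total %d)\n",
              x$n_ibs0, x$n_ibs1, x$n_ibs2_hom, x$n_ibs2_star,
              x$n_missing, x$n_total))
  invisible(x)
}

#' IBS2* ratio statistic and test against the 2/3 null
#'
#' Computes the informative-IBS summary of a pair: the IBS2* ratio
#' `IBS2* / (IBS0 + IBS2*)` (expectation 2/3 for unrelated individuals of one
#' population, regardless of allele frequencies), the fraction of informative
#' SNPs `(IBS0 + IBS2*) / (IBS0 + IBS1 + IBS2)`, and a two-sided one-sample
#' binomial-proportion Z-test of the ratio against 2/3 on the
#' `m = IBS0 + IBS2*` informative markers.  Significance is assessed at
#' `alpha / n_tests` (Bonferroni).  A ratio above `flag_threshold` flags the
#' pair as potentially related, the empirical screen used for cohort QC.
#'
#' @param counts a `pair_ibs_counts`.
#' @param n_tests number of pairwise tests performed (Bonferroni divisor).
#' @param alpha family-wise significance level.
#' @param flag_threshold empirical relatedness screen on the ratio.
#' @return An object of class `ibs2star_stat`: list with `ratio`,
#'   `pct_informative`, `m` (informative marker count), `z`, `p_two_sided`,
#'   `significant`, `flagged_related` plus the inputs.
#' @seealso [exact_binom_p()] for the exact-test alternative.
#' @export
ibs2star_stat <- function(counts, n_tests = 1L, alpha = 0.05,
                          flag_threshold = 0.70) {
  m <- counts$n_ibs0 + counts$n_ibs2_star
  if (m <= 0L)
    stop("no informative markers (IBS0 + IBS2* = 0): IBS2* ratio undefined")
  ratio <- counts$n_ibs2_star / m
  denom <- counts$n_ibs0 + counts$n_ibs1 + counts$n_ibs2_hom + counts$n_ibs2_star
  pct_informative <- if (denom > 0) m / denom else NA_real_
  p0 <- 2 / 3
  z <- (ratio - p0) / sqrt(p0 * (1 - p0) / m)
  p <- 2 * stats::pnorm(-abs(z))
  out <- list(sample_a = counts$sample_a, sample_b = counts$sample_b,
              ratio = ratio, pct_informative = pct_informative, m = m,
              z = z, p_two_sided = p,
              significant = p <= alpha / n_tests,
              flagged_related = ratio > flag_threshold,
              n_tests = n_tests, alpha = alpha)
  class(out) <- "ibs2star_stat"
  out
}

#' @export
print.ibs2star_stat <- function(x, ...) {
  cat("ibs2star_stat: ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  IBS2*_ratio %.4f (m = %d informative), %%informative %.4f\n",
              x$ratio, x$m, x$pct_informative))
  cat(sprintf("  Z = %.3f, two-sided p = %.3g%s%s\n", x$z, x$p_two_sided,
              if (x$significant) " [significant]" else "",
              if (x$flagged_related) " [flagged related]" else ""))
  invisible(x)
}

#' Exact binomial test of the IBS2* ratio against 2/3
#'
#' Two-sided exact binomial p-value for observing `n_ibs2_star` successes in
#' `m = n_ibs0 + n_ibs2_star` trials with success probability 2/3 (the
#' minimum-likelihood two-sided convention of [stats::binom.test()]).
#'
#' @param counts a `pair_ibs_counts`.
#' @return The two-sided p-value.
#' @export
exact_binom_p <- function(counts) {
  m <- counts$n_ibs0 + counts$n_ibs2_star
  if (m <= 0L)
    stop("no informative markers (IBS0 + IBS2* = 0): exact test undefined")
  stats::binom.test(counts$n_ibs2_star, m, p = 2 / 3)$p.value
}

#' Enumerate sample pairs by group structure
#'
#' @param sheet data.frame with `sample_id` and `group`.
#' @param mode `"within"` (pairs inside each group), `"between"` (pairs
#'   across distinct groups) or `"all"` (every unordered pair).
#' @return data.frame with columns `sample_a`, `sample_b`, `group_a`,
#'   `group_b`.  With g groups of sizes n_g, `within` yields sum C(n_g, 2)
#'   rows and `between` sum_{g<h} n_g n_h rows.
#' @export
pair_grid <- function(sheet, mode = c("within", "between", "all")) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "group") %in% names(sheet)))
  if (anyNA(sheet$group) && mode != "all")
    stop("missing group labels in sample sheet")
  n <- nrow(sheet)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  ga <- sheet$group[a]; gb <- sheet$group[b]
  keep <- switch(mode,
                 within = ga == gb,
                 between = ga != gb,
                 all = rep(TRUE, length(a)))
  data.frame(sample_a = sheet$sample_id[a][keep],
             sample_b = sheet$sample_id[b][keep],
             group_a = ga[keep], group_b = gb[keep],
             stringsAsFactors = FALSE)
}

#' IBS2* statistics for all sample pairs of a cohort
#'
#' Runs [count_pair()] and [ibs2star_stat()] over every pair selected by
#' `mode`; the Bonferroni divisor defaults to the number of emitted pairs.
#' Pairs with zero informative markers are kept with `NA` statistics and
#' `degenerate = TRUE` rather than dropped.
#'
#' @param table an autosome-filtered `genotype_table`.
#' @param sheet data.frame with `sample_id`, `group`; if `NULL`, all samples
#'   form one group.
#' @param mode pair selection, see [pair_grid()].
#' @param n_tests Bonferroni divisor; default = number of pairs.
#' @param alpha family-wise significance level.
#' @param flag_threshold empirical relatedness screen on the ratio.
#' @return data.frame with one row per pair: ids, groups, the five IBS
#'   tallies, `ratio`, `pct_informative`, `z`, `p`, `significant`, `flagged`,
#'   `degenerate`.
#' @export
all_pairs <- function(table, sheet = NULL, mode = c("within", "between", "all"),
                      n_tests = NULL, alpha = 0.05, flag_threshold = 0.70) {
  mode <- match.arg(mode)
  if (is.null(sheet))
    sheet <- data.frame(sample_id = sample_ids(table), group = "all",
                        stringsAsFactors = FALSE)
  missing_ids <- setdiff(sample_ids(table), sheet$sample_id)
  if (length(missing_ids) && mode != "all")
    stop("samples absent from sheet: ", paste(missing_ids, collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% sample_ids(table), , drop = FALSE]
  pairs <- pair_grid(sheet, mode)
  np <- nrow(pairs)
  if (is.null(n_tests)) n_tests <- max(np, 1L)
  cols <- c("n_ibs0", "n_ibs1", "n_ibs2_hom", "n_ibs2_star", "n_missing")
  res <- matrix(NA_real_, np, 10,
                dimnames = list(NULL, c(cols, "ratio", "pct_informative",
                                        "z", "p", "m")))
  degen <- logical(np)
  for (i in seq_len(np)) {
    cnt <- count_pair(table, pairs$sample_a[i], pairs$sample_b[i])
    res[i, cols] <- unlist(cnt[cols])
    if (cnt$n_ibs0 + cnt$n_ibs2_star > 0L) {
      st <- ibs2star_stat(cnt, n_tests = n_tests, alpha = alpha,
                          flag_threshold = flag_threshold)
      res[i, 6:10] <- c(st$ratio, st$pct_informative, st$z, st$p_two_sided, st$m)
    } else degen[i] <- TRUE
  }
  out <- cbind(pairs, as.data.frame(res))
  out$significant <- !degen & out$p <= alpha / n_tests
  out$flagged <- !degen & out$ratio > flag_threshold
  out$degenerate <- degen
  out
}

#' Per-chromosome IBS track for a pair
#'
#' Positions with their IBS state along one chromosome, the data behind
#' shared-region visualisations (an identical pair shows no IBS0 anywhere; a
#' parent-child pair shows IBS0 only at genotyping errors).
#'
#' @param table a `genotype_table`.
#' @param sample_a,sample_b sample ids.
#' @param chromosome chromosome label as it appears in the marker map.
#' @return data.frame with `position` (ascending) and `state` (factor with
#'   the [ibs_state()] levels; missing loci are included as `missing`).
#' @export
ibs_track <- function(table, sample_a, sample_b, chromosome) {
  keep <- table$markers$chromosome == chromosome
  if (!any(keep) && nrow(table$markers) > 0L)
    stop("unknown chromosome: ", chromosome)
  s <- pair_state_codes(sample_column(table, sample_a)[keep],
                        sample_column(table, sample_b)[keep])
  data.frame(position = table$markers$position[keep],
             state = factor(IBS_LEVELS[ifelse(is.na(s), 5L, s + 1L)],
                            levels = IBS_LEVELS))
}
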