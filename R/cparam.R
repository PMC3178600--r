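# Allele-frequency parameter c -----------------------------------------------

#' Conditional IBS probabilities given IBD state
#'
#' For one biallelic marker with B-allele frequency `p` under Hardy-Weinberg
#' equilibrium, the probability of each informative IBS outcome within each
#' IBD state, as used by the windowed model.  Concordant homozygotes make up
#' the remaining mass of each column.  Note `P(IBS0 | IBD1) =
#' P(IBS0 | IBD2) = 0`, and that within IBD0
#' `P(IBS0) / (P(IBS0) + P(IBS2*)) = 1/3` for every `p` — the identity behind
#' the 2/3 null of the IBS2* ratio and the 1/3 event rate of the d0 track.
#'
#' The IBD1-column heterozygote-concordance entry (`1/2 - pq`) is the model's
#' working form, from which the allele-frequency integral behind
#' [compute_c()] is built.  Under exact HWE algebra for a pair sharing one
#' allele, `P(IBS2* | IBD1) = pq`, which would make the IBS1 fraction among
#' informative IBD1 observations 2/3 at every `p`.  The window posteriors are
#' insensitive to this distinction: the IBD1-vs-IBD2 split only requires the
#' IBD1 event rate to exceed `c`, and estimates are stable for any
#' `c >= 0.25` (see the methods vignette).
#'
#' @param p B-allele frequency, strictly inside (0, 1).
#' @return 3 x 3 numeric matrix, rows `IBS0`, `IBS1`, `IBS2star`, columns
#'   `IBD0`, `IBD1`, `IBD2`.
#' @examples
#' ibs_given_ibd(0.5)
#' @export
ibs_given_ibd <- function(p) {
  stopifnot(length(p) == 1L, is.finite(p))
  if (p <= 0 || p >= 1) stop("p must lie strictly inside (0, 1)")
  q <- 1 - p
  matrix(c(2 * p^2 * q^2, 4 * p^3 * q + 4 * p * q^3, 4 * p^2 * q^2,
           0,             2 * p * q,                 0.5 - p * q,
           0,             0,                         2 * p * q),
         nrow = 3, ncol = 3,
         dimnames = list(c("IBS0", "IBS1", "IBS2star"),
                         c("IBD0", "IBD1", "IBD2")))
}

# expected IBS1 fraction among IBS1 + IBS2* loci within IBD1, at frequency p
ibs1_fraction_ibd1 <- function(p) {
  pq <- p * (1 - p)
  2 * pq / (2 * pq + (0.5 - pq))
}

#' Expected IBS1 fraction in IBD1 regions (parameter c)
#'
#' Integrates `f(p) = 2pq / (2pq + (1/2 - pq))` — the chance that an
#' informative d12-track observation in an IBD1 region is IBS1 rather than
#' IBS2* — over a prior on the allele frequency `p`:
#' \describe{
#'   \item{`uniform`}{flat prior on (0, 1); gives approximately 0.479.}
#'   \item{`empirical_bayes`}{starts from a flat prior and applies two Bayes
#'     updates with `P(O | p) = 1/2 + p(1-p)`, the chance that a SNP in an
#'     IBD1 region shows observable variation between the two samples (the
#'     complement of a concordant-homozygote call); the resulting weight is
#'     proportional to `P(O | p)^2` and gives 0.518, the default of
#'     [ibd_params()].}
#' }
#' `c` must exceed the genotyping error rate and cannot exceed its
#' theoretical maximum `f(1/2) = 2/3`; K1/K2 estimates are insensitive to
#' the exact choice for `c >= 0.25`.
#'
#' @param prior `"empirical_bayes"` (default) or `"uniform"`.
#' @return The expected fraction, a scalar in (0, 2/3\].
#' @examples
#' compute_c("empirical_bayes")  # 0.518
#' compute_c("uniform")          # 0.479
#' @export
compute_c <- function(prior = c("empirical_bayes", "uniform")) {
  prior <- match.arg(prior)
  w <- switch(prior,
              uniform = function(p) rep(1, length(p)),
              empirical_bayes = function(p) (0.5 + p * (1 - p))^2)
  num <- stats::integrate(function(p) ibs1_fraction_ibd1(p) * w(p), 0, 1,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(w, 0, 1, rel.tol = 1e-10)$value
  num / den
}
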