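# IBS states, the IBS2* ratio statistic and its tests

test_that("per-locus IBS state follows the genotype pair", {
  expect_equal(as.character(ibs_state("AA", "BB")), "IBS0")
  expect_equal(as.character(ibs_state("AB", "AB")), "IBS2star")
  expect_equal(as.character(ibs_state("AA", "NC")), "missing")
  # full truth table against an independent allele-sharing oracle
  oracle <- function(a, b) {
    if (a == "NC" || b == "NC") return("missing")
    alleles <- function(g) switch(g, AA = c("A", "A"), AB = c("A", "B"),
                                  BB = c("B", "B"))
    x <- alleles(a); y <- alleles(b)
    shared <- sum(sort(x) == sort(y))    # 0/1/2 alleles identical in state
    if (shared == 2) { if (a == "AB") "IBS2star" else "IBS2hom" }
    else if (shared == 0 || (a != "AB" && b != "AB" && a != b)) "IBS0"
    else "IBS1"
  }
  calls <- c("AA", "AB", "BB", "NC")
  grid <- expand.grid(a = calls, b = calls, stringsAsFactors = FALSE)
  expect_equal(as.character(ibs_state(grid$a, grid$b)),
               mapply(oracle, grid$a, grid$b, USE.NAMES = FALSE))
  expect_error(ibs_state("AC", "AA"), "invalid")
})

test_that("pair counts match hand enumeration and are conserved and symmetric", {
  gt <- make_table(cbind(c("AA", "AB", "BB"), c("BB", "AB", "AB")))
  cnt <- count_pair(gt, "s1", "s2")
  expect_equal(cnt$n_ibs0, 1L)
  expect_equal(cnt$n_ibs2_star, 1L)
  expect_equal(cnt$n_ibs1, 1L)
  # self-comparison: heterozygous loci all become IBS2*
  gt2 <- make_table(cbind(c("AA", "AB", "AB", "BB"), c("AA", "AB", "AB", "BB")))
  cnt2 <- count_pair(gt2, "s1", "s2")
  expect_equal(cnt2$n_ibs0, 0L)
  expect_equal(cnt2$n_ibs2_star, 2L)
  # conservation + symmetry over random tables
  for (seed in 1:5) {
    gt3 <- random_hwe_table(n = 200, ns = 2, seed = seed)
    gt3$geno[sample(length(gt3$geno), 20)] <- NA_integer_
    a <- count_pair(gt3, "s1", "s2")
    b <- count_pair(gt3, "s2", "s1")
    expect_equal(a$n_ibs0 + a$n_ibs1 + a$n_ibs2_hom + a$n_ibs2_star + a$n_missing,
                 a$n_total)
    expect_equal(a$n_total, 200L)
    for (f in c("n_ibs0", "n_ibs1", "n_ibs2_hom", "n_ibs2_star", "n_missing"))
      expect_identical(a[[f]], b[[f]])
  }
  expect_error(count_pair(gt, "s1", "nope"), "unknown sample")
})

test_that("IBS2* statistic hits the null value and the identical-pair extreme", {
  st <- ibs2star_stat(fake_counts(n_ibs0 = 100, n_ibs2_star = 200))
  expect_equal(st$ratio, 2 / 3)
  expect_equal(st$z, 0)
  expect_equal(st$p_two_sided, 1)
  # identical samples lack IBS0, ratio 1.0
  st1 <- ibs2star_stat(fake_counts(n_ibs0 = 0, n_ibs2_star = 5000))
  expect_equal(st1$ratio, 1.0)
  expect_true(st1$flagged_related)
  expect_true(st1$significant)
  # type invariants
  cnt <- fake_counts(n_ibs0 = 50, n_ibs2_star = 150, n_ibs1 = 300,
                     n_ibs2_hom = 500, n_missing = 10)
  st2 <- ibs2star_stat(cnt)
  expect_equal(st2$ratio, 150 / 200)
  expect_equal(st2$pct_informative, 200 / 1000)
  expect_error(ibs2star_stat(fake_counts(0, 0, n_ibs1 = 10)), "informative")
})

test_that("exact binomial p matches an enumeration oracle", {
  # most probable outcome has p = 1
  expect_equal(exact_binom_p(fake_counts(n_ibs0 = 1, n_ibs2_star = 2)),
               exact_binom_oracle(2, 3, 2 / 3))
  expect_equal(exact_binom_oracle(2, 3, 2 / 3), 1)
  # zero successes in 30 trials: (1/3)^30-scale tail
  p0 <- exact_binom_p(fake_counts(n_ibs0 = 30, n_ibs2_star = 0))
  expect_lt(p0, 1e-4)
  expect_equal(p0, exact_binom_oracle(0, 30, 2 / 3))
  # all successes: extreme upper tail
  pm <- exact_binom_p(fake_counts(n_ibs0 = 0, n_ibs2_star = 200))
  expect_lt(pm, (2 / 3)^200 * 200)
  # grid agreement with the oracle
  for (m in c(5, 17, 40)) for (k in c(0, floor(m / 3), floor(2 * m / 3), m))
    expect_equal(exact_binom_p(fake_counts(m - k, k)),
                 exact_binom_oracle(k, m, 2 / 3), tolerance = 1e-12)
})

test_that("Z-test and exact binomial decisions agree on large-m nulls", {
  set.seed(42)
  m <- 1000
  k <- stats::rbinom(300, m, 2 / 3)
  agree <- vapply(k, function(ki) {
    cnt <- fake_counts(m - ki, ki)
    (ibs2star_stat(cnt)$p_two_sided <= 0.05) == (exact_binom_p(cnt) <= 0.05)
  }, TRUE)
  expect_gte(mean(agree), 0.99)
})

test_that("pair enumeration matches the cohort combinatorics", {
  sheet <- data.frame(sample_id = sprintf("s%03d", 1:400),
                      group = rep(paste0("pop", 1:4), each = 100),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(pair_grid(sheet, "within")), 19800L)
  expect_equal(nrow(pair_grid(sheet, "between")), 60000L)
  expect_equal(nrow(pair_grid(sheet, "all")), choose(400, 2))
  tiny <- data.frame(sample_id = c("a", "b"), group = "g")
  expect_equal(nrow(pair_grid(tiny, "within")), 1L)
})

test_that("all_pairs covers the requested pairs and keeps degenerate ones", {
  gt <- random_hwe_table(n = 300, ns = 8, seed = 5)
  sheet <- data.frame(sample_id = sample_ids(gt),
                      group = rep(c("g1", "g2"), each = 4),
                      stringsAsFactors = FALSE)
  w <- all_pairs(gt, sheet, "within")
  expect_equal(nrow(w), 2 * choose(4, 2))
  b <- all_pairs(gt, sheet, "between")
  expect_equal(nrow(b), 16L)
  expect_true(all(w$n_ibs0 + w$n_ibs1 + w$n_ibs2_hom + w$n_ibs2_star +
                    w$n_missing == 300))
  # a pair with no informative markers is reported, not dropped
  gtd <- make_table(cbind(c("AA", "AA"), c("AA", "AB"), c("BB", "NC")))
  res <- all_pairs(gtd, mode = "all")
  expect_equal(nrow(res), 3L)
  expect_true(any(res$degenerate))
  expect_true(all(is.na(res$ratio[res$degenerate])))
})

test_that("unrelated HWE pairs center on 2/3 regardless of the allele spectrum", {
  ratios <- function(freq_fun, n = 4000, reps = 12) {
    vapply(seq_len(reps), function(i) {
      gt <- random_hwe_table(n = n, ns = 2, freq = freq_fun(n), seed = 100 + i)
      ibs2star_stat(count_pair(gt, "s1", "s2"))$ratio
    }, numeric(1))
  }
  set.seed(9)
  flat <- ratios(function(n) stats::runif(n, 0.05, 0.95))
  skew <- ratios(function(n) stats::rbeta(n, 0.8, 2.5) * 0.9 + 0.05)
  for (r in list(flat, skew)) {
    expect_equal(mean(r), 2 / 3, tolerance = 0.01)
    expect_lt(abs(mean(r) - 2 / 3), 3 * stats::sd(r) / sqrt(length(r)) + 0.005)
  }
})

test_that("percent informative rises with pair heterozygosity", {
  set.seed(21)
  pct <- vapply(c(0.10, 0.25, 0.50), function(maf) {
    gt <- random_hwe_table(n = 4000, ns = 2,
                           freq = rep(maf, 4000), seed = round(1000 * maf))
    ibs2star_stat(count_pair(gt, "s1", "s2"))$pct_informative
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("IBS tracks expose shared chromosomal regions", {
  # identical pair: no IBS0 anywhere
  gt <- random_hwe_table(n = 500, ns = 1, seed = 13)
  dup <- genotype_table(gt$markers, cbind(s1 = gt$geno[, 1], s2 = gt$geno[, 1]),
                        sort = FALSE)
  tr <- ibs_track(dup, "s1", "s2", "1")
  expect_false(any(tr$state == "IBS0"))
  expect_true(!is.unsorted(tr$position))
  # missing loci included but distinguishable
  dup$geno[3, 2] <- NA_integer_
  tr2 <- ibs_track(dup, "s1", "s2", "1")
  expect_equal(sum(tr2$state == "missing"), 1L)
  expect_error(ibs_track(dup, "s1", "s2", "17"), "unknown chromosome")
})
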