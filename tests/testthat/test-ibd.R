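# Windowed Bayesian IBD estimator

test_that("informative tracks keep the right loci and events", {
  gt <- make_table(cbind(c("AA", "AB", "AA", "AA", "AB"),
                         c("AA", "AB", "BB", "AB", "NC")))
  tr <- build_tracks(gt, "s1", "s2")
  # d0 track: IBS2* (locus 2) and IBS0 (locus 3); event = IBS0
  expect_equal(tr$d0$position, c(200L, 300L))
  expect_equal(tr$d0$event, c(FALSE, TRUE))
  # d12 track: IBS2* (locus 2) and IBS1 (locus 4); event = IBS1
  expect_equal(tr$d12$position, c(200L, 400L))
  expect_equal(tr$d12$event, c(FALSE, TRUE))
  # identical error-free pair: no IBS0 events
  gt2 <- random_hwe_table(n = 300, ns = 1, seed = 2)
  dup <- genotype_table(gt2$markers,
                        cbind(a = gt2$geno[, 1], b = gt2$geno[, 1]),
                        sort = FALSE)
  expect_equal(sum(build_tracks(dup, "a", "b")$d0$event), 0L)
  # no shared polymorphism: both tracks empty, warning
  mono <- make_table(cbind(c("AA", "BB"), c("AA", "BB")))
  expect_warning(tr3 <- build_tracks(mono, "s1", "s2"), "no informative")
  expect_equal(nrow(tr3$d0), 0L)
})

test_that("window layout follows size, step and chromosome boundaries", {
  mk_tracks <- function(n_per_chrom) {
    d0 <- do.call(rbind, lapply(seq_along(n_per_chrom), function(ci)
      data.frame(chromosome = as.character(ci),
                 position = seq_len(n_per_chrom[ci]) * 10L,
                 event = FALSE)))
    structure(list(d0 = d0, d12 = d0[0, ], sample_a = "a", sample_b = "b"),
              class = "informative_tracks")
  }
  p <- ibd_params(window_size = 300, step = 100)
  # exactly one window for 300 SNPs
  w1 <- iter_windows(mk_tracks(300), p)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$n_snps, 300L)
  # 600 SNPs: full windows at 1, 101, 201, 301
  w2 <- iter_windows(mk_tracks(600), p)
  expect_equal(w2$start_idx, c(1L, 101L, 201L, 301L))
  expect_equal(w2$n_snps, rep(300L, 4))
  # 650 SNPs: uncovered tail (50 < 150) merges into the last window
  w3 <- iter_windows(mk_tracks(650), p)
  expect_equal(max(w3$end_idx), 651L)
  expect_equal(w3$n_snps[nrow(w3)], 350L)
  # a large uncovered tail (200 >= 150) is emitted as its own partial window
  p_wide <- ibd_params(window_size = 300, step = 250)
  w4 <- iter_windows(mk_tracks(1000), p_wide)
  expect_equal(w4$start_idx, c(1L, 251L, 501L, 801L))
  expect_equal(w4$n_snps[nrow(w4)], 200L)
  # windows never cross chromosomes; small chromosome skipped with warning
  expect_warning(w5 <- iter_windows(mk_tracks(c(300, 100, 400)), p),
                 "skipped")
  expect_false("2" %in% w5$chromosome)
  expect_true(all(tapply(w5$end_idx - w5$start_idx, w5$chromosome, sum) >= 300))
  # span is inclusive first-to-last position
  expect_equal(w1$span_bp, 300L * 10L - 10L + 1L)
})

test_that("window posteriors equal the brute-force Bayes computation", {
  p <- ibd_params(window_size = 20, step = 7)
  for (n in c(5, 12, 20)) for (k in 0:n) {
    w <- data.frame(n_events = k, n_snps = n)
    # d0 track: direct evaluation of the two binomial likelihoods
    brute0 <- (dbinom(k, n, 1 / 3) * p$prior_d0) /
      (dbinom(k, n, 1 / 3) * p$prior_d0 +
         dbinom(k, n, p$error) * (1 - p$prior_d0))
    expect_equal(posterior_d0(w, p), brute0, tolerance = 1e-12)
    # d12 track split
    brute1 <- dbinom(k, n, p$c) / (dbinom(k, n, p$c) + dbinom(k, n, p$error))
    sp <- posterior_split_d1_d2(w, p, p_not_d0 = 0.8)
    expect_equal(sp$p_d1, 0.8 * brute1, tolerance = 1e-10)
    expect_equal(sp$p_d1 + sp$p_d2, 0.8, tolerance = 1e-12)
  }
})

test_that("window posteriors saturate at the expected extremes", {
  p <- ibd_params()
  expect_gt(posterior_d0(data.frame(n_events = 100, n_snps = 300), p), 0.999)
  expect_lt(posterior_d0(data.frame(n_events = 0, n_snps = 300), p), 1e-6)
  # all-event window: the error model makes not-IBD0 vanishingly unlikely
  expect_gt(posterior_d0(data.frame(n_events = 300, n_snps = 300), p), 0.999)
  # d12: event fraction c -> IBD1; zero events -> IBD2; conditioning on 0 -> 0
  w_c <- data.frame(n_events = round(300 * p$c), n_snps = 300)
  expect_gt(posterior_split_d1_d2(w_c, p, 1)$p_d1, 0.999)
  w_0 <- data.frame(n_events = 0, n_snps = 300)
  expect_gt(posterior_split_d1_d2(w_0, p, 1)$p_d2, 0.999)
  expect_equal(unlist(posterior_split_d1_d2(w_0, p, 0)), c(p_d1 = 0, p_d2 = 0))
})

test_that("posterior and K normalization hold on simulated pairs", {
  sp <- simulate_scenario("full_sib", small_genome(20000), noise_model(),
                          seed = 71)
  tab <- filter_autosomes(sp$table)
  p <- ibd_params()
  tr <- build_tracks(tab, sp$sample_a, sp$sample_b)
  win <- suppressWarnings(iter_windows(tr, p))
  w0 <- win[win$track == "d0", ]
  pd0 <- posterior_d0(w0, p)
  split <- posterior_split_d1_d2(w0, p, 1 - pd0)
  expect_true(all(abs(pd0 + split$p_d1 + split$p_d2 - 1) < 1e-9))
  for (sc in c("unrelated", "half_sib")) {
    spx <- simulate_scenario(sc, small_genome(15000), noise_model(), seed = 72)
    k <- suppressWarnings(estimate_k(filter_autosomes(spx$table),
                                     spx$sample_a, spx$sample_b, p))
    expect_equal(k$k0 + k$k1 + k$k2, 1, tolerance = 1e-9)
    expect_true(all(c(k$k0, k$k1, k$k2) >= 0))
  }
})

test_that("K estimates recover duplicate, parent-child and unrelated pairs", {
  g <- small_genome(20000)
  kdup <- local({
    sp <- simulate_scenario("identical", g, noise_model(), seed = 81)
    suppressWarnings(estimate_k(filter_autosomes(sp$table),
                                sp$sample_a, sp$sample_b))
  })
  expect_gt(kdup$k2, 0.99)
  kpc <- local({
    sp <- simulate_scenario("parent_child", g, noise_model(), seed = 82)
    suppressWarnings(estimate_k(filter_autosomes(sp$table),
                                sp$sample_a, sp$sample_b))
  })
  expect_gt(kpc$k1, 0.99)
  expect_lt(kpc$k2, 0.01)
  kun <- local({
    sp <- simulate_scenario("unrelated", g, noise_model(), seed = 83)
    suppressWarnings(estimate_k(filter_autosomes(sp$table),
                                sp$sample_a, sp$sample_b))
  })
  expect_gt(kun$k0, 0.95)
  expect_lte(kun$k1, 0.03)
})

test_that("K1/K2 are insensitive to the choice of c at or above 0.25", {
  g <- genome_model()
  for (sc in c("full_sib", "parent_child")) {
    sp <- simulate_scenario(sc, g, noise_model(), seed = 91)
    tab <- filter_autosomes(sp$table)
    ks <- vapply(c(0.25, 0.4, 0.518, 0.6), function(cc) {
      k <- suppressWarnings(estimate_k(tab, sp$sample_a, sp$sample_b,
                                       ibd_params(c = cc)))
      c(k$k1, k$k2)
    }, numeric(2))
    expect_lt(diff(range(ks[1, ])), 0.02)
    expect_lt(diff(range(ks[2, ])), 0.02)
  }
})

test_that("sibling K2 is stable across window sizes 150-600", {
  g <- genome_model()
  pairs <- lapply(1:6, function(i)
    simulate_scenario("full_sib", g, noise_model(), seed = 2000 + i))
  for (ws in c(150, 300, 600)) {
    k2 <- vapply(pairs, function(sp)
      suppressWarnings(estimate_k(filter_autosomes(sp$table), sp$sample_a,
                                  sp$sample_b, ibd_params(window_size = ws)))$k2,
      numeric(1))
    expect_lt(abs(mean(k2) - 0.25), 0.05)
  }
})

test_that("estimator errors cleanly without usable windows", {
  gt <- make_table(cbind(c("AA", "AB"), c("AA", "AB")))
  expect_error(suppressWarnings(estimate_k(gt, "s1", "s2")), "no usable windows")
})
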