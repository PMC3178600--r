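# Fixture builders used across the suite; everything is generated in code.

# genotype_table from character calls: markers x samples matrix of
# AA/AB/BB/NC strings
make_table <- function(calls, chromosome = NULL, position = NULL,
                       sample_ids = NULL, marker_ids = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(chromosome)) chromosome <- rep("1", n)
  if (is.null(position)) position <- seq_len(n) * 100L
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(calls)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(n))
  code <- matrix(c(0L, 1L, 2L, NA_integer_)[match(calls, c("AA", "AB", "BB", "NC"))],
                 n, ncol(calls), dimnames = list(NULL, sample_ids))
  genotype_table(data.frame(marker_id = marker_ids, chromosome = chromosome,
                            position = position, stringsAsFactors = FALSE),
                 code)
}

# random HWE table: ns unrelated samples, n markers on one chromosome
random_hwe_table <- function(n = 500, ns = 2, freq = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(freq)) freq <- stats::runif(n, 0.05, 0.95)
  geno <- vapply(seq_len(ns), function(j)
    stats::rbinom(n, 1L, freq) + stats::rbinom(n, 1L, freq), integer(n))
  colnames(geno) <- paste0("s", seq_len(ns))
  genotype_table(data.frame(marker_id = paste0("m", seq_len(n)),
                            chromosome = "1",
                            position = sort(sample.int(1e7, n)),
                            stringsAsFactors = FALSE),
                 geno)
}

# counts object without going through a table
fake_counts <- function(n_ibs0, n_ibs2_star, n_ibs1 = 0, n_ibs2_hom = 0,
                        n_missing = 0) {
  structure(list(sample_a = "a", sample_b = "b", n_ibs0 = n_ibs0,
                 n_ibs1 = n_ibs1, n_ibs2_hom = n_ibs2_hom,
                 n_ibs2_star = n_ibs2_star, n_missing = n_missing,
                 n_total = n_ibs0 + n_ibs1 + n_ibs2_hom + n_ibs2_star + n_missing),
            class = "pair_ibs_counts")
}

# small genome for fast simulation tests
small_genome <- function(n_markers = 5000) genome_model(n_markers = n_markers)

# independent two-sided exact binomial oracle (minimum-likelihood convention)
exact_binom_oracle <- function(k, m, p) {
  pm <- stats::dbinom(0:m, m, p)
  sum(pm[pm <= stats::dbinom(k, m, p) * (1 + 1e-7)])
}
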