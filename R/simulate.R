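# Gene-dropping pedigree simulator -------------------------------------------
#
# Founders are drawn in Hardy-Weinberg equilibrium from a configurable
# B-allele-frequency spectrum; each meiosis places crossovers by a Poisson
# process at the genetic map rate (Haldane model, no interference) and
# transmits the recombined haplotype.  Founder haplotypes carry unique
# ancestry labels, so the per-marker IBD state of any pair is known exactly.

# GRCh37 autosome lengths in Mb, chr1..chr22
HUMAN_AUTOSOME_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                       135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Genome model for simulation
#'
#' The default is a desk-scale genome: the 22 human autosomes scaled to 10%
#' of their physical length carrying ~50,000 markers in total, enough for
#' fast, well-powered validation runs.  `scale = 1` with
#' `n_markers = 870000` mirrors a genome-wide SNP-array density.
#'
#' @param n_markers total marker count, allocated to chromosomes in
#'   proportion to length.
#' @param scale multiplier on the human autosome lengths.
#' @param cm_per_mb genetic map rate (centimorgan per megabase).
#' @param freq_range range of the uniform B-allele-frequency spectrum.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(n_markers = 50000L, scale = 0.1, cm_per_mb = 1,
                         freq_range = c(0.05, 0.95)) {
  stopifnot(n_markers >= 22L, scale > 0, cm_per_mb > 0,
            length(freq_range) == 2L, freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] <= freq_range[2])
  len_bp <- as.integer(round(HUMAN_AUTOSOME_MB * 1e6 * scale))
  share <- as.numeric(n_markers) * as.numeric(len_bp) / sum(as.numeric(len_bp))
  m <- floor(share)
  rem <- n_markers - sum(m)
  if (rem > 0) {
    extra <- order(share - m, decreasing = TRUE)[seq_len(rem)]
    m[extra] <- m[extra] + 1L
  }
  structure(list(chromosomes = data.frame(name = as.character(1:22),
                                          length_bp = len_bp,
                                          n_markers = as.integer(m),
                                          stringsAsFactors = FALSE),
                 cm_per_mb = cm_per_mb, freq_range = freq_range),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb, %d markers, %.2g cM/Mb\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_bp) / 1e6,
              sum(x$chromosomes$n_markers), x$cm_per_mb))
  invisible(x)
}

#' Noise model for simulated genotypes
#'
#' @param error_rate per-call genotyping error (default 0.01); an erroneous
#'   call moves to an adjacent genotype (AA/BB to AB; AB to AA or BB with
#'   equal probability).
#' @param nc_rate per-call no-call rate (default 0.005).
#' @param roh optional data.frame (`sample`, `chromosome`, `start`, `end`)
#'   of forced runs of homozygosity: heterozygous calls inside an interval
#'   are replaced by the homozygote of the sample's first haplotype allele.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(error_rate = 0.01, nc_rate = 0.005, roh = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1, nc_rate >= 0, nc_rate < 1)
  if (!is.null(roh))
    stopifnot(is.data.frame(roh),
              all(c("sample", "chromosome", "start", "end") %in% names(roh)))
  structure(list(error_rate = error_rate, nc_rate = nc_rate, roh = roh),
            class = "noise_model")
}

#' Pedigree specification
#'
#' @param id character vector of individual ids.
#' @param father,mother parent ids aligned to `id`; `NA` for founders (both
#'   parents must be present or both absent).
#' @return data.frame of class `pedigree_spec`, validated to be acyclic with
#'   all parents present.
#' @export
pedigree_spec <- function(id, father = NA, mother = NA) {
  ped <- data.frame(id = as.character(id),
                    father = as.character(rep_len(father, length(id))),
                    mother = as.character(rep_len(mother, length(id))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicated pedigree ids")
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("individuals must have both parents or neither: ",
         paste(ped$id[half], collapse = ", "))
  known <- c(NA, ped$id)
  if (!all(ped$father %in% known) || !all(ped$mother %in% known))
    stop("pedigree references unknown parents")
  # topological order check (also rejects cycles)
  done <- character(0)
  todo <- ped$id
  while (length(todo)) {
    ready <- todo[vapply(todo, function(i) {
      r <- ped[ped$id == i, ]
      is.na(r$father) || (r$father %in% done && r$mother %in% done)
    }, TRUE)]
    if (!length(ready)) stop("pedigree contains a cycle")
    done <- c(done, ready)
    todo <- setdiff(todo, ready)
  }
  attr(ped, "topo_order") <- done
  class(ped) <- c("pedigree_spec", "data.frame")
  ped
}

# one meiosis on one chromosome: returns selector (1/2) per marker
meiosis_selector <- function(pos, len_bp, cm_per_mb) {
  morgans <- len_bp / 1e6 * cm_per_mb / 100
  n_cross <- stats::rpois(1, morgans)
  start <- sample.int(2L, 1L)
  if (n_cross == 0L) return(rep(start, length(pos)))
  xpos <- sort(stats::runif(n_cross, 0, len_bp))
  (start - 1L + findInterval(pos, xpos)) %% 2L + 1L
}

# gamete from a parent: list(allele =, label =) across all markers
make_gamete <- function(parent, markers_by_chrom, genome) {
  alle <- integer(0); lab <- integer(0)
  for (ci in seq_along(markers_by_chrom)) {
    idx <- markers_by_chrom[[ci]]
    sel <- meiosis_selector(attr(markers_by_chrom, "pos")[[ci]],
                            genome$chromosomes$length_bp[ci], genome$cm_per_mb)
    alle <- c(alle, ifelse(sel == 1L, parent$allele[idx, 1], parent$allele[idx, 2]))
    lab <- c(lab, ifelse(sel == 1L, parent$label[idx, 1], parent$label[idx, 2]))
  }
  list(allele = alle, label = lab)
}

#' Gene-drop a pedigree over a simulated genome
#'
#' Generates the marker map (positions uniform per chromosome, then sorted),
#' draws founder haplotypes in HWE from the allele-frequency spectrum, drops
#' genes down the pedigree with Haldane recombination, forms unordered
#' genotypes, and applies the noise model (ROH first, then genotype errors,
#' then no-calls).  Deterministic for a fixed seed.
#'
#' @param genome a [genome_model()].
#' @param pedigree a [pedigree_spec()].
#' @param noise a [noise_model()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param clones optional named character vector: each element adds an extra
#'   sample (name = new id) that shares the haplotypes of an existing
#'   individual (value) but receives independent noise — the
#'   technical-replicate scenario.
#' @return An object of class `sim_cohort`: list with `table` (the noisy
#'   [genotype_table()]), `freq` (B-allele frequencies), `labels` (per
#'   individual, an n_markers x 2 integer matrix of founder-haplotype
#'   ancestry labels), `genome`, `pedigree`, `noise`, `seed`.
#' @export
simulate_cohort <- function(genome, pedigree, noise = noise_model(),
                            seed = NULL, clones = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(pedigree, "pedigree_spec"),
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- genome$chromosomes
  pos_list <- lapply(seq_len(nrow(chroms)), function(ci)
    sort(sample.int(chroms$length_bp[ci], chroms$n_markers[ci])))
  n <- sum(chroms$n_markers)
  markers <- data.frame(
    marker_id = sprintf("m%06d", seq_len(n)),
    chromosome = rep(chroms$name, chroms$n_markers),
    position = unlist(pos_list), stringsAsFactors = FALSE)
  freq <- stats::runif(n, genome$freq_range[1], genome$freq_range[2])
  offs <- c(0L, cumsum(chroms$n_markers))
  markers_by_chrom <- lapply(seq_len(nrow(chroms)), function(ci)
    (offs[ci] + 1L):offs[ci + 1L])
  attr(markers_by_chrom, "pos") <- pos_list

  indiv <- list()
  next_label <- 1L
  for (id in attr(pedigree, "topo_order")) {
    row <- pedigree[pedigree$id == id, ]
    if (is.na(row$father)) {
      alle <- cbind(stats::rbinom(n, 1L, freq), stats::rbinom(n, 1L, freq))
      lab <- cbind(rep(next_label, n), rep(next_label + 1L, n))
      next_label <- next_label + 2L
      indiv[[id]] <- list(allele = alle, label = lab)
    } else {
      gf <- make_gamete(indiv[[row$father]], markers_by_chrom, genome)
      gm <- make_gamete(indiv[[row$mother]], markers_by_chrom, genome)
      indiv[[id]] <- list(allele = cbind(gf$allele, gm$allele),
                          label = cbind(gf$label, gm$label))
    }
  }
  if (!is.null(clones)) {
    for (new_id in names(clones)) {
      src <- clones[[new_id]]
      if (!src %in% names(indiv)) stop("clone source not in pedigree: ", src)
      indiv[[new_id]] <- indiv[[src]]
    }
  }
  ids <- names(indiv)
  geno <- vapply(indiv, function(x) x$allele[, 1] + x$allele[, 2], integer(n))
  labels <- lapply(indiv, `[[`, "label")
  hap1 <- vapply(indiv, function(x) x$allele[, 1], integer(n))
  geno <- apply_noise(geno, hap1, markers, noise)
  tab <- genotype_table(markers, geno, sort = FALSE)
  structure(list(table = tab, freq = freq, labels = labels, genome = genome,
                 pedigree = pedigree, noise = noise, seed = seed),
            class = "sim_cohort")
}

apply_noise <- function(geno, hap1, markers, noise) {
  if (!is.null(noise$roh)) {
    for (i in seq_len(nrow(noise$roh))) {
      r <- noise$roh[i, ]
      j <- match(r$sample, colnames(geno))
      if (is.na(j)) stop("ROH spec names unknown sample: ", r$sample)
      in_iv <- markers$chromosome == as.character(r$chromosome) &
        markers$position >= r$start & markers$position <= r$end
      het <- in_iv & geno[, j] == 1L
      geno[het, j] <- 2L * hap1[het, j]
    }
  }
  if (noise$error_rate > 0) {
    err <- which(stats::runif(length(geno)) < noise$error_rate)
    g <- geno[err]
    flip <- ifelse(g == 1L,
                   ifelse(stats::runif(length(g)) < 0.5, 0L, 2L),
                   1L)
    geno[err] <- flip
  }
  if (noise$nc_rate > 0)
    geno[stats::runif(length(geno)) < noise$nc_rate] <- NA_integer_
  geno
}

#' Exact per-marker IBD state of a simulated pair
#'
#' Counts matched founder-haplotype labels between the two individuals'
#' haplotype pairs at each marker.
#'
#' @param cohort a `sim_cohort`.
#' @param sample_a,sample_b individual ids.
#' @return Integer vector over markers with values 0, 1, 2.
#' @export
pair_ibd_truth <- function(cohort, sample_a, sample_b) {
  la <- cohort$labels[[sample_a]]; lb <- cohort$labels[[sample_b]]
  if (is.null(la) || is.null(lb)) stop("unknown sample id in cohort")
  m11 <- la[, 1] == lb[, 1]; m12 <- la[, 1] == lb[, 2]
  m21 <- la[, 2] == lb[, 1]; m22 <- la[, 2] == lb[, 2]
  ibd2 <- (m11 & m22) | (m12 & m21)
  ibd1 <- !ibd2 & (m11 | m12 | m21 | m22)
  as.integer(2L * ibd2 + ibd1)
}

#' Realized Cotterman coefficients from an IBD truth track
#'
#' Base-pair-length-weighted genome fractions in IBD state 0/1/2.  Each
#' marker is weighted by the midpoint interval to its neighbours within its
#' chromosome.
#'
#' @param true_ibd integer vector of per-marker IBD states (0/1/2).
#' @param markers marker map data.frame (`chromosome`, `position`) aligned
#'   to `true_ibd`.
#' @return Named numeric vector `c(k0, k1, k2)` summing to 1.
#' @export
realized_k <- function(true_ibd, markers) {
  stopifnot(length(true_ibd) == nrow(markers))
  w <- numeric(length(true_ibd))
  for (ch in unique(markers$chromosome)) {
    i <- which(markers$chromosome == ch)
    p <- markers$position[i]
    if (length(p) == 1L) { w[i] <- 1; next }
    b <- c(p[1], (p[-1] + p[-length(p)]) / 2, p[length(p)])
    w[i] <- diff(b)
  }
  tot <- sum(w)
  c(k0 = sum(w[true_ibd == 0L]) / tot,
    k1 = sum(w[true_ibd == 1L]) / tot,
    k2 = sum(w[true_ibd == 2L]) / tot)
}

SCENARIO_NAMES <- c("identical", "parent_child", "full_sib", "half_sib",
                    "avuncular", "first_cousin", "r_1_64", "unrelated")

#' Pedigree-expected Cotterman coefficients of the built-in scenarios
#'
#' @param name scenario name, one of `identical`, `parent_child`,
#'   `full_sib`, `half_sib`, `avuncular`, `first_cousin`, `r_1_64` (second
#'   cousins once removed, coefficient of relatedness 1/64), `unrelated`.
#' @return Named numeric vector `c(k0, k1, k2)`.
#' @export
expected_k <- function(name) {
  name <- match.arg(name, SCENARIO_NAMES)
  k <- switch(name,
              identical    = c(0, 0, 1),
              parent_child = c(0, 1, 0),
              full_sib     = c(0.25, 0.5, 0.25),
              half_sib     = c(0.5, 0.5, 0),
              avuncular    = c(0.5, 0.5, 0),
              first_cousin = c(0.75, 0.25, 0),
              r_1_64       = c(1 - 1 / 32, 1 / 32, 0),
              unrelated    = c(1, 0, 0))
  stats::setNames(k, c("k0", "k1", "k2"))
}

scenario_pedigree <- function(name) {
  p <- function(...) pedigree_spec(...)
  switch(name,
    identical = list(ped = p("A"), pair = c("A", "A_rep"),
                     clones = c(A_rep = "A")),
    parent_child = list(ped = p(c("F", "M", "C"),
                                father = c(NA, NA, "F"),
                                mother = c(NA, NA, "M")),
                        pair = c("F", "C")),
    full_sib = list(ped = p(c("F", "M", "C1", "C2"),
                            father = c(NA, NA, "F", "F"),
                            mother = c(NA, NA, "M", "M")),
                    pair = c("C1", "C2")),
    half_sib = list(ped = p(c("F", "M1", "M2", "C1", "C2"),
                            father = c(NA, NA, NA, "F", "F"),
                            mother = c(NA, NA, NA, "M1", "M2")),
                    pair = c("C1", "C2")),
    avuncular = list(ped = p(c("GF", "GM", "SP", "S1", "S2", "N"),
                             father = c(NA, NA, NA, "GF", "GF", "S1"),
                             mother = c(NA, NA, NA, "GM", "GM", "SP")),
                     pair = c("S2", "N")),
    first_cousin = list(ped = p(c("GF", "GM", "P1", "P2", "S1", "S2", "C1", "C2"),
                                father = c(NA, NA, NA, NA, "GF", "GF", "S1", "S2"),
                                mother = c(NA, NA, NA, NA, "GM", "GM", "P1", "P2")),
                        pair = c("C1", "C2")),
    r_1_64 = list(ped = p(c("GF", "GM", "P1", "P2", "P3", "P4", "P5",
                            "S1", "S2", "A1", "B1", "A2", "B2", "A3"),
                          father = c(NA, NA, NA, NA, NA, NA, NA,
                                     "GF", "GF", "S1", "S2", "A1", "B1", "A2"),
                          mother = c(NA, NA, NA, NA, NA, NA, NA,
                                     "GM", "GM", "P1", "P2", "P3", "P4", "P5")),
                  pair = c("A3", "B2")),
    unrelated = list(ped = p(c("U1", "U2")), pair = c("U1", "U2")))
}

#' Simulate a genotype pair of known relationship
#'
#' Builds the minimal pedigree realizing the named relationship, gene-drops
#' it, and returns the focal pair with its exact IBD truth.
#'
#' @param name scenario name, see [expected_k()].
#' @param genome a [genome_model()].
#' @param noise a [noise_model()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `simulated_pair`: list with `table`
#'   (a two-sample [genotype_table()]), `sample_a`, `sample_b`, `true_ibd`
#'   (per-marker IBD state), `realized_k`, `expected_k`, `scenario`,
#'   `cohort` (the full `sim_cohort`) and `seed`.
#' @export
simulate_scenario <- function(name, genome = genome_model(),
                              noise = noise_model(), seed = NULL) {
  name <- match.arg(name, SCENARIO_NAMES)
  sc <- scenario_pedigree(name)
  cohort <- simulate_cohort(genome, sc$ped, noise, seed = seed,
                            clones = sc$clones)
  a <- sc$pair[1]; b <- sc$pair[2]
  true_ibd <- pair_ibd_truth(cohort, a, b)
  keep <- match(c(a, b), colnames(cohort$table$geno))
  tab <- genotype_table(cohort$table$markers,
                        cohort$table$geno[, keep, drop = FALSE], sort = FALSE)
  structure(list(table = tab, sample_a = a, sample_b = b,
                 true_ibd = true_ibd,
                 realized_k = realized_k(true_ibd, cohort$table$markers),
                 expected_k = expected_k(name), scenario = name,
                 cohort = cohort, seed = seed),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("simulated_pair: scenario '", x$scenario, "' (", x$sample_a, " vs ",
      x$sample_b, ")\n", sep = "")
  cat(sprintf("  realized k = (%.3f, %.3f, %.3f), expected k = (%.3f, %.3f, %.3f)\n",
              x$realized_k[1], x$realized_k[2], x$realized_k[3],
              x$expected_k[1], x$expected_k[2], x$expected_k[3]))
  invisible(x)
}
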