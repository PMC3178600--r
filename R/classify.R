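# Relationship classification -------------------------------------------------
#
# Maps a pair's (IBS2*_ratio, K0, K1, K2, heterozygosity) to a relationship
# category.  The numeric boundaries are a synthesis of the bands observed in
# practice: identical and parent-child pairs have ratios near 1 and are
# separated by K2; sibling pairs sit in a 0.92-0.95 ratio band with
# (k1, k2) near (0.5, 0.25); 0.03125 (= k1 of a 1/64 relationship) is the
# detection floor below which elevated ratios are attributed to atypical
# heterozygosity rather than relatedness.

#' Classification thresholds
#'
#' All boundaries of [classify_pair()] in one configuration object.
#'
#' @param ratio_identical minimum IBS2* ratio for identical/parent-child.
#'   An error-free pair of these classes has no informative IBS0, so the
#'   ratio is 1 less the genotyping-error contribution (about `1 - e` for a
#'   parent-child pair at per-call error rate `e`); the default 0.98 keeps a
#'   margin of two default error rates.
#' @param k2_identical minimum K2 for the identical call.
#' @param k1_parent_child minimum K1 for the parent-child call.
#' @param k2_parent_child maximum K2 for the parent-child call.
#' @param sibling_ratio_band IBS2* ratio band of full siblings.
#' @param k1_detection_floor smallest K1 treated as evidence of relatedness
#'   (the 1/64-relationship limit, 0.03125).
#' @param k1_distant_max upper K1 bound of the `distant` class (third-degree
#'   and closer take over above it).
#' @param ratio_flag empirical relatedness screen on the ratio.
#' @param alpha two-sided significance level for the low-ratio outlier test.
#' @return An object of class `classify_thresholds`.
#' @export
classify_thresholds <- function(ratio_identical = 0.98, k2_identical = 0.9,
                                k1_parent_child = 0.9, k2_parent_child = 0.1,
                                sibling_ratio_band = c(0.90, 0.96),
                                k1_detection_floor = 0.03125,
                                k1_distant_max = 0.15,
                                ratio_flag = 0.70, alpha = 0.05) {
  structure(list(ratio_identical = ratio_identical,
                 k2_identical = k2_identical,
                 k1_parent_child = k1_parent_child,
                 k2_parent_child = k2_parent_child,
                 sibling_ratio_band = sibling_ratio_band,
                 k1_detection_floor = k1_detection_floor,
                 k1_distant_max = k1_distant_max,
                 ratio_flag = ratio_flag, alpha = alpha),
            class = "classify_thresholds")
}

RELATIONSHIP_CLASSES <- c("identical", "parent_child", "full_sibling",
                          "second_degree", "third_degree", "distant",
                          "unrelated", "high_het_artifact", "low_het_outlier")

# reference (k1, k2) points for nearest-expected assignment
K_REFERENCE <- rbind(full_sibling = c(0.5, 0.25),
                     second_degree = c(0.5, 0),
                     third_degree = c(0.25, 0))

#' Classify one pair's relationship
#'
#' Decision cascade over the IBS2* statistic and the K coefficients:
#' identical (high K2, ratio near 1), parent-child (high K1, low K2, ratio
#' near 1), then nearest-expected assignment in (k1, k2) space among full
#' sibling (0.5, 0.25), second degree (0.5, 0) and third degree (0.25, 0)
#' for pairs with `K1` above `k1_distant_max` — full sibling additionally
#' requires the sibling ratio band; `distant` covers K1 between the 1/64
#' detection floor and `k1_distant_max`; an elevated ratio without K1
#' support is reported as a heterozygosity artifact; a ratio significantly
#' below 2/3 with below-reference pair heterozygosity as a low-heterozygosity
#' outlier; everything else as unrelated.
#'
#' @param stat an [ibs2star_stat()] (or list with `ratio`, `z`,
#'   `p_two_sided`).
#' @param k a [estimate_k()] result (or list with `k0`, `k1`, `k2`).
#' @param het_pair mean heterozygosity of the two samples (optional; only
#'   used for the low-heterozygosity outlier call).
#' @param het_ref cohort reference heterozygosity (e.g. the median pair
#'   value of within-group comparisons).
#' @param thresholds a [classify_thresholds()] object.
#' @return List with `class` (one of the relationship classes) and
#'   `rationale`, a character vector of the numeric conditions that fired.
#' @export
classify_pair <- function(stat, k, het_pair = NULL, het_ref = NULL,
                          thresholds = classify_thresholds()) {
  th <- thresholds
  ratio <- stat$ratio; k1 <- k$k1; k2 <- k$k2
  out <- function(class, ...) list(class = class, rationale = c(...))
  if (k2 >= th$k2_identical && ratio >= th$ratio_identical)
    return(out("identical",
               sprintf("K2=%.3f>=%.2f", k2, th$k2_identical),
               sprintf("ratio=%.3f>=%.2f", ratio, th$ratio_identical)))
  if (k1 >= th$k1_parent_child && k2 < th$k2_parent_child &&
      ratio >= th$ratio_identical)
    return(out("parent_child",
               sprintf("K1=%.3f>=%.2f", k1, th$k1_parent_child),
               sprintf("K2=%.3f<%.2f", k2, th$k2_parent_child),
               sprintf("ratio=%.3f>=%.2f", ratio, th$ratio_identical)))
  if (k1 >= th$k1_distant_max || k2 >= th$k2_parent_child) {
    d <- sqrt((K_REFERENCE[, 1] - k1)^2 + (K_REFERENCE[, 2] - k2)^2)
    nearest <- rownames(K_REFERENCE)[which.min(d)]
    near_code <- sprintf("nearest (k1,k2)=(%.2f,%.2f) at d=%.3f",
                         K_REFERENCE[which.min(d), 1],
                         K_REFERENCE[which.min(d), 2], min(d))
    if (nearest == "full_sibling") {
      in_band <- ratio >= th$sibling_ratio_band[1] &&
        ratio <= th$sibling_ratio_band[2]
      # the ratio band annotates the sibling call but does not veto it: the
      # band's location depends on the cohort's allele-frequency spectrum,
      # while the (k1, k2) evidence does not
      return(out("full_sibling", near_code,
                 sprintf("ratio=%.3f %s sibling band [%.2f, %.2f]", ratio,
                         if (in_band) "inside" else "outside",
                         th$sibling_ratio_band[1], th$sibling_ratio_band[2])))
    }
    return(out(nearest, near_code))
  }
  if (k1 >= th$k1_detection_floor)
    return(out("distant",
               sprintf("K1=%.4f in [%.5f, %.2f)", k1,
                       th$k1_detection_floor, th$k1_distant_max)))
  if (ratio > th$ratio_flag)
    return(out("high_het_artifact",
               sprintf("ratio=%.3f>%.2f but K1=%.4f<%.5f", ratio,
                       th$ratio_flag, k1, th$k1_detection_floor)))
  low_sig <- !is.null(stat$z) && stat$z < 0 && stat$p_two_sided <= th$alpha
  if (low_sig && !is.null(het_pair) && !is.null(het_ref) &&
      !is.na(het_pair) && !is.na(het_ref) && het_pair < het_ref)
    return(out("low_het_outlier",
               sprintf("ratio=%.3f significantly < 2/3 (p=%.2g)", ratio,
                       stat$p_two_sided),
               sprintf("pair het %.3f < reference %.3f", het_pair, het_ref)))
  out("unrelated", sprintf("K1=%.4f<%.5f, ratio=%.3f", k1,
                           th$k1_detection_floor, ratio))
}

#' Full relationship report for selected pairs
#'
#' Computes IBS2* statistics, K coefficients, heterozygosities and the
#' relationship class for each requested pair; the layout mirrors a cohort
#' QC table (ids, group, ratio, K0, K1, K2, class).
#'
#' @param table an autosome-filtered `genotype_table`.
#' @param pairs data.frame with `sample_a`, `sample_b` (e.g. the flagged rows
#'   of [all_pairs()]); if `NULL`, every unordered pair.
#' @param sheet optional sample sheet supplying group labels.
#' @param params an [ibd_params()] object.
#' @param thresholds a [classify_thresholds()] object.
#' @param n_tests Bonferroni divisor for the pair tests.
#' @param het_ref reference heterozygosity for the low-het outlier rule;
#'   default = median pair heterozygosity over the requested pairs.
#' @return data.frame with one row per pair: ids, group labels, `ratio`,
#'   `pct_informative`, `z`, `p`, `k0`, `k1`, `k2`, `het_pair`, `class`,
#'   `rationale` (collapsed with `"; "`).
#' @export
relationship_report <- function(table, pairs = NULL, sheet = NULL,
                                params = ibd_params(),
                                thresholds = classify_thresholds(),
                                n_tests = NULL, het_ref = NULL) {
  ids <- sample_ids(table)
  if (is.null(pairs)) {
    sheet0 <- data.frame(sample_id = ids, group = "all",
                         stringsAsFactors = FALSE)
    pairs <- pair_grid(sheet0, "all")
  }
  np <- nrow(pairs)
  if (np == 0L) stop("no pairs requested")
  if (is.null(n_tests)) n_tests <- np
  grp <- function(id) {
    if (is.null(sheet)) return(NA_character_)
    g <- sheet$group[match(id, sheet$sample_id)]
    if (length(g)) g else NA_character_
  }
  het <- vapply(ids, function(s) suppressWarnings(heterozygosity(table, s)),
                numeric(1))
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
    cnt <- count_pair(table, a, b)
    st <- ibs2star_stat(cnt, n_tests = n_tests, alpha = thresholds$alpha,
                        flag_threshold = thresholds$ratio_flag)
    kk <- estimate_k(table, a, b, params)
    rows[[i]] <- data.frame(
      sample_a = a, sample_b = b, group_a = grp(a), group_b = grp(b),
      ratio = st$ratio, pct_informative = st$pct_informative,
      z = st$z, p = st$p_two_sided, k0 = kk$k0, k1 = kk$k1, k2 = kk$k2,
      het_pair = mean(c(het[[a]], het[[b]])), stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  if (is.null(het_ref)) het_ref <- stats::median(rep$het_pair, na.rm = TRUE)
  cls <- lapply(seq_len(np), function(i) {
    classify_pair(list(ratio = rep$ratio[i], z = rep$z[i],
                       p_two_sided = rep$p[i]),
                  list(k0 = rep$k0[i], k1 = rep$k1[i], k2 = rep$k2[i]),
                  het_pair = rep$het_pair[i], het_ref = het_ref,
                  thresholds = thresholds)
  })
  rep$class <- vapply(cls, `[[`, "", "class")
  rep$rationale <- vapply(cls, function(x) paste(x$rationale, collapse = "; "), "")
  rep
}
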