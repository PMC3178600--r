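# Genotype container ---------------------------------------------------------
#
# Genotypes are stored as the count of B alleles: 0 = AA, 1 = AB, 2 = BB,
# NA = no-call.  The A/B labelling at a marker is arbitrary (A is assigned to
# the lexicographically smaller observed allele when reading PED files);
# every downstream IBS quantity is invariant to swapping the labels.

GENO_LEVELS <- c("AA", "AB", "BB", "NC")

#' Construct a genotype table
#'
#' A `genotype_table` holds an ordered marker map and one genotype call vector
#' per sample, coded as B-allele counts (0 = AA, 1 = AB, 2 = BB, NA = NC).
#' Markers are sorted by (chromosome, position); marker ids and sample ids
#' must be unique.
#'
#' @param markers data.frame with columns `marker_id`, `chromosome`,
#'   `position` (1-based base pairs).
#' @param geno integer matrix, markers x samples, values in \{0, 1, 2, NA\};
#'   column names are the sample ids.
#' @param sort logical; sort markers by (chromosome, position). Chromosomes
#'   are ordered numerically where their (chr-stripped) label is numeric,
#'   then alphabetically.
#' @return An object of class `genotype_table`: a list with elements
#'   `markers` (data.frame) and `geno` (integer matrix).
#' @examples
#' gt <- genotype_table(
#'   data.frame(marker_id = c("rs1", "rs2"), chromosome = "1",
#'              position = c(100L, 200L)),
#'   matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(NULL, c("s1", "s2"))))
#' gt
#' @export
genotype_table <- function(markers, geno, sort = TRUE) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chromosome", "position") %in% names(markers)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(markers))
    stop("geno has ", nrow(geno), " rows but markers has ", nrow(markers))
  if (is.null(colnames(geno)))
    stop("geno must have sample ids as column names")
  if (anyDuplicated(colnames(geno)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(geno)[duplicated(colnames(geno))]), collapse = ", "))
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker ids: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", "))
  if (any(markers$position < 1L))
    stop("marker positions must be >= 1")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position <- as.integer(markers$position)
  if (sort) {
    ord <- order(chrom_rank(markers$chromosome), markers$position)
    markers <- markers[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
  }
  rownames(markers) <- NULL
  structure(list(markers = markers, geno = geno), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", nrow(x$markers), " markers x ",
      ncol(x$geno), " samples\n", sep = "")
  cat("chromosomes: ", paste(unique(x$markers$chromosome), collapse = " "), "\n",
      sep = "")
  nc <- mean(is.na(x$geno))
  cat(sprintf("no-call rate: %.4f\n", nc))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$markers), ncol(x$geno))

#' Sample ids of a genotype table
#' @param table a `genotype_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(table) colnames(table$geno)

# ordering rank for chromosome labels: numeric labels first in numeric order,
# then everything else alphabetically
chrom_rank <- function(chrom) {
  s <- sub("^chr", "", chrom, ignore.case = TRUE)
  n <- suppressWarnings(as.numeric(s))
  r <- ifelse(is.na(n), NA_real_, n)
  alpha <- sort(unique(s[is.na(n)]))
  r[is.na(n)] <- 1e6 + match(s[is.na(n)], alpha)
  r
}

# labels treated as non-autosomal; both lettered and PLINK numeric dialects.
# 23-26 cover X, Y and (depending on dialect) XY/MT.
NON_AUTOSOMES <- c("X", "Y", "MT", "M", "XY", "23", "24", "25", "26")

is_autosome <- function(chrom) {
  s <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  !(s %in% NON_AUTOSOMES)
}

#' Restrict a genotype table to autosomal markers
#'
#' Sex-chromosome and mitochondrial markers are excluded from all relatedness
#' statistics; labels `X`, `Y`, `MT`, `M`, `XY` (optionally `chr`-prefixed) and
#' the PLINK numeric codes 23-26 are treated as non-autosomal.
#'
#' @param table a `genotype_table`.
#' @return A `genotype_table` containing only autosomal markers; the sample
#'   list is unchanged.  An empty marker set is allowed (with a warning).
#' @export
filter_autosomes <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- is_autosome(table$markers$chromosome)
  if (!any(keep))
    warning("no autosomal markers remain after filtering")
  genotype_table(table$markers[keep, , drop = FALSE],
                 table$geno[keep, , drop = FALSE], sort = FALSE)
}

#' Autosomal heterozygosity of one sample
#'
#' Fraction of non-missing calls that are heterozygous (AB).  Callers should
#' pass an autosome-filtered table; the ratio itself uses every marker in the
#' table.
#'
#' @param table a `genotype_table`.
#' @param sample sample id.
#' @return Heterozygosity rate in \[0, 1\]; `NA` (with a warning) if the sample
#'   has no called genotypes.
#' @export
heterozygosity <- function(table, sample) {
  g <- sample_column(table, sample)
  if (all(is.na(g))) {
    warning("sample ", sample, " has no called genotypes; heterozygosity undefined")
    return(NA_real_)
  }
  mean(g == 1L, na.rm = TRUE)
}

sample_column <- function(table, sample) {
  stopifnot(inherits(table, "genotype_table"))
  j <- match(sample, colnames(table$geno))
  if (is.na(j))
    stop("unknown sample id: ", sample)
  table$geno[, j]
}
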