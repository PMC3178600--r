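# Readers / writers ----------------------------------------------------------
#
# Text dialects only: PLINK PED/MAP, TPED/TFAM and a simple TSV genotype
# matrix.  All readers are gzip-transparent (file() handles .gz).

read_lines_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

read_map <- function(map_path) {
  fields <- split_ws(read_lines_any(map_path))
  fields <- fields[lengths(fields) > 0]
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("MAP line ", bad[1], " has ", lengths(fields)[bad[1]],
         " fields (expected 4: chrom, id, cM, bp)")
  m <- do.call(rbind, fields)
  data.frame(marker_id = m[, 2], chromosome = m[, 1],
             position = as.integer(m[, 4]), stringsAsFactors = FALSE)
}

# recode per-marker allele pairs to B-allele counts; A = lexicographically
# smaller observed allele.  alle1/alle2: character matrices markers x samples.
recode_biallelic <- function(alle1, alle2, marker_id) {
  n <- nrow(alle1)
  geno <- matrix(NA_integer_, n, ncol(alle1))
  multi <- character(0)
  for (i in seq_len(n)) {
    a1 <- alle1[i, ]; a2 <- alle2[i, ]
    miss <- a1 == "0" | a2 == "0"
    obs <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(obs) > 2L) { multi <- c(multi, marker_id[i]); next }
    if (length(obs) == 0L) next              # all missing: stays NA
    b <- if (length(obs) == 2L) obs[2] else ""   # monomorphic: everything is AA
    g <- (a1 == b) + (a2 == b)
    g[miss] <- NA_integer_
    geno[i, ] <- g
  }
  if (length(multi))
    stop("markers with more than two alleles: ", paste(multi, collapse = ", "))
  geno
}

#' Read PLINK PED/MAP genotypes
#'
#' Parses the text PED/MAP dialect: a MAP file with four columns (chromosome,
#' marker id, genetic position, base-pair position) and a PED file with six
#' metadata columns followed by two allele columns per marker.  Allele pairs
#' are recoded to AA/AB/BB relative to the two observed alleles at each marker
#' (A = lexicographically smaller allele); `0 0` becomes a no-call.  Markers
#' are sorted by (chromosome, position).
#'
#' @param ped_path,map_path paths to the PED and MAP files (may be gzipped).
#' @return A [genotype_table()].
#' @export
read_plink <- function(ped_path, map_path) {
  map <- read_map(map_path)
  m <- nrow(map)
  rows <- split_ws(read_lines_any(ped_path))
  rows <- rows[lengths(rows) > 0]
  bad <- which(lengths(rows) != 6L + 2L * m)
  if (length(bad))
    stop("PED line ", bad[1], " has ", lengths(rows)[bad[1]],
         " fields (expected ", 6L + 2L * m, " for ", m, " markers)")
  ids <- vapply(rows, `[[`, "", 2L)
  if (anyDuplicated(ids))
    ids <- paste(vapply(rows, `[[`, "", 1L), ids, sep = "_")
  body <- do.call(rbind, lapply(rows, function(r) r[-(1:6)]))
  alle1 <- t(body[, seq(1L, 2L * m, by = 2L), drop = FALSE])
  alle2 <- t(body[, seq(2L, 2L * m, by = 2L), drop = FALSE])
  geno <- recode_biallelic(alle1, alle2, map$marker_id)
  colnames(geno) <- ids
  genotype_table(map, geno)
}

#' Read PLINK TPED/TFAM genotypes
#'
#' Transposed text dialect: each TPED row carries one marker (chromosome, id,
#' genetic position, base-pair position, then two alleles per sample); the
#' TFAM file supplies sample ids.  Recoding follows [read_plink()].
#'
#' @param tped_path,tfam_path paths to the TPED and TFAM files.
#' @return A [genotype_table()].
#' @export
read_tped <- function(tped_path, tfam_path) {
  fam <- split_ws(read_lines_any(tfam_path))
  fam <- fam[lengths(fam) > 0]
  if (any(lengths(fam) < 2L))
    stop("TFAM rows need at least 2 columns (family id, individual id)")
  ids <- vapply(fam, `[[`, "", 2L)
  if (anyDuplicated(ids))
    ids <- paste(vapply(fam, `[[`, "", 1L), ids, sep = "_")
  ns <- length(ids)
  rows <- split_ws(read_lines_any(tped_path))
  rows <- rows[lengths(rows) > 0]
  bad <- which(lengths(rows) != 4L + 2L * ns)
  if (length(bad))
    stop("TPED line ", bad[1], " has ", lengths(rows)[bad[1]],
         " fields (expected ", 4L + 2L * ns, " for ", ns, " samples)")
  meta <- do.call(rbind, lapply(rows, `[`, 1:4))
  map <- data.frame(marker_id = meta[, 2], chromosome = meta[, 1],
                    position = as.integer(meta[, 4]), stringsAsFactors = FALSE)
  body <- do.call(rbind, lapply(rows, function(r) r[-(1:4)]))
  alle1 <- body[, seq(1L, 2L * ns, by = 2L), drop = FALSE]
  alle2 <- body[, seq(2L, 2L * ns, by = 2L), drop = FALSE]
  geno <- recode_biallelic(alle1, alle2, map$marker_id)
  colnames(geno) <- ids
  genotype_table(map, geno)
}

#' Read a TSV genotype matrix
#'
#' Header row holds `marker_id`, `chromosome`, `position` followed by sample
#' ids; cells are `AA`, `AB`, `BA`, `BB` or `NC`.  `BA` is normalized to `AB`
#' (heterozygotes are unordered).  Rows are sorted by (chromosome, position).
#'
#' @param path path to the TSV file (may be gzipped).
#' @return A [genotype_table()].
#' @export
read_genotype_matrix <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty genotype matrix file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4L)
    stop("genotype matrix needs marker_id, chromosome, position + >=1 sample")
  ids <- header[-(1:3)]
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("genotype matrix line ", bad[1] + 1L, " has ", lengths(cells)[bad[1]],
         " fields (expected ", length(header), ")")
  m <- do.call(rbind, cells)
  map <- data.frame(marker_id = m[, 1], chromosome = m[, 2],
                    position = as.integer(m[, 3]), stringsAsFactors = FALSE)
  calls <- m[, -(1:3), drop = FALSE]
  calls[calls == "BA"] <- "AB"
  code <- match(calls, GENO_LEVELS)    # AA=1, AB=2, BB=3, NC=4
  if (anyNA(code)) {
    idx <- which(is.na(code))[1]
    r <- (idx - 1L) %% nrow(calls) + 1L
    k <- (idx - 1L) %/% nrow(calls) + 1L
    stop("invalid genotype token '", calls[r, k], "' at marker ",
         map$marker_id[r], ", sample ", ids[k])
  }
  geno <- matrix(c(0L, 1L, 2L, NA_integer_)[code], nrow(calls), ncol(calls))
  colnames(geno) <- ids
  genotype_table(map, geno)
}

#' Write a genotype table as a TSV matrix
#'
#' Inverse of [read_genotype_matrix()]: reading the written file reproduces
#' calls, marker order and sample order exactly.
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  lab <- matrix(GENO_LEVELS[ifelse(is.na(table$geno), 4L, table$geno + 1L)],
                nrow(table$geno), ncol(table$geno))
  out <- cbind(table$markers$marker_id, table$markers$chromosome,
               as.character(table$markers$position), lab)
  lines <- c(paste(c("marker_id", "chromosome", "position",
                     colnames(table$geno)), collapse = "\t"),
             apply(out, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genotype table as PLINK PED/MAP
#'
#' Alleles are written as the letters `A`/`B` (the internal coding); no-calls
#' become `0 0`.  Metadata columns are filled with the sample id and zeros.
#'
#' @param table a `genotype_table`.
#' @param ped_path,map_path output paths.
#' @return `ped_path`, invisibly.
#' @export
write_plink <- function(table, ped_path, map_path) {
  stopifnot(inherits(table, "genotype_table"))
  map <- table$markers
  writeLines(paste(map$chromosome, map$marker_id, 0, map$position, sep = "\t"),
             map_path)
  a1 <- c("A", "A", "B")[table$geno + 1L]; a1[is.na(table$geno)] <- "0"
  a2 <- c("A", "B", "B")[table$geno + 1L]; a2[is.na(table$geno)] <- "0"
  dim(a1) <- dim(a2) <- dim(table$geno)
  ids <- colnames(table$geno)
  lines <- vapply(seq_along(ids), function(j) {
    paste(c(ids[j], ids[j], 0, 0, 0, -9,
            as.vector(rbind(a1[, j], a2[, j]))), collapse = " ")
  }, "")
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id` and `group` (additional columns are kept as
#' annotations).
#'
#' @param path path to the TSV file.
#' @return data.frame with at least `sample_id` and `group`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id and group")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample ids in sample sheet")
  sheet
}
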