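#' Read PLINK text PED/MAP files
#'
#' Parses the plain-text PLINK pedigree format.  Each PED line is
#' `family id father mother sex phenotype` followed by two allele symbols per
#' marker; `0 0` encodes a missing genotype.  Per marker, genotypes are
#' recoded to counts of the lexicographically larger allele symbol (all
#' downstream statistics are allele-label symmetric, so the choice only fixes
#' orientation).  Markers are sorted by (chromosome, bp) and the call matrix
#' permuted to match.
#'
#' @param ped_path path to the PED file
#' @param map_path path to the MAP file (4 columns: chrom, id, cM, bp)
#' @return a [genotypes] object; the family column is kept as attribute
#'   `family` so a write/read round trip is exact
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4)
    stop("MAP file must have 4 columns (chrom, id, cM, bp), found ",
         ncol(map_raw))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  expect <- 6L + 2L * m
  bad <- which(len != expect)
  if (length(bad))
    stop(sprintf("PED line %d has %d fields, expected %d (6 + 2 x %d markers)",
                 bad[1], len[bad[1]], expect, m))
  tab <- do.call(rbind, toks)
  fam <- tab[, 1]
  ids <- tab[, 2]
  a1 <- tab[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tab[, 6L + 2L * seq_len(m), drop = FALSE]

  calls <- matrix(NA_integer_, nrow = nrow(tab), ncol = m)
  allele_a <- allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    als <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(als) > 2)
      stop("marker ", map_raw[j, 2], " has more than two alleles: ",
           paste(als, collapse = ", "))
    if (length(als) >= 1) {
      counted <- als[length(als)]          # lexicographically larger
      allele_a[j] <- als[1]
      allele_b[j] <- counted
      calls[, j] <- (x1 == counted) + (x2 == counted)
    }
    calls[miss, j] <- NA_integer_
  }
  rownames(calls) <- ids
  map <- data.frame(marker_id = map_raw[, 2], chrom = map_raw[, 1],
                    pos_bp = as.integer(map_raw[, 4]),
                    allele_a = allele_a, allele_b = allele_b,
                    stringsAsFactors = FALSE)
  g <- genotypes(calls, map)
  attr(g, "family") <- stats::setNames(fam, ids)
  g
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map]: emits one PED line per sample and a 4-column
#' MAP.  Allele symbols come from the map's `allele_a`/`allele_b` columns when
#' present ("A"/"B" otherwise, "B" being the counted allele); missing calls
#' are written as `0 0`.
#'
#' The round trip through [read_ped_map] reproduces calls and map exactly
#' whenever each marker's counted allele is observed at least once; a marker
#' whose calls are all 0 (or missing) re-reads as count 2 of its only
#' observed allele, since the text format carries no orientation for it.
#'
#' @param g a [genotypes] object
#' @param ped_path,map_path output paths
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "genotypes"))
  map <- g$map
  aa <- if ("allele_a" %in% names(map)) map$allele_a else rep(NA_character_, nrow(map))
  ab <- if ("allele_b" %in% names(map)) map$allele_b else rep(NA_character_, nrow(map))
  aa[is.na(aa)] <- "A"
  ab[is.na(ab)] <- "B"
  fam <- attr(g, "family")
  ids <- rownames(g$calls)
  famv <- if (is.null(fam)) rep("FAM1", length(ids)) else unname(fam[ids])
  famv[is.na(famv)] <- "FAM1"

  m <- nrow(map)
  ped_lines <- vapply(seq_len(nrow(g$calls)), function(i) {
    cl <- g$calls[i, ]
    x1 <- ifelse(is.na(cl), "0", ifelse(cl >= 1, ab, aa))
    x2 <- ifelse(is.na(cl), "0", ifelse(cl == 2, ab, aa))
    paste(c(famv[i], ids[i], "0", "0", "0", "-9", rbind(x1, x2)),
          collapse = " ")
  }, character(1))
  writeLines(ped_lines, ped_path)
  map_out <- data.frame(map$chrom, map$marker_id, 0L, map$pos_bp)
  utils::write.table(map_out, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a sample-to-group assignment table
#'
#' Tab-separated file with header columns `sample_id` and `group`.
#'
#' @param path file path
#' @param g optional [genotypes] object; if given, every grouped sample must
#'   exist in it
#' @return data.frame with columns `sample_id`, `group`
#' @export
read_group_file <- function(path, g = NULL) {
  gr <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(gr)))
    stop("group file must have header columns `sample_id` and `group`")
  gr <- gr[, c("sample_id", "group")]
  validate_groups(gr, g)
}

#' Write a sample-to-group assignment table
#' @param groups data.frame with columns `sample_id`, `group`
#' @param path output path
#' @export
write_group_file <- function(groups, path) {
  utils::write.table(groups[, c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_groups <- function(groups, g = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("sample_id", "group") %in% names(groups)))
  groups$sample_id <- as.character(groups$sample_id)
  groups$group <- as.character(groups$group)
  if (anyDuplicated(groups$sample_id))
    stop("duplicate sample ids in group assignment")
  if (!is.null(g)) {
    miss <- setdiff(groups$sample_id, sample_ids(g))
    if (length(miss))
      stop("grouped sample(s) absent from genotypes: ",
           paste(miss, collapse = ", "))
  }
  groups
}
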