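#' Genotype container for SNP-array data
#'
#' Bundles a samples x markers matrix of diploid allele counts with its marker
#' map.  Calls are integer counts of the counted allele per marker (0, 1 or 2);
#' missing genotypes are `NA`.  On construction the map is sorted by
#' (chromosome, position) with natural chromosome ordering and the call matrix
#' columns are permuted accordingly.
#'
#' @param calls numeric/integer matrix, samples in rows, markers in columns,
#'   values in `{0, 1, 2, NA}`.  Row names are sample ids (generated if
#'   absent); column order must correspond to the rows of `map`.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp`
#'   (1-based bp) and optionally `allele_a`/`allele_b` (allele symbols, with
#'   `allele_b` the counted allele).
#' @return an object of class `genotypes` with elements `calls` and `map`.
#' @export
genotypes <- function(calls, map) {
  calls <- as.matrix(calls)
  if (!is.data.frame(map)) stop("`map` must be a data.frame")
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("`map` must have columns: ", paste(need, collapse = ", "))
  if (ncol(calls) != nrow(map))
    stop("dimension mismatch: ", ncol(calls), " call columns vs ",
         nrow(map), " map rows")
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids in map")
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1L))
    stop("marker positions must be integers >= 1")
  bad <- !(calls %in% c(0, 1, 2) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("sample_%03d", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")

  ord <- order(chrom_rank(map$chrom), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(calls) <- map$marker_id
  # strictly increasing positions within each chromosome
  dup <- stats::ave(map$pos_bp, map$chrom,
                    FUN = function(p) c(0L, as.integer(diff(p) <= 0)))
  if (any(dup == 1L))
    stop("marker positions must be strictly increasing within a chromosome")
  structure(list(calls = calls, map = map), class = "genotypes")
}

#' Natural (numeric-aware) chromosome ordering rank
#'
#' Numeric labels sort numerically and come first; non-numeric labels follow
#' alphabetically.  Used everywhere a stable chromosome order is needed.
#'
#' @param chrom character vector of chromosome labels
#' @return integer rank usable as a sort key
#' @export
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  lev <- unique(chrom[order(is.na(num), ifelse(is.na(num), 0, num), chrom)])
  match(chrom, lev)
}

#' Chromosome labels of a genotypes object, in natural order
#' @param g a `genotypes` object
#' @export
chromosomes <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  unique(g$map$chrom)
}

#' Sample identifiers of a genotypes object
#' @param g a `genotypes` object
#' @export
sample_ids <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  rownames(g$calls)
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' Filter markers by call rate
#'
#' Retains markers whose fraction of non-missing calls across all samples is
#' at least `min_rate`; marker order is preserved.
#'
#' @param g a `genotypes` object
#' @param min_rate minimum call rate in `[0, 1]` (default 0.99, the usual
#'   array QC threshold)
#' @return a filtered `genotypes` object
#' @export
filter_call_rate <- function(g, min_rate = 0.99) {
  stopifnot(inherits(g, "genotypes"))
  if (min_rate < 0 || min_rate > 1) stop("`min_rate` must be in [0, 1]")
  rate <- colMeans(!is.na(g$calls))
  keep <- rate >= min_rate
  if (!any(keep)) warning("no markers pass the call-rate filter")
  subset_markers(g, keep)
}

#' Restrict a genotypes object to a set of chromosomes
#'
#' @param g a `genotypes` object
#' @param chrom_set chromosome labels to retain (non-empty)
#' @return a `genotypes` object with only markers on `chrom_set`
#' @export
restrict_chromosomes <- function(g, chrom_set) {
  stopifnot(inherits(g, "genotypes"))
  chrom_set <- as.character(chrom_set)
  if (length(chrom_set) == 0) stop("`chrom_set` must be non-empty")
  known <- unique(g$map$chrom)
  unknown <- setdiff(chrom_set, known)
  if (length(unknown))
    stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "),
         "; known labels: ", paste(known, collapse = ", "))
  subset_markers(g, g$map$chrom %in% chrom_set)
}

# marker subset keeping class invariants (order already valid)
subset_markers <- function(g, keep) {
  out <- list(calls = g$calls[, keep, drop = FALSE],
              map = g$map[keep, , drop = FALSE])
  rownames(out$map) <- NULL
  class(out) <- "genotypes"
  out
}

# sample subset by ids or logical/integer index
subset_samples <- function(g, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, rownames(g$calls))
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    idx <- match(idx, rownames(g$calls))
  }
  out <- list(calls = g$calls[idx, , drop = FALSE], map = g$map)
  class(out) <- "genotypes"
  out
}

#' Combine two genotype cohorts sharing one marker map
#'
#' Samples are stacked; the maps must be identical (same markers, same order).
#'
#' @param a,b `genotypes` objects on the same map
#' @return a `genotypes` object with the union of samples
#' @export
bind_cohorts <- function(a, b) {
  stopifnot(inherits(a, "genotypes"), inherits(b, "genotypes"))
  if (!identical(a$map$marker_id, b$map$marker_id) ||
      !identical(a$map$pos_bp, b$map$pos_bp))
    stop("cohorts are not on the same marker map")
  if (length(intersect(rownames(a$calls), rownames(b$calls))))
    stop("duplicate sample ids between cohorts")
  out <- list(calls = rbind(a$calls, b$calls), map = a$map)
  class(out) <- "genotypes"
  out
}
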