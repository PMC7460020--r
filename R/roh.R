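#' Constraint set for consecutive-method ROH detection
#'
#' Defaults follow common array practice for excluding short LD-driven
#' homozygous stretches: at least 1 Mb and 150 homozygous SNPs, no
#' heterozygous and no missing call inside a run, and a maximum adjacent-SNP
#' gap of 1 Mb so marker density cannot create spurious runs.
#'
#' @param min_snps minimum number of homozygous SNPs in a run
#' @param min_length_bp minimum run length, `end_bp - start_bp`
#' @param max_gap_bp maximum bp gap between adjacent markers inside a run
#' @param max_het maximum heterozygous calls allowed inside a run
#' @param max_missing maximum missing calls allowed inside a run
#' @return a `roh_params` list
#' @export
roh_params <- function(min_snps = 150L, min_length_bp = 1e6,
                       max_gap_bp = 1e6, max_het = 0L, max_missing = 0L) {
  stopifnot(min_snps >= 0, min_length_bp >= 1, max_gap_bp >= 0,
            max_het >= 0, max_missing >= 0)
  structure(list(min_snps = as.integer(min_snps),
                 min_length_bp = as.numeric(min_length_bp),
                 max_gap_bp = as.numeric(max_gap_bp),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing)),
            class = "roh_params")
}

empty_roh <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = integer(), end_bp = integer(),
             n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity (consecutive method)
#'
#' Scans each sample's markers chromosome by chromosome in map order.  A
#' candidate run is a maximal stretch of consecutive markers containing at
#' most `max_het` heterozygous and `max_missing` missing calls, in which every
#' adjacent-marker gap is at most `max_gap_bp` (a larger gap terminates the
#' candidate).  A candidate is reported when its homozygous-SNP count reaches
#' `min_snps` and its length (`end_bp - start_bp`, positions of the first and
#' last marker in the stretch) reaches `min_length_bp`.  With the default
#' zero heterozygote/missing budgets maximal runs are unique and
#' non-overlapping; with positive budgets maximal windows are emitted
#' left-to-right and windows contained in another emitted window are dropped.
#'
#' @param g a [genotypes] object
#' @param params a [roh_params]
#' @return data.frame with columns `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps` (homozygous SNPs in the run) and `length_bp`
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotypes"), inherits(params, "roh_params"))
  if (nrow(g$calls) == 0 || ncol(g$calls) == 0) return(empty_roh())
  chrom_levels <- unique(g$map$chrom)
  chrom_idx <- split(seq_len(nrow(g$map)),
                     factor(g$map$chrom, levels = chrom_levels))
  out <- list()
  for (sid in rownames(g$calls)) {
    row <- g$calls[sid, ]
    for (cc in chrom_levels) {
      ci <- chrom_idx[[cc]]
      recs <- scan_chromosome(row[ci], g$map$pos_bp[ci], params)
      if (!is.null(recs)) {
        recs$sample_id <- sid
        recs$chrom <- cc
        out[[length(out) + 1L]] <- recs
      }
    }
  }
  if (!length(out)) return(empty_roh())
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps",
                 "length_bp")]
  res <- res[order(res$sample_id, chrom_rank(res$chrom), res$start_bp), ]
  rownames(res) <- NULL
  res
}

# one sample x one chromosome; calls/pos in map order
scan_chromosome <- function(calls, pos, params) {
  m <- length(calls)
  if (m == 0) return(NULL)
  # gap rule splits the chromosome into segments scanned independently
  breaks <- which(diff(pos) > params$max_gap_bp)
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, m)
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  hom <- !is.na(calls) & calls != 1L
  recs <- list()
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    if (params$max_het == 0L && params$max_missing == 0L) {
      # fast path: maximal clean stretches via run-length encoding
      ok <- hom[a:b]
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i <- a + starts[k] - 1L; j <- a + ends[k] - 1L
        n_hom <- j - i + 1L
        len <- pos[j] - pos[i]
        if (n_hom >= params$min_snps && len >= params$min_length_bp)
          recs[[length(recs) + 1L]] <- data.frame(
            start_bp = pos[i], end_bp = pos[j], n_snps = n_hom,
            length_bp = as.numeric(len))
      }
    } else {
      # two-pointer scan over het/missing budgets; for each right edge r the
      # smallest feasible left edge l(r) is non-decreasing, and the window
      # [l(r), r] is maximal iff r is the segment end or l(r+1) > l(r)
      idx <- a:b
      ch <- cumsum(het[idx]); cm <- cumsum(mis[idx]); co <- cumsum(hom[idx])
      n <- length(idx)
      lvec <- integer(n)
      l <- 1L
      for (r in seq_len(n)) {
        while ((ch[r] - if (l > 1L) ch[l - 1L] else 0L) > params$max_het ||
               (cm[r] - if (l > 1L) cm[l - 1L] else 0L) > params$max_missing)
          l <- l + 1L
        lvec[r] <- l
      }
      maximal <- which(c(lvec[-1] > lvec[-n], TRUE))
      if (n == 1L) maximal <- 1L
      for (r in maximal) {
        i <- idx[lvec[r]]; j <- idx[r]
        n_hom <- co[r] - if (lvec[r] > 1L) co[lvec[r] - 1L] else 0L
        len <- pos[j] - pos[i]
        if (n_hom >= params$min_snps && len >= params$min_length_bp)
          recs[[length(recs) + 1L]] <- data.frame(
            start_bp = pos[i], end_bp = pos[j], n_snps = n_hom,
            length_bp = as.numeric(len))
      }
    }
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

#' Brute-force ROH oracle
#'
#' Reference implementation for testing: enumerates every marker window per
#' sample and chromosome, keeps windows satisfying the gap and
#' heterozygote/missing budgets, discards windows contained in a larger
#' satisfying window, then applies the SNP-count and length thresholds.
#' Refuses instances larger than `max_cells` marker x sample cells.
#'
#' @inheritParams detect_roh
#' @param max_cells refuse instances with more cells than this
#' @return data.frame with the same columns and canonical order as
#'   [detect_roh]
#' @export
detect_roh_oracle <- function(g, params = roh_params(), max_cells = 1e4) {
  stopifnot(inherits(g, "genotypes"), inherits(params, "roh_params"))
  if (nrow(g$calls) * ncol(g$calls) > max_cells)
    stop("instance too large for the brute-force oracle")
  if (nrow(g$calls) == 0 || ncol(g$calls) == 0) return(empty_roh())
  chrom_levels <- unique(g$map$chrom)
  out <- list()
  for (sid in rownames(g$calls)) {
    for (cc in chrom_levels) {
      ci <- which(g$map$chrom == cc)
      calls <- g$calls[sid, ci]
      pos <- g$map$pos_bp[ci]
      m <- length(ci)
      het <- cumsum(!is.na(calls) & calls == 1L)
      mis <- cumsum(is.na(calls))
      hom <- cumsum(!is.na(calls) & calls != 1L)
      cnt <- function(cs, i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0L
      # budget+gap validity of window [i, j]
      valid <- function(i, j) {
        if (i < 1L || j > m || i > j) return(FALSE)
        if (j > i && any(diff(pos[i:j]) > params$max_gap_bp)) return(FALSE)
        cnt(het, i, j) <= params$max_het &&
          cnt(mis, i, j) <= params$max_missing
      }
      for (i in seq_len(m)) {
        for (j in i:m) {
          if (!valid(i, j)) next
          # maximal = both one-marker extensions violate a constraint
          if (valid(i - 1L, j) || valid(i, j + 1L)) next
          n_hom <- cnt(hom, i, j)
          len <- pos[j] - pos[i]
          if (n_hom >= params$min_snps && len >= params$min_length_bp)
            out[[length(out) + 1L]] <- data.frame(
              sample_id = sid, chrom = cc, start_bp = pos[i],
              end_bp = pos[j], n_snps = n_hom, length_bp = as.numeric(len),
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_roh())
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, chrom_rank(res$chrom), res$start_bp), ]
  rownames(res) <- NULL
  res
}

#' Write ROH records as TSV
#' @param rohs data.frame from [detect_roh]
#' @param path output path
#' @export
write_roh_tsv <- function(rohs, path) {
  utils::write.table(rohs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROH records as BED (0-based half-open)
#'
#' ROH coordinates are 1-based closed marker positions; BED start is
#' `start_bp - 1` and BED end is `end_bp`, so the interval covers the same
#' bases.  The name column is the sample id.
#'
#' @param rohs data.frame from [detect_roh]
#' @param path output path
#' @export
write_roh_bed <- function(rohs, path) {
  bed <- data.frame(chrom = rohs$chrom, start = rohs$start_bp - 1L,
                    end = rohs$end_bp, name = rohs$sample_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
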