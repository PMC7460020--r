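#' Length-class configuration for ROH
#'
#' Classes are half-open Mb intervals `[a, b)` partitioning `(0, Inf)`; the
#' default `[0,2) [2,4) [4,8) [8,Inf)` matches the usual short/medium/long
#' split, with an overflow class so the partition is total.
#'
#' @param breaks_mb increasing interior breakpoints in Mb (0 and Inf are
#'   added automatically)
#' @return a `length_classes` object (character labels + numeric breaks)
#' @export
length_classes <- function(breaks_mb = c(2, 4, 8)) {
  breaks_mb <- as.numeric(breaks_mb)
  if (any(diff(breaks_mb) <= 0) || any(breaks_mb <= 0))
    stop("breaks must be strictly increasing and positive")
  edges <- c(0, breaks_mb, Inf)
  labels <- sprintf("[%s-%s)", edges[-length(edges)], edges[-1])
  labels[length(labels)] <- sprintf("[%s-Inf)", edges[length(edges) - 1])
  structure(list(edges_mb = edges, labels = labels), class = "length_classes")
}

#' Assign each ROH to a length class
#' @param rohs data.frame from [detect_roh]
#' @param classes a [length_classes]
#' @return factor of class labels, one per ROH
#' @export
assign_length_class <- function(rohs, classes = length_classes()) {
  stopifnot(inherits(classes, "length_classes"))
  cut(rohs$length_bp / 1e6, breaks = classes$edges_mb,
      labels = classes$labels, right = FALSE, include.lowest = TRUE)
}

# group lookup: named vector sample_id -> group
group_of <- function(groups) {
  stats::setNames(groups$group, groups$sample_id)
}

#' Per-sample ROH summary
#'
#' Every sample in `sample_ids` appears, including those with zero ROH
#' (count 0, length statistics `NA`).
#'
#' @param rohs data.frame from [detect_roh]
#' @param samples character vector of all sample ids in the cohort
#' @param groups optional sample_id/group data.frame
#' @return data.frame: sample_id, group (if given), n_roh, total_length_bp,
#'   mean/min/max length_bp
#' @export
summarize_per_sample <- function(rohs, samples, groups = NULL) {
  sp <- split(rohs$length_bp, factor(rohs$sample_id, levels = samples))
  out <- data.frame(
    sample_id = samples,
    n_roh = vapply(sp, length, integer(1)),
    total_length_bp = vapply(sp, function(x) sum(as.numeric(x)), numeric(1)),
    mean_length_bp = vapply(sp, function(x) if (length(x)) mean(x) else NA_real_,
                            numeric(1)),
    min_length_bp = vapply(sp, function(x) if (length(x)) min(x) else NA_real_,
                           numeric(1)),
    max_length_bp = vapply(sp, function(x) if (length(x)) max(x) else NA_real_,
                           numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(groups))
    out <- cbind(out[1], group = unname(group_of(groups)[out$sample_id]),
                 out[-1])
  out
}

#' Per-group ROH descriptive statistics
#'
#' One row per group: sample count, total ROH count, min-max (mean) ROH count
#' per sample, and min-max (mean) ROH length in Mb (mean to 3 decimals in the
#' formatted columns; raw values kept alongside).
#'
#' @param rohs data.frame from [detect_roh]
#' @param groups sample_id/group data.frame covering all samples
#' @return data.frame, one row per group
#' @export
group_summary <- function(rohs, groups) {
  groups <- validate_groups(groups)
  g_of <- group_of(groups)
  per <- summarize_per_sample(rohs, groups$sample_id)
  per$group <- unname(g_of[per$sample_id])
  roh_grp <- if (nrow(rohs)) unname(g_of[rohs$sample_id]) else character()
  labs <- unique(groups$group)
  rows <- lapply(labs, function(lab) {
    cnt <- per$n_roh[per$group == lab]
    len <- rohs$length_bp[roh_grp == lab] / 1e6
    data.frame(group = lab, n_samples = sum(per$group == lab),
               n_roh = sum(cnt),
               min_n_roh = min(cnt), max_n_roh = max(cnt),
               mean_n_roh = mean(cnt),
               min_length_mb = if (length(len)) min(len) else NA_real_,
               max_length_mb = if (length(len)) max(len) else NA_real_,
               mean_length_mb = if (length(len)) round(mean(len), 3) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROH counts and percentages per length class and group
#'
#' @param rohs data.frame from [detect_roh]
#' @param groups sample_id/group data.frame
#' @param classes a [length_classes]
#' @return data.frame: group, class, n, pct (exact), pct_rounded (nearest
#'   integer, as reported in descriptive tables)
#' @export
classify_lengths <- function(rohs, groups, classes = length_classes()) {
  groups <- validate_groups(groups)
  cls <- assign_length_class(rohs, classes)
  grp <- factor(unname(group_of(groups)[rohs$sample_id]),
                levels = unique(groups$group))
  tab <- table(group = grp, class = cls)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  tot <- stats::ave(out$n, out$group, FUN = sum)
  out$pct <- ifelse(tot > 0, 100 * out$n / tot, NA_real_)
  out$pct_rounded <- ifelse(is.na(out$pct), NA_integer_,
                            as.integer(round(out$pct)))
  out
}

#' Per-chromosome ROH count and mean length
#'
#' Chromosomes with no ROH are reported with count 0 and mean `NA`.
#'
#' @param rohs data.frame from [detect_roh]
#' @param chromosomes all chromosome labels of the map (so empty ones appear)
#' @return data.frame: chrom, n_roh, mean_length_mb
#' @export
chromosome_summary <- function(rohs, chromosomes) {
  chromosomes <- as.character(chromosomes)
  sp <- split(rohs$length_bp, factor(rohs$chrom, levels = chromosomes))
  data.frame(chrom = chromosomes,
             n_roh = vapply(sp, length, integer(1)),
             mean_length_mb = vapply(sp, function(x)
               if (length(x)) mean(x) / 1e6 else NA_real_, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-marker ROH incidence by group
#'
#' For each group and marker, the fraction of the group's samples having a
#' ROH that covers the marker position (`start_bp <= pos <= end_bp`).  The
#' denominator is the full group size, including samples without any ROH.
#'
#' @param rohs data.frame from [detect_roh]
#' @param g the [genotypes] object the ROH came from (supplies the map)
#' @param groups sample_id/group data.frame
#' @return an `incidence_profile`: list with `map` (marker_id, chrom,
#'   pos_bp), `incidence` (markers x groups matrix) and `group_sizes`
#' @export
snp_incidence <- function(rohs, g, groups) {
  stopifnot(inherits(g, "genotypes"))
  groups <- validate_groups(groups, g)
  sizes <- table(groups$group)
  if (any(sizes == 0)) stop("empty group")
  map <- g$map
  labs <- unique(groups$group)
  inc <- matrix(0, nrow(map), length(labs),
                dimnames = list(map$marker_id, labs))
  pos_by_chrom <- split(seq_len(nrow(map)),
                        factor(map$chrom, levels = unique(map$chrom)))
  g_of <- group_of(groups)
  if (nrow(rohs)) {
    # per sample+chrom, merge intervals then mark covered markers once
    key <- paste(rohs$sample_id, rohs$chrom, sep = "\r")
    for (k in unique(key)) {
      rr <- rohs[key == k, , drop = FALSE]
      sid <- rr$sample_id[1]; cc <- rr$chrom[1]
      if (is.na(g_of[sid])) next
      ci <- pos_by_chrom[[cc]]
      if (is.null(ci)) next
      pos <- map$pos_bp[ci]
      merged <- merge_intervals(rr$start_bp, rr$end_bp)
      covered <- logical(length(ci))
      for (t in seq_len(nrow(merged))) {
        lo <- findInterval(merged$start[t] - 1L, pos) + 1L
        hi <- findInterval(merged$end[t], pos)
        if (hi >= lo) covered[lo:hi] <- TRUE
      }
      inc[ci[covered], g_of[sid]] <- inc[ci[covered], g_of[sid]] + 1
    }
  }
  inc <- sweep(inc, 2, as.numeric(sizes[labs]), "/")
  structure(list(map = map[, c("marker_id", "chrom", "pos_bp")],
                 incidence = inc,
                 group_sizes = stats::setNames(as.integer(sizes[labs]), labs)),
            class = "incidence_profile")
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Call ROH islands from an incidence profile
#'
#' Islands are maximal stretches of consecutive markers (per group and
#' chromosome) whose incidence is at least `threshold` (inclusive, "at least
#' 70%"); stretches with fewer than `min_snps` qualifying markers are
#' dropped.  Island start/end are the first/last qualifying marker positions
#' and island length follows the same `end - start` convention as ROH.
#'
#' @param profile an `incidence_profile` from [snp_incidence]
#' @param threshold minimum incidence, in `(0, 1]`
#' @param min_snps minimum qualifying markers per island (default 2; a
#'   single-marker island has zero length)
#' @return data.frame: group, chrom, start_bp, end_bp, length_bp, n_snps,
#'   min_incidence, mean_incidence
#' @export
find_islands <- function(profile, threshold = 0.70, min_snps = 2L) {
  stopifnot(inherits(profile, "incidence_profile"),
            threshold > 0, threshold <= 1)
  map <- profile$map
  out <- list()
  for (lab in colnames(profile$incidence)) {
    v <- profile$incidence[, lab]
    for (cc in unique(map$chrom)) {
      ci <- which(map$chrom == cc)
      ok <- v[ci] >= threshold
      r <- rle(ok)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_snps)) {
        ii <- ci[starts[k]:ends[k]]
        out[[length(out) + 1L]] <- data.frame(
          group = lab, chrom = cc,
          start_bp = map$pos_bp[ii[1]],
          end_bp = map$pos_bp[ii[length(ii)]],
          length_bp = as.numeric(map$pos_bp[ii[length(ii)]] -
                                 map$pos_bp[ii[1]]),
          n_snps = length(ii),
          min_incidence = min(v[ii]), mean_incidence = mean(v[ii]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(group = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = numeric(), n_snps = integer(),
                      min_incidence = numeric(), mean_incidence = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$group, chrom_rank(res$chrom), res$start_bp), ]
  rownames(res) <- NULL
  res
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based closed coordinates;
#' GFF3 features are filtered to `type == "gene"` when a type column exists.
#' Gene names are taken from the BED name column or from the first available
#' GFF attribute among `name_keys`.
#'
#' @param path BED or GFF3 file (format inferred from the extension)
#' @param name_keys GFF attribute keys tried, in order, for the gene name
#' @return data.frame: gene, chrom, start_bp, end_bp
#' @export
read_gene_intervals <- function(path, name_keys = c("gene", "Name", "ID")) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  nm <- NULL
  for (k in c(name_keys, "name"))
    if (k %in% names(df) && any(!is.na(df[[k]]))) { nm <- as.character(df[[k]]); break }
  if (is.null(nm)) nm <- sprintf("feature_%d", seq_len(nrow(df)))
  out <- data.frame(gene = nm, chrom = as.character(df$seqnames),
                    start_bp = df$start, end_bp = df$end,
                    stringsAsFactors = FALSE)
  out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
}

#' Annotate ROH islands with overlapping gene intervals
#'
#' A gene is reported for an island when the two 1-based closed intervals
#' share at least 1 bp on the same chromosome; genes are listed sorted by
#' start position.
#'
#' @param islands data.frame from [find_islands]
#' @param genes data.frame with columns gene, chrom, start_bp, end_bp
#' @return `islands` with added columns `n_genes` and `genes`
#'   (comma-separated names)
#' @export
annotate_islands <- function(islands, genes) {
  stopifnot(all(c("gene", "chrom", "start_bp", "end_bp") %in% names(genes)))
  islands$n_genes <- 0L
  islands$genes <- ""
  if (!nrow(islands) || !nrow(genes)) return(islands)
  if (!length(intersect(unique(islands$chrom), unique(genes$chrom)))) {
    warning("no shared chromosome labels between islands and genes")
    return(islands)
  }
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start_bp, islands$end_bp))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(isl_gr, gene_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(islands))) {
    gi <- sh[qh == i]
    gi <- gi[order(genes$start_bp[gi])]
    islands$n_genes[i] <- length(gi)
    islands$genes[i] <- paste(genes$gene[gi], collapse = ",")
  }
  islands
}

#' Write islands as TSV and BED
#' @param islands (annotated) islands data.frame
#' @param tsv_path,bed_path output paths (`NULL` to skip one)
#' @export
write_islands <- function(islands, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(islands, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(islands$chrom, islands$start_bp - 1L, islands$end_bp,
                      islands$group)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
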