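#' Excess-homozygosity inbreeding coefficient F
#'
#' Per sample, over its non-missing markers with a defined allele frequency:
#' `O_hom` is the observed homozygous count, `E_hom = sum_i (1 - 2 p_i q_i)`
#' the Hardy-Weinberg expectation at the reference frequencies, and
#' `F = (O_hom - E_hom) / (L - E_hom)`.  Monomorphic markers contribute 1 to
#' both `O` (necessarily homozygous) and `E`, so they cancel from the
#' denominator.  Negative values indicate heterozygote excess relative to the
#' reference set, as in hybrid crosses of unrelated inbred lines.
#'
#' @param g a [genotypes] object
#' @param freqs optional [allele_freqs] table; defaults to frequencies over
#'   the full cohort, which is what makes hybrid heterozygote excess visible
#' @param size_corrected if `TRUE`, use the small-sample expectation
#'   `2 p q * 2n/(2n-1)` per marker (`n` = non-missing samples at the
#'   marker), the unbiased estimator of heterozygosity from `2n` alleles;
#'   removes the `-1/(2n-1)` bias of the plug-in expectation in small
#'   cohorts
#' @return data.frame: sample_id, O_hom, E_hom, L (non-missing markers used)
#'   and F; `F` is `NA` with a warning when `L - E_hom` is 0
#' @export
excess_hom_f <- function(g, freqs = NULL, size_corrected = FALSE) {
  stopifnot(inherits(g, "genotypes"))
  if (is.null(freqs)) freqs <- allele_freqs(g)
  if (!identical(freqs$marker_id, g$map$marker_id))
    stop("frequency table is not aligned to the genotype markers")
  p <- freqs$p
  exp_hom_i <- 1 - 2 * p * (1 - p)
  if (size_corrected) {
    n <- freqs$n
    corr <- ifelse(n > 0, 2 * n / (2 * n - 1), 1)
    exp_hom_i <- 1 - 2 * p * (1 - p) * corr
  }
  usable <- !is.na(p)
  res <- lapply(rownames(g$calls), function(sid) {
    cl <- g$calls[sid, ]
    idx <- usable & !is.na(cl)
    L <- sum(idx)
    O <- sum(cl[idx] != 1L)
    E <- sum(exp_hom_i[idx])
    denom <- L - E
    f <- if (L == 0 || abs(denom) < 1e-12) NA_real_ else (O - E) / denom
    data.frame(sample_id = sid, O_hom = O, E_hom = E, L = L, F = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$F))
    warning("F undefined (L - E_hom = 0) for: ",
            paste(out$sample_id[is.na(out$F)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding from ROH (FROH)
#'
#' `FROH` is the total ROH length of a sample divided by the genome length
#' covered by markers.  The default denominator is derived from the map as
#' the sum over chromosomes of (max marker position - min marker position);
#' a fixed constant can be supplied instead to mirror a published assembly
#' span.  Per-length-class values share the total denominator, so they sum
#' exactly to the total; per-chromosome values use per-chromosome spans.
#'
#' @param rohs data.frame from [detect_roh]
#' @param g [genotypes] object supplying the map (may be `NULL` when
#'   `denominator_bp` is given and no per-chromosome output is needed)
#' @param samples sample ids to report (defaults to those in `g`); samples
#'   without ROH get 0
#' @param denominator_bp optional fixed genome length in bp
#' @param classes a [length_classes]
#' @return list: `total` (sample_id, total_length_bp, froh), `by_class`
#'   (sample x class froh matrix as data.frame), `by_chromosome` (long
#'   data.frame with per-chromosome denominators), `denominator_bp`
#' @export
f_roh <- function(rohs, g = NULL, samples = NULL, denominator_bp = NULL,
                  classes = length_classes()) {
  if (is.null(samples)) {
    if (is.null(g)) stop("supply `samples` or a genotypes object")
    samples <- sample_ids(g)
  }
  chrom_span <- NULL
  if (!is.null(g)) {
    sp <- split(g$map$pos_bp, factor(g$map$chrom, levels = unique(g$map$chrom)))
    chrom_span <- vapply(sp, function(p) as.numeric(max(p) - min(p)), numeric(1))
  }
  if (is.null(denominator_bp)) {
    if (is.null(chrom_span)) stop("supply `denominator_bp` or a genotypes object")
    denominator_bp <- sum(chrom_span)
  }
  stopifnot(denominator_bp > 0)

  fs <- factor(rohs$sample_id, levels = samples)
  total_len <- vapply(split(as.numeric(rohs$length_bp), fs), sum, numeric(1))
  total <- data.frame(sample_id = samples,
                      total_length_bp = unname(total_len),
                      froh = unname(total_len) / denominator_bp,
                      stringsAsFactors = FALSE)

  cls <- assign_length_class(rohs, classes)
  by_class <- sapply(classes$labels, function(lab) {
    len <- vapply(split(as.numeric(rohs$length_bp[cls == lab]),
                        factor(rohs$sample_id[cls == lab], levels = samples)),
                  sum, numeric(1))
    unname(len) / denominator_bp
  })
  by_class <- data.frame(sample_id = samples, by_class, check.names = FALSE,
                         stringsAsFactors = FALSE)

  by_chrom <- NULL
  if (!is.null(chrom_span)) {
    rows <- lapply(names(chrom_span), function(cc) {
      sel <- rohs$chrom == cc
      len <- vapply(split(as.numeric(rohs$length_bp[sel]),
                          factor(rohs$sample_id[sel], levels = samples)),
                    sum, numeric(1))
      data.frame(sample_id = samples, chrom = cc,
                 roh_length_bp = unname(len),
                 denominator_bp = chrom_span[[cc]],
                 froh = if (chrom_span[[cc]] > 0)
                   unname(len) / chrom_span[[cc]] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    by_chrom <- do.call(rbind, rows)
    rownames(by_chrom) <- NULL
  }
  list(total = total, by_class = by_class, by_chromosome = by_chrom,
       denominator_bp = denominator_bp)
}

#' Observed and expected homozygosity/heterozygosity per group
#'
#' Observed percentages are means over the group's samples of the per-sample
#' homozygous (heterozygous) fraction among non-missing calls; expected
#' percentages are means over markers of `1 - 2pq` (`2pq`) at the chosen
#' reference frequencies.
#'
#' @param g a [genotypes] object
#' @param groups sample_id/group data.frame
#' @param freq_scope `"group"` (expectation from within-group frequencies,
#'   the usual descriptive-table convention) or `"cohort"`
#' @return data.frame: group, obs_hom, exp_hom, obs_het, exp_het (percent)
#' @export
hom_het_summary <- function(g, groups, freq_scope = c("group", "cohort")) {
  stopifnot(inherits(g, "genotypes"))
  freq_scope <- match.arg(freq_scope)
  groups <- validate_groups(groups, g)
  cohort_freqs <- if (freq_scope == "cohort") allele_freqs(g) else NULL
  rows <- lapply(unique(groups$group), function(lab) {
    ids <- groups$sample_id[groups$group == lab]
    sub <- subset_samples(g, ids)
    obs_hom <- mean(apply(sub$calls, 1, function(cl) {
      nm <- !is.na(cl); mean(cl[nm] != 1L)
    }))
    fr <- if (freq_scope == "group") allele_freqs(sub) else cohort_freqs
    p <- fr$p[!is.na(fr$p)]
    exp_het <- mean(2 * p * (1 - p))
    data.frame(group = lab, obs_hom = 100 * obs_hom,
               exp_hom = 100 * (1 - exp_het),
               obs_het = 100 * (1 - obs_hom), exp_het = 100 * exp_het,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group regression of F on FROH
#'
#' Ordinary least squares of the excess-homozygosity coefficient on FROH,
#' reported with the coefficient of determination.  Populations whose
#' homozygosity sits mainly inside ROH show a tight linear relationship;
#' hybrid cohorts do not.
#'
#' @param f data.frame from [excess_hom_f]
#' @param froh data.frame `total` from [f_roh]
#' @param groups sample_id/group data.frame
#' @return data.frame: group, n, slope, intercept, r2 (r2 also rounded to
#'   2 dp in `r2_2dp`); slope/r2 are `NA` when FROH has zero variance
#' @export
regress_f_froh <- function(f, froh, groups) {
  groups <- validate_groups(groups)
  d <- merge(merge(f[, c("sample_id", "F")],
                   froh[, c("sample_id", "froh")], by = "sample_id"),
             groups, by = "sample_id")
  rows <- lapply(unique(groups$group), function(lab) {
    dd <- d[d$group == lab & !is.na(d$F), ]
    if (nrow(dd) < 3)
      stop("need at least 3 samples with defined F per group (", lab, ")")
    if (stats::var(dd$froh) < 1e-16)
      return(data.frame(group = lab, n = nrow(dd), slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_,
                        r2_2dp = NA_real_))
    fit <- stats::lm(F ~ froh, data = dd)
    r2 <- summary(fit)$r.squared
    data.frame(group = lab, n = nrow(dd),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = r2, r2_2dp = round(r2, 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
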