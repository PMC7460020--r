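#' Allele frequency table
#'
#' Frequency of the counted allele per marker over a stated set of samples:
#' `p = (sum of allele counts) / (2 x non-missing samples)`.  Markers with no
#' non-missing call in the subset get `p = NA`.
#'
#' @param g a [genotypes] object
#' @param samples optional sample ids to restrict to (default: all)
#' @return data.frame: marker_id, p, n (non-missing sample count)
#' @export
allele_freqs <- function(g, samples = NULL) {
  stopifnot(inherits(g, "genotypes"))
  if (!is.null(samples)) {
    if (!length(samples)) stop("`samples` must be non-empty")
    g <- subset_samples(g, samples)
  }
  n <- colSums(!is.na(g$calls))
  p <- ifelse(n > 0, colSums(g$calls, na.rm = TRUE) / (2 * n), NA_real_)
  data.frame(marker_id = g$map$marker_id, p = unname(p), n = unname(n),
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) variance components for two populations at one
# marker set; p/h/n are per-marker frequency, observed het freq, sample size
wc_components <- function(p1, h1, n1, p2, h2, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, pbar = pbar)
}

#' Pairwise FST between groups
#'
#' Weir-Cockerham (1984) estimator by default: the ratio of summed
#' among-population variance components to summed total components across
#' markers (ratio of sums, not mean of ratios).  Markers monomorphic across
#' the pooled pair, or with fewer than one genotyped sample in either group,
#' are skipped.  The Hudson estimator (mean numerator/denominator form) is
#' available for sensitivity analysis.  Raw (possibly negative) estimates are
#' kept in `fst`; `fst_truncated` floors them at 0 for summary tables.
#'
#' @param g a [genotypes] object
#' @param groups sample_id/group data.frame (every group needs >= 2 samples)
#' @param estimator `"weir-cockerham"` or `"hudson"`
#' @return data.frame: group1, group2, n_markers, fst, fst_truncated
#' @export
pairwise_fst <- function(g, groups, estimator = c("weir-cockerham", "hudson")) {
  stopifnot(inherits(g, "genotypes"))
  estimator <- match.arg(estimator)
  groups <- validate_groups(groups, g)
  labs <- unique(groups$group)
  if (any(table(groups$group) < 2)) stop("every group needs at least 2 samples")
  per_group <- lapply(labs, function(lab) {
    sub <- subset_samples(g, groups$sample_id[groups$group == lab])
    n <- colSums(!is.na(sub$calls))
    p <- ifelse(n > 0, colSums(sub$calls, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colMeans(sub$calls == 1L, na.rm = TRUE), NA_real_)
    list(p = p, h = h, n = n)
  })
  names(per_group) <- labs
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    g1 <- per_group[[pr[1]]]; g2 <- per_group[[pr[2]]]
    use <- g1$n >= 1 & g2$n >= 1
    pool <- (g1$n * g1$p + g2$n * g2$p) / (g1$n + g2$n)
    use <- use & !is.na(pool) & pool > 0 & pool < 1
    if (!any(use))
      return(data.frame(group1 = pr[1], group2 = pr[2], n_markers = 0L,
                        fst = NA_real_, fst_truncated = NA_real_))
    est <- if (estimator == "weir-cockerham") {
      wc <- wc_components(g1$p[use], g1$h[use], g1$n[use],
                          g2$p[use], g2$h[use], g2$n[use])
      sum(wc$a) / sum(wc$a + wc$b + wc$c)
    } else {
      # Hudson: num = (p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1), den = p1 q2 + p2 q1
      p1 <- g1$p[use]; p2 <- g2$p[use]
      n1 <- 2 * g1$n[use]; n2 <- 2 * g2$n[use]
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      sum(num) / sum(den)
    }
    data.frame(group1 = pr[1], group2 = pr[2], n_markers = sum(use),
               fst = est, fst_truncated = max(0, est),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal components of the genotype matrix
#'
#' Missing calls are mean-imputed per marker, markers with no data are
#' dropped, columns are centred (and optionally scaled by `sqrt(p(1-p))`),
#' and scores come from the singular value decomposition of the resulting
#' matrix.  Eigenvalues are those of the sample covariance matrix.  Signs
#' are fixed by making each component's largest-magnitude loading positive,
#' so results are deterministic.
#'
#' @param g a [genotypes] object
#' @param n_components number of components to return (truncated to the rank
#'   with a warning if too large)
#' @param scale `"none"` (plain covariance of allele counts) or `"binom"`
#'   (unit binomial variance per marker)
#' @return list: `scores` (samples x components), `eigenvalues`,
#'   `loadings` (markers x components)
#' @export
pca_genotypes <- function(g, n_components = 10, scale = c("none", "binom")) {
  stopifnot(inherits(g, "genotypes"))
  scale <- match.arg(scale)
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  keep <- !is.nan(mu)
  if (!all(keep)) {
    warning(sum(!keep), " all-missing marker(s) dropped before PCA")
    x <- x[, keep, drop = FALSE]; mu <- mu[keep]
  }
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- mu[(idx - 1) %/% nrow(x) + 1]
  x <- sweep(x, 2, mu)
  if (scale == "binom") {
    p <- mu / 2
    sd_b <- sqrt(pmax(p * (1 - p), 0))
    ok <- sd_b > 0
    x[, ok] <- sweep(x[, ok, drop = FALSE], 2, sd_b[ok], "/")
    x[, !ok] <- 0
  }
  n <- nrow(x)
  if (n < 2) {
    # a single sample carries no variance: zero scores by convention
    return(list(scores = matrix(0, n, n_components,
                                dimnames = list(rownames(g$calls),
                                                paste0("PC", seq_len(n_components)))),
                eigenvalues = rep(0, n_components),
                loadings = matrix(0, ncol(x), n_components)))
  }
  sv <- svd(x)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_components > rank) {
    warning("n_components reduced to the matrix rank (", rank, ")")
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  loadings <- sv$v[, k, drop = FALSE]
  for (j in k) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(rownames(g$calls), paste0("PC", k))
  colnames(loadings) <- paste0("PC", k)
  list(scores = scores, eigenvalues = eig[k], loadings = loadings)
}

#' Monomorphic marker counts per group
#'
#' A marker is monomorphic within a group when its within-group frequency of
#' the counted allele is 0 or 1 (computed over non-missing calls; markers
#' with no data in the group are not counted).
#'
#' @param g a [genotypes] object
#' @param groups sample_id/group data.frame
#' @param by_chromosome if `TRUE` (default), tabulate per chromosome
#' @return data.frame: group, (chrom,) n_markers, n_monomorphic
#' @export
monomorphic_counts <- function(g, groups, by_chromosome = TRUE) {
  stopifnot(inherits(g, "genotypes"))
  groups <- validate_groups(groups, g)
  rows <- lapply(unique(groups$group), function(lab) {
    fr <- allele_freqs(g, groups$sample_id[groups$group == lab])
    mono <- !is.na(fr$p) & (fr$p == 0 | fr$p == 1)
    if (by_chromosome) {
      ch <- factor(g$map$chrom, levels = unique(g$map$chrom))
      data.frame(group = lab, chrom = levels(ch),
                 n_markers = as.integer(table(ch)),
                 n_monomorphic = as.integer(tapply(mono, ch, sum)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = lab, n_markers = nrow(fr),
                 n_monomorphic = sum(mono), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
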