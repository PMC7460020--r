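#' Population specification for the genotype simulator
#'
#' @param label group label
#' @param n_samples number of diploid samples
#' @param drift_F Balding-Nichols drift parameter in `[0, 1)`; the expected
#'   FST of this population against the ancestral pool
#' @param alpha per-sample target autozygous genome fraction: a scalar, a
#'   vector of length `n_samples`, or a `function(n)` returning one
#' @param tract_mean_bp mean autozygous tract length in bp
#' @param tract_law `"exponential"` (lengths ~ Exp with the given mean) or
#'   `"constant"`
#' @return a `sim_pop` list used inside [sim_config]
#' @export
sim_pop <- function(label, n_samples, drift_F = 0, alpha = 0,
                    tract_mean_bp = 3e6,
                    tract_law = c("exponential", "constant")) {
  tract_law <- match.arg(tract_law)
  stopifnot(n_samples >= 1, drift_F >= 0, drift_F < 1, tract_mean_bp >= 1)
  structure(list(label = as.character(label), n_samples = as.integer(n_samples),
                 drift_F = drift_F, alpha = alpha,
                 tract_mean_bp = tract_mean_bp, tract_law = tract_law),
            class = "sim_pop")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome: 10 chromosomes of 20 Mb with 2,000
#' markers each (1 marker / 10 kb), dense enough that a 1 Mb / 150-SNP run of
#' homozygosity is attainable, mirroring genome-wide array densities.
#'
#' @param n_chromosomes number of autosomes
#' @param chrom_length_bp chromosome length in bp (common to all chromosomes)
#' @param n_markers_per_chrom markers per chromosome, placed uniformly at
#'   random without replacement and sorted
#' @param ancestral_freq_range range of the Uniform law for ancestral allele
#'   frequencies
#' @param pops list of [sim_pop] specifications
#' @param missing_rate independent per-call missingness probability
#' @param seed integer seed; fully determines the output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_chromosomes = 10, chrom_length_bp = 20e6,
                       n_markers_per_chrom = 2000,
                       ancestral_freq_range = c(0.05, 0.95),
                       pops = list(sim_pop("POP1", 30, alpha = 0.15)),
                       missing_rate = 0, seed = 1) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp >= n_markers_per_chrom,
            n_markers_per_chrom >= 1,
            length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!length(pops) || !all(vapply(pops, inherits, logical(1), "sim_pop")))
    stop("`pops` must be a non-empty list of sim_pop()")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_markers_per_chrom = as.integer(n_markers_per_chrom),
                 ancestral_freq_range = ancestral_freq_range,
                 pops = pops, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# uniform marker placement per chromosome, sorted
sim_map <- function(cfg) {
  per <- lapply(seq_len(cfg$n_chromosomes), function(cc) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_markers_per_chrom))
    data.frame(marker_id = sprintf("snp_%02d_%06d", cc,
                                   seq_len(cfg$n_markers_per_chrom)),
               chrom = as.character(cc), pos_bp = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per)
}

sim_ancestral <- function(cfg, m) {
  stats::runif(m, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
}

# Balding-Nichols population frequencies around ancestral p
bn_freqs <- function(p, drift_F) {
  if (drift_F <= 0) return(p)
  k <- (1 - drift_F) / drift_F
  stats::rbeta(length(p), p * k, (1 - p) * k)
}

resolve_alpha <- function(alpha, n) {
  a <- if (is.function(alpha)) alpha(n)
       else if (length(alpha) == 1) rep(alpha, n)
       else alpha
  if (length(a) != n) stop("alpha must resolve to length n_samples")
  if (any(a < 0 | a >= 1)) stop("alpha values must lie in [0, 1)")
  a
}

# place non-overlapping autozygous tracts until target_bp is covered;
# the last tract is truncated so the realized fraction hits the target
place_tracts <- function(target_bp, chrom_labels, chrom_len, rlen,
                         max_retries = 1000L) {
  out <- list()
  placed <- lapply(chrom_labels, function(x) NULL)   # per-chrom intervals
  names(placed) <- chrom_labels
  remaining <- target_bp
  retries <- 0L
  while (remaining >= 1) {
    # a tract cannot exceed one chromosome; the final tract is truncated so
    # the realized autozygous fraction equals the target
    len <- min(max(1, round(rlen())), remaining, chrom_len)
    ok <- FALSE
    while (!ok) {
      cc <- sample(chrom_labels, 1)
      start <- sample.int(chrom_len - len + 1L, 1)
      end <- start + len - 1L
      iv <- placed[[cc]]
      clash <- !is.null(iv) && any(start <= iv[, 2] & end >= iv[, 1])
      if (!clash) {
        placed[[cc]] <- rbind(iv, c(start, end))
        out[[length(out) + 1L]] <- data.frame(chrom = cc, start_bp = start,
                                              end_bp = end, length_bp = len,
                                              stringsAsFactors = FALSE)
        remaining <- remaining - len
        ok <- TRUE
      } else retries <- retries + 1L
      if (retries > max_retries)
        stop("could not place autozygous tracts: target fraction too large")
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# genotype vector for one sample: HWE draws outside tracts, doubled single
# allele draws inside (strict IBD)
sample_genotypes <- function(p_pop, map, tracts) {
  g <- stats::rbinom(length(p_pop), 2L, p_pop)
  if (nrow(tracts)) {
    for (t in seq_len(nrow(tracts))) {
      idx <- which(map$chrom == tracts$chrom[t] &
                   map$pos_bp >= tracts$start_bp[t] &
                   map$pos_bp <= tracts$end_bp[t])
      if (length(idx))
        g[idx] <- 2L * stats::rbinom(length(idx), 1L, p_pop[idx])
    }
  }
  g
}

#' Simulate a multi-population SNP cohort with known autozygosity
#'
#' Marker positions are placed uniformly per chromosome; each population's
#' allele frequencies drift from a shared ancestral pool under the
#' Balding-Nichols model, so `drift_F` is the expected FST against the pool.
#' Per sample, non-overlapping autozygous tracts are placed until the target
#' genome fraction `alpha` is covered (the last tract is truncated), genotypes
#' inside tracts are homozygous for a single drawn allele, genotypes outside
#' follow Hardy-Weinberg proportions, and missing calls are sprinkled
#' independently.
#'
#' @param cfg a [sim_config]
#' @return list with elements `genotypes` ([genotypes]), `groups`
#'   (sample_id/group data.frame) and `truth` (list: `tracts` per-sample
#'   tract table, `alpha` per-sample target and realized autozygous fraction,
#'   `pop_freqs` markers x populations frequency matrix)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  m <- nrow(map)
  anc <- sim_ancestral(cfg, m)
  simulate_cohort_on(cfg, map, anc)
}

# core shared with simulate_study_cohort (map/ancestral supplied, RNG hot)
simulate_cohort_on <- function(cfg, map, anc) {
  m <- nrow(map)
  chrom_labels <- unique(map$chrom)
  genome_bp <- as.numeric(cfg$n_chromosomes) * cfg$chrom_length_bp
  pop_freqs <- matrix(NA_real_, m, length(cfg$pops),
                      dimnames = list(map$marker_id,
                                      vapply(cfg$pops, `[[`, "", "label")))
  calls <- NULL
  groups <- tracts_all <- alpha_all <- list()
  for (k in seq_along(cfg$pops)) {
    pop <- cfg$pops[[k]]
    p_pop <- bn_freqs(anc, pop$drift_F)
    pop_freqs[, k] <- p_pop
    alphas <- resolve_alpha(pop$alpha, pop$n_samples)
    rlen <- switch(pop$tract_law,
                   exponential = function() stats::rexp(1, 1 / pop$tract_mean_bp),
                   constant = function() pop$tract_mean_bp)
    ids <- sprintf("%s_%03d", pop$label, seq_len(pop$n_samples))
    gm <- matrix(NA_integer_, pop$n_samples, m, dimnames = list(ids, NULL))
    for (i in seq_len(pop$n_samples)) {
      tr <- place_tracts(round(alphas[i] * genome_bp), chrom_labels,
                         cfg$chrom_length_bp, rlen)
      gm[i, ] <- sample_genotypes(p_pop, map, tr)
      if (nrow(tr)) {
        tr$sample_id <- ids[i]
        tracts_all[[length(tracts_all) + 1L]] <- tr
      }
      alpha_all[[length(alpha_all) + 1L]] <-
        data.frame(sample_id = ids[i], group = pop$label,
                   target_alpha = alphas[i],
                   realized_alpha = sum(tr$length_bp) / genome_bp,
                   stringsAsFactors = FALSE)
    }
    calls <- rbind(calls, gm)
    groups[[k]] <- data.frame(sample_id = ids, group = pop$label,
                              stringsAsFactors = FALSE)
  }
  if (cfg$missing_rate > 0) {
    drop <- which(stats::runif(length(calls)) < cfg$missing_rate)
    calls[drop] <- NA_integer_
  }
  tracts <- if (length(tracts_all)) do.call(rbind, tracts_all) else
    data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
               length_bp = integer(), sample_id = character())
  rownames(tracts) <- NULL
  list(genotypes = genotypes(calls, map),
       groups = do.call(rbind, groups),
       truth = list(tracts = tracts[, c("sample_id", "chrom", "start_bp",
                                        "end_bp", "length_bp")],
                    alpha = do.call(rbind, alpha_all),
                    pop_freqs = pop_freqs))
}

#' Simulate a four-way hybrid-cross cohort
#'
#' Four inbred lines drift independently from the ancestral pool with a high
#' drift parameter (`line_inbreeding`), so their frequencies are near
#' fixation.  Each offspring receives one gamete from an (A x B) parent and
#' one from a (C x D) parent; each gamete is a one-generation recombinant
#' mosaic of the two line haplotypes, with crossovers following a Poisson
#' process along bp.  Because the two gametes come from unrelated line pairs,
#' observed heterozygosity exceeds the Hardy-Weinberg expectation at pooled
#' frequencies, i.e. the cohort shows a negative excess-homozygosity F.
#'
#' @param cfg a [sim_config]; the first `pops` entry supplies the offspring
#'   group label and sample count
#' @param n_lines number of parental lines (only 4, the classic commercial
#'   cross, is supported)
#' @param line_inbreeding drift parameter of each parental line in `(0, 1)`;
#'   values near 1 give near-fixed lines
#' @param recomb_rate_per_bp expected crossovers per bp per gamete
#'   (default 1e-8, i.e. ~1 cM/Mb)
#' @param shared_selection_frac fraction of the genome placed in regions
#'   where all four lines are fixed for the same allele, emulating common
#'   directional selection of the parental lines; these are the only regions
#'   where hybrid offspring carry ROH
#' @param shared_tract_mean_bp mean length (Exp law) of those shared regions
#' @return list with `genotypes`, `groups` and `truth` (list with
#'   `line_freqs`, a markers x 4 frequency matrix, and `shared_tracts`)
#' @export
simulate_hybrid_cross <- function(cfg, n_lines = 4, line_inbreeding = 0.45,
                                  recomb_rate_per_bp = 1e-8,
                                  shared_selection_frac = 0.13,
                                  shared_tract_mean_bp = 2e6) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_lines != 4) stop("only the four-way cross (A x B) x (C x D) is supported")
  stopifnot(line_inbreeding > 0, line_inbreeding < 1,
            shared_selection_frac >= 0, shared_selection_frac < 1)
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  anc <- sim_ancestral(cfg, nrow(map))
  simulate_hybrid_on(cfg, map, anc, line_inbreeding, recomb_rate_per_bp,
                     shared_selection_frac, shared_tract_mean_bp)
}

simulate_hybrid_on <- function(cfg, map, anc, line_inbreeding,
                               recomb_rate_per_bp,
                               shared_selection_frac = 0.13,
                               shared_tract_mean_bp = 2e6) {
  pop <- cfg$pops[[1]]
  m <- nrow(map)
  line_freqs <- vapply(1:4, function(i) bn_freqs(anc, line_inbreeding),
                       numeric(m))
  colnames(line_freqs) <- c("A", "B", "C", "D")
  chrom_labels <- unique(map$chrom)
  genome_bp <- as.numeric(cfg$n_chromosomes) * cfg$chrom_length_bp
  shared <- data.frame(chrom = character(), start_bp = integer(),
                       end_bp = integer(), length_bp = integer())
  if (shared_selection_frac > 0) {
    shared <- place_tracts(round(shared_selection_frac * genome_bp),
                           chrom_labels, cfg$chrom_length_bp,
                           function() stats::rexp(1, 1 / shared_tract_mean_bp))
    for (t in seq_len(nrow(shared))) {
      idx <- which(map$chrom == shared$chrom[t] &
                   map$pos_bp >= shared$start_bp[t] &
                   map$pos_bp <= shared$end_bp[t])
      if (length(idx))
        line_freqs[idx, ] <- stats::rbinom(length(idx), 1L, anc[idx])
    }
  }
  chrom_idx <- split(seq_len(m), factor(map$chrom, levels = unique(map$chrom)))

  gamete <- function(fa, fb) {
    out <- integer(m)
    for (ci in chrom_idx) {
      pos <- map$pos_bp[ci]
      hapA <- stats::rbinom(length(ci), 1L, fa[ci])
      hapB <- stats::rbinom(length(ci), 1L, fb[ci])
      nx <- stats::rpois(1, recomb_rate_per_bp * cfg$chrom_length_bp)
      xpos <- sort(stats::runif(nx, 1, cfg$chrom_length_bp))
      phase <- (findInterval(pos, xpos) + stats::rbinom(1, 1L, 0.5)) %% 2L
      out[ci] <- ifelse(phase == 0L, hapA, hapB)
    }
    out
  }

  ids <- sprintf("%s_%03d", pop$label, seq_len(pop$n_samples))
  calls <- matrix(NA_integer_, pop$n_samples, m, dimnames = list(ids, NULL))
  for (i in seq_len(pop$n_samples)) {
    calls[i, ] <- gamete(line_freqs[, "A"], line_freqs[, "B"]) +
                  gamete(line_freqs[, "C"], line_freqs[, "D"])
  }
  if (cfg$missing_rate > 0) {
    drop <- which(stats::runif(length(calls)) < cfg$missing_rate)
    calls[drop] <- NA_integer_
  }
  list(genotypes = genotypes(calls, map),
       groups = data.frame(sample_id = ids, group = pop$label,
                           stringsAsFactors = FALSE),
       truth = list(line_freqs = line_freqs, shared_tracts = shared))
}

#' Simulate a three-group cohort emulating a hybrid vs. autochthonous study
#'
#' One shared marker map and ancestral frequency pool; a commercial-type
#' hybrid group produced by a four-way cross of inbred lines, and two
#' autochthonous groups drifted from the same pool with per-sample autozygous
#' tracts whose target fractions are drawn from Beta laws spanning the low to
#' high autozygosity range seen in unmanaged populations.
#'
#' @param seed integer seed
#' @param n_hyb,n_mex1,n_mex2 group sizes (defaults 38/19/11)
#' @param drift_mex Balding-Nichols drift of each autochthonous group
#' @param line_inbreeding drift of the four hybrid parental lines; the
#'   default, together with `shared_selection_frac`, puts hybrid-vs-
#'   autochthonous differentiation and the hybrid heterozygote excess in the
#'   range typical of commercial-versus-local-population comparisons
#' @param tract_mean_bp mean autozygous tract length of the autochthonous
#'   groups
#' @param shared_selection_frac,shared_tract_mean_bp co-selected fixed
#'   regions of the hybrid parental lines (see [simulate_hybrid_cross])
#' @param missing_rate per-call missingness
#' @param n_chromosomes,chrom_length_bp,n_markers_per_chrom genome layout;
#'   the default density (1 marker / 3.3 kb) is array-like, so runs of
#'   1-2 Mb clear the 150-SNP rule and short runs dominate the length
#'   distribution as they do on dense arrays
#' @return list with `genotypes`, `groups`, `truth` (as in [simulate_cohort];
#'   hybrid line frequencies under `truth$line_freqs`)
#' @export
simulate_study_cohort <- function(seed, n_hyb = 38, n_mex1 = 19, n_mex2 = 11,
                                  drift_mex = 0.09, line_inbreeding = 0.45,
                                  tract_mean_bp = 1.3e6,
                                  shared_selection_frac = 0.13,
                                  shared_tract_mean_bp = 1.2e6,
                                  missing_rate = 0.002,
                                  n_chromosomes = 10, chrom_length_bp = 20e6,
                                  n_markers_per_chrom = 6000) {
  # alpha laws: clamp Beta draws to the plausible autozygosity band
  alpha_law <- function(s1, s2, lo = 0.003, hi = 0.38) {
    function(n) pmin(pmax(stats::rbeta(n, s1, s2), lo), hi)
  }
  cfg_mex <- sim_config(
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    n_markers_per_chrom = n_markers_per_chrom,
    pops = list(sim_pop("MEX_cl_1", n_mex1, drift_F = drift_mex,
                        alpha = alpha_law(1.2, 6.3),
                        tract_mean_bp = tract_mean_bp),
                sim_pop("MEX_cl_2", n_mex2, drift_F = drift_mex,
                        alpha = alpha_law(1.1, 15.0),
                        tract_mean_bp = tract_mean_bp)),
    missing_rate = missing_rate, seed = seed)
  cfg_hyb <- sim_config(
    n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
    n_markers_per_chrom = n_markers_per_chrom,
    pops = list(sim_pop("HYB", n_hyb)),
    missing_rate = missing_rate, seed = seed)

  set.seed(seed)
  map <- sim_map(cfg_mex)
  anc <- sim_ancestral(cfg_mex, nrow(map))
  hyb <- simulate_hybrid_on(cfg_hyb, map, anc, line_inbreeding, 1e-8,
                            shared_selection_frac, shared_tract_mean_bp)
  mex <- simulate_cohort_on(cfg_mex, map, anc)
  list(genotypes = bind_cohorts(hyb$genotypes, mex$genotypes),
       groups = rbind(hyb$groups, mex$groups),
       truth = c(mex$truth, hyb$truth[c("line_freqs", "shared_tracts")]))
}
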