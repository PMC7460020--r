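test_that("allele frequencies match a brute-force tally", {
  g <- mk_geno(rbind(c(0L, 2L), c(1L, 2L), c(2L, 2L)))
  fr <- allele_freqs(g)
  expect_equal(fr$p, c(0.5, 1))      # {0,1,2} -> 3/6; monomorphic -> 1
  set.seed(15)
  g <- rand_instance(12, 100, het_rate = 0.3, miss_rate = 0.1)
  fr <- allele_freqs(g, sample_ids(g)[1:7])
  for (j in sample(100, 20)) {
    cl <- g$calls[1:7, j]
    nm <- sum(!is.na(cl))
    expect_equal(fr$p[j], if (nm) sum(cl, na.rm = TRUE) / (2 * nm) else NA_real_)
    expect_equal(fr$n[j], nm)
  }
  # all-missing marker -> NA
  calls <- matrix(c(NA, NA, 0L, 1L), 2, 2)
  fr2 <- allele_freqs(mk_geno(calls))
  expect_true(is.na(fr2$p[1]))
})

test_that("FST is ~0 for identical groups and 1 for fixed alternates", {
  set.seed(16)
  calls <- matrix(sample(0:2, 25 * 5000, TRUE,
                         prob = c(0.25, 0.5, 0.25)), 25)
  both <- rbind(calls, calls)
  rownames(both) <- sprintf("s%02d", 1:50)
  g <- mk_geno(both, pos = 100L * seq_len(5000))
  groups <- data.frame(sample_id = rownames(both),
                       group = rep(c("A", "B"), each = 25))
  fst <- pairwise_fst(g, groups)
  expect_lte(fst$fst_truncated, 0.001)
  expect_lte(fst$fst, 0.05)
  # alternate fixation
  calls2 <- rbind(matrix(2L, 5, 100), matrix(0L, 5, 100))
  rownames(calls2) <- sprintf("t%02d", 1:10)
  g2 <- mk_geno(calls2, pos = 1000L * 1:100)
  groups2 <- data.frame(sample_id = rownames(calls2),
                        group = rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(g2, groups2)$fst, 1)
  expect_error(pairwise_fst(g2, data.frame(sample_id = rownames(calls2),
                                           group = c("A", rep("B", 9)))),
               "at least 2 samples")
})

test_that("FST is invariant to allele relabeling and marker order", {
  set.seed(18)
  cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 1000,
                    pops = list(sim_pop("P1", 12, drift_F = 0.1),
                                sim_pop("P2", 12, drift_F = 0.1)),
                    missing_rate = 0.01, seed = 18)
  sim <- simulate_cohort(cfg)
  base <- pairwise_fst(sim$genotypes, sim$groups)$fst
  # swap allele labels at a random half of the markers
  flip <- sample(c(TRUE, FALSE), ncol(sim$genotypes$calls), TRUE)
  calls <- sim$genotypes$calls
  calls[, flip] <- 2L - calls[, flip]
  gs <- genotypes(calls, sim$genotypes$map)
  expect_equal(pairwise_fst(gs, sim$groups)$fst, base, tolerance = 1e-12)
  # feed markers in scrambled order (constructor restores map order)
  perm <- sample(ncol(calls))
  gp <- genotypes(sim$genotypes$calls[, perm], sim$genotypes$map[perm, ])
  expect_equal(pairwise_fst(gp, sim$groups)$fst, base, tolerance = 1e-12)
})

test_that("Weir-Cockerham and Hudson agree on balanced simulated data", {
  cfg <- sim_config(n_chromosomes = 5, n_markers_per_chrom = 2000,
                    pops = list(sim_pop("P1", 25, drift_F = 0.1),
                                sim_pop("P2", 25, drift_F = 0.1)), seed = 23)
  sim <- simulate_cohort(cfg)
  wc <- pairwise_fst(sim$genotypes, sim$groups)$fst
  hud <- pairwise_fst(sim$genotypes, sim$groups, estimator = "hudson")$fst
  expect_lt(abs(wc - hud), 0.01)
})

test_that("FST estimates rank simulated drift levels correctly", {
  drifts <- c(0.02, 0.05, 0.1, 0.2)
  for (seed in 1:5) {
    est <- vapply(drifts, function(d) {
      cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 1500,
                        chrom_length_bp = 15e6,
                        pops = list(sim_pop("P1", 20, drift_F = d),
                                    sim_pop("P2", 20, drift_F = d)),
                        seed = seed * 100 + round(1000 * d))
      sim <- simulate_cohort(cfg)
      pairwise_fst(sim$genotypes, sim$groups)$fst
    }, numeric(1))
    expect_equal(order(est), 1:4)
  }
})

test_that("PCA separates duplicated-row clusters and matches a dense eigen oracle", {
  set.seed(25)
  proto <- rbind(sample(0:2, 400, TRUE), sample(0:2, 400, TRUE))
  calls <- proto[rep(1:2, each = 6), ] # two clusters of identical samples
  calls <- calls + 0L
  rownames(calls) <- sprintf("s%02d", 1:12)
  g <- mk_geno(calls, pos = 500L * 1:400)
  pca <- pca_genotypes(g, n_components = 2)
  pc1 <- pca$scores[, 1]
  expect_true(all(pc1[1:6] * pc1[7:12] < 0))        # perfect split
  expect_equal(stats::sd(pc1[1:6]), 0, tolerance = 1e-9)
  # eigenvalue oracle on a noisy matrix with missing values
  gm <- rand_instance(15, 120, het_rate = 0.3, miss_rate = 0.05)
  res <- pca_genotypes(gm, n_components = 5)
  x <- gm$calls; storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, ev[1:5], tolerance = 1e-8)
  expect_true(all(abs(colMeans(res$scores)) < 1e-8))
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # marker permutation leaves scores unchanged (sign fixed deterministically)
  perm <- sample(ncol(gm$calls))
  gp <- genotypes(gm$calls[, perm], gm$map[perm, ])
  res2 <- pca_genotypes(gp, n_components = 5)
  expect_equal(abs(res2$scores), abs(res$scores), tolerance = 1e-6)
  # single sample: zero scores
  g1 <- subset_one <- mk_geno(matrix(c(0L, 1L, 2L), 1))
  p1 <- pca_genotypes(g1, n_components = 2)
  expect_true(all(p1$scores == 0))
})

test_that("monomorphic counts match a brute-force recount", {
  g <- mk_geno(rbind(rep(2L, 6), rep(2L, 6)))    # clones: all monomorphic
  groups <- data.frame(sample_id = sample_ids(g), group = "G")
  out <- monomorphic_counts(g, groups, by_chromosome = FALSE)
  expect_equal(out$n_monomorphic, 6L)
  # one heterozygote breaks monomorphism
  g2 <- mk_geno(rbind(c(2L, 2L), c(2L, 1L)))
  out2 <- monomorphic_counts(g2, data.frame(sample_id = sample_ids(g2),
                                            group = "G"),
                             by_chromosome = FALSE)
  expect_equal(out2$n_monomorphic, 1L)
  set.seed(29)
  g3 <- rand_instance(10, 200, het_rate = 0.1, miss_rate = 0.1)
  groups3 <- data.frame(sample_id = sample_ids(g3),
                        group = rep(c("A", "B"), each = 5))
  out3 <- monomorphic_counts(g3, groups3)
  for (lab in c("A", "B")) {
    ids <- groups3$sample_id[groups3$group == lab]
    for (cc in unique(g3$map$chrom)) {
      jj <- which(g3$map$chrom == cc)
      brute <- sum(vapply(jj, function(j) {
        cl <- g3$calls[ids, j]; cl <- cl[!is.na(cl)]
        length(cl) > 0 && (all(cl == 0L) || all(cl == 2L))
      }, logical(1)))
      expect_equal(out3$n_monomorphic[out3$group == lab & out3$chrom == cc],
                   brute)
    }
  }
})
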