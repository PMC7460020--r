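fake_roh <- function(sample_id, chrom, start, end) {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start_bp = as.integer(start), end_bp = as.integer(end),
             n_snps = 150L, length_bp = as.numeric(end - start),
             stringsAsFactors = FALSE)
}

rand_roh_set <- function(n, samples, chroms = c("1", "2", "3")) {
  start <- sample.int(5e7, n)
  len <- sample(1e6:8e6, n, replace = TRUE)
  fake_roh(sample(samples, n, TRUE), sample(chroms, n, TRUE),
           start, start + len)
}

test_that("per-sample summary handles zero-ROH samples and unit conversion", {
  rohs <- fake_roh("s1", "1", 1000, 1718000)   # one 1,717,000 bp run
  out <- summarize_per_sample(rohs, c("s1", "s2"))
  expect_equal(out$n_roh, c(1L, 0L))
  expect_equal(out$mean_length_bp[1] / 1e6, 1.717)
  expect_true(is.na(out$mean_length_bp[2]))
  expect_equal(out$total_length_bp[2], 0)
})

test_that("group aggregation matches an independent recomputation", {
  set.seed(5)
  samples <- sprintf("s%02d", 1:12)
  groups <- data.frame(sample_id = samples,
                       group = rep(c("A", "B"), each = 6))
  rohs <- rand_roh_set(200, samples)
  gs <- group_summary(rohs, groups)
  for (lab in c("A", "B")) {
    ids <- groups$sample_id[groups$group == lab]
    lens <- rohs$length_bp[rohs$sample_id %in% ids] / 1e6
    cnts <- vapply(ids, function(s) sum(rohs$sample_id == s), integer(1))
    row <- gs[gs$group == lab, ]
    expect_equal(row$n_roh, sum(cnts))
    expect_equal(row$mean_n_roh, mean(cnts))
    expect_equal(row$mean_length_mb, round(mean(lens), 3))
    expect_equal(row$min_length_mb, min(lens))
    expect_equal(row$max_length_mb, max(lens))
  }
})

test_that("length classes are half-open and percentages add to ~100", {
  groups <- data.frame(sample_id = "s1", group = "G")
  # exactly 2 Mb belongs to [2,4)
  rohs <- fake_roh("s1", "1", c(0, 0, 0), c(2e6, 1e6, 9e6))
  out <- classify_lengths(rohs, groups)
  expect_equal(out$n[out$class == "[2-4)"], 1L)
  expect_equal(out$n[out$class == "[0-2)"], 1L)
  expect_equal(out$n[out$class == "[8-Inf)"], 1L)
  set.seed(6)
  samples <- sprintf("s%02d", 1:8)
  groups <- data.frame(sample_id = samples,
                       group = rep(c("A", "B"), each = 4))
  rohs <- rand_roh_set(300, samples)
  out <- classify_lengths(rohs, groups)
  cls <- length_classes()
  for (lab in c("A", "B")) {
    ids <- samples[groups$group == lab]
    lens <- rohs$length_bp[rohs$sample_id %in% ids] / 1e6
    brute <- table(cut(lens, cls$edges_mb, labels = cls$labels, right = FALSE))
    expect_equal(out$n[out$group == lab], as.integer(brute))
    expect_equal(sum(out$n[out$group == lab]), length(lens))
    expect_lte(abs(sum(out$pct_rounded[out$group == lab]) - 100), 1)
  }
})

test_that("chromosome summary reports empty chromosomes with count zero", {
  rohs <- fake_roh(c("s1", "s1"), c("1", "1"), c(0, 5e6), c(2e6, 8e6))
  out <- chromosome_summary(rohs, c("1", "2", "18"))
  expect_equal(out$n_roh, c(2L, 0L, 0L))
  expect_equal(out$mean_length_mb[1], 2.5)
  expect_true(all(is.na(out$mean_length_mb[2:3])))
})

test_that("incidence equals a per-marker brute-force membership count", {
  set.seed(9)
  g <- rand_instance(10, 200, n_chrom = 2, het_rate = 0.3, miss_rate = 0)
  groups <- data.frame(sample_id = sample_ids(g),
                       group = rep(c("A", "B"), each = 5))
  p <- roh_params(min_snps = 5, min_length_bp = 3e4, max_gap_bp = 5e4)
  rohs <- detect_roh(g, p)
  prof <- snp_incidence(rohs, g, groups)
  for (j in sample(nrow(g$map), 40)) {
    cc <- g$map$chrom[j]; pp <- g$map$pos_bp[j]
    for (lab in c("A", "B")) {
      ids <- groups$sample_id[groups$group == lab]
      covered <- vapply(ids, function(s)
        any(rohs$sample_id == s & rohs$chrom == cc &
            rohs$start_bp <= pp & rohs$end_bp >= pp), logical(1))
      expect_equal(prof$incidence[j, lab], mean(covered))
    }
  }
  # single-sample groups have a {0,1}-valued profile
  solo <- data.frame(sample_id = sample_ids(g)[1], group = "solo")
  ps <- snp_incidence(rohs[rohs$sample_id == solo$sample_id, ], g, solo)
  expect_true(all(ps$incidence %in% c(0, 1)))
})

test_that("islands are maximal runs of markers at or above the threshold", {
  pos <- 1000L * 1:12
  g <- mk_geno(matrix(0L, 10, 12), pos = pos)
  groups <- data.frame(sample_id = sample_ids(g), group = "G")
  inc <- c(0.5, 0.7, 0.8, 0.9, 0.6, 0.95, 1, 0.69, 0.7, 0.7, 0.7, 0.5)
  prof <- structure(list(map = g$map[, c("marker_id", "chrom", "pos_bp")],
                         incidence = matrix(inc, ncol = 1,
                                            dimnames = list(g$map$marker_id, "G")),
                         group_sizes = c(G = 10L)),
                    class = "incidence_profile")
  isl <- find_islands(prof, threshold = 0.70)
  # two plateaus separated by sub-threshold markers; 0.70 itself qualifies
  expect_equal(nrow(isl), 3L)
  expect_equal(isl$start_bp, c(2000L, 6000L, 9000L))
  expect_equal(isl$end_bp, c(4000L, 7000L, 11000L))
  expect_equal(isl$length_bp, isl$end_bp - isl$start_bp)
  expect_true(all(isl$min_incidence >= 0.70))
  # flanking markers are below threshold
  for (i in seq_len(nrow(isl))) {
    w <- which(pos >= isl$start_bp[i] & pos <= isl$end_bp[i])
    if (min(w) > 1) expect_lt(inc[min(w) - 1], 0.70)
    if (max(w) < 12) expect_lt(inc[max(w) + 1], 0.70)
  }
  # all markers below threshold: no islands
  prof$incidence[] <- 0.69
  expect_equal(nrow(find_islands(prof, 0.70)), 0L)
})

test_that("a fraction of 7 in 10 samples meets the 70% threshold", {
  set.seed(14)
  g <- mk_geno(matrix(1L, 10, 60), pos = 1000L * 1:60)
  groups <- data.frame(sample_id = sample_ids(g), group = "G")
  rohs <- do.call(rbind, lapply(sample_ids(g)[1:7], function(s)
    fake_roh(s, "1", 5000, 50000)))
  prof <- snp_incidence(rohs, g, groups)
  inside <- g$map$pos_bp >= 5000 & g$map$pos_bp <= 50000
  expect_true(all(prof$incidence[inside, "G"] == 0.7))
  expect_true(all(prof$incidence[!inside, "G"] == 0))
  expect_gt(nrow(find_islands(prof, 0.70)), 0)
})

test_that("island-gene overlap matches a quadratic all-pairs oracle", {
  # 1 bp of shared closed-interval span is enough; touching ends are not
  isl <- data.frame(group = "G", chrom = "1", start_bp = 150L, end_bp = 400L,
                    length_bp = 250, n_snps = 5L, min_incidence = 0.8,
                    mean_incidence = 0.9)
  genes <- data.frame(gene = c("in1", "out1"), chrom = "1",
                      start_bp = c(100L, 100L), end_bp = c(200L, 149L))
  ann <- annotate_islands(isl, genes)
  expect_equal(ann$genes, "in1")
  set.seed(33)
  n <- 40
  isl <- data.frame(group = "G", chrom = sample(c("1", "2"), n, TRUE),
                    start_bp = sample.int(1e5, n), n_snps = 3L,
                    min_incidence = 0.8, mean_incidence = 0.9)
  isl$end_bp <- isl$start_bp + sample.int(2e4, n)
  isl$length_bp <- isl$end_bp - isl$start_bp
  genes <- data.frame(gene = sprintf("g%03d", 1:60),
                      chrom = sample(c("1", "2"), 60, TRUE),
                      start_bp = sample.int(1e5, 60))
  genes$end_bp <- genes$start_bp + sample.int(2e4, 60)
  ann <- annotate_islands(isl, genes)
  for (i in seq_len(n)) {
    hit <- genes$chrom == isl$chrom[i] &
      genes$start_bp <= isl$end_bp[i] & genes$end_bp >= isl$start_bp[i]
    expected <- genes$gene[hit][order(genes$start_bp[hit])]
    expect_equal(ann$genes[i], paste(expected, collapse = ","))
    expect_equal(ann$n_genes[i], sum(hit))
  }
  # disjoint chromosome labels warn and annotate nothing
  g2 <- transform(genes, chrom = "99")
  expect_warning(a2 <- annotate_islands(isl, g2), "no shared chromosome")
  expect_true(all(a2$n_genes == 0))
})

test_that("gene intervals load from BED (shifted) and GFF3", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tGENE1", bed)
  gi <- read_gene_intervals(bed)
  expect_equal(gi$start_bp, 100L)   # 0-based BED start -> 1-based
  expect_equal(gi$end_bp, 200L)
  expect_equal(gi$gene, "GENE1")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t500\t900\t.\t+\t.\tID=g1;Name=GENE2",
               "1\tsrc\texon\t500\t600\t.\t+\t.\tID=e1"), gff)
  gi2 <- read_gene_intervals(gff)
  expect_equal(nrow(gi2), 1L)
  expect_equal(gi2$gene, "GENE2")
  expect_equal(gi2$start_bp, 500L)
})
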