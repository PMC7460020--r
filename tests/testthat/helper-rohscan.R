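# small in-code fixture builders shared across the suite

mk_map <- function(pos, chrom = "1", ids = NULL) {
  if (!length(pos))
    return(data.frame(marker_id = character(), chrom = character(),
                      pos_bp = integer(), stringsAsFactors = FALSE))
  data.frame(marker_id = if (is.null(ids)) sprintf("m_%s_%04d", chrom,
                                                   seq_along(pos)) else ids,
             chrom = chrom, pos_bp = pos, stringsAsFactors = FALSE)
}

# one-chromosome genotypes from a calls matrix (samples x markers)
mk_geno <- function(calls, pos = NULL, chrom = "1") {
  calls <- rbind(calls)
  if (is.null(pos)) pos <- 10000L * seq_len(ncol(calls))
  genotypes(calls, mk_map(pos, chrom))
}

# multi-chromosome random instance for detector/oracle comparisons
rand_instance <- function(n_samples = 5, m = 120, n_chrom = 2,
                          het_rate = 0.2, miss_rate = 0.05,
                          max_step = 40000L) {
  per <- ceiling(m / n_chrom)
  maps <- lapply(seq_len(n_chrom), function(cc) {
    steps <- sample.int(max_step, per, replace = TRUE)
    mk_map(cumsum(steps), chrom = as.character(cc),
           ids = sprintf("c%d_%04d", cc, seq_len(per)))
  })
  map <- do.call(rbind, maps)
  calls <- matrix(sample(c(0L, 1L, 2L, NA),
                         n_samples * nrow(map), replace = TRUE,
                         prob = c((1 - het_rate - miss_rate) / 2, het_rate,
                                  (1 - het_rate - miss_rate) / 2, miss_rate)),
                  nrow = n_samples)
  rownames(calls) <- sprintf("s%02d", seq_len(n_samples))
  genotypes(calls, map)
}

# canonical form for ROH-record comparisons
roh_key <- function(r) {
  if (!nrow(r)) return(character())
  sprintf("%s|%s|%d|%d|%d", r$sample_id, r$chrom, r$start_bp, r$end_bp,
          r$n_snps)
}

expect_same_roh <- function(a, b) {
  expect_identical(sort(roh_key(a)), sort(roh_key(b)))
}
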