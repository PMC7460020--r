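#' End-to-end ROH / inbreeding / population-structure pipeline
#'
#' Runs the full analysis on a genotype cohort: call-rate filtering,
#' optional chromosome restriction, ROH detection, per-sample / per-group /
#' per-class / per-chromosome summaries, SNP-in-ROH incidence, island
#' calling (with optional gene annotation), both inbreeding coefficients and
#' their per-group regression, pairwise FST, PCA and monomorphic-marker
#' counts.  Every table is written as TSV into `out_dir` together with a
#' JSON manifest (parameter echo, input hashes, per-table md5) so reruns are
#' byte-comparable.
#'
#' @param g a [genotypes] object (or give `ped`/`map` paths instead)
#' @param groups sample_id/group data.frame, or a path to a group TSV
#' @param out_dir output directory (created if absent)
#' @param ped,map optional PED/MAP paths used when `g` is `NULL`
#' @param min_call_rate marker call-rate threshold (default 0.99)
#' @param chromosomes optional chromosome include-list
#' @param params a [roh_params]
#' @param classes a [length_classes]
#' @param island_threshold minimum ROH incidence for islands
#' @param island_min_snps minimum markers per island
#' @param froh_denominator_bp optional fixed FROH denominator
#' @param genes optional gene intervals (data.frame or BED/GFF3 path)
#' @param freq_scope reference set for expected homozygosity summaries
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(g = NULL, groups, out_dir,
                         ped = NULL, map = NULL,
                         min_call_rate = 0.99, chromosomes = NULL,
                         params = roh_params(), classes = length_classes(),
                         island_threshold = 0.70, island_min_snps = 2L,
                         froh_denominator_bp = NULL, genes = NULL,
                         freq_scope = "group") {
  t0 <- Sys.time()
  stage <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                              format(Sys.time(), "%H:%M:%S"), ...))
  inputs <- list()
  if (is.null(g)) {
    if (is.null(ped) || is.null(map))
      stop("config error: supply either `g` or both `ped` and `map`")
    stage("reading PED/MAP: %s", ped)
    inputs$ped <- unname(tools::md5sum(ped))
    inputs$map <- unname(tools::md5sum(map))
    g <- read_ped_map(ped, map)
  }
  if (is.character(groups)) {
    inputs$groups <- unname(tools::md5sum(groups))
    groups <- read_group_file(groups)
  }
  groups <- validate_groups(groups, g)
  if (is.character(genes)) {
    inputs$genes <- unname(tools::md5sum(genes))
    genes <- read_gene_intervals(genes)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_input <- ncol(g$calls)
  stage("filtering %d markers at call rate >= %g", n_input, min_call_rate)
  g <- filter_call_rate(g, min_call_rate)
  if (!is.null(chromosomes)) g <- restrict_chromosomes(g, chromosomes)
  stage("%d markers retained", ncol(g$calls))

  stage("detecting ROH (min %d SNPs, min %g bp, max gap %g bp)",
        params$min_snps, params$min_length_bp, params$max_gap_bp)
  rohs <- detect_roh(g, params)
  stage("%d ROH found", nrow(rohs))

  per_sample <- summarize_per_sample(rohs, sample_ids(g), groups)
  grp_sum <- group_summary(rohs, groups)
  cls_tab <- classify_lengths(rohs, groups, classes)
  chr_sum <- chromosome_summary(rohs, chromosomes(g))

  stage("computing incidence and islands (threshold %g)", island_threshold)
  profile <- snp_incidence(rohs, g, groups)
  islands <- find_islands(profile, island_threshold, island_min_snps)
  if (!is.null(genes)) islands <- annotate_islands(islands, genes)

  stage("computing inbreeding coefficients")
  f_tab <- excess_hom_f(g)
  froh <- f_roh(rohs, g, denominator_bp = froh_denominator_bp,
                classes = classes)
  reg <- regress_f_froh(f_tab, froh$total, groups)
  hh <- hom_het_summary(g, groups, freq_scope)

  stage("computing FST, PCA and monomorphic counts")
  fst <- if (length(unique(groups$group)) >= 2)
    pairwise_fst(g, groups) else NULL
  pca <- pca_genotypes(g, n_components = min(10, nrow(g$calls) - 1))
  mono <- monomorphic_counts(g, groups)

  inb <- merge(f_tab, froh$total, by = "sample_id")
  inc_long <- data.frame(profile$map,
                         round(profile$incidence, 6), check.names = FALSE)
  tables <- list(
    roh = rohs, per_sample = per_sample, group_summary = grp_sum,
    length_classes = cls_tab, chromosome_summary = chr_sum,
    incidence = inc_long, islands = islands,
    inbreeding = inb, froh_by_class = froh$by_class,
    froh_by_chromosome = froh$by_chromosome,
    hom_het = hh, f_froh_regression = reg,
    fst = fst,
    pca_scores = data.frame(sample_id = rownames(pca$scores), pca$scores),
    pca_eigenvalues = data.frame(component = seq_along(pca$eigenvalues),
                                 eigenvalue = pca$eigenvalues),
    monomorphic = mono)
  tables <- Filter(Negate(is.null), tables)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  write_roh_bed(rohs, file.path(out_dir, "roh.bed"))
  paths["roh_bed"] <- file.path(out_dir, "roh.bed")

  manifest <- list(
    package_version = as.character(utils::packageVersion("rohscan")),
    r_version = R.version.string,
    inputs = inputs,
    parameters = list(min_call_rate = min_call_rate,
                      chromosomes = chromosomes,
                      roh_params = unclass(params),
                      class_edges_mb = classes$edges_mb,
                      island_threshold = island_threshold,
                      island_min_snps = island_min_snps,
                      froh_denominator_bp = froh$denominator_bp,
                      freq_scope = freq_scope),
    n_markers_input = n_input, n_markers_used = ncol(g$calls),
    n_samples = nrow(g$calls), n_roh = nrow(rohs),
    tables = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stage("done in %.1f s; %d tables in %s",
        as.numeric(difftime(Sys.time(), t0, units = "secs")),
        length(paths), out_dir)
  invisible(manifest)
}
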