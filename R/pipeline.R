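#' Pipeline configuration and end-to-end driver
#'
#' One configuration object carries every stage threshold; every value is
#' echoed into the run manifest so a result can always be traced to its
#' parameters. Two input paths are supported: the read path (SAM alignments +
#' genome + annotation) runs PAS discovery first, while the fast path starts
#' from a PAS x sample count table assumed pre-filtered for internal priming.
#'
#' @name cli_report
NULL

pipeline_defaults <- function() list(
  max_gap = 24, min_unaligned_t = 2, orientation = "same",
  hexamer_window = c(-40, -1),
  alpha = 0.05, min_delta = 0.05, min_gene_reads = 20, pseudocount = 0.5,
  fc_cut = 1.2, fdr_cut = 0.1,
  n_bins = 5, min_introns = 4, min_reads = 2, min_cluster_reads = 2,
  utr3_extension = 1000, ip_window = 10, ip_min_a = 6,
  internal_priming_filter = NA,  # NA = on for the read path, off for counts
  seed = 1
)

#' Build a validated pipeline configuration
#'
#' @param ... overrides of the default parameters (see
#'   [pipeline_defaults()]); unknown keys are rejected.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with config keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Read a sample sheet TSV (sample_id, condition, timepoint, replicate)
#' @param path TSV path.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!all(df$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  df
}

#' Read miRNA-site or domain intervals from BED6(+1)
#'
#' Columns: chrom, start, end, name (feature_id), score, strand, and a 7th
#' column with the gene id.
#'
#' @param path BED path.
#' @export
read_feature_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("feature BED needs 7 columns (gene id in column 7)")
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             feature_id = df[[4]], strand = df[[6]], gene_id = df[[7]],
             stringsAsFactors = FALSE)
}

tsv <- function(df, out_dir, name) {
  utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full APA pipeline
#'
#' Read path: extract PAS reads, cluster, quantify, filter internal priming.
#' Both paths: annotate regions (and hexamers when a genome is available),
#' census, 3'UTR and intronic APA calls, weighted 3'UTR lengths, aUTR bins,
#' intron-position profile; optional DE + coupling when RNA-seq counts are
#' supplied and consequence annotation when site/domain intervals are.
#' All tables are written to `out_dir` along with a manifest echoing every
#' threshold; reruns with the same seed are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param inputs list. Read path: `sam_files` (named), `genome_fasta`, `gtf`,
#'   `samples`. Fast path: `pas_matrix` (a `pas_matrix` or TSV path),
#'   `samples`, optional `gtf`, optional `genome_fasta`. Optional everywhere:
#'   `rnaseq_counts` (gene x sample matrix), `mirna_sites`, `domains`
#'   (data frames or BED paths).
#' @param out_dir output directory.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs, out_dir) {
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, "secs"), msg))
  read_path <- !is.null(inputs$sam_files)
  if (read_path && (is.null(inputs$genome_fasta) || is.null(inputs$gtf)))
    stop("read path requires genome_fasta and gtf")
  if (!read_path && is.null(inputs$pas_matrix))
    stop("inputs need either sam_files (read path) or pas_matrix (fast path)")
  if (is.null(inputs$samples)) stop("inputs$samples (sample sheet) is required")
  samples <- if (is.character(inputs$samples)) read_sample_sheet(inputs$samples)
             else inputs$samples
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  res <- list()
  genome <- if (!is.null(inputs$genome_fasta)) load_genome(inputs$genome_fasta)

  if (read_path) {
    stage("extracting PAS reads")
    reads <- extract_pas_reads(inputs$sam_files, genome,
                               config$min_unaligned_t, config$orientation)
    stage(sprintf("clustering %d PAS reads", nrow(reads)))
    clusters <- cluster_pas(reads, config$max_gap)
    mat <- quantify(clusters, reads, samples)
    ip <- is.na(config$internal_priming_filter) || config$internal_priming_filter
    if (ip) {
      mat <- filter_internal_priming(mat, genome, config$ip_window,
                                     config$ip_min_a)
      stage(sprintf("internal-priming filter dropped %d clusters",
                    attr(mat, "n_dropped")))
    }
  } else {
    mat <- if (is.character(inputs$pas_matrix))
      read_pas_matrix(inputs$pas_matrix, samples) else inputs$pas_matrix
    if (isTRUE(config$internal_priming_filter)) {
      if (is.null(genome)) stop("internal-priming filter needs genome_fasta")
      mat <- filter_internal_priming(mat, genome, config$ip_window,
                                     config$ip_min_a)
    }
  }

  if (!is.null(inputs$gtf)) {
    stage("annotating regions")
    models <- load_annotation(inputs$gtf)
    mat <- annotate_regions(mat, models, config$utr3_extension)
    res$models <- models
  }
  if (!is.null(genome)) {
    stage("classifying hexamers")
    mat <- annotate_hexamers(mat, genome, config$hexamer_window)
  }
  res$pas_matrix <- mat
  write_pas_matrix(mat, file.path(out_dir, "pas_matrix.tsv"))
  export_pas_bed(mat, file.path(out_dir, "pas_clusters.bed"))
  export_bedgraph(mat, file.path(out_dir, "tracks"))

  stage("census")
  cs <- census(mat, config$min_cluster_reads)
  res$census <- cs
  tsv(as.data.frame.matrix(cs$region_counts), out_dir, "census_regions.tsv")
  tsv(as.data.frame.matrix(cs$hexamer_fractions), out_dir, "census_hexamers.tsv")
  tsv(as.data.frame(cs$pas_per_gene), out_dir, "census_pas_per_gene.tsv")

  stage("3'UTR APA calls")
  ev_u <- call_utr3_apa(mat, config$alpha, config$min_delta,
                        config$min_gene_reads, config$pseudocount)
  res$utr3_events <- ev_u
  write_events(ev_u, file.path(out_dir, "events_utr3.tsv"))
  stage("intronic APA calls")
  ev_i <- call_intronic_apa(mat, config$alpha, config$min_delta,
                            config$min_gene_reads, config$pseudocount)
  res$intronic_events <- ev_i
  write_events(ev_i, file.path(out_dir, "events_intronic.tsv"))
  if (nrow(ev_u) && nrow(ev_i))
    tsv(as.data.frame(apa_quadrants(ev_u, ev_i)), out_dir, "apa_quadrants.tsv")

  if (any(!is.na(mat$pas$utr3_len))) {
    wl <- weighted_utr3_length(mat)
    res$weighted_length <- wl
    tsv(wl, out_dir, "weighted_utr3_length.tsv")
    if (nrow(ev_u))
      tsv(length_change_by_class(wl, ev_u), out_dir, "length_change_by_class.tsv")
  }
  if (nrow(ev_u) >= config$n_bins) {
    ab <- autr_bin_analysis(ev_u, config$n_bins)
    res$autr_bins <- ab
    if (!is.null(ab$bins)) tsv(ab$bins, out_dir, "autr_bins.tsv")
  }
  ip_prof <- intron_position_profile(mat, config$min_introns,
                                     config$min_reads, config$pseudocount)
  res$intron_profile <- ip_prof
  tsv(ip_prof$profile, out_dir, "intron_profile.tsv")

  if (!is.null(inputs$rnaseq_counts)) {
    stage("differential expression")
    de <- de_test(inputs$rnaseq_counts,
                  samples$condition[match(colnames(inputs$rnaseq_counts),
                                          samples$sample_id)],
                  config$fc_cut, config$fdr_cut)
    res$de <- de
    tsv(as.data.frame(de), out_dir, "de.tsv")
    if (nrow(ev_u)) {
      cp <- apa_expression_coupling(ev_u, de)
      res$coupling_utr3 <- cp
      tsv(cp$summary, out_dir, "coupling_utr3_summary.tsv")
      if (!is.null(cp$tests)) tsv(cp$tests, out_dir, "coupling_utr3_tests.tsv")
    }
    if (nrow(ev_i)) {
      cpi <- apa_expression_coupling(ev_i, de)
      res$coupling_intronic <- cpi
      tsv(cpi$summary, out_dir, "coupling_intronic_summary.tsv")
    }
  }
  if (!is.null(inputs$mirna_sites) && nrow(ev_u)) {
    sites <- if (is.character(inputs$mirna_sites))
      read_feature_bed(inputs$mirna_sites) else inputs$mirna_sites
    ms <- removed_mirna_sites(ev_u, sites)
    res$mirna <- ms
    tsv(ms$sites, out_dir, "mirna_sites.tsv")
  }
  if (!is.null(inputs$domains) && nrow(ev_i) && !is.null(res$models)) {
    doms <- if (is.character(inputs$domains))
      read_feature_bed(inputs$domains) else inputs$domains
    dm <- removed_domains(ev_i, doms, res$models)
    res$domains <- dm
    tsv(dm$domains, out_dir, "domains.tsv")
  }

  manifest <- c(list(package = "apakit",
                     version = as.character(utils::packageVersion("apakit")),
                     path = if (read_path) "reads" else "counts",
                     n_samples = nrow(samples),
                     elapsed_sec = round(as.numeric(Sys.time() - t0, "secs"), 1)),
                unclass(config))
  manifest$hexamer_window <- paste(config$hexamer_window, collapse = ",")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  stage("done")
  invisible(res)
}
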