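## Orchestration of the two end-to-end workflows with provenance: a
## time-series run (filter -> CPM -> log2-center -> PCA + rate-of-change ->
## time-course LRT -> BH -> cluster -> order -> enrich) and a degron (AID)
## run (count filter -> upper-quartile + spike-based unwanted-variation
## factor -> pairwise LRTs -> set classification -> spike regression ->
## attomoles per worm -> spike read proportion). Every run writes its stage
## tables, a verbatim copy of the configuration, a manifest of content
## hashes, and a log.

#' Default run configurations
#'
#' Stage parameters default to the published settings: expressed = CPM > 1
#' in >= 4 libraries (time series) or counts > 10 in >= 4 samples (AID);
#' FDR 0.05; clustering significance cutoff q < 1e-30; maximum cluster
#' diameter 0.2; one factor of unwanted variation (k = 1); pseudocount 1.
#'
#' @param counts,samples,spikes,genesets input file paths (genesets optional).
#' @param out_dir output directory.
#' @param ... overrides of the defaults listed above.
#' @return configuration list.
#' @export
timeseries_config <- function(counts, samples, spikes = NULL, genesets = NULL,
                              out_dir, ...) {
  cfg <- list(workflow = "timeseries", counts = counts, samples = samples,
              spikes = spikes, genesets = genesets, out_dir = out_dir,
              filter_threshold = 1, filter_min_libs = 4, filter_mode = "cpm",
              pseudocount = 1, fdr = 0.05, sig_cutoff = 1e-30,
              max_diameter = 0.2, cluster_seed = 1, enrich_alpha = 0.01,
              enrich_universe = "expressed")
  utils::modifyList(cfg, list(...))
}

#' @rdname timeseries_config
#' @export
aid_config <- function(counts, samples, spikes, genesets = NULL, out_dir, ...) {
  cfg <- list(workflow = "aid", counts = counts, samples = samples,
              spikes = spikes, genesets = genesets, out_dir = out_dir,
              filter_threshold = 10, filter_min_libs = 4, filter_mode = "count",
              fdr = 0.05, k = 1, classify_mode = "strict")
  utils::modifyList(cfg, list(...))
}

run_setup <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  unlink(log_path)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                         file = log_path, append = TRUE)
}

write_manifest <- function(out_dir, inputs) {
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  paths <- file.path(out_dir, files)
  manifest <- rbind(
    data.frame(role = "input", file = names(inputs),
               md5 = unname(tools::md5sum(unlist(inputs)))),
    data.frame(role = "output", file = files,
               md5 = unname(tools::md5sum(paths)))
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the starvation time-series workflow
#'
#' @param config from [timeseries_config()].
#' @return invisibly, a list with the output directory, the manifest and
#'   key in-memory results.
#' @export
run_timeseries <- function(config) {
  logmsg <- run_setup(config)
  out <- config$out_dir
  p <- function(f) file.path(out, f)

  counts <- stage("read", read_counts(config$counts))
  sheet <- stage("read", read_samples(config$samples))
  logmsg("read %d genes x %d samples", nrow(counts), ncol(counts))

  expressed <- stage("filter", filter_expressed(
    counts, config$filter_threshold, config$filter_min_libs,
    mode = config$filter_mode))
  logmsg("filter: %d of %d genes expressed (%s > %g in >= %d libraries)",
      length(expressed), sum(!is_spike(counts)), config$filter_mode,
      config$filter_threshold, config$filter_min_libs)
  writeLines(expressed, p("expressed_genes.txt"))
  gc_counts <- counts[expressed, , drop = FALSE]

  cpm_mat <- stage("cpm", cpm(counts)[expressed, , drop = FALSE])
  lg <- stage("log2_center", log2_mean_centered(cpm_mat, config$pseudocount))
  write_matrix_tsv(lg, p("log2cpm_centered.tsv"),
                   comments = c(unit = "log2CPM_mean_centered",
                                pseudocount = config$pseudocount))

  pca <- stage("pca", pca_scores(lg))
  write_matrix_tsv(pca$scores, p("pca_scores.tsv"), id_col = "sample_id",
                   comments = c(var_explained = paste(
                     signif(pca$var_explained[1:min(5, length(pca$var_explained))], 4),
                     collapse = ",")))
  roc <- stage("rate_of_change", rate_of_change(lg, sheet))
  write_tsv(roc, p("rate_of_change.tsv"))

  de <- stage("lrt_timecourse", lrt_timecourse(
    gc_counts, groups = sheet$time_h[match(colnames(gc_counts),
                                           sheet$sample_id)]))
  write_tsv(de, p("de_timecourse.tsv"))
  logmsg("time-course LRT: %d of %d genes at q < %g",
      sum(de$q < config$fdr, na.rm = TRUE), nrow(de), config$fdr)

  sig <- de$gene_id[!is.na(de$q) & de$q < config$sig_cutoff]
  logmsg("clustering input: %d genes at q < %g", length(sig), config$sig_cutoff)
  times <- sheet$time_h[match(colnames(cpm_mat), sheet$sample_id)]
  profiles <- t(apply(cpm_mat[sig, , drop = FALSE], 1, function(x)
    tapply(x, times, mean)))
  clustering <- stage("cluster", diameter_cluster(
    correlation_distance(profiles), config$max_diameter,
    seed = config$cluster_seed))
  logmsg("clustering: %d clusters (max diameter %g, seed %d)",
      length(clustering$sizes), config$max_diameter, config$cluster_seed)
  z <- stage("zscore", zscore_profiles(profiles))
  ordering <- stage("order", order_clusters(clustering, z))
  write_tsv(data.frame(gene_id = ordering$gene_order,
                       cluster = clustering$cluster[ordering$gene_order],
                       rank = seq_along(ordering$gene_order)),
            p("clusters.tsv"))
  write_tsv(ordering$summary, p("cluster_summary.tsv"))
  stage("heatmap", export_heatmap(z, ordering, clustering, p("heatmap")))

  enrichment <- NULL
  if (!is.null(config$genesets)) {
    groups <- stage("enrich", read_gmt(config$genesets))
    universe <- if (identical(config$enrich_universe, "clustered")) sig
                else expressed
    enrichment <- do.call(rbind, lapply(groups, function(g) {
      gf <- filter_to_expressed(g, universe)
      hypergeom_enrichment(gf, clustering, universe = universe)
    }))
    write_tsv(enrichment, p("enrichment.tsv"))
    logmsg("enrichment: %d group x cluster cells, %d at p < %g",
        nrow(enrichment), sum(enrichment$p < config$enrich_alpha),
        config$enrich_alpha)
  }

  manifest <- write_manifest(out, list(counts = config$counts,
                                       samples = config$samples))
  invisible(list(out_dir = out, manifest = manifest, de = de,
                 clustering = clustering, ordering = ordering,
                 enrichment = enrichment, expressed = expressed))
}

#' Run the degron (AID) perturbation workflow
#'
#' @param config from [aid_config()].
#' @return invisibly, a list with the output directory, manifest, the
#'   per-contrast DE tables and the classified sets.
#' @export
run_aid <- function(config) {
  logmsg <- run_setup(config)
  out <- config$out_dir
  p <- function(f) file.path(out, f)

  counts <- stage("read", read_counts(config$counts))
  sheet <- stage("read", read_samples(config$samples))
  mix <- stage("read", read_spikes(config$spikes))
  if (!all(c("strain", "treatment") %in% names(sheet)))
    stopf("stage 'read' failed: sample sheet lacks strain/treatment columns")

  expressed <- stage("filter", filter_expressed(
    counts, config$filter_threshold, config$filter_min_libs,
    mode = config$filter_mode))
  logmsg("filter: %d of %d genes with counts > %g in >= %d samples",
      length(expressed), sum(!is_spike(counts)), config$filter_threshold,
      config$filter_min_libs)
  gc_counts <- counts[expressed, , drop = FALSE]

  uq <- stage("upper_quartile", upper_quartile_factors(counts))
  spike_ids <- intersect(rownames(counts), mix$spike_id)
  uv <- stage("unwanted_variation", unwanted_variation_factor(
    log(counts + 1), spike_ids, k = config$k))
  write_matrix_tsv(uv$W, p("unwanted_factor.tsv"), id_col = "sample_id")

  sel <- function(strain, time, treat)
    sheet$sample_id[sheet$strain == strain & sheet$time_h == time &
                      sheet$treatment == treat]
  strains <- unique(sheet$strain)
  de_auxin <- list(); de_time <- list()
  for (s in strains) {
    de_auxin[[s]] <- stage(paste0("lrt_auxin_", s), lrt_pairwise(
      gc_counts, sel(s, 132, "ethanol"), sel(s, 132, "auxin"),
      covariates = uv, norm_factors = uq))
    write_tsv(de_auxin[[s]], p(sprintf("de_auxin_vs_etoh_132h_%s.tsv", s)))
    de_time[[s]] <- stage(paste0("lrt_time_", s), lrt_pairwise(
      gc_counts, sel(s, 36, "ethanol"), sel(s, 132, "ethanol"),
      covariates = uv, norm_factors = uq))
    write_tsv(de_time[[s]], p(sprintf("de_132h_vs_36h_etoh_%s.tsv", s)))
    logmsg("%s: auxin contrast %d DE at q < %g; time contrast %d DE",
        s, sum(de_auxin[[s]]$q < config$fdr, na.rm = TRUE), config$fdr,
        sum(de_time[[s]]$q < config$fdr, na.rm = TRUE))
  }

  classified <- stage("classify", classify_sets(
    de_auxin[["soma_TIR1_AID"]], de_time, fdr = config$fdr,
    strains = strains, mode = config$classify_mode))
  write_gmt(list(
    gene_set("transcription_dependent", classified$transcription_dependent,
             "down under soma-AID auxin at 132 h"),
    gene_set("high_confidence_upregulated",
             classified$high_confidence_upregulated,
             "up 36 h -> 132 h (ethanol) in all strains"),
    gene_set("td_upregulated", classified$td_upregulated, "intersection"),
    gene_set("ti_upregulated", classified$ti_upregulated, "difference")
  ), p("classified_sets.gmt"))
  logmsg("classified: td %d, high-conf up %d, td-up %d (%.0f%%), ti-up %d",
      length(classified$transcription_dependent),
      length(classified$high_confidence_upregulated),
      length(classified$td_upregulated), 100 * classified$overlap_fraction,
      length(classified$ti_upregulated))

  fit <- stage("spike_regression", fit_spike_regression(counts, mix))
  write_tsv(fit, p("spike_fit.tsv"))
  amol <- stage("attomoles", to_attomoles_per_worm(
    counts[expressed, , drop = FALSE], fit, sheet))
  write_matrix_tsv(amol, p("attomoles_per_worm.tsv"),
                   comments = c(unit = "attomol_per_worm"))
  prop <- stage("spike_proportion", spike_read_proportion(counts))
  write_tsv(data.frame(sample_id = names(prop), spike_read_proportion = prop),
            p("spike_read_proportion.tsv"))

  manifest <- write_manifest(out, list(counts = config$counts,
                                       samples = config$samples,
                                       spikes = config$spikes))
  invisible(list(out_dir = out, manifest = manifest, de_auxin = de_auxin,
                 de_time = de_time, classified = classified,
                 spike_fit = fit, spike_proportion = prop,
                 expressed = expressed))
}

#' Per-gene expression-over-time table and figure
#'
#' Writes the numeric table behind a single-gene trajectory plot (one row
#' per time point: mean CPM and the replicate values) plus a PDF figure.
#'
#' @param gene_id gene to plot.
#' @param expr gene x sample expression matrix (e.g. CPM).
#' @param sheet sample sheet with `sample_id`, `time_h`.
#' @param prefix output path prefix (`<prefix>.tsv`, `<prefix>.pdf`).
#' @return data.frame of the per-time-point values, invisibly.
#' @export
plot_gene <- function(gene_id, expr, sheet, prefix) {
  if (!gene_id %in% rownames(expr))
    stopf("unknown gene id: %s", gene_id)
  times <- sheet$time_h[match(colnames(expr), sheet$sample_id)]
  y <- expr[gene_id, ]
  tab <- do.call(rbind, lapply(sort(unique(times)), function(tt)
    data.frame(time_h = tt, mean = mean(y[times == tt]),
               values = paste(signif(y[times == tt], 6), collapse = ","))))
  write_tsv(tab, paste0(prefix, ".tsv"))
  grDevices::pdf(paste0(prefix, ".pdf"), width = 5, height = 4)
  graphics::plot(times, y, xlab = "time (h)", ylab = "expression",
                 main = gene_id)
  graphics::lines(tab$time_h, tab$mean, col = "red")
  grDevices::dev.off()
  scrub_pdf_dates(paste0(prefix, ".pdf"))
  invisible(tab)
}
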