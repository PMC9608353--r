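## Gene-group enrichment against clusters (exact hypergeometric
## over-representation), the set-logic classification separating
## transcription-driven from stability-driven up-regulation, KS distribution
## comparisons, and bootstrapped group-mean Z profiles.

#' Restrict a gene set to expressed genes
#'
#' Gene groups of interest are intersected with the expressed-gene universe
#' before enrichment; a group with no expressed members is unusable.
#'
#' @param group a `gene_set`.
#' @param expressed character vector of expressed gene ids.
#' @return the filtered `gene_set`.
#' @export
filter_to_expressed <- function(group, expressed) {
  kept <- intersect(group$genes, expressed)
  if (length(kept) == 0)
    stopf("gene set '%s' has no expressed members", group$name)
  gene_set(group$name, kept, note = group$note)
}

#' Hypergeometric enrichment of a gene group in each cluster
#'
#' Upper-tail exact test: with a universe of N genes, a cluster of K genes
#' and a group of n genes overlapping the cluster in k genes,
#' p = P(X >= k) for X ~ hypergeometric(N, K, n). One-sided
#' over-representation only; no normal approximation.
#'
#' @param group a `gene_set` (must be contained in the universe).
#' @param clustering an `arrest_clustering` (clustered genes must be in the
#'   universe).
#' @param universe character vector of gene ids (e.g. all expressed genes).
#' @return data.frame: `group`, `cluster`, `N`, `K`, `n`, `k`, `p`.
#' @export
hypergeom_enrichment <- function(group, clustering, universe) {
  universe <- unique(universe)
  if (!all(group$genes %in% universe))
    stopf("gene set '%s' is not contained in the universe", group$name)
  cl <- clustering$cluster
  if (!all(names(cl) %in% universe))
    stopf("clustered genes are not contained in the universe")
  N <- length(universe)
  n <- length(group$genes)
  ids <- sort(unique(cl))
  res <- do.call(rbind, lapply(ids, function(ci) {
    members <- names(cl)[cl == ci]
    K <- length(members)
    k <- length(intersect(members, group$genes))
    data.frame(group = group$name, cluster = ci, N = N, K = K, n = n, k = k,
               p = stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE))
  }))
  rownames(res) <- NULL
  res
}

#' Classify transcription-dependent vs stability-driven up-regulation
#'
#' Combines the degron-experiment contrasts into four gene sets:
#' \describe{
#'   \item{transcription_dependent}{genes down (q < fdr, log2FC < 0) when
#'     somatic RNA Pol II is degraded (soma-AID auxin vs ethanol at 132 h).}
#'   \item{high_confidence_upregulated}{genes up (q < fdr, log2FC > 0)
#'     between 36 h and 132 h with ethanol in every strain (lenient mode:
#'     positive log2FC in all strains, q < fdr in at least one).}
#'   \item{td_upregulated}{their intersection — up-regulation driven by
#'     ongoing transcription.}
#'   \item{ti_upregulated}{high-confidence up-regulated genes that are not
#'     transcription-dependent — apparent up-regulation driven by relative
#'     transcript stability.}
#' }
#' Also reports the overlap fraction and its hypergeometric p over the
#' shared gene basis.
#'
#' @param de_soma_auxin DETable of the soma-AID auxin-vs-ethanol contrast at
#'   132 h (log2FC positive = higher with auxin).
#' @param de_time_by_strain named list of DETables (one per strain) for the
#'   132 h-ethanol-vs-36 h contrast (log2FC positive = higher at 132 h).
#' @param fdr FDR threshold on q.
#' @param strains required strain names.
#' @param mode `"strict"` (q < fdr in every strain) or `"lenient"`.
#' @return list of class `arrest_classified`: the four sets, thresholds,
#'   `overlap_fraction`, `overlap_p`, `universe`.
#' @export
classify_sets <- function(de_soma_auxin, de_time_by_strain, fdr = 0.05,
                          strains = c("soma_TIR1", "germline_TIR1",
                                      "soma_TIR1_AID", "germline_TIR1_AID"),
                          mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  missing <- setdiff(strains, names(de_time_by_strain))
  if (length(missing) > 0)
    stopf("missing strain contrast(s): %s", paste(missing, collapse = ", "))
  basis <- Reduce(intersect, c(list(de_soma_auxin$gene_id),
                               lapply(de_time_by_strain[strains],
                                      `[[`, "gene_id")))
  sel <- function(tab) tab[match(basis, tab$gene_id), ]
  aux <- sel(de_soma_auxin)
  td <- basis[!is.na(aux$q) & aux$q < fdr & aux$log2FC < 0]
  up <- vapply(strains, function(s) {
    tab <- sel(de_time_by_strain[[s]])
    !is.na(tab$q) & tab$log2FC > 0 & tab$q < fdr
  }, logical(length(basis)))
  pos <- vapply(strains, function(s) {
    tab <- sel(de_time_by_strain[[s]])
    !is.na(tab$log2FC) & tab$log2FC > 0
  }, logical(length(basis)))
  hc <- if (mode == "strict") basis[rowSums(up) == length(strains)]
        else basis[rowSums(pos) == length(strains) & rowSums(up) >= 1]
  td_up <- intersect(hc, td)
  ti_up <- setdiff(hc, td)
  N <- length(basis)
  overlap_p <- if (length(hc) > 0 && length(td) > 0)
    stats::phyper(length(td_up) - 1, length(td), N - length(td),
                  length(hc), lower.tail = FALSE)
  else 1
  structure(list(
    transcription_dependent = td,
    high_confidence_upregulated = hc,
    td_upregulated = td_up,
    ti_upregulated = ti_up,
    fdr = fdr, mode = mode, universe = basis,
    overlap_fraction = if (length(hc) > 0) length(td_up) / length(hc) else NA,
    overlap_p = overlap_p
  ), class = "arrest_classified")
}

#' @export
print.arrest_classified <- function(x, ...) {
  cat(sprintf(paste0("classified sets (FDR %g, %s mode):\n",
                     "  transcription-dependent:      %d\n",
                     "  high-confidence up-regulated: %d\n",
                     "  td up-regulated (overlap):    %d (%.0f%%, hypergeometric p = %.3g)\n",
                     "  ti up-regulated:              %d\n"),
              x$fdr, x$mode, length(x$transcription_dependent),
              length(x$high_confidence_upregulated),
              length(x$td_upregulated), 100 * x$overlap_fraction,
              x$overlap_p, length(x$ti_upregulated)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test of a distributional difference (e.g. log2
#' CPM of a gene set across conditions).
#'
#' @param values_a,values_b numeric samples (non-empty).
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stopf("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(values_a, values_b,
                                        alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Group-mean Z profile with bootstrap confidence band
#'
#' Per time point, the mean Z over the group's genes with a percentile
#' bootstrap confidence interval obtained by resampling genes.
#'
#' @param group a `gene_set`.
#' @param z gene x time Z matrix.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level (default 0.99).
#' @param seed RNG seed.
#' @return data.frame: `timepoint`, `mean_z`, `lower`, `upper`, `n_genes`.
#' @export
target_profile_summary <- function(group, z, n_boot = 1000, conf = 0.99,
                                   seed = 1) {
  genes <- intersect(group$genes, rownames(z))
  if (length(genes) == 0) stopf("gene set '%s' absent from Z matrix", group$name)
  zz <- z[genes, , drop = FALSE]
  set.seed(seed)
  boots <- matrix(0, n_boot, ncol(zz))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(zz), replace = TRUE)
    boots[b, ] <- colMeans(zz[idx, , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  data.frame(
    timepoint = colnames(zz) %||% as.character(seq_len(ncol(zz))),
    mean_z = colMeans(zz),
    lower = apply(boots, 2, stats::quantile, alpha),
    upper = apply(boots, 2, stats::quantile, 1 - alpha),
    n_genes = length(genes),
    row.names = NULL
  )
}
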