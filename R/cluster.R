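## Correlation-distance diameter-constrained clustering and the heatmap
## ordering procedure: genes in the same cluster must pairwise satisfy
## 1 - Pearson r <= max_diameter (default 0.2, i.e. r >= 0.8). The
## construction is a seeded greedy scan with consolidation passes; the
## diameter invariant holds for every output unconditionally.

#' Pairwise correlation distance of expression profiles
#'
#' d(i, j) = 1 - Pearson r between the genes' profiles over time; values lie
#' in `[0, 2]` with zeros on the diagonal. Genes with zero variance across
#' time have undefined correlation and are rejected.
#'
#' @param profiles gene x time matrix (e.g. mean CPM per time point).
#' @return symmetric distance matrix.
#' @export
correlation_distance <- function(profiles) {
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0))
    stopf("zero-variance profile(s): %s",
          paste(utils::head(rownames(profiles)[v == 0], 5), collapse = ", "))
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  d
}

#' Diameter-constrained clustering
#'
#' Greedy randomized construction: genes are scanned in a seed-shuffled
#' order and each is assigned to the first existing cluster whose *every*
#' member lies within `max_diameter` (complete-diameter criterion), else a
#' new cluster is opened. Consolidation passes then re-scan all genes,
#' moving each to the earliest cluster that can accept it, until the
#' partition is stable. Cluster ids are relabelled by decreasing size.
#'
#' @param dist symmetric correlation-distance matrix with gene dimnames.
#' @param max_diameter maximum within-cluster pairwise distance, in (0, 2).
#' @param seed RNG seed for the scan order (required; the procedure is
#'   order-dependent, mirroring the non-determinism of the original
#'   analysis).
#' @param max_passes cap on consolidation passes.
#' @return list of class `arrest_clustering`: `cluster` (named integer
#'   vector), `sizes`, `params`.
#' @export
diameter_cluster <- function(dist, max_diameter = 0.2, seed, max_passes = 25) {
  if (missing(seed)) stopf("seed is required (the scan order is randomized)")
  if (!(max_diameter > 0 && max_diameter < 2))
    stopf("max_diameter must lie in (0, 2)")
  n <- nrow(dist)
  if (n != ncol(dist) || max(abs(dist - t(dist))) > 1e-8)
    stopf("dist must be a symmetric square matrix")
  ids <- rownames(dist) %||% as.character(seq_len(n))
  set.seed(seed)
  ord <- sample.int(n)

  members <- list()                      # cluster -> member indices
  assign_of <- integer(n)
  first_fit <- function(g, skip_self = 0L) {
    dg <- dist[g, ]
    for (ci in seq_along(members)) {
      m <- members[[ci]]
      if (ci == skip_self) m <- setdiff(m, g)
      if (length(m) == 0) next
      if (max(dg[m]) <= max_diameter) return(ci)
    }
    0L
  }
  for (g in ord) {
    ci <- first_fit(g)
    if (ci == 0L) {
      members[[length(members) + 1]] <- g
      ci <- length(members)
    } else {
      members[[ci]] <- c(members[[ci]], g)
    }
    assign_of[g] <- ci
  }
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (g in ord) {
      cur <- assign_of[g]
      best <- first_fit(g, skip_self = cur)
      if (best != 0L && best != cur) {
        members[[cur]] <- setdiff(members[[cur]], g)
        members[[best]] <- c(members[[best]], g)
        assign_of[g] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  keep <- lengths(members) > 0
  members <- members[keep]
  sizes <- lengths(members)
  relabel <- order(-sizes, vapply(members, min, integer(1)))
  cluster <- integer(n)
  for (new_id in seq_along(relabel))
    cluster[members[[relabel[new_id]]]] <- new_id
  names(cluster) <- ids
  structure(list(cluster = cluster,
                 sizes = as.integer(table(cluster)),
                 params = list(max_diameter = max_diameter, seed = seed)),
            class = "arrest_clustering")
}

#' @export
print.arrest_clustering <- function(x, ...) {
  cat(sprintf("diameter clustering: %d genes in %d clusters (max diameter %g, seed %d)\n",
              length(x$cluster), length(x$sizes),
              x$params$max_diameter, x$params$seed))
  invisible(x)
}

#' Z-score expression profiles
#'
#' Per gene: (x - mean) / sd with the sample standard deviation (n - 1
#' denominator); every row has mean 0 and sd 1.
#'
#' @param profiles gene x time matrix with nonzero row variance.
#' @return Z matrix of the same shape.
#' @export
zscore_profiles <- function(profiles) {
  s <- apply(profiles, 1, stats::sd)
  if (any(s == 0))
    stopf("zero-variance profile(s): %s",
          paste(utils::head(rownames(profiles)[s == 0], 5), collapse = ", "))
  (profiles - rowMeans(profiles)) / s
}

#' Centroid time point of a cluster-mean Z profile
#'
#' The profile is shifted so its minimum is 0; the centroid is the first
#' time-point index at which the cumulative sum reaches at least half of the
#' total (default `mode = "half_mass"`). `mode = "tail"` gives the literal
#' alternative reading: the first index from which the remaining sum is less
#' than half the total.
#'
#' @param mean_z numeric profile (length >= 2).
#' @param mode `"half_mass"` or `"tail"`.
#' @return integer time-point index.
#' @export
cluster_centroid_timepoint <- function(mean_z, mode = c("half_mass", "tail")) {
  mode <- match.arg(mode)
  if (length(mean_z) < 2) stopf("profile must have length >= 2")
  shifted <- mean_z - min(mean_z)
  tot <- sum(shifted)
  if (tot == 0) {
    warning("all-zero shifted profile; centroid set to first time point")
    return(1L)
  }
  if (mode == "half_mass") {
    which(cumsum(shifted) >= tot / 2)[1]
  } else {
    rem <- rev(cumsum(rev(shifted)))     # sum from index i to end
    idx <- which(rem < tot / 2)
    if (length(idx) == 0) length(mean_z) else idx[1]
  }
}

#' Display order of clusters and genes for the heatmap
#'
#' Clusters are sorted by (1) time point of highest cluster-mean Z, earliest
#' first; (2) centroid time point; (3) peak Z value — descending for peaks
#' in the first half of the time points and ascending for peaks in the
#' second half. Genes within a cluster keep their input order and stay
#' contiguous.
#'
#' @param clustering an `arrest_clustering`.
#' @param z gene x time Z matrix on the same gene basis.
#' @param centroid_mode passed to [cluster_centroid_timepoint()].
#' @return list: `summary` (per-cluster keys in display order),
#'   `cluster_order`, `gene_order`.
#' @export
order_clusters <- function(clustering, z, centroid_mode = "half_mass") {
  cl <- clustering$cluster
  if (!setequal(names(cl), rownames(z)))
    stopf("clustering and z must share the same gene basis")
  z <- z[names(cl), , drop = FALSE]
  n_tp <- ncol(z)
  ids <- sort(unique(cl))
  mean_z <- t(vapply(ids, function(ci)
    colMeans(z[cl == ci, , drop = FALSE]), numeric(n_tp)))
  peak_tp <- apply(mean_z, 1, which.max)
  peak_z <- apply(mean_z, 1, max)
  centroid <- apply(mean_z, 1, cluster_centroid_timepoint, mode = centroid_mode)
  ## peaks in the first half sort high-to-low on peak Z, second half low-to-high
  z_key <- ifelse(peak_tp <= n_tp / 2, -peak_z, peak_z)
  disp <- order(peak_tp, centroid, z_key)
  summary <- data.frame(cluster = ids[disp],
                        size = as.integer(table(cl)[as.character(ids[disp])]),
                        peak_timepoint = peak_tp[disp],
                        centroid_timepoint = centroid[disp],
                        peak_z = peak_z[disp])
  rownames(summary) <- NULL
  gene_order <- unlist(lapply(summary$cluster, function(ci)
    rownames(z)[cl == ci]), use.names = FALSE)
  list(summary = summary, cluster_order = summary$cluster,
       gene_order = gene_order)
}

#' Write the clustered heatmap and its row order
#'
#' Writes a PDF heatmap of the Z matrix in display order and, as the
#' testable surface, a TSV of the exact gene order (`<prefix>.pdf`,
#' `<prefix>_row_order.tsv`).
#'
#' @param z gene x time Z matrix.
#' @param ordering result of [order_clusters()].
#' @param clustering the `arrest_clustering` behind `ordering`.
#' @param prefix output path prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
export_heatmap <- function(z, ordering, clustering, prefix) {
  genes <- ordering$gene_order
  tsv <- paste0(prefix, "_row_order.tsv")
  pdf_path <- paste0(prefix, ".pdf")
  write_tsv(data.frame(gene_id = genes,
                       cluster = clustering$cluster[genes],
                       rank = seq_along(genes)),
            tsv)
  zo <- z[genes, , drop = FALSE]
  grDevices::pdf(pdf_path, width = 6, height = 8)
  graphics::image(t(zo[rev(seq_len(nrow(zo))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "time point", ylab = "genes (display order)")
  grDevices::dev.off()
  scrub_pdf_dates(pdf_path)
  invisible(c(row_order = tsv, heatmap = pdf_path))
}
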