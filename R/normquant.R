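## Normalization and absolute quantification: CPM, upper-quartile scale
## factors, a control-gene SVD factor of unwanted variation, per-sample
## log-log spike-in regression, conversion of counts to attomoles per worm,
## and the spike read-proportion diagnostic of mRNA content.

new_expression_matrix <- function(values, unit, pseudocount = NA_real_) {
  attr(values, "unit") <- unit
  attr(values, "pseudocount") <- pseudocount
  values
}

#' Counts per million
#'
#' The library-size basis excludes spike-in rows by default: spike content
#' tracks the mRNA-to-total-RNA ratio rather than the mRNA pool, so including
#' it would distort gene CPM. Columns sum to 1e6 over the basis rows.
#'
#' @param counts gene x sample count matrix (spike rows `"ERCC-"` prefixed).
#' @param exclude_spikes compute library sizes over non-spike rows only.
#' @return CPM matrix (same rows as input) with a `unit` attribute.
#' @export
cpm <- function(counts, exclude_spikes = TRUE) {
  assert_count_matrix(counts)
  basis <- if (exclude_spikes) !is_spike(counts) else rep(TRUE, nrow(counts))
  lib <- colSums(counts[basis, , drop = FALSE])
  if (any(lib == 0))
    stopf("all-zero library for sample(s): %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  new_expression_matrix(sweep(counts, 2, lib, `/`) * 1e6, "CPM")
}

#' Log2 mean-normalized CPM
#'
#' Per gene, log2(CPM + pseudocount) centered on the gene's mean across
#' samples; every row has mean zero. This is the input space for PCA and the
#' rate-of-change statistic.
#'
#' @param cpm_mat CPM matrix from [cpm()].
#' @param pseudocount added before the log (> 0, default 1).
#' @return centered log2 matrix with `unit` attribute.
#' @export
log2_mean_centered <- function(cpm_mat, pseudocount = 1) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  lg <- log2(cpm_mat + pseudocount)
  new_expression_matrix(lg - rowMeans(lg), "log2CPM_mean_centered",
                        pseudocount = pseudocount)
}

#' Upper-quartile scale factors
#'
#' Per-sample 75th percentile of nonzero gene counts (linear-interpolation
#' quantile, R type 7), rescaled so the factors have geometric mean 1.
#' Dividing a sample's counts by its factor equalizes upper quartiles across
#' samples.
#'
#' @param counts gene x sample count matrix; spike rows are excluded.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
upper_quartile_factors <- function(counts) {
  assert_count_matrix(counts)
  genes <- counts[!is_spike(counts), , drop = FALSE]
  uq <- apply(genes, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) < 4)
      stopf("sample has fewer than 4 nonzero gene counts")
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  })
  uq / exp(mean(log(uq)))
}

#' Factor(s) of unwanted variation from control genes
#'
#' Centers each control gene's log-scale values across samples and scores
#' samples on the first `k` right-singular vectors of the centered control
#' submatrix. With spike-ins as controls and k = 1 this captures the
#' dominant technical/mRNA-content axis for use as a covariate in the GLMs.
#' Factors are unit-norm and defined only up to sign.
#'
#' @param logcounts gene x sample matrix on a log scale.
#' @param control_ids row names of the control genes.
#' @param k number of factors.
#' @return list of class `arrest_uvfactor`: `W` (samples x k scores), `k`,
#'   `control_ids`.
#' @export
unwanted_variation_factor <- function(logcounts, control_ids, k = 1) {
  missing <- setdiff(control_ids, rownames(logcounts))
  if (length(missing) > 0)
    stopf("control genes absent from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  if (length(control_ids) < k + 2)
    stopf("need at least k + 2 control genes")
  if (k >= ncol(logcounts))
    stopf("k must be smaller than the number of samples")
  M <- logcounts[control_ids, , drop = FALSE]
  M <- M - rowMeans(M)
  W <- matrix(0, ncol(logcounts), k,
              dimnames = list(colnames(logcounts), paste0("W", seq_len(k))))
  if (sum(M^2) > 0) {
    sv <- svd(M, nu = 0, nv = k)
    W[, ] <- sv$v[, seq_len(k), drop = FALSE]
  }
  structure(list(W = W, k = k, control_ids = control_ids),
            class = "arrest_uvfactor")
}

#' Per-sample spike-in regression
#'
#' Least-squares fit of log10(count) on log10(concentration) over the
#' spike-ins with nonzero counts in each sample; zero-count spike-ins are
#' dropped (no pseudocount). With `pooled = TRUE` a single fit over all
#' samples' points is reported for every sample.
#'
#' @param counts count matrix containing spike rows.
#' @param mix spike table with `spike_id`, `conc_attomol_per_ul`.
#' @param pooled fit one regression over all samples instead of per sample.
#' @return data.frame: `sample`, `slope`, `intercept` (log10-log10 scale),
#'   `r_squared`, `n_spikes`.
#' @export
fit_spike_regression <- function(counts, mix, pooled = FALSE) {
  sp <- intersect(rownames(counts), mix$spike_id)
  if (length(sp) < 3) stopf("fewer than 3 spike-in rows in the count matrix")
  conc <- mix$conc_attomol_per_ul[match(sp, mix$spike_id)]
  spk <- counts[sp, , drop = FALSE]
  one_fit <- function(y, x) {
    use <- y > 0
    if (sum(use) < 3) return(NULL)
    fit <- stats::lm(log10(y[use]) ~ log10(x[use]))
    ## exact synthetic fits trigger a benign "perfect fit" warning
    r2 <- if (stats::var(log10(y[use])) == 0) 1 else
      suppressWarnings(summary(fit)$r.squared)
    unname(c(stats::coef(fit)[2], stats::coef(fit)[1], r2, sum(use)))
  }
  if (pooled) {
    f <- one_fit(as.vector(spk), rep(conc, ncol(spk)))
    if (is.null(f)) stopf("fewer than 3 usable spike-ins in pooled fit")
    res <- data.frame(sample = colnames(counts), slope = f[1],
                      intercept = f[2], r_squared = f[3], n_spikes = f[4])
  } else {
    res <- do.call(rbind, lapply(colnames(spk), function(s) {
      f <- one_fit(spk[, s], conc)
      if (is.null(f))
        stopf("fewer than 3 spike-ins with nonzero counts in sample %s", s)
      data.frame(sample = s, slope = f[1], intercept = f[2],
                 r_squared = f[3], n_spikes = f[4])
    }))
  }
  rownames(res) <- NULL
  res
}

#' Absolute quantification in attomoles per worm
#'
#' Inverts the per-sample spike regression: counts map to attomoles/uL via
#' 10^((log10(count) - intercept)/slope) (zero counts map to 0), then to
#' attomoles per worm via the spike volume and the worms-per-sample recorded
#' in the sample sheet.
#'
#' @param counts count matrix; only non-spike rows are converted.
#' @param fit per-sample regression table from [fit_spike_regression()].
#' @param sheet sample sheet with `sample_id`, `worms_per_sample`,
#'   `spike_volume_ul`.
#' @return gene x sample matrix, unit `attomol_per_worm`.
#' @export
to_attomoles_per_worm <- function(counts, fit, sheet) {
  need <- c("sample_id", "worms_per_sample", "spike_volume_ul")
  if (!all(need %in% names(sheet)))
    stopf("sample sheet lacks field(s): %s",
          paste(setdiff(need, names(sheet)), collapse = ", "))
  if (any(fit$slope == 0)) stopf("spike regression slope of 0 cannot be inverted")
  genes <- counts[!is_spike(counts), , drop = FALSE]
  idx <- match(colnames(genes), sheet$sample_id)
  if (anyNA(idx)) stopf("samples missing from sheet")
  fidx <- match(colnames(genes), fit$sample)
  if (anyNA(fidx)) stopf("samples missing from spike fit")
  out <- genes
  for (j in seq_len(ncol(genes))) {
    y <- genes[, j]
    amol_ul <- ifelse(y > 0,
                      10^((log10(pmax(y, 1e-300)) - fit$intercept[fidx[j]]) /
                            fit$slope[fidx[j]]),
                      0)
    out[, j] <- amol_ul * sheet$spike_volume_ul[idx[j]] /
      sheet$worms_per_sample[idx[j]]
  }
  new_expression_matrix(out, "attomol_per_worm")
}

#' Proportion of reads mapping to spike-ins
#'
#' A proxy for the mRNA-to-total-RNA ratio: spike-ins are added per unit of
#' total RNA, so their read share rises when the mRNA pool shrinks (e.g.
#' when somatic transcription is abolished).
#'
#' @param counts count matrix with spike rows flagged by `"ERCC-"` prefix.
#' @return named per-sample proportion in `[0, 1]`.
#' @export
spike_read_proportion <- function(counts) {
  sp <- is_spike(counts)
  colSums(counts[sp, , drop = FALSE]) / colSums(counts)
}
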