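## Expression filtering, negative-binomial GLM likelihood-ratio tests
## (time-course "ANOVA-like" and pairwise with log2 fold changes),
## Benjamini-Hochberg FDR, PCA of samples, and the rate-of-change statistic.
##
## The NB machinery is self-contained: per-gene IRLS with a log link and a
## log-library-size offset, dispersion estimated per gene by a Pearson
## moment estimator and shrunk 50/50 toward a mean-dispersion trend
## (floor 1e-8, cap 10). The LRT compares the full model against a reduced
## model without the group coefficients, with a chi-squared reference.

#' Filter to expressed genes
#'
#' CPM mode keeps genes with CPM strictly greater than `threshold` in at
#' least `min_libs` libraries (time-series default: CPM > 1 in >= 4); count
#' mode uses raw counts (degron-experiment default: counts > 10 in >= 4).
#' Spike-in rows are never returned.
#'
#' @param counts gene x sample count matrix.
#' @param threshold CPM or count threshold (strict >).
#' @param min_libs minimum number of libraries meeting the threshold.
#' @param mode `"cpm"` or `"count"`.
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(counts, threshold = 1, min_libs = 4,
                             mode = c("cpm", "count")) {
  mode <- match.arg(mode)
  if (min_libs > ncol(counts)) stopf("min_libs exceeds the number of samples")
  vals <- if (mode == "cpm") cpm(counts) else counts
  keep <- rowSums(vals > threshold) >= min_libs
  rownames(counts)[keep & !is_spike(counts)]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH q-values. NA/NaN p-values propagate as NA and are
#' excluded from the number of tests m.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(q)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(ok)
  o <- order(p[ok])                       # stable ties
  ranked <- p[ok][o] * m / seq_len(m)
  q[ok[o]] <- pmin(1, rev(cummin(rev(ranked))))
  q
}

## ---- NB GLM internals -------------------------------------------------

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-12) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

## IRLS fit of an NB log-linear model with fixed dispersion phi and offset.
## Returns coefficients, fitted mu, log-likelihood, convergence flag.
nb_glm_fit <- function(y, X, offset, phi, maxit = 100, tol = 1e-8) {
  mu <- pmax(y, 0.5) + mean(y) / 10
  eta <- log(mu) - offset
  beta <- NULL
  ll_old <- -Inf
  conv <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)       # guard against divergence
    mu <- exp(eta + offset)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      conv <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(beta = beta, mu = mu, loglik = ll_old, converged = conv)
}

## Pearson moment dispersion: solve sum (y-mu)^2/(mu + phi mu^2) = n - p
## by bisection; mu from a Poisson fit of the full design.
moment_dispersion <- function(y, mu, resid_df) {
  pearson <- function(phi) sum((y - mu)^2 / (mu + phi * mu^2))
  if (pearson(0) <= resid_df) return(0)
  lo <- 0; hi <- 10
  if (pearson(hi) > resid_df) return(hi)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (pearson(mid) > resid_df) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Per-gene dispersions shrunk toward a binned-median trend on mean count.
estimate_dispersions <- function(counts, X, offsets, shrink = 0.5,
                                 floor = 1e-8, cap = 10) {
  n <- ncol(counts); p <- qr(X)$rank
  raw <- numeric(nrow(counts))
  means <- rowMeans(counts)
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    fit <- nb_glm_fit(y, X, offsets, phi = 0)
    raw[g] <- if (is.null(fit$beta)) NA else moment_dispersion(y, fit$mu, n - p)
  }
  ok <- !is.na(raw)
  trend <- rep(stats::median(raw[ok]), length(raw))
  if (sum(ok) >= 50) {
    br <- unique(stats::quantile(log(means[ok] + 1), probs = seq(0, 1, 0.05)))
    if (length(br) > 2) {
      bin <- cut(log(means + 1), br, include.lowest = TRUE)
      med <- tapply(raw[ok], bin[ok], stats::median)
      trend <- med[as.character(bin)]
      trend[is.na(trend)] <- stats::median(raw[ok])
    }
  }
  disp <- pmin(pmax(shrink * ifelse(ok, raw, trend) + (1 - shrink) * trend,
                    floor), cap)
  unname(disp)
}

## Shared LRT engine: full design vs reduced design.
nb_lrt <- function(counts, X_full, X_red, offsets, df,
                   fc_coef = NULL) {
  assert_count_matrix(counts)
  disp <- estimate_dispersions(counts, X_full, offsets)
  n_genes <- nrow(counts)
  stat <- p <- lfc <- rep(NA_real_, n_genes)
  n_fail <- 0
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    f_full <- nb_glm_fit(y, X_full, offsets, disp[g])
    f_red <- nb_glm_fit(y, X_red, offsets, disp[g])
    if (is.null(f_full$beta) || is.null(f_red$beta) ||
        !f_full$converged || !f_red$converged) {
      n_fail <- n_fail + 1
      next
    }
    stat[g] <- max(0, 2 * (f_full$loglik - f_red$loglik))
    p[g] <- stats::pchisq(stat[g], df, lower.tail = FALSE)
    if (!is.null(fc_coef)) lfc[g] <- f_full$beta[fc_coef] / log(2)
  }
  if (n_fail > 0)
    warning(sprintf("%d gene(s) failed to converge; p set to NA", n_fail))
  cpm_mat <- sweep(counts, 2, exp(offsets), `/`) * 1e6
  res <- data.frame(
    gene_id = rownames(counts),
    lrt_statistic = stat, df = df, p = p, q = bh_adjust(p),
    mean_log2cpm = rowMeans(log2(cpm_mat + 1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(fc_coef)) res$log2FC <- lfc
  res$dispersion <- disp
  rownames(res) <- NULL
  res
}

make_offsets <- function(counts, norm_factors = NULL) {
  lib <- colSums(counts)
  if (!is.null(norm_factors)) {
    nf <- norm_factors[colnames(counts)]
    if (anyNA(nf)) stopf("norm_factors missing for some samples")
    lib <- lib * nf
  }
  log(lib)
}

covariate_matrix <- function(covariates, samples) {
  if (is.null(covariates)) return(NULL)
  W <- if (inherits(covariates, "arrest_uvfactor")) covariates$W else
    as.matrix(covariates)
  W <- W[samples, , drop = FALSE]
  W
}

#' Time-course likelihood-ratio test
#'
#' Per gene, an NB log-linear model with one coefficient per group (time
#' point) plus optional covariates and a log-library-size offset is compared
#' against a reduced model without the group coefficients: an ANOVA-like
#' test for any difference across the time points, with
#' df = (number of groups - 1).
#'
#' @param counts gene x sample count matrix (genes only; filter first).
#' @param groups per-sample group labels (e.g. time points).
#' @param covariates optional `arrest_uvfactor` or numeric matrix of
#'   per-sample covariates.
#' @param norm_factors optional per-sample scale factors (e.g. upper
#'   quartile); offsets become log(library size x factor).
#' @return a DETable data.frame: `gene_id`, `lrt_statistic`, `df`, `p`,
#'   `q` (BH), `mean_log2cpm`, `dispersion`.
#' @export
lrt_timecourse <- function(counts, groups, covariates = NULL,
                           norm_factors = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("need at least 2 replicates per group")
  W <- covariate_matrix(covariates, colnames(counts))
  X_full <- stats::model.matrix(~groups)
  X_red <- stats::model.matrix(~1, data.frame(row.names = colnames(counts)))
  if (!is.null(W)) {
    X_full <- cbind(X_full, W)
    X_red <- cbind(X_red, W)
  }
  nb_lrt(counts, X_full, X_red, make_offsets(counts, norm_factors),
         df = nlevels(groups) - 1)
}

#' Pairwise likelihood-ratio test with log2 fold change
#'
#' As [lrt_timecourse()] with two groups (df = 1); `log2FC` is the B-vs-A
#' coefficient on the log2 scale (positive = higher in B).
#'
#' @param counts gene x sample count matrix restricted to the two groups.
#' @param group_a,group_b sample ids of conditions A (reference) and B.
#' @inheritParams lrt_timecourse
#' @return DETable data.frame including `log2FC`.
#' @export
lrt_pairwise <- function(counts, group_a, group_b, covariates = NULL,
                         norm_factors = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("both groups must be non-empty")
  samples <- c(group_a, group_b)
  if (!all(samples %in% colnames(counts)))
    stopf("sample ids missing from count matrix")
  counts <- counts[, samples, drop = FALSE]
  grp <- factor(rep(c("A", "B"), c(length(group_a), length(group_b))),
                levels = c("A", "B"))
  W <- covariate_matrix(covariates, samples)
  X_full <- stats::model.matrix(~grp)
  X_red <- X_full[, 1, drop = FALSE]
  if (!is.null(W)) {
    X_full <- cbind(X_full, W)
    X_red <- cbind(X_red, W)
  }
  nb_lrt(counts, X_full, X_red, make_offsets(counts, norm_factors),
         df = 1, fc_coef = 2)
}

#' Principal-component scores of samples
#'
#' PCA of samples over genes on an already gene-centered matrix (no further
#' centering or scaling). Sign convention: for each component the
#' largest-magnitude gene loading is made positive, so scores are
#' reproducible rather than sign-arbitrary.
#'
#' @param expr gene x sample matrix (log2 mean-normalized CPM).
#' @return list: `scores` (samples x PC), `var_explained`, `loadings`.
#' @export
pca_scores <- function(expr) {
  if (ncol(expr) < 3) stopf("need at least 3 samples")
  X <- t(expr)
  if (sum(X^2) == 0 || all(apply(X, 2, stats::var) == 0))
    stopf("matrix has no variance")
  sv <- svd(X)
  d2 <- sv$d^2
  keep <- which(d2 / sum(d2) > 1e-12)
  flip <- vapply(keep, function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                                      length(keep)), 2, flip, `*`)
  loadings <- sweep(sv$v[, keep, drop = FALSE], 2, flip, `*`)
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_along(keep)))
  dimnames(loadings) <- list(rownames(expr), paste0("PC", seq_along(keep)))
  list(scores = scores, var_explained = d2[keep] / sum(d2),
       loadings = loadings)
}

#' Rate of change of expression between adjacent time points
#'
#' For each adjacent pair of time points, the Euclidean distance between
#' sample expression profiles is averaged over all cross-time replicate
#' pairs (or between time-point centroids with `mode = "centroid"`) and
#' divided by the elapsed time.
#'
#' @param expr gene x sample matrix (same basis as the PCA input).
#' @param sheet sample sheet with `sample_id` and `time_h`.
#' @param mode `"pairs"` (mean over cross-replicate pairs) or `"centroid"`.
#' @return data.frame: `t_from`, `t_to`, `delta_h`, `distance`, `rate`.
#' @export
rate_of_change <- function(expr, sheet, mode = c("pairs", "centroid")) {
  mode <- match.arg(mode)
  times <- sheet$time_h[match(colnames(expr), sheet$sample_id)]
  if (anyNA(times)) stopf("samples missing from sheet")
  tp <- sort(unique(times))
  if (length(tp) < 2) stopf("need at least 2 time points")
  out <- lapply(seq_len(length(tp) - 1), function(i) {
    a <- expr[, times == tp[i], drop = FALSE]
    b <- expr[, times == tp[i + 1], drop = FALSE]
    d <- if (mode == "centroid") {
      sqrt(sum((rowMeans(a) - rowMeans(b))^2))
    } else {
      mean(apply(a, 2, function(x)
        apply(b, 2, function(y) sqrt(sum((x - y)^2)))))
    }
    dt <- tp[i + 1] - tp[i]
    data.frame(t_from = tp[i], t_to = tp[i + 1], delta_h = dt,
               distance = d, rate = d / dt)
  })
  do.call(rbind, out)
}
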