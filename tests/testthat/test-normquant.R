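toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(as.integer(values), nrow = length(genes %||% rownames(values)))
  matrix(as.integer(values),
         nrow = length(genes),
         dimnames = list(genes, samples))
}

test_that("cpm matches hand arithmetic and flags empty libraries", {
  m <- matrix(as.integer(c(13, 0, 2, 8)), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cp <- cpm(m)
  expect_equal(unname(cp["g1", "s1"]), 1e6)   # whole library
  expect_equal(unname(cp["g2", "s1"]), 0)
  expect_equal(unname(cp[, "s2"]), c(2e5, 8e5))
  expect_equal(unname(colSums(cp)), c(1e6, 1e6))
  bad <- matrix(c(0L, 0L, 1L, 1L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(cpm(bad), "s1")
})

test_that("cpm library basis excludes spikes when asked", {
  m <- matrix(as.integer(c(90, 10, 40, 60)), 2, 2,
              dimnames = list(c("g1", "ERCC-00001"), c("s1", "s2")))
  cp <- cpm(m, exclude_spikes = TRUE)
  expect_equal(unname(cp["g1", ]), c(1e6, 1e6))   # basis = gene rows only
  cp2 <- cpm(m, exclude_spikes = FALSE)
  expect_equal(unname(cp2["g1", ]), c(9e5, 4e5))
})

test_that("log2 mean-centering gives zero-mean rows and hand values", {
  cp <- matrix(c(1, 7, 5, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lg <- log2_mean_centered(cp, pseudocount = 1)
  expect_equal(unname(lg["g1", ]), c(-1, 1))      # log2(2), log2(8) centered
  expect_equal(unname(lg["g2", ]), c(0, 0))       # constant gene
  expect_true(all(abs(rowMeans(lg)) < 1e-12))
  expect_error(log2_mean_centered(cp, pseudocount = 0), "pseudocount")
})

test_that("upper-quartile factors: symmetry, scaling and the quantile
           convention", {
  m <- matrix(as.integer(rep(c(10, 20, 30, 40, 50), 2)), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  expect_equal(unname(upper_quartile_factors(m)), c(1, 1))
  m2 <- m; m2[, 2] <- 2L * m2[, 2]
  f <- upper_quartile_factors(m2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  ## linear-interpolation percentile against a sort-based oracle on 8 values
  x <- as.integer(c(3, 14, 8, 22, 5, 17, 11, 40))
  m3 <- matrix(rep(x, 2), ncol = 2,
               dimnames = list(paste0("g", 1:8), c("a", "b")))
  xs <- sort(x)
  h <- (8 - 1) * 0.75 + 1
  oracle <- xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
  raw_uq <- stats::quantile(x[x > 0], 0.75, names = FALSE)
  expect_equal(raw_uq, oracle)
  expect_equal(unname(upper_quartile_factors(m3)), c(1, 1))
  thin <- matrix(as.integer(c(1, 0, 0, 2, 0, 0)), ncol = 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_error(upper_quartile_factors(thin), "fewer than 4")
})

test_that("unwanted-variation factor recovers a planted sample offset", {
  set.seed(21)
  offset <- rnorm(6, sd = 1)
  controls <- matrix(rnorm(10 * 6, sd = 0.05), 10, 6) +
    outer(runif(10, 0.5, 1.5), offset)
  rownames(controls) <- paste0("c", 1:10)
  colnames(controls) <- paste0("s", 1:6)
  uv <- unwanted_variation_factor(controls, rownames(controls), k = 1)
  expect_equal(sum(uv$W[, 1]^2), 1)                 # unit norm
  expect_gt(abs(cor(uv$W[, 1], offset)), 0.99)
  ## independent dense SVD oracle via eigen decomposition
  M <- controls - rowMeans(controls)
  v1 <- eigen(crossprod(M))$vectors[, 1]
  expect_equal(abs(cor(uv$W[, 1], v1)), 1, tolerance = 1e-8)
  ## constant controls give a zero factor
  const <- matrix(5, 5, 6, dimnames = list(paste0("c", 1:5), paste0("s", 1:6)))
  expect_equal(unname(unwanted_variation_factor(const, rownames(const))$W[, 1]),
               rep(0, 6))
  expect_error(unwanted_variation_factor(controls, rownames(controls), k = 6),
               "smaller than the number of samples")
  expect_error(unwanted_variation_factor(controls, paste0("c", 1:2), k = 1),
               "at least k \\+ 2")
})

test_that("sign of the unwanted factor does not change LRT p-values", {
  ds <- small_aid()
  sub <- ds$samples$sample_id[ds$samples$strain == "soma_TIR1_AID" &
                                ds$samples$time_h == 132]
  counts <- ds$counts[!is_spike(ds$counts), sub][1:50, ]
  a <- ds$samples$sample_id[ds$samples$strain == "soma_TIR1_AID" &
                              ds$samples$time_h == 132 &
                              ds$samples$treatment == "ethanol"]
  b <- setdiff(sub, a)
  uv <- unwanted_variation_factor(log(ds$counts[, sub] + 1),
                                  rownames(ds$counts)[is_spike(ds$counts)])
  uv_flip <- uv
  uv_flip$W <- -uv$W
  t1 <- lrt_pairwise(counts, a, b, covariates = uv)
  t2 <- lrt_pairwise(counts, a, b, covariates = uv_flip)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
})

test_that("spike regression reproduces exact and degenerate fits", {
  m <- matrix(as.integer(c(5, 50, 500, 7, 7, 7)), 3, 2,
              dimnames = list(sprintf("ERCC-%05d", 1:3), c("s1", "s2")))
  mix <- data.frame(spike_id = sprintf("ERCC-%05d", 1:3),
                    conc_attomol_per_ul = c(1, 10, 100))
  fit <- fit_spike_regression(m, mix)
  expect_equal(fit$slope[1], 1)
  expect_equal(fit$intercept[1], log10(5))
  expect_equal(fit$r_squared[1], 1)
  expect_equal(fit$slope[2], 0)                    # constant counts
  expect_equal(fit$n_spikes, c(3, 3))
  m0 <- m; m0[2:3, 1] <- 0L
  expect_error(fit_spike_regression(m0, mix), "s1")
  pooled <- fit_spike_regression(m, mix, pooled = TRUE)
  expect_equal(length(unique(pooled$slope)), 1)
})

test_that("attomoles per worm inverts the regression by hand", {
  m <- matrix(as.integer(c(50, 0)), 2, 1,
              dimnames = list(c("g1", "g2"), "s1"))
  fit <- data.frame(sample = "s1", slope = 1, intercept = log10(5),
                    r_squared = 1, n_spikes = 10)
  sheet <- data.frame(sample_id = "s1", worms_per_sample = 4,
                      spike_volume_ul = 2)
  am <- to_attomoles_per_worm(m, fit, sheet)
  expect_equal(unname(am["g1", 1]), 5)             # 10 amol/uL * 2 uL / 4 worms
  expect_equal(unname(am["g2", 1]), 0)
  expect_error(to_attomoles_per_worm(m, transform(fit, slope = 0), sheet),
               "slope")
  expect_error(to_attomoles_per_worm(m, fit, sheet[, 1, drop = FALSE]),
               "lacks field")
})

test_that("spike read proportion is a simple share and relabel-invariant", {
  m <- matrix(as.integer(c(900, 100)), 2, 1,
              dimnames = list(c("g1", "ERCC-00001"), "s1"))
  expect_equal(unname(spike_read_proportion(m)), 0.1)
  m2 <- m; m2["ERCC-00001", 1] <- 0L
  expect_equal(unname(spike_read_proportion(m2)), 0)
  m3 <- m; m3["g1", 1] <- 0L
  expect_equal(unname(spike_read_proportion(m3)), 1)
  perm <- m[c(2, 1), , drop = FALSE]
  expect_equal(spike_read_proportion(perm), spike_read_proportion(m))
})

test_that("spike regression and absolute quantification recover the
           generator truth", {
  ds <- small_aid()
  ## slope 1 on noiseless expected counts
  sh <- expected_read_shares(ds$truth, ds$spikes)
  exp_counts <- round(sh * ds$design$library_depth)
  storage.mode(exp_counts) <- "integer"
  fit_exp <- fit_spike_regression(exp_counts, ds$spikes)
  expect_true(all(abs(fit_exp$slope - 1) < 0.05))
  ## noiseless per-worm estimates invert the generator within 2 % for
  ## genes with expected count >= 10
  am <- to_attomoles_per_worm(exp_counts, fit_exp, ds$samples)
  tru <- ds$truth$abundance[rownames(am), colnames(am)]
  sel <- exp_counts[rownames(am), ] >= 10 & tru > 0
  rel <- abs(am * 6.02214076e5 - tru) / tru
  expect_lt(max(rel[sel]), 0.02)
  ## sampled counts: slope within 0.1, Spearman > 0.95 against truth
  fit_obs <- fit_spike_regression(ds$counts, ds$spikes)
  expect_true(all(abs(fit_obs$slope - 1) < 0.1))
  am_obs <- to_attomoles_per_worm(ds$counts, fit_obs, ds$samples)
  use <- tru > 0 & am_obs > 0
  expect_gt(cor(am_obs[use], tru[use], method = "spearman"), 0.95)
})
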