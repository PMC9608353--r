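## Shared fixtures and independent oracles. Expensive simulations are built
## once per test run and cached here; all fixtures are generated in code.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## small datasets for module-level tests
small_ts <- function() cached("small_ts", simulate_timeseries(300, seed = 11))
small_aid <- function() cached("small_aid", simulate_aid(300, seed = 12))

## full-scale datasets and runs for the acceptance criteria
full_ts <- function() cached("full_ts", simulate_timeseries(2000, seed = 1))
full_aid <- function() cached("full_aid", simulate_aid(2000, seed = 1))
full_aid_run <- function() cached("full_aid_run", {
  ds <- full_aid()
  dir <- tempfile("aidsim")
  write_dataset(ds, dir)
  run_aid(aid_config(file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"),
                     file.path(dir, "spikes.tsv"),
                     out_dir = tempfile("aidrun")))
})

## mean CPM per time point over replicates (clustering input space)
mean_cpm_profiles <- function(counts, sheet, genes = NULL) {
  cp <- cpm(counts)
  if (!is.null(genes)) cp <- cp[genes, , drop = FALSE]
  else cp <- cp[!is_spike(cp), , drop = FALSE]
  times <- sheet$time_h[match(colnames(cp), sheet$sample_id)]
  t(apply(cp, 1, function(x) tapply(x, times, mean)))
}

## adjusted Rand index (independent of any clustering internals)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## brute-force diameter check of a clustering against its distance matrix
max_within_cluster_distance <- function(dist, cluster) {
  m <- 0
  for (ci in unique(cluster)) {
    idx <- which(cluster == ci)
    if (length(idx) > 1) m <- max(m, max(dist[idx, idx]))
  }
  m
}

## step-up FDR oracle: literal definition, quadratic time
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(vapply(i:m, function(j) p[o[j]] * m / j,
                                 numeric(1))))
  }
  q
}

## exhaustive hypergeometric upper tail by enumerating all draws (N <= 12)
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inK <- colSums(draws <= K)      # treat genes 1..K as the cluster
  mean(inK >= k)
}

## two-sample KS statistic by direct ECDF sweep
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

## forward-Euler integration of da/dt = s(t) - k a (trajectory oracle)
euler_trajectory <- function(gene, t_grid, shutdown_time = NULL, dt = 0.001) {
  gene <- as.list(gene)
  k <- log(2) / gene$decay_halflife
  hv <- gene$s_halving
  hv <- if (is.null(hv) || is.na(hv)) Inf else hv
  t0 <- if (is.null(shutdown_time)) Inf else shutdown_time
  s_at <- function(t) {
    if (t >= t0 || t >= gene$t_off) return(0)
    base <- if (!is.na(gene$burst_end) && t < gene$burst_end)
      gene$burst_rate else gene$s0
    if (is.finite(hv)) base * 2^(-t / hv) else base
  }
  tt <- seq(0, max(t_grid), by = dt)
  a <- numeric(length(tt))
  a[1] <- gene$a0
  for (i in seq_along(tt)[-1])
    a[i] <- a[i - 1] + dt * (s_at(tt[i - 1]) - k * a[i - 1])
  a[vapply(t_grid, function(x) which.min(abs(tt - x)), integer(1))]
}
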