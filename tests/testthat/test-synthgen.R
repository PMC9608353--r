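test_that("gene catalog validates inputs and is deterministic", {
  expect_error(make_gene_catalog(0), "at least 10")
  expect_error(make_gene_catalog(100, fractions = c(early_peak = 0.6,
                                                    flat = 0.5)),
               "sum to 1")
  expect_error(make_gene_catalog(100, fractions = c(bogus = 1)),
               "unknown archetype")
  c1 <- make_gene_catalog(1000, seed = 1)
  c2 <- make_gene_catalog(1000, seed = 1)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_gene_catalog(1000, seed = 2)))
})

test_that("archetype draws match the recorded RNG stream", {
  fr <- c(early_peak = 0.5, monotone_up_stable = 0.5)
  cat <- make_gene_catalog(200, fractions = fr, seed = 7)
  set.seed(7)
  expected <- sample(names(fr), 200, replace = TRUE, prob = fr)
  expect_identical(cat$archetype, expected)
  ## roughly balanced split
  expect_gt(sum(cat$archetype == "early_peak"), 70)
  expect_lt(sum(cat$archetype == "early_peak"), 130)
})

test_that("catalog invariants hold", {
  cat <- make_gene_catalog(2000, seed = 3)
  expect_true(all(cat$decay_halflife > 0))
  germ <- cat$archetype == "monotone_up_stable"
  expect_true(all(cat$compartment[germ] == "germline"))
  expect_true(all(cat$s0[germ] == 0))
  ## germline half-life at least 5x the soma median
  soma_med <- median(cat$decay_halflife[cat$compartment != "germline"])
  expect_true(all(cat$decay_halflife[germ] >= 5 * soma_med))
  ## transcription dependence is a pure soma property with ongoing s(t)
  expect_identical(cat$transcription_dependent,
                   cat$compartment == "soma" & cat$s0 > 0 & cat$t_off > 36)
  expect_false(any(cat$transcription_dependent[cat$compartment == "muscle"]))
})

test_that("abundance trajectories follow the birth-death closed forms", {
  decay <- list(gene_id = "g", compartment = "germline",
                archetype = "monotone_up_stable", s0 = 0, burst_rate = NA,
                burst_end = NA, t_off = 0, s_halving = Inf,
                decay_halflife = 1, a0 = 100)
  expect_equal(abundance_trajectory(decay, c(0, 1, 2)), c(100, 50, 25))
  expect_error(abundance_trajectory(decay, c(-1, 2)), "negative time")
  expect_error(abundance_trajectory(decay, c(3, 2)), "ascending")

  ## constant transcription approaches the steady state s/k
  flat <- list(gene_id = "g", compartment = "soma", archetype = "flat",
               s0 = 7, burst_rate = NA, burst_end = NA, t_off = Inf,
               s_halving = Inf, decay_halflife = 2, a0 = 0)
  k <- log(2) / 2
  expect_equal(abundance_trajectory(flat, 1000), 7 / k, tolerance = 1e-10)
})

test_that("shutdown gives exact exponential decay and matches Euler oracle", {
  cat <- make_gene_catalog(50, seed = 5)
  ep <- cat[cat$archetype == "early_peak", ][1, ]
  tr <- abundance_trajectory(ep, c(36, 60, 132), shutdown_time = 36)
  expect_equal(tr[2], tr[1] * 2^(-(60 - 36) / ep$decay_halflife))
  expect_equal(tr[3], tr[1] * 2^(-96 / ep$decay_halflife))
  ## closed form vs fine-step numerical integration, with and without
  ## shutdown, for every archetype (incl. the decaying-rate flat gene)
  for (arch in unique(cat$archetype)) {
    g <- cat[cat$archetype == arch, ][1, ]
    grid <- c(6, 36, 132)
    expect_equal(abundance_trajectory(g, grid),
                 euler_trajectory(g, grid), tolerance = 1e-3)
    expect_equal(abundance_trajectory(g, grid, shutdown_time = 36),
                 euler_trajectory(g, grid, shutdown_time = 36),
                 tolerance = 1e-3)
  }
})

test_that("sample_counts splits reads evenly for two equal expected shares", {
  worms <- 10
  a <- 1000                              # molecules/worm for the one gene
  vol <- 2
  conc <- a * worms / (vol * 6.02214076e5)  # spike molecules == gene molecules
  truth <- structure(list(
    genes = data.frame(gene_id = "gene00001"),
    abundance = matrix(a, 1, 1, dimnames = list("gene00001", "s1")),
    samples = data.frame(sample_id = "s1", strain = "N2", treatment = "none",
                         time_h = 0, replicate = 1, worms_per_sample = worms,
                         spike_volume_ul = vol, total_rna_ng = 100)
  ), class = "arrest_truth")
  mix <- data.frame(spike_id = "ERCC-00001", conc_attomol_per_ul = conc,
                    volume_ul = vol)
  design <- structure(list(samples = truth$samples, library_depth = 1e6),
                      class = "arrest_design")
  drawn <- sample_counts(truth, design, mix, overdispersion = 0,
                         spike_noise_sd = 0, seed = 1)
  expect_equal(sum(drawn$counts), 1e6)
  expect_equal(unname(drawn$counts["gene00001", 1]), 5e5,
               tolerance = 5 * sqrt(2.5e5) / 5e5)
})

test_that("library totals are exact and draws are seed-deterministic", {
  ds <- small_ts()
  expect_true(all(colSums(ds$counts) == ds$design$library_depth))
  d2 <- simulate_timeseries(300, seed = 11)
  expect_identical(ds$counts, d2$counts)
  d3 <- simulate_timeseries(300, seed = 13)
  expect_false(identical(ds$counts, d3$counts))
})

test_that("soma shutdown raises the spike read share as predicted by the
           expected-share oracle", {
  ds <- small_aid()
  sh <- expected_read_shares(ds$truth, ds$spikes)
  spike_rows <- is_spike(sh)
  exp_prop <- colSums(sh[spike_rows, ])
  sm <- ds$samples
  soma_aux <- sm$strain == "soma_TIR1_AID" & sm$treatment == "auxin"
  etoh132 <- sm$treatment == "ethanol" & sm$time_h == 132
  expect_gt(min(exp_prop[soma_aux]), max(exp_prop[etoh132]))
  ## observed counts reproduce the analytic prediction (no spike noise)
  drawn <- sample_counts(ds$truth, ds$design, ds$spikes,
                         overdispersion = 0.05, spike_noise_sd = 0, seed = 4)
  obs_prop <- spike_read_proportion(drawn$counts)
  expect_equal(unname(obs_prop), unname(exp_prop), tolerance = 0.1)
  expect_gt(mean(obs_prop[soma_aux]), mean(obs_prop[etoh132]))
})

test_that("truth tables encode the stated starvation biology", {
  ds <- small_aid()
  tru <- ds$truth$samples
  ## two-fold total-RNA decline per worm between 36 h and 132 h
  fold <- mean(tru$total_rna_ng_per_worm[tru$time_h == 36]) /
    mean(tru$total_rna_ng_per_worm[tru$time_h == 132])
  expect_equal(fold, 2, tolerance = 1e-10)
  ## mRNA:total-RNA ratio approximately constant under solvent
  r36 <- mean(tru$mrna_total_rna_ratio[tru$time_h == 36])
  r132 <- mean(tru$mrna_total_rna_ratio[tru$time_h == 132 &
                                          tru$treatment == "ethanol"])
  expect_lt(abs(log(r132 / r36)), log(1.35))
  ## germline CPM rises 36 -> 132 even with all transcription off, while
  ## soma molecules/worm decline (from the truth alone)
  cat <- ds$truth$genes
  all_off <- t(vapply(seq_len(nrow(cat)), function(g)
    abundance_trajectory(cat[g, ], c(36, 132), shutdown_time = 36),
    numeric(2)))
  share <- sweep(all_off, 2, colSums(all_off), `/`)
  germ <- cat$compartment == "germline"
  expect_true(all(share[germ, 2] > share[germ, 1]))
  soma <- cat$compartment != "germline"
  expect_true(all(all_off[soma, 2] < all_off[soma, 1]))
})

test_that("datasets round-trip losslessly through the writers and readers", {
  ds <- small_ts()
  dir <- tempfile("roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$counts, ds$counts, ignore_attr = TRUE)
  expect_equal(back$samples, ds$samples, ignore_attr = TRUE)
  expect_equal(back$spikes$conc_attomol_per_ul,
               ds$spikes$conc_attomol_per_ul)
  expect_equal(back$truth$abundance, ds$truth$abundance)
  ## GMT: one record per compartment
  sets <- read_gmt(file.path(dir, "genesets.gmt"))
  expect_setequal(names(sets), unique(ds$truth$genes$compartment))
  for (nm in names(sets))
    expect_setequal(sets[[nm]]$genes,
                    ds$truth$genes$gene_id[ds$truth$genes$compartment == nm])
  ## identical seed and config give byte-identical files
  dir2 <- tempfile("roundtrip2")
  write_dataset(simulate_timeseries(300, seed = 11), dir2)
  for (f in list.files(dir)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))), label = f)
  }
})

test_that("default fixtures match the stated design", {
  mix <- default_spike_mix()
  expect_equal(nrow(mix), 92)
  expect_equal(length(unique(mix$spike_id)), 92)
  expect_true(all(mix$conc_attomol_per_ul > 0))
  expect_gte(max(mix$conc_attomol_per_ul) / min(mix$conc_attomol_per_ul), 1e4)
  expect_equal(length(default_timepoints()), 12)
  expect_equal(nrow(timeseries_design()$samples), 48)
  aid <- aid_design()$samples
  expect_equal(nrow(aid), 48)
  expect_equal(length(unique(aid$strain)), 4)
  expect_error(build_truth(make_gene_catalog(10),
                           structure(list(samples = data.frame()),
                                     class = "arrest_design")),
               "empty design")
})
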