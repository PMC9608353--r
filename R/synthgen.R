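## Synthetic data generator
##
## Emulates whole-worm mRNA-seq of starvation-arrested L1 larvae: per-gene
## linear birth-death mRNA dynamics da/dt = s(t) - k*a with archetype-specific
## piecewise transcription profiles s(t), a transcriptionally quiescent but
## stable germline, ongoing somatic transcription that can be abolished
## per-compartment (auxin-inducible degron), a deterministic two-fold decline
## in total RNA per worm between 36 h and 132 h, and spike-in standards added
## in proportion to total RNA. Counts are gamma-mixed multinomial draws
## (negative-binomial-like marginally) with library totals fixed exactly.

ARCHETYPES <- c("early_peak", "monotone_down", "monotone_up_stable", "flat")
COMPARTMENTS <- c("soma", "germline", "muscle")

#' Default sampling times of the starvation time series (hours after hatch)
#'
#' Twelve time points, dense in the first day when expression dynamics are
#' fast and sparse thereafter, extending to day 12 when most larvae die.
#'
#' @return numeric vector of 12 times in hours.
#' @export
default_timepoints <- function() {
  c(0, 2, 4, 6, 12, 24, 48, 72, 96, 144, 192, 288)
}

#' Default spike-in mix
#'
#' A pool of 92 synthetic spike-in species at known concentrations spanning
#' four orders of magnitude (log-uniform grid), totalling ~8 attomoles/uL so
#' that at the default added volume the spike-ins draw a realistic few percent
#' of reads.
#'
#' @param n_spikes number of species (default 92).
#' @param total_conc total concentration over all species, attomoles/uL.
#' @param volume_ul volume of mix added per sample (uL).
#' @return data.frame with `spike_id`, `conc_attomol_per_ul`, `volume_ul`.
#' @export
default_spike_mix <- function(n_spikes = 92, total_conc = 8, volume_ul = 2) {
  w <- 10^seq(-2, 2, length.out = n_spikes)
  data.frame(
    spike_id = sprintf("ERCC-%05d", seq_len(n_spikes)),
    conc_attomol_per_ul = total_conc * w / sum(w),
    volume_ul = volume_ul,
    stringsAsFactors = FALSE
  )
}

#' Experimental designs
#'
#' `timeseries_design()` describes the starvation time course: one wild-type
#' strain sampled at 12 time points with 4 replicates. `aid_design()` describes
#' the auxin-inducible-degron (AID) experiment: four strains (TIR1-only
#' controls and TIR1 + AID-tagged RNA Pol II for soma and germline), each
#' sampled at a 36 h baseline and at 132 h after continuous exposure to
#' solvent (ethanol) or auxin from 36 h onward. Auxin in an AID strain
#' abolishes transcription in the targeted compartment(s) from 36 h.
#'
#' @param timepoints_h sampling times, hours.
#' @param n_replicates biological replicates per condition.
#' @param library_depth sequencing reads per library.
#' @return list of class `arrest_design` with a per-sample `samples` table.
#' @export
timeseries_design <- function(timepoints_h = default_timepoints(),
                              n_replicates = 4, library_depth = 5e6) {
  if (length(timepoints_h) < 2 || is.unsorted(timepoints_h, strictly = TRUE))
    stopf("timepoints_h must be strictly ascending")
  if (any(timepoints_h < 0)) stopf("negative time points not allowed")
  grid <- expand.grid(replicate = seq_len(n_replicates), time_h = timepoints_h,
                      KEEP.OUT.ATTRS = FALSE)
  samples <- data.frame(
    sample_id = sprintf("N2_t%03dh_r%d", grid$time_h, grid$replicate),
    strain = "N2", treatment = "none",
    time_h = grid$time_h, replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, library_depth = library_depth,
                 workflow = "timeseries"),
            class = "arrest_design")
}

#' @rdname timeseries_design
#' @export
aid_design <- function(n_replicates = 4, library_depth = 5e6) {
  strains <- c("soma_TIR1", "germline_TIR1", "soma_TIR1_AID", "germline_TIR1_AID")
  cond <- rbind(
    data.frame(time_h = 36, treatment = "ethanol"),
    data.frame(time_h = 132, treatment = "ethanol"),
    data.frame(time_h = 132, treatment = "auxin")
  )
  grid <- merge(merge(data.frame(strain = strains), cond),
                data.frame(replicate = seq_len(n_replicates)))
  grid <- grid[order(grid$strain, grid$time_h, grid$treatment, grid$replicate), ]
  samples <- data.frame(
    sample_id = sprintf("%s_%s_t%03dh_r%d", grid$strain,
                        substr(grid$treatment, 1, 4), grid$time_h, grid$replicate),
    strain = grid$strain, treatment = grid$treatment,
    time_h = grid$time_h, replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  structure(list(samples = samples, library_depth = library_depth,
                 workflow = "aid"),
            class = "arrest_design")
}

#' Generate a gene catalog with ground-truth parameters
#'
#' Draws `n_genes` genes over four expression archetypes mirroring the
#' dominant temporal patterns of the starved-L1 transcriptome:
#' \describe{
#'   \item{early_peak}{somatic starvation-response genes: a transcription
#'     burst in the first 6 h after hatch followed by a low maintenance rate;
#'     short half-life, so expression peaks early and then settles at a
#'     transcription-dependent plateau.}
#'   \item{monotone_down}{abundant soma/muscle transcripts whose transcription
#'     ceases within 6 h of hatch; they decay with a long half-life and
#'     decline monotonically.}
#'   \item{monotone_up_stable}{germline transcripts: transcriptionally
#'     quiescent after hatch (maternally deposited), extremely stable, so
#'     their *relative* expression rises as the rest of the transcriptome
#'     decays.}
#'   \item{flat}{constitutive somatic genes with ongoing transcription that
#'     attenuates in step with the global decline of the transcriptome
#'     (halving every 96 h, the halving time of total RNA per worm), so
#'     their *relative* expression stays approximately flat.}
#' }
#' A gene is labelled `transcription_dependent` iff it is somatic and still
#' transcribed beyond 36 h of arrest (early_peak and flat archetypes).
#'
#' @param n_genes number of genes (>= 10).
#' @param fractions named archetype proportions summing to 1.
#' @param seed RNG seed.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-gene abundance scale (molecules/worm).
#' @return data.frame of per-gene specs (one row per gene).
#' @export
make_gene_catalog <- function(n_genes,
                              fractions = c(early_peak = 0.25,
                                            monotone_down = 0.30,
                                            monotone_up_stable = 0.20,
                                            flat = 0.25),
                              seed = 1,
                              abundance_meanlog = log(150),
                              abundance_sdlog = 1.2) {
  if (n_genes < 10) stopf("n_genes must be at least 10")
  if (!all(names(fractions) %in% ARCHETYPES))
    stopf("unknown archetype in fractions: %s",
          paste(setdiff(names(fractions), ARCHETYPES), collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("archetype fractions must sum to 1 (got %.12f)", sum(fractions))
  set.seed(seed)
  archetype <- sample(names(fractions), n_genes, replace = TRUE, prob = fractions)
  A <- stats::rlnorm(n_genes, abundance_meanlog, abundance_sdlog)
  ## early-response transcripts are abundant at the start of arrest
  A[archetype == "monotone_down"] <- 3 * A[archetype == "monotone_down"]

  compartment <- rep("soma", n_genes)
  compartment[archetype == "monotone_up_stable"] <- "germline"
  ## a subset of the early-terminating genes are muscle-expressed; muscle is
  ## somatic tissue but carries no transcription beyond 36 h, so the
  ## transcription-dependence label stays a pure soma property
  down <- which(archetype == "monotone_down")
  if (length(down) > 0)
    compartment[down][stats::runif(length(down)) < 0.2] <- "muscle"

  hl <- c(early_peak = 4, monotone_down = 40, monotone_up_stable = 400, flat = 6)
  decay_halflife <- unname(hl[archetype])
  k <- log(2) / decay_halflife

  s0 <- k * A                     # maintenance transcription rate
  s0[archetype == "monotone_up_stable"] <- 0
  burst_rate <- rep(NA_real_, n_genes)
  burst_rate[archetype == "early_peak"] <- 20 * s0[archetype == "early_peak"]
  burst_end <- ifelse(archetype == "early_peak", 6, NA_real_)
  t_off <- rep(Inf, n_genes)      # time transcription shuts off without auxin
  t_off[archetype == "monotone_down"] <- 6
  t_off[archetype == "monotone_up_stable"] <- 0
  ## flat genes: transcription attenuates with the global decline
  s_halving <- ifelse(archetype == "flat", 96, Inf)
  a0 <- A                          # abundance at hatch (steady state / deposit)

  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    compartment = compartment,
    archetype = archetype,
    s0 = s0,
    burst_rate = burst_rate,
    burst_end = burst_end,
    t_off = t_off,
    s_halving = s_halving,
    decay_halflife = decay_halflife,
    a0 = a0,
    transcription_dependent = compartment == "soma" & s0 > 0 & t_off > 36,
    stringsAsFactors = FALSE
  )
}

## transcription rate of one gene at time t (vectorised over t), before any
## degron-induced shutdown: piecewise base rate, optionally attenuated by
## 2^(-t / s_halving)
gene_s <- function(gene, t) {
  s <- rep(gene$s0, length(t))
  if (gene$archetype == "early_peak")
    s[t < gene$burst_end] <- gene$burst_rate
  s[t >= gene$t_off] <- 0
  hv <- gene$s_halving %||% Inf
  if (is.finite(hv)) s <- s * 2^(-t / hv)
  s
}

#' Deterministic mRNA abundance trajectory of one gene
#'
#' Integrates da/dt = s(t) - k a exactly over the piecewise-constant
#' transcription profile of the gene's archetype, with k = ln(2)/half-life.
#' If `shutdown_time` is given, transcription is set to zero from that time
#' on (degron-induced RNA Pol II loss), so for t > t0 the trajectory is
#' exactly a(t0) * exp(-k (t - t0)).
#'
#' @param gene one row of a gene catalog (data.frame or list).
#' @param t_grid ascending non-negative times (hours).
#' @param shutdown_time optional transcription shutdown time (hours).
#' @return numeric vector of molecules/worm over `t_grid`.
#' @export
abundance_trajectory <- function(gene, t_grid, shutdown_time = NULL) {
  gene <- as.list(gene)
  if (any(t_grid < 0)) stopf("negative time in t_grid")
  if (is.unsorted(t_grid)) stopf("t_grid must be ascending")
  k <- log(2) / gene$decay_halflife
  t0 <- if (is.null(shutdown_time)) Inf else shutdown_time
  knots <- sort(unique(c(0, t_grid,
                         gene$burst_end[!is.na(gene$burst_end)],
                         gene$t_off[is.finite(gene$t_off)],
                         t0[is.finite(t0)])))
  knots <- knots[knots <= max(t_grid)]
  hv <- gene$s_halving %||% Inf
  hv <- if (is.null(hv) || is.na(hv)) Inf else hv
  beta <- if (is.finite(hv)) log(2) / hv else 0
  a <- numeric(length(knots))
  a[1] <- if (knots[1] == 0) gene$a0 else NA
  for (i in seq_along(knots)[-1]) {
    u <- knots[i - 1]; v <- knots[i]
    ## on [u, v] the rate is s(t) = b * exp(-beta t) with b constant
    s_u <- if (u >= t0) 0 else gene_s(gene, u)
    if (s_u == 0) {
      a[i] <- a[i - 1] * exp(-k * (v - u))
    } else {
      b <- s_u / exp(-beta * u)
      p_u <- b * exp(-beta * u) / (k - beta)
      p_v <- b * exp(-beta * v) / (k - beta)
      a[i] <- (a[i - 1] - p_u) * exp(-k * (v - u)) + p_v
    }
  }
  pmax(a[match(t_grid, knots)], 0)
}

## per-worm total RNA (ng): deterministic exponential decline halving every
## `rna_halflife_h` hours, so 36 h -> 132 h is exactly a two-fold drop at the
## default 96 h halving time
total_rna_per_worm <- function(t, rna0_ng = 0.2, rna_halflife_h = 96) {
  rna0_ng * 2^(-t / rna_halflife_h)
}

## compartments whose transcription is abolished in a given sample
shutdown_compartments <- function(strain, treatment) {
  if (treatment != "auxin") return(character(0))
  switch(strain,
         soma_TIR1_AID = c("soma", "muscle"),
         germline_TIR1_AID = "germline",
         character(0))
}

#' Build the ground-truth abundance tables for a design
#'
#' Evaluates every gene's trajectory at every sample's collection time,
#' applying the degron shutdown (from `shutdown_start_h`, default 36 h) to
#' the compartments targeted in that sample. Also records the deterministic
#' per-worm total RNA, the worms-per-sample implied by preparing libraries
#' from a fixed mass of total RNA, and the spike volume.
#'
#' @param catalog gene catalog from [make_gene_catalog()].
#' @param design an `arrest_design`.
#' @param mix spike-in mix (for the recorded spike volume).
#' @param rna0_ng total RNA per worm at hatch (ng).
#' @param rna_halflife_h halving time of total RNA per worm (hours).
#' @param rna_mass_ng total RNA used per library (ng).
#' @param shutdown_start_h time at which auxin exposure begins.
#' @return list of class `arrest_truth`: `genes`, `abundance` (gene x sample
#'   molecules/worm), `samples` (per-sample truth incl. total RNA per worm).
#' @export
build_truth <- function(catalog, design, mix = default_spike_mix(),
                        rna0_ng = 0.2, rna_halflife_h = 96,
                        rna_mass_ng = 100, shutdown_start_h = 36) {
  sm <- design$samples
  if (nrow(sm) == 0) stopf("empty design")
  ab <- matrix(0, nrow(catalog), nrow(sm),
               dimnames = list(catalog$gene_id, sm$sample_id))
  ## group samples by (time, shutdown) so trajectories are computed once
  key <- vapply(seq_len(nrow(sm)), function(i) {
    paste(sm$time_h[i],
          paste(shutdown_compartments(sm$strain[i], sm$treatment[i]),
                collapse = "+"))
  }, character(1))
  for (kk in unique(key)) {
    idx <- which(key == kk)
    i1 <- idx[1]
    comps <- shutdown_compartments(sm$strain[i1], sm$treatment[i1])
    t <- sm$time_h[i1]
    sd_time <- if (length(comps) > 0) shutdown_start_h else NULL
    vals <- vapply(seq_len(nrow(catalog)), function(g) {
      shut <- if (!is.null(sd_time) && catalog$compartment[g] %in% comps)
        sd_time else NULL
      abundance_trajectory(catalog[g, ], t, shutdown_time = shut)
    }, numeric(1))
    ab[, idx] <- vals
  }
  rna <- total_rna_per_worm(sm$time_h, rna0_ng, rna_halflife_h)
  samples <- cbind(sm, data.frame(
    total_rna_ng_per_worm = rna,
    worms_per_sample = rna_mass_ng / rna,
    total_rna_ng = rna_mass_ng,
    spike_volume_ul = mix$volume_ul[1],
    mrna_molecules_per_worm = colSums(ab),
    mrna_total_rna_ratio = colSums(ab) / rna
  ))
  structure(list(genes = catalog, abundance = ab, samples = samples,
                 params = list(rna0_ng = rna0_ng, rna_halflife_h = rna_halflife_h,
                               rna_mass_ng = rna_mass_ng,
                               shutdown_start_h = shutdown_start_h)),
            class = "arrest_truth")
}

#' Expected read shares for every row of the simulated library
#'
#' Gene rows contribute molecules proportional to molecules/worm times the
#' worms-equivalent of the fixed RNA mass in the tube; spike rows contribute
#' concentration x volume (converted to molecules). Shares are the testable
#' analytic surface behind [sample_counts()].
#'
#' @param truth an `arrest_truth`.
#' @param mix spike-in mix.
#' @return matrix of expected read shares (rows: genes then spikes).
#' @export
expected_read_shares <- function(truth, mix) {
  worms <- truth$samples$worms_per_sample
  gene_mol <- sweep(truth$abundance, 2, worms, `*`)
  spike_mol <- outer(mix$conc_attomol_per_ul * MOLECULES_PER_ATTOMOLE,
                     truth$samples$spike_volume_ul)
  rownames(spike_mol) <- mix$spike_id
  colnames(spike_mol) <- colnames(gene_mol)
  mol <- rbind(gene_mol, spike_mol)
  sweep(mol, 2, colSums(mol), `/`)
}

#' Draw sequencing counts from the ground truth
#'
#' Counts are gamma-mixed multinomial: expected shares from
#' [expected_read_shares()] are perturbed by an independent per-row,
#' per-sample gamma factor with mean 1 and variance `overdispersion`
#' (negative-binomial-like marginal noise), renormalized, and each library is
#' drawn as a single multinomial of size `library_depth`, so per-library
#' totals are exact. The realized spike-in content of each sample is
#' additionally scaled by a log-normal pipetting factor (`spike_noise_sd` on
#' the log scale): spike addition is technically noisy in real library
#' preparation, and this sample-level factor is the unwanted variation the
#' control-gene normalization is meant to absorb. The realized factors are
#' returned as the `"spike_factor"` attribute of the count matrix (they are
#' technical unknowns, deliberately not in the sample sheet).
#'
#' @param truth an `arrest_truth`.
#' @param design the `arrest_design` (provides `library_depth`).
#' @param mix spike-in mix.
#' @param overdispersion gamma variance (>= 0; 0 gives pure multinomial).
#' @param spike_noise_sd log-scale sd of the per-sample spike-addition
#'   factor (0 disables it).
#' @param seed RNG seed.
#' @return list with `counts` (gene+spike x sample integer matrix) and
#'   `samples` (sample sheet data.frame).
#' @export
sample_counts <- function(truth, design, mix = default_spike_mix(),
                          overdispersion = 0.05, spike_noise_sd = 0.15,
                          seed = 1) {
  if (nrow(design$samples) == 0) stopf("empty design")
  if (overdispersion < 0) stopf("overdispersion must be >= 0")
  set.seed(seed)
  shares <- expected_read_shares(truth, mix)
  depth <- design$library_depth
  spike_rows <- rownames(shares) %in% mix$spike_id
  spike_factor <- if (spike_noise_sd > 0)
    stats::rlnorm(ncol(shares), 0, spike_noise_sd) else rep(1, ncol(shares))
  names(spike_factor) <- colnames(shares)
  counts <- matrix(0L, nrow(shares), ncol(shares), dimnames = dimnames(shares))
  for (j in seq_len(ncol(shares))) {
    p <- shares[, j]
    p[spike_rows] <- p[spike_rows] * spike_factor[j]
    if (overdispersion > 0) {
      f <- stats::rgamma(length(p), shape = 1 / overdispersion,
                         rate = 1 / overdispersion)
      p <- p * f
    }
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
  }
  attr(counts, "spike_factor") <- spike_factor
  sheet_cols <- c("sample_id", "strain", "treatment", "time_h", "replicate",
                  "worms_per_sample", "spike_volume_ul", "total_rna_ng")
  list(counts = counts, samples = truth$samples[, sheet_cols])
}

#' One-call simulation of the two default experiments
#'
#' `simulate_timeseries()` produces the 12-time-point x 4-replicate
#' starvation time course; `simulate_aid()` the 4-strain degron experiment
#' (36 h baseline; 132 h with ethanol or auxin; 4 replicates). Both return
#' counts, sample sheet, spike table and full ground truth.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed (drives catalog and counts).
#' @param overdispersion count noise (gamma variance).
#' @param library_depth reads per library.
#' @param ... passed to [make_gene_catalog()].
#' @return list of class `arrest_dataset` with `counts`, `samples`, `spikes`,
#'   `truth`, `design`.
#' @export
simulate_timeseries <- function(n_genes = 2000, seed = 1,
                                overdispersion = 0.05, library_depth = 5e6,
                                ...) {
  simulate_dataset(timeseries_design(library_depth = library_depth),
                   n_genes, seed, overdispersion, ...)
}

#' @rdname simulate_timeseries
#' @export
simulate_aid <- function(n_genes = 2000, seed = 1,
                         overdispersion = 0.05, library_depth = 5e6, ...) {
  simulate_dataset(aid_design(library_depth = library_depth),
                   n_genes, seed, overdispersion, ...)
}

simulate_dataset <- function(design, n_genes, seed, overdispersion, ...) {
  mix <- default_spike_mix()
  catalog <- make_gene_catalog(n_genes, seed = seed, ...)
  truth <- build_truth(catalog, design, mix)
  drawn <- sample_counts(truth, design, mix, overdispersion,
                         seed = seed + 10000L)
  structure(list(counts = drawn$counts, samples = drawn$samples,
                 spikes = mix, truth = truth, design = design),
            class = "arrest_dataset")
}

#' Expected gene CPM implied by the ground truth
#'
#' Relative expression (counts per million over gene rows, spikes excluded)
#' that an infinitely deep, noise-free library would report.
#'
#' @param truth an `arrest_truth`.
#' @return gene x sample matrix of expected CPM.
#' @export
true_cpm <- function(truth) {
  sweep(truth$abundance, 2, colSums(truth$abundance), `/`) * 1e6
}
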