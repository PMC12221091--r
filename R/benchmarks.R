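# Ground-truth benchmarks of the pipeline on its own synthetic generator:
# type-I error and false-discovery control of the DE engine, hyperparameter
# recovery, clustering agreement, and screen operating characteristics.
# These are the quantities the test suite asserts on.

#' Benchmark the differential-abundance engine against planted truth
#'
#' Runs the full normalization/DE path (glog, batch correction, moderated
#' fit, BH calling) on (a) one all-null simulation, measuring the fraction
#' of raw p-values below 0.05, and (b) `n_seeds` planted-effect simulations,
#' measuring sensitivity at the full-effect timepoints (with sign
#' agreement) and the false-discovery proportion among called contrasts.
#'
#' @param seed Base seed; per-repeat seeds derive from it.
#' @param n_proteins Proteins per simulated data set.
#' @param n_seeds Planted-effect repeats.
#' @return List: `null_p_lt_05`, `sensitivity_mean`, `fdp_mean`,
#'   `n_proteins`, `n_seeds`.
#' @export
benchmark_de <- function(seed = 1, n_proteins = 5000, n_seeds = 20) {
  null_cfg <- simulation_config(n_proteins = n_proteins,
                                de_fraction = rep(1e-12, 4),
                                n_restricted = 0,
                                seed = stream_seed(seed, "null"))
  fit <- fit_moderated(batch_correct(glog_normalize(
    simulate_intensities(null_cfg)$matrix)))
  null_p <- mean(fit$table$p_raw < 0.05, na.rm = TRUE)

  sens <- fdp <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(n_proteins = n_proteins,
                             seed = stream_seed(seed, paste0("planted", i)))
    sim <- simulate_intensities(cfg)
    tab <- adjust_and_call(fit_moderated(batch_correct(glog_normalize(
      sim$matrix)))$table)
    truth <- sim$truth
    tps <- setdiff(attr(truth, "timepoints"), attr(truth, "timepoints")[1])
    eff <- as.matrix(truth[, paste0("eff_T", tps)])
    teff <- eff[cbind(match(tab$protein_id, truth$protein_id),
                      match(tab$timepoint, tps))]
    full <- abs(teff) >= cfg$effect_size_log2 - 1e-9
    called <- tab$significant
    sens[i] <- mean(called[full] &
                      sign(tab$log2fc[full]) == sign(teff[full]), na.rm = TRUE)
    V <- sum(called & teff == 0, na.rm = TRUE)
    R <- sum(called, na.rm = TRUE)
    fdp[i] <- V / max(R, 1)
  }
  list(null_p_lt_05 = null_p, sensitivity_mean = mean(sens),
       fdp_mean = mean(fdp), n_proteins = n_proteins, n_seeds = n_seeds)
}

#' Benchmark variance-prior hyperparameter recovery
#'
#' Draws per-protein variances from the hierarchical model
#' \eqn{\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}},
#' \eqn{s_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g} and recovers `(d0, s0_sq)`
#' with [estimate_variance_prior()].
#'
#' @param seed Seed.
#' @param n_proteins Number of simulated variances.
#' @param d0,s0_sq,dg True hyperparameters and residual df.
#' @return List with recovered `d0`, `s0_sq` and the truth.
#' @export
benchmark_eb_recovery <- function(seed = 1, n_proteins = 2000, d0 = 4,
                                  s0_sq = 2, dg = 10) {
  with_stream_seed(seed, "eb_recovery", {
    sigma2 <- s0_sq * d0 / stats::rchisq(n_proteins, d0)
    s2 <- sigma2 * stats::rchisq(n_proteins, dg) / dg
    pr <- estimate_variance_prior(s2, dg)
    list(d0 = pr$d0, s0_sq = pr$s0_sq, true_d0 = d0, true_s0_sq = s0_sq,
         n_proteins = n_proteins)
  })
}

#' Benchmark temporal clustering against planted archetypes
#'
#' Simulates the default time course, clusters the planted differential
#' proteins with [kmeans_pearson()], and scores the Adjusted Rand Index and
#' the per-archetype name agreement of the relabeling convention.
#'
#' @param seed Seed.
#' @param n_proteins Simulation size.
#' @param n_restarts K-means restarts.
#' @return List: `ari`, `label_accuracy`, `n_clustered`.
#' @export
benchmark_clustering <- function(seed = 1, n_proteins = 3783,
                                 n_restarts = 25) {
  if (!requireNamespace("mclust", quietly = TRUE))
    abort_sp("benchmark_clustering needs the mclust package for the ARI")
  cfg <- simulation_config(n_proteins = n_proteins,
                           seed = stream_seed(seed, "clustering"))
  sim <- simulate_intensities(cfg)
  truth <- sim$truth
  de_ids <- truth$protein_id[truth$archetype != "null"]
  bc <- batch_correct(glog_normalize(sim$matrix))
  model <- kmeans_pearson(center_profiles(bc)[de_ids, , drop = FALSE],
                          k = 4, seed = stream_seed(seed, "kmeans_bench"),
                          n_restarts = n_restarts, design = bc$design)
  ids <- names(model$assignments)
  planted <- truth$archetype[match(ids, truth$protein_id)]
  list(ari = mclust::adjustedRandIndex(unname(model$assignments), planted),
       label_accuracy = mean(unname(model$assignments) == planted),
       n_clustered = length(ids))
}

#' Benchmark the lineage screen against planted candidates
#'
#' Runs the homology classification, delta binning, orthogroup filter and
#' candidate combination on simulated inputs with truth-derived
#' upregulation calls, and scores precision/recall for the planted
#' candidate set plus the count of broad-lineage decoys passing.
#'
#' @param seed Base seed.
#' @param n_seeds Repeats (each on a fresh simulation).
#' @param bitscore_noise_sd Gaussian noise added to simulated bitscores.
#' @param n_proteins Simulation size.
#' @return List: `precision_mean`, `recall_mean`, `broad_decoy_passes`
#'   (total across repeats), `n_seeds`, `n_proteins`.
#' @export
benchmark_screen <- function(seed = 1, n_seeds = 1, bitscore_noise_sd = 0,
                             n_proteins = 3783) {
  prec <- rec <- numeric(n_seeds)
  broad_total <- 0L
  scfg <- screen_config()
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(n_proteins = n_proteins,
                             bitscore_noise_sd = bitscore_noise_sd,
                             seed = stream_seed(seed, paste0("screen", i)))
    sim <- simulate_intensities(cfg)
    truth <- sim$truth
    hits <- simulate_hit_tables(truth, cfg)
    og <- simulate_orthogroups(truth, cfg)
    up <- lapply(strsplit(truth$up_timepoints, ","), function(v)
      as.numeric(v[nzchar(v)]))
    names(up) <- truth$protein_id
    calls <- bin_deltas(classify_lineage(
      select_top_hits(hits$screen_hits, scfg$top_n), truth$protein_id, scfg))
    flags <- orthogroup_filter(og, up, scfg)
    cand <- combine_candidates(calls, flags, up, scfg)
    found <- cand$protein_id[cand$candidate]
    planted <- truth$protein_id[truth$is_candidate]
    prec[i] <- length(intersect(found, planted)) / max(length(found), 1)
    rec[i] <- length(intersect(found, planted)) / length(planted)
    broad <- truth$protein_id[truth$lineage_class == "broad"]
    broad_total <- broad_total + sum(found %in% broad)
  }
  list(precision_mean = mean(prec), recall_mean = mean(rec),
       broad_decoy_passes = broad_total, n_seeds = n_seeds,
       n_proteins = n_proteins)
}
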