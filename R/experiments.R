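#' Parameter-recovery experiment
#'
#' Simulates replicate communities from known ground truth and refits the
#' model to each, recording for every monitored parameter whether the 95%
#' credible interval covers the generating value and whether the reliable
#' flag (CI excludes zero) fired. This is the package's calibration check:
#' coverage should be near nominal for nonzero effects, and the reliable
#' flag should rarely fire for effects generated at exactly zero.
#'
#' The generating model uses log-normal wealth (Gini-calibrated), a positive
#' wealth sender effect, a wealth-distance effect of exactly zero (the null
#' being calibrated), correlated sender/receiver and dyadic random effects,
#' and — in double mode — question-specific recall and false-positive rates.
#'
#' @param reps number of simulated replicates.
#' @param n households per replicate.
#' @param mode `"double"` (default; reports pass through the measurement
#'   model and the fit estimates it) or `"single"`.
#' @param alpha,gamma_wealth,gamma_wdist,sigma_re,rho_gen,sigma_delta,rho_dyad
#'   generating structural parameters (`sigma_re` is used for both sender
#'   and receiver scales).
#' @param recall,fp generating reporting rates (both questions).
#' @param mcmc `mcmc_control` for the refits.
#' @param seed master seed; replicate seeds derive from it.
#' @return data frame with one row per replicate x parameter: `rep`,
#'   `parameter`, `truth`, `median`, `ci_low`, `ci_high`, `covered`,
#'   `reliable`, `rhat`.
#' @export
recovery_experiment <- function(reps = 20, n = 44, mode = c("double", "single"),
                                alpha = -2, gamma_wealth = 0.75,
                                gamma_wdist = 0, sigma_re = 0.6,
                                rho_gen = 0, sigma_delta = 1, rho_dyad = 0.6,
                                recall = 0.9, fp = 0.05,
                                mcmc = mcmc_control(chains = 2, warmup = 400,
                                                    samples = 400, L = 15),
                                seed = 1) {
  mode <- match.arg(mode)
  params <- srm_parameters(
    alpha = alpha,
    gamma = c(log_wealth = gamma_wealth, wealth_distance = gamma_wdist),
    sigma_lambda = sigma_re, sigma_pi = sigma_re, rho_gen = rho_gen,
    sigma_delta = sigma_delta, rho_dyad = rho_dyad)
  meas <- measurement_parameters(recall, recall, fp, fp)
  truth <- c(alpha = alpha, gamma_log_wealth = gamma_wealth,
             gamma_wealth_distance = gamma_wdist,
             sigma_lambda = sigma_re, sigma_pi = sigma_re, rho_gen = rho_gen,
             sigma_delta = sigma_delta, rho_dyad = rho_dyad)
  if (mode == "double")
    truth <- c(truth, recall_give = recall, recall_receive = recall,
               fp_give = fp, fp_receive = fp)
  par_map <- c(alpha = "alpha", gamma_log_wealth = "gamma_log_wealth",
               gamma_wealth_distance = "gamma_wealth_distance",
               sigma_lambda = "sigma_lambda", sigma_pi = "sigma_pi",
               rho_gen = "rho_gen", sigma_delta = "sigma_delta",
               rho_dyad = "rho_dyad", recall_give = "recall_give",
               recall_receive = "recall_receive", fp_give = "fp_give",
               fp_receive = "fp_receive")

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, reps)
  cfg <- scenario_config()
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    wealth <- stats::rlnorm(n, log(cfg$median_wealth),
                            lognormal_sigma_for_gini(cfg$gini_wealth))
    ids <- sprintf("H%03d", seq_len(n))
    wc <- wealth_covariates(wealth)
    Wbar <- wc$Wbar
    dimnames(Wbar) <- list(ids, ids)
    hh <- as_household_table(data.frame(
      household_id = ids, wealth_total = wealth, status_flag = 0L,
      dev_group_flag = 0L, hamlet = "hamlet_1",
      latitude = -5.2, longitude = 39.75))
    bundle <- srm_covariates(sender = list(log_wealth = wc$W),
                             dyadic = list(wealth_distance = Wbar))
    sim <- simulate_network(params, bundle, name = "layer")
    dimnames(sim$layer$adjacency) <- list(ids, ids)
    layer <- if (mode == "double")
      simulate_reports(sim$layer, meas, name = "layer") else sim$layer
    data <- multiplex_dataset(hh, NULL, list(layer = layer),
                              list(wealth_distance = Wbar))
    mc <- mcmc
    mc$seed <- rep_seeds[r]
    fit <- suppressWarnings(fit_srm(
      data, "layer",
      srm_model_spec(sender = "log_wealth", dyadic = "wealth_distance",
                     blocks = character(0)),
      mc, store_effects = FALSE))
    sm <- summarize_draws(fit, pars = unname(par_map[names(truth)]))
    sm$truth <- unname(truth)
    sm$covered <- sm$ci_low <= sm$truth & sm$truth <= sm$ci_high
    sm$rep <- r
    out[[r]] <- data.frame(rep = sm$rep, parameter = sm$parameter,
                           truth = sm$truth, median = sm$median,
                           ci_low = sm$ci_low, ci_high = sm$ci_high,
                           covered = sm$covered, reliable = sm$reliable,
                           rhat = sm$rhat)
  }
  do.call(rbind, out)
}

#' Coverage and null-calibration rates from a recovery experiment
#'
#' @param rec output of [recovery_experiment()].
#' @return data frame per parameter: replicates, coverage count and rate,
#'   reliable count and rate.
#' @export
recovery_rates <- function(rec) {
  agg <- split(rec, rec$parameter)
  out <- do.call(rbind, lapply(agg, function(d) data.frame(
    parameter = d$parameter[1], reps = nrow(d),
    covered = sum(d$covered), coverage = mean(d$covered),
    reliable = sum(d$reliable), reliable_rate = mean(d$reliable))))
  rownames(out) <- NULL
  out
}
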