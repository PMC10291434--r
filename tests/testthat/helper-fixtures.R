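# Programmatic fixtures shared across test files.

# A small valid household table (n households, deterministic values).
make_households <- function(n = 6, seed = 1) {
  set.seed(seed)
  as_household_table(data.frame(
    household_id = sprintf("H%02d", seq_len(n)),
    wealth_total = rlnorm(n, 13, 0.7),
    status_flag = rbinom(n, 1, 0.4),
    dev_group_flag = rbinom(n, 1, 0.4),
    hamlet = rep(c("east", "west"), length.out = n),
    latitude = -5.2 + runif(n, 0, 0.01),
    longitude = 39.75 + runif(n, 0, 0.01)))
}

# Covariate bundle + parameters for simulation-based tests.
make_bundle <- function(hh, blocks = TRUE) {
  wc <- wealth_covariates(hh$wealth_total)
  ids <- hh$household_id
  Wbar <- wc$Wbar
  dimnames(Wbar) <- list(ids, ids)
  b <- if (blocks)
    list(status = hh$status_flag + 1L, dev_group = hh$dev_group_flag + 1L)
  else list()
  srm_covariates(sender = list(log_wealth = wc$W),
                 dyadic = list(wealth_distance = Wbar), blocks = b)
}

# Three-generation pedigree with known relatedness values:
# gpF x gpM -> sibs A, B; A's child C (cousin chain), B's child D.
make_pedigree <- function() {
  data.frame(
    individual_id = c("gpF", "gpM", "A", "B", "wifeA", "wifeB", "C", "D"),
    household_id = c("h1", "h1", "h2", "h3", "h2", "h3", "h2", "h3"),
    father_id = c(NA, NA, "gpF", "gpF", NA, NA, "A", "B"),
    mother_id = c(NA, NA, "gpM", "gpM", NA, NA, "wifeA", "wifeB"),
    stringsAsFactors = FALSE)
}

# Brute-force marginal log-likelihood for double-sampled reports: enumerate
# every latent-network configuration (2^(n(n-1)) of them), independent of
# the analytic marginalization.
enumerate_loglik_double <- function(params, effects, covs, meas, reports) {
  n <- covs$n
  pairs <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  np <- nrow(pairs)
  p <- tie_probabilities(params, effects, covs)
  total <- 0
  for (cfg in 0:(2^np - 1)) {
    bits <- as.integer(intToBits(cfg))[seq_len(np)]
    pr <- 1
    for (k in seq_len(np)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      t <- bits[k]
      pr <- pr * (if (t == 1) p[i, j] else 1 - p[i, j])
      po <- if (t == 1) meas$recall_give else meas$fp_give
      pi_ <- if (t == 1) meas$recall_receive else meas$fp_receive
      o <- reports$out_reports[i, j]; q <- reports$in_reports[i, j]
      pr <- pr * (if (o == 1) po else 1 - po) * (if (q == 1) pi_ else 1 - pi_)
    }
    total <- total + pr
  }
  log(total)
}

# Tiny single-layer dataset built from a simulated network.
make_sim_dataset <- function(n = 12, seed = 5, mode = "single",
                             meas = measurement_parameters(0.9, 0.9, 0.05, 0.05)) {
  hh <- make_households(n, seed = seed)
  bundle <- make_bundle(hh, blocks = FALSE)
  params <- srm_parameters(alpha = -1, gamma = c(log_wealth = 0.5),
                           sigma_lambda = 0.5, sigma_pi = 0.5,
                           sigma_delta = 0.8, rho_dyad = 0.3)
  set.seed(seed + 100)
  sim <- simulate_network(params, bundle, name = "net")
  ids <- hh$household_id
  dimnames(sim$layer$adjacency) <- list(ids, ids)
  layer <- if (mode == "double") simulate_reports(sim$layer, meas, name = "net")
           else sim$layer
  Wbar <- bundle$dyadic$wealth_distance
  list(data = multiplex_dataset(hh, NULL, list(net = layer),
                                list(wealth_distance = Wbar)),
       params = params, effects = sim$effects, bundle = bundle, meas = meas)
}
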