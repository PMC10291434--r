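test_that("linear predictor assembles intercept, effects and covariates", {
  hh <- make_households(5, seed = 2)
  covs <- make_bundle(hh)
  n <- 5
  eff <- srm_effects(numeric(n), numeric(n), matrix(0, n, n))

  p0 <- srm_parameters(alpha = 1.3,
                       B = list(status = matrix(0, 2, 2),
                                dev_group = matrix(0, 2, 2)))
  expect_equal(linear_predictor(p0, eff, covs, 1, 2), 1.3)
  expect_error(linear_predictor(p0, eff, covs, 2, 2), "i == j")

  p1 <- srm_parameters(alpha = 0, gamma = c(log_wealth = 2))
  expect_equal(linear_predictor(p1, eff, covs, 3, 1),
               2 * covs$sender$log_wealth[3])

  # with only symmetric dyadic covariates and symmetric blocks, swapping
  # i and j leaves phi unchanged
  p2 <- srm_parameters(alpha = 0.4, gamma = c(wealth_distance = -0.7),
                       B = list(status = matrix(c(0, .2, .2, .5), 2, 2)))
  expect_equal(linear_predictor(p2, eff, covs, 2, 4),
               linear_predictor(p2, eff, covs, 4, 2))
})

test_that("tie probabilities are the logistic map with structural diagonal", {
  hh <- make_households(4)
  covs <- make_bundle(hh, blocks = FALSE)
  eff <- srm_effects(numeric(4), numeric(4), matrix(0, 4, 4))
  p <- tie_probabilities(srm_parameters(alpha = 0), eff, covs)
  off <- row(p) != col(p)
  expect_true(all(p[off] == 0.5))
  expect_equal(diag(p), rep(0, 4))

  plow <- tie_probabilities(srm_parameters(alpha = -30), eff, covs)
  expect_true(all(plow[off] < 1e-12))

  set.seed(1)
  phi <- rnorm(20)
  expect_equal(plogis(phi) + plogis(-phi), rep(1, 20))
})

test_that("random effect draws honour scales, seeds and correlations", {
  p0 <- srm_parameters(sigma_lambda = 0, sigma_pi = 0, sigma_delta = 0)
  e0 <- sample_effects(p0, 10, seed = 1)
  expect_equal(e0$lambda, rep(0, 10))
  expect_equal(e0$pi, rep(0, 10))
  expect_equal(e0$delta, matrix(0, 10, 10))

  p <- srm_parameters(sigma_lambda = 1, sigma_pi = 1, rho_gen = 0.6,
                      sigma_delta = 1, rho_dyad = -0.4)
  e1 <- sample_effects(p, 50, seed = 7)
  e2 <- sample_effects(p, 50, seed = 7)
  expect_identical(e1, e2)

  big <- sample_effects(p, 5000, seed = 8)
  expect_equal(cor(big$lambda, big$pi), 0.6, tolerance = 0.03)
  up <- upper.tri(big$delta)
  expect_equal(cor(big$delta[up], t(big$delta)[up]), -0.4, tolerance = 0.03)
})

test_that("simulated networks match their generating probabilities", {
  hh <- make_households(44, seed = 3)
  covs <- make_bundle(hh, blocks = FALSE)
  p_empty <- srm_parameters(alpha = -20)
  s <- simulate_network(p_empty, covs, seed = 1)
  expect_equal(sum(s$layer$adjacency), 0)

  p_half <- srm_parameters(alpha = 0)
  s2 <- simulate_network(p_half, covs, seed = 2)
  dens <- sum(s2$layer$adjacency) / (44 * 43)
  expect_lt(abs(dens - 0.5), 3 * sqrt(0.25 / (44 * 43)))

  s3 <- simulate_network(p_half, covs, seed = 2)
  expect_identical(s2$layer$adjacency, s3$layer$adjacency)
})

test_that("report simulation reflects recall and false-positive rates", {
  n <- 44
  true_adj <- matrix(0L, n, n)
  perfect <- measurement_parameters(1, 1, 0, 0)
  set.seed(5)
  dense <- matrix(rbinom(n * n, 1L, 0.3), n, n); diag(dense) <- 0L

  r0 <- simulate_reports(dense, perfect, seed = 1)
  expect_identical(r0$out_reports, dense)
  expect_identical(r0$in_reports, dense)

  noisy <- measurement_parameters(0.9, 0.9, 0.1, 0.1)
  r1 <- simulate_reports(true_adj, noisy, seed = 2)
  dens <- sum(r1$out_reports) / (n * (n - 1))
  expect_lt(abs(dens - 0.1), 3 * sqrt(0.1 * 0.9 / (n * (n - 1))))

  amnesiac <- measurement_parameters(0, 0, 0, 0)
  r2 <- simulate_reports(dense, amnesiac, seed = 3)
  expect_equal(sum(r2$out_reports), 0)
  expect_equal(sum(r2$in_reports), 0)
})

test_that("single-layer log-likelihood matches brute-force recomputation", {
  covs <- srm_covariates(sender = list(log_wealth = c(0, 0)))
  eff <- srm_effects(numeric(2), numeric(2), matrix(0, 2, 2))
  p0 <- srm_parameters(alpha = 0, gamma = c(log_wealth = 0))
  A <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(loglik_single(p0, eff, covs, A), 2 * log(0.5))

  hh4 <- make_households(4, seed = 6)
  covs4 <- make_bundle(hh4)
  p <- srm_parameters(alpha = -0.5, gamma = c(log_wealth = 0.4,
                                              wealth_distance = -0.3),
                      B = list(status = matrix(rnorm(4), 2, 2),
                               dev_group = matrix(rnorm(4), 2, 2)))
  eff4 <- sample_effects(srm_parameters(sigma_lambda = 1, sigma_pi = 1,
                                        sigma_delta = 1), 4, seed = 9)
  set.seed(10)
  A4 <- matrix(rbinom(16, 1, 0.5), 4, 4); diag(A4) <- 0
  brute <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    pij <- plogis(linear_predictor(p, eff4, covs4, i, j))
    brute <- brute + dbinom(A4[i, j], 1, pij, log = TRUE)
  }
  expect_equal(loglik_single(p, eff4, covs4, A4), brute, tolerance = 1e-12)
})

test_that("marginalized double-sample likelihood equals latent enumeration", {
  set.seed(20)
  for (rep in 1:3) {
    hh <- make_households(3, seed = rep)
    covs <- make_bundle(hh, blocks = FALSE)
    p <- srm_parameters(alpha = rnorm(1), gamma = c(log_wealth = rnorm(1)))
    eff <- sample_effects(srm_parameters(sigma_lambda = .7, sigma_pi = .7,
                                         sigma_delta = .7), 3)
    meas <- measurement_parameters(runif(1, .6, .95), runif(1, .6, .95),
                                   runif(1, .01, .2), runif(1, .01, .2))
    reports <- list(out_reports = matrix(rbinom(9, 1, .5), 3, 3),
                    in_reports = matrix(rbinom(9, 1, .5), 3, 3))
    diag(reports$out_reports) <- 0L; diag(reports$in_reports) <- 0L
    expect_equal(loglik_double(p, eff, covs, meas, reports),
                 enumerate_loglik_double(p, eff, covs, meas, reports),
                 tolerance = 1e-10)
  }
})

test_that("noiseless double sampling collapses to the single likelihood", {
  sim <- make_sim_dataset(n = 6, seed = 8)
  A <- sim$data$layers$net$adjacency
  perfect <- measurement_parameters(1, 1, 0, 0)
  consistent <- list(out_reports = A, in_reports = A)
  expect_equal(
    loglik_double(sim$params, sim$effects, sim$bundle, perfect, consistent),
    loglik_single(sim$params, sim$effects, sim$bundle, A))

  conflict <- consistent
  conflict$out_reports[1, 2] <- 1L
  conflict$in_reports[1, 2] <- 0L
  expect_equal(
    loglik_double(sim$params, sim$effects, sim$bundle, perfect, conflict),
    -Inf)
})

test_that("likelihood is invariant under simultaneous household permutation", {
  sim <- make_sim_dataset(n = 6, seed = 30)
  set.seed(31)
  perm <- sample(6)
  pm <- function(m) m[perm, perm]
  covs_p <- srm_covariates(
    sender = list(log_wealth = sim$bundle$sender$log_wealth[perm]),
    dyadic = list(wealth_distance = pm(sim$bundle$dyadic$wealth_distance)))
  eff_p <- srm_effects(sim$effects$lambda[perm], sim$effects$pi[perm],
                       pm(sim$effects$delta))
  A <- sim$data$layers$net$adjacency
  expect_equal(loglik_single(sim$params, eff_p, covs_p, pm(A)),
               loglik_single(sim$params, sim$effects, sim$bundle, A),
               tolerance = 1e-10)
})

test_that("log prior evaluates documented densities and support bounds", {
  h <- list(sd_coef = 2.5, sd_scale = 1, recall_shape = c(8, 2),
            fp_shape = c(1, 10))
  # at the prior mode: all coefficients and scales 0, correlations 0
  p_mode <- srm_parameters(alpha = 0, gamma = c(a = 0),
                           sigma_lambda = 0, sigma_pi = 0, sigma_delta = 0)
  expected <- 2 * dnorm(0, 0, 2.5, log = TRUE) +
    3 * (dnorm(0, 0, 1, log = TRUE) + log(2)) + 2 * log(0.5)
  expect_equal(log_prior(p_mode), expected)

  p_bad <- p_mode
  p_bad$sigma_lambda <- -1
  expect_equal(log_prior(p_bad), -Inf)

  meas <- measurement_parameters(0.9, 0.8, 0.05, 0.1)
  expect_equal(log_prior(p_mode, meas) - log_prior(p_mode),
               dbeta(0.9, 8, 2, log = TRUE) + dbeta(0.8, 8, 2, log = TRUE) +
                 dbeta(0.05, 1, 10, log = TRUE) +
                 dbeta(0.1, 1, 10, log = TRUE))
})

test_that("parameters survive a JSON round trip", {
  p <- srm_parameters(alpha = -1.2, gamma = c(log_wealth = .4, rel = -.2),
                      sigma_lambda = .5, sigma_pi = .6, rho_gen = .1,
                      sigma_delta = 1, rho_dyad = .3,
                      B = list(status = matrix(1:4 / 10, 2, 2)))
  m <- measurement_parameters(.9, .85, .05, .03)
  back <- params_from_json(params_to_json(p, m))
  expect_equal(back$params, p)
  expect_equal(back$meas, m)
})
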