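#' Social relations model parameters
#'
#' Container for all generative-model unknowns of the dyadic tie model
#' \deqn{A_{ij} \sim \mathrm{Bernoulli}(\mathrm{logistic}(\phi_{ij})),}
#' \deqn{\phi_{ij} = \alpha + \lambda_i + \pi_j + \delta_{ij} +
#'   B_{S(i),S(j)} + B_{M(i),M(j)} + \sum_k \gamma_k x_{k}[i,j],}
#' where \eqn{\lambda} are sender and \eqn{\pi} receiver random effects with
#' correlation `rho_gen` (generalized reciprocity), \eqn{\delta} are dyadic
#' effects with within-dyad correlation `rho_dyad` (dyadic reciprocity), and
#' the `B` matrices are 2x2 block effects indexed (sender group, receiver
#' group).
#'
#' @param alpha intercept (log-odds scale).
#' @param gamma named numeric vector of slopes; names must match covariate
#'   names in the bundle passed to the model (sender covariates act through
#'   the sender's value, dyadic covariates through the pair's value).
#' @param sigma_lambda,sigma_pi nonnegative sender/receiver effect scales.
#' @param rho_gen correlation in (-1, 1) between a household's sender and
#'   receiver effects.
#' @param sigma_delta nonnegative dyadic effect scale.
#' @param rho_dyad correlation in (-1, 1) between \eqn{\delta_{ij}} and
#'   \eqn{\delta_{ji}}.
#' @param B named list of 2x2 block-effect matrices (e.g. `S`, `M`), indexed
#'   by (sender group, receiver group) with group 1 = flag absent, group 2 =
#'   flag present.
#' @return object of class `srm_parameters`.
#' @export
srm_parameters <- function(alpha = 0, gamma = numeric(0),
                           sigma_lambda = 0, sigma_pi = 0, rho_gen = 0,
                           sigma_delta = 0, rho_dyad = 0, B = list()) {
  stopifnot(sigma_lambda >= 0, sigma_pi >= 0, sigma_delta >= 0,
            rho_gen > -1, rho_gen < 1, rho_dyad > -1, rho_dyad < 1)
  for (b in B) stopifnot(is.matrix(b), all(dim(b) == c(2, 2)))
  structure(list(alpha = alpha, gamma = gamma, sigma_lambda = sigma_lambda,
                 sigma_pi = sigma_pi, rho_gen = rho_gen,
                 sigma_delta = sigma_delta, rho_dyad = rho_dyad, B = B),
            class = "srm_parameters")
}

#' Measurement parameters for double-sampled reports
#'
#' Reporting-error model for a double-sampled name generator: each directed
#' tie i -> j is probed twice, once on the giver question (answered by i) and
#' once on the receiver question (answered by j). A true tie is reported with
#' probability `recall_*` (forgetting = 1 - recall); a non-tie is reported
#' with probability `fp_*` (false positives). Question-specific rates absorb
#' mean differences between how the two questions are asked.
#'
#' @param recall_give,recall_receive probability a true tie is reported on
#'   the giver/receiver question.
#' @param fp_give,fp_receive probability a non-tie is reported.
#' @return object of class `measurement_parameters`.
#' @export
measurement_parameters <- function(recall_give = 0.9, recall_receive = 0.9,
                                   fp_give = 0.05, fp_receive = 0.05) {
  p <- c(recall_give, recall_receive, fp_give, fp_receive)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(recall_give = recall_give, recall_receive = recall_receive,
                 fp_give = fp_give, fp_receive = fp_receive),
            class = "measurement_parameters")
}

#' Covariate bundle for the dyadic model
#'
#' @param sender named list of length-n numeric vectors (household-level
#'   covariates acting through the sender, e.g. standardized log wealth).
#' @param dyadic named list of n x n numeric matrices (dyad-level
#'   covariates: wealth distance, relatedness, spatial distance, cross-layer
#'   adjacencies).
#' @param blocks named list of integer group vectors in `{1, 2}` (1 = flag
#'   absent, 2 = flag present), one per block structure (e.g. `S`, `M`).
#' @return object of class `srm_covariates`.
#' @export
srm_covariates <- function(sender = list(), dyadic = list(), blocks = list()) {
  n <- NULL
  for (v in sender) { stopifnot(is.numeric(v)); n <- n %||% length(v) }
  for (m in dyadic) { stopifnot(is.matrix(m), nrow(m) == ncol(m)); n <- n %||% nrow(m) }
  for (g in blocks) { stopifnot(all(g %in% c(1L, 2L))); n <- n %||% length(g) }
  structure(list(sender = sender, dyadic = dyadic, blocks = blocks, n = n),
            class = "srm_covariates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random effects realization
#'
#' @param lambda length-n sender effects.
#' @param pi length-n receiver effects.
#' @param delta n x n dyadic effects, zero diagonal.
#' @return object of class `srm_effects`.
#' @export
srm_effects <- function(lambda, pi, delta) {
  stopifnot(length(lambda) == length(pi), nrow(delta) == length(lambda),
            ncol(delta) == length(lambda))
  diag(delta) <- 0
  structure(list(lambda = lambda, pi = pi, delta = delta),
            class = "srm_effects")
}

zero_effects <- function(n) srm_effects(numeric(n), numeric(n), matrix(0, n, n))

# Full n x n matrix of linear predictors (diagonal meaningless, set to 0).
phi_matrix <- function(params, effects, covs) {
  n <- covs$n %||% length(effects$lambda)
  phi <- matrix(params$alpha, n, n)
  phi <- phi + outer(effects$lambda, rep(1, n)) +
    outer(rep(1, n), effects$pi) + effects$delta
  for (bn in names(params$B)) {
    g <- covs$blocks[[bn]]
    if (is.null(g)) stop("block '", bn, "' missing from covariates")
    phi <- phi + params$B[[bn]][cbind(as.vector(outer(g, rep(1L, n))),
                                      as.vector(outer(rep(1L, n), g)))]
  }
  for (nm in names(params$gamma)) {
    if (nm %in% names(covs$sender)) {
      phi <- phi + params$gamma[[nm]] * covs$sender[[nm]]  # recycles by row = sender
    } else if (nm %in% names(covs$dyadic)) {
      phi <- phi + params$gamma[[nm]] * covs$dyadic[[nm]]
    } else {
      stop("covariate '", nm, "' named in gamma but absent from bundle")
    }
  }
  diag(phi) <- 0
  phi
}

#' Linear predictor for one ordered household pair
#'
#' Evaluates \eqn{\phi_{ij}} — intercept, sender/receiver/dyadic random
#' effects, block effects, and covariate terms — for the directed pair
#' (i, j).
#'
#' @param params `srm_parameters`.
#' @param effects `srm_effects`.
#' @param covs `srm_covariates`.
#' @param i,j household indices, `i != j`.
#' @return scalar log-odds of the tie i -> j.
#' @export
linear_predictor <- function(params, effects, covs, i, j) {
  if (i == j) stop("self-ties are undefined (i == j)", call. = FALSE)
  phi <- params$alpha + effects$lambda[i] + effects$pi[j] + effects$delta[i, j]
  for (bn in names(params$B)) {
    g <- covs$blocks[[bn]]
    phi <- phi + params$B[[bn]][g[i], g[j]]
  }
  for (nm in names(params$gamma)) {
    x <- if (nm %in% names(covs$sender)) covs$sender[[nm]][i]
         else covs$dyadic[[nm]][i, j]
    phi <- phi + params$gamma[[nm]] * x
  }
  phi
}

#' Tie probability matrix
#'
#' @inheritParams linear_predictor
#' @return n x n matrix with entries `plogis(phi)` off-diagonal and a
#'   structural 0 diagonal.
#' @export
tie_probabilities <- function(params, effects, covs) {
  p <- stats::plogis(phi_matrix(params, effects, covs))
  diag(p) <- 0
  p
}

#' Draw sender/receiver and dyadic random effects
#'
#' `(lambda_i, pi_i)` are jointly normal with scales `sigma_lambda`,
#' `sigma_pi` and correlation `rho_gen`; `(delta_ij, delta_ji)` are jointly
#' normal with common scale `sigma_delta` and correlation `rho_dyad`,
#' independent across dyads.
#'
#' @param params `srm_parameters`.
#' @param n number of households.
#' @param seed optional integer seed for reproducible draws.
#' @return `srm_effects`.
#' @export
sample_effects <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cg <- sqrt(1 - params$rho_gen^2)
  lambda <- params$sigma_lambda * z1
  pi <- params$sigma_pi * (params$rho_gen * z1 + cg * z2)
  delta <- matrix(0, n, n)
  if (n >= 2) {
    up <- which(upper.tri(delta))
    nd <- length(up)
    u1 <- stats::rnorm(nd); u2 <- stats::rnorm(nd)
    cd <- sqrt(1 - params$rho_dyad^2)
    delta[up] <- params$sigma_delta * u1
    partner <- matrix(0, n, n)
    partner[up] <- params$sigma_delta * (params$rho_dyad * u1 + cd * u2)
    delta <- delta + t(partner)
  }
  srm_effects(lambda, pi, delta)
}

#' Simulate a directed binary network from the model
#'
#' Draws random effects (unless supplied) and then independent Bernoulli
#' ties at [tie_probabilities()].
#'
#' @param params `srm_parameters`.
#' @param covs `srm_covariates`.
#' @param seed optional integer seed.
#' @param name layer name for the returned `network_layer`.
#' @param effects optional `srm_effects` to condition on.
#' @return list with `layer` (single-mode `network_layer`) and `effects`
#'   (the latent effects used, for recovery experiments).
#' @export
simulate_network <- function(params, covs, seed = NULL, name = "simulated",
                             effects = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- covs$n
  if (is.null(effects)) effects <- sample_effects(params, n)
  p <- tie_probabilities(params, effects, covs)
  A <- matrix(stats::rbinom(n * n, 1L, as.vector(p)), n, n)
  diag(A) <- 0L
  ids <- names(covs$sender[[1]]) %||% rownames(covs$dyadic[[1]])
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  list(layer = new_layer(name, "single", adjacency = A), effects = effects)
}

#' Simulate double-sampled reports of a true network
#'
#' Given the true adjacency T, each ordered pair is reported twice:
#' `out_reports[i,j] ~ Bernoulli(T recall_give + (1-T) fp_give)` (giver
#' question, answered by i) and `in_reports[i,j] ~ Bernoulli(T
#' recall_receive + (1-T) fp_receive)` (receiver question, answered by j),
#' independently given T.
#'
#' @param true_layer single-mode `network_layer` or binary adjacency matrix.
#' @param meas `measurement_parameters`.
#' @param seed optional integer seed.
#' @param name layer name.
#' @return double-mode `network_layer`.
#' @export
simulate_reports <- function(true_layer, meas, seed = NULL,
                             name = "reported") {
  if (inherits(true_layer, "network_layer")) true_layer <- true_layer$adjacency
  stopifnot(all(true_layer %in% c(0L, 1L)), all(diag(true_layer) == 0))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(true_layer)
  p_out <- ifelse(true_layer == 1, meas$recall_give, meas$fp_give)
  p_in <- ifelse(true_layer == 1, meas$recall_receive, meas$fp_receive)
  out_r <- matrix(stats::rbinom(n * n, 1L, as.vector(p_out)), n, n)
  in_r <- matrix(stats::rbinom(n * n, 1L, as.vector(p_in)), n, n)
  dimnames(out_r) <- dimnames(in_r) <- dimnames(true_layer)
  new_layer(name, "double", out_reports = out_r, in_reports = in_r)
}

# log(1 + exp(x)) without overflow
log1p_exp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Log-likelihood of a single-sampled layer
#'
#' Sum over ordered pairs i != j of the Bernoulli log-likelihood at the
#' logistic linear predictor.
#'
#' @inheritParams linear_predictor
#' @param adjacency binary n x n matrix (or single-mode `network_layer`).
#' @return scalar log-likelihood.
#' @export
loglik_single <- function(params, effects, covs, adjacency) {
  if (inherits(adjacency, "network_layer")) adjacency <- adjacency$adjacency
  phi <- phi_matrix(params, effects, covs)
  off <- row(phi) != col(phi)
  sum(adjacency[off] * phi[off] - log1p_exp(phi[off]))
}

#' Marginal log-likelihood of double-sampled reports
#'
#' The latent tie T[i,j] is marginalized exactly per ordered pair:
#' \deqn{P(o, q) = p\, r_g^o (1-r_g)^{1-o} r_r^q (1-r_r)^{1-q} +
#'   (1-p)\, f_g^o (1-f_g)^{1-o} f_r^q (1-f_r)^{1-q}}
#' with \eqn{p = \mathrm{logistic}(\phi_{ij})}, summed in log over ordered
#' pairs via log-sum-exp. Returns `-Inf` only for observations of prior
#' probability zero (e.g. conflicting reports when the error rates make them
#' impossible).
#'
#' @inheritParams linear_predictor
#' @param meas `measurement_parameters`.
#' @param reports double-mode `network_layer` (or list with `out_reports`,
#'   `in_reports`).
#' @return scalar marginal log-likelihood.
#' @export
loglik_double <- function(params, effects, covs, meas, reports) {
  o <- reports$out_reports; q <- reports$in_reports
  phi <- phi_matrix(params, effects, covs)
  off <- row(phi) != col(phi)
  o <- o[off]; q <- q[off]; phi <- phi[off]
  # log p and log(1-p) stably
  lp1 <- -log1p_exp(-phi)
  lp0 <- -log1p_exp(phi)
  lbern <- function(y, p) ifelse(y == 1, log(p), log1p(-p))
  l1 <- lp1 + lbern(o, meas$recall_give) + lbern(q, meas$recall_receive)
  l0 <- lp0 + lbern(o, meas$fp_give) + lbern(q, meas$fp_receive)
  hi <- pmax(l1, l0)
  term <- ifelse(is.infinite(hi) & hi < 0, -Inf,
                 hi + log(exp(l1 - hi) + exp(l0 - hi)))
  sum(term)
}

#' Log prior density of the model parameters
#'
#' Weakly informative defaults on the logistic scale: intercept, slopes and
#' block entries Normal(0, 2.5); random-effect scales half-Normal(1);
#' correlations uniform on (-1, 1); recall Beta(8, 2) and false-positive
#' Beta(1, 10), which keeps recall above the false-positive rate with high
#' prior probability (the identifiability guard for the measurement model).
#'
#' @param params `srm_parameters`.
#' @param meas optional `measurement_parameters`.
#' @param hyper list overriding prior hyperparameters: `sd_coef`, `sd_scale`,
#'   `recall_shape` (length 2), `fp_shape` (length 2).
#' @return scalar log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(params, meas = NULL, hyper = list()) {
  h <- prior_hyper(hyper)
  coefs <- c(params$alpha, unlist(params$gamma),
             unlist(lapply(params$B, as.vector)))
  lp <- sum(stats::dnorm(coefs, 0, h$sd_coef, log = TRUE))
  for (s in c(params$sigma_lambda, params$sigma_pi, params$sigma_delta)) {
    if (s < 0) return(-Inf)
    lp <- lp + stats::dnorm(s, 0, h$sd_scale, log = TRUE) + log(2)
  }
  for (r in c(params$rho_gen, params$rho_dyad)) {
    if (r <= -1 || r >= 1) return(-Inf)
    lp <- lp + log(0.5)
  }
  if (!is.null(meas)) {
    for (p in c(meas$recall_give, meas$recall_receive)) {
      if (p < 0 || p > 1) return(-Inf)
      lp <- lp + stats::dbeta(p, h$recall_shape[1], h$recall_shape[2],
                              log = TRUE)
    }
    for (p in c(meas$fp_give, meas$fp_receive)) {
      if (p < 0 || p > 1) return(-Inf)
      lp <- lp + stats::dbeta(p, h$fp_shape[1], h$fp_shape[2], log = TRUE)
    }
  }
  lp
}

prior_hyper <- function(hyper = list()) {
  utils::modifyList(list(sd_coef = 2.5, sd_scale = 1,
                         recall_shape = c(8, 2), fp_shape = c(1, 10)),
                    hyper)
}

#' Serialize model parameters to JSON
#'
#' @param params `srm_parameters`.
#' @param meas optional `measurement_parameters`.
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
params_to_json <- function(params, meas = NULL, path = NULL) {
  x <- unclass(params)
  x$gamma <- as.list(params$gamma) # keep names through serialization
  x$B <- lapply(params$B, function(b) unclass(b))
  if (!is.null(meas)) x$measurement <- unclass(meas)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize model parameters from JSON
#'
#' @param json JSON string or path to a JSON file.
#' @return list with `params` (`srm_parameters`) and `meas`
#'   (`measurement_parameters` or `NULL`).
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  meas <- NULL
  if (!is.null(x$measurement)) {
    meas <- do.call(measurement_parameters, x$measurement)
    x$measurement <- NULL
  }
  x$gamma <- unlist(x$gamma) %||% numeric(0)
  x$B <- lapply(x$B, function(b) matrix(unlist(b), 2, 2))
  params <- do.call(srm_parameters, x)
  list(params = params, meas = meas)
}
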