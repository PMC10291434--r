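#' Model specification for a layer fit
#'
#' Names the covariates entering the linear predictor. Only sender and
#' dyadic-similarity terms are included (receiver terms are excluded for
#' identifiability, since sender, receiver and dyadic terms of the same
#' covariate are collinear in the social relations model).
#'
#' @param sender character vector of household-level covariate names; the
#'   default `"log_wealth"` is built internally as standardized log wealth.
#' @param dyadic character vector of dyadic covariate names; each must match
#'   an entry of the dataset's `dyadic_covariates` or the name of another
#'   layer (whose observed adjacency then enters as a cross-layer predictor;
#'   for double-sampled layers the union of the two report matrices is used).
#' @param blocks character vector of block structures: `"status"`
#'   (religious/secular influence) and/or `"dev_group"` (development labour
#'   cooperative membership).
#' @return object of class `srm_model_spec`.
#' @export
srm_model_spec <- function(sender = "log_wealth",
                           dyadic = character(0),
                           blocks = c("status", "dev_group")) {
  structure(list(sender = sender, dyadic = dyadic, blocks = blocks),
            class = "srm_model_spec")
}

#' MCMC control settings
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param warmup warmup (adaptation) iterations per chain.
#' @param samples post-warmup iterations per chain.
#' @param L base number of leapfrog steps (jittered +/- 20% per iteration).
#' @param adapt_delta target acceptance rate for step-size adaptation.
#' @param seed integer seed; the fit is deterministic given `seed` and the
#'   iteration budget.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, samples = 1000,
                         L = 20, adapt_delta = 0.8, seed = 1) {
  structure(list(chains = chains, warmup = warmup, samples = samples,
                 L = L, adapt_delta = adapt_delta, seed = seed),
            class = "mcmc_control")
}

# Assemble the data list consumed by the C++ log-posterior.
build_model_inputs <- function(data, layer, spec, hyper = list()) {
  if (!layer %in% names(data$layers))
    stop("unknown layer '", layer, "'", call. = FALSE)
  l <- data$layers[[layer]]
  hh <- data$households
  n <- nrow(hh)
  h <- prior_hyper(hyper)

  sender <- list()
  for (nm in spec$sender) {
    if (nm == "log_wealth") {
      sender[[nm]] <- wealth_covariates(hh$wealth_total)$W
    } else stop("unknown sender covariate '", nm, "'", call. = FALSE)
  }
  dyadic <- list()
  for (nm in spec$dyadic) {
    if (nm %in% names(data$dyadic_covariates)) {
      dyadic[[nm]] <- data$dyadic_covariates[[nm]]
    } else if (nm %in% names(data$layers)) {
      if (nm == layer) stop("layer cannot predict itself", call. = FALSE)
      dyadic[[nm]] <- layer_adjacency(data$layers[[nm]]) * 1.0
    } else stop("unknown dyadic covariate '", nm, "'", call. = FALSE)
  }
  blocks <- list()
  for (nm in spec$blocks) {
    fl <- switch(nm, status = hh$status_flag, dev_group = hh$dev_group_flag,
                 stop("unknown block '", nm, "'", call. = FALSE))
    blocks[[nm]] <- as.integer(fl) + 1L # 1 = flag absent, 2 = present
  }

  inputs <- list(mode = if (l$mode == "double") 1L else 0L, n = as.integer(n),
                 Xs = sender, Xd = dyadic, blocks = blocks,
                 sd_coef = h$sd_coef, sd_scale = h$sd_scale,
                 recall_a = h$recall_shape[1], recall_b = h$recall_shape[2],
                 fp_a = h$fp_shape[1], fp_b = h$fp_shape[2])
  if (l$mode == "double") {
    storage.mode(l$out_reports) <- "integer"
    storage.mode(l$in_reports) <- "integer"
    inputs$OUT <- l$out_reports
    inputs$IN <- l$in_reports
  } else {
    A <- l$adjacency
    storage.mode(A) <- "integer"
    inputs$A <- A
  }
  inputs
}

# Parameter bookkeeping shared by the sampler and the draw extraction.
theta_layout <- function(inputs) {
  n <- inputs$n
  nd <- n * (n - 1) / 2
  ks <- length(inputs$Xs); kd <- length(inputs$Xd)
  nb <- length(inputs$blocks)
  nm <- "alpha"
  if (ks) nm <- c(nm, paste0("gamma_", names(inputs$Xs)))
  if (kd) nm <- c(nm, paste0("gamma_", names(inputs$Xd)))
  for (b in names(inputs$blocks))
    nm <- c(nm, paste0("B_", b, c("[1,1]", "[2,1]", "[1,2]", "[2,2]")))
  nm <- c(nm, "log_sigma_lambda", "log_sigma_pi", "atanh_rho_gen",
          "log_sigma_delta", "atanh_rho_dyad")
  meas_names <- character(0)
  if (inputs$mode == 1L) {
    meas_names <- c("recall_give", "recall_receive", "fp_give", "fp_receive")
    nm <- c(nm, paste0("logit_", meas_names))
  }
  n_top <- length(nm)
  P <- n_top + 2 * n + 2 * nd
  list(P = P, n_top = n_top, top_names = nm, meas_names = meas_names,
       ks = ks, kd = kd, nb = nb, n = n, nd = nd,
       off_re = 2 + ks + kd + 4 * nb, # R index of log_sigma_lambda
       off_zg = n_top + 1)
}

# Natural-scale top-level draws from an unconstrained theta row.
natural_params <- function(theta_top, layout) {
  v <- theta_top
  names(v) <- layout$top_names
  i <- layout$off_re
  out <- v
  out[i:(i + 4)] <- c(exp(v[i]), exp(v[i + 1]), tanh(v[i + 2]),
                      exp(v[i + 3]), tanh(v[i + 4]))
  names(out)[i:(i + 4)] <- c("sigma_lambda", "sigma_pi", "rho_gen",
                             "sigma_delta", "rho_dyad")
  if (length(layout$meas_names)) {
    j <- i + 5
    out[j:(j + 3)] <- stats::plogis(v[j:(j + 3)])
    names(out)[j:(j + 3)] <- layout$meas_names
  }
  out
}

# Static HMC with dual-averaging step-size adaptation and a diagonal mass
# matrix estimated during warmup. fn(theta) must return list(lp, grad).
run_hmc <- function(fn, init, warmup, samples, L, adapt_delta = 0.8) {
  P <- length(init)
  q <- init
  mvar <- rep(1, P) # inverse mass (posterior variance estimate)
  cur <- fn(q)
  if (!is.finite(cur$lp)) stop("non-finite log-posterior at initial value")

  leapfrog <- function(q, r, eps, nstep) {
    st <- fn(q)
    for (s in seq_len(nstep)) {
      r <- r + 0.5 * eps * st$grad
      q <- q + eps * mvar * r
      st <- fn(q)
      if (!all(is.finite(st$grad))) return(list(q = q, r = r, lp = -Inf))
      r <- r + 0.5 * eps * st$grad
    }
    list(q = q, r = r, lp = st$lp)
  }
  hamiltonian <- function(lp, r) -lp + 0.5 * sum(r^2 * mvar)

  find_eps <- function(q) {
    eps <- 0.1
    st0 <- fn(q)
    r <- stats::rnorm(P, 0, sqrt(1 / mvar))
    h0 <- hamiltonian(st0$lp, r)
    step <- leapfrog(q, r, eps, 1L)
    dh <- h0 - hamiltonian(step$lp, step$r)
    if (!is.finite(dh)) dh <- -Inf
    a <- if (dh > log(0.5)) 1 else -1
    for (k in 1:30) {
      eps <- eps * 2^a
      step <- leapfrog(q, r, eps, 1L)
      dh <- h0 - hamiltonian(step$lp, step$r)
      if (!is.finite(dh)) dh <- -Inf
      if (a == 1 && dh <= log(0.5)) break
      if (a == -1 && dh > log(0.5)) break
    }
    eps
  }

  n_iter <- warmup + samples
  draws <- matrix(NA_real_, samples, P)
  n_div <- 0L
  accept_sum <- 0
  # dual averaging state
  da_init <- function(eps0) list(mu = log(10 * eps0), log_eps = log(eps0),
                                 log_eps_bar = 0, h_bar = 0, m = 0)
  da_update <- function(da, a_prob) {
    da$m <- da$m + 1
    frac <- 1 / (da$m + 10)
    da$h_bar <- (1 - frac) * da$h_bar + frac * (adapt_delta - a_prob)
    da$log_eps <- da$mu - sqrt(da$m) / 0.05 * da$h_bar
    w <- da$m^(-0.75)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }
  eps <- find_eps(q)
  da <- da_init(eps)
  phase1_end <- max(2L, floor(warmup * 0.5))
  var_from <- max(1L, floor(warmup * 0.25))
  var_buf <- matrix(NA_real_, phase1_end - var_from + 1L, P)

  for (it in seq_len(n_iter)) {
    in_warmup <- it <= warmup
    eps_it <- if (in_warmup) exp(da$log_eps) else eps
    nstep <- max(1L, round(L * stats::runif(1, 0.8, 1.2)))
    r0 <- stats::rnorm(P, 0, sqrt(1 / mvar))
    h0 <- hamiltonian(cur$lp, r0)
    prop <- leapfrog(q, r0, eps_it, nstep)
    dh <- h0 - hamiltonian(prop$lp, prop$r)
    if (!is.finite(dh)) dh <- -Inf
    if (dh < -1000) n_div <- n_div + 1L
    a_prob <- min(1, exp(dh))
    if (stats::runif(1) < a_prob) {
      q <- prop$q
      cur <- fn(q)
    }
    if (in_warmup) {
      da <- da_update(da, a_prob)
      if (it >= var_from && it <= phase1_end) var_buf[it - var_from + 1L, ] <- q
      if (it == phase1_end) {
        v <- apply(var_buf, 2, stats::var)
        nobs <- nrow(var_buf)
        mvar <- pmax((nobs * v + 5) / (nobs + 5), 1e-6) # shrink toward unit
        eps <- find_eps(q)
        da <- da_init(eps)
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - warmup, ] <- q
      accept_sum <- accept_sum + a_prob
    }
  }
  list(draws = draws, eps = eps, n_divergent = n_div,
       accept_rate = accept_sum / samples)
}

#' Fit the social relations model to one network layer
#'
#' Posterior computation by Hamiltonian Monte Carlo. Single-sampled layers
#' use the Bernoulli likelihood directly; double-sampled layers use the
#' latent-network measurement model with the latent tie marginalized
#' analytically per dyad, so the false-positive and recall rates of both
#' questions are estimated jointly with the structural parameters. Random
#' effects are non-centered in the sampler parameterization.
#'
#' @param data `multiplex_dataset`.
#' @param layer name of the layer to model.
#' @param spec `srm_model_spec` naming covariates and blocks.
#' @param mcmc `mcmc_control`.
#' @param hyper prior hyperparameter overrides (see [log_prior()]).
#' @param store_effects keep posterior draws of `lambda[i]` and `pi[i]`
#'   (default `TRUE`; dyadic effects are never stored).
#' @return object of class `srm_fit` with per-chain draw matrices on the
#'   natural scale, sampler diagnostics, and the seed record.
#' @export
fit_srm <- function(data, layer, spec = srm_model_spec(),
                    mcmc = mcmc_control(), hyper = list(),
                    store_effects = TRUE) {
  inputs <- build_model_inputs(data, layer, spec, hyper)
  layout <- theta_layout(inputs)
  fn <- function(theta) .srm_lp_grad(theta, inputs)

  set.seed(mcmc$seed)
  chain_seeds <- sample.int(2147483646L, mcmc$chains)
  keep <- layout$n_top
  eff_names <- character(0)
  if (store_effects) {
    eff_names <- c(paste0("lambda[", seq_len(layout$n), "]"),
                   paste0("pi[", seq_len(layout$n), "]"))
  }
  chains <- vector("list", mcmc$chains)
  diags <- list()
  h <- prior_hyper(hyper)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[ch])
    init <- c(stats::rnorm(keep, 0, 0.1),
              stats::rnorm(layout$P - keep, 0, 0.1))
    if (inputs$mode == 1L) {
      # start reporting rates at their prior means: recall and false-positive
      # rates are exchangeable in the likelihood (complementing the latent
      # network swaps them), and initialization at 0.5/0.5 sits on that
      # ridge; the prior separates the modes.
      im <- layout$off_re + 5:8
      init[im] <- stats::qlogis(c(rep(h$recall_shape[1] /
                                        sum(h$recall_shape), 2),
                                  rep(h$fp_shape[1] / sum(h$fp_shape), 2))) +
        stats::rnorm(4, 0, 0.1)
    }
    res <- run_hmc(fn, init, mcmc$warmup, mcmc$samples, mcmc$L,
                   mcmc$adapt_delta)
    top <- t(apply(res$draws[, seq_len(keep), drop = FALSE], 1,
                   natural_params, layout = layout))
    colnames(top) <- names(natural_params(res$draws[1, seq_len(keep)], layout))
    if (store_effects) {
      i <- layout$off_re
      sl <- top[, "sigma_lambda"]; sp <- top[, "sigma_pi"]
      rg <- top[, "rho_gen"]
      z1 <- res$draws[, layout$off_zg:(layout$off_zg + layout$n - 1),
                      drop = FALSE]
      z2 <- res$draws[, (layout$off_zg + layout$n):
                        (layout$off_zg + 2 * layout$n - 1), drop = FALSE]
      lam <- z1 * sl
      pii <- (z1 * rg + z2 * sqrt(1 - rg^2)) * sp
      top <- cbind(top, lam, pii)
      colnames(top)[(ncol(top) - 2 * layout$n + 1):ncol(top)] <- eff_names
    }
    chains[[ch]] <- top
    diags[[ch]] <- res[c("eps", "n_divergent", "accept_rate")]
  }

  fit <- structure(list(chains = chains, layer = layer, spec = spec,
                        mcmc = mcmc, layout = layout, diagnostics = diags,
                        seed = mcmc$seed, warnings = character(0)),
                   class = "srm_fit")
  sm <- summarize_draws(fit)
  top_pars <- colnames(chains[[1]])[seq_len(keep + length(eff_names))]
  bad <- sm$parameter[sm$rhat > 1.05 & sm$parameter %in%
                        colnames(chains[[1]])[seq_len(keep)]]
  if (length(bad)) {
    w <- paste0("convergence warning: rhat > 1.05 for ",
                paste(bad, collapse = ", "))
    fit$warnings <- w
    warning(w, call. = FALSE)
  }
  ndiv <- sum(vapply(diags, function(d) d$n_divergent, 0L))
  if (ndiv > 0) {
    w <- paste0(ndiv, " divergent transition(s)")
    fit$warnings <- c(fit$warnings, w)
  }
  fit
}

#' @export
print.srm_fit <- function(x, ...) {
  cat("srm_fit: layer '", x$layer, "', ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " draws (seed ", x$seed, ")\n", sep = "")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

# Stacked draws for a parameter across chains (list of numeric vectors).
chain_draws <- function(fit, par) {
  lapply(fit$chains, function(m) m[, par])
}

# Split-chain potential scale reduction factor.
split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    h <- floor(length(x) / 2)
    halves <- c(halves, list(x[1:h]), list(x[(h + 1):(2 * h)]))
  }
  m <- length(halves); l <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- l * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((l - 1) / l * W + B / l) / W)
}

# Effective sample size by truncated autocorrelation (Geyer initial
# positive-pair criterion), averaged across chains.
ess_basic <- function(chains) {
  m <- length(chains); l <- length(chains[[1]])
  W <- mean(vapply(chains, stats::var, 0))
  if (W < 1e-300) return(m * l)
  max_lag <- min(l - 1, 200)
  rho <- rep(0, max_lag + 1)
  for (x in chains) {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    rho <- rho + a * stats::var(x) / (m * W)
  }
  s <- 0; t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, m * l / (1 + 2 * s))
}

#' Posterior summary table
#'
#' Per parameter: posterior median, central 95% credible interval (2.5% and
#' 97.5% quantiles), the reliability flag (CI excludes zero — the criterion
#' behind statements like "no reliable association"), split-chain rhat, and
#' effective sample size.
#'
#' @param fit `srm_fit`, or a named list of per-chain draw matrices.
#' @param pars parameters to include (default: all stored).
#' @return data frame of class `posterior_summary`.
#' @export
summarize_draws <- function(fit, pars = NULL) {
  chains <- if (inherits(fit, "srm_fit")) fit$chains else fit
  if (is.null(pars)) pars <- colnames(chains[[1]])
  rows <- lapply(pars, function(p) {
    per_chain <- lapply(chains, function(m) m[, p])
    x <- unlist(per_chain)
    qs <- unname(stats::quantile(x, c(0.025, 0.5, 0.975)))
    data.frame(parameter = p, median = qs[2], ci_low = qs[1], ci_high = qs[3],
               reliable = qs[1] > 0 || qs[3] < 0,
               rhat = split_rhat(per_chain), ess = ess_basic(per_chain))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
summary.srm_fit <- function(object, ...) summarize_draws(object, ...)

#' Reciprocity correlation estimates
#'
#' Posterior summaries of generalized reciprocity (`rho_gen`, the
#' correlation between a household's sender and receiver effects: do
#' households that nominate many also receive many?) and dyadic reciprocity
#' (`rho_dyad`, the within-dyad correlation: does a tie i -> j co-occur with
#' j -> i beyond what covariates explain?).
#'
#' @param fit `srm_fit`.
#' @return `posterior_summary` with rows `rho_gen` and `rho_dyad`.
#' @export
reciprocity_estimates <- function(fit) {
  summarize_draws(fit, pars = c("rho_gen", "rho_dyad"))
}

#' Block offset and contrast table
#'
#' For each (sender group, receiver group) cell of a block structure,
#' computes per draw the baseline tie probability
#' `p(g,h) = plogis(alpha + B[g,h])` (zero covariates, zero random effects)
#' and the contrast `Delta(g,h) = p(g,h) - p(ref)` relative to the reference
#' cell. The reference defaults to (2,2): both households have the flag,
#' matching contrasts framed relative to ties between flag-holding
#' households. Offsets are reported on the probability scale by default; the
#' log-odds alternative reports `alpha + B[g,h]` and its differences.
#'
#' @param fit `srm_fit` from a model that included the block.
#' @param block block name (`"status"` or `"dev_group"`).
#' @param reference integer pair (sender group, receiver group) of the
#'   reference cell; group 1 = flag absent, 2 = flag present.
#' @param scale `"probability"` (default) or `"logodds"`.
#' @return data frame of class `contrast_table`, one row per cell, with
#'   offset and Delta medians and 95% CIs.
#' @export
block_contrasts <- function(fit, block, reference = c(2, 2),
                            scale = c("probability", "logodds")) {
  scale <- match.arg(scale)
  cells <- expand.grid(g = 1:2, h = 1:2)
  par_of <- function(g, h) paste0("B_", block, "[", g, ",", h, "]")
  if (!par_of(1, 1) %in% colnames(fit$chains[[1]]))
    stop("block '", block, "' not present in fit", call. = FALSE)
  alpha <- unlist(chain_draws(fit, "alpha"))
  off_draw <- function(g, h) {
    eta <- alpha + unlist(chain_draws(fit, par_of(g, h)))
    if (scale == "probability") stats::plogis(eta) else eta
  }
  ref <- off_draw(reference[1], reference[2])
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    g <- cells$g[k]; h <- cells$h[k]
    o <- off_draw(g, h)
    d <- o - ref
    qo <- unname(stats::quantile(o, c(0.025, 0.5, 0.975)))
    qd <- unname(stats::quantile(d, c(0.025, 0.5, 0.975)))
    data.frame(block = block, sender_group = g, receiver_group = h,
               reference = g == reference[1] && h == reference[2],
               offset_median = qo[2], offset_low = qo[1], offset_high = qo[3],
               delta_median = qd[2], delta_low = qd[1], delta_high = qd[3],
               delta_reliable = qd[1] > 0 || qd[3] < 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- scale
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Export posterior draws as a long table
#'
#' @param x `srm_fit`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns `chain`, `iteration`, then one column per
#'   parameter.
#' @export
as.data.frame.srm_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$chains), function(ch) {
    data.frame(chain = ch, iteration = seq_len(nrow(x$chains[[ch]])),
               x$chains[[ch]], check.names = FALSE)
  }))
}
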