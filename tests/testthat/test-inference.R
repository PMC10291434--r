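# A fake fit object (chains of known draws) for summary/contrast tests.
fake_fit <- function(draw_list) {
  structure(list(chains = draw_list, layer = "fake"), class = "srm_fit")
}

test_that("posterior summaries follow the quantile rule and reliability flag", {
  const <- matrix(0.7, 100, 1, dimnames = list(NULL, "a"))
  s <- summarize_draws(list(const, const))
  expect_equal(s$median, 0.7)
  expect_equal(s$ci_low, 0.7)
  expect_equal(s$ci_high, 0.7)
  expect_true(s$reliable)

  sym <- matrix(c(-(1:50), 1:50) / 10, ncol = 1,
                dimnames = list(NULL, "b"))
  expect_false(summarize_draws(list(sym, sym))$reliable)

  grid <- matrix((1:100) / 100, ncol = 1, dimnames = list(NULL, "c"))
  s3 <- summarize_draws(list(grid))
  expect_equal(s3$median, 0.505)
  expect_equal(s3$ci_low, 0.03475, tolerance = 1e-10)
  expect_equal(s3$ci_high, 0.97525, tolerance = 1e-10)
})

test_that("summaries are invariant to chain concatenation order", {
  set.seed(1)
  c1 <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(200, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  s12 <- summarize_draws(list(c1, c2))
  s21 <- summarize_draws(list(c2, c1))
  expect_equal(s12[, c("median", "ci_low", "ci_high", "rhat", "ess")],
               s21[, c("median", "ci_low", "ci_high", "rhat", "ess")])
})

test_that("block contrasts transform draws through the logistic baseline", {
  m <- 200
  mk <- function(B11, B21, B12, B22, alpha = 0) {
    cbind(alpha = rep(alpha, m),
          `B_status[1,1]` = B11, `B_status[2,1]` = B21,
          `B_status[1,2]` = B12, `B_status[2,2]` = B22)
  }
  # identical cells: all deltas 0
  eq <- fake_fit(list(mk(0.3, 0.3, 0.3, 0.3)))
  ct <- block_contrasts(eq, "status")
  expect_equal(ct$delta_median, rep(0, 4))

  # alpha = 0, reference cell 0, target cell 1 in every draw
  one <- fake_fit(list(mk(1, 1, 1, 0)))
  ct2 <- block_contrasts(one, "status", reference = c(2, 2))
  d11 <- ct2$delta_median[ct2$sender_group == 1 & ct2$receiver_group == 1]
  expect_equal(d11, plogis(1) - 0.5, tolerance = 1e-12)

  ref_row <- ct2[ct2$reference, ]
  expect_equal(ref_row$delta_median, 0)
  expect_equal(ref_row$delta_low, 0)
  expect_equal(ref_row$delta_high, 0)

  lo <- block_contrasts(one, "status", reference = c(2, 2), scale = "logodds")
  expect_equal(lo$delta_median[lo$sender_group == 1 & lo$receiver_group == 1],
               1)
  expect_error(block_contrasts(one, "dev_group"), "not present")
})

test_that("the sampler log-posterior gradient matches finite differences", {
  sim <- make_sim_dataset(n = 5, seed = 17, mode = "double")
  inputs <- srmnet:::build_model_inputs(
    sim$data, "net",
    srm_model_spec(sender = "log_wealth", dyadic = "wealth_distance",
                   blocks = character(0)))
  layout <- srmnet:::theta_layout(inputs)
  set.seed(18)
  theta <- rnorm(layout$P, 0, 0.4)
  got <- srmnet:::.srm_lp_grad(theta, inputs)
  eps <- 1e-6
  fd <- vapply(seq_len(layout$P), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + eps; tm[k] <- tm[k] - eps
    (srmnet:::.srm_lp_grad(tp, inputs)$lp -
       srmnet:::.srm_lp_grad(tm, inputs)$lp) / (2 * eps)
  }, 0)
  expect_equal(got$grad, fd, tolerance = 1e-5)
})

test_that("fits are deterministic given a seed and within support", {
  sim <- make_sim_dataset(n = 10, seed = 23)
  mc <- mcmc_control(chains = 2, warmup = 150, samples = 100, L = 10,
                     seed = 42)
  spec <- srm_model_spec(sender = "log_wealth", dyadic = "wealth_distance",
                         blocks = character(0))
  f1 <- suppressWarnings(fit_srm(sim$data, "net", spec, mc))
  f2 <- suppressWarnings(fit_srm(sim$data, "net", spec, mc))
  expect_identical(f1$chains, f2$chains)

  rho <- unlist(lapply(f1$chains, function(m) m[, c("rho_gen", "rho_dyad")]))
  expect_true(all(rho > -1 & rho < 1))
  sig <- unlist(lapply(f1$chains, function(m) m[, "sigma_delta"]))
  expect_true(all(sig > 0))

  rec <- reciprocity_estimates(f1)
  expect_equal(rec$parameter, c("rho_gen", "rho_dyad"))

  tab <- as.data.frame(f1)
  expect_equal(nrow(tab), 200)
  expect_true(all(c("chain", "iteration", "alpha") %in% names(tab)))
})

test_that("posterior sign tracks extreme intercepts (empty/complete graphs)", {
  hh <- make_households(12, seed = 31)
  ids <- hh$household_id
  n <- 12
  empty <- matrix(0L, n, n, dimnames = list(ids, ids))
  full <- 1L - diag(n); dimnames(full) <- list(ids, ids)
  mc <- mcmc_control(chains = 2, warmup = 150, samples = 100, L = 10,
                     seed = 7)
  spec <- srm_model_spec(sender = character(0), dyadic = character(0),
                         blocks = character(0))
  for (adj in list(empty, full)) {
    data <- multiplex_dataset(hh, NULL,
                              list(net = srmnet:::new_layer("net", "single",
                                                            adjacency = adj)))
    f <- suppressWarnings(fit_srm(data, "net", spec, mc,
                                  store_effects = FALSE))
    a <- unlist(lapply(f$chains, function(m) m[, "alpha"]))
    if (sum(adj) == 0) expect_true(all(a < 0)) else expect_true(all(a > 0))
  }
})
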