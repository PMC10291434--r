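test_that("log-normal Gini calibration hits its target", {
  sig <- lognormal_sigma_for_gini(0.38)
  expect_equal(2 * pnorm(sig / sqrt(2)) - 1, 0.38, tolerance = 1e-12)

  cfg <- scenario_config()
  w <- generate_wealth(cfg, seed = 2, n = 10000)
  expect_equal(gini(w), 0.38, tolerance = 0.01)
  expect_equal(gini(100 * w), gini(w), tolerance = 1e-12)

  tiny <- generate_wealth(cfg, seed = 3, n = 5000, target_gini = 1e-6)
  expect_lt(gini(tiny), 1e-4)
})

test_that("pedigrees are acyclic, reproducible, and relate households", {
  cfg <- scenario_config(n_households = 20)
  p1 <- generate_pedigree(cfg, seed = 5)
  p2 <- generate_pedigree(cfg, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$households), 20)

  r <- kinship_relatedness(p1$individuals) # errors on any cycle
  hr <- household_relatedness(r, p1$individuals,
                              households = p1$households$household_id)
  off <- hr[upper.tri(hr)]
  expect_gt(mean(off), 0) # settlement by related patrilines

  # brother households: sons of the same origin couple head different
  # households; their household relatedness reflects shared ancestry
  sibs <- p1$individuals[!is.na(p1$individuals$father_id), ]
  fam <- split(sibs, sibs$father_id)
  fam <- Filter(function(d) length(unique(d$household_id)) > 1, fam)
  expect_gt(length(fam), 0)
  d <- fam[[1]]
  hhs <- unique(d$household_id)[1:2]
  expect_gt(hr[hhs[1], hhs[2]], 0)
})

test_that("two-generation founders are related only through descent", {
  ped <- data.frame(
    individual_id = c("f1", "m1", "f2", "m2", "k1", "k2"),
    household_id = c("h1", "h1", "h2", "h2", "h1", "h2"),
    father_id = c(NA, NA, NA, NA, "f1", "f2"),
    mother_id = c(NA, NA, NA, NA, "m1", "m2"))
  r <- kinship_relatedness(ped)
  expect_equal(r["f1", "f2"], 0)
  expect_equal(r["k1", "k2"], 0)
  expect_equal(r["f1", "k1"], 0.5)
})

test_that("generated communities satisfy every dataset invariant", {
  com <- generate_community(scenario_config(), seed = 1)
  expect_length(validate_dataset(com$data), 0)
  expect_equal(nrow(com$data$households), 44)
  expect_equal(length(unique(com$data$households$hamlet)), 4)
  expect_length(com$data$layers, 5)
  expect_equal(com$data$layers$food_sharing$mode, "double")

  # determinism down to the written fixture files
  com2 <- generate_community(scenario_config(), seed = 1)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(com$data, d1)
  write_dataset(com2$data, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("realized layer densities match the generating probabilities", {
  com <- generate_community(scenario_config(), seed = 9)
  n <- nrow(com$data$households)
  np <- n * (n - 1)
  for (nm in names(com$truth$layers)) {
    tr <- com$truth$layers[[nm]]
    dens <- sum(tr$true_adjacency) / np
    pbar <- tr$mean_prob # implied density given the realized effects
    expect_lt(abs(dens - pbar), 3 * sqrt(pbar * (1 - pbar) / np))
  }
  # the double-sampled reports have elevated density only through error
  fl <- com$data$layers$food_sharing
  tr <- com$truth$layers$food_sharing
  d_true <- sum(tr$true_adjacency) / np
  d_out <- sum(fl$out_reports) / np
  m <- tr$meas
  expected_out <- d_true * m$recall_give + (1 - d_true) * m$fp_give
  expect_lt(abs(d_out - expected_out),
            3 * sqrt(expected_out * (1 - expected_out) / np))
})

test_that("scenario YAML round-trips into a usable configuration", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_households: 16",
    "n_hamlets: 2",
    "gini_wealth: 0.40",
    "layers:",
    "  friendship_f:",
    "    mode: single",
    "    params:",
    "      alpha: -2.0",
    "      gamma: {log_wealth: 0.5, wealth_distance: -0.3,",
    "              relatedness: 0.4, distance: -0.4}",
    "      sigma_lambda: 0.5",
    "      sigma_pi: 0.5",
    "      sigma_delta: 0.8",
    "      B_status: [[0, 0], [0, 0.5]]",
    "  food_sharing:",
    "    mode: double",
    "    cross: [friendship_f]",
    "    params:",
    "      alpha: -2.0",
    "      gamma: {log_wealth: 0.5, wealth_distance: 0.0,",
    "              relatedness: 0.4, distance: -0.4, friendship_f: 0.6}",
    "      sigma_lambda: 0.5",
    "      sigma_pi: 0.5",
    "      sigma_delta: 0.8",
    "    meas:",
    "      recall_give: 0.9",
    "      recall_receive: 0.85",
    "      fp_give: 0.05",
    "      fp_receive: 0.03"), path)
  cfg <- scenario_from_yaml(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$n_households, 16)
  expect_equal(cfg$layers$food_sharing$meas$recall_receive, 0.85)
  expect_equal(cfg$layers$friendship_f$params$B$status[2, 2], 0.5)
  com <- generate_community(cfg, seed = 4)
  expect_length(validate_dataset(com$data), 0)
  expect_length(com$data$layers, 2)
})
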