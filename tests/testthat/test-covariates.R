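test_that("kinship relatedness reproduces the canonical pedigree values", {
  r <- kinship_relatedness(make_pedigree())
  expect_equal(r["gpF", "A"], 0.5)    # parent-offspring
  expect_equal(r["A", "B"], 0.5)      # full sibs
  expect_equal(r["C", "D"], 0.125)    # first cousins (parents full sibs)
  expect_equal(r["A", "wifeA"], 0)    # unrelated founders
  expect_equal(r["A", "A"], 1)        # non-inbred diagonal

  half <- data.frame(individual_id = c("f", "m1", "m2", "k1", "k2"),
                     household_id = "h",
                     father_id = c(NA, NA, NA, "f", "f"),
                     mother_id = c(NA, NA, NA, "m1", "m2"))
  expect_equal(kinship_relatedness(half)["k1", "k2"], 0.25) # half sibs
})

test_that("relatedness halves per generation along a descent chain", {
  ids <- c("a0", paste0("m", 1:4), paste0("a", 1:4))
  ped <- data.frame(
    individual_id = ids, household_id = "h",
    father_id = c(NA, rep(NA, 4), paste0("a", 0:3)),
    mother_id = c(NA, rep(NA, 4), paste0("m", 1:4)))
  r <- kinship_relatedness(ped)
  for (k in 1:4) expect_equal(r["a0", paste0("a", k)], 0.5^k)
})

test_that("pedigree cycles are rejected with the offending individual named", {
  bad <- data.frame(individual_id = c("x", "y"), household_id = "h",
                    father_id = c("y", "x"), mother_id = c(NA, NA))
  expect_error(kinship_relatedness(bad), "cycle")
})

test_that("household relatedness averages cross pairs and ignores ordering", {
  r <- matrix(0, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d")))
  r["a", "c"] <- r["c", "a"] <- 0.5
  r["a", "d"] <- r["d", "a"] <- 0.25
  r["b", "c"] <- r["c", "b"] <- 0.25
  diag(r) <- 1
  mem <- data.frame(individual_id = c("a", "b", "c", "d"),
                    household_id = c("g", "g", "h", "h"))
  hr <- household_relatedness(r, mem)
  expect_equal(hr["g", "h"], mean(c(0.5, 0.25, 0.25, 0)))
  expect_equal(diag(hr), c(g = 0, h = 0))

  perm <- sample(4)
  hr2 <- household_relatedness(r[perm, perm], mem[perm, ],
                               households = c("g", "h"))
  expect_equal(hr2, hr)

  single <- household_relatedness(r[c("a", "c"), c("a", "c")],
                                  mem[mem$individual_id %in% c("a", "c"), ])
  expect_equal(single["g", "h"], 0.5)

  expect_error(household_relatedness(r, mem, households = c("g", "h", "z")),
               "zero members")
})

test_that("geographic distance matches closed-form arcs on the sphere", {
  hh <- data.frame(household_id = c("o", "north", "antip"),
                   latitude = c(0, 1, 0), longitude = c(0, 0, 180))
  d <- geographic_distance(hh)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "north"], pi * 6371000 / 180, tolerance = 0.1 / 111194)
  expect_equal(d["o", "antip"], pi * 6371000, tolerance = 1 / 2e7)
  expect_true(isSymmetric(unname(d)))
})

test_that("geographic distance satisfies the triangle inequality", {
  set.seed(9)
  for (k in 1:20) {
    hh <- data.frame(household_id = c("a", "b", "c"),
                     latitude = runif(3, -80, 80),
                     longitude = runif(3, -180, 180))
    d <- geographic_distance(hh)
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-6 * d["a", "c"])
  }
})

test_that("standardization centers, scales, and is idempotent", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$center, 2)
  expect_equal(s$scale, 1)
  expect_equal(standardize(s$values)$values, s$values, tolerance = 1e-12)
  expect_error(standardize(rep(4, 5)), "constant")

  set.seed(2)
  m <- matrix(rnorm(49, 5, 3), 7, 7)
  sm <- standardize(m)
  off <- row(m) != col(m)
  expect_equal(mean(sm$values[off]), 0, tolerance = 1e-8)
  expect_equal(sd(sm$values[off]), 1, tolerance = 1e-8)
  expect_equal(diag(sm$values), rep(0, 7))
})

test_that("wealth covariates standardize log wealth and its dyadic distance", {
  wc <- wealth_covariates(c(1, exp(1), exp(2)))
  expect_equal(wc$W, c(-1, 0, 1))
  expect_equal(wc$W_std$center, 1)
  set.seed(3)
  w <- rlnorm(10, 12, 1)
  wb <- wealth_covariates(w)$Wbar
  expect_equal(wb, t(wb))
  expect_error(wealth_covariates(c(1, 0, 2)), "positive")
  # equal wealth: dyadic distances are all zero, a degenerate input for
  # standardization
  expect_error(wealth_covariates(rep(10, 5)), "constant")
})

test_that("polygynous male property splits equally among wives", {
  own <- data.frame(household_id = c("w1", "w2"), own_value = c(10, 20))
  mar <- data.frame(husband_id = c("hub", "hub"), household_id = c("w1", "w2"))
  prop <- data.frame(husband_id = "hub", value = 100)
  out <- split_polygynous(own, mar, prop)
  expect_equal(out$wealth_total[match(c("w1", "w2"), out$household_id)],
               c(60, 70))

  mono <- split_polygynous(data.frame(household_id = "w", own_value = 5),
                           data.frame(husband_id = "h", household_id = "w"),
                           data.frame(husband_id = "h", value = 40))
  expect_equal(mono$wealth_total, 45)

  none <- split_polygynous(own, mar,
                           data.frame(husband_id = character(0),
                                      value = numeric(0)))
  expect_equal(none$wealth_total, c(10, 20))

  expect_error(split_polygynous(own, mar,
                                data.frame(husband_id = "ghost", value = 1)),
               "no mapped husband")
})

test_that("gini matches the pairwise-difference oracle and is scale invariant", {
  gini_brute <- function(x) {
    s <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) s <- s + abs(x[i] - x[j])
    s / (2 * length(x)^2 * mean(x))
  }
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(rep(7, 9)), 0)
  set.seed(4)
  for (k in 1:5) {
    x <- rlnorm(30, 0, 1)
    expect_equal(gini(x), gini_brute(x), tolerance = 1e-12)
    expect_equal(gini(100 * x), gini(x), tolerance = 1e-12)
  }
  expect_equal(gini(c(1, 2, 3), corrected = TRUE),
               gini(c(1, 2, 3)) * 3 / 2)
  expect_error(gini(c(0, 0)), "all-zero")
  expect_error(gini(c(-1, 2)), "nonnegative")
})
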