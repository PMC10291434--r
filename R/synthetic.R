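#' Scenario configuration for the synthetic community generator
#'
#' Defaults emulate the study community: 44 households across 4 hamlets
#' within roughly a 1 km square, right-skewed household wealth with a
#' log-normal calibrated so the population Gini equals 0.38 (clove-tree
#' value 0.62), a shallow patrilocal pedigree descending from a few related
#' founder men (which yields nonzero between-household relatedness), binary
#' religious-status and development-group flags, and five directed network
#' layers simulated from known social-relations-model parameters — food
#' sharing double-sampled through the reporting-error model, the
#' gender-specific friendship and co-working layers single-sampled.
#'
#' @param n_households number of households (>= 4).
#' @param n_hamlets number of hamlets.
#' @param hamlet_spread_m side of the square (metres) over which hamlet
#'   centroids are placed.
#' @param hamlet_jitter_m within-hamlet scatter (sd, metres).
#' @param gini_wealth target population Gini of cash wealth.
#' @param gini_clove target population Gini of clove-tree value.
#' @param median_wealth median household wealth in local currency units.
#' @param status_prev,dev_prev prevalence of the status and
#'   development-group flags.
#' @param n_lineages founder patrilines; `generations` pedigree depth;
#'   `kids_mean` mean number of children per couple; `patrilocal_rate`
#'   probability a new household settles in the father's hamlet;
#'   `intermarry_rate` probability a groom marries within the village.
#' @param generations,kids_mean,patrilocal_rate,intermarry_rate see above.
#' @param layers named list of per-layer truth: each element has `mode`,
#'   `params` (`srm_parameters`), optional `meas`
#'   (`measurement_parameters`), and `cross` (names of earlier layers
#'   entering as dyadic predictors). Defaults via [default_layer_truth()].
#' @param standardize_covariates standardize relatedness and distance
#'   matrices (wealth terms are always standardized).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_households = 44, n_hamlets = 4,
                            hamlet_spread_m = 700, hamlet_jitter_m = 60,
                            gini_wealth = 0.38, gini_clove = 0.62,
                            median_wealth = 1e6,
                            status_prev = 0.2, dev_prev = 0.35,
                            n_lineages = 5, generations = 3,
                            kids_mean = 3.5, patrilocal_rate = 0.85,
                            intermarry_rate = 0.6,
                            layers = default_layer_truth(),
                            standardize_covariates = TRUE) {
  stopifnot(n_households >= 4, status_prev >= 0, status_prev <= 1,
            dev_prev >= 0, dev_prev <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Default ground-truth parameters for the five layers
#'
#' Illustrative parameter sets whose qualitative sign structure matches the
#' patterns the model is meant to detect: positive wealth-sender effects in
#' every layer; wealth homophily (negative wealth-distance) only in the
#' women's layers; relatedness effects in food sharing and the women's
#' layers but not the men's; distance decay everywhere except men's
#' co-working; dyadic reciprocity concentrated in men's co-working; food
#' sharing predicted by all four other layers.
#'
#' @return named list of layer truth blocks (see [scenario_config()]).
#' @export
default_layer_truth <- function() {
  base <- function(alpha, gamma, rho_dyad = 0.1, B_S = matrix(0, 2, 2),
                   B_M = matrix(0, 2, 2)) {
    srm_parameters(alpha = alpha, gamma = gamma,
                   sigma_lambda = 0.7, sigma_pi = 0.7, rho_gen = 0.1,
                   sigma_delta = 1, rho_dyad = rho_dyad,
                   B = list(status = B_S, dev_group = B_M))
  }
  BM_friend <- matrix(c(0, 0, 0, 0.6), 2, 2) # (2,2): both in dev group
  BS_food <- matrix(c(0, 0, 0, -0.6), 2, 2)
  BM_food <- matrix(c(-0.5, 0, -0.5, 0), 2, 2) # (1,1) and (1,2) lower
  list(
    friendship_f = list(mode = "single", cross = character(0),
      params = base(-2.5, c(log_wealth = 0.4, wealth_distance = -0.3,
                            relatedness = 0.5, distance = -0.4),
                    B_M = BM_friend)),
    coworking_f = list(mode = "single", cross = "friendship_f",
      params = base(-2.5, c(log_wealth = 0.4, wealth_distance = -0.3,
                            relatedness = 0.5, distance = -0.4,
                            friendship_f = 0.8))),
    friendship_m = list(mode = "single", cross = character(0),
      params = base(-2.5, c(log_wealth = 0.4, wealth_distance = 0,
                            relatedness = 0.1, distance = -0.4),
                    B_M = BM_friend)),
    coworking_m = list(mode = "single", cross = "friendship_m",
      params = base(-2.5, c(log_wealth = 0.4, wealth_distance = 0,
                            relatedness = 0.1, distance = 0,
                            friendship_m = 0.8), rho_dyad = 0.5)),
    food_sharing = list(mode = "double",
      cross = c("friendship_f", "coworking_f", "friendship_m", "coworking_m"),
      params = base(-2.5, c(log_wealth = 0.4, wealth_distance = 0,
                            relatedness = 0.5, distance = -0.4,
                            friendship_f = 0.4, coworking_f = 0.6,
                            friendship_m = 0.4, coworking_m = 0.4),
                    B_S = BS_food, B_M = BM_food),
      meas = measurement_parameters(recall_give = 0.9, recall_receive = 0.85,
                                    fp_give = 0.05, fp_receive = 0.03)))
}

#' Log-normal scale parameter matching a target Gini
#'
#' For a log-normal distribution the population Gini is
#' \eqn{G = 2\Phi(\sigma/\sqrt 2) - 1}, so the scale solving a target G is
#' \eqn{\sigma = \sqrt 2\, \Phi^{-1}((1+G)/2)}.
#'
#' @param target_gini Gini in (0, 1).
#' @return log-normal sdlog.
#' @export
lognormal_sigma_for_gini <- function(target_gini) {
  stopifnot(target_gini > 0, target_gini < 1)
  sqrt(2) * stats::qnorm((1 + target_gini) / 2)
}

#' Generate household wealth draws
#'
#' Log-normal draws with the scale calibrated so the population Gini equals
#' the configured target; the location sets the median wealth.
#'
#' @param config `scenario_config`.
#' @param seed integer seed.
#' @param n number of draws (defaults to the configured household count).
#' @param target_gini Gini target (defaults to the cash-wealth target).
#' @return positive numeric vector.
#' @export
generate_wealth <- function(config = scenario_config(), seed = 1,
                            n = config$n_households,
                            target_gini = config$gini_wealth) {
  set.seed(seed)
  sig <- lognormal_sigma_for_gini(target_gini)
  stats::rlnorm(n, meanlog = log(config$median_wealth), sdlog = sig)
}

#' Generate a patrilocal pedigree and household roster
#'
#' Builds a shallow pedigree descending from a few patrilines of related
#' founder men (brothers sharing an origin couple), with sons founding new
#' households at marriage — in the father's hamlet with probability
#' `patrilocal_rate` — and marrying village daughters from other lineages
#' with probability `intermarry_rate` (immigrant brides otherwise). The
#' process stops opening households at the configured count; a shortfall is
#' filled with unrelated immigrant founder couples.
#'
#' @param config `scenario_config`.
#' @param seed integer seed.
#' @return list with `individuals` (individual_id, household_id, father_id,
#'   mother_id, sex) and `households` (household_id, hamlet).
#' @export
generate_pedigree <- function(config = scenario_config(), seed = 1) {
  set.seed(seed)
  hamlets <- paste0("hamlet_", seq_len(config$n_hamlets))
  n_target <- config$n_households

  ind <- list()
  hh_id <- character(0); hh_ham <- character(0)
  nid <- 0L
  new_ind <- function(hh, fa = NA_character_, mo = NA_character_, sex) {
    nid <<- nid + 1L
    id <- sprintf("I%04d", nid)
    ind[[id]] <<- data.frame(individual_id = id, household_id = hh,
                             father_id = fa, mother_id = mo, sex = sex)
    id
  }
  new_hh <- function(ham) {
    k <- length(hh_id) + 1L
    id <- sprintf("H%03d", k)
    hh_id <<- c(hh_id, id); hh_ham <<- c(hh_ham, ham)
    id
  }
  move <- function(id, hh) ind[[id]]$household_id <<- hh

  # couples awaiting children: list of (father, mother, household, lineage)
  couples <- list()
  brides <- list() # unmarried village daughters: (id, lineage)

  for (l in seq_len(config$n_lineages)) {
    if (length(hh_id) >= n_target) break
    ham <- hamlets[(l - 1L) %% config$n_hamlets + 1L]
    h1 <- new_hh(ham)
    gf <- new_ind(h1, sex = "m") # origin couple lives with the first brother
    gm <- new_ind(h1, sex = "f")
    n_brothers <- sample(2:3, 1)
    for (b in seq_len(n_brothers)) {
      hh <- if (b == 1) h1 else if (length(hh_id) < n_target) new_hh(ham)
            else NA_character_
      if (is.na(hh)) next
      son <- new_ind(hh, gf, gm, "m")
      wife <- new_ind(hh, sex = "f") # immigrant founder bride
      couples[[length(couples) + 1L]] <-
        list(fa = son, mo = wife, hh = hh, lineage = l)
    }
  }

  for (g in seq_len(max(0, config$generations - 1))) {
    next_couples <- list()
    for (cp in couples) {
      n_kids <- stats::rpois(1, config$kids_mean)
      if (n_kids == 0) next
      sexes <- sample(c("m", "f"), n_kids, replace = TRUE)
      for (s in sexes) {
        kid <- new_ind(cp$hh, cp$fa, cp$mo, s)
        if (s == "f") {
          brides[[length(brides) + 1L]] <- list(id = kid, lineage = cp$lineage)
        } else if (length(hh_id) < n_target) {
          # son marries and founds a patrilocal household
          ham <- if (stats::runif(1) < config$patrilocal_rate)
            hh_ham[match(cp$hh, hh_id)] else sample(hamlets, 1)
          hh_new <- new_hh(ham)
          move(kid, hh_new)
          ok <- vapply(brides, function(b) b$lineage != cp$lineage, TRUE)
          if (any(ok) && stats::runif(1) < config$intermarry_rate) {
            pick <- sample(which(ok), 1)
            wife <- brides[[pick]]$id
            brides <- brides[-pick]
            move(wife, hh_new)
          } else {
            wife <- new_ind(hh_new, sex = "f")
          }
          next_couples[[length(next_couples) + 1L]] <-
            list(fa = kid, mo = wife, hh = hh_new, lineage = cp$lineage)
        }
      }
    }
    couples <- next_couples
    if (length(hh_id) >= n_target && g >= 1) next
  }

  while (length(hh_id) < n_target) { # immigrant founder couples fill up
    hh <- new_hh(sample(hamlets, 1))
    new_ind(hh, sex = "m")
    new_ind(hh, sex = "f")
  }

  individuals <- do.call(rbind, unname(ind))
  rownames(individuals) <- NULL
  list(individuals = individuals,
       households = data.frame(household_id = hh_id, hamlet = hh_ham))
}

#' Generate a full synthetic community with known ground truth
#'
#' Composes the generator: pedigree and households, hamlet-clustered GPS
#' coordinates, log-normal wealth, binary flags, dyadic covariates built
#' through the covariate constructors, and the configured network layers
#' simulated from their true parameters (double-sampled layers pass through
#' the reporting-error model). Everything derives from one master seed.
#'
#' @param config `scenario_config`.
#' @param seed master seed.
#' @return list with `data` (`multiplex_dataset`), `truth` (per-layer true
#'   parameters, measurement parameters, realized random effects and true
#'   adjacencies), and `config`.
#' @export
generate_community <- function(config = scenario_config(), seed = 1) {
  ped <- generate_pedigree(config, seed = seed)
  set.seed(seed + 1L)
  hh <- ped$households
  n <- nrow(hh)
  ids <- hh$household_id

  # hamlet centroids on a square grid, coordinates jittered around them
  base_lat <- -5.20; base_lon <- 39.75
  m_per_deg <- pi * 6371000 / 180
  side <- ceiling(sqrt(config$n_hamlets))
  cent <- expand.grid(x = seq_len(side), y = seq_len(side))[
    seq_len(config$n_hamlets), ]
  cent <- cent * config$hamlet_spread_m / side
  hi <- match(hh$hamlet, paste0("hamlet_", seq_len(config$n_hamlets)))
  ey <- cent$y[hi] + stats::rnorm(n, 0, config$hamlet_jitter_m)
  ex <- cent$x[hi] + stats::rnorm(n, 0, config$hamlet_jitter_m)
  lat <- base_lat + ey / m_per_deg
  lon <- base_lon + ex / (m_per_deg * cos(base_lat * pi / 180))

  wealth <- generate_wealth(config, seed = seed + 2L, n = n)
  clove <- generate_wealth(config, seed = seed + 3L, n = n,
                           target_gini = config$gini_clove)
  set.seed(seed + 4L)
  status <- stats::rbinom(n, 1, config$status_prev)
  devg <- stats::rbinom(n, 1, config$dev_prev)

  households <- as_household_table(data.frame(
    household_id = ids, wealth_total = wealth, status_flag = status,
    dev_group_flag = devg, hamlet = hh$hamlet,
    latitude = lat, longitude = lon))
  households$clove_value <- clove

  # dyadic covariates
  r_ind <- kinship_relatedness(ped$individuals)
  R <- household_relatedness(r_ind, ped$individuals, households = ids)
  D <- geographic_distance(households)
  wc <- wealth_covariates(wealth)
  covs <- list(wealth_distance = wc$Wbar)
  if (config$standardize_covariates) {
    covs$relatedness <- tryCatch(standardize(R)$values, error = function(e) R)
    covs$distance <- standardize(D)$values
  } else {
    covs$relatedness <- R
    covs$distance <- D
  }
  for (nm in names(covs)) dimnames(covs[[nm]]) <- list(ids, ids)

  # network layers, in configuration order so cross-layer predictors exist
  layers <- list()
  truth <- list(layers = list())
  blocks <- list(status = status + 1L, dev_group = devg + 1L)
  seed_k <- seed + 10L
  for (nm in names(config$layers)) {
    def <- config$layers[[nm]]
    dy <- covs[c("wealth_distance", "relatedness", "distance")]
    for (cl in def$cross) dy[[cl]] <- layer_adjacency(layers[[cl]]) * 1.0
    bundle <- srm_covariates(sender = list(log_wealth = wc$W),
                             dyadic = dy, blocks = blocks)
    sim <- simulate_network(def$params, bundle, seed = seed_k, name = nm)
    seed_k <- seed_k + 1L
    dimnames(sim$layer$adjacency) <- list(ids, ids)
    pmat <- tie_probabilities(def$params, sim$effects, bundle)
    tr <- list(params = def$params, effects = sim$effects,
               true_adjacency = sim$layer$adjacency,
               mean_prob = mean(pmat[row(pmat) != col(pmat)]))
    if (def$mode == "double") {
      layers[[nm]] <- simulate_reports(sim$layer, def$meas,
                                       seed = seed_k, name = nm)
      seed_k <- seed_k + 1L
      tr$meas <- def$meas
    } else {
      layers[[nm]] <- sim$layer
    }
    truth$layers[[nm]] <- tr
  }

  data <- multiplex_dataset(households, ped$individuals, layers, covs)
  list(data = data, truth = truth, config = config, seed = seed)
}

#' Read a scenario configuration from YAML
#'
#' The YAML mirrors [scenario_config()]; per-layer `params` blocks are plain
#' mappings (`alpha`, `gamma`, `sigma_lambda`, ..., `B_status`, `B_dev_group`
#' as 4-element row-major lists) and `meas` maps to
#' [measurement_parameters()] fields.
#'
#' @param path YAML file.
#' @return `scenario_config`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$layers)) {
    y$layers <- lapply(y$layers, function(def) {
      p <- def$params
      B <- list()
      for (bn in c("status", "dev_group")) {
        key <- paste0("B_", bn)
        if (!is.null(p[[key]])) {
          B[[bn]] <- matrix(unlist(p[[key]]), 2, 2, byrow = TRUE)
          p[[key]] <- NULL
        }
      }
      p$gamma <- unlist(p$gamma)
      p$B <- B
      def$params <- do.call(srm_parameters, p)
      if (!is.null(def$meas))
        def$meas <- do.call(measurement_parameters, def$meas)
      def$cross <- as.character(def$cross %||% character(0))
      def
    })
  }
  do.call(scenario_config, y)
}
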