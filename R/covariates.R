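#' Pairwise relatedness from a pedigree
#'
#' Computes Wright's coefficient of relatedness \eqn{r} for every pair of
#' individuals by the tabular kinship recursion: processing individuals so
#' that parents precede offspring, the kinship coefficient is
#' \eqn{\phi(i,j) = (\phi(f_i,j) + \phi(m_i,j))/2} with missing parents
#' contributing zero, \eqn{\phi(i,i) = (1 + \phi(f_i,m_i))/2}, and
#' \eqn{r = 2\phi}. Founders are assumed unrelated and non-inbred, so the
#' diagonal is 1 for founders (and only exceeds 1 under inbred matings).
#'
#' @param individuals data frame with columns `individual_id`,
#'   `household_id`, `father_id`, `mother_id` (parents `NA` for founders).
#' @return symmetric matrix of relatedness values with individual ids as
#'   dimnames; off-diagonal entries lie in `[0, 1]` for non-inbred pedigrees.
#' @examples
#' ped <- data.frame(individual_id = c("f", "m", "kid"),
#'                   household_id  = c("h1", "h1", "h1"),
#'                   father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"))
#' kinship_relatedness(ped)["f", "kid"]  # 0.5
#' @export
kinship_relatedness <- function(individuals) {
  individuals <- validate_individuals(individuals)
  ids <- individuals$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- match(individuals$father_id, ids)
  mo <- match(individuals$mother_id, ids)

  ord <- pedigree_order(ids, fa, mo)

  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    pf <- fa[i]; pm <- mo[i]
    phi_fm <- if (!is.na(pf) && !is.na(pm)) phi[pf, pm] else 0
    phi[i, i] <- 0.5 * (1 + phi_fm)
    for (j in ord) {
      if (j == i) break
      v <- 0
      if (!is.na(pf)) v <- v + phi[pf, j]
      if (!is.na(pm)) v <- v + phi[pm, j]
      phi[i, j] <- phi[j, i] <- 0.5 * v
    }
  }
  2 * phi
}

# Topological order (parents before children); names the individual on a cycle.
pedigree_order <- function(ids, fa, mo) {
  n <- length(ids)
  state <- integer(n) # 0 unvisited, 1 in progress, 2 done
  ord <- integer(0)
  visit <- function(i) {
    if (state[i] == 2L) return(invisible())
    if (state[i] == 1L)
      stop("pedigree cycle involving individual '", ids[i], "'", call. = FALSE)
    state[i] <<- 1L
    if (!is.na(fa[i])) visit(fa[i])
    if (!is.na(mo[i])) visit(mo[i])
    state[i] <<- 2L
    ord <<- c(ord, i)
  }
  for (i in seq_len(n)) visit(i)
  ord
}

validate_individuals <- function(individuals) {
  req <- c("individual_id", "household_id", "father_id", "mother_id")
  miss <- setdiff(req, names(individuals))
  if (length(miss))
    stop("individuals table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$father_id <- as.character(individuals$father_id)
  individuals$mother_id <- as.character(individuals$mother_id)
  dup <- individuals$individual_id[duplicated(individuals$individual_id)]
  if (length(dup))
    stop("duplicate individual_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (col in c("father_id", "mother_id")) {
    ref <- individuals[[col]]
    bad <- !is.na(ref) & !(ref %in% individuals$individual_id)
    if (any(bad))
      stop("unknown ", col, ": ", paste(unique(ref[bad]), collapse = ", "),
           call. = FALSE)
  }
  individuals
}

#' Aggregate individual relatedness to the household level
#'
#' Household-pair relatedness is the arithmetic mean of relatedness over all
#' cross pairs (one member from each household). Self-relatedness never enters
#' the aggregation: the diagonal of the returned matrix is set to zero, since
#' the dyadic model has no self-ties.
#'
#' @param r symmetric individual relatedness matrix with ids as dimnames.
#' @param membership data frame with columns `individual_id`, `household_id`,
#'   or a named character vector mapping individual id to household id.
#' @param households optional character vector fixing household order of the
#'   output; defaults to order of first appearance.
#' @return symmetric n x n household matrix, zero diagonal.
#' @export
household_relatedness <- function(r, membership, households = NULL) {
  if (is.data.frame(membership)) {
    map <- stats::setNames(as.character(membership$household_id),
                           as.character(membership$individual_id))
  } else {
    map <- membership
  }
  ids <- rownames(r)
  if (is.null(ids)) stop("relatedness matrix must carry individual ids")
  if (!all(ids %in% names(map)))
    stop("individuals without household mapping: ",
         paste(setdiff(ids, names(map)), collapse = ", "), call. = FALSE)
  hh_of <- map[ids]
  if (is.null(households)) households <- unique(unname(hh_of))
  empty <- setdiff(households, hh_of)
  if (length(empty))
    stop("household with zero members: ", paste(empty, collapse = ", "),
         call. = FALSE)
  n <- length(households)
  out <- matrix(0, n, n, dimnames = list(households, households))
  members <- split(seq_along(ids), hh_of)
  for (g in seq_len(n)) {
    for (h in seq_len(n)) {
      if (h >= g) next
      block <- r[members[[households[g]]], members[[households[h]]],
                 drop = FALSE]
      out[g, h] <- out[h, g] <- mean(block)
    }
  }
  out
}

#' Great-circle distance matrix between households
#'
#' Haversine distance on a sphere of radius 6,371,000 m from decimal-degree
#' GPS coordinates.
#'
#' @param households a `household_table` (or data frame with `household_id`,
#'   `latitude`, `longitude`).
#' @return symmetric n x n matrix of distances in metres, zero diagonal,
#'   household ids as dimnames.
#' @export
geographic_distance <- function(households) {
  check_coords(households)
  pts <- cbind(households$longitude, households$latitude)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000))
  ids <- as.character(households$household_id)
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  d
}

check_coords <- function(households) {
  la <- households$latitude; lo <- households$longitude
  if (any(is.na(la)) || any(is.na(lo)))
    stop("missing GPS coordinates", call. = FALSE)
  if (any(la < -90 | la > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lo < -180 | lo > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(households)
}

#' Standardize a vector or dyadic matrix
#'
#' Centers and scales to mean 0, sd 1. For a matrix only the off-diagonal
#' entries define the center and scale (the diagonal is structural in dyadic
#' matrices and is left at zero). The pre-standardization center and scale are
#' retained for back-transformation.
#'
#' @param x numeric vector or square matrix.
#' @return object of class `standardized` with fields `values`, `center`,
#'   `scale`.
#' @export
standardize <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("matrix must be square", call. = FALSE)
    off <- row(x) != col(x)
    ctr <- mean(x[off])
    scl <- stats::sd(x[off])
    if (!is.finite(scl) || scl < 1e-14)
      stop("cannot standardize a constant input (sd = 0)", call. = FALSE)
    v <- x
    v[off] <- (x[off] - ctr) / scl
    diag(v) <- 0
  } else {
    ctr <- mean(x)
    scl <- stats::sd(x)
    if (!is.finite(scl) || scl < 1e-14)
      stop("cannot standardize a constant input (sd = 0)", call. = FALSE)
    v <- (x - ctr) / scl
  }
  structure(list(values = v, center = ctr, scale = scl),
            class = "standardized")
}

#' @export
print.standardized <- function(x, ...) {
  cat("standardized", if (is.matrix(x$values)) "matrix" else "vector",
      sprintf("(center %.4g, scale %.4g)\n", x$center, x$scale))
  invisible(x)
}

#' Wealth covariates for the dyadic model
#'
#' Builds the household-level wealth term `W` (standardized log wealth) and
#' the dyadic wealth-distance term `Wbar` (standardized absolute difference in
#' log wealth), the operationalization of wealth homophily: a negative
#' coefficient on `Wbar` means ties concentrate among similarly wealthy
#' households.
#'
#' @param wealth positive numeric vector of household wealth (cash value).
#' @return list with `W` (standardized vector), `Wbar` (standardized matrix),
#'   and the `standardized` objects `W_std`, `Wbar_std` carrying center/scale.
#' @export
wealth_covariates <- function(wealth) {
  if (any(!is.finite(wealth)) || any(wealth <= 0))
    stop("wealth must be positive", call. = FALSE)
  lw <- log(wealth)
  raw <- abs(outer(lw, lw, "-"))
  diag(raw) <- 0
  W_std <- standardize(lw)
  Wbar_std <- standardize(raw)
  list(W = W_std$values, Wbar = Wbar_std$values,
       W_std = W_std, Wbar_std = Wbar_std)
}

#' Assign wealth to wives' households in polygynous marriages
#'
#' Each wife heads her own household holding her own assets plus an equal
#' share of the cash value of items culturally viewed as male property
#' (trees, fishing tackle, equipment), split across the husband's wives.
#'
#' @param own_assets data frame with `household_id`, `own_value`.
#' @param marriages data frame with `husband_id`, `household_id` (one row per
#'   wife's household).
#' @param male_property data frame with `husband_id`, `value`.
#' @return data frame `household_id`, `wealth_total`.
#' @export
split_polygynous <- function(own_assets, marriages, male_property) {
  unmapped <- setdiff(male_property$husband_id, marriages$husband_id)
  if (length(unmapped))
    stop("male property with no mapped husband: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  prop <- stats::setNames(male_property$value, male_property$husband_id)
  n_wives <- table(marriages$husband_id)
  share <- stats::setNames(numeric(nrow(own_assets)), own_assets$household_id)
  for (k in seq_len(nrow(marriages))) {
    hb <- as.character(marriages$husband_id[k])
    hh <- as.character(marriages$household_id[k])
    if (hb %in% names(prop))
      share[hh] <- share[hh] + prop[[hb]] / as.numeric(n_wives[[hb]])
  }
  data.frame(household_id = own_assets$household_id,
             wealth_total = own_assets$own_value +
               share[as.character(own_assets$household_id)],
             row.names = NULL)
}

#' Gini coefficient of a nonnegative vector
#'
#' Population Gini by mean absolute difference,
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}; scale invariant.
#' The small-sample corrected variant multiplies by \eqn{n/(n-1)}.
#'
#' @param x nonnegative numeric vector with at least one positive value.
#' @param corrected logical; apply the `n/(n-1)` correction (default `FALSE`).
#' @return Gini coefficient in `[0, 1)` (corrected variant can reach 1).
#' @export
gini <- function(x, corrected = FALSE) {
  if (any(!is.finite(x)) || any(x < 0)) stop("values must be nonnegative")
  if (all(x == 0)) stop("Gini undefined for an all-zero vector", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  # sum_i sum_j |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  mad2 <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  g <- mad2 / (2 * n^2 * mean(x))
  if (corrected) g <- g * n / (n - 1)
  g
}
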