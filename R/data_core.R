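#' Load a household table from CSV
#'
#' Reads the per-household attribute table: wealth (cash value), the binary
#' religious/secular-influence flag, development-group membership, hamlet and
#' GPS coordinates. Row order in the file fixes the household ordering used by
#' every matrix downstream.
#'
#' @param path CSV file with header columns `household_id`, `wealth_total`,
#'   `status_flag`, `dev_group_flag`, `hamlet`, `latitude`, `longitude`.
#' @return data frame of class `household_table`, one row per household in
#'   file order.
#' @export
load_households <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_household_table(df)
}

#' Construct and validate a household table
#'
#' @param df data frame with the columns documented in [load_households()].
#' @return validated `household_table`.
#' @export
as_household_table <- function(df) {
  req <- c("household_id", "wealth_total", "status_flag", "dev_group_flag",
           "hamlet", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("household table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$household_id <- as.character(df$household_id)
  dup <- unique(df$household_id[duplicated(df$household_id)])
  if (length(dup))
    stop("duplicate household_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad_w <- which(!is.finite(df$wealth_total) | df$wealth_total <= 0)
  if (length(bad_w))
    stop("non-positive wealth_total in row ", bad_w[1],
         " (household ", df$household_id[bad_w[1]], ")", call. = FALSE)
  for (fl in c("status_flag", "dev_group_flag")) {
    if (!all(df[[fl]] %in% c(0L, 1L)))
      stop(fl, " must be binary (0/1)", call. = FALSE)
  }
  check_coords(df)
  class(df) <- c("household_table", "data.frame")
  df
}

household_ids <- function(households) as.character(households$household_id)

#' Load a directed network layer from an edgelist CSV
#'
#' Each row is one nomination. Single-sampled layers have columns
#' `ego, alter` and produce one adjacency matrix with `adjacency[ego, alter]
#' = 1`. Double-sampled layers additionally carry `question` (`"give"` or
#' `"receive"`): a `give` row means ego reported "ego gives to alter" and
#' sets `out_reports[ego, alter] = 1`; a `receive` row means ego reported
#' "alter gives to ego" and is reoriented to `in_reports[alter, ego] = 1`,
#' so both report matrices index the same tie direction i -> j.
#'
#' @param path CSV edgelist.
#' @param name layer label.
#' @param mode `"single"` or `"double"`.
#' @param households `household_table` fixing matrix order.
#' @param drop_unknown if `TRUE`, nominations to labels absent from the
#'   household table (e.g. out-of-village alters) are dropped with a warning
#'   rather than raising an error.
#' @return object of class `network_layer`.
#' @export
load_edgelist <- function(path, name, mode = c("single", "double"),
                          households, drop_unknown = FALSE) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  edgelist_to_layer(df, name, mode, households, drop_unknown)
}

edgelist_to_layer <- function(df, name, mode, households,
                              drop_unknown = FALSE) {
  req <- c("ego", "alter")
  if (mode == "double") req <- c(req, "question")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("edgelist '", name, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- household_ids(households)
  n <- length(ids)
  df$ego <- as.character(df$ego); df$alter <- as.character(df$alter)
  if (any(df$ego == df$alter)) {
    bad <- which(df$ego == df$alter)[1]
    stop("self-nomination in layer '", name, "' row ", bad,
         " (", df$ego[bad], ")", call. = FALSE)
  }
  unknown <- !(df$ego %in% ids) | !(df$alter %in% ids)
  if (any(unknown)) {
    if (drop_unknown) {
      warning(sum(unknown), " nomination(s) to unknown household(s) dropped ",
              "from layer '", name, "'")
      df <- df[!unknown, , drop = FALSE]
    } else {
      labs <- unique(c(df$ego[unknown], df$alter[unknown]))
      labs <- setdiff(labs, ids)
      stop("unknown household label(s) in layer '", name, "': ",
           paste(labs, collapse = ", "), call. = FALSE)
    }
  }
  empty <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (mode == "single") {
    adj <- empty
    adj[cbind(df$ego, df$alter)] <- 1L
    new_layer(name, "single", adjacency = adj)
  } else {
    if (!all(df$question %in% c("give", "receive")))
      stop("question column must be 'give' or 'receive'", call. = FALSE)
    out_r <- empty; in_r <- empty
    g <- df[df$question == "give", , drop = FALSE]
    r <- df[df$question == "receive", , drop = FALSE]
    out_r[cbind(g$ego, g$alter)] <- 1L
    in_r[cbind(r$alter, r$ego)] <- 1L # reorient: alter gives to ego
    new_layer(name, "double", out_reports = out_r, in_reports = in_r)
  }
}

new_layer <- function(name, mode, adjacency = NULL, out_reports = NULL,
                      in_reports = NULL) {
  l <- structure(list(name = name, mode = mode), class = "network_layer")
  if (mode == "single") {
    stopifnot(!is.null(adjacency))
    diag(adjacency) <- 0L
    l$adjacency <- adjacency
  } else {
    stopifnot(!is.null(out_reports), !is.null(in_reports))
    diag(out_reports) <- 0L; diag(in_reports) <- 0L
    l$out_reports <- out_reports
    l$in_reports <- in_reports
  }
  l
}

#' Observed adjacency of a layer
#'
#' For single-sampled layers this is the adjacency matrix. For double-sampled
#' layers it is the element-wise union (OR) of the two report matrices — the
#' convention used when a double-sampled layer enters another layer's model as
#' an observed dyadic predictor.
#'
#' @param layer a `network_layer`.
#' @return n x n binary matrix.
#' @export
layer_adjacency <- function(layer) {
  if (layer$mode == "single") layer$adjacency
  else (layer$out_reports | layer$in_reports) * 1L
}

#' @export
print.network_layer <- function(x, ...) {
  n <- nrow(if (x$mode == "single") x$adjacency else x$out_reports)
  cat("network_layer '", x$name, "' (", x$mode, "-sampled, ", n,
      " households)\n", sep = "")
  invisible(x)
}

#' Assemble a multiplex dataset
#'
#' Binds households, individuals, network layers and dyadic covariate
#' matrices under one shared household ordering.
#'
#' @param households `household_table`.
#' @param individuals data frame of individual records (may be `NULL` when
#'   relatedness is supplied directly as a covariate).
#' @param layers named list of `network_layer` objects.
#' @param dyadic_covariates named list of n x n numeric matrices.
#' @return object of class `multiplex_dataset`.
#' @export
multiplex_dataset <- function(households, individuals = NULL,
                              layers = list(), dyadic_covariates = list()) {
  d <- structure(list(households = households, individuals = individuals,
                      layers = layers, dyadic_covariates = dyadic_covariates),
                 class = "multiplex_dataset")
  viol <- validate_dataset(d)
  if (length(viol))
    stop("invalid multiplex dataset:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  d
}

#' @export
print.multiplex_dataset <- function(x, ...) {
  cat("multiplex_dataset:", nrow(x$households), "households,",
      length(x$layers), "layers,", length(x$dyadic_covariates),
      "dyadic covariates\n")
  invisible(x)
}

#' Validate a multiplex dataset
#'
#' Reporting operation: checks every structural invariant (shared ordering
#' and dimension of all matrices, zero diagonals, binary layers, household
#' invariants) and returns the list of violations. An empty character vector
#' means the dataset is analysis-ready.
#'
#' @param data `multiplex_dataset` (or a plain list with the same fields).
#' @return character vector of violation messages (empty if none).
#' @export
validate_dataset <- function(data) {
  v <- character(0)
  hh <- data$households
  ids <- household_ids(hh)
  n <- length(ids)
  if (anyDuplicated(ids)) v <- c(v, "duplicate household ids")
  if (any(hh$wealth_total <= 0)) v <- c(v, "non-positive household wealth")
  chk_mat <- function(m, what, binary = FALSE) {
    out <- character(0)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      return(paste0(what, ": wrong shape (expected ", n, "x", n, ")"))
    }
    if (any(diag(m) != 0)) out <- c(out, paste0(what, ": nonzero diagonal"))
    if (binary && !all(m %in% c(0, 1)))
      out <- c(out, paste0(what, ": non-binary entries"))
    if (!is.null(rownames(m)) && !identical(rownames(m), ids))
      out <- c(out, paste0(what, ": row labels disagree with household order"))
    out
  }
  for (nm in names(data$layers)) {
    l <- data$layers[[nm]]
    if (l$mode == "single") {
      v <- c(v, chk_mat(l$adjacency, paste0("layer '", nm, "'"), binary = TRUE))
    } else {
      v <- c(v, chk_mat(l$out_reports, paste0("layer '", nm, "' out_reports"),
                        binary = TRUE))
      v <- c(v, chk_mat(l$in_reports, paste0("layer '", nm, "' in_reports"),
                        binary = TRUE))
    }
  }
  for (nm in names(data$dyadic_covariates)) {
    v <- c(v, chk_mat(data$dyadic_covariates[[nm]],
                      paste0("covariate '", nm, "'")))
  }
  if (!is.null(data$individuals)) {
    tryCatch(validate_individuals(data$individuals),
             error = function(e) v <<- c(v, conditionMessage(e)))
    unk <- setdiff(unique(as.character(data$individuals$household_id)), ids)
    if (length(unk))
      v <- c(v, paste0("individuals mapped to unknown household(s): ",
                       paste(unk, collapse = ", ")))
  }
  v
}

#' Write a multiplex dataset to a directory of CSV files
#'
#' Emits `households.csv`, `individuals.csv` (if present), one edgelist CSV
#' per layer, and one labelled matrix CSV per dyadic covariate — the exact
#' dialects [load_dataset()] reads back.
#'
#' @param data `multiplex_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(data$households))[
    , c("household_id", "wealth_total", "status_flag", "dev_group_flag",
        "hamlet", "latitude", "longitude")],
    file.path(dir, "households.csv"), row.names = FALSE)
  if (!is.null(data$individuals))
    utils::write.csv(data$individuals, file.path(dir, "individuals.csv"),
                     row.names = FALSE)
  for (nm in names(data$layers)) {
    l <- data$layers[[nm]]
    if (l$mode == "single") {
      e <- which(l$adjacency == 1L, arr.ind = TRUE)
      df <- data.frame(ego = rownames(l$adjacency)[e[, 1]],
                       alter = colnames(l$adjacency)[e[, 2]])
      df <- df[order(df$ego, df$alter), , drop = FALSE]
    } else {
      eo <- which(l$out_reports == 1L, arr.ind = TRUE)
      ei <- which(l$in_reports == 1L, arr.ind = TRUE)
      df <- rbind(
        data.frame(ego = rownames(l$out_reports)[eo[, 1]],
                   alter = colnames(l$out_reports)[eo[, 2]],
                   question = "give"),
        # in_reports[i, j] = 1 means household j answered "i gives to me"
        data.frame(ego = colnames(l$in_reports)[ei[, 2]],
                   alter = rownames(l$in_reports)[ei[, 1]],
                   question = "receive"))
      df <- df[order(df$question, df$ego, df$alter), , drop = FALSE]
    }
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(data$dyadic_covariates)) {
    utils::write.csv(data.frame(household_id = rownames(data$dyadic_covariates[[nm]]),
                                data$dyadic_covariates[[nm]],
                                check.names = FALSE),
                     file.path(dir, paste0("cov_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a multiplex dataset written by [write_dataset()]
#'
#' @param dir directory containing `households.csv`, optional
#'   `individuals.csv`, layer edgelists and `cov_*.csv` matrices.
#' @param layers named character vector of layer modes, e.g.
#'   `c(food_sharing = "double", friendship_f = "single")`.
#' @return `multiplex_dataset`.
#' @export
load_dataset <- function(dir, layers) {
  hh <- load_households(file.path(dir, "households.csv"))
  ind <- NULL
  if (file.exists(file.path(dir, "individuals.csv")))
    ind <- utils::read.csv(file.path(dir, "individuals.csv"),
                           stringsAsFactors = FALSE)
  lay <- list()
  for (nm in names(layers)) {
    lay[[nm]] <- load_edgelist(file.path(dir, paste0(nm, ".csv")), nm,
                               layers[[nm]], hh)
  }
  covs <- list()
  for (f in list.files(dir, pattern = "^cov_.*\\.csv$")) {
    nm <- sub("^cov_(.*)\\.csv$", "\\1", f)
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    covs[[nm]] <- m
  }
  multiplex_dataset(hh, ind, lay, covs)
}
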