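#' Analysis configuration
#'
#' @param layers named character vector of layer modes, e.g.
#'   `c(food_sharing = "double", friendship_f = "single", ...)`; defaults to
#'   the five-layer study layout.
#' @param dyadic_covariates dyadic covariate names shared by every model.
#' @param blocks block structures shared by every model.
#' @param cross_layer_predictors if `TRUE` (default), each layer's model also
#'   includes every other layer's observed adjacency as a dyadic predictor
#'   (a double-sampled layer contributes the union of its two report
#'   matrices).
#' @param mcmc `mcmc_control`.
#' @param contrast_reference reference cell for block contrasts.
#' @param out_dir optional output directory for CSV/JSON results.
#' @param seed master seed (overrides `mcmc$seed`).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(layers = c(food_sharing = "double",
                                       friendship_f = "single",
                                       coworking_f = "single",
                                       friendship_m = "single",
                                       coworking_m = "single"),
                            dyadic_covariates = c("wealth_distance",
                                                  "relatedness", "distance"),
                            blocks = c("status", "dev_group"),
                            cross_layer_predictors = TRUE,
                            mcmc = mcmc_control(), contrast_reference = c(2, 2),
                            out_dir = NULL, seed = NULL) {
  if (anyDuplicated(names(layers))) stop("layer names must be unique")
  if (!is.null(seed)) mcmc$seed <- seed
  structure(list(layers = layers, dyadic_covariates = dyadic_covariates,
                 blocks = blocks,
                 cross_layer_predictors = cross_layer_predictors,
                 mcmc = mcmc, contrast_reference = contrast_reference,
                 out_dir = out_dir, seed = mcmc$seed),
            class = "analysis_config")
}

#' Run the full multiplex analysis
#'
#' Fits every configured layer with an identical model specification (the
#' shared covariates, both block structures, and — when enabled — all other
#' layers as cross-layer dyadic predictors), then assembles per-layer
#' posterior summaries, block offset/contrast tables for both blocks,
#' reciprocity estimates, network descriptives and wealth inequality
#' statistics. Aborts before any fit if the dataset fails validation.
#'
#' @param data `multiplex_dataset`.
#' @param config `analysis_config`.
#' @return list of class `results_bundle` with elements `fits`, `summaries`,
#'   `contrasts`, `reciprocity`, `descriptives`, `gini`, `meta`.
#' @export
run_analysis <- function(data, config = analysis_config()) {
  viol <- validate_dataset(data)
  if (length(viol))
    stop("dataset failed validation:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  missing_layers <- setdiff(names(config$layers), names(data$layers))
  if (length(missing_layers))
    stop("configured layer(s) absent from dataset: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)

  fits <- list(); summaries <- list(); contrasts <- list(); recip <- list()
  for (k in seq_along(config$layers)) {
    nm <- names(config$layers)[k]
    dy <- config$dyadic_covariates
    if (config$cross_layer_predictors)
      dy <- c(dy, setdiff(names(config$layers), nm))
    spec <- srm_model_spec(sender = "log_wealth", dyadic = dy,
                           blocks = config$blocks)
    mc <- config$mcmc
    mc$seed <- config$mcmc$seed + k - 1L
    fits[[nm]] <- fit_srm(data, nm, spec, mc)
    summaries[[nm]] <- summarize_draws(
      fits[[nm]], pars = fits[[nm]]$layout$top_names_natural %||%
        setdiff(colnames(fits[[nm]]$chains[[1]]),
                grep("^(lambda|pi)\\[", colnames(fits[[nm]]$chains[[1]]),
                     value = TRUE)))
    contrasts[[nm]] <- lapply(stats::setNames(config$blocks, config$blocks),
                              function(b)
      block_contrasts(fits[[nm]], b, reference = config$contrast_reference))
    recip[[nm]] <- reciprocity_estimates(fits[[nm]])
  }

  bundle <- structure(list(
    fits = fits, summaries = summaries, contrasts = contrasts,
    reciprocity = recip, descriptives = descriptives(data),
    gini = c(wealth = gini(data$households$wealth_total)),
    meta = list(seed = config$seed, layers = config$layers,
                dyadic_covariates = config$dyadic_covariates,
                blocks = config$blocks,
                cross_layer_predictors = config$cross_layer_predictors,
                double_layer_predictor = "union (OR) of the two report matrices",
                warnings = lapply(fits, function(f) f$warnings),
                timestamp = NULL)), class = "results_bundle")
  if ("clove_value" %in% names(data$households))
    bundle$gini["clove_value"] <- gini(data$households$clove_value)
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle:", length(x$fits), "layer fits; Gini:",
      paste(names(x$gini), round(x$gini, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Write a results bundle to CSV/JSON files
#'
#' @param bundle `results_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$summaries)) {
    utils::write.csv(bundle$summaries[[nm]],
                     file.path(dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
    for (b in names(bundle$contrasts[[nm]]))
      utils::write.csv(bundle$contrasts[[nm]][[b]],
                       file.path(dir, paste0("contrasts_", nm, "_", b, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(bundle$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(gini = as.list(bundle$gini), meta = bundle$meta),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Network descriptives and inequality statistics
#'
#' Per layer (double-sampled layers evaluated on the union of their report
#' matrices): density over ordered pairs, reciprocated proportion (ordered
#' present ties whose reverse tie is also present / present ties), and
#' in/out-degree means and standard deviations. Degree means are equal by
#' construction (every tie is one out- and one in-nomination).
#'
#' @param data `multiplex_dataset`.
#' @return data frame, one row per layer, with the wealth Gini attached as
#'   attribute `gini_wealth`.
#' @export
descriptives <- function(data) {
  rows <- lapply(names(data$layers), function(nm) {
    A <- layer_adjacency(data$layers[[nm]])
    n <- nrow(A)
    ties <- sum(A)
    mutual <- sum(A * t(A))
    data.frame(layer = nm, mode = data$layers[[nm]]$mode,
               density = ties / (n * (n - 1)),
               reciprocated = if (ties > 0) mutual / ties else 0,
               out_degree_mean = mean(rowSums(A)),
               out_degree_sd = stats::sd(rowSums(A)),
               in_degree_mean = mean(colSums(A)),
               in_degree_sd = stats::sd(colSums(A)))
  })
  out <- do.call(rbind, rows)
  attr(out, "gini_wealth") <- gini(data$households$wealth_total)
  out
}

#' Export a layer as a GraphML digraph
#'
#' Nodes carry `wealth_rank` (1 = poorest) and `total_degree` (in + out
#' nominations) attributes — the quantities used to colour and size nodes in
#' network digraph figures. Edge direction is preserved; for double-sampled
#' layers the union of the two report matrices is exported.
#'
#' @param data `multiplex_dataset`.
#' @param layer layer name.
#' @param path output file (GraphML).
#' @return `path`, invisibly.
#' @export
export_digraph <- function(data, layer, path) {
  if (!layer %in% names(data$layers))
    stop("unknown layer '", layer, "'", call. = FALSE)
  A <- layer_adjacency(data$layers[[layer]])
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::V(g)$wealth_rank <- rank(data$households$wealth_total,
                                   ties.method = "first")
  igraph::V(g)$total_degree <- rowSums(A) + colSums(A)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
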