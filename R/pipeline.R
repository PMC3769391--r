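#' Pipeline run configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].  Can be
#' populated from a JSON file (`run_config_from_json()`), whose top-level
#' keys mirror the arguments here.
#'
#' @param input Path to a recording readable by [read_raw()], or NULL when
#'   `simulate` is given.
#' @param format Input format passed to [read_raw()].
#' @param simulate NULL, or a list with the [hyper_brain_spec()] fields
#'   (`channels_per_brain`, `noise_sd`, `seed`, optional `couplings` data
#'   frame) plus `epoch_length` and `n_epochs` — used instead of `input`.
#' @param montage A [montage_spec()] (default the 21-channel 10-20 montage);
#'   set to NULL to skip montage selection (in a JSON config, use
#'   `"montage": "none"`).
#' @param preprocess NULL to skip (input already clean/epoched), or a list
#'   with any of `mastoids` (2 labels), `band` (c(low, high)), `eog`
#'   (labels), `target_rate`, `epoch_length`, `criteria`
#'   ([artifact_criteria()]).
#' @param wavelet A [wavelet_params()] object.
#' @param measures Coupling measures to compute.
#' @param threshold List: `alpha`, `n_bootstrap`, `method`, `seed`,
#'   `n_shuffles`.
#' @param graph List: `small_world` (logical), `n_null`, `seed`, `weighted`.
#' @param community List: `restarts`, `variant`, `seed`.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, format = "auto", simulate = NULL,
                       montage = montage_1020(), preprocess = NULL,
                       wavelet = wavelet_params(),
                       measures = c("psi", "pci", "nci", "aci", "ici"),
                       threshold = list(), graph = list(),
                       community = list(), out_dir = "hyperbrain_out") {
  if (is.null(input) && is.null(simulate))
    stop("config needs either `input` or `simulate`", call. = FALSE)
  if (!is.null(input) && !file.exists(input))
    stop("input file does not exist: ", input, call. = FALSE)
  if (!is.null(montage) && !inherits(montage, "montage_spec"))
    stop("`montage` must be a montage_spec (or NULL)", call. = FALSE)
  threshold <- utils::modifyList(
    list(alpha = 1e-4, n_bootstrap = 1000, method = "quantile",
         seed = 1L, n_shuffles = 1L), threshold)
  graph <- utils::modifyList(
    list(small_world = FALSE, n_null = 20, seed = 1L, weighted = FALSE), graph)
  community <- utils::modifyList(
    list(restarts = 20, variant = "auto", seed = 1L), community)
  measures <- match.arg(measures, c("psi", "pci", "nci", "aci", "ici"),
                        several.ok = TRUE)
  structure(list(input = input, format = format, simulate = simulate,
                 montage = montage, preprocess = preprocess,
                 wavelet = wavelet, measures = measures,
                 threshold = threshold, graph = graph,
                 community = community, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a JSON configuration file.
#' @export
run_config_from_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (k in c("input", "format", "out_dir", "measures"))
    if (!is.null(j[[k]])) args[[k]] <- j[[k]]
  if (!is.null(j$simulate)) {
    args$simulate <- as.list(j$simulate)
    if (!is.null(args$simulate$couplings))
      args$simulate$couplings <- as.data.frame(args$simulate$couplings)
  }
  if (!is.null(j$wavelet))
    args$wavelet <- do.call(wavelet_params, as.list(j$wavelet))
  if (!is.null(j$montage)) {
    if (identical(j$montage, "none")) {
      args["montage"] <- list(NULL)
    } else {
      m <- as.data.frame(j$montage)
      args$montage <- montage_spec(m$label, stats::setNames(m$region, m$label))
    }
  }
  if (!is.null(j$preprocess)) {
    args$preprocess <- as.list(j$preprocess)
    if (!is.null(args$preprocess$criteria))
      args$preprocess$criteria <-
        do.call(artifact_criteria, as.list(args$preprocess$criteria))
  }
  for (k in c("threshold", "graph", "community"))
    if (!is.null(j[[k]])) args[[k]] <- as.list(j[[k]])
  do.call(run_config, args)
}

stage_msg <- function(stage, ...) message(sprintf("[%s] ", stage), ...)

#' Run the full hyper-brain analysis pipeline
#'
#' Executes load/simulate -> preprocess -> spectral/coupling ->
#' surrogate thresholding -> graph metrics -> community detection, writing
#' all results (coupling matrices, thresholds, GraphML graphs, node metric
#' tables, partitions, role tables) plus a provenance file into
#' `config$out_dir`.  Stage failures abort with the stage name in the
#' error.  Identical configuration and seeds reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and the output
#'   manifest (`files`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config", call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  epochs <- run_stage("input", {
    if (!is.null(config$simulate)) {
      s <- config$simulate
      spec <- hyper_brain_spec(
        channels_per_brain = s$channels_per_brain %||% 21,
        couplings = s$couplings,
        noise_sd = s$noise_sd %||% 1,
        seed = s$seed %||% 1)
      generate_hyper_brain_dataset(spec,
                                   epoch_length = s$epoch_length %||% 10,
                                   n_epochs = s$n_epochs %||% 1,
                                   sampling_rate = s$sampling_rate %||% 250)
    } else {
      raw <- read_raw(config$input, config$format)
      pp <- config$preprocess
      if (!is.null(pp)) {
        if (!is.null(pp$mastoids))
          raw <- rereference_linked_mastoids(raw, pp$mastoids[1], pp$mastoids[2])
        band <- pp$band %||% c(0.5, 70)
        raw <- bandpass(raw, band[1], band[2])
        if (length(pp$eog %||% raw$eog))
          raw <- correct_eog_regression(raw, pp$eog %||% raw$eog)
        ep <- resample_and_epoch(raw, pp$target_rate %||% 250,
                                 pp$epoch_length %||% 10)
        ep <- reject_artifacts(ep, pp$criteria %||% artifact_criteria())
        log <- rejection_log(ep)
        utils::write.table(log, file.path(out, "rejection_log.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        ep
      } else {
        resample_and_epoch(raw, raw$sampling_rate,
                           ncol(raw$samples) / raw$sampling_rate)
      }
    }
  })
  if (!is.null(config$montage))
    epochs <- run_stage("montage", select_montage(epochs, config$montage))
  stage_msg("input", sprintf("%d channels, %d epochs @ %g Hz",
                             dim(epochs)[1], n_epochs(epochs),
                             epochs$sampling_rate))

  mats <- run_stage("coupling",
                    connectivity_matrices(epochs, config$wavelet,
                                          config$measures))
  write_coupling_matrices(mats, file.path(out, "matrices"))

  th <- config$threshold
  thresholds <- run_stage("thresholding", {
    ens <- surrogate_distribution(epochs, config$wavelet, config$measures,
                                  seed = th$seed, n_shuffles = th$n_shuffles)
    estimate_threshold(ens, n_bootstrap = th$n_bootstrap, alpha = th$alpha,
                       seed = th$seed, method = th$method)
  })
  write_thresholds(thresholds, file.path(out, "thresholds.tsv"))

  dir.create(file.path(out, "graphs"), showWarnings = FALSE)
  fois <- attr(mats, "fois")
  node_tables <- list()
  graph_tables <- list()
  role_tables <- list()
  run_stage("graph", {
    for (m in config$measures) {
      for (foi in fois) {
        g <- apply_threshold(mats, thresholds, m, foi)
        if (n_edges(g) == 0) next
        export_graphml(g, file.path(out, "graphs",
                                    sprintf("%s_%gHz.graphml", m, foi)))
        st <- strengths(g)
        st$measure <- m
        st$foi <- foi
        node_tables[[length(node_tables) + 1L]] <- st
        cc <- clustering_coefficient(g,
                                     if (config$graph$weighted) "weighted" else "binary")
        cpl <- characteristic_path_length(g, config$graph$weighted)
        grow <- data.frame(measure = m, foi = foi, n_edges = n_edges(g),
                           cc = cc$cc, cpl = as.numeric(cpl),
                           stringsAsFactors = FALSE)
        if (config$graph$small_world && n_edges(g) >= 4) {
          sw <- try(small_worldness(g, config$graph$n_null,
                                    seed = config$graph$seed), silent = TRUE)
          if (!inherits(sw, "try-error")) {
            grow$sigma <- sw$sigma
            grow$omega <- sw$omega
          }
        }
        graph_tables[[length(graph_tables) + 1L]] <- grow
        part <- try(optimize_partition(g, config$community$variant,
                                       config$community$restarts,
                                       config$community$seed), silent = TRUE)
        if (!inherits(part, "try-error")) {
          rt <- node_roles(g, part)
          rt$measure <- m
          rt$foi <- foi
          rt$modularity <- part$modularity
          role_tables[[length(role_tables) + 1L]] <- rt
        }
      }
    }
  })
  files <- c("matrices", "thresholds.tsv", "graphs")
  if (length(node_tables)) {
    utils::write.table(do.call(rbind, node_tables),
                       file.path(out, "node_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, "node_metrics.tsv")
  }
  if (length(graph_tables)) {
    utils::write.table(do.call(rbind, graph_tables),
                       file.path(out, "graph_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, "graph_metrics.tsv")
  }
  if (length(role_tables)) {
    utils::write.table(do.call(rbind, role_tables),
                       file.path(out, "node_roles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, "node_roles.tsv")
  }
  prov <- list(
    package = "hyperbrain",
    version = as.character(utils::packageVersion("hyperbrain")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seeds = list(threshold = th$seed, graph = config$graph$seed,
                 community = config$community$seed,
                 simulate = config$simulate$seed),
    config = config[setdiff(names(config), c("montage", "wavelet"))],
    wavelet = unclass(config$wavelet),
    montage = if (!is.null(config$montage)) as.data.frame(config$montage))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE,
                       digits = NA)
  files <- c(files, "provenance.json")
  invisible(list(epochs = epochs, matrices = mats, thresholds = thresholds,
                 node_metrics = if (length(node_tables)) do.call(rbind, node_tables),
                 graph_metrics = if (length(graph_tables)) do.call(rbind, graph_tables),
                 node_roles = if (length(role_tables)) do.call(rbind, role_tables),
                 files = file.path(out, files)))
}
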