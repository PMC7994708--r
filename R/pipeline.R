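#' Configuration for the full study pipeline
#'
#' @param cor_method Correlation input for the main cross-sectional
#'   networks: `"spearman"` (default, recommended for skewed ordinal
#'   scores) or `"pearson"`.
#' @param method Main network estimator: `"nonregularized"` (default) or
#'   `"ebic_glasso"`.
#' @param gamma EBIC hyperparameter when `method = "ebic_glasso"`.
#' @param nct_estimator [estimator_config()] used inside the Network
#'   Comparison Test; default EBIC glasso on Pearson input.
#' @param n_perm Permutations per NCT (default 1000).
#' @param stability Run bootstrap accuracy and case-drop stability per wave
#'   (default `FALSE`; these dominate runtime).
#' @param n_boot Bootstrap resamples when `stability = TRUE`.
#' @param drop_grid Case-drop proportions when `stability = TRUE`.
#' @param alpha Level for the temporal Wald edge tests.
#' @param display_threshold Reporting threshold for [display_filter()]
#'   edge lists (default 0.1).
#' @param gvar_centering,standardize Passed to [estimate_panel_gvar()].
#' @param seed Base seed; stage seeds are derived deterministically.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cor_method = c("spearman", "pearson"),
                         method = c("nonregularized", "ebic_glasso"),
                         gamma = 0.5,
                         nct_estimator = estimator_config("ebic_glasso",
                                                          "pearson"),
                         n_perm = 1000, stability = FALSE, n_boot = 250,
                         drop_grid = seq(0.05, 0.75, by = 0.05),
                         alpha = 0.05, display_threshold = 0.1,
                         gvar_centering = c("none", "subject_mean"),
                         standardize = FALSE, seed = 1) {
  structure(list(cor_method = match.arg(cor_method),
                 method = match.arg(method), gamma = gamma,
                 nct_estimator = nct_estimator, n_perm = n_perm,
                 stability = stability, n_boot = n_boot,
                 drop_grid = drop_grid, alpha = alpha,
                 display_threshold = display_threshold,
                 gvar_centering = match.arg(gvar_centering),
                 standardize = standardize, seed = seed),
            class = "study_config")
}

#' Run the full symptom-network study workflow
#'
#' Executes, in order: per-wave descriptive statistics; one cross-sectional
#' partial-correlation network per wave; per-wave node predictability;
#' optional bootstrap accuracy and case-drop stability analyses; a
#' permutation Network Comparison Test on global strength for every wave
#' pair; and one panel GVAR temporal network with its contemporaneous
#' residual network. Deterministic given the config seed. A failing stage
#' is recorded with its diagnostic; later independent stages still run.
#'
#' @param panel A [symptom_panel()] with at least 2 waves.
#' @param config A [study_config()].
#' @return An object of class `study_report`: `descriptives`, `networks`,
#'   `predictability` (symptoms x waves matrix), `stability` (or `NULL`),
#'   `nct` (one `nct_result` per wave pair), `temporal`, `temporal_edges`,
#'   `stationarity`, `stages` (status per stage), `config`, `version`.
#' @export
run_full_study <- function(panel, config = study_config()) {
  stopifnot(inherits(panel, "symptom_panel"),
            inherits(config, "study_config"))
  waves <- panel$wave_labels
  if (length(waves) < 2L) stop("at least 2 waves are required")
  stages <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             value = conditionMessage(e)))
    stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$value)
    if (res$ok) res$value else NULL
  }

  descriptives <- run_stage("descriptives", {
    stats::setNames(lapply(waves, summarize_panel, panel = panel), waves)
  })
  wave_mats <- run_stage("wave_matrices", {
    stats::setNames(lapply(waves, wave_matrix, panel = panel), waves)
  })
  main_cfg <- estimator_config(config$method, config$cor_method,
                               gamma = config$gamma)
  networks <- run_stage("networks", {
    if (is.null(wave_mats)) stop("wave matrices unavailable")
    stats::setNames(lapply(wave_mats, fit_network, config = main_cfg), waves)
  })
  predictability <- run_stage("predictability", {
    if (is.null(wave_mats)) stop("wave matrices unavailable")
    cors <- lapply(wave_mats, function(X) {
      if (config$cor_method == "spearman") spearman_matrix(X)
      else pearson_matrix(X)
    })
    vapply(cors, node_predictability, numeric(length(panel$symptom_names)))
  })
  stability <- if (config$stability) run_stage("stability", {
    if (is.null(wave_mats)) stop("wave matrices unavailable")
    stats::setNames(lapply(seq_along(waves), function(j) {
      list(edge_ci = edge_ci_bootstrap(wave_mats[[j]],
                                       n_boot = max(config$n_boot, 100),
                                       seed = config$seed + 100 + j,
                                       estimator = main_cfg),
           case_drop = case_drop_stability(wave_mats[[j]],
                                           drop_grid = config$drop_grid,
                                           n_boot = config$n_boot,
                                           seed = config$seed + 200 + j,
                                           estimator = main_cfg))
    }), waves)
  }) else NULL
  nct <- run_stage("nct", {
    if (is.null(wave_mats)) stop("wave matrices unavailable")
    pairs <- utils::combn(seq_along(waves), 2, simplify = FALSE)
    out <- lapply(seq_along(pairs), function(k) {
      pr <- pairs[[k]]
      nct_global_strength(wave_mats[[pr[1]]], wave_mats[[pr[2]]],
                          n_perm = config$n_perm,
                          seed = config$seed + 300 + k,
                          estimator = config$nct_estimator)
    })
    names(out) <- vapply(pairs, function(pr) {
      paste(waves[pr[1]], waves[pr[2]], sep = "_vs_")
    }, "")
    out
  })
  temporal <- run_stage("temporal", {
    estimate_panel_gvar(panel, centering = config$gvar_centering,
                        standardize = config$standardize)
  })
  temporal_edges <- run_stage("temporal_edge_test", {
    if (is.null(temporal)) stop("temporal model unavailable")
    temporal_edge_test(temporal, alpha = config$alpha)
  })
  stationarity <- if (!is.null(temporal)) check_stationarity(temporal) else NULL

  structure(
    list(descriptives = descriptives, networks = networks,
         predictability = predictability, stability = stability,
         nct = nct, temporal = temporal, temporal_edges = temporal_edges,
         stationarity = stationarity, stages = stages, config = config,
         version = as.character(utils::packageVersion("symptomnet"))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-20s %s\n", nm, x$stages[[nm]]))
  }
  if (!is.null(x$networks)) {
    gs <- vapply(x$networks, global_strength, 0)
    cat("  global strength:",
        paste(sprintf("%s = %.3f", names(gs), gs), collapse = ", "), "\n")
  }
  if (!is.null(x$nct)) {
    pv <- vapply(x$nct, function(r) r$p_value, 0)
    cat("  NCT p-values:  ",
        paste(sprintf("%s: %.4g", names(pv), pv), collapse = ", "), "\n")
  }
  if (!is.null(x$stationarity)) {
    cat(sprintf("  temporal spectral radius: %.3f\n",
                x$stationarity$spectral_radius))
  }
  invisible(x)
}

#' Export a study report to a directory
#'
#' Writes, per wave: descriptives CSV, weight-matrix CSV, edge-list CSV
#' (display-filtered edge list additionally) and GraphML; a predictability
#' CSV (one row per symptom, one column per wave); one JSON per NCT;
#' directed temporal edge list and GraphML; stability CSVs when present;
#' and a single `summary.json` echoing the configuration.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created recursively).
#' @return Character vector of written file paths, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  fp <- function(...) file.path(dir, paste0(...))

  for (wv in names(report$descriptives)) {
    utils::write.csv(report$descriptives[[wv]],
                     fp("descriptives_", wv, ".csv"), row.names = FALSE)
    add(fp("descriptives_", wv, ".csv"))
  }
  for (wv in names(report$networks)) {
    net <- report$networks[[wv]]
    add(write_weight_csv(net, fp("weights_", wv, ".csv")))
    utils::write.csv(as_edge_list(net), fp("edges_", wv, ".csv"),
                     row.names = FALSE)
    add(fp("edges_", wv, ".csv"))
    utils::write.csv(display_filter(net, report$config$display_threshold),
                     fp("edges_display_", wv, ".csv"), row.names = FALSE)
    add(fp("edges_display_", wv, ".csv"))
    add(write_graphml(net, fp("network_", wv, ".graphml")))
  }
  if (!is.null(report$predictability)) {
    pred <- data.frame(symptom = rownames(report$predictability),
                       report$predictability, check.names = FALSE,
                       stringsAsFactors = FALSE)
    utils::write.csv(pred, fp("predictability.csv"), row.names = FALSE)
    add(fp("predictability.csv"))
  }
  for (nm in names(report$nct)) {
    add(write_nct_json(report$nct[[nm]], fp("nct_", nm, ".json")))
  }
  if (!is.null(report$stability)) {
    for (wv in names(report$stability)) {
      add(write_bootstrap_csv(report$stability[[wv]]$edge_ci,
                              fp("edge_ci_", wv, ".csv")))
      add(write_bootstrap_csv(report$stability[[wv]]$case_drop,
                              fp("case_drop_", wv, ".csv")))
    }
  }
  if (!is.null(report$temporal)) {
    add(write_temporal_csv(report$temporal, fp("temporal_edges.csv"),
                           alpha = report$config$alpha))
    add(write_temporal_graphml(report$temporal, fp("temporal.graphml")))
  }
  summary <- list(
    version = report$version,
    stages = report$stages,
    config = .jsonable_config(report$config),
    global_strength = if (!is.null(report$networks)) {
      as.list(vapply(report$networks, global_strength, 0))
    },
    nct_p_values = if (!is.null(report$nct)) {
      as.list(vapply(report$nct, function(r) r$p_value, 0))
    },
    mean_predictability = if (!is.null(report$predictability)) {
      as.list(colMeans(report$predictability))
    },
    temporal_spectral_radius = if (!is.null(report$stationarity)) {
      report$stationarity$spectral_radius
    })
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  add(fp("summary.json"))
  invisible(files)
}

.jsonable_config <- function(config) {
  out <- unclass(config)
  out$nct_estimator <- unclass(out$nct_estimator)
  out
}
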