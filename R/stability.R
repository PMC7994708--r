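#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric accuracy analysis: subjects are resampled with replacement
#' `n_boot` times, the network is re-estimated per resample, and the 2.5%
#' and 97.5% quantiles of each edge weight are reported around the
#' full-sample point estimate. A resample on which the estimator fails
#' (e.g. a zero-variance column) is redrawn and the redraw counted.
#'
#' @param X A [wave_matrix()] or numeric score matrix.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed RNG seed; results are fully reproducible given the seed.
#' @param estimator An [estimator_config()].
#' @return An object of class `bootstrap_result` with `kind = "edge_ci"`,
#'   an `edges` data frame (`node_a`, `node_b`, `estimate`, `lower`,
#'   `upper`), `n_boot`, `seed` and the redraw count `n_redrawn`.
#' @export
edge_ci_bootstrap <- function(X, n_boot = 1000, seed = 1,
                              estimator = estimator_config()) {
  X <- .as_score_matrix(X)
  if (n_boot < 100) stop("n_boot must be at least 100")
  fun <- .weights_fun(estimator)
  W0 <- fun(X)
  n <- nrow(X)
  ut <- upper.tri(W0)
  boot <- matrix(NA_real_, n_boot, sum(ut))
  n_redrawn <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in 1:25) {
        W <- tryCatch(fun(X[sample.int(n, n, replace = TRUE), , drop = FALSE]),
                      error = function(e) NULL)
        if (!is.null(W)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(W)) stop("estimator failed on 25 consecutive resamples")
      boot[b, ] <- W[ut]
    }
  })
  qs <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  idx <- which(ut, arr.ind = TRUE)
  nodes <- colnames(X)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(X)))
  edges <- data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                      estimate = W0[ut], lower = qs[1, ], upper = qs[2, ],
                      stringsAsFactors = FALSE)
  structure(list(kind = "edge_ci", edges = edges, n_boot = n_boot,
                 seed = seed, n_redrawn = n_redrawn, estimator = estimator),
            class = "bootstrap_result")
}

#' Case-drop stability of strength centrality
#'
#' Subsampling stability analysis: for each drop proportion in `drop_grid`,
#' subjects are subsampled without replacement, the network re-estimated,
#' and the strength centrality of the subsample correlated (Spearman) with
#' the full-sample strength. The correlation-stability (CS) coefficient is
#' the largest drop proportion at which that correlation is at least 0.7 in
#' at least 95% of resamples (and in all smaller drops as well, enforcing a
#' monotone reading of the curve). A CS below the smallest grid value is
#' reported as `"<0.05"`; one at the top of the grid as `">0.75"`.
#'
#' @inheritParams edge_ci_bootstrap
#' @param statistic Centrality to track; only `"strength"` is implemented.
#' @param drop_grid Strictly increasing drop proportions in `(0, 0.75]`.
#' @param n_boot Resamples per grid point.
#' @return A `bootstrap_result` with `kind = "case_drop"`: `curve` data
#'   frame (`drop`, `n_sub`, `mean_cor`, `prop_ge_07`), `cs_coefficient`,
#'   `cs_label`, skipped grid points, `n_boot`, `seed`.
#' @export
case_drop_stability <- function(X, statistic = "strength",
                                drop_grid = seq(0.05, 0.75, by = 0.05),
                                n_boot = 250, seed = 1,
                                estimator = estimator_config()) {
  X <- .as_score_matrix(X)
  statistic <- match.arg(statistic, "strength")
  if (any(drop_grid <= 0 | drop_grid > 0.75)) {
    stop("drop_grid proportions must lie in (0, 0.75]")
  }
  drop_grid <- sort(drop_grid)
  fun <- .weights_fun(estimator)
  n <- nrow(X)
  p <- ncol(X)
  s0 <- colSums(abs(fun(X)))
  curve <- data.frame(drop = drop_grid, n_sub = NA_integer_,
                      mean_cor = NA_real_, prop_ge_07 = NA_real_)
  skipped <- character(0)
  .with_seed(seed, {
    for (g in seq_along(drop_grid)) {
      m <- round((1 - drop_grid[g]) * n)
      if (m < p + 2L) {
        skipped <- c(skipped, sprintf(
          "drop %.2f skipped: subsample %d below p + 2", drop_grid[g], m))
        next
      }
      cors <- vapply(seq_len(n_boot), function(b) {
        W <- tryCatch(fun(X[sample.int(n, m), , drop = FALSE]),
                      error = function(e) NULL)
        if (is.null(W)) return(NA_real_)
        suppressWarnings(stats::cor(colSums(abs(W)), s0, method = "spearman"))
      }, 0)
      curve$n_sub[g] <- m
      curve$mean_cor[g] <- mean(cors, na.rm = TRUE)
      curve$prop_ge_07[g] <- mean(!is.na(cors) & cors >= 0.7)
    }
  })
  eval_ok <- !is.na(curve$prop_ge_07)
  pass <- eval_ok & curve$prop_ge_07 >= 0.95
  cs <- 0
  for (g in which(eval_ok)) {
    if (pass[g]) cs <- curve$drop[g] else break
  }
  cs_label <- if (cs == 0) "<0.05"
  else if (cs >= 0.75) ">0.75"
  else sprintf("%.2f", cs)
  structure(list(kind = "case_drop", statistic = statistic, curve = curve,
                 cs_coefficient = cs, cs_label = cs_label, skipped = skipped,
                 n_boot = n_boot, seed = seed, estimator = estimator),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  if (x$kind == "edge_ci") {
    cat(sprintf("<bootstrap_result> edge CIs, %d edges, n_boot = %d (seed %d",
                nrow(x$edges), x$n_boot, x$seed))
    cat(sprintf(", %d resamples redrawn)\n", x$n_redrawn))
  } else {
    cat(sprintf(
      "<bootstrap_result> case-drop stability of %s: CS %s (n_boot = %d, seed %d)\n",
      x$statistic, x$cs_label, x$n_boot, x$seed))
  }
  invisible(x)
}

#' Export a bootstrap result as tidy CSV
#'
#' Edge-CI results write one row per edge; case-drop results one row per
#' drop proportion.
#'
#' @param x A `bootstrap_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_csv <- function(x, path) {
  stopifnot(inherits(x, "bootstrap_result"))
  out <- if (x$kind == "edge_ci") x$edges else x$curve
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
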