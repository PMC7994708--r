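#' Panel graphical vector autoregression
#'
#' Estimates the lag-1 temporal (Granger-causal) network and the
#' contemporaneous residual network from a few-wave panel by pooled least
#' squares: all consecutive wave transitions (t0->t1, t1->t2, ...) are
#' stacked under a stationarity assumption and wave-t scores are regressed
#' on wave-(t-1) scores in one multivariate regression. A nonzero entry
#' `B[j, k]` means symptom k at the previous wave predicts symptom j at the
#' next wave beyond all other symptoms' past — the Granger-causal reading of
#' a temporal network. The contemporaneous network is the partial-correlation
#' matrix of the same-wave residuals.
#'
#' Subjects contribute every complete consecutive wave pair they have;
#' incomplete pairs are dropped. Optional subject-mean centering removes the
#' stable between-person level before regression (note: with very few waves
#' this induces Nickell-type bias toward zero autoregression, so the default
#' is no centering). With `standardize = TRUE` all scores are z-scored with
#' pooled mean/sd per symptom first, making `B` invariant to per-symptom
#' affine rescaling.
#'
#' @param panel A [symptom_panel()] with at least 2 waves, or a continuous
#'   subjects x waves x symptoms array (e.g. the latent array attached to a
#'   generated panel), which is used as-is.
#' @param centering `"none"` (default) or `"subject_mean"`.
#' @param standardize Logical; default `FALSE`.
#' @return An object of class `temporal_model`: `B` (p x p, rows = outcome
#'   at wave t, columns = predictor at wave t-1), `intercepts`,
#'   `contemporaneous` (residual partial-correlation matrix),
#'   `residual_covariance`, `n_transitions`, `centering`, `standardized`,
#'   plus the ingredients for Wald tests (`xtx_inv`, `sigma2`, `df`).
#' @export
estimate_panel_gvar <- function(panel, centering = c("none", "subject_mean"),
                                standardize = FALSE) {
  centering <- match.arg(centering)
  if (inherits(panel, "symptom_panel")) {
    sc <- panel$scores
    symptom_names <- panel$symptom_names
  } else if (is.array(panel) && length(dim(panel)) == 3L) {
    sc <- panel
    symptom_names <- dimnames(sc)[[3]]
    if (is.null(symptom_names)) symptom_names <- paste0("V", seq_len(dim(sc)[3]))
  } else {
    stop("expected a symptom_panel or a 3-way array")
  }
  d <- dim(sc)
  if (d[2] < 2L) stop("at least 2 waves are required")
  p <- d[3]
  if (standardize) {
    for (k in seq_len(p)) {
      v <- sc[, , k]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) stop("zero-variance symptom: ",
                                   symptom_names[k])
      sc[, , k] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  if (centering == "subject_mean") {
    for (i in seq_len(d[1])) {
      si <- matrix(sc[i, , , drop = FALSE], d[2], p)
      sc[i, , ] <- sweep(si, 2L, colMeans(si, na.rm = TRUE))
    }
  }
  ## stack complete consecutive transitions across subjects and wave pairs
  Xl <- NULL
  Y <- NULL
  for (j in seq_len(d[2] - 1L)) {
    prev <- matrix(sc[, j, , drop = FALSE], d[1], p)
    nxt <- matrix(sc[, j + 1L, , drop = FALSE], d[1], p)
    ok <- rowSums(is.na(prev)) == 0L & rowSums(is.na(nxt)) == 0L
    Xl <- rbind(Xl, prev[ok, , drop = FALSE])
    Y <- rbind(Y, nxt[ok, , drop = FALSE])
  }
  N <- nrow(Xl)
  if (N <= p + 2L) {
    stop(sprintf("only %d complete transitions; more than p + 2 = %d required",
                 N, p + 2L))
  }
  D <- cbind(1, Xl)
  qr_d <- qr(D)
  if (qr_d$rank < p + 1L) stop("predictor matrix is rank deficient")
  coefs <- qr.coef(qr_d, Y)            # (p + 1) x p: column = outcome
  resid <- Y - D %*% coefs
  df <- N - p - 1L
  Sigma <- crossprod(resid) / df
  K <- tryCatch(solve(Sigma), error = function(e) {
    solve(nearest_pd(stats::cov2cor(Sigma)) *
            tcrossprod(sqrt(diag(Sigma))))
  })
  contemporaneous <- precision_to_pcor((K + t(K)) / 2)
  B <- t(coefs[-1L, , drop = FALSE])   # B[outcome, predictor]
  nm <- symptom_names
  dimnames(B) <- list(nm, nm)
  dimnames(contemporaneous) <- list(nm, nm)
  dimnames(Sigma) <- list(nm, nm)
  structure(
    list(B = B, intercepts = stats::setNames(coefs[1L, ], nm),
         contemporaneous = contemporaneous, residual_covariance = Sigma,
         n_transitions = N, centering = centering,
         standardized = standardize, nodes = nm,
         xtx_inv = chol2inv(qr.R(qr_d)), sigma2 = diag(Sigma), df = df),
    class = "temporal_model")
}

#' @export
print.temporal_model <- function(x, ...) {
  st <- check_stationarity(x$B)
  cat(sprintf(
    "<temporal_model> %d nodes, %d pooled transitions (centering %s%s)\n",
    length(x$nodes), x$n_transitions, x$centering,
    if (x$standardized) ", standardized" else ""))
  cat(sprintf("  spectral radius of B = %.3f (%s)\n", st$spectral_radius,
              if (st$stationary) "stationary" else "non-stationary"))
  invisible(x)
}

#' Stationarity check for a temporal coefficient matrix
#'
#' The lag-1 dynamics are stationary when the spectral radius (largest
#' eigenvalue modulus) of the temporal matrix is below 1.
#'
#' @param B Square temporal coefficient matrix (or a `temporal_model`).
#' @return List with `spectral_radius` and logical `stationary`.
#' @export
check_stationarity <- function(B) {
  if (inherits(B, "temporal_model")) B <- B$B
  if (!is.matrix(B) || nrow(B) != ncol(B)) stop("B must be square")
  r <- max(Mod(eigen(B, only.values = TRUE)$values))
  list(spectral_radius = r, stationary = r < 1)
}

#' Wald tests for temporal edges
#'
#' Per-coefficient two-sided Wald (t) test of each cross-lagged and
#' autoregressive coefficient from the least-squares standard errors:
#' `se(B[j, k]) = sqrt(sigma2_j * (X'X)^-1_kk)` with residual degrees of
#' freedom `N - p - 1`. No multiplicity correction by default.
#'
#' @param model A `temporal_model` from [estimate_panel_gvar()].
#' @param alpha Two-sided level; edges with `p < alpha` are flagged
#'   retained. `alpha = 0` retains nothing.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Directed edge-list data frame: `from` (predictor, wave t-1),
#'   `to` (outcome, wave t), `coefficient`, `se`, `statistic`, `p`,
#'   `retained`.
#' @export
temporal_edge_test <- function(model, alpha = 0.05,
                               adjust = c("none", "holm")) {
  stopifnot(inherits(model, "temporal_model"))
  adjust <- match.arg(adjust)
  if (any(model$sigma2 <= 0)) stop("degenerate residual variance")
  p <- length(model$nodes)
  ## xtx_inv is (p + 1) x (p + 1) including the intercept; predictors follow
  pred_var <- diag(model$xtx_inv)[-1L]
  se <- sqrt(outer(model$sigma2, pred_var))        # [outcome, predictor]
  tstat <- model$B / se
  pv <- 2 * stats::pt(-abs(tstat), df = model$df)
  idx <- expand.grid(to = seq_len(p), from = seq_len(p))
  out <- data.frame(
    from = model$nodes[idx$from], to = model$nodes[idx$to],
    coefficient = model$B[cbind(idx$to, idx$from)],
    se = se[cbind(idx$to, idx$from)],
    statistic = tstat[cbind(idx$to, idx$from)],
    p = pv[cbind(idx$to, idx$from)],
    stringsAsFactors = FALSE)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$retained <- out$p < alpha
  out
}

#' Export a temporal network
#'
#' `write_temporal_csv()` writes the directed edge list with tests;
#' `write_temporal_graphml()` writes a directed weighted GraphML graph
#' (edges from predictor to outcome).
#'
#' @param model A `temporal_model`.
#' @param path Output file path.
#' @param alpha Level passed to [temporal_edge_test()] for the CSV.
#' @return `path`, invisibly.
#' @export
write_temporal_csv <- function(model, path, alpha = 0.05) {
  utils::write.csv(temporal_edge_test(model, alpha = alpha), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_temporal_csv
#' @export
write_temporal_graphml <- function(model, path) {
  stopifnot(inherits(model, "temporal_model"))
  ## adjacency[from, to] = B[to, from]
  g <- igraph::graph_from_adjacency_matrix(t(model$B), mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
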