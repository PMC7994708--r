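#' Convert a precision matrix to partial correlations
#'
#' The Gaussian graphical model's edge weights are the standardized negated
#' off-diagonal entries of the precision (inverse covariance) matrix:
#' `w_ij = -K_ij / sqrt(K_ii * K_jj)`, with a zero diagonal.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
#' @examples
#' precision_to_pcor(matrix(c(1, -0.5, -0.5, 1), 2))  # single edge 0.5
precision_to_pcor <- function(K) {
  if (!is.matrix(K) || !isSymmetric(unname(K), tol = 1e-8)) {
    stop("precision matrix must be symmetric")
  }
  d <- diag(K)
  if (any(d <= 0) || min(eigen((K + t(K)) / 2, symmetric = TRUE,
                               only.values = TRUE)$values) <= 0) {
    stop("precision matrix is not positive definite; repair the ",
         "correlation input (see nearest_pd) before inverting")
  }
  W <- -K / tcrossprod(sqrt(d))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(K)
  W
}

.new_network_model <- function(weights, nodes, method, input_correlation,
                               n, lambda_selected = NA_real_,
                               gamma = NA_real_, repaired = FALSE) {
  dimnames(weights) <- list(nodes, nodes)
  structure(
    list(weights = weights, nodes = nodes, method = method,
         input_correlation = input_correlation, n = n,
         lambda_selected = lambda_selected, gamma = gamma,
         repaired = repaired),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<network_model> %s (%s input), %d nodes, %d nonzero edges, n = %d\n",
              x$method, x$input_correlation, length(x$nodes), ne, x$n))
  if (!is.na(x$lambda_selected)) {
    cat(sprintf("  lambda = %.4g (EBIC gamma = %g)\n",
                x$lambda_selected, x$gamma))
  }
  cat(sprintf("  global strength = %.3f\n", global_strength(x)))
  invisible(x)
}

#' Nonregularized Gaussian graphical model
#'
#' Estimates the partial correlation network by inverting the (PSD-repaired)
#' correlation matrix — the saturated, unregularized GGM. Every pairwise
#' partial correlation is reported as an edge weight; no sparsity is imposed.
#' An optional Fisher-z significance screen is available separately via
#' [ggm_edge_test()].
#'
#' @param C A `cor_matrix` (from [spearman_matrix()] or [pearson_matrix()])
#'   or a bare symmetric correlation matrix.
#' @param n Sample size; taken from the `cor_matrix` when omitted. Must
#'   exceed the number of variables.
#' @return A `network_model` with `method = "nonregularized"`.
#' @export
estimate_ggm <- function(C, n = NULL) {
  C <- .as_cor_matrix(C, n)
  n <- C$n_effective
  p <- ncol(C$values)
  if (n <= p) stop("sample size must exceed the number of variables")
  C <- nearest_pd(C)
  K <- tryCatch(solve(C$values),
                error = function(e) stop("correlation matrix is singular ",
                                         "even after PSD repair"))
  W <- precision_to_pcor((K + t(K)) / 2)
  nodes <- colnames(C$values)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  .new_network_model(W, nodes, "nonregularized", C$method, n,
                     repaired = C$repaired)
}

#' EBIC graphical lasso
#'
#' L1-penalized sparse precision estimation over a log-spaced penalty grid,
#' selecting the penalty by the extended Bayesian information criterion
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)`, where `E` counts
#' nonzero upper-triangle precision entries and the log-likelihood is the
#' Gaussian profile likelihood of the estimated precision against the sample
#' correlation. The grid runs from `lambda_max` (the largest absolute
#' off-diagonal correlation, at which the network is empty) down to
#' `lambda_max * lambda_min_ratio`. The diagonal is not penalized.
#'
#' @inheritParams estimate_ggm
#' @param gamma EBIC hyperparameter; `0.5` (default) prefers sparser models,
#'   `0` reduces to the ordinary BIC.
#' @param n_lambda Number of grid points (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @return A `network_model` with `method = "ebic_glasso"` and the selected
#'   penalty in `lambda_selected`.
#' @export
ebic_glasso <- function(C, n = NULL, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
  C <- .as_cor_matrix(C, n)
  n <- C$n_effective
  if (n <= 3L) stop("sample size must exceed 3")
  C <- nearest_pd(C)
  S <- C$values
  p <- ncol(S)
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max == 0) lambda_max <- 1e-4  # diagonal input: any grid works
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  lambdas[1] <- lambda_max  # guard against exp(log()) rounding below the max
  fit <- glasso_path_ebic(unname(S), lambdas, n, gamma)
  if (fit$index < 1 || !all(is.finite(fit$ebic))) {
    stop("no converged graphical-lasso fit on the grid")
  }
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(S)
  W <- precision_to_pcor(Theta)
  W[abs(W) < 1e-12] <- 0
  nodes <- colnames(S)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  .new_network_model(W, nodes, "ebic_glasso", C$method, n,
                     lambda_selected = lambdas[fit$index], gamma = gamma,
                     repaired = C$repaired)
}

#' Node predictability
#'
#' The proportion of each node's variance explained by all remaining nodes —
#' an absolute measure of how well connected a node is. Under a Gaussian
#' working model on standardized variables, `R^2_j = 1 - 1 / K_jj` with `K`
#' the inverse correlation matrix; this equals the OLS R-squared of node j
#' regressed on all others.
#'
#' @inheritParams estimate_ggm
#' @return Named numeric vector of per-node R-squared values in `[0, 1]`.
#' @export
node_predictability <- function(C, n = NULL) {
  C <- .as_cor_matrix(C, n)
  C <- nearest_pd(C)
  K <- tryCatch(solve(C$values),
                error = function(e) stop("correlation matrix is singular ",
                                         "even after PSD repair"))
  r2 <- pmin(pmax(1 - 1 / diag(K), 0), 1)
  names(r2) <- colnames(C$values)
  r2
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over the strict upper triangle — the
#' statistic compared across measurement occasions by the Network Comparison
#' Test ([nct_global_strength()]).
#'
#' @param net A `network_model`, or a symmetric weight matrix.
#' @return A single nonnegative number.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "network_model")) net$weights else net
  sum(abs(W[upper.tri(W)]))
}

#' Strength centrality
#'
#' Per-node sum of absolute incident edge weights. Node strengths sum to
#' twice the global strength.
#'
#' @inheritParams global_strength
#' @return Named numeric vector, one value per node.
#' @export
strength_centrality <- function(net) {
  W <- if (inherits(net, "network_model")) net$weights else net
  colSums(abs(W))
}

#' Filter edges for display
#'
#' Reporting-only thresholding: returns the edge list with edges whose
#' absolute weight is at or below `min_abs_weight` omitted (figures of dense
#' partial-correlation networks commonly report only edges with weight
#' above 0.1). The model itself is never modified.
#'
#' @param net A `network_model`.
#' @param min_abs_weight Nonnegative display threshold; default 0.1.
#' @return A data frame with columns `from`, `to`, `weight`.
#' @export
display_filter <- function(net, min_abs_weight = 0.1) {
  stopifnot(min_abs_weight >= 0)
  el <- as_edge_list(net)
  el[abs(el$weight) > min_abs_weight, , drop = FALSE]
}

#' Fisher-z significance screen for GGM edges
#'
#' Optional two-sided test of each partial correlation against zero using
#' the Fisher z transform with standard error `1 / sqrt(n - p - 1)` (p - 2
#' conditioning variables). No multiplicity correction is applied unless
#' `adjust = "holm"`. This is a reporting aid; the estimated model keeps all
#' edges.
#'
#' @param net A `network_model`.
#' @param alpha Two-sided significance level; default 0.05.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Edge-list data frame with `weight`, `z`, `p`, `retained`.
#' @export
ggm_edge_test <- function(net, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(net, "network_model"))
  p <- length(net$nodes)
  df_se <- net$n - p - 1
  if (df_se <= 0) stop("sample too small for the Fisher-z edge test")
  el <- as_edge_list(net, drop_zero = FALSE)
  z <- atanh(pmin(pmax(el$weight, -1 + 1e-12), 1 - 1e-12)) * sqrt(df_se)
  pv <- 2 * stats::pnorm(-abs(z))
  if (adjust == "holm") pv <- stats::p.adjust(pv, "holm")
  el$z <- z
  el$p <- pv
  el$retained <- pv < alpha
  el
}

#' Edge list of an undirected network
#'
#' @param net A `network_model` or symmetric weight matrix.
#' @param drop_zero Drop zero-weight pairs (default `TRUE`).
#' @return Data frame with columns `from`, `to`, `weight`, one row per
#'   unordered node pair.
#' @export
as_edge_list <- function(net, drop_zero = TRUE) {
  W <- if (inherits(net, "network_model")) net$weights else net
  nodes <- colnames(W)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(W)))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  el <- data.frame(from = nodes[ut[, 1]], to = nodes[ut[, 2]],
                   weight = W[ut], stringsAsFactors = FALSE)
  if (drop_zero) el <- el[el$weight != 0, , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Write a network to GraphML
#'
#' Undirected weighted GraphML via igraph, loadable by standard graph tools.
#'
#' @param net A `network_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "network_model"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a labeled weight matrix to CSV
#'
#' @param net A `network_model` (or `cor_matrix`, whose values are written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weight_csv <- function(net, path) {
  M <- if (inherits(net, "network_model")) net$weights
  else if (inherits(net, "cor_matrix")) net$values
  else net
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}
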