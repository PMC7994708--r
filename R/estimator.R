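#' Network estimator configuration
#'
#' Bundles the choices that define how a network is (re-)estimated from raw
#' scores: the correlation input and the GGM estimator. Used by the
#' bootstrap, case-drop and network-comparison routines, which must
#' re-estimate networks many times with one fixed recipe.
#'
#' @param method `"nonregularized"` (invert the repaired correlation matrix;
#'   the main estimator for these data) or `"ebic_glasso"`.
#' @param correlation `"spearman"` (default, robust for skewed ordinal
#'   scores) or `"pearson"`.
#' @param gamma,n_lambda,lambda_min_ratio Passed to [ebic_glasso()] when
#'   `method = "ebic_glasso"`.
#' @return An object of class `estimator_config`.
#' @export
#' @examples
#' estimator_config("ebic_glasso", "pearson")
estimator_config <- function(method = c("nonregularized", "ebic_glasso"),
                             correlation = c("spearman", "pearson"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01) {
  structure(list(method = match.arg(method),
                 correlation = match.arg(correlation),
                 gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf("<estimator_config> %s, %s input\n", x$method, x$correlation))
  invisible(x)
}

#' Estimate a network from raw scores under a configuration
#'
#' @param X A [wave_matrix()] or numeric score matrix.
#' @param config An [estimator_config()].
#' @return A `network_model`.
#' @export
fit_network <- function(X, config = estimator_config()) {
  stopifnot(inherits(config, "estimator_config"))
  C <- if (config$correlation == "spearman") spearman_matrix(X)
  else pearson_matrix(X)
  if (config$method == "nonregularized") {
    estimate_ggm(C)
  } else {
    ebic_glasso(C, gamma = config$gamma, n_lambda = config$n_lambda,
                lambda_min_ratio = config$lambda_min_ratio)
  }
}

## Lean weight-matrix estimator for resampling loops: skips the S3 ceremony
## of fit_network and uses a Cholesky inverse with PSD repair on failure.
.weights_fun <- function(config) {
  spearman <- config$correlation == "spearman"
  if (config$method == "nonregularized") {
    function(X) {
      C <- if (spearman) stats::cor(X, method = "spearman") else stats::cor(X)
      if (anyNA(C)) stop("zero-variance column in resample")
      K <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
      if (is.null(K)) {
        C <- nearest_pd(C)
        K <- chol2inv(chol(C + diag(1e-10, ncol(C))))
      }
      W <- -K / tcrossprod(sqrt(diag(K)))
      diag(W) <- 0
      (W + t(W)) / 2
    }
  } else {
    function(X) {
      C <- if (spearman) stats::cor(X, method = "spearman") else stats::cor(X)
      if (anyNA(C)) stop("zero-variance column in resample")
      ebic_glasso(.as_cor_matrix(C, n = nrow(X), method = config$correlation),
                  gamma = config$gamma, n_lambda = config$n_lambda,
                  lambda_min_ratio = config$lambda_min_ratio)$weights
    }
  }
}
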