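#' Correlation matrices for network estimation
#'
#' Compute the Spearman or Pearson correlation matrix of a score matrix, the
#' input to every network estimator in the package. Spearman (rank)
#' correlation is the recommended input for skewed ordinal symptom scores;
#' ranks use the average-rank treatment of ties. Rank-based matrices can be
#' indefinite in small samples, so [nearest_pd()] repairs them before
#' inversion.
#'
#' @param X A [wave_matrix()] or numeric matrix (rows = subjects, columns =
#'   symptoms). At least 3 rows; every column must have nonzero variance.
#' @return An object of class `cor_matrix`: list with `values` (p x p labeled
#'   matrix), `method`, `n_effective`, `repaired` (logical).
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' spearman_matrix(X)
spearman_matrix <- function(X) {
  .cor_matrix(X, "spearman")
}

#' @rdname spearman_matrix
#' @export
pearson_matrix <- function(X) {
  .cor_matrix(X, "pearson")
}

.cor_matrix <- function(X, method) {
  X <- .as_score_matrix(X)
  if (nrow(X) < 3L) stop("at least 3 complete subjects are required")
  if (anyNA(X)) stop("score matrix contains missing values")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
    stop("zero-variance symptom(s): ",
         paste(nm[v == 0], collapse = ", "))
  }
  C <- stats::cor(X, method = method)
  structure(list(values = C, method = method, n_effective = nrow(X),
                 repaired = FALSE),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("<cor_matrix> %s, p = %d, n = %d%s\n", x$method,
              ncol(x$values), x$n_effective,
              if (isTRUE(x$repaired)) " (PSD-repaired)" else ""))
  invisible(x)
}

#' Repair an indefinite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps` and the
#' reconstructed matrix is rescaled to unit diagonal. A positive
#' semi-definite input is returned unchanged with `repaired = FALSE`.
#'
#' @param C A `cor_matrix` or symmetric numeric matrix.
#' @param eps Eigenvalue floor; default `1e-8`.
#' @return Same class as the input, positive semi-definite, with the
#'   `repaired` flag set when any eigenvalue was clipped.
#' @export
nearest_pd <- function(C, eps = 1e-8) {
  is_cm <- inherits(C, "cor_matrix")
  M <- if (is_cm) C$values else C
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("matrix is not symmetric")
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= eps) {
    if (is_cm) return(C)
    return(M)
  }
  lam <- pmax(e$values, eps)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(M)
  if (is_cm) {
    C$values <- R
    C$repaired <- TRUE
    C
  } else R
}

## Coerce any accepted correlation input to a cor_matrix, attaching n when
## only a bare matrix was given.
.as_cor_matrix <- function(C, n = NULL, method = NA_character_) {
  if (inherits(C, "cor_matrix")) return(C)
  if (!is.matrix(C) || !isSymmetric(unname(C), tol = 1e-8)) {
    stop("expected a cor_matrix or a symmetric correlation matrix")
  }
  if (is.null(n)) stop("`n` must be supplied with a bare correlation matrix")
  structure(list(values = C, method = method, n_effective = n,
                 repaired = FALSE),
            class = "cor_matrix")
}
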