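## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (had_seed) assign(".Random.seed", old, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Correlation matrix implied by a partial-correlation network
#'
#' Inverts the precision matrix implied by a partial-correlation matrix under
#' unit partial variances (`K_jj = 1`, `K_jk = -pcor_jk`) and standardizes it.
#' Useful for simulating data whose true conditional-independence network is
#' known.
#'
#' @param P Symmetric partial-correlation matrix with zero diagonal and
#'   entries in `(-1, 1)`; the implied precision must be positive definite.
#' @return Correlation matrix.
#' @export
pcor_to_cor <- function(P) {
  if (!is.matrix(P) || !isSymmetric(unname(P), tol = 1e-8)) {
    stop("partial-correlation matrix must be symmetric")
  }
  if (any(abs(diag(P)) > 1e-12)) stop("diagonal must be zero")
  if (any(abs(P) >= 1)) stop("entries must lie in (-1, 1)")
  K <- -P
  diag(K) <- 1
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("implied precision matrix is not positive definite")
  S <- solve(K)
  R <- stats::cov2cor(S)
  dimnames(R) <- dimnames(P)
  (R + t(R)) / 2
}
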