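#' Default sparse contemporaneous network for simulation
#'
#' A clinically flavored sparse partial-correlation structure over the 11
#' YMRS symptoms: mood tied to motor activity, speech and insight;
#' irritability to aggressive behavior; language-thought disorder to
#' content; speech to content; plus a few weaker links. The implied
#' precision matrix is positive definite.
#'
#' @return 11 x 11 symmetric partial-correlation matrix, zero diagonal.
#' @export
default_contemporaneous_pcor <- function() {
  nm <- ymrs_symptoms()
  P <- matrix(0, 11, 11, dimnames = list(nm, nm))
  edge <- function(a, b, w) {
    P[a, b] <<- w
    P[b, a] <<- w
  }
  edge("Mood", "Motor", 0.30)
  edge("Mood", "Insight", 0.20)
  edge("Mood", "Speech", 0.15)
  edge("Irritable", "Aggressive", 0.35)
  edge("LgTtAbn", "Content", 0.35)
  edge("Speech", "Content", 0.25)
  edge("Sleep", "Motor", 0.20)
  edge("Sleep", "Irritable", 0.15)
  edge("Sexual", "Content", 0.15)
  edge("Appearance", "Insight", 0.20)
  edge("Motor", "Speech", 0.15)
  P
}

#' Default sparse temporal matrix for simulation
#'
#' Lag-1 coefficients `B[outcome, predictor]` with modest autoregression on
#' every symptom and a handful of cross-lagged effects converging on mood,
#' motor activity and sleep (the symptoms that receive many temporal
#' influences in treated mania). Spectral radius well below 1.
#'
#' @return 11 x 11 temporal coefficient matrix.
#' @export
default_temporal_B <- function() {
  nm <- ymrs_symptoms()
  B <- diag(0.25, 11)
  dimnames(B) <- list(nm, nm)
  B["Mood", "Motor"] <- 0.15
  B["Mood", "Sleep"] <- 0.12
  B["Mood", "Insight"] <- 0.12
  B["Motor", "Mood"] <- 0.15
  B["Motor", "Speech"] <- 0.10
  B["Sleep", "Irritable"] <- 0.12
  B["Sleep", "Mood"] <- 0.10
  B
}

#' Configuration for the synthetic panel generator
#'
#' Defines a latent-Gaussian ordinal panel with known network structure.
#' Latent scores follow a stationary-in-deviation VAR(1) around possibly
#' nonstationary wave means plus a stable person effect, and are discretized
#' into 0--4 by fixed thresholds. The defaults emulate the design of an
#' acute-mania inpatient study: 100 subjects, 3 waves (admission, middle of
#' stay, discharge), 11 YMRS symptoms, high wave-0 latent means declining by
#' wave 2 as treatment takes effect.
#'
#' @param n_subjects Number of subjects (default 100).
#' @param waves Number of waves (default 3).
#' @param p Number of symptoms (default 11).
#' @param symptom_names Symptom names; default [ymrs_symptoms()] for p = 11.
#' @param B_true p x p temporal matrix, spectral radius < 1; default
#'   [default_temporal_B()].
#' @param contemporaneous_pcor p x p partial-correlation matrix of the
#'   innovations (unit partial variances); default
#'   [default_contemporaneous_pcor()].
#' @param between_sd Per-symptom standard deviation of the stable person
#'   effect; scalar recycled. Default 0.4.
#' @param wave_means waves x p matrix of latent population means, rows in
#'   time order; the default declines from high admission values to low
#'   discharge values.
#' @param thresholds Four strictly increasing cut-points mapping latent
#'   scores to \{0..4\}; default `c(-1.5, -0.5, 0.5, 1.5)`.
#' @param seed RNG seed (default 1).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 100, waves = 3, p = 11,
                             symptom_names = NULL, B_true = NULL,
                             contemporaneous_pcor = NULL, between_sd = 0.4,
                             wave_means = NULL,
                             thresholds = c(-1.5, -0.5, 0.5, 1.5), seed = 1) {
  if (is.null(symptom_names)) {
    symptom_names <- if (p == 11) ymrs_symptoms() else paste0("V", seq_len(p))
  }
  if (is.null(B_true)) {
    B_true <- if (p == 11) default_temporal_B() else diag(0.25, p)
  }
  if (is.null(contemporaneous_pcor)) {
    contemporaneous_pcor <- if (p == 11) default_contemporaneous_pcor()
    else matrix(0, p, p)
  }
  if (length(between_sd) == 1L) between_sd <- rep(between_sd, p)
  if (is.null(wave_means)) {
    t0 <- c(2.0, 1.2, -0.7, 1.0, 1.0, 1.2, 0.8, 1.0, 0.7, 0.2, 1.6)
    if (p != 11) t0 <- rep(1.5, p)
    drops <- seq(0, 2.2, length.out = max(waves, 2))[seq_len(waves)]
    wave_means <- t(vapply(drops, function(d) t0 - d, numeric(p)))
  }
  cfg <- structure(
    list(n_subjects = n_subjects, waves = waves, p = p,
         symptom_names = symptom_names, B_true = B_true,
         contemporaneous_pcor = contemporaneous_pcor,
         between_sd = between_sd, wave_means = wave_means,
         thresholds = thresholds, seed = seed),
    class = "generator_config")
  .validate_generator_config(cfg)
  cfg
}

.validate_generator_config <- function(cfg) {
  p <- cfg$p
  stopifnot(cfg$n_subjects >= 1, cfg$waves >= 1, p >= 1)
  if (!all(dim(cfg$B_true) == c(p, p))) stop("B_true must be p x p")
  r <- max(Mod(eigen(cfg$B_true, only.values = TRUE)$values))
  if (r >= 1) stop(sprintf("spectral radius of B_true is %.3f; must be < 1", r))
  P <- cfg$contemporaneous_pcor
  if (!all(dim(P) == c(p, p)) || !isSymmetric(unname(P), tol = 1e-8)) {
    stop("contemporaneous_pcor must be symmetric p x p")
  }
  if (any(abs(diag(P)) > 1e-12)) stop("contemporaneous_pcor diagonal must be 0")
  if (any(abs(P) >= 1)) stop("partial correlations must lie in (-1, 1)")
  K <- -P
  diag(K) <- 1
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("contemporaneous_pcor implies a non-positive-definite precision")
  }
  if (length(cfg$between_sd) != p || any(cfg$between_sd < 0)) {
    stop("between_sd must be p nonnegative values")
  }
  if (!all(dim(cfg$wave_means) == c(cfg$waves, p))) {
    stop("wave_means must be waves x p")
  }
  if (length(cfg$thresholds) != 4L || any(diff(cfg$thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing cut-points")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d subjects x %d waves x %d symptoms (seed %d)\n",
    x$n_subjects, x$waves, x$p, x$seed))
  cat(sprintf("  spectral radius of B_true = %.3f; %d contemporaneous edges\n",
              max(Mod(eigen(x$B_true, only.values = TRUE)$values)),
              sum(x$contemporaneous_pcor[upper.tri(x$contemporaneous_pcor)]
                  != 0)))
  invisible(x)
}

#' Generate a synthetic ordinal symptom panel
#'
#' Simulates the latent-Gaussian panel defined by a [generator_config()]:
#' per subject, a stable person effect `mu_i ~ N(0, diag(between_sd^2))`;
#' the wave-0 latent deviation drawn from the stationary distribution of the
#' within-subject VAR(1); subsequent waves
#' `y_t = m_t + mu_i + B (y_(t-1) - m_(t-1) - mu_i) + eps_t` with
#' `eps_t ~ N(0, Sigma)`, where `Sigma` is the covariance implied by the
#' contemporaneous partial-correlation matrix under unit partial variances.
#' Latent scores are discretized into \{0..4\} by the thresholds. Fully
#' reproducible given the config seed.
#'
#' @param config A [generator_config()].
#' @return A [symptom_panel()]. The continuous latent array (subjects x
#'   waves x symptoms) is attached as attribute `"latent"` and the config as
#'   attribute `"config"`, for use as simulation oracles.
#' @export
generate_panel <- function(config = generator_config()) {
  .validate_generator_config(config)
  n <- config$n_subjects
  w <- config$waves
  p <- config$p
  K <- -config$contemporaneous_pcor
  diag(K) <- 1
  Sigma <- solve(K)
  B <- config$B_true
  ## stationary covariance of the deviation process: S0 = B S0 B' + Sigma
  S0 <- matrix(solve(diag(p * p) - kronecker(B, B), as.vector(Sigma)), p, p)
  S0 <- (S0 + t(S0)) / 2
  cS <- chol(Sigma)
  cS0 <- chol(S0)
  latent <- array(NA_real_, dim = c(n, w, p))
  .with_seed(config$seed, {
    mu <- matrix(stats::rnorm(n * p), n, p) %*% diag(config$between_sd, p)
    dev <- matrix(stats::rnorm(n * p), n, p) %*% cS0
    latent[, 1L, ] <- matrix(config$wave_means[1L, ], n, p, byrow = TRUE) +
      mu + dev
    for (t in seq_len(w - 1L)) {
      eps <- matrix(stats::rnorm(n * p), n, p) %*% cS
      dev <- dev %*% t(B) + eps
      latent[, t + 1L, ] <- matrix(config$wave_means[t + 1L, ], n, p,
                                   byrow = TRUE) + mu + dev
    }
  })
  scores <- array(discretize(matrix(latent, n * w, p), config$thresholds),
                  dim = c(n, w, p))
  ids <- sprintf("s%03d", seq_len(n))
  panel <- symptom_panel(scores, ids,
                         wave_labels = paste0("t", seq_len(w) - 1L),
                         symptom_names = config$symptom_names)
  dimnames(latent) <- dimnames(panel$scores)
  attr(panel, "latent") <- latent
  attr(panel, "config") <- config
  panel
}

#' Discretize latent scores into ordinal categories
#'
#' Each score is the count of thresholds lying below the latent value, so
#' four cut-points give categories 0 through 4.
#'
#' @param latent Numeric matrix (or vector) of latent scores.
#' @param thresholds Strictly increasing cut-points.
#' @return Integer scores with the same shape as `latent`.
#' @export
#' @examples
#' discretize(c(-9, 0, 9), c(-1.5, -0.5, 0.5, 1.5))  # 0 2 4
discretize <- function(latent, thresholds) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  out <- findInterval(latent, thresholds)
  if (is.matrix(latent)) out <- matrix(out, nrow(latent), ncol(latent),
                                       dimnames = dimnames(latent))
  out
}

#' Serialize or restore a generator configuration as JSON
#'
#' @param config A [generator_config()].
#' @param path JSON file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a validated `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    n_subjects = x$n_subjects, waves = x$waves, p = x$p,
    symptom_names = x$symptom_names, B_true = as.matrix(x$B_true),
    contemporaneous_pcor = as.matrix(x$contemporaneous_pcor),
    between_sd = x$between_sd, wave_means = as.matrix(x$wave_means),
    thresholds = x$thresholds, seed = x$seed)
}
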