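#' Default YMRS symptom names
#'
#' The eleven clinician-rated items of the Young Mania Rating Scale, in the
#' order used throughout this package: elevated mood, increased motor
#' activity/energy, sexual interest, sleep, irritability, speech (rate and
#' amount), language-thought disorder, content, aggressive behavior,
#' appearance, and insight.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' ymrs_symptoms()
ymrs_symptoms <- function() {
  c("Mood", "Motor", "Sexual", "Sleep", "Irritable", "Speech",
    "LgTtAbn", "Content", "Aggressive", "Appearance", "Insight")
}

#' Construct an ordinal symptom panel
#'
#' A `symptom_panel` holds repeated ordinal symptom assessments: one score in
#' 0--4 (or `NA`) per subject, measurement wave and symptom. It is the common
#' input to every estimator in the package.
#'
#' @param scores Numeric array of dimension subjects x waves x symptoms.
#'   Non-missing entries must be integers in `[0, 4]`.
#' @param subject_ids Character or integer vector of unique subject
#'   identifiers (length `dim(scores)[1]`).
#' @param wave_labels Character vector of wave labels, ordered in time
#'   (length `dim(scores)[2]`). Default `c("t0", "t1", "t2")` for three waves.
#' @param symptom_names Character vector of symptom names without duplicates
#'   (length `dim(scores)[3]`). Defaults to [ymrs_symptoms()] when the panel
#'   has 11 symptoms.
#'
#' @return An object of class `symptom_panel` with elements `scores`,
#'   `subject_ids`, `wave_labels`, `symptom_names`.
#' @export
#' @examples
#' sc <- array(sample(0:4, 2 * 3 * 11, TRUE), dim = c(2, 3, 11))
#' symptom_panel(sc, subject_ids = c("s1", "s2"))
symptom_panel <- function(scores, subject_ids,
                          wave_labels = NULL, symptom_names = NULL) {
  if (!is.array(scores) || length(dim(scores)) != 3L) {
    stop("`scores` must be a 3-way array (subjects x waves x symptoms)")
  }
  d <- dim(scores)
  if (is.null(wave_labels)) {
    wave_labels <- paste0("t", seq_len(d[2]) - 1L)
  }
  if (is.null(symptom_names)) {
    symptom_names <- if (d[3] == 11L) ymrs_symptoms() else
      paste0("V", seq_len(d[3]))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != d[1]) {
    stop("`subject_ids` length does not match the number of subjects")
  }
  if (anyDuplicated(subject_ids)) stop("`subject_ids` must be unique")
  if (length(wave_labels) != d[2]) {
    stop("`wave_labels` length does not match the number of waves")
  }
  if (anyDuplicated(wave_labels)) stop("`wave_labels` must be unique")
  if (length(symptom_names) != d[3]) {
    stop("`symptom_names` length does not match the number of symptoms")
  }
  if (anyDuplicated(symptom_names)) stop("`symptom_names` must be unique")
  storage.mode(scores) <- "double"
  .validate_scores(scores, subject_ids, wave_labels, symptom_names)
  dimnames(scores) <- list(subject_ids, wave_labels, symptom_names)
  structure(
    list(scores = scores, subject_ids = subject_ids,
         wave_labels = as.character(wave_labels),
         symptom_names = as.character(symptom_names)),
    class = "symptom_panel")
}

## Every non-missing score must be an integer in [0, 4]; offenders are
## reported by (subject, wave, symptom), never silently clipped.
.validate_scores <- function(scores, subject_ids, wave_labels, symptom_names) {
  x <- as.vector(scores)
  bad <- !is.na(x) & (x < 0 | x > 4 | x != round(x))
  if (any(bad)) {
    idx <- which(array(bad, dim = dim(scores)), arr.ind = TRUE)
    idx <- idx[seq_len(min(nrow(idx), 5L)), , drop = FALSE]
    cells <- apply(idx, 1L, function(i) {
      sprintf("(subject=%s, wave=%s, symptom=%s, value=%g)",
              subject_ids[i[1]], wave_labels[i[2]], symptom_names[i[3]],
              scores[i[1], i[2], i[3]])
    })
    stop("scores must be integers in [0, 4]; offending cells: ",
         paste(cells, collapse = ", "),
         if (sum(bad) > 5L) sprintf(" ... and %d more", sum(bad) - 5L) else "")
  }
  invisible(TRUE)
}

#' @export
print.symptom_panel <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<symptom_panel> %d subjects x %d waves x %d symptoms\n",
              d[1], d[2], d[3]))
  cat("  waves:   ", paste(x$wave_labels, collapse = ", "), "\n")
  cat("  symptoms:", paste(x$symptom_names, collapse = ", "), "\n")
  nmiss <- sum(is.na(x$scores))
  if (nmiss > 0) cat(sprintf("  missing scores: %d\n", nmiss))
  invisible(x)
}

#' Read a symptom panel from CSV
#'
#' Two dialects are supported. `long`: columns `subject`, `wave`, then one
#' column per symptom; one row per subject-wave. `wide`: one row per subject
#' with wave-indexed columns named `<symptom><waveindex>` (`Mood0`, `Mood1`,
#' ..., `Insight2`), the naming used in printed descriptive tables for this
#' kind of panel.
#'
#' @param path Path to a CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param symptom_names Symptom names expected in the file; defaults to
#'   [ymrs_symptoms()]. For the long dialect any extra columns are an error;
#'   scores outside `[0, 4]` raise a validation error naming the cells.
#' @param wave_labels For the wide dialect, labels given to the integer wave
#'   indices found in the column names; default `t<index>`.
#'
#' @return A validated [symptom_panel()].
#' @seealso [write_panel()]
#' @export
read_panel <- function(path, dialect = c("long", "wide"),
                       symptom_names = ymrs_symptoms(), wave_labels = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "long") {
    .panel_from_long(df, symptom_names)
  } else {
    .panel_from_wide(df, symptom_names, wave_labels)
  }
}

.panel_from_long <- function(df, symptom_names) {
  need <- c("subject", "wave", symptom_names)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("long panel is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$subject <- as.character(df$subject)
  df$wave <- as.character(df$wave)
  if (anyDuplicated(df[c("subject", "wave")])) {
    stop("each (subject, wave) pair may occur at most once")
  }
  subject_ids <- sort(unique(df$subject))
  wave_labels <- unique(df$wave)  # file order defines time order
  sc <- array(NA_real_,
              dim = c(length(subject_ids), length(wave_labels),
                      length(symptom_names)))
  i <- match(df$subject, subject_ids)
  j <- match(df$wave, wave_labels)
  for (k in seq_along(symptom_names)) {
    sc[cbind(i, j, k)] <- as.numeric(df[[symptom_names[k]]])
  }
  symptom_panel(sc, subject_ids, wave_labels, symptom_names)
}

.panel_from_wide <- function(df, symptom_names, wave_labels) {
  if (!"subject" %in% names(df)) {
    stop("wide panel is missing required column: subject")
  }
  cols <- setdiff(names(df), "subject")
  ## a column matches when it is <known symptom name><integer wave index>;
  ## prefixes are matched longest-first so names ending in digits still parse
  widx <- rep(NA_integer_, length(cols))
  for (sym in symptom_names[order(-nchar(symptom_names))]) {
    hit <- is.na(widx) & startsWith(cols, sym) &
      grepl("^[0-9]+$", substring(cols, nchar(sym) + 1L))
    widx[hit] <- as.integer(substring(cols[hit], nchar(sym) + 1L))
  }
  if (all(is.na(widx))) {
    stop("no wave-indexed symptom columns (e.g. Mood0) found")
  }
  waves <- sort(unique(widx[!is.na(widx)]))
  need <- as.vector(outer(symptom_names, waves, paste0))
  missing_cols <- setdiff(need, cols)
  if (length(missing_cols)) {
    stop("wide panel is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(wave_labels)) wave_labels <- paste0("t", waves)
  subject_ids <- as.character(df$subject)
  sc <- array(NA_real_, dim = c(nrow(df), length(waves), length(symptom_names)))
  for (j in seq_along(waves)) {
    for (k in seq_along(symptom_names)) {
      sc[, j, k] <- as.numeric(df[[paste0(symptom_names[k], waves[j])]])
    }
  }
  ord <- order(subject_ids)
  symptom_panel(sc[ord, , , drop = FALSE], subject_ids[ord],
                wave_labels, symptom_names)
}

#' Write a symptom panel to CSV
#'
#' @param panel A [symptom_panel()].
#' @param path Output file path.
#' @param dialect `"long"` (default; one row per subject-wave) or `"wide"`
#'   (wave-indexed columns `Mood0`, ..., `Insight2`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "symptom_panel"))
  sc <- panel$scores
  if (dialect == "long") {
    rows <- expand.grid(subject = panel$subject_ids,
                        wave = panel$wave_labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$subject, match(rows$wave, panel$wave_labels)), ]
    out <- rows
    for (k in seq_along(panel$symptom_names)) {
      out[[panel$symptom_names[k]]] <-
        sc[cbind(match(rows$subject, panel$subject_ids),
                 match(rows$wave, panel$wave_labels),
                 rep(k, nrow(rows)))]
    }
  } else {
    out <- data.frame(subject = panel$subject_ids, stringsAsFactors = FALSE)
    for (j in seq_along(panel$wave_labels)) {
      for (k in seq_along(panel$symptom_names)) {
        out[[paste0(panel$symptom_names[k], j - 1L)]] <- sc[, j, k]
      }
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Per-wave descriptive statistics
#'
#' Mean, standard deviation (n-1 denominator), minimum and maximum per
#' symptom at one wave, the per-wave summary usually reported for ordinal
#' symptom panels. Missing scores are excluded per symptom.
#'
#' @param panel A [symptom_panel()].
#' @param wave A wave label present in the panel.
#' @return A data frame with one row per symptom and columns `symptom`,
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_panel <- function(panel, wave) {
  stopifnot(inherits(panel, "symptom_panel"))
  j <- match(wave, panel$wave_labels)
  if (is.na(j)) stop("unknown wave label: ", wave)
  d <- dim(panel$scores)
  X <- matrix(panel$scores[, j, , drop = FALSE], d[1], d[3])
  data.frame(
    symptom = panel$symptom_names,
    mean = apply(X, 2L, mean, na.rm = TRUE),
    sd = apply(X, 2L, stats::sd, na.rm = TRUE),
    min = apply(X, 2L, min, na.rm = TRUE),
    max = apply(X, 2L, max, na.rm = TRUE),
    n = apply(X, 2L, function(v) sum(!is.na(v))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract one wave as a complete-case score matrix
#'
#' Subjects with any missing score at the requested wave are dropped
#' (listwise deletion); rows are ordered by sorted subject id so repeated
#' extractions are deterministic.
#'
#' @param panel A [symptom_panel()].
#' @param wave A wave label present in the panel.
#' @param missing_policy Only `"listwise"` is implemented.
#' @return An object of class `wave_matrix`: list with `wave`, `data`
#'   (n x p numeric matrix with symptom columns and subject-id rownames) and
#'   `subject_ids`.
#' @export
wave_matrix <- function(panel, wave, missing_policy = "listwise") {
  stopifnot(inherits(panel, "symptom_panel"))
  missing_policy <- match.arg(missing_policy, "listwise")
  j <- match(wave, panel$wave_labels)
  if (is.na(j)) stop("unknown wave label: ", wave)
  d <- dim(panel$scores)
  X <- matrix(panel$scores[, j, , drop = FALSE], d[1], d[3])
  rownames(X) <- panel$subject_ids
  complete <- rowSums(is.na(X)) == 0L
  X <- X[complete, , drop = FALSE]
  ids <- panel$subject_ids[complete]
  ord <- order(ids)
  X <- X[ord, , drop = FALSE]
  ids <- ids[ord]
  p <- length(panel$symptom_names)
  if (nrow(X) < p + 2L) {
    stop(sprintf(
      "wave %s has %d complete subjects; at least p + 2 = %d are required",
      wave, nrow(X), p + 2L))
  }
  dimnames(X) <- list(ids, panel$symptom_names)
  structure(list(wave = wave, data = X, subject_ids = ids),
            class = "wave_matrix")
}

#' @export
print.wave_matrix <- function(x, ...) {
  cat(sprintf("<wave_matrix> wave %s: %d subjects x %d symptoms\n",
              x$wave, nrow(x$data), ncol(x$data)))
  invisible(x)
}

## Accept either a wave_matrix or a plain numeric matrix everywhere.
.as_score_matrix <- function(X) {
  if (inherits(X, "wave_matrix")) return(X$data)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("expected a wave_matrix or a numeric matrix")
  }
  X
}
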