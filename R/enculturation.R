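## Two-culture analysis: per-piece mean information content under a model
## of the listener's own culture (by k-fold cross-validation) and under a
## model of the other culture (full-corpus training), rotated 45 degrees
## into cultural distance (perpendicular distance from the line of
## equality) and culture-neutral complexity.

melody_mean_ics <- function(melody, ltm) {
  m <- mean_ic(ic_profile(melody, ltm = ltm))
  c(pitch = m$pitch, onset = m$onset, joint = m$joint)
}

#' Within-culture information content by cross-validation
#'
#' Assigns melodies to `folds` folds by a seeded pseudo-random permutation
#' dealt round-robin, trains a long-term model on the complement of each
#' fold, and computes every melody's mean information content under the
#' model that excludes it.  The short-term model is not used.
#'
#' @param corpus a [corpus()].
#' @param config a [prediction_config()]; its subsystems are forced to
#'   `"ltm"`.  Basic alphabets should be fixed (e.g. resolved over both
#'   corpora of a comparison) for comparability.
#' @param folds number of folds (default 10; at least 2, at most the
#'   corpus size).
#' @param seed integer seed for the fold assignment.
#' @return A data frame with columns `id`, `fold`, `ic_pitch`, `ic_onset`,
#'   `ic_joint` (bits per note).
#' @export
within_culture_ic <- function(corpus, config = prediction_config(),
                              folds = 10L, seed = 1L) {
  stopifnot(inherits(corpus, "corpus"))
  folds <- as.integer(folds)
  n <- length(corpus)
  if (is.na(folds) || folds < 2L)
    stop("'folds' must be an integer >= 2", call. = FALSE)
  if (folds > n)
    stop("'folds' exceeds the corpus size", call. = FALSE)
  config$subsystems <- "ltm"
  ab <- resolve_alphabets(corpus, config)
  config$pitch_alphabet <- ab$pitch
  config$ioi_alphabet <- ab$ioi
  fold_of <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of[sample.int(n)] <- rep_len(seq_len(folds), n)
  res <- matrix(NA_real_, nrow = n, ncol = 3L,
                dimnames = list(NULL, c("pitch", "onset", "joint")))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    ltm <- train_ltm(corpus[fold_of != f], config)
    for (i in test_idx)
      res[i, ] <- melody_mean_ics(corpus[[i]], ltm)
  }
  data.frame(id = corpus_ids(corpus), fold = fold_of,
             ic_pitch = res[, "pitch"], ic_onset = res[, "onset"],
             ic_joint = res[, "joint"], row.names = NULL)
}

#' Between-culture information content
#'
#' Mean information content of every melody in a corpus under an already
#' trained long-term model of another culture (no retraining, no
#' short-term model).
#'
#' @param ltm a [train_ltm()] object.
#' @param corpus a [corpus()].
#' @return A data frame with columns `id`, `ic_pitch`, `ic_onset`,
#'   `ic_joint`.
#' @export
between_culture_ic <- function(ltm, corpus) {
  stopifnot(inherits(ltm, "ltm"), inherits(corpus, "corpus"))
  ltm$config$subsystems <- "ltm"
  res <- t(vapply(corpus$melodies, melody_mean_ics,
                  numeric(3), ltm = ltm))
  data.frame(id = corpus_ids(corpus),
             ic_pitch = res[, "pitch"], ic_onset = res[, "onset"],
             ic_joint = res[, "joint"], row.names = NULL)
}

#' Cultural distance and culture-neutral complexity
#'
#' A 45-degree rotation of the (own-model IC, other-model IC) plane:
#' `distance = (ic_other - ic_own) / sqrt(2)` is the signed perpendicular
#' distance from the line of equality (positive when the piece is more
#' predictable under its own culture's model), and
#' `complexity = (ic_own + ic_other) / sqrt(2)` is the orthogonal,
#' culture-neutral coordinate.
#'
#' @param ic_own,ic_other mean information content (bits per note) under
#'   the own-culture and other-culture models; vectorized.
#' @return A data frame of class `"cultural_distance"` with columns
#'   `ic_own`, `ic_other`, `distance`, `complexity`.
#' @examples
#' cultural_distance(2.44, 6.53)$distance  # 2.89
#' @export
cultural_distance <- function(ic_own, ic_other) {
  if (!all(is.finite(ic_own)) || !all(is.finite(ic_other)))
    stop("information content values must be finite", call. = FALSE)
  structure(data.frame(ic_own = ic_own, ic_other = ic_other,
                       distance = (ic_other - ic_own) / sqrt(2),
                       complexity = (ic_own + ic_other) / sqrt(2)),
            class = c("cultural_distance", "data.frame"))
}

#' Classify a melody by minimum information content
#'
#' The melody is assigned to the culture whose model compresses it better
#' (lower mean information content); an exact tie returns `"undecided"`.
#'
#' @param melody a [melody()].
#' @param ltm_a,ltm_b trained [train_ltm()] objects with identical
#'   viewpoint configurations.
#' @param labels culture labels for the two models.
#' @return One of `labels` or `"undecided"`.
#' @export
classify_piece <- function(melody, ltm_a, ltm_b, labels = c("A", "B")) {
  pick <- function(m) if (!is.na(m["joint"])) m[["joint"]]
                      else if (!is.na(m["pitch"])) m[["pitch"]]
                      else m[["onset"]]
  ic_a <- pick(melody_mean_ics(melody, ltm_a))
  ic_b <- pick(melody_mean_ics(melody, ltm_b))
  if (ic_a == ic_b) return("undecided")
  labels[[if (ic_a < ic_b) 1L else 2L]]
}

#' Two-culture corpus comparison
#'
#' Runs the full two-culture analysis: within-culture information content
#' by cross-validation, between-culture information content by
#' full-corpus training, per-piece cultural distances (own-culture IC as
#' `ic_own`), and a summary per attribute configuration (pitch only,
#' onset only, pitch and onset).  Overall accuracy is the fraction of
#' pieces with positive distance (equivalently, lower IC under their own
#' culture's model); overall cultural distance is the mean of the
#' per-piece signed distances.
#'
#' Both corpora should have been deduplicated first (see
#' [deduplicate_corpus()]).  Basic alphabets are resolved over the union
#' of the two corpora so that all models share a common support.
#'
#' @param corpus_a,corpus_b [corpus()] objects for the two cultures.
#' @param config a [prediction_config()] (long-term model enforced).
#' @param folds,seed passed to [within_culture_ic()].
#' @return An object of class `"culture_summary"`: a list with `table`
#'   (data frame: attribute, accuracy in percent, mean distance in bits)
#'   and `pieces` (per-piece long data frame with culture, attribute,
#'   ic_own, ic_other, distance, complexity).
#' @export
corpus_summary <- function(corpus_a, corpus_b, config = prediction_config(),
                           folds = 10L, seed = 1L) {
  stopifnot(inherits(corpus_a, "corpus"), inherits(corpus_b, "corpus"))
  config$subsystems <- "ltm"
  both <- corpus(c(corpus_a$melodies, corpus_b$melodies), name = "union")
  ab <- resolve_alphabets(both, config)
  config$pitch_alphabet <- ab$pitch
  config$ioi_alphabet <- ab$ioi
  within_a <- within_culture_ic(corpus_a, config, folds, seed)
  within_b <- within_culture_ic(corpus_b, config, folds, seed)
  ltm_a <- train_ltm(corpus_a, config)
  ltm_b <- train_ltm(corpus_b, config)
  between_a <- between_culture_ic(ltm_b, corpus_a)   # A pieces, B model
  between_b <- between_culture_ic(ltm_a, corpus_b)   # B pieces, A model
  attrs <- c(pitch = "ic_pitch", onset = "ic_onset", joint = "ic_joint")
  pieces <- do.call(rbind, lapply(names(attrs), function(a) {
    col <- attrs[[a]]
    cd <- cultural_distance(c(within_a[[col]], within_b[[col]]),
                            c(between_a[[col]], between_b[[col]]))
    data.frame(id = c(within_a$id, within_b$id),
               culture = rep(c(corpus_a$name, corpus_b$name),
                             c(nrow(within_a), nrow(within_b))),
               attribute = a, cd, row.names = NULL)
  }))
  tab <- do.call(rbind, lapply(names(attrs), function(a) {
    d <- pieces$distance[pieces$attribute == a]
    data.frame(attribute = a,
               accuracy = 100 * mean(d > 0),
               mean_distance = mean(d))
  }))
  structure(list(table = tab, pieces = pieces,
                 models = list(a = ltm_a, b = ltm_b),
                 folds = folds, seed = seed),
            class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat("Two-culture comparison (accuracy %, mean cultural distance bits):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## save/restore .Random.seed so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
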