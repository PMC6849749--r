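#' Detect phrase boundaries as marked rises in information content
#'
#' Perceived grouping boundaries tend to fall before contextually
#' unpredictable events, so an event opens a new phrase when its
#' information content rises markedly above the recent trend.  Event `n`
#' is marked as group-initial when
#' `ic[n] > mean(ic[(n-w):(n-1)]) + k * sd(ic[(n-w):(n-1)])` and
#' `ic[n] > ic[n-1]`; its strength is the deviation in window standard
#' deviations.  The sample standard deviation is floored at `1e-6` so that
#' flat windows cannot produce spurious boundaries.
#'
#' @param ic numeric vector of per-event information content (bits), e.g.
#'   the `ic_joint` or `ic_pitch` column of an [ic_profile()], or an
#'   `ic_profile` itself (joint IC used where available, else pitch).
#' @param w window length in events (default 10; must be at least 2).
#' @param k threshold in window standard deviations (default 2, positive).
#' @return An object of class `"boundary_set"`: a list with integer
#'   `indices` (event positions marked group-initial) and numeric
#'   `strengths`.
#' @export
detect_boundaries <- function(ic, w = 10L, k = 2) {
  if (inherits(ic, "ic_profile")) {
    ic <- if (!all(is.na(ic$ic_joint))) ic$ic_joint else ic$ic_pitch
  }
  w <- as.integer(w)
  if (is.na(w) || w < 2L)
    stop("'w' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(k) || k <= 0)
    stop("'k' must be a positive real", call. = FALSE)
  if (length(ic) < w + 1L)
    stop("profile must contain at least w + 1 events", call. = FALSE)
  indices <- integer(0)
  strengths <- numeric(0)
  for (n in (w + 1L):length(ic)) {
    win <- ic[(n - w):(n - 1L)]
    if (anyNA(win) || is.na(ic[n])) next
    mu <- mean(win)
    sdev <- max(stats::sd(win), 1e-6)
    if (ic[n] > mu + k * sdev && ic[n] > ic[n - 1L]) {
      indices <- c(indices, n)
      strengths <- c(strengths, (ic[n] - mu) / sdev)
    }
  }
  structure(list(indices = indices, strengths = strengths),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("Boundary set: %d boundaries at [%s]\n", length(x$indices),
              paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Score predicted boundaries against annotations
#'
#' Standard precision / recall / F1 with a +/- `tolerance` matching
#' window; each annotated boundary is matched by at most one prediction
#' and vice versa (greedy nearest-first matching).  With no predictions,
#' precision is reported as 0 by convention.
#'
#' @param predicted a [detect_boundaries()] result or an integer vector of
#'   predicted positions.
#' @param annotated integer vector of annotated boundary positions.
#' @param tolerance allowed positional slack in events (default 0).
#' @return A list with `precision`, `recall`, `f1`, and the count of
#'   matched pairs `n_hit`.
#' @export
evaluate_boundaries <- function(predicted, annotated, tolerance = 0L) {
  if (inherits(predicted, "boundary_set")) predicted <- predicted$indices
  predicted <- sort(unique(as.integer(predicted)))
  annotated <- sort(unique(as.integer(annotated)))
  used <- logical(length(predicted))
  hits <- 0L
  for (a in annotated) {
    d <- abs(predicted - a)
    d[used] <- NA
    if (length(d) && any(!is.na(d) & d <= tolerance)) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  precision <- if (length(predicted)) hits / length(predicted) else 0
  recall <- if (length(annotated)) hits / length(annotated) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall /
          (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, n_hit = hits)
}
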