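## Seeded generators of synthetic corpora with known Markov structure:
## two stylistically distinct "cultures" (first-order chains over scale
## degrees and over ioi ratios), metrically structured rhythms, and
## perturbed variants of a melody for similarity experiments.  All
## generators are pure functions of (spec, seed).

check_stochastic <- function(mat, what) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop(what, " must be a square matrix", call. = FALSE)
  if (any(mat < 0) || any(abs(rowSums(mat) - 1) > 1e-9))
    stop(what, " rows must be non-negative and sum to 1", call. = FALSE)
  invisible(mat)
}

#' Specify a synthetic musical culture
#'
#' A culture is a pair of first-order Markov chains: one over chromatic
#' scale degrees (semitones above the tonic) governing pitch, and one over
#' ioi ratios governing rhythm.  Melodies start from `sd_init` and an
#' initial ioi of `base_ioi` ticks; each subsequent ioi multiplies the
#' previous one by a sampled ratio, clamped to the `[ioi_min, ioi_max]`
#' tick range (ratios that would leave the range are excluded and the row
#' renormalized).
#'
#' @param name culture label.
#' @param sd_states integer vector of scale-degree states.
#' @param sd_init initial distribution over `sd_states`.
#' @param sd_trans row-stochastic transition matrix over `sd_states`.
#' @param ratio_states character vector of reduced ioi ratios
#'   (e.g. `"1/2"`, `"1/1"`, `"2/1"`).
#' @param ratio_trans row-stochastic transition matrix over
#'   `ratio_states`; its stationary start uses the first row.
#' @param tonic tonic MIDI pitch (default 60).
#' @param base_ioi initial inter-onset interval in ticks (default 24, a
#'   crotchet).
#' @param ioi_min,ioi_max admissible ioi range in ticks.
#' @param length_range inclusive range of melody lengths (events).
#' @return An object of class `"culture_spec"`.
#' @seealso [default_culture_specs()], [generate_culture()]
#' @export
culture_spec <- function(name, sd_states, sd_init, sd_trans,
                         ratio_states, ratio_trans, tonic = 60L,
                         base_ioi = 24L, ioi_min = 6L, ioi_max = 96L,
                         length_range = c(15L, 25L)) {
  sd_states <- as.integer(sd_states)
  if (length(sd_init) != length(sd_states) ||
      abs(sum(sd_init) - 1) > 1e-9 || any(sd_init < 0))
    stop("'sd_init' must be a distribution over 'sd_states'", call. = FALSE)
  check_stochastic(sd_trans, "'sd_trans'")
  check_stochastic(ratio_trans, "'ratio_trans'")
  if (nrow(sd_trans) != length(sd_states))
    stop("'sd_trans' dimension must match 'sd_states'", call. = FALSE)
  if (nrow(ratio_trans) != length(ratio_states))
    stop("'ratio_trans' dimension must match 'ratio_states'", call. = FALSE)
  structure(list(name = name, sd_states = sd_states, sd_init = sd_init,
                 sd_trans = sd_trans, ratio_states = ratio_states,
                 ratio_trans = ratio_trans, tonic = as.integer(tonic),
                 base_ioi = as.integer(base_ioi),
                 ioi_min = as.integer(ioi_min),
                 ioi_max = as.integer(ioi_max),
                 length_range = as.integer(length_range)),
            class = "culture_spec")
}

ratio_value <- function(r) {
  parts <- strsplit(r, "/", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) / as.numeric(p[2]), numeric(1))
}

#' Default two-culture fixture
#'
#' Two well-separated synthetic cultures sharing a tonic of middle C: a
#' diatonic-flavoured culture (seven-state scale-degree chain favouring
#' stepwise motion, rhythm dominated by even ratios) and a
#' pentatonic-flavoured culture (five-state chain with wider gaps, rhythm
#' favouring halving and doubling).  The contrast loosely echoes a
#' Western/Chinese folk-song comparison but makes no claim of ethnographic
#' fidelity; it exists so that every analysis stage can be validated on
#' corpora whose generating statistics are known exactly.
#'
#' @return A list with elements `A` (diatonic) and `B` (pentatonic), each
#'   a [culture_spec()].
#' @export
default_culture_specs <- function() {
  ## diatonic: strong preference for +/- one scale step
  sdA <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  nA <- length(sdA)
  tA <- matrix(0.02, nA, nA)
  for (i in seq_len(nA)) {
    if (i > 1L) tA[i, i - 1L] <- tA[i, i - 1L] + 0.40
    if (i < nA) tA[i, i + 1L] <- tA[i, i + 1L] + 0.40
    tA[i, i] <- tA[i, i] + 0.06
  }
  tA <- tA / rowSums(tA)
  ratA <- c("1/2", "1/1", "2/1")
  rtA <- rbind(c(0.15, 0.70, 0.15),
               c(0.10, 0.80, 0.10),
               c(0.15, 0.70, 0.15))
  ## pentatonic: gapped scale, more leaps, restless rhythm
  sdB <- c(0L, 2L, 4L, 7L, 9L)
  nB <- length(sdB)
  tB <- matrix(0, nB, nB)
  tB[1, ] <- c(0.10, 0.15, 0.15, 0.45, 0.15)
  tB[2, ] <- c(0.35, 0.10, 0.10, 0.10, 0.35)
  tB[3, ] <- c(0.15, 0.10, 0.10, 0.50, 0.15)
  tB[4, ] <- c(0.40, 0.10, 0.25, 0.10, 0.15)
  tB[5, ] <- c(0.15, 0.40, 0.10, 0.25, 0.10)
  ratB <- c("1/2", "1/1", "2/1")
  rtB <- rbind(c(0.15, 0.25, 0.60),
               c(0.45, 0.10, 0.45),
               c(0.60, 0.25, 0.15))
  list(A = culture_spec("A", sdA, rep(1 / nA, nA), tA, ratA, rtA),
       B = culture_spec("B", sdB, rep(1 / nB, nB), tB, ratB, rtB))
}

sample_chain <- function(states, init, trans, n) {
  idx <- integer(n)
  idx[1L] <- sample.int(length(states), 1L, prob = init)
  for (i in seq_len(n - 1L))
    idx[i + 1L] <- sample.int(length(states), 1L, prob = trans[idx[i], ])
  states[idx]
}

#' Generate a corpus from a culture specification
#'
#' Melodies are sampled from the culture's scale-degree and ioi-ratio
#' chains; output is bitwise reproducible for a fixed seed.
#'
#' @param spec a [culture_spec()].
#' @param n number of melodies (at least 1).
#' @param seed integer seed.
#' @return A [corpus()] whose melodies carry tonic and culture metadata.
#' @export
generate_culture <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "culture_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rvals <- ratio_value(spec$ratio_states)
  lens <- spec$length_range[1L]:spec$length_range[2L]
  mels <- lapply(seq_len(n), function(k) {
    len <- lens[sample.int(length(lens), 1L)]
    sds <- sample_chain(spec$sd_states, spec$sd_init, spec$sd_trans, len)
    pitch <- spec$tonic + sds
    ioi <- integer(len - 1L)
    ioi[1L] <- spec$base_ioi
    r_idx <- sample.int(length(spec$ratio_states), 1L,
                        prob = spec$ratio_trans[1L, ])
    if (len > 2L) {
      for (i in 2:(len - 1L)) {
        next_iois <- ioi[i - 1L] * rvals
        feasible <- next_iois >= spec$ioi_min & next_iois <= spec$ioi_max &
          next_iois == round(next_iois)
        probs <- spec$ratio_trans[r_idx, ] * feasible
        if (sum(probs) == 0) {
          ioi[i] <- ioi[i - 1L]
          r_idx <- which(rvals == 1)[1L]
        } else {
          r_idx <- sample.int(length(rvals), 1L, prob = probs / sum(probs))
          ioi[i] <- as.integer(ioi[i - 1L] * rvals[r_idx])
        }
      }
    }
    melody(onset = cumsum(c(0L, ioi)), pitch = pitch,
           id = sprintf("%s%04d", spec$name, k), tonic = spec$tonic,
           culture = spec$name)
  })
  corpus(mels, name = spec$name)
}

#' Generate metrically structured rhythms
#'
#' Onsets fall on a tick grid; each grid position within a bar carries an
#' onset with the probability given by the accent profile.  The first
#' position of the first bar always carries an onset, anchoring the phase
#' at zero.  Melodies carry the true category as their time signature;
#' pitch is a constant filler since only rhythm matters here.
#'
#' @param category time-signature label, e.g. `"3/4"`.
#' @param accent_profile vector of onset probabilities per grid position;
#'   its length times `grid` must equal the bar period of `category`.
#' @param n number of rhythms.
#' @param bars bars per rhythm (default 8).
#' @param grid tick grid (default 24, one position per crotchet).
#' @param seed integer seed.
#' @return A [corpus()].
#' @export
generate_metrical_rhythms <- function(category, accent_profile, n,
                                      bars = 8L, grid = 24L, seed = 1L) {
  period <- meter_period(category)
  if (length(accent_profile) == 0L)
    stop("'accent_profile' must be non-empty", call. = FALSE)
  if (length(accent_profile) * grid != period)
    stop("accent profile length x grid must equal the bar period (",
         period, " ticks)", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  positions <- as.vector(outer((seq_along(accent_profile) - 1L) * grid,
                               (seq_len(bars) - 1L) * period, `+`))
  probs <- rep(accent_profile, bars)
  mels <- lapply(seq_len(n), function(k) {
    keep <- stats::runif(length(positions)) < probs
    keep[1L] <- TRUE
    onsets <- positions[keep]
    melody(onset = onsets, pitch = rep(60L, length(onsets)),
           id = sprintf("%s-%04d", gsub("/", "-", category), k),
           time_signature = category)
  })
  corpus(mels, name = category)
}

#' Perturb a melody with a controlled error type
#'
#' Produces manipulated variants of the kinds used in melodic-similarity
#' experiments.  `magnitude` counts edited positions (for `"rhythm"`,
#' `"interval"` and `"contour"`), the length of each swapped segment (for
#' `"phrase-order"`), or the transposition in semitones applied to the
#' second half (for `"modulation"`).  `magnitude = 0` returns the melody
#' unchanged; edits are seeded and reproducible.
#'
#' @param melody a [melody()].
#' @param error_type one of `"rhythm"`, `"interval"`, `"contour"`,
#'   `"phrase-order"`, `"modulation"`.
#' @param magnitude non-negative integer (see above).
#' @param seed integer seed.
#' @return A [melody()] with id suffixed by the error type.
#' @export
perturb_melody <- function(melody,
                           error_type = c("rhythm", "interval", "contour",
                                          "phrase-order", "modulation"),
                           magnitude = 1L, seed = 1L) {
  stopifnot(inherits(melody, "melody"))
  error_type <- match.arg(error_type)
  magnitude <- as.integer(magnitude)
  if (magnitude < 0L) stop("'magnitude' must be >= 0", call. = FALSE)
  if (magnitude == 0L) return(melody)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(melody$onset)
  ioi <- diff(melody$onset)
  iv <- diff(melody$pitch)
  rebuild <- function(pitch, ioi) {
    m <- melody
    m$pitch <- as.integer(pitch)
    m$onset <- as.integer(cumsum(c(melody$onset[1L], ioi)))
    m$id <- paste0(melody$id, "-", error_type)
    m
  }
  switch(error_type,
    rhythm = {
      if (magnitude > length(ioi))
        stop("melody too short for the requested edit", call. = FALSE)
      at <- sample(seq_along(ioi), magnitude)
      ioi[at] <- pmax(6L, as.integer(ioi[at] *
                                       sample(c(0.5, 2), magnitude,
                                              replace = TRUE)))
      rebuild(melody$pitch, ioi)
    },
    interval = {
      if (magnitude > length(iv))
        stop("melody too short for the requested edit", call. = FALSE)
      at <- sample(seq_along(iv), magnitude)
      delta <- sample(1:2, magnitude, replace = TRUE)
      iv[at] <- iv[at] + ifelse(iv[at] >= 0, delta, -delta)  # keep contour
      rebuild(melody$pitch[1L] + cumsum(c(0L, iv)), ioi)
    },
    contour = {
      if (magnitude > length(iv))
        stop("melody too short for the requested edit", call. = FALSE)
      at <- sample(seq_along(iv), magnitude)
      iv[at] <- -iv[at]
      rebuild(melody$pitch[1L] + cumsum(c(0L, iv)), ioi)
    },
    `phrase-order` = {
      if (2L * magnitude > n)
        stop("melody too short for the requested edit", call. = FALSE)
      seg1 <- seq_len(magnitude)
      seg2 <- magnitude + seq_len(magnitude)
      perm <- c(seg2, seg1, setdiff(seq_len(n), c(seg1, seg2)))
      rebuild(melody$pitch[perm], ioi)
    },
    modulation = {
      if (n < 4L)
        stop("melody too short for the requested edit", call. = FALSE)
      cut <- n %/% 2L
      pitch <- melody$pitch
      pitch[(cut + 1L):n] <- pitch[(cut + 1L):n] + magnitude
      rebuild(pitch, ioi)
    })
}
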