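#' Construct a melody
#'
#' A melody is a monophonic sequence of note events, each with an onset time
#' in integer ticks (24 ticks per crotchet) and a MIDI pitch number
#' (60 = middle C).  Optional metadata carry the tonic (needed for
#' scale-degree viewpoints), the notated time signature and a culture label.
#'
#' @param onset integer vector of onset times in ticks; strictly increasing.
#' @param pitch integer vector of MIDI note numbers in `[0, 127]`, same
#'   length as `onset`.
#' @param id character scalar identifying the melody.
#' @param tonic optional MIDI pitch number of the tonic; only its pitch
#'   class is used.
#' @param time_signature optional time-signature label such as `"4/4"`.
#' @param culture optional culture label.
#' @return An object of class `"melody"`.
#' @examples
#' m <- melody(onset = c(0, 24, 48), pitch = c(67, 71, 74), tonic = 67)
#' m
#' @export
melody <- function(onset, pitch, id = "melody", tonic = NULL,
                   time_signature = NULL, culture = NULL) {
  onset <- as.integer(onset)
  pitch <- as.integer(pitch)
  if (length(onset) == 0L)
    stop("a melody must contain at least one event", call. = FALSE)
  if (length(onset) != length(pitch))
    stop("'onset' and 'pitch' must have the same length", call. = FALSE)
  if (anyNA(onset) || anyNA(pitch))
    stop("'onset' and 'pitch' must not contain missing values", call. = FALSE)
  if (any(pitch < 0L | pitch > 127L))
    stop("MIDI pitch numbers must lie in [0, 127]", call. = FALSE)
  if (length(onset) > 1L && any(diff(onset) <= 0L))
    stop("onsets must be strictly increasing within a melody", call. = FALSE)
  if (!is.null(tonic)) tonic <- as.integer(tonic)
  structure(
    list(id = as.character(id), onset = onset, pitch = pitch,
         tonic = tonic, time_signature = time_signature, culture = culture),
    class = "melody")
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("Melody '%s': %d events, onsets %d..%d ticks\n",
              x$id, length(x$onset), x$onset[1L],
              x$onset[length(x$onset)]))
  if (!is.null(x$tonic)) cat(sprintf("  tonic: %d\n", x$tonic))
  if (!is.null(x$time_signature))
    cat(sprintf("  time signature: %s\n", x$time_signature))
  if (!is.null(x$culture)) cat(sprintf("  culture: %s\n", x$culture))
  invisible(x)
}

#' @export
length.melody <- function(x) length(x$onset)

#' Construct a corpus of melodies
#'
#' @param melodies a list of [melody()] objects with unique ids.
#' @param name character scalar naming the corpus.
#' @return An object of class `"corpus"`, a list with elements
#'   `melodies` and `name`.
#' @examples
#' corp <- corpus(list(melody(0, 60, id = "a"), melody(0, 62, id = "b")))
#' corp
#' @export
corpus <- function(melodies, name = "corpus") {
  if (!is.list(melodies) || length(melodies) == 0L)
    stop("'melodies' must be a non-empty list of melody objects",
         call. = FALSE)
  ok <- vapply(melodies, inherits, logical(1), what = "melody")
  if (!all(ok))
    stop("all elements of 'melodies' must be melody objects", call. = FALSE)
  ids <- vapply(melodies, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    stop("melody ids must be unique within a corpus; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(melodies) <- ids
  structure(list(melodies = melodies, name = as.character(name)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  n_ev <- sum(vapply(x$melodies, length, integer(1)))
  cat(sprintf("Corpus '%s': %d melodies, %d events\n",
              x$name, length(x$melodies), n_ev))
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$melodies)

#' @export
`[.corpus` <- function(x, i) {
  corpus(x$melodies[i], name = x$name)
}

#' @export
`[[.corpus` <- function(x, i) x$melodies[[i]]

corpus_ids <- function(x) names(x$melodies)

#' Remove duplicate compositions from a corpus
#'
#' Two melodies count as duplicates when they share the same opening
#' sequence of melodic pitch intervals, regardless of rhythm.  Among a set
#' of duplicates only the first in corpus order is retained, so the result
#' is deterministic given file order.  Melodies shorter than
#' `opening_length` intervals are compared over their full interval
#' sequence.
#'
#' @param corpus a [corpus()] in which every melody has at least two events.
#' @param opening_length number of opening pitch intervals compared
#'   (default 10).
#' @return A [corpus()] containing the retained melodies, in their original
#'   order.
#' @examples
#' a <- melody(c(0, 24, 48), c(60, 64, 67), id = "a")
#' b <- melody(c(0, 12, 72), c(62, 66, 69), id = "b")  # transposed copy of a
#' length(deduplicate_corpus(corpus(list(a, b)), opening_length = 2))
#' @export
deduplicate_corpus <- function(corpus, opening_length = 10L) {
  stopifnot(inherits(corpus, "corpus"))
  opening_length <- as.integer(opening_length)
  if (is.na(opening_length) || opening_length < 1L)
    stop("'opening_length' must be a positive integer", call. = FALSE)
  short <- vapply(corpus$melodies, length, integer(1)) < 2L
  if (any(short))
    stop("every melody needs >= 2 events to form an interval opening; ",
         "offending ids: ",
         paste(corpus_ids(corpus)[short], collapse = ", "), call. = FALSE)
  keys <- vapply(corpus$melodies, function(m) {
    iv <- diff(m$pitch)
    paste(utils::head(iv, opening_length), collapse = " ")
  }, character(1))
  corpus(corpus$melodies[!duplicated(keys)], name = corpus$name)
}
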