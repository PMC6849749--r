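## Viewpoints: derived symbolic attributes of a note sequence.  A viewpoint
## value is a character symbol; positions where the defining function is
## undefined carry NA (the undefined marker, printed as "⊥" in the
## literature).  Linked viewpoints pair two components and are undefined
## wherever either component is.

basic_viewpoints <- c("pitch", "onset", "ioi", "ioi-ratio", "pi", "sd")

vp_components <- function(name) {
  strsplit(name, " x ", fixed = TRUE)[[1]]
}

#' Link two viewpoints
#'
#' The linked viewpoint `a x b` takes the paired value of its components
#' wherever both are defined and is undefined elsewhere.
#'
#' @param a,b distinct viewpoint names (see [derive_viewpoint()]).
#' @return The linked viewpoint name, e.g. `"pi x sd"`.
#' @examples
#' link_viewpoints("pi", "sd")
#' @export
link_viewpoints <- function(a, b) {
  if (identical(a, b))
    stop("cannot link a viewpoint with itself", call. = FALSE)
  if (!all(c(a, b) %in% basic_viewpoints))
    stop("unknown viewpoint name; known: ",
         paste(basic_viewpoints, collapse = ", "), call. = FALSE)
  paste(a, b, sep = " x ")
}

reduce_ratio <- function(num, den) {
  g <- mapply(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, abs(num), abs(den))
  paste0(num %/% g, "/", den %/% g)
}

#' Derive a viewpoint sequence from a melody
#'
#' Computes the value of a viewpoint at every event of a melody.  Supported
#' viewpoints: `pitch` (MIDI note number), `onset` (ticks), `ioi`
#' (inter-onset interval, undefined at the first note), `ioi-ratio` (ratio
#' of successive iois as an exact reduced fraction, undefined at the first
#' two notes), `pi` (pitch interval in semitones, undefined at the first
#' note), `sd` (chromatic scale degree, semitones above the tonic mod 12),
#' and any linked pair `"a x b"` such as `"pi x sd"`.
#'
#' @param melody a [melody()]; must carry a tonic if `sd` is involved.
#' @param name viewpoint name.
#' @return Character vector of symbols, one per event, with `NA` marking
#'   undefined positions.
#' @examples
#' m <- melody(c(0, 24, 48), c(67, 71, 74), tonic = 67)
#' derive_viewpoint(m, "pi")        # NA "4" "3"
#' derive_viewpoint(m, "pi x sd")
#' @export
derive_viewpoint <- function(melody, name) {
  stopifnot(inherits(melody, "melody"))
  comps <- vp_components(name)
  if (length(comps) == 2L) {
    a <- derive_viewpoint(melody, comps[1L])
    b <- derive_viewpoint(melody, comps[2L])
    out <- paste(a, b, sep = ",")
    out[is.na(a) | is.na(b)] <- NA_character_
    return(out)
  }
  n <- length(melody$onset)
  switch(name,
    pitch = as.character(melody$pitch),
    onset = as.character(melody$onset),
    ioi   = c(NA_character_, as.character(diff(melody$onset))),
    pi    = c(NA_character_, as.character(diff(melody$pitch))),
    sd    = {
      if (is.null(melody$tonic))
        stop("scale-degree viewpoint requested but melody '", melody$id,
             "' has no tonic annotation", call. = FALSE)
      as.character((melody$pitch - melody$tonic) %% 12L)
    },
    `ioi-ratio` = {
      if (n < 3L) return(rep(NA_character_, n))
      ioi <- diff(melody$onset)
      c(NA_character_, NA_character_,
        reduce_ratio(ioi[-1L], ioi[-length(ioi)]))
    },
    stop("unknown viewpoint '", name, "'", call. = FALSE))
}

## Derived symbol each candidate basic value would take at position n.
## `candidates` are basic symbols of the attribute ("pitch": MIDI numbers;
## "onset": candidate iois).  Returns NA when the viewpoint is undefined at
## this position regardless of the candidate.
candidate_symbols <- function(name, candidates, attribute,
                              prev_pitch = NULL, tonic = NULL,
                              prev_ioi = NULL) {
  comps <- vp_components(name)
  if (length(comps) == 2L) {
    a <- candidate_symbols(comps[1L], candidates, attribute,
                           prev_pitch, tonic, prev_ioi)
    b <- candidate_symbols(comps[2L], candidates, attribute,
                           prev_pitch, tonic, prev_ioi)
    if (anyNA(a) || anyNA(b)) return(rep(NA_character_, length(candidates)))
    return(paste(a, b, sep = ","))
  }
  und <- rep(NA_character_, length(candidates))
  if (attribute == "pitch") {
    switch(name,
      pitch = as.character(candidates),
      pi    = if (is.null(prev_pitch) || is.na(prev_pitch)) und
              else as.character(candidates - prev_pitch),
      sd    = {
        if (is.null(tonic))
          stop("scale-degree viewpoint requires a tonic", call. = FALSE)
        as.character((candidates - tonic) %% 12L)
      },
      stop("viewpoint '", name, "' cannot predict the pitch attribute",
           call. = FALSE))
  } else {
    switch(name,
      ioi  = as.character(candidates),
      `ioi-ratio` = if (is.null(prev_ioi) || is.na(prev_ioi)) und
                    else reduce_ratio(candidates, rep(prev_ioi,
                                                      length(candidates))),
      stop("viewpoint '", name, "' cannot predict the onset attribute",
           call. = FALSE))
  }
}

#' Map a distribution over derived symbols onto a basic alphabet
#'
#' Given a predictive distribution over the symbols of a derived viewpoint
#' and the context needed to invert it (previous pitch for `pi`, tonic for
#' `sd`, previous ioi for `ioi-ratio`), returns the induced distribution
#' over basic symbols.  When several basic symbols share one derived symbol
#' (e.g. scale degree over a multi-octave pitch alphabet) the derived mass
#' is split equally among them; mass on derived symbols outside the image
#' of the basic alphabet is redistributed by renormalization.
#'
#' @param dist named numeric vector: probability per derived symbol.
#' @param name viewpoint name.
#' @param basic_alphabet integer vector of basic symbols (MIDI pitches, or
#'   candidate iois for temporal viewpoints).
#' @param attribute `"pitch"` or `"onset"`.
#' @param prev_pitch,tonic,prev_ioi inversion context, as required by the
#'   viewpoint.
#' @return Named numeric vector over `basic_alphabet`, summing to 1.
#' @examples
#' to_basic_distribution(c(`0` = 0.5, `4` = 0.5), "pi",
#'                       basic_alphabet = c(67, 71), attribute = "pitch",
#'                       prev_pitch = 67)
#' @export
to_basic_distribution <- function(dist, name, basic_alphabet,
                                  attribute = "pitch", prev_pitch = NULL,
                                  tonic = NULL, prev_ioi = NULL) {
  syms <- candidate_symbols(name, basic_alphabet, attribute,
                            prev_pitch, tonic, prev_ioi)
  if (anyNA(syms))
    stop("viewpoint '", name, "' is undefined in this context and cannot ",
         "be inverted", call. = FALSE)
  share <- table(syms)
  p <- unname(dist[syms])
  p[is.na(p)] <- 0
  p <- p / as.numeric(share[syms])
  tot <- sum(p)
  if (tot <= 0)
    stop("derived distribution places no mass on the image of the basic ",
         "alphabet", call. = FALSE)
  stats::setNames(p / tot, as.character(basic_alphabet))
}
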