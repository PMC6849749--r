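# Shared fixtures and independent oracles, built in code at test time.

make_melody <- function(pitch, ioi = rep(24L, length(pitch) - 1L),
                        id = "m", tonic = 60L, ...) {
  melody(onset = cumsum(c(0L, ioi)), pitch = pitch, id = id, tonic = tonic,
         ...)
}

# Independent PPM oracle: recounts n-grams from the raw training
# sequences with embed() and evaluates the interpolated-escape recursion
# directly, sharing no code with the package's count store.
oracle_ppm <- function(train_seqs, context, alphabet, order_bound = Inf) {
  if (!is.list(train_seqs)) train_seqs <- list(train_seqs)
  train_seqs <- lapply(train_seqs, function(s) s[!is.na(s)])
  count_after <- function(ctx) {
    counts <- stats::setNames(numeric(length(alphabet)), alphabet)
    L <- length(ctx)
    for (s in train_seqs) {
      if (length(s) < L + 1L) next
      for (i in seq_len(length(s) - L)) {
        if (L == 0L || all(s[i:(i + L - 1L)] == ctx)) {
          sym <- s[i + L]
          counts[sym] <- counts[sym] + 1
        }
      }
    }
    counts
  }
  if (is.finite(order_bound) && length(context) > order_bound)
    context <- context[(length(context) - order_bound + 1L):length(context)]
  # longest suffix of the context with nonzero total count
  match_len <- 0L
  if (length(context) > 0L) {
    for (len in length(context):1L) {
      ctx <- context[(length(context) - len + 1L):length(context)]
      if (sum(count_after(ctx)) > 0) { match_len <- len; break }
    }
  }
  rec <- function(len) {
    if (len < 0L) return(stats::setNames(rep(1 / length(alphabet),
                                             length(alphabet)), alphabet))
    ctx <- if (len == 0L) character(0)
           else context[(length(context) - len + 1L):length(context)]
    cnt <- count_after(ctx)
    n <- sum(cnt)
    t <- sum(cnt > 0)
    if (n == 0) return(rec(len - 1L))
    cnt / (n + t) + (t / (n + t)) * rec(len - 1L)
  }
  rec(match_len)
}

# Phrase-concatenation fixture for segmentation: each phrase repeats a
# motif drawn from its own pitch pool (a distinct generating chain per
# phrase), so phrase-initial notes are the contextually novel events.
# Returns the melody and the true phrase-initial positions.
make_phrased_melody <- function(seed, n_phrases = 5L, phrase_len = 12L) {
  set.seed(seed)
  pools <- split(48:83, rep_len(seq_len(n_phrases), 36))
  pitch <- integer(0)
  starts <- integer(0)
  for (ph in sample(seq_len(n_phrases))) {
    starts <- c(starts, length(pitch) + 1L)
    motif <- sample(pools[[ph]], 3L)
    pitch <- c(pitch, rep_len(motif, phrase_len))
  }
  list(melody = make_melody(pitch, id = paste0("phr", seed)),
       boundaries = sort(starts)[-1L])
}

# Minimal Standard MIDI File (format 0) from onsets/pitches, as raw bytes.
make_midi_bytes <- function(onset, pitch, division = 480L) {
  u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  vlq <- function(x) {
    out <- as.raw(x %% 128L)
    x <- x %/% 128L
    while (x > 0L) {
      out <- c(as.raw(128L + x %% 128L), out)
      x <- x %/% 128L
    }
    out
  }
  ticks <- onset * division / 24L
  ev <- raw(0)
  t_prev <- 0
  for (i in seq_along(ticks)) {
    ev <- c(ev, vlq(ticks[i] - t_prev), as.raw(c(0x90, pitch[i], 64)))
    t_prev <- ticks[i]
    ev <- c(ev, vlq(division %/% 2), as.raw(c(0x80, pitch[i], 0)))
    t_prev <- t_prev + division %/% 2
  }
  ev <- c(ev, vlq(0), as.raw(c(0xFF, 0x2F, 0x00)))
  c(charToRaw("MThd"), u32(6L), u16(0L), u16(1L), u16(division),
    charToRaw("MTrk"), u32(length(ev)), ev)
}
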