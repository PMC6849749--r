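#' Parse a monophonic melody from a symbolic music source
#'
#' Supported formats are a plain tabular dialect (CSV/TSV with a header
#' naming `onset` and `pitch` columns), single-spine `**kern`, EsAC, and
#' Standard MIDI Files (format 0 or 1; the first track containing notes is
#' used).  All onsets are expressed at 24 ticks per crotchet; tied notes
#' are merged into a single event and rests simply lengthen the following
#' inter-onset interval.  Grace notes, which have no independent metrical
#' onset, are dropped.
#'
#' @param source a file path, or (for text formats) the literal text of the
#'   source, or (for MIDI) a raw vector.
#' @param format one of `"tabular"`, `"kern"`, `"esac"`, `"midi"`.
#' @param id melody id; defaults to the file name without extension, or
#'   `"melody"` for literal text.
#' @param tonic,time_signature,culture optional metadata overriding
#'   anything found in the source.
#' @return A [melody()].
#' @examples
#' parse_melody("onset,pitch\n0,67\n24,71", format = "tabular")
#' @export
parse_melody <- function(source, format = c("tabular", "kern", "esac", "midi"),
                         id = NULL, tonic = NULL, time_signature = NULL,
                         culture = NULL) {
  format <- match.arg(format)
  if (is.null(id)) {
    id <- if (is.character(source) && length(source) == 1L &&
              !grepl("\n", source, fixed = TRUE) && file.exists(source))
      sub("\\.[^.]*$", "", basename(source)) else "melody"
  }
  m <- switch(format,
    tabular = parse_tabular(source, id),
    kern    = parse_kern(source, id),
    esac    = parse_esac(source, id),
    midi    = parse_midi(source, id))
  if (!is.null(tonic)) m$tonic <- as.integer(tonic)
  if (!is.null(time_signature)) m$time_signature <- time_signature
  if (!is.null(culture)) m$culture <- culture
  m
}

source_lines <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source))
    readLines(source, warn = FALSE)
  else unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
}

## ---- tabular ---------------------------------------------------------------

parse_tabular <- function(source, id) {
  lines <- source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("tabular source needs a header line and at least one event",
         call. = FALSE)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("onset", "pitch") %in% names(df)))
    stop("tabular header must name 'onset' and 'pitch' columns",
         call. = FALSE)
  melody(df$onset, df$pitch, id = id)
}

#' Write a melody in the tabular format
#'
#' The inverse of `parse_melody(format = "tabular")`: a CSV with the header
#' `onset,pitch`.
#'
#' @param melody a [melody()].
#' @param file path to write to, or `""` to return the text invisibly.
#' @return Invisibly, the lines written.
#' @export
write_melody_tabular <- function(melody, file = "") {
  stopifnot(inherits(melody, "melody"))
  lines <- c("onset,pitch",
             paste(melody$onset, melody$pitch, sep = ","))
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

## ---- **kern ----------------------------------------------------------------

kern_pitch <- function(token) {
  letters_part <- regmatches(token, regexpr("[a-gA-G]+", token))
  if (length(letters_part) == 0L) return(NA_integer_)
  ch <- strsplit(letters_part, "")[[1]]
  if (length(unique(tolower(ch))) != 1L) return(NA_integer_)
  pc_map <- c(c = 0L, d = 2L, e = 4L, f = 5L, g = 7L, a = 9L, b = 11L)
  pc <- pc_map[[tolower(ch[1L])]]
  k <- length(ch)
  octave <- if (ch[1L] %in% letters) 3L + k else 4L - k
  midi <- 12L * (octave + 1L) + pc
  midi <- midi + sum(strsplit(token, "")[[1]] == "#") -
    sum(strsplit(token, "")[[1]] == "-")
  as.integer(midi)
}

kern_duration <- function(token) {
  num <- regmatches(token, regexpr("[0-9]+", token))
  if (length(num) == 0L) return(NA_real_)
  r <- as.numeric(num)
  base <- if (r == 0) 192 else 96 / r
  dots <- sum(strsplit(token, "")[[1]] == ".")
  base * (2 - 0.5 ^ dots)
}

parse_kern <- function(source, id) {
  lines <- source_lines(source)
  time <- 0
  onset <- integer(0)
  pitch <- integer(0)
  tonic <- NULL
  timesig <- NULL
  seen_spine <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "!")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) > 1L)
      stop(sprintf("kern line %d: multiple spines (polyphony) not supported",
                   ln), call. = FALSE)
    tok <- fields[[1]]
    if (startsWith(tok, "*")) {
      if (tok == "**kern") seen_spine <- TRUE
      ts <- regmatches(tok, regexec("^\\*M([0-9]+/[0-9]+)$", tok))[[1]]
      if (length(ts) == 2L) timesig <- ts[2L]
      key <- regmatches(tok, regexec("^\\*([a-gA-G][#-]?):", tok))[[1]]
      if (length(key) == 2L) {
        kp <- kern_pitch(tolower(key[2L]))
        if (!is.na(kp)) tonic <- kp
      }
      next
    }
    if (startsWith(tok, "=")) next
    if (grepl("[qQ]", tok)) next               # grace note: no metrical onset
    dur <- kern_duration(tok)
    if (is.na(dur))
      stop(sprintf("kern line %d: token '%s' has no duration", ln, tok),
           call. = FALSE)
    if (grepl("r", tok, fixed = TRUE)) {       # rest: time passes, no event
      time <- time + dur
      next
    }
    p <- kern_pitch(tok)
    if (is.na(p))
      stop(sprintf("kern line %d: cannot read pitch from '%s'", ln, tok),
           call. = FALSE)
    tied_continuation <- grepl("[]_]", tok)
    if (!tied_continuation) {                  # tie continuations merge
      onset <- c(onset, round(time))
      pitch <- c(pitch, p)
    }
    time <- time + dur
  }
  if (!seen_spine && length(onset) == 0L)
    stop("no **kern spine or note tokens found", call. = FALSE)
  melody(onset, pitch, id = id, tonic = tonic, time_signature = timesig)
}

## ---- EsAC ------------------------------------------------------------------

esac_tonic_midi <- function(letter) {
  pc_map <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  base <- pc_map[[toupper(substr(letter, 1L, 1L))]]
  acc <- substr(letter, 2L, 2L)
  if (acc == "#") base <- base + 1L
  if (acc %in% c("b", "-")) base <- base - 1L
  60L + (base %% 12L)
}

parse_esac <- function(source, id) {
  txt <- paste(source_lines(source), collapse = "\n")
  key <- regmatches(txt, regexec(
    "KEY\\[\\s*(\\S+)\\s+([0-9]+)\\s+([A-Ga-g][#b]?)\\s*([0-9]+/[0-9]+)?[^]]*\\]",
    txt))[[1]]
  if (length(key) < 4L)
    stop("EsAC source has no parseable KEY[] field", call. = FALSE)
  unit <- as.numeric(key[3L])
  tonic <- esac_tonic_midi(key[4L])
  timesig <- if (length(key) >= 5L && nzchar(key[5L])) key[5L] else NULL
  mel <- regmatches(txt, regexec("MEL\\[([^]]*)\\]", txt))[[1]]
  if (length(mel) != 2L)
    stop("EsAC source has no MEL[] field", call. = FALSE)
  body <- sub("//.*$", "", mel[2L])
  major <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  base_dur <- 96 / unit
  chars <- strsplit(body, "")[[1]]
  time <- 0
  onset <- integer(0)
  pitch <- integer(0)
  i <- 1L
  oct_shift <- 0L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") { oct_shift <- oct_shift - 12L; i <- i + 1L; next }
    if (ch == "+") { oct_shift <- oct_shift + 12L; i <- i + 1L; next }
    if (grepl("[0-7]", ch)) {
      deg <- as.integer(ch)
      i <- i + 1L
      acc <- 0L
      while (i <= length(chars) && chars[i] %in% c("#", "b")) {
        acc <- acc + if (chars[i] == "#") 1L else -1L
        i <- i + 1L
      }
      dur <- base_dur
      while (i <= length(chars) && chars[i] %in% c("_", ".")) {
        if (chars[i] == "_") dur <- dur + base_dur else dur <- dur * 1.5
        i <- i + 1L
      }
      if (deg > 0L) {
        onset <- c(onset, round(time))
        pitch <- c(pitch, tonic + major[deg] + acc + oct_shift)
      }
      time <- time + dur
      oct_shift <- 0L
    } else {
      i <- i + 1L                              # whitespace, phrase marks, etc.
    }
  }
  if (length(onset) == 0L)
    stop("EsAC MEL[] field contains no notes", call. = FALSE)
  melody(onset, pitch, id = id, tonic = tonic, time_signature = timesig)
}

## ---- Standard MIDI File ----------------------------------------------------

midi_u32 <- function(b, i) sum(as.integer(b[i:(i + 3L)]) * 256 ^ (3:0))
midi_u16 <- function(b, i) sum(as.integer(b[i:(i + 1L)]) * c(256, 1))

midi_vlq <- function(b, i) {
  val <- 0
  repeat {
    byte <- as.integer(b[i])
    val <- val * 128 + (byte %% 128L)
    i <- i + 1L
    if (byte < 128L) break
  }
  list(value = val, i = i)
}

parse_midi_track <- function(b, i, end) {
  tick <- 0
  status <- NA_integer_
  onset <- numeric(0)
  pitch <- integer(0)
  while (i <= end) {
    v <- midi_vlq(b, i); tick <- tick + v$value; i <- v$i
    byte <- as.integer(b[i])
    if (byte >= 128L) { status <- byte; i <- i + 1L }
    else if (is.na(status))
      stop(sprintf("malformed MIDI track: data byte %d with no running status",
                   i), call. = FALSE)
    hi <- status %/% 16L
    if (status == 255L) {                      # meta event
      i <- i + 1L                              # type
      v <- midi_vlq(b, i); i <- v$i + v$value
    } else if (status %in% c(240L, 247L)) {    # sysex
      v <- midi_vlq(b, i); i <- v$i + v$value
    } else if (hi %in% c(12L, 13L)) {          # program change / ch pressure
      i <- i + 1L
    } else {
      d1 <- as.integer(b[i]); d2 <- as.integer(b[i + 1L]); i <- i + 2L
      if (hi == 9L && d2 > 0L) {               # note on
        if (length(onset) && onset[length(onset)] == tick)
          stop("polyphonic MIDI content (simultaneous note-ons) not supported",
               call. = FALSE)
        onset <- c(onset, tick)
        pitch <- c(pitch, d1)
      }
    }
  }
  list(onset = onset, pitch = pitch)
}

parse_midi <- function(source, id) {
  b <- if (is.raw(source)) source
       else readBin(source, "raw", n = file.info(source)$size)
  if (length(b) < 14L || rawToChar(b[1:4]) != "MThd")
    stop("not a Standard MIDI File (missing MThd header)", call. = FALSE)
  division <- midi_u16(b, 13L)
  if (division >= 32768L)
    stop("SMPTE time division not supported", call. = FALSE)
  ntrks <- midi_u16(b, 11L)
  i <- 9L + midi_u32(b, 5L)
  for (tr in seq_len(ntrks)) {
    if (rawToChar(b[i:(i + 3L)]) != "MTrk")
      stop(sprintf("malformed MIDI file at byte %d: expected MTrk", i),
           call. = FALSE)
    len <- midi_u32(b, i + 4L)
    track <- parse_midi_track(b, i + 8L, i + 7L + len)
    if (length(track$onset) > 0L) {
      onset <- round(track$onset * 24 / division)
      return(melody(onset, track$pitch, id = id))
    }
    i <- i + 8L + len
  }
  stop("no MIDI track contains note events", call. = FALSE)
}

## ---- corpus I/O ------------------------------------------------------------

#' Read a corpus from a directory with a JSON-lines manifest
#'
#' The manifest (`manifest.jsonl` by default) holds one JSON object per
#' line with fields `id`, `file`, `format` (default `"tabular"`) and
#' optional `tonic`, `time_signature`, `culture`.
#'
#' @param dir directory containing the manifest and melody files.
#' @param manifest manifest file name within `dir`.
#' @param name corpus name; defaults to the directory name.
#' @return A [corpus()].
#' @export
read_corpus <- function(dir, manifest = "manifest.jsonl", name = basename(dir)) {
  path <- file.path(dir, manifest)
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mels <- lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line)
    parse_melody(file.path(dir, rec$file),
                 format = if (is.null(rec$format)) "tabular" else rec$format,
                 id = rec$id, tonic = rec$tonic,
                 time_signature = rec$time_signature, culture = rec$culture)
  })
  corpus(mels, name = name)
}

#' Write a corpus as tabular files plus a JSON-lines manifest
#'
#' @param corpus a [corpus()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- vapply(corpus$melodies, function(m) {
    file <- paste0(m$id, ".csv")
    write_melody_tabular(m, file.path(dir, file))
    rec <- list(id = m$id, file = file, format = "tabular")
    if (!is.null(m$tonic)) rec$tonic <- m$tonic
    if (!is.null(m$time_signature)) rec$time_signature <- m$time_signature
    if (!is.null(m$culture)) rec$culture <- m$culture
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  path <- file.path(dir, "manifest.jsonl")
  writeLines(recs, path)
  invisible(path)
}
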