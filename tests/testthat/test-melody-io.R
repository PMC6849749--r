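test_that("tabular parsing transcribes events directly and round-trips", {
  m <- parse_melody("onset,pitch\n0,67\n24,71", format = "tabular")
  expect_equal(m$onset, c(0L, 24L))
  expect_equal(m$pitch, c(67L, 71L))

  one <- parse_melody("onset,pitch\n0,60", format = "tabular")
  expect_equal(length(one), 1L)

  orig <- make_melody(c(60L, 62L, 64L, 65L), ioi = c(24L, 12L, 48L),
                      id = "rt", tonic = NULL)
  txt <- paste(write_melody_tabular(orig), collapse = "\n")
  back <- parse_melody(txt, format = "tabular", id = "rt")
  expect_equal(back$onset, orig$onset)
  expect_equal(back$pitch, orig$pitch)
  expect_equal(back$id, orig$id)
})

test_that("melody constructor enforces its invariants", {
  expect_error(melody(integer(0), integer(0)), "at least one")
  expect_error(melody(c(0, 0), c(60, 62)), "strictly increasing")
  expect_error(melody(0, 200), "\\[0, 127\\]")
})

test_that("kern parsing merges ties, skips rests and grace notes", {
  # two tied quarter-note Gs then a quarter A: tie yields one event
  src <- c("**kern", "*G:", "*M4/4", "[4g", "4g]", "4a", "*-")
  m <- parse_melody(paste(src, collapse = "\n"), format = "kern")
  expect_equal(m$onset, c(0L, 48L))
  expect_equal(m$pitch, c(67L, 69L))
  expect_equal(m$tonic, 67L)
  expect_equal(m$time_signature, "4/4")

  # rests lengthen the inter-onset interval without creating events
  src <- c("**kern", "4c", "4r", "4d")
  m <- parse_melody(paste(src, collapse = "\n"), format = "kern")
  expect_equal(m$onset, c(0L, 48L))
  expect_equal(m$pitch, c(60L, 62L))

  # grace notes are dropped; octaves and accidentals resolve
  src <- c("**kern", "8cc#", "gq", "4C", "2.e-")
  m <- parse_melody(paste(src, collapse = "\n"), format = "kern")
  expect_equal(m$pitch, c(73L, 48L, 63L))
  expect_equal(m$onset, c(0L, 12L, 36L))

  expect_error(parse_melody("**kern\t**kern\n4c\t4e", format = "kern"),
               "polyphony")
})

test_that("EsAC parsing resolves scale degrees, octaves and durations", {
  src <- paste0("CUT[test song]\n",
                "KEY[T0001 8 G 3/4]\n",
                "MEL[1 2 3_ -5 0 1. //]\n")
  m <- parse_melody(src, format = "esac")
  # tonic G: degrees 1,2,3 -> G,A,B; -5 one octave below the 5th
  expect_equal(m$pitch, c(67L, 69L, 71L, 62L, 67L))
  # eighth-note unit = 12 ticks; "3_" lasts 24; rest "0" lasts 12
  expect_equal(m$onset, c(0L, 12L, 24L, 48L, 72L))
  expect_equal(m$tonic, 67L)
  expect_equal(m$time_signature, "3/4")
})

test_that("MIDI parsing reads note-ons and rescales the division", {
  bytes <- make_midi_bytes(c(0L, 24L, 60L), c(60L, 64L, 67L))
  path <- withr::local_tempfile(fileext = ".mid")
  writeBin(bytes, path)
  m <- parse_melody(path, format = "midi")
  expect_equal(m$onset, c(0L, 24L, 60L))
  expect_equal(m$pitch, c(60L, 64L, 67L))
  expect_error(parse_melody(as.raw(1:20), format = "midi"), "MThd")
})

test_that("corpus writer and reader round-trip melodies with metadata", {
  corp <- corpus(list(
    make_melody(c(60L, 64L, 67L), id = "x", tonic = 60L, culture = "A",
                time_signature = "4/4"),
    make_melody(c(62L, 65L), id = "y", tonic = 62L)), name = "demo")
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir, name = "demo")
  expect_equal(length(back), 2L)
  expect_equal(back[["x"]]$pitch, corp[["x"]]$pitch)
  expect_equal(back[["x"]]$culture, "A")
  expect_equal(back[["x"]]$time_signature, "4/4")
  expect_equal(back[["y"]]$tonic, 62L)
})

test_that("duplicate removal compares interval openings, ignoring rhythm", {
  a <- make_melody(c(60L, 64L, 67L, 65L), ioi = c(24L, 24L, 24L), id = "a")
  b <- make_melody(c(60L, 64L, 67L, 65L), ioi = c(12L, 48L, 6L), id = "b")
  c2 <- make_melody(c(62L, 66L, 69L, 67L), id = "c")   # a transposed +2
  d <- make_melody(c(60L, 65L, 67L, 65L), id = "d")    # differs at interval 1
  corp <- corpus(list(a, b, c2, d))

  out <- deduplicate_corpus(corp, opening_length = 3L)
  expect_equal(names(out$melodies), c("a", "d"))

  # idempotent, and the first occurrence always survives
  again <- deduplicate_corpus(out, opening_length = 3L)
  expect_equal(names(again$melodies), names(out$melodies))

  # melodies differing within the opening are both retained
  out2 <- deduplicate_corpus(corpus(list(a, d)), opening_length = 10L)
  expect_equal(length(out2), 2L)

  expect_error(deduplicate_corpus(corp, opening_length = 0L), "positive")
  expect_error(deduplicate_corpus(corpus(list(melody(0, 60, id = "solo"), a))),
               ">= 2 events")
})
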