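test_that("training counts every (context, continuation) pair up to the bound", {
  m <- ppm_model(order_bound = 1L)
  ppm_train(m, c("a", "b", "a"))
  counts <- function(ctx) get(melopredict:::ctx_key(ctx), envir = m$counts)
  expect_equal(counts(character(0)), c(a = 2, b = 1))
  expect_equal(counts("a"), c(b = 1))
  expect_equal(counts("b"), c(a = 1))

  # training twice doubles every count
  ppm_train(m, c("a", "b", "a"))
  expect_equal(counts(character(0)), c(a = 4, b = 2))
  expect_equal(counts("a"), c(b = 2))
})

test_that("undefined positions are neither contexts nor predictands", {
  m <- ppm_model(order_bound = 2L)
  ppm_train(m, c(NA, "4", "3"))
  counts <- function(ctx) get(melopredict:::ctx_key(ctx), envir = m$counts)
  expect_equal(counts(character(0)), c(`4` = 1, `3` = 1))
  expect_equal(counts("4"), c(`3` = 1))
  expect_false(exists(melopredict:::ctx_key("NA"), envir = m$counts))
  expect_equal(sort(m$alphabet), c("3", "4"))
})

test_that("an untrained model predicts the uniform floor", {
  m <- ppm_model(alphabet = c("a", "b", "c", "d"))
  p <- predict(m, context = c("a", "b"))
  expect_equal(unname(p), rep(0.25, 4))
})

test_that("prediction matches the brute-force interpolated-escape oracle", {
  set.seed(11)
  alphabet <- c("a", "b", "c", "d")
  for (trial in 1:30) {
    ab_size <- sample(2:4, 1)
    ab <- alphabet[seq_len(ab_size)]
    n_seq <- sample(1:3, 1)
    seqs <- lapply(seq_len(n_seq), function(i)
      sample(ab, sample(5:15, 1), replace = TRUE))
    bound <- sample(c(1L, 2L, 3L, Inf), 1)
    m <- ppm_model(alphabet = ab, order_bound = bound)
    ppm_train(m, seqs)
    for (len in 0:3) {
      ctx <- if (len == 0) character(0) else sample(ab, len, replace = TRUE)
      got <- predict(m, context = ctx)
      want <- oracle_ppm(seqs, ctx, alphabet = ab, order_bound = bound)
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-12)
    }
  }
})

test_that("unseen context extensions back off to the longest stored suffix", {
  m <- ppm_model(order_bound = Inf)
  ppm_train(m, c("a", "b", "a", "b", "a"))
  with_x <- predict(m, context = c("x", "b"), alphabet = "x")
  plain <- predict(m, context = c("b"), alphabet = "x")
  expect_equal(with_x, plain)
})

test_that("every prediction is a full-support distribution", {
  set.seed(23)
  for (trial in 1:20) {
    ab <- as.character(seq_len(sample(2:8, 1)))
    m <- ppm_model(alphabet = ab, order_bound = sample(c(2L, Inf), 1))
    ppm_train(m, lapply(1:2, function(i)
      sample(ab, sample(3:20, 1), replace = TRUE)))
    ctx <- sample(ab, sample(0:4, 1), replace = TRUE)
    p <- predict(m, context = ctx)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
  }
})

test_that("observing (context, symbol) strictly raises its predicted probability", {
  set.seed(31)
  ab <- c("a", "b", "c")
  m <- ppm_model(alphabet = ab, order_bound = Inf, mode = "online")
  ppm_train(m, sample(ab, 12, replace = TRUE))
  for (trial in 1:10) {
    ctx <- sample(ab, sample(0:2, 1), replace = TRUE)
    sym <- sample(ab, 1)
    before <- predict(m, context = ctx)[[sym]]
    ppm_observe(m, sym, context = ctx)
    after <- predict(m, context = ctx)[[sym]]
    expect_gt(after, before)
  }
})

test_that("online processing of a sequence reproduces batch counts", {
  s <- c("a", "b", "b", "a", "c", "a", "b")
  online <- ppm_model(order_bound = 2L, mode = "online")
  for (i in seq_along(s)) {
    predict(online, context = s[seq_len(i - 1L)], alphabet = unique(s))
    ppm_observe(online, s[i], context = s[seq_len(i - 1L)])
  }
  batch <- ppm_model(order_bound = 2L)
  ppm_train(batch, s)
  keys <- ls(batch$counts, all.names = TRUE)
  expect_setequal(keys, ls(online$counts, all.names = TRUE))
  for (k in keys) {
    a <- get(k, envir = batch$counts)
    b <- get(k, envir = online$counts)
    expect_equal(a[order(names(a))], b[order(names(b))])
  }
})

test_that("short-term models reset to empty between pieces", {
  m <- ppm_model(mode = "online")
  ppm_observe(m, "a")
  ppm_observe(m, "b", context = "a")
  ppm_reset(m)
  expect_equal(length(ls(m$counts, all.names = TRUE)), 0L)
  expect_error(ppm_observe(ppm_model(mode = "static"), "a"), "online")
})

test_that("serialization round-trips counts, alphabet and configuration", {
  m <- ppm_model(order_bound = 2L)
  ppm_train(m, list(c("4,0", "2,2", "-2,0"), c("4,0", "4,4")))
  path <- withr::local_tempfile(fileext = ".json")
  ppm_save(m, path)
  back <- ppm_load(path)
  expect_equal(sort(back$alphabet), sort(m$alphabet))
  expect_equal(back$order_bound, m$order_bound)
  ctx <- c("4,0")
  expect_equal(predict(back, ctx), predict(m, ctx))

  unbounded <- ppm_model(order_bound = Inf, mode = "online")
  ppm_observe(unbounded, "x")
  back2 <- ppm_load(ppm_save(unbounded))
  expect_equal(back2$order_bound, Inf)
  expect_equal(back2$mode, "online")
})
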