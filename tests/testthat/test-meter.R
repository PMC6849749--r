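# Two synthetic meter categories with distinct accent profiles: a waltz-like
# 3/4 (strong downbeat, light afterbeats) and a 4/4 with a strong mid-bar
# accent.  The crotchet grid keeps the hypothesis space small.
meter_fixture <- function(n_train = 40L, seed = 1L) {
  c34 <- generate_metrical_rhythms("3/4", c(1.0, 0.8, 0.35), n_train,
                                   bars = 8L, seed = seed)
  c44 <- generate_metrical_rhythms("4/4", c(1.0, 0.25, 0.9, 0.3), n_train,
                                   bars = 8L, seed = seed + 1L)
  corpus(c(c34$melodies, c44$melodies), name = "meter-train")
}

test_that("the meter prior is the relative category frequency", {
  mels <- c(lapply(1:3, function(i)
    make_melody(c(60L, 62L, 64L), id = paste0("a", i),
                time_signature = "4/4")),
    list(make_melody(c(60L, 62L, 64L), id = "b1", time_signature = "3/4")))
  pr <- meter_prior(corpus(mels))
  expect_equal(pr[["4/4"]], 0.75)
  expect_equal(pr[["3/4"]], 0.25)

  solo <- meter_prior(corpus(mels[4]))
  expect_equal(unname(solo), 1)

  no_ts <- corpus(list(make_melody(c(60L, 62L), id = "x")))
  expect_error(meter_prior(no_ts), "x")
  expect_equal(meter_period("3/4"), 72L)
  expect_equal(meter_period("6/8"), 72L)
  expect_equal(meter_period("4/4"), 96L)
})

test_that("likelihood models prefer the trained periodic pattern", {
  iso <- generate_metrical_rhythms("4/4", c(1, 1, 1, 1), 10L, bars = 4L,
                                   seed = 3L)
  lik <- meter_likelihood(iso)
  # strictly isochronous training: at every bar position, ioi 24 beats
  # any other ioi
  positions <- c(0L, 24L, 48L, 72L)
  pd <- predict(lik$models[["4/4"]], context = character(0),
                alphabet = paste0("48@", positions))
  for (p in positions)
    expect_gt(pd[[paste0("24@", p)]], pd[[paste0("48@", p)]])
})

test_that("posteriors normalize, fix the prior on equal likelihoods, and
           concentrate on the generating meter", {
  train <- meter_fixture()
  prior <- meter_prior(train)
  lik <- meter_likelihood(train)
  rhythm <- generate_metrical_rhythms("3/4", c(1.0, 0.8, 0.35), 1L,
                                      bars = 8L, seed = 77L)[[1L]]
  post <- infer_meter(rhythm, prior, lik)
  expect_equal(unname(rowSums(post$posterior)),
               rep(1, nrow(post$posterior)), tolerance = 1e-9)

  # single hypothesis: posterior is identically 1
  solo_prior <- stats::setNames(1, "3/4")
  solo <- infer_meter(rhythm, solo_prior, lik)
  cat34 <- solo$hypotheses$category == "3/4"
  expect_equal(unname(rowSums(solo$posterior[, cat34, drop = FALSE])),
               rep(1, nrow(solo$posterior)), tolerance = 1e-9)

  # identical likelihoods across categories leave the posterior at the prior
  iso <- corpus(c(
    generate_metrical_rhythms("2/4", c(1, 1), 10L, bars = 4L,
                              seed = 5L)$melodies,
    lapply(generate_metrical_rhythms("4/4", c(1, 1, 1, 1), 10L, bars = 4L,
                                     seed = 6L)$melodies,
           function(m) { m$id <- paste0(m$id, "b"); m })),
    name = "iso")
  iso_prior <- meter_prior(iso)
  iso_lik <- meter_likelihood(iso, order = 0L)
  iso_rhythm <- generate_metrical_rhythms("4/4", c(1, 1, 1, 1), 1L,
                                          bars = 4L, seed = 7L)[[1L]]
  iso_post <- infer_meter(iso_rhythm, iso_prior, iso_lik)
  final <- iso_post$posterior[nrow(iso_post$posterior), ]
  by_cat <- tapply(final, iso_post$hypotheses$category, sum)
  expect_equal(as.numeric(by_cat[names(iso_prior)]), unname(iso_prior),
               tolerance = 1e-9)

  # well-separated categories: mass on the true meter grows past 0.9
  mass_true <- rowSums(post$posterior[, post$hypotheses$category == "3/4",
                                      drop = FALSE])
  expect_gt(mass_true[min(10L, length(mass_true))], 0.9)
})

test_that("posterior-mixture ioi predictions are proper distributions", {
  train <- meter_fixture(20L)
  prior <- meter_prior(train)
  lik <- meter_likelihood(train)
  rhythm <- generate_metrical_rhythms("4/4", c(1.0, 0.25, 0.9, 0.3), 1L,
                                      bars = 4L, seed = 42L)[[1L]]
  post <- infer_meter(rhythm, prior, lik)
  nxt <- predict_next_ioi(rhythm, post, lik)
  expect_equal(sum(nxt), 1, tolerance = 1e-9)
  expect_true(all(nxt >= 0))
})

test_that("meter classification recovers the generating category", {
  train <- meter_fixture()
  prior <- meter_prior(train)
  lik <- meter_likelihood(train)
  test34 <- generate_metrical_rhythms("3/4", c(1.0, 0.8, 0.35), 25L,
                                      bars = 8L, seed = 101L)
  test44 <- generate_metrical_rhythms("4/4", c(1.0, 0.25, 0.9, 0.3), 25L,
                                      bars = 8L, seed = 102L)
  pred <- c(vapply(test34$melodies, classify_meter, "", prior, lik),
            vapply(test44$melodies, classify_meter, "", prior, lik))
  truth <- rep(c("3/4", "4/4"), each = 25L)
  expect_gte(mean(pred == truth), 0.9)
})

test_that("metrical inference reduces temporal prediction error", {
  train <- meter_fixture()
  prior <- meter_prior(train)
  lik <- meter_likelihood(train)
  base <- train_ioi_model(train)
  test_set <- c(
    generate_metrical_rhythms("3/4", c(1.0, 0.8, 0.35), 10L, bars = 8L,
                              seed = 201L)$melodies,
    generate_metrical_rhythms("4/4", c(1.0, 0.25, 0.9, 0.3), 10L, bars = 8L,
                              seed = 202L)$melodies)
  with_meter <- mean(unlist(lapply(test_set, function(m)
    infer_meter(m, prior, lik)$ic)), na.rm = TRUE)
  without <- mean(unlist(lapply(test_set, function(m)
    meterfree_ic(m, base, candidates = infer_meter(m, prior,
                                                   lik)$ioi_alphabet))),
    na.rm = TRUE)
  expect_lte(with_meter, without)
})
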