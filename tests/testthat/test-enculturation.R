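enc_cfg <- prediction_config(subsystems = "ltm")

test_that("cultural distance and complexity are the 45-degree rotation", {
  cd <- cultural_distance(2.44, 6.53)
  expect_equal(cd$distance, (6.53 - 2.44) / sqrt(2))
  expect_equal(round(cd$distance, 2), 2.89)
  expect_equal(cd$complexity, (2.44 + 6.53) / sqrt(2))

  cd2 <- cultural_distance(2.36, 4.77)
  expect_equal(round(cd2$distance, 2), 1.70)

  # on the line of equality the distance vanishes
  expect_equal(cultural_distance(3.3, 3.3)$distance, 0)
  expect_error(cultural_distance(Inf, 1), "finite")
})

test_that("the rotation is an isometry", {
  set.seed(13)
  own <- stats::runif(300, 0, 12)
  other <- stats::runif(300, 0, 12)
  cd <- cultural_distance(own, other)
  expect_equal(cd$distance^2 + cd$complexity^2, own^2 + other^2,
               tolerance = 1e-6)
})

test_that("two-fold cross-validation trains each melody's model on the other fold", {
  a <- make_melody(rep(c(60L, 64L, 67L), 4), id = "a")
  b <- make_melody(rep(c(60L, 62L, 64L), 4), id = "b")
  res <- within_culture_ic(corpus(list(a, b)), enc_cfg, folds = 2L,
                           seed = 1L)
  expect_setequal(res$fold, c(1L, 2L))
  # oracle: melody a scored under an LTM trained only on b
  cfg <- enc_cfg
  ab <- melopredict:::resolve_alphabets(corpus(list(a, b)), cfg)
  cfg$pitch_alphabet <- ab$pitch
  cfg$ioi_alphabet <- ab$ioi
  ltm_b <- train_ltm(corpus(list(b)), cfg)
  want <- mean_ic(ic_profile(a, ltm = ltm_b))$joint
  expect_equal(res$ic_joint[res$id == "a"], want, tolerance = 1e-12)
  expect_error(within_culture_ic(corpus(list(a, b)), enc_cfg, folds = 3L),
               "exceeds")
})

test_that("identical melodies across folds approach the predictability floor", {
  mels <- lapply(1:6, function(i)
    make_melody(rep(c(60L, 64L, 67L, 64L), 5), id = paste0("m", i)))
  res <- within_culture_ic(corpus(mels), enc_cfg, folds = 3L, seed = 2L)
  expect_lt(mean(res$ic_joint), 1)
})

test_that("between-culture IC is higher under the foreign model", {
  specs <- default_culture_specs()
  corp_a <- generate_culture(specs$A, 30L, seed = 501L)
  corp_b <- generate_culture(specs$B, 30L, seed = 502L)
  cfg <- enc_cfg
  both <- corpus(c(corp_a$melodies, corp_b$melodies), name = "u")
  ab <- melopredict:::resolve_alphabets(both, cfg)
  cfg$pitch_alphabet <- ab$pitch
  cfg$ioi_alphabet <- ab$ioi
  ltm_a <- train_ltm(corp_a, cfg)
  ltm_b <- train_ltm(corp_b, cfg)
  own <- between_culture_ic(ltm_a, corp_a)    # no CV: optimistic floor
  foreign <- between_culture_ic(ltm_b, corp_a)
  expect_gt(mean(foreign$ic_joint), mean(own$ic_joint))
  expect_equal(nrow(between_culture_ic(ltm_a, corp_a[1])), 1L)
})

test_that("pieces are classified to the culture that compresses them", {
  specs <- default_culture_specs()
  corp_a <- generate_culture(specs$A, 30L, seed = 601L)
  corp_b <- generate_culture(specs$B, 30L, seed = 602L)
  test_a <- generate_culture(specs$A, 20L, seed = 603L)
  test_b <- generate_culture(specs$B, 20L, seed = 604L)
  cfg <- enc_cfg
  all4 <- corpus(c(corp_a$melodies, corp_b$melodies,
                   lapply(test_a$melodies, function(m) {
                     m$id <- paste0("t", m$id); m }),
                   lapply(test_b$melodies, function(m) {
                     m$id <- paste0("t", m$id); m })), name = "u")
  ab <- melopredict:::resolve_alphabets(all4, cfg)
  cfg$pitch_alphabet <- ab$pitch
  cfg$ioi_alphabet <- ab$ioi
  ltm_a <- train_ltm(corp_a, cfg)
  ltm_b <- train_ltm(corp_b, cfg)
  pred <- c(vapply(test_a$melodies, classify_piece, "", ltm_a, ltm_b),
            vapply(test_b$melodies, classify_piece, "", ltm_a, ltm_b))
  truth <- rep(c("A", "B"), c(20L, 20L))
  expect_gte(mean(pred == truth), 0.95)
})

test_that("same-generator corpora are indistinguishable: accuracy near chance, distance near zero", {
  specs <- default_culture_specs()
  base <- generate_culture(specs$A, 24L, seed = 701L)
  twin <- generate_culture(specs$A, 24L, seed = 702L)
  twin <- corpus(lapply(twin$melodies, function(m) {
    m$id <- paste0("c", m$id); m$culture <- "A2"; m
  }), name = "A2")
  summ <- corpus_summary(base, twin, enc_cfg, folds = 4L, seed = 3L)
  joint <- summ$table[summ$table$attribute == "joint", ]
  expect_lt(abs(joint$accuracy - 50), 25)
  expect_lt(abs(joint$mean_distance), 0.25)
})
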