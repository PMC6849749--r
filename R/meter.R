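## Empirical-Bayes metrical inference.  The metrical interpretation of a
## rhythm is a hidden variable consisting of a meter category (time
## signature, i.e. bar period in ticks) and a phase aligning the bar grid
## to the rhythm.  A prior over categories is estimated from corpus
## annotations; the likelihood of each onset given an interpretation comes
## from a PPM model over (ioi, position-within-bar) symbols, so both prior
## and likelihood are conditional on the preceding rhythmic context.

#' Bar period in ticks of a time-signature label
#'
#' At 24 ticks per crotchet, `"4/4"` spans 96 ticks and `"3/4"` 72.
#'
#' @param label a time-signature string such as `"3/4"` or `"6/8"`.
#' @return Integer bar period in ticks.
#' @export
meter_period <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
    stop("cannot parse time signature '", label, "'", call. = FALSE)
  num <- as.integer(parts[1L]); den <- as.integer(parts[2L])
  as.integer(num * 96L / den)
}

#' Empirical prior over meter categories
#'
#' Relative frequency of each annotated time signature in a corpus.  The
#' phase prior is uniform within each category and applied at inference
#' time.
#'
#' @param corpus a [corpus()]; every melody must carry a
#'   `time_signature`.
#' @return Named numeric vector of category probabilities.
#' @export
meter_prior <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  ts <- vapply(corpus$melodies, function(m)
    if (is.null(m$time_signature)) NA_character_ else m$time_signature,
    character(1))
  if (anyNA(ts))
    stop("melodies without time-signature annotation: ",
         paste(corpus_ids(corpus)[is.na(ts)], collapse = ", "),
         call. = FALSE)
  tab <- table(ts)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

meter_symbol <- function(ioi, pos) paste0(ioi, "@", pos)

## (ioi, bar position) symbol sequence of a melody under a period/phase;
## events 2..N (the first event has no ioi)
rhythm_symbols <- function(melody, period, phase = 0L) {
  n <- length(melody$onset)
  if (n < 2L) return(character(0))
  ioi <- diff(melody$onset)
  pos <- (melody$onset[-1L] + phase) %% period
  meter_symbol(ioi, pos)
}

#' Train per-category rhythm likelihood models
#'
#' For each meter category present in the corpus, fits a PPM model over
#' the sequence of (inter-onset interval, metrical position) symbols,
#' where the metrical position is the onset modulo the bar period under
#' the annotated alignment (melodies are assumed notated from the start of
#' a bar).
#'
#' @param corpus a [corpus()] with time-signature annotations.
#' @param order order bound of the likelihood models (default 2).
#' @return An object of class `"meter_likelihood"`: per-category models,
#'   bar periods, the ioi alphabet seen in training, and the phase grid
#'   (the smallest observed ioi).
#' @export
meter_likelihood <- function(corpus, order = 2L) {
  stopifnot(inherits(corpus, "corpus"))
  ts <- vapply(corpus$melodies, function(m)
    if (is.null(m$time_signature)) NA_character_ else m$time_signature,
    character(1))
  if (anyNA(ts))
    stop("melodies without time-signature annotation: ",
         paste(corpus_ids(corpus)[is.na(ts)], collapse = ", "),
         call. = FALSE)
  cats <- sort(unique(ts))
  iois <- sort(unique(unlist(lapply(corpus$melodies,
                                    function(m) diff(m$onset)))))
  models <- lapply(cats, function(cat) {
    period <- meter_period(cat)
    m <- ppm_model(order_bound = order, mode = "static")
    seqs <- lapply(corpus$melodies[ts == cat], rhythm_symbols,
                   period = period)
    ppm_train(m, seqs)
    m
  })
  names(models) <- cats
  structure(list(models = models,
                 periods = stats::setNames(vapply(cats, meter_period,
                                                  integer(1)), cats),
                 ioi_alphabet = as.integer(iois),
                 grid = as.integer(min(iois))),
            class = "meter_likelihood")
}

meter_hypotheses <- function(prior, likelihoods) {
  cats <- names(prior)
  hyps <- do.call(rbind, lapply(cats, function(cat) {
    period <- likelihoods$periods[[cat]]
    phases <- seq(0L, period - likelihoods$grid, by = likelihoods$grid)
    data.frame(category = cat, period = period, phase = phases,
               stringsAsFactors = FALSE)
  }))
  hyps$log_prior <- log(prior[hyps$category]) -
    log(ave(hyps$phase, hyps$category, FUN = length))
  hyps
}

## Per-hypothesis conditional distribution over candidate iois at event i.
hyp_ioi_dist <- function(model, ctx, onset_prev, phase, period, cand_ioi) {
  pos <- (onset_prev + cand_ioi + phase) %% period
  syms <- meter_symbol(cand_ioi, pos)
  pd <- predict(model, context = ctx, alphabet = unique(syms))
  p <- unname(pd[syms])
  p / sum(p)
}

#' Event-by-event posterior over metrical interpretations
#'
#' Combines the category prior (uniform over phases within category) with
#' the context-conditional likelihood of each observed onset under each
#' interpretation, renormalizing after every event.  Accumulation is in
#' the log domain.  Also returns the predictive probability of each
#' realized inter-onset interval under the posterior-weighted mixture
#' (using the posterior *before* the event), whose negative log is the
#' information content of temporal prediction with metrical inference.
#'
#' @param melody a [melody()] (only onsets are used).
#' @param prior a [meter_prior()].
#' @param likelihoods a [meter_likelihood()].
#' @return An object of class `"meter_posterior"`: a list with
#'   `hypotheses` (data frame of category / period / phase), `posterior`
#'   (matrix, events x hypotheses, each row summing to 1), `ic` (bits per
#'   event, events 2..N), and the candidate ioi alphabet used.
#' @export
infer_meter <- function(melody, prior, likelihoods) {
  stopifnot(inherits(melody, "melody"),
            inherits(likelihoods, "meter_likelihood"))
  if (!all(names(prior) %in% names(likelihoods$models)))
    stop("prior contains categories with no trained likelihood model",
         call. = FALSE)
  hyps <- meter_hypotheses(prior, likelihoods)
  n_h <- nrow(hyps)
  n_ev <- length(melody$onset)
  ioi <- diff(melody$onset)
  cand <- sort(union(likelihoods$ioi_alphabet, ioi))
  loglik <- hyps$log_prior
  posterior <- matrix(NA_real_, nrow = n_ev, ncol = n_h)
  norm_row <- function(lp) { p <- exp(lp - max(lp)); p / sum(p) }
  posterior[1L, ] <- norm_row(loglik)
  ctxs <- rep(list(character(0)), n_h)
  ic <- rep(NA_real_, n_ev)
  for (i in 2:n_ev) {
    prev_post <- posterior[i - 1L, ]
    p_real <- numeric(n_h)
    for (h in seq_len(n_h)) {
      model <- likelihoods$models[[hyps$category[h]]]
      pd <- hyp_ioi_dist(model, ctxs[[h]], melody$onset[i - 1L],
                         hyps$phase[h], hyps$period[h], cand)
      p_h <- pd[match(ioi[i - 1L], cand)]
      p_h <- max(p_h, 1e-12)
      p_real[h] <- p_h
      loglik[h] <- loglik[h] + log(p_h)
      ctxs[[h]] <- c(ctxs[[h]],
                     meter_symbol(ioi[i - 1L],
                                  (melody$onset[i] + hyps$phase[h]) %%
                                    hyps$period[h]))
    }
    ic[i] <- -log2(sum(prev_post * p_real))
    posterior[i, ] <- norm_row(loglik)
  }
  structure(list(hypotheses = hyps, posterior = posterior, ic = ic,
                 ioi_alphabet = cand),
            class = "meter_posterior")
}

#' @export
print.meter_posterior <- function(x, ...) {
  final <- x$posterior[nrow(x$posterior), ]
  best <- which.max(final)
  cat(sprintf("Meter posterior over %d hypotheses; MAP: %s (phase %d) p = %.3f\n",
              nrow(x$hypotheses), x$hypotheses$category[best],
              x$hypotheses$phase[best], final[best]))
  invisible(x)
}

#' Predictive distribution over the next inter-onset interval
#'
#' The posterior-weighted mixture of each interpretation's
#' context-conditional ioi distribution, after the last observed event.
#'
#' @param melody the [melody()] processed so far.
#' @param posterior an [infer_meter()] result for `melody`.
#' @param likelihoods the [meter_likelihood()] used for inference.
#' @return Named numeric vector over candidate iois, summing to 1.
#' @export
predict_next_ioi <- function(melody, posterior, likelihoods) {
  stopifnot(inherits(posterior, "meter_posterior"))
  hyps <- posterior$hypotheses
  cand <- posterior$ioi_alphabet
  final <- posterior$posterior[nrow(posterior$posterior), ]
  mix <- numeric(length(cand))
  for (h in seq_len(nrow(hyps))) {
    model <- likelihoods$models[[hyps$category[h]]]
    ctx <- rhythm_symbols(melody, hyps$period[h], hyps$phase[h])
    pd <- hyp_ioi_dist(model, ctx, melody$onset[length(melody$onset)],
                       hyps$phase[h], hyps$period[h], cand)
    mix <- mix + final[h] * pd
  }
  stats::setNames(mix / sum(mix), as.character(cand))
}

#' Classify the meter of a rhythm
#'
#' Returns the category with maximal posterior mass (summed over phases)
#' at the final event; ties are broken by prior probability, then label
#' order.
#'
#' @inheritParams infer_meter
#' @return The winning category label.
#' @export
classify_meter <- function(melody, prior, likelihoods) {
  post <- infer_meter(melody, prior, likelihoods)
  final <- post$posterior[nrow(post$posterior), ]
  mass <- tapply(final, post$hypotheses$category, sum)
  cats <- names(mass)
  ord <- order(-mass, -prior[cats], cats)
  cats[ord][1L]
}

#' Train a meter-free temporal model
#'
#' A plain PPM model over inter-onset intervals, the baseline against
#' which metrical inference is compared.
#'
#' @param corpus a [corpus()].
#' @param order order bound (default 2, matching [meter_likelihood()]).
#' @return A [ppm_model()] over ioi symbols.
#' @export
train_ioi_model <- function(corpus, order = 2L) {
  m <- ppm_model(order_bound = order, mode = "static")
  ppm_train(m, lapply(corpus$melodies,
                      function(x) as.character(diff(x$onset))))
  m
}

#' Information content of a rhythm under a meter-free ioi model
#'
#' Per-event information content of each inter-onset interval under a
#' plain PPM model, scored over the same candidate ioi alphabet as
#' [infer_meter()] so the two are directly comparable.
#'
#' @param melody a [melody()].
#' @param model a [train_ioi_model()].
#' @param candidates candidate ioi alphabet; defaults to the model
#'   alphabet extended by the melody's own iois.
#' @return Numeric vector of bits per event (events 2..N; `NA` at event 1).
#' @export
meterfree_ic <- function(melody, model, candidates = NULL) {
  ioi <- diff(melody$onset)
  if (is.null(candidates))
    candidates <- sort(union(as.integer(model$alphabet), ioi))
  ic <- rep(NA_real_, length(melody$onset))
  syms <- as.character(ioi)
  for (i in seq_along(ioi)) {
    pd <- predict(model, context = syms[seq_len(i - 1L)],
                  alphabet = as.character(candidates))
    pd <- pd[as.character(candidates)]
    pd <- pd / sum(pd)
    ic[i + 1L] <- -log2(pd[[syms[i]]])
  }
  ic
}
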