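## Event-level prediction: distributions from several viewpoint models are
## mapped onto the basic pitch and ioi alphabets, combined by entropy
## weighting within each subsystem (long-term, short-term) and then across
## subsystems, and scored as probability / information content / entropy.

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Prediction configuration
#'
#' Collects the tunable choices of the predictor: which viewpoints predict
#' each attribute, which subsystems are active, how distributions are
#' combined, the model order bounds, and (optionally) fixed basic
#' alphabets.
#'
#' @param pitch_viewpoints character vector of viewpoints predicting pitch
#'   (`"pitch"`, `"pi"`, `"sd"`, `"pi x sd"`); `NULL` disables pitch
#'   prediction.
#' @param onset_viewpoints character vector of viewpoints predicting the
#'   next inter-onset interval (`"ioi"`, `"ioi-ratio"`); `NULL` disables
#'   onset prediction.
#' @param subsystems subset of `c("ltm", "stm")`.
#' @param scheme `"arithmetic"` (weighted mean) or `"geometric"` (weighted
#'   product, renormalized).
#' @param bias positive exponent \eqn{b} of the entropy weights
#'   \eqn{w_m = (H_m / H_{max})^{-b}}; larger values favour more certain
#'   models more strongly.
#' @param ltm_order,stm_order order bounds of the long- and short-term
#'   models.
#' @param pitch_alphabet,ioi_alphabet optional fixed basic alphabets
#'   (integer vectors); when `NULL` they are taken from the training
#'   corpus.
#' @return An object of class `"prediction_config"`.
#' @export
prediction_config <- function(pitch_viewpoints = "pi x sd",
                              onset_viewpoints = "ioi-ratio",
                              subsystems = c("ltm", "stm"),
                              scheme = c("arithmetic", "geometric"),
                              bias = 2,
                              ltm_order = 3L, stm_order = Inf,
                              pitch_alphabet = NULL, ioi_alphabet = NULL) {
  scheme <- match.arg(scheme)
  subsystems <- match.arg(subsystems, c("ltm", "stm"), several.ok = TRUE)
  if (!is.numeric(bias) || bias <= 0)
    stop("'bias' must be a positive real", call. = FALSE)
  if (is.null(pitch_viewpoints) && is.null(onset_viewpoints))
    stop("at least one attribute must have an active viewpoint",
         call. = FALSE)
  ok_pitch <- c("pitch", "pi", "sd", "pi x sd", "sd x pi")
  ok_onset <- c("ioi", "ioi-ratio")
  if (!all(pitch_viewpoints %in% ok_pitch))
    stop("pitch viewpoints must be among: ",
         paste(ok_pitch, collapse = ", "), call. = FALSE)
  if (!all(onset_viewpoints %in% ok_onset))
    stop("onset viewpoints must be among: ",
         paste(ok_onset, collapse = ", "), call. = FALSE)
  structure(list(pitch_viewpoints = pitch_viewpoints,
                 onset_viewpoints = onset_viewpoints,
                 subsystems = subsystems, scheme = scheme, bias = bias,
                 ltm_order = ltm_order, stm_order = stm_order,
                 pitch_alphabet = pitch_alphabet,
                 ioi_alphabet = ioi_alphabet),
            class = "prediction_config")
}

#' Combine probability distributions by entropy weighting
#'
#' Models generating more certain (lower-entropy) predictions receive
#' higher weights: \eqn{w_m = (H(p_m)/H_{max})^{-b}} with
#' \eqn{H_{max} = \log_2 |A|}, normalized to sum to one.  The arithmetic
#' scheme returns the weighted mean \eqn{\sum_m w_m p_m(s)}; the geometric
#' scheme the renormalized weighted product \eqn{\prod_m p_m(s)^{w_m}}.
#'
#' @param dists list of named numeric vectors over one common alphabet.
#' @param scheme `"arithmetic"` or `"geometric"`.
#' @param bias positive weighting exponent \eqn{b}.
#' @return Named numeric vector over the common alphabet.
#' @examples
#' p1 <- c(a = 0.9, b = 0.1); p2 <- c(a = 0.5, b = 0.5)
#' combine_distributions(list(p1, p2), bias = 1)
#' @export
combine_distributions <- function(dists, scheme = c("arithmetic", "geometric"),
                                  bias = 2) {
  scheme <- match.arg(scheme)
  if (length(dists) == 0L)
    stop("'dists' must contain at least one distribution", call. = FALSE)
  ab <- names(dists[[1L]])
  same <- vapply(dists, function(d) setequal(names(d), ab), logical(1))
  if (!all(same))
    stop("all distributions must share one alphabet", call. = FALSE)
  dists <- lapply(dists, function(d) d[ab])
  if (length(dists) == 1L) return(dists[[1L]])
  if (length(ab) < 2L) return(dists[[1L]])
  h_max <- log2(length(ab))
  h <- vapply(dists, entropy_bits, numeric(1))
  w <- (pmax(h, 1e-6) / h_max) ^ (-bias)
  w <- w / sum(w)
  out <- if (scheme == "arithmetic") {
    Reduce(`+`, Map(`*`, w, dists))
  } else {
    logp <- Reduce(`+`, Map(function(wi, d) wi * log(d), w, dists))
    p <- exp(logp - max(logp))
    p / sum(p)
  }
  out / sum(out)
}

#' Joint probability of a note's pitch and onset
#'
#' The final probability of a note is the joint likelihood of its pitch
#' and its onset time, i.e. the product of the two component
#' probabilities; equivalently the joint information content is the sum of
#' the pitch and onset information contents.
#'
#' @param p_pitch,p_onset probabilities in `(0, 1]`.
#' @return The joint probability.
#' @examples
#' -log2(joint_probability(0.5, 0.5))  # 2 bits
#' @export
joint_probability <- function(p_pitch, p_onset) {
  if (any(p_pitch <= 0) || any(p_onset <= 0) ||
      any(p_pitch > 1) || any(p_onset > 1))
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  p_pitch * p_onset
}

#' Information content from mean betting capital
#'
#' In the betting paradigm, participants bet a proportion of their capital
#' on each candidate pitch out of 20; a correct prediction multiplies the
#' capital by 20 times the proportion bet.  The information content
#' implied by a mean final capital \eqn{S} is
#' \eqn{\log_2 20 - \log_2 S} bits.
#'
#' @param S mean capital, positive.
#' @return Information content in bits.
#' @examples
#' betting_ic(10)  # 1 bit
#' @export
betting_ic <- function(S) {
  if (any(S <= 0)) stop("'S' must be positive", call. = FALSE)
  log2(20) - log2(S)
}

## resolved per-attribute alphabets from a corpus + config
resolve_alphabets <- function(corp, config) {
  pitch_ab <- config$pitch_alphabet
  ioi_ab <- config$ioi_alphabet
  if (is.null(pitch_ab))
    pitch_ab <- sort(unique(unlist(lapply(corp$melodies, `[[`, "pitch"))))
  if (is.null(ioi_ab))
    ioi_ab <- sort(unique(unlist(lapply(corp$melodies,
                                        function(m) diff(m$onset)))))
  list(pitch = as.integer(pitch_ab), ioi = as.integer(ioi_ab))
}

#' Train the long-term models of a prediction configuration
#'
#' Fits one static PPM model per active viewpoint on the derived sequences
#' of every melody in the corpus, and resolves the basic pitch and ioi
#' alphabets (from the corpus, unless the configuration fixes them).
#'
#' @param corpus a [corpus()]; melodies must carry tonics if scale-degree
#'   viewpoints are active.
#' @param config a [prediction_config()].
#' @return An object of class `"ltm"` holding the trained models and the
#'   resolved configuration.
#' @export
train_ltm <- function(corpus, config = prediction_config()) {
  stopifnot(inherits(corpus, "corpus"), inherits(config, "prediction_config"))
  ab <- resolve_alphabets(corpus, config)
  config$pitch_alphabet <- ab$pitch
  config$ioi_alphabet <- ab$ioi
  fit_attr <- function(vps) {
    models <- lapply(vps, function(vp) {
      m <- ppm_model(order_bound = config$ltm_order, mode = "static")
      ppm_train(m, lapply(corpus$melodies, derive_viewpoint, name = vp))
      m
    })
    names(models) <- vps
    models
  }
  structure(list(pitch = fit_attr(config$pitch_viewpoints),
                 onset = fit_attr(config$onset_viewpoints),
                 config = config),
            class = "ltm")
}

#' @export
print.ltm <- function(x, ...) {
  cat(sprintf("Long-term models: pitch [%s], onset [%s]\n",
              paste(names(x$pitch), collapse = ", "),
              paste(names(x$onset), collapse = ", ")))
  invisible(x)
}

## Distribution over candidates for one attribute at event n under one set
## of viewpoint models; returns NULL when no viewpoint is defined here.
attr_event_dist <- function(models, melody, n, attribute, candidates,
                            dseqs, config) {
  prev_pitch <- if (n > 1L) melody$pitch[n - 1L] else NULL
  prev_ioi <- if (n > 2L) melody$onset[n - 1L] - melody$onset[n - 2L] else NULL
  dists <- list()
  for (vp in names(models)) {
    syms <- candidate_symbols(vp, candidates, attribute,
                              prev_pitch = prev_pitch, tonic = melody$tonic,
                              prev_ioi = prev_ioi)
    if (anyNA(syms)) next
    ctx <- dseqs[[vp]][seq_len(n - 1L)]
    pd <- predict(models[[vp]], context = ctx, alphabet = unique(syms))
    share <- table(syms)
    p <- unname(pd[syms]) / as.numeric(share[syms])
    p <- p / sum(p)
    dists[[vp]] <- stats::setNames(p, as.character(candidates))
  }
  if (length(dists) == 0L) return(NULL)
  combine_distributions(dists, scheme = config$scheme, bias = config$bias)
}

#' Per-note information content and entropy profile
#'
#' Processes a melody event by event.  For each event, every active
#' viewpoint model of each active subsystem predicts its attribute; the
#' derived distributions are mapped onto the basic alphabet, combined by
#' entropy weighting within the subsystem and then across subsystems, and
#' the realized symbol is scored.  The short-term models start empty and
#' are updated online after each prediction.
#'
#' Onset (ioi) predictions exist from the second event on; joint
#' probabilities are reported where both attributes are defined.
#'
#' @param melody a [melody()].
#' @param ltm a trained [train_ltm()] object, or `NULL` for a short-term
#'   only configuration.
#' @param config a [prediction_config()]; defaults to the configuration
#'   stored in `ltm`.
#' @return A data frame of class `"ic_profile"` with one row per event:
#'   onset, pitch, per-attribute probability / information content (bits) /
#'   entropy (bits), and the joint probability and information content.
#' @export
ic_profile <- function(melody, ltm = NULL, config = NULL) {
  stopifnot(inherits(melody, "melody"))
  if (is.null(config))
    config <- if (!is.null(ltm)) ltm$config else prediction_config()
  use_ltm <- "ltm" %in% config$subsystems
  use_stm <- "stm" %in% config$subsystems
  if (use_ltm && is.null(ltm))
    stop("configuration activates the long-term model but none was given",
         call. = FALSE)
  one_corp <- corpus(list(melody), name = "self")
  ab <- resolve_alphabets(one_corp, config)
  if (!is.null(ltm)) {
    ab$pitch <- sort(union(ltm$config$pitch_alphabet, ab$pitch))
    ab$ioi <- sort(union(ltm$config$ioi_alphabet, ab$ioi))
  }
  vps <- list(pitch = config$pitch_viewpoints,
              onset = config$onset_viewpoints)
  dseqs <- list()
  for (vp in unique(unlist(vps)))
    dseqs[[vp]] <- derive_viewpoint(melody, vp)
  stm <- lapply(vps, function(v) {
    ms <- lapply(v, function(vp)
      ppm_model(order_bound = config$stm_order, mode = "online"))
    names(ms) <- v
    ms
  })
  n_ev <- length(melody$onset)
  out <- data.frame(event = seq_len(n_ev), onset = melody$onset,
                    pitch = melody$pitch,
                    p_pitch = NA_real_, ic_pitch = NA_real_,
                    h_pitch = NA_real_,
                    p_onset = NA_real_, ic_onset = NA_real_,
                    h_onset = NA_real_,
                    p_joint = NA_real_, ic_joint = NA_real_)
  for (n in seq_len(n_ev)) {
    for (attribute in c("pitch", "onset")) {
      if (is.null(vps[[attribute]])) next
      if (attribute == "onset" && n == 1L) next
      realized <- if (attribute == "pitch") melody$pitch[n]
                  else melody$onset[n] - melody$onset[n - 1L]
      candidates <- sort(union(ab[[if (attribute == "pitch") "pitch"
                                   else "ioi"]], realized))
      subs <- list()
      if (use_ltm)
        subs$ltm <- attr_event_dist(ltm[[attribute]], melody, n, attribute,
                                    candidates, dseqs, config)
      if (use_stm)
        subs$stm <- attr_event_dist(stm[[attribute]], melody, n, attribute,
                                    candidates, dseqs, config)
      subs <- Filter(Negate(is.null), subs)
      dist <- if (length(subs) == 0L)
        stats::setNames(rep(1 / length(candidates), length(candidates)),
                        as.character(candidates))
      else combine_distributions(subs, scheme = config$scheme,
                                 bias = config$bias)
      p <- unname(dist[as.character(realized)])
      if (attribute == "pitch") {
        out$p_pitch[n] <- p
        out$ic_pitch[n] <- -log2(p)
        out$h_pitch[n] <- entropy_bits(dist)
      } else {
        out$p_onset[n] <- p
        out$ic_onset[n] <- -log2(p)
        out$h_onset[n] <- entropy_bits(dist)
      }
    }
    if (use_stm) {
      for (attribute in c("pitch", "onset")) {
        for (vp in vps[[attribute]]) {
          sym <- dseqs[[vp]][n]
          if (is.na(sym)) next
          ppm_observe(stm[[attribute]][[vp]], sym,
                      context = dseqs[[vp]][seq_len(n - 1L)])
        }
      }
    }
  }
  both <- !is.na(out$p_pitch) & !is.na(out$p_onset)
  out$p_joint[both] <- joint_probability(out$p_pitch[both],
                                         out$p_onset[both])
  out$ic_joint[both] <- out$ic_pitch[both] + out$ic_onset[both]
  class(out) <- c("ic_profile", "data.frame")
  attr(out, "melody_id") <- melody$id
  out
}

#' Mean information content of a profiled melody
#'
#' Means are taken over the events where both attributes are defined (all
#' events but the first, when both pitch and onset are predicted), so that
#' the joint mean equals the sum of the pitch and onset means exactly.
#'
#' @param profile an [ic_profile()].
#' @return A list with components `pitch`, `onset` and `joint` (bits per
#'   note; `NA` for inactive attributes).
#' @export
mean_ic <- function(profile) {
  stopifnot(inherits(profile, "ic_profile"))
  has_p <- !all(is.na(profile$ic_pitch))
  has_o <- !all(is.na(profile$ic_onset))
  rows <- if (has_p && has_o) !is.na(profile$ic_pitch) & !is.na(profile$ic_onset)
          else if (has_p) !is.na(profile$ic_pitch)
          else !is.na(profile$ic_onset)
  list(pitch = if (has_p) mean(profile$ic_pitch[rows]) else NA_real_,
       onset = if (has_o) mean(profile$ic_onset[rows]) else NA_real_,
       joint = if (has_p && has_o) mean(profile$ic_joint[rows]) else NA_real_)
}
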