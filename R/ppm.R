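## Variable-order Markov engine with interpolated escape smoothing.
##
## Counts live in a hash environment keyed by the context (a tuple of
## symbols joined by an unprintable separator); each entry is a named
## numeric vector of continuation counts.  Models use reference semantics
## (the object is an environment), so training and online updates modify
## the model in place, mirroring how the counts of a learning listener
## accumulate.

CTX_SEP <- "\x1f"

## keys get a one-byte prefix so the empty context maps to a legal
## environment binding name
ctx_key <- function(context) paste0("\x02", paste(context, collapse = CTX_SEP))

#' Create a variable-order Markov model
#'
#' The model stores continuation counts for every context up to
#' `order_bound` and predicts by blending maximum-likelihood estimates of
#' all orders from the longest matching context down to a uniform
#' order minus-one floor (interpolated smoothing with escape method C): at
#' each order with total count \eqn{N} and \eqn{T} distinct continuation
#' types, \eqn{p(s) = n(s)/(N+T) + T/(N+T)\, p_{lower}(s)}.
#'
#' @param alphabet character vector of symbols the model may predict; grown
#'   automatically as training data arrive.
#' @param order_bound maximum context length used (non-negative integer or
#'   `Inf` for unbounded).
#' @param mode `"static"` (long-term model, trained once on a corpus) or
#'   `"online"` (short-term model, updated incrementally within a piece and
#'   reset between pieces).
#' @return An object of class `"ppm_model"`.
#' @seealso [ppm_train()], [predict.ppm_model()], [ppm_observe()],
#'   [ppm_reset()]
#' @export
ppm_model <- function(alphabet = character(0), order_bound = Inf,
                      mode = c("static", "online")) {
  mode <- match.arg(mode)
  if (!identical(order_bound, Inf)) {
    order_bound <- as.integer(order_bound)
    if (is.na(order_bound) || order_bound < 0L)
      stop("'order_bound' must be a non-negative integer or Inf",
           call. = FALSE)
  }
  m <- new.env(parent = emptyenv())
  m$counts <- new.env(parent = emptyenv())
  m$alphabet <- unique(as.character(alphabet))
  m$order_bound <- order_bound
  m$mode <- mode
  class(m) <- "ppm_model"
  m
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(sprintf("PPM model (%s): |alphabet| = %d, order bound = %s, %d contexts\n",
              x$mode, length(x$alphabet),
              if (is.finite(x$order_bound)) x$order_bound else "unbounded",
              length(ls(x$counts, all.names = TRUE))))
  invisible(x)
}

add_count <- function(model, context, sym) {
  key <- ctx_key(context)
  cnt <- get0(key, envir = model$counts, inherits = FALSE)
  if (is.null(cnt)) cnt <- numeric(0)
  cur <- cnt[sym]
  cnt[sym] <- if (is.na(cur)) 1 else cur + 1
  assign(key, cnt, envir = model$counts)
}

## Count one position: (all context suffixes up to order_bound, sym).
count_position <- function(model, context, sym) {
  max_len <- min(length(context), model$order_bound)
  for (len in 0:max_len) {
    ctx <- if (len == 0L) character(0)
           else context[(length(context) - len + 1L):length(context)]
    add_count(model, ctx, sym)
  }
}

#' Train a model on symbol sequences
#'
#' Each sequence contributes a count for every (context, next symbol) pair
#' up to the model's order bound.  Undefined positions (`NA`) contribute
#' neither as context elements nor as predictands: they are removed and
#' the remaining symbols treated as contiguous.
#'
#' @param model a [ppm_model()].
#' @param sequences a character vector or a list of character vectors.
#' @return The model, invisibly (modified in place).
#' @export
ppm_train <- function(model, sequences) {
  stopifnot(inherits(model, "ppm_model"))
  if (!is.list(sequences)) sequences <- list(sequences)
  for (s in sequences) {
    s <- as.character(s)
    s <- s[!is.na(s)]
    if (length(s) == 0L) next
    new_syms <- setdiff(unique(s), model$alphabet)
    if (length(new_syms)) model$alphabet <- c(model$alphabet, new_syms)
    for (i in seq_along(s))
      count_position(model, if (i > 1L) s[seq_len(i - 1L)] else character(0),
                     s[i])
  }
  invisible(model)
}

#' Predict the next symbol
#'
#' Returns a full-support probability distribution over the union of the
#' model's alphabet and any additionally declared symbols.  The estimate
#' starts from the longest stored suffix of `context` (no longer than the
#' order bound) and blends each order with all lower orders down to the
#' uniform floor, so unseen-but-declared symbols receive mass only through
#' the escape chain.
#'
#' @param object a [ppm_model()].
#' @param context character vector of preceding symbols (most recent last);
#'   `NA` positions are dropped.
#' @param alphabet optional extra symbols to include in the support (e.g. a
#'   fixed test alphabet).
#' @param ... unused.
#' @return Named numeric vector of probabilities summing to 1, with every
#'   symbol's mass strictly positive.
#' @examples
#' m <- ppm_model()
#' ppm_train(m, c("a", "b", "a", "b", "a"))
#' predict(m, context = "b")
#' @export
predict.ppm_model <- function(object, context = character(0),
                              alphabet = NULL, ...) {
  context <- as.character(context)
  context <- context[!is.na(context)]
  support <- unique(c(object$alphabet, as.character(alphabet)))
  if (length(support) == 0L)
    stop("model has an empty alphabet and no symbols were declared",
         call. = FALSE)
  if (is.finite(object$order_bound) &&
      length(context) > object$order_bound)
    context <- context[(length(context) - object$order_bound + 1L):
                       length(context)]
  ## longest stored suffix
  max_len <- 0L
  if (length(context) > 0L) {
    for (len in length(context):1L) {
      key <- ctx_key(context[(length(context) - len + 1L):length(context)])
      cnt <- get0(key, envir = object$counts, inherits = FALSE)
      if (!is.null(cnt) && sum(cnt) > 0) { max_len <- len; break }
    }
  }
  p <- stats::setNames(rep(1 / length(support), length(support)), support)
  for (len in 0:max_len) {
    ctx <- if (len == 0L) character(0)
           else context[(length(context) - len + 1L):length(context)]
    cnt <- get0(ctx_key(ctx), envir = object$counts, inherits = FALSE)
    if (is.null(cnt) || sum(cnt) == 0) next
    n <- sum(cnt)
    t <- length(cnt)
    full <- stats::setNames(numeric(length(support)), support)
    full[names(cnt)] <- cnt
    p <- full / (n + t) + (t / (n + t)) * p
  }
  p
}

#' Observe a symbol with an online (short-term) model
#'
#' Implements the prediction-then-update contract of the short-term model:
#' call [predict.ppm_model()] first for the current position, then
#' `ppm_observe()` to add the realized symbol to the counts.  Undefined
#' (`NA`) symbols are ignored.
#'
#' @param model a [ppm_model()] with `mode = "online"`.
#' @param observed the realized symbol.
#' @param context character vector of preceding symbols (`NA` dropped).
#' @return The model, invisibly (modified in place).
#' @export
ppm_observe <- function(model, observed, context = character(0)) {
  stopifnot(inherits(model, "ppm_model"))
  if (model$mode != "online")
    stop("ppm_observe() requires a model with mode = 'online'",
         call. = FALSE)
  if (is.na(observed)) return(invisible(model))
  observed <- as.character(observed)
  context <- as.character(context)
  context <- context[!is.na(context)]
  if (!(observed %in% model$alphabet))
    model$alphabet <- c(model$alphabet, observed)
  count_position(model, context, observed)
  invisible(model)
}

#' Empty an online model of all learned content
#'
#' The short-term model is reset before each new piece so that only
#' within-piece structure informs its predictions.
#'
#' @param model a [ppm_model()].
#' @param keep_alphabet keep the symbol alphabet (default) or clear it too.
#' @return The model, invisibly (modified in place).
#' @export
ppm_reset <- function(model, keep_alphabet = TRUE) {
  stopifnot(inherits(model, "ppm_model"))
  model$counts <- new.env(parent = emptyenv())
  if (!keep_alphabet) model$alphabet <- character(0)
  invisible(model)
}

#' Serialize a model to a versioned JSON document
#'
#' @param model a [ppm_model()].
#' @param file path to write; if `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when written to a file).
#' @seealso [ppm_load()]
#' @export
ppm_save <- function(model, file = NULL) {
  stopifnot(inherits(model, "ppm_model"))
  keys <- ls(model$counts, all.names = TRUE)
  counts <- lapply(keys, function(k) as.list(get(k, envir = model$counts)))
  names(counts) <- keys
  doc <- list(format = "melopredict-ppm", version = 1L,
              alphabet = model$alphabet,
              order_bound = if (is.finite(model$order_bound))
                model$order_bound else "unbounded",
              mode = model$mode,
              counts = counts)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Load a model serialized with [ppm_save()]
#'
#' @param file path to a JSON document, or the JSON text itself.
#' @return A [ppm_model()].
#' @export
ppm_load <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!identical(doc$format, "melopredict-ppm"))
    stop("not a serialized melopredict PPM model", call. = FALSE)
  ob <- if (identical(doc$order_bound, "unbounded")) Inf else doc$order_bound
  m <- ppm_model(alphabet = unlist(doc$alphabet), order_bound = ob,
                 mode = doc$mode)
  for (key in names(doc$counts)) {
    cnt <- unlist(doc$counts[[key]])
    assign(key, cnt, envir = m$counts)
  }
  m
}
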