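#' Probabilistic linguistic term sets
#'
#' A probabilistic linguistic term set (PLTS) attaches a probability to each
#' linguistic term an assessor hesitates between, e.g.
#' `{s-3:0.5, s-2:0.1, s-1:0.1, s0:0.3}` ("50% very strong negative, 10%
#' strong negative, ..."). It is the universal value type of this package:
#' both concept states and edge weights of a probabilistic linguistic fuzzy
#' cognitive map are PLTSs.
#'
#' User-supplied PLTSs must use integer term indices within the attached
#' scale's \eqn{[-\tau, \tau]} range, pairwise distinct, with probabilities in
#' \eqn{[0, 1]} summing to at most 1 (a raw PLTS; see [plts_normalize()] for
#' the standard form). PLTSs produced by the inference engine may carry
#' continuous (non-integer) term values, because the inverse equivalent
#' transformation of an iterated membership rarely lands on a whole term.
#'
#' @param term numeric vector of term indices (integers for user input).
#' @param prob numeric vector of probabilities, same length as `term`.
#' @param scale a [pl_scale()] (or bare tau).
#' @return An object of class `"plts"`: entries stored in ascending term
#'   order.
#' @examples
#' sc <- pl_scale(5)
#' plts(c(-3, 0, 3), c(0.15, 0.4, 0.45), sc)
#' @seealso [plts_parse()], [plts_normalize()], [plts_score()]
#' @export
plts <- function(term, prob, scale) {
  scale <- as_pl_scale(scale)
  tau <- scale$tau
  if (!is.numeric(term) || !is.numeric(prob)) {
    stop("`term` and `prob` must be numeric", call. = FALSE)
  }
  if (length(term) == 0L || length(term) != length(prob)) {
    stop("`term` and `prob` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(term)) || any(!is.finite(prob))) {
    stop("non-finite term index or probability", call. = FALSE)
  }
  if (any(term != round(term))) {
    stop("user-supplied term indices must be integers", call. = FALSE)
  }
  if (anyDuplicated(term)) {
    stop("term indices must be pairwise distinct", call. = FALSE)
  }
  if (any(term < -tau) || any(term > tau)) {
    stop(sprintf("term index outside the scale range [%g, %g]", -tau, tau),
         call. = FALSE)
  }
  if (any(prob < 0) || any(prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(prob) > 1 + 1e-9) {
    stop("probabilities must sum to at most 1", call. = FALSE)
  }
  new_plts(term, prob, scale)
}

# Internal constructor: no integer/distinctness checks, so the engine can
# build continuous-term PLTSs and zero-probability padded entries.
new_plts <- function(term, prob, scale, sort = TRUE) {
  if (sort) {
    o <- order(term, prob)   # zero-probability padding sorts first in ties
    term <- term[o]
    prob <- prob[o]
  }
  structure(list(term = as.numeric(term), prob = as.numeric(prob),
                 scale = as_pl_scale(scale)),
            class = "plts")
}

#' @export
print.plts <- function(x, digits = 4, ...) {
  cat(plts_format(x, digits = digits), "\n")
  invisible(x)
}

#' @export
length.plts <- function(x) length(x$term)

#' Format a PLTS as text
#'
#' The canonical text syntax, used in model files and connection-matrix
#' cells, is `{s-3:0.5, s0:0.3, s3:0.2}` with entries in ascending term
#' order.
#'
#' @param x a [plts()].
#' @param digits significant digits for probabilities (and non-integer term
#'   values); the default preserves doubles so that file round trips are
#'   exact.
#' @return A single character string.
#' @export
plts_format <- function(x, digits = 15) {
  stopifnot(inherits(x, "plts"))
  fmt_num <- function(v) {
    ifelse(v == round(v), sprintf("%g", v),
           sprintf("%.*g", digits, v))
  }
  entries <- sprintf("s%s:%s", fmt_num(x$term), fmt_num(x$prob))
  paste0("{", paste(entries, collapse = ", "), "}")
}

#' Parse the PLTS text syntax
#'
#' Accepts entries in arbitrary order (they are re-sorted ascending), with or
#' without the surrounding braces and the `s` term prefix. Probabilities are
#' kept raw; call [plts_normalize()] to rescale them to sum 1.
#'
#' @param text a string such as `"{s-3:0.5, s0:0.3, s3:0.2}"`.
#' @param scale a [pl_scale()] (or bare tau) the terms must live on.
#' @return A [plts()].
#' @examples
#' plts_parse("{s3:0.45, s0:0.4, s-3:0.15}", pl_scale(5))
#' @export
plts_parse <- function(text, scale) {
  stopifnot(is.character(text), length(text) == 1L)
  body <- gsub("^\\s*\\{|\\}\\s*$", "", trimws(text))
  if (!nzchar(body)) stop("empty PLTS string", call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  rx <- "^\\s*s?\\s*(-?[0-9]+(?:\\.[0-9]+)?)\\s*[:(]\\s*([0-9.eE+-]+)\\s*\\)?\\s*$"
  m <- regmatches(parts, regexec(rx, parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed PLTS entry: '", trimws(parts[bad][1]), "'", call. = FALSE)
  }
  term <- vapply(m, function(g) as.numeric(g[2]), 1)
  prob <- vapply(m, function(g) as.numeric(g[3]), 1)
  plts(term, prob, scale)
}

#' Standardise a PLTS (probabilities rescaled to sum 1)
#'
#' Divides the probabilities by their total, turning a raw PLTS (probability
#' sum at most 1) into its standard form. Term indices and their order are
#' untouched; the operation is idempotent.
#'
#' @param x a [plts()] with at least one positive probability.
#' @return A [plts()] whose probabilities sum to 1.
#' @examples
#' plts_normalize(plts(c(-1, 1), c(0.2, 0.2), pl_scale(3)))
#' @export
plts_normalize <- function(x) {
  stopifnot(inherits(x, "plts"))
  s <- sum(x$prob)
  if (s <= 0) {
    stop("cannot normalize a PLTS whose probabilities are all zero",
         call. = FALSE)
  }
  new_plts(x$term, x$prob / s, x$scale, sort = FALSE)
}

#' Pad two PLTSs to a common length
#'
#' When two PLTSs have different numbers of entries, the shorter one is
#' extended with zero-probability entries so that positional operations
#' (such as the Euclidean distance) are well defined. The padding entries
#' repeat the shorter set's smallest term index with probability zero, which
#' keeps the procedure deterministic and order-preserving.
#'
#' @param a,b two [plts()] on the same scale.
#' @return A list with elements `a` and `b`, both of length
#'   `max(length(a), length(b))`.
#' @export
plts_pad_pair <- function(a, b) {
  check_same_scale(a, b)
  la <- length(a); lb <- length(b)
  if (la == lb) return(list(a = a, b = b))
  pad <- function(x, l) {
    k <- l - length(x)
    new_plts(c(rep(min(x$term), k), x$term),
             c(rep(0, k), x$prob), x$scale)
  }
  l <- max(la, lb)
  list(a = pad(a, l), b = pad(b, l))
}

#' Score (expectation) of a PLTS
#'
#' The score of a PLTS is the probability-weighted expectation of its term
#' indices, computed on the standard (normalised) form: the index
#' \eqn{\bar\alpha = \sum_\theta L^\theta \dot p^\theta} of the expected term
#' \eqn{s_{\bar\alpha}}. It is the usual defuzzification of a probabilistic
#' linguistic value; mapping it through the equivalent transformation `g`
#' gives a crisp activation in \eqn{[0, 1]}.
#'
#' @param x a normalizable [plts()].
#' @return A number in \eqn{[-\tau, \tau]}.
#' @examples
#' plts_score(plts_parse("{s3:0.45, s0:0.40, s-3:0.15}", 5))  # 0.9
#' @export
plts_score <- function(x) {
  n <- plts_normalize(x)
  sum(n$term * n$prob)
}

#' Complement of a PLTS
#'
#' Negates every term index (probabilities are kept), reflecting the value
#' about the scale midpoint \eqn{s_0}. The complement is an involution and is
#' the value at maximal distance from the original at the scale endpoints.
#'
#' @param x a [plts()].
#' @return A [plts()].
#' @export
plts_complement <- function(x) {
  stopifnot(inherits(x, "plts"))
  new_plts(-x$term, x$prob, x$scale)
}

check_same_scale <- function(a, b) {
  stopifnot(inherits(a, "plts"), inherits(b, "plts"))
  if (a$scale$tau != b$scale$tau) {
    stop("PLTS operands live on different scales (tau ", a$scale$tau,
         " vs ", b$scale$tau, ")", call. = FALSE)
  }
  invisible(TRUE)
}
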