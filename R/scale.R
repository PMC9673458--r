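#' Symmetric linguistic term scale
#'
#' A linguistic scale is the ordered set of terms
#' \eqn{s_{-\tau}, \ldots, s_{-1}, s_0, s_1, \ldots, s_{\tau}}, so it has
#' \eqn{2\tau + 1} terms in total. The granularity parameter \eqn{\tau}
#' controls how finely judgments are graded: the package defaults are
#' \eqn{\tau = 5} for concept states (an 11-term scale from "extremely poor"
#' to "extremely good") and \eqn{\tau = 3} for edge weights ("very strong
#' negative impact" through "very strong positive impact").
#'
#' @param tau positive integer granularity.
#' @param labels optional character vector of `2 * tau + 1` human-readable
#'   term names, ordered from \eqn{s_{-\tau}} to \eqn{s_{\tau}}.
#' @return An object of class `"pl_scale"`.
#' @examples
#' pl_scale(3, labels = c(
#'   "very strong negative", "strong negative", "weak negative",
#'   "undetermined", "weak positive", "strong positive",
#'   "very strong positive"
#' ))
#' @export
pl_scale <- function(tau, labels = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < 1 || tau != round(tau)) {
    stop("`tau` must be a single positive integer (tau >= 1)", call. = FALSE)
  }
  tau <- as.numeric(tau)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != 2 * tau + 1) {
      stop("`labels` must have exactly 2 * tau + 1 = ", 2 * tau + 1,
           " entries", call. = FALSE)
    }
  }
  structure(list(tau = tau, labels = labels), class = "pl_scale")
}

#' @export
print.pl_scale <- function(x, ...) {
  cat(sprintf("<pl_scale> tau = %g (%d terms: s%g .. s%g)\n",
              x$tau, as.integer(2 * x$tau + 1), -x$tau, x$tau))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  invisible(x)
}

# Accept a pl_scale or a bare tau; return tau as a number.
as_tau <- function(scale) {
  if (inherits(scale, "pl_scale")) return(scale$tau)
  if (is.numeric(scale) && length(scale) == 1L && scale >= 1) {
    return(as.numeric(scale))
  }
  stop("expected a `pl_scale` object or a single tau >= 1", call. = FALSE)
}

as_pl_scale <- function(scale) {
  if (inherits(scale, "pl_scale")) scale else pl_scale(scale)
}
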