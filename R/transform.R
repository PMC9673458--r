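#' Equivalent transformation between term indices and memberships
#'
#' `g_transform()` is the affine bijection \eqn{g: [-\tau, \tau] \to [0, 1]},
#' \eqn{\eta = (\gamma + \tau) / (2\tau)}, that maps a term index to a
#' membership degree so that arithmetic can be done on the unit interval;
#' `g_inverse()` maps back, \eqn{\gamma = (2\eta - 1)\tau}. On the 11-term
#' state scale (\eqn{\tau = 5}) the triple \eqn{(s_{-3}, s_0, s_3)} maps to
#' \eqn{(0.2, 0.5, 0.8)}.
#'
#' Applied to a PLTS, `g_transform()` converts every entry's term index and
#' carries the probabilities through unchanged, returning a transformed PLTS
#' (class `"plts_g"`). `g_inverse()` on such an object (or on raw membership
#' values) recovers term values exactly; non-integer results are permitted
#' because iterated memberships rarely correspond to whole terms.
#'
#' @param x a numeric vector of term indices (for `g_transform`) or
#'   memberships in \eqn{[0, 1]} (for `g_inverse`), or a [plts()] /
#'   `"plts_g"` object.
#' @param scale a [pl_scale()] or bare tau; ignored (taken from the object)
#'   when `x` carries its own scale.
#' @return A numeric vector, a `"plts_g"` object (memberships +
#'   probabilities), or a [plts()].
#' @examples
#' g_transform(c(-3, 0, 3), 5)        # 0.2 0.5 0.8
#' g_inverse(0.2, 5)                  # -3
#' @export
g_transform <- function(x, scale = NULL) {
  if (inherits(x, "plts")) {
    tau <- x$scale$tau
    return(structure(list(eta = (x$term + tau) / (2 * tau),
                          prob = x$prob,
                          scale = x$scale),
                     class = "plts_g"))
  }
  tau <- as_tau(scale)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric term indices", call. = FALSE)
  }
  if (any(x < -tau) || any(x > tau)) {
    stop(sprintf("term index outside [%g, %g]", -tau, tau), call. = FALSE)
  }
  (x + tau) / (2 * tau)
}

#' @rdname g_transform
#' @export
g_inverse <- function(x, scale = NULL) {
  if (inherits(x, "plts_g")) {
    tau <- x$scale$tau
    return(new_plts((2 * x$eta - 1) * tau, x$prob, x$scale, sort = FALSE))
  }
  tau <- as_tau(scale)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric memberships", call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("membership outside [0, 1]", call. = FALSE)
  }
  (2 * x - 1) * tau
}

#' @export
print.plts_g <- function(x, digits = 4, ...) {
  entries <- sprintf("%.*g(%.*g)", digits, x$eta, digits, x$prob)
  cat("<plts_g tau=", x$scale$tau, "> {", paste(entries, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

# --- PLTS algebra (Cartesian operators on transformed memberships) --------

# Combine two transformed PLTSs entry-by-entry over the Cartesian product,
# with `combine(eta1, eta2)` on memberships and p1 * p2 on probabilities.
# Duplicate resulting memberships are merged by summing probabilities and
# results are kept in ascending membership order, which bounds growth while
# preserving the distribution.
cartesian_op <- function(a, b, combine) {
  check_same_scale(a, b)
  ga <- g_transform(a); gb <- g_transform(b)
  idx <- expand.grid(i = seq_along(ga$eta), j = seq_along(gb$eta))
  eta <- combine(ga$eta[idx$i], gb$eta[idx$j])
  prob <- ga$prob[idx$i] * gb$prob[idx$j]
  merged <- merge_memberships(eta, prob)
  g_inverse(structure(list(eta = merged$eta, prob = merged$prob,
                           scale = a$scale), class = "plts_g"))
}

merge_memberships <- function(eta, prob, tol = 1e-12) {
  o <- order(eta)
  eta <- eta[o]; prob <- prob[o]
  group <- cumsum(c(TRUE, diff(eta) > tol))
  list(eta = as.numeric(tapply(eta, group, function(e) e[1])),
       prob = as.numeric(tapply(prob, group, sum)))
}

#' PLTS arithmetic
#'
#' Operational laws on PLTSs, defined through the equivalent transformation:
#' every pair of entries is combined (Cartesian product), memberships by the
#' probabilistic sum \eqn{\eta_1 + \eta_2 - \eta_1\eta_2} (`plts_add`) or the
#' product \eqn{\eta_1 \eta_2} (`plts_mult`), and the pair probability is
#' \eqn{p_1 p_2}. The scalar multiple uses
#' \eqn{1 - (1 - \eta)^{\lambda}} and the power \eqn{\eta^{\lambda}}.
#' Results are mapped back through the inverse transformation, so term
#' values may be non-integers. If both inputs are normalized the result's
#' probabilities sum to 1; duplicate memberships are merged by summing
#' probabilities.
#'
#' @param a,b [plts()] operands on the same scale.
#' @param lambda a positive real scalar.
#' @return A [plts()] (possibly with continuous term values).
#' @examples
#' x <- plts(0, 1, 3)                # eta = 0.5
#' plts_add(x, x)                    # single entry with eta = 0.75
#' @export
plts_add <- function(a, b) {
  cartesian_op(a, b, function(x, y) x + y - x * y)
}

#' @rdname plts_add
#' @export
plts_mult <- function(a, b) {
  cartesian_op(a, b, function(x, y) x * y)
}

#' @rdname plts_add
#' @export
plts_scalar_mult <- function(lambda, a) {
  stopifnot(inherits(a, "plts"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  ga <- g_transform(a)
  merged <- merge_memberships(1 - (1 - ga$eta)^lambda, ga$prob)
  g_inverse(structure(list(eta = merged$eta, prob = merged$prob,
                           scale = a$scale), class = "plts_g"))
}

#' @rdname plts_add
#' @export
plts_power <- function(a, lambda) {
  stopifnot(inherits(a, "plts"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  ga <- g_transform(a)
  merged <- merge_memberships(ga$eta^lambda, ga$prob)
  g_inverse(structure(list(eta = merged$eta, prob = merged$prob,
                           scale = a$scale), class = "plts_g"))
}

#' Pool expert opinions expressed as PLTSs
#'
#' Aggregates several experts' probabilistic linguistic judgments of the same
#' quantity into one PLTS: the result's support is the union of all term
#' indices, and each term's probability is the weighted mean of that term's
#' probabilities across experts (an absent term counts as probability 0).
#' The output is normalized. With three equally-weighted experts giving
#' `{s-3:0.6, s-1:0.3, s0:0.1}`, `{s-3:0.5, s0:0.5}` and
#' `{s-3:0.4, s-2:0.3, s0:0.3}`, the pooled value is
#' `{s-3:0.5, s-2:0.1, s-1:0.1, s0:0.3}`.
#'
#' @param opinions a non-empty list of [plts()] on one scale.
#' @param weights numeric vector of non-negative expert weights summing to 1;
#'   defaults to equal weights.
#' @return A normalized [plts()].
#' @export
plts_aggregate <- function(opinions, weights = NULL) {
  if (!is.list(opinions) || length(opinions) == 0L) {
    stop("`opinions` must be a non-empty list of plts", call. = FALSE)
  }
  if (!all(vapply(opinions, inherits, TRUE, "plts"))) {
    stop("every opinion must be a plts", call. = FALSE)
  }
  taus <- vapply(opinions, function(x) x$scale$tau, 1)
  if (length(unique(taus)) != 1L) {
    stop("all opinions must share one scale", call. = FALSE)
  }
  n <- length(opinions)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) {
    stop("`weights` must have one entry per opinion", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  }
  terms <- sort(unique(unlist(lapply(opinions, `[[`, "term"))))
  prob <- numeric(length(terms))
  for (k in seq_len(n)) {
    ok <- opinions[[k]]
    pos <- match(ok$term, terms)
    contrib <- numeric(length(terms))
    contrib[pos] <- ok$prob
    prob <- prob + weights[k] * contrib
  }
  plts_normalize(new_plts(terms, prob, opinions[[1]]$scale, sort = FALSE))
}
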