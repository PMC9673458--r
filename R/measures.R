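#' Z-mapping functions
#'
#' The four standard decreasing calibrations \eqn{Z: [0,1] \to [0,1]} used to
#' turn a distance into a similarity: `linear` \eqn{Z(t) = 1 - t}, `rational`
#' \eqn{Z(t) = (1-t)/(1+t)}, `exponential` \eqn{Z(t) = 1 - t e^{t-1}} and
#' `quadratic` \eqn{Z(t) = 1 - t^2}.
#'
#' @format A named list of functions.
#' @keywords internal
z_forms <- list(
  linear      = function(t) 1 - t,
  rational    = function(t) (1 - t) / (1 + t),
  exponential = function(t) 1 - t * exp(t - 1),
  quadratic   = function(t) 1 - t^2
)

z_form_names <- function() names(z_forms)

get_z <- function(z_form) {
  if (is.function(z_form)) return(z_form)
  z_form <- match.arg(z_form, names(z_forms))
  z_forms[[z_form]]
}

#' Probabilistic linguistic Euclidean distance
#'
#' The Euclidean distance between two PLTSs,
#' \deqn{d(L_1(P), L_2(P)) = \sqrt{\frac{1}{l} \sum_{\theta=1}^{l}
#'   (v_1^\theta - v_2^\theta)^2},}
#' where \eqn{l = \max(\#L_1, \#L_2)} and \eqn{v^\theta} is the scalar value
#' of position \eqn{\theta}. Both operands are normalized and padded to the
#' common length first, with entries aligned by ascending term index.
#'
#' The position scalar is a convention this package documents rather than a
#' universal definition: with `scalarization = "prob_weighted"` (default) it
#' is the g-transformed membership times the probability; with
#' `"membership"` the probability factor is dropped (the degenerate hesitant
#' fuzzy linguistic reading used by the HFLCM baseline).
#'
#' @param a,b [plts()] on one scale.
#' @param scalarization `"prob_weighted"` or `"membership"`.
#' @return A number in \eqn{[0, 1]}; symmetric, and 0 for identical
#'   operands.
#' @examples
#' sc <- pl_scale(5)
#' plts_distance(plts(5, 1, sc), plts(-5, 1, sc))  # 1
#' @export
plts_distance <- function(a, b,
                          scalarization = c("prob_weighted", "membership")) {
  scalarization <- match.arg(scalarization)
  check_same_scale(a, b)
  p <- plts_pad_pair(plts_normalize(a), plts_normalize(b))
  va <- position_values(p$a, scalarization)
  vb <- position_values(p$b, scalarization)
  sqrt(mean((va - vb)^2))
}

position_values <- function(x, scalarization) {
  eta <- g_transform(x$term, x$scale)
  if (scalarization == "prob_weighted") eta * x$prob else eta
}

#' Z-mapping similarity between PLTSs
#'
#' Converts the probabilistic linguistic Euclidean distance into a similarity
#' degree through a decreasing Z-mapping:
#' \deqn{S(L_1(P), L_2(P)) = \frac{Z(d) - Z(1)}{Z(0) - Z(1)}.}
#' For every supported Z form the similarity lies in \eqn{[0, 1]}, is
#' symmetric, equals 1 exactly at equality and 0 exactly at maximal distance
#' (attained by complementary values at the scale endpoints).
#'
#' @inheritParams plts_distance
#' @param z_form one of `"linear"`, `"rational"`, `"exponential"`,
#'   `"quadratic"`, or a decreasing function \eqn{[0,1] \to [0,1]}.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' sc <- pl_scale(5)
#' a <- plts(c(-3, 0, 3), c(0.15, 0.4, 0.45), sc)
#' plts_similarity(a, a, "rational")   # 1
#' @export
plts_similarity <- function(a, b, z_form = "rational",
                            scalarization = c("prob_weighted", "membership")) {
  d <- plts_distance(a, b, match.arg(scalarization))
  similarity_from_distance(d, z_form)
}

#' @rdname plts_similarity
#' @param d a distance in \eqn{[0, 1]}.
#' @export
similarity_from_distance <- function(d, z_form = "rational") {
  z <- get_z(z_form)
  (z(d) - z(1)) / (z(0) - z(1))
}
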