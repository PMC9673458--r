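#' Generate a random PLFCM for property testing
#'
#' Draws a random directed graph without self-loops in which every node
#' state and edge weight is a random PLTS. States are drawn on the given
#' term template with Dirichlet-distributed probabilities (symmetric, with
#' the given concentration); weights pick one to three adjacent terms from
#' the negative-leaning or positive-leaning half of the weight scale
#' according to `sign_mix`. The draw is fully determined by `seed`.
#'
#' The defaults mirror the desk-scale study conditions this package is
#' exercised under: 13 nodes (matching the case study), states on the
#' \eqn{\{s_{-3}, s_0, s_3\}} triple of the 11-term state scale, a 7-term
#' weight scale, edge density 0.3 (typical of expert-drawn causal maps,
#' which are sparse), and a 30% share of negative-leaning influences.
#'
#' @param n_nodes number of nodes (>= 2); the last node is the outcome `R`.
#' @param edge_density probability in (0, 1] that any ordered pair carries
#'   an edge.
#' @param sign_mix share of negative-leaning edge weights, in \[0, 1\].
#' @param state_terms integer term indices states are drawn on.
#' @param concentration symmetric Dirichlet concentration for the state and
#'   weight probabilities (1 = uniform on the simplex).
#' @param seed integer random seed; required, so the same spec always
#'   yields the identical model.
#' @param state_scale,weight_scale [pl_scale()]s.
#' @return A [plfcm_model()].
#' @examples
#' m <- generate_synthetic(n_nodes = 6, seed = 42)
#' nrow(m$edges)
#' @export
generate_synthetic <- function(n_nodes = 13, edge_density = 0.3,
                               sign_mix = 0.3,
                               state_terms = c(-3, 0, 3),
                               concentration = 1, seed,
                               state_scale = pl_scale(5),
                               weight_scale = pl_scale(3)) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_nodes < 2) stop("`n_nodes` must be at least 2", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1) {
    stop("`edge_density` must be in (0, 1]", call. = FALSE)
  }
  if (sign_mix < 0 || sign_mix > 1) {
    stop("`sign_mix` must be in [0, 1]", call. = FALSE)
  }
  state_scale <- as_pl_scale(state_scale)
  weight_scale <- as_pl_scale(weight_scale)
  if (any(abs(state_terms) > state_scale$tau)) {
    stop("state terms outside the state scale", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  ids <- c(paste0("C", seq_len(n_nodes - 1)), "R")
  rdirichlet <- function(k) {
    x <- stats::rgamma(k, shape = concentration)
    x / sum(x)
  }
  states <- lapply(ids, function(id) {
    plts(state_terms, rdirichlet(length(state_terms)), state_scale)
  })

  tw <- weight_scale$tau
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < edge_density
  pairs <- pairs[keep, , drop = FALSE]

  weights <- lapply(seq_len(nrow(pairs)), function(e) {
    negative <- stats::runif(1) < sign_mix
    pool <- if (negative) seq(-tw, 0) else seq(0, tw)
    k <- sample(1:min(3, length(pool)), 1)
    start <- sample(seq_len(length(pool) - k + 1), 1)
    terms <- pool[start:(start + k - 1)]
    plts(terms, rdirichlet(k), weight_scale)
  })

  nodes <- data.frame(id = ids, label = ids, group = "synthetic",
                      role = c(rep("factor", n_nodes - 1), "outcome"),
                      stringsAsFactors = FALSE)
  nodes$state <- I(states)
  edges <- if (nrow(pairs)) {
    ed <- pairs
    ed$weight <- I(weights)
    ed
  }
  plfcm_model(nodes, edges, state_scale, weight_scale)
}
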