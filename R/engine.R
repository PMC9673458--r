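#' Hyperbolic-tangent threshold function
#'
#' The squashing map \eqn{f(x) = \tanh(\lambda x)} applied at every
#' iteration to keep activations bounded; the steepness \eqn{\lambda > 0}
#' controls how fast the map saturates (towards \eqn{\tanh(\lambda)} for
#' inputs near 1).
#'
#' @param x numeric input.
#' @param lam steepness \eqn{\lambda > 0}.
#' @return `tanh(lam * x)`, an odd, monotone increasing function of `x` with
#'   values in \eqn{(-1, 1)}.
#' @examples
#' pl_threshold(1, 1)  # 0.7615942
#' @export
pl_threshold <- function(x, lam = 1) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a single positive number", call. = FALSE)
  }
  tanh(lam * x)
}

#' Iteration settings for the inference engine
#'
#' @param lam threshold steepness \eqn{\lambda > 0} (default 1).
#' @param tol convergence threshold on the max-norm change across both
#'   channels (default `1e-6`).
#' @param max_iter iteration cap before the run is classified chaotic
#'   (default 500).
#' @param cycle_window how many past states are scanned for a recurrence
#'   when detecting limit cycles (default 50).
#' @param threshold optional replacement threshold hook, a
#'   `function(x, lam)` mapping \eqn{[0, \infty)} inputs into \eqn{[0, 1]};
#'   `NULL` means [pl_threshold()].
#' @param apply_f_prob whether the threshold is applied to the probability
#'   channel before its per-node renormalisation (default `TRUE`; the
#'   renormalisation makes the printed trajectories insensitive to this
#'   flag's exact placement, so it is kept configurable).
#' @return A list of class `"plfcm_settings"`.
#' @export
plfcm_settings <- function(lam = 1, tol = 1e-6, max_iter = 500,
                           cycle_window = 50, threshold = NULL,
                           apply_f_prob = TRUE) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0,
            is.numeric(tol), length(tol) == 1L, tol > 0,
            is.numeric(max_iter), max_iter >= 1,
            is.numeric(cycle_window), cycle_window >= 1)
  if (!is.null(threshold) && !is.function(threshold)) {
    stop("`threshold` must be NULL or a function(x, lam)", call. = FALSE)
  }
  structure(list(lam = lam, tol = tol, max_iter = as.integer(max_iter),
                 cycle_window = as.integer(cycle_window),
                 threshold = threshold,
                 apply_f_prob = isTRUE(apply_f_prob)),
            class = "plfcm_settings")
}

#' Align a model onto a common position template
#'
#' The two-channel update rule combines states and weights position by
#' position, so every PLTS in the model must first be expanded onto one
#' ordered template. The template is the ascending union of the term indices
#' appearing in any node state (the 13-node case study yields
#' \eqn{(s_{-3}, s_0, s_3)}, hence 3-component state vectors). Node states
#' are expanded by term matching: position \eqn{k} carries the membership
#' \eqn{g} of the template term on the state scale and the node's
#' probability for that term (0 when absent). Edge weights are aligned
#' positionally: their entries are sorted ascending, padded per the
#' zero-probability rule to the template length, and keep the memberships of
#' their own terms under \eqn{g} on the weight scale. (Term-matching weights
#' onto the state template would pin every edge's lowest position to
#' membership 0 and freeze that position of the whole map, which contradicts
#' the model's intended dynamics.)
#'
#' @param model a [plfcm_model()].
#' @return A list with the template, initial membership / probability
#'   matrices (`n` nodes by `l` positions), weight membership / probability
#'   arrays (`n` by `n` by `l`), and the adjacency matrix.
#' @export
plfcm_align <- function(model) {
  stopifnot(inherits(model, "plfcm_model"))
  ids <- model$nodes$id
  n <- length(ids)
  template <- sort(unique(unlist(lapply(model$states, `[[`, "term"))))
  l <- length(template)

  eta0 <- matrix(rep(g_transform(template, model$state_scale), each = n),
                 nrow = n, dimnames = list(ids, paste0("k", seq_len(l))))
  prob0 <- matrix(0, n, l, dimnames = dimnames(eta0))
  for (i in seq_len(n)) {
    st <- plts_normalize(model$states[[ids[i]]])
    prob0[i, match(st$term, template)] <- st$prob
  }

  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  wm <- array(0, c(n, n, l), dimnames = list(ids, ids, NULL))
  wp <- array(0, c(n, n, l), dimnames = list(ids, ids, NULL))
  if (nrow(model$edges) > 0) {
    for (e in seq_len(nrow(model$edges))) {
      j <- model$edges$from[e]   # source
      i <- model$edges$to[e]     # target
      w <- plts_normalize(model$weights[[e]])
      if (length(w) > l) {
        stop(sprintf(
          "edge %s -> %s has %d entries but the position template has %d",
          j, i, length(w), l), call. = FALSE)
      }
      k <- l - length(w)
      term <- c(rep(min(w$term), k), w$term)
      prob <- c(rep(0, k), w$prob)
      adj[j, i] <- TRUE
      wm[j, i, ] <- g_transform(term, model$weight_scale)
      wp[j, i, ] <- prob
    }
  }
  list(template = template, eta0 = eta0, prob0 = prob0,
       wm = wm, wp = wp, adj = adj, ids = ids,
       outcome = model_outcome(model))
}

# One synchronous update of both channels. For node i and position k the
# incoming influence is the probabilistic sum over source nodes j with an
# edge j -> i:
#   a_i^k = 1 - prod_j (1 - eta_j^k * w_{ji}^k)
# and the new membership is f(eta_i^k (+) a_i^k) with (+) the probabilistic
# sum. The probability channel is updated analogously with the edge-weight
# probabilities, then renormalised so each node's probability row sums to 1.
plfcm_step_ <- function(eta, prob, layout, settings) {
  f <- settings$threshold
  if (is.null(f)) f <- function(x, lam) tanh(lam * x)
  n <- nrow(eta); l <- ncol(eta)
  new_eta <- eta
  new_prob <- prob
  for (k in seq_len(l)) {
    wm_k <- matrix(layout$wm[, , k], n, n)
    wp_k <- matrix(layout$wp[, , k], n, n)
    fac_e <- 1 - (eta[, k] * wm_k) * layout$adj
    fac_p <- 1 - (prob[, k] * wp_k) * layout$adj
    a_e <- 1 - apply(fac_e, 2, prod)
    a_p <- 1 - apply(fac_p, 2, prod)
    new_eta[, k] <- f(eta[, k] + a_e - eta[, k] * a_e, settings$lam)
    x_p <- prob[, k] + a_p - prob[, k] * a_p
    new_prob[, k] <- if (settings$apply_f_prob) f(x_p, settings$lam) else x_p
  }
  rs <- rowSums(new_prob)
  if (any(rs <= 0)) {
    stop("degenerate probability row (sums to 0) during iteration",
         call. = FALSE)
  }
  list(eta = new_eta, prob = new_prob / rs)
}

#' One iteration of the two-channel update rule
#'
#' Exposed mainly for inspection and testing; [plfcm_run()] drives the
#' iteration to a terminal state.
#'
#' @param eta,prob node-by-position membership and probability matrices (as
#'   produced by [plfcm_align()]).
#' @param model a [plfcm_model()] (used for its alignment), or the result of
#'   [plfcm_align()] itself.
#' @param settings a [plfcm_settings()].
#' @return A list with the updated `eta` and `prob` matrices.
#' @export
plfcm_step <- function(eta, prob, model, settings = plfcm_settings()) {
  layout <- if (inherits(model, "plfcm_model")) plfcm_align(model) else model
  if (any(!is.finite(eta)) || any(!is.finite(prob))) {
    stop("non-finite state input", call. = FALSE)
  }
  plfcm_step_(eta, prob, layout, settings)
}

#' Run a PLFCM to its terminal state
#'
#' Iterates the two-channel update synchronously until one of the three
#' terminal behaviours is reached: a fixed point (the max-norm change over
#' all nodes, positions and both channels drops to `tol` or below), a limit
#' cycle (the current state recurs, within `tol`, among the last
#' `cycle_window` states), or a chaotic classification when `max_iter` is
#' exhausted without either.
#'
#' @param model a [plfcm_model()] with at least its states; a model without
#'   edges is legal (each node then evolves autonomously).
#' @param settings a [plfcm_settings()].
#' @return An object of class `"plfcm_trace"`: arrays `membership` and
#'   `probability` of dimension (steps + 1) x nodes x positions recording
#'   the whole history (step 1 is the initial state), the terminal `status`
#'   (`"fixed_point"`, `"limit_cycle"` or `"chaotic"`), `n_iter`, and
#'   `cycle_length` (NA unless a cycle was found).
#' @examples
#' m <- plfcm_model(
#'   nodes = data.frame(id = c("C1", "R"),
#'                      state = c("{s-3:0.3, s3:0.7}",
#'                                "{s-3:0.15, s0:0.4, s3:0.45}"),
#'                      role = c("factor", "outcome")),
#'   edges = data.frame(from = "C1", to = "R", weight = "{s2:1}")
#' )
#' tr <- plfcm_run(m)
#' tr$status
#' @export
plfcm_run <- function(model, settings = plfcm_settings()) {
  stopifnot(inherits(model, "plfcm_model"),
            inherits(settings, "plfcm_settings"))
  layout <- plfcm_align(model)
  n <- length(layout$ids); l <- length(layout$template)

  eta_hist <- array(NA_real_, c(settings$max_iter + 1L, n, l),
                    dimnames = list(NULL, layout$ids, NULL))
  prob_hist <- eta_hist
  eta <- layout$eta0; prob <- layout$prob0
  eta_hist[1, , ] <- eta; prob_hist[1, , ] <- prob

  status <- "chaotic"; n_iter <- settings$max_iter; cycle_length <- NA_integer_
  for (t in seq_len(settings$max_iter)) {
    nxt <- plfcm_step_(eta, prob, layout, settings)
    eta_hist[t + 1, , ] <- nxt$eta
    prob_hist[t + 1, , ] <- nxt$prob
    delta <- max(abs(nxt$eta - eta), abs(nxt$prob - prob))
    eta <- nxt$eta; prob <- nxt$prob
    if (delta <= settings$tol) {
      status <- "fixed_point"; n_iter <- t
      break
    }
    # recurrence against states before the immediate predecessor
    first <- max(1L, t + 1L - settings$cycle_window)
    hit <- NA_integer_
    if (t - 1L >= first) {
      for (s in first:(t - 1L)) {
        diff <- max(abs(eta_hist[s, , ] - eta), abs(prob_hist[s, , ] - prob))
        if (diff <= settings$tol) { hit <- s; break }
      }
    }
    if (!is.na(hit)) {
      status <- "limit_cycle"; n_iter <- t
      cycle_length <- (t + 1L) - hit
      break
    }
  }
  keep <- seq_len(n_iter + 1L)
  structure(list(membership = eta_hist[keep, , , drop = FALSE],
                 probability = prob_hist[keep, , , drop = FALSE],
                 status = status, n_iter = n_iter,
                 cycle_length = cycle_length,
                 template = layout$template, ids = layout$ids,
                 outcome = layout$outcome, settings = settings),
            class = "plfcm_trace")
}

#' @export
print.plfcm_trace <- function(x, ...) {
  cat(sprintf("<plfcm_trace> %s after %d iteration(s); %d nodes, %d positions\n",
              x$status, x$n_iter, length(x$ids), length(x$template)))
  if (!is.na(x$cycle_length)) cat("  cycle length:", x$cycle_length, "\n")
  invisible(x)
}

#' Back-transform a converged trace into steady-state PLTSs
#'
#' Maps the final membership matrix through the inverse equivalent
#' transformation on the state scale (term values are generally
#' non-integer) and attaches the final probability channel, yielding one
#' PLTS per node — the "steady value of concepts" that the similarity
#' ranking operates on.
#'
#' @param trace a `"plfcm_trace"` with `status == "fixed_point"`.
#' @param model the [plfcm_model()] that produced it.
#' @return A named list of [plts()], one per node.
#' @export
steady_state_plts <- function(trace, model) {
  stopifnot(inherits(trace, "plfcm_trace"))
  if (trace$status != "fixed_point") {
    stop("trace did not converge (status: ", trace$status, ")",
         call. = FALSE)
  }
  last <- dim(trace$membership)[1]
  n <- length(trace$ids); l <- length(trace$template)
  eta <- matrix(trace$membership[last, , , drop = FALSE], n, l)
  prob <- matrix(trace$probability[last, , , drop = FALSE], n, l)
  out <- vector("list", length(trace$ids))
  names(out) <- trace$ids
  for (i in seq_along(trace$ids)) {
    term <- g_inverse(eta[i, ], model$state_scale)
    out[[i]] <- new_plts(term, prob[i, ], model$state_scale, sort = FALSE)
  }
  out
}

#' Export a trace in long format
#'
#' @param x a `"plfcm_trace"`.
#' @param ... unused.
#' @return A data frame with columns `step` (0 = initial state), `node`,
#'   `position`, `membership` and `probability`.
#' @export
as.data.frame.plfcm_trace <- function(x, ...) {
  steps <- dim(x$membership)[1]
  n <- length(x$ids); l <- length(x$template)
  grid <- expand.grid(step = seq_len(steps) - 1L,
                      node = x$ids, position = seq_len(l),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$membership <- as.vector(x$membership)
  grid$probability <- as.vector(x$probability)
  grid[order(grid$step, match(grid$node, x$ids), grid$position), ,
       drop = FALSE]
}
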