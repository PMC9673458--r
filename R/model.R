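#' Build a probabilistic linguistic fuzzy cognitive map
#'
#' A PLFCM is a directed graph \eqn{G = (C, E, X, f)}: concept nodes with
#' PLTS-valued initial states, PLTS-valued directed edge weights, and a
#' threshold function driving the iteration. Exactly one node plays the
#' `outcome` role (the quantity the remaining factor nodes are ranked
#' against); self-edges are not allowed because a node never drives itself
#' directly in the update rule.
#'
#' @param nodes a data frame with columns `id` (unique short symbols such as
#'   `C1`..`C12`, `R`), `state` (PLTS text, see [plts_parse()], or a list
#'   column of [plts()]), and optionally `label`, `group` (first-level
#'   category) and `role` (`"factor"` or `"outcome"`; defaults to `factor`
#'   except for a node with id `R`).
#' @param edges `NULL` (edgeless model) or a data frame with columns `from`,
#'   `to` and `weight` (PLTS text or list column of [plts()]).
#' @param state_scale,weight_scale [pl_scale()]s for states (default
#'   \eqn{\tau = 5}) and weights (default \eqn{\tau = 3}).
#' @return An object of class `"plfcm_model"`.
#' @examples
#' m <- plfcm_model(
#'   nodes = data.frame(
#'     id = c("C1", "R"),
#'     state = c("{s-3:0.3, s3:0.7}", "{s-3:0.15, s0:0.4, s3:0.45}"),
#'     role = c("factor", "outcome")
#'   ),
#'   edges = data.frame(from = "C1", to = "R", weight = "{s2:0.6, s3:0.4}")
#' )
#' @export
plfcm_model <- function(nodes, edges = NULL,
                        state_scale = pl_scale(5),
                        weight_scale = pl_scale(3)) {
  state_scale <- as_pl_scale(state_scale)
  weight_scale <- as_pl_scale(weight_scale)
  stopifnot(is.data.frame(nodes), nrow(nodes) >= 1)
  if (!all(c("id", "state") %in% names(nodes))) {
    stop("`nodes` needs columns `id` and `state`", call. = FALSE)
  }
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) stop("node ids must be unique", call. = FALSE)

  role <- if ("role" %in% names(nodes)) as.character(nodes$role) else
    ifelse(ids == "R", "outcome", "factor")
  role[is.na(role) | role == ""] <- "factor"
  if (!all(role %in% c("factor", "outcome"))) {
    stop("node roles must be 'factor' or 'outcome'", call. = FALSE)
  }
  if (sum(role == "outcome") != 1L) {
    stop("exactly one node must have role 'outcome'", call. = FALSE)
  }

  states <- coerce_plts_column(nodes$state, state_scale, "state", ids)
  for (i in seq_along(states)) {
    plts_normalize(states[[i]])  # errors on an all-zero probability vector
  }
  names(states) <- ids

  node_df <- data.frame(
    id = ids,
    label = if ("label" %in% names(nodes)) as.character(nodes$label) else ids,
    group = if ("group" %in% names(nodes)) as.character(nodes$group) else "",
    role = role,
    stringsAsFactors = FALSE
  )

  edge_df <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  weights <- list()
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0) {
    edges <- as.data.frame(edges)
    if (!all(c("from", "to", "weight") %in% names(edges))) {
      stop("`edges` needs columns `from`, `to` and `weight`", call. = FALSE)
    }
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (any(!from %in% ids) || any(!to %in% ids)) {
      bad <- setdiff(unique(c(from, to)), ids)
      stop("edge endpoint(s) not among node ids: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(from == to)) {
      stop("self-edges are not allowed", call. = FALSE)
    }
    if (anyDuplicated(paste(from, to))) {
      stop("duplicate edges", call. = FALSE)
    }
    weights <- coerce_plts_column(edges$weight, weight_scale, "weight",
                                  paste(from, "->", to))
    for (w in weights) plts_normalize(w)
    edge_df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  }

  structure(list(nodes = node_df, states = states,
                 edges = edge_df, weights = weights,
                 state_scale = state_scale, weight_scale = weight_scale),
            class = "plfcm_model")
}

coerce_plts_column <- function(col, scale, what, who) {
  out <- vector("list", length(col))
  for (i in seq_along(col)) {
    v <- if (is.list(col)) col[[i]] else col[i]
    out[[i]] <- tryCatch({
      if (inherits(v, "plts")) {
        if (v$scale$tau != scale$tau) stop("scale mismatch")
        v
      } else {
        plts_parse(as.character(v), scale)
      }
    }, error = function(e) {
      stop("invalid ", what, " PLTS for ", who[i], ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out
}

#' @export
print.plfcm_model <- function(x, ...) {
  cat(sprintf("<plfcm_model> %d nodes (%s outcome), %d edges\n",
              nrow(x$nodes), x$nodes$id[x$nodes$role == "outcome"],
              nrow(x$edges)))
  cat(sprintf("  state scale tau = %g, weight scale tau = %g\n",
              x$state_scale$tau, x$weight_scale$tau))
  invisible(x)
}

model_outcome <- function(model) {
  model$nodes$id[model$nodes$role == "outcome"]
}

model_factors <- function(model) {
  model$nodes$id[model$nodes$role == "factor"]
}
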