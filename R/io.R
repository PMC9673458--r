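#' Read and write PLFCM model files
#'
#' A model file is a YAML document with blocks `scale_state` / `scale_weight`
#' (each with a `tau` field), `nodes` (id, label, group, role, `state` as
#' PLTS text) and optional `edges` (from, to, `weight` as PLTS text). Files
#' written by [write_plfcm_model()] round-trip through [read_plfcm_model()]
#' bit-exactly at the PLTS-string level.
#'
#' @param path file path.
#' @return [read_plfcm_model()] returns a [plfcm_model()];
#'   [write_plfcm_model()] returns `path` invisibly.
#' @export
read_plfcm_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$nodes)) stop("model file has no `nodes` block", call. = FALSE)
  state_scale <- pl_scale(doc$scale_state$tau %||% 5,
                          doc$scale_state$labels)
  weight_scale <- pl_scale(doc$scale_weight$tau %||% 3,
                           doc$scale_weight$labels)
  nodes <- do.call(rbind, lapply(doc$nodes, function(nd) {
    data.frame(id = nd$id, label = nd$label %||% nd$id,
               group = nd$group %||% "", role = nd$role %||% "factor",
               state = nd$state, stringsAsFactors = FALSE)
  }))
  edges <- NULL
  if (!is.null(doc$edges) && length(doc$edges)) {
    edges <- do.call(rbind, lapply(doc$edges, function(e) {
      data.frame(from = e$from, to = e$to, weight = e$weight,
                 stringsAsFactors = FALSE)
    }))
  }
  plfcm_model(nodes, edges, state_scale, weight_scale)
}

#' @rdname read_plfcm_model
#' @param model a [plfcm_model()].
#' @export
write_plfcm_model <- function(model, path) {
  stopifnot(inherits(model, "plfcm_model"))
  doc <- list(
    scale_state = c(list(tau = model$state_scale$tau),
                    if (!is.null(model$state_scale$labels))
                      list(labels = model$state_scale$labels)),
    scale_weight = c(list(tau = model$weight_scale$tau),
                     if (!is.null(model$weight_scale$labels))
                       list(labels = model$weight_scale$labels)),
    nodes = lapply(seq_len(nrow(model$nodes)), function(i) {
      nd <- model$nodes[i, ]
      list(id = nd$id, label = nd$label, group = nd$group, role = nd$role,
           state = plts_format(model$states[[nd$id]]))
    }),
    edges = if (nrow(model$edges)) {
      lapply(seq_len(nrow(model$edges)), function(e) {
        list(from = model$edges$from[e], to = model$edges$to[e],
             weight = plts_format(model$weights[[e]]))
      })
    }
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PLTS-valued connection matrix
#'
#' The matrix dialect for transcribing a published (or elicited) connection
#' matrix: a delimited table whose first column holds the source node ids,
#' whose header holds the target node ids, and whose cells are PLTS strings
#' (blank for "no edge"). Cell (row `j`, column `i`) is the influence of
#' concept `j` on concept `i`.
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `from`, `to`, `weight` (PLTS text),
#'   suitable for [attach_matrix()].
#' @export
read_connection_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                         colClasses = "character")
  from_ids <- rownames(tab)
  to_ids <- colnames(tab)
  out <- list()
  for (j in seq_along(from_ids)) {
    for (i in seq_along(to_ids)) {
      cell <- trimws(tab[j, i])
      if (is.na(cell) || !nzchar(cell)) next
      out[[length(out) + 1L]] <- data.frame(
        from = from_ids[j], to = to_ids[i], weight = cell,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0),
                      weight = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Attach a connection matrix to a model
#'
#' Replaces the model's edge set with the one read from a connection-matrix
#' file (or data frame), validating node ids and PLTS cells with row/column
#' context in error messages.
#'
#' @param model a [plfcm_model()] (its states are kept).
#' @param matrix a path to a matrix CSV, or a data frame with columns
#'   `from`, `to`, `weight`.
#' @return A [plfcm_model()] with the new edges.
#' @export
attach_matrix <- function(model, matrix) {
  stopifnot(inherits(model, "plfcm_model"))
  edges <- if (is.character(matrix)) read_connection_matrix(matrix)
           else as.data.frame(matrix)
  ids <- model$nodes$id
  unknown <- setdiff(unique(c(edges$from, edges$to)), ids)
  if (length(unknown)) {
    stop("connection matrix names unknown node id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  nodes <- model$nodes
  nodes$state <- I(unname(model$states[nodes$id]))
  plfcm_model(nodes, if (nrow(edges)) edges else NULL,
              model$state_scale, model$weight_scale)
}

#' Write an empty connection-matrix template
#'
#' Produces a CSV skeleton with the model's node ids as both row and column
#' labels and empty cells, ready for transcribing an externally published
#' connection matrix into the dialect [read_connection_matrix()] consumes.
#'
#' @param model a [plfcm_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_template <- function(model, path) {
  ids <- model$nodes$id
  tab <- matrix("", length(ids), length(ids),
                dimnames = list(ids, ids))
  utils::write.csv(as.data.frame(tab), path, quote = TRUE)
  invisible(path)
}
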