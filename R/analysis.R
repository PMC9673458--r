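#' Rank causal factors by similarity to the outcome concept
#'
#' Runs the map to its fixed point, back-transforms the steady state, and
#' computes the Z-mapping similarity between each factor's steady PLTS and
#' the outcome node's steady PLTS. Rank 1 is the highest similarity (the
#' factor whose settled behaviour tracks the outcome most closely); tied
#' similarities share the mean of the tied rank positions. First-level group
#' scores are arithmetic means of member ranks, so a *lower* group score
#' marks a more influential category.
#'
#' @param model a [plfcm_model()] with edges attached.
#' @param settings a [plfcm_settings()].
#' @param z_form Z-mapping id (see [plts_similarity()]); the rational form
#'   \eqn{Z(t) = (1-t)/(1+t)} is the default.
#' @return An object of class `"similarity_ranking"`: a data frame
#'   `ranking` (factor id, label, group, similarity, rank), a data frame
#'   `group_scores`, and the run metadata.
#' @seealso [sensitivity_z()], [sensitivity_lambda()], [hflcm_run()],
#'   [fcm_run()]
#' @export
rank_factors <- function(model, settings = plfcm_settings(),
                         z_form = "rational") {
  trace <- plfcm_run(model, settings)
  if (trace$status != "fixed_point") {
    stop("model did not reach a fixed point (status: ", trace$status,
         "); cannot rank factors", call. = FALSE)
  }
  steady <- steady_state_plts(trace, model)
  ranking_from_steady(model, steady, z_form, settings$lam,
                      scalarization = "prob_weighted", mode = "plfcm",
                      trace = trace)
}

ranking_from_steady <- function(model, steady, z_form, lam, scalarization,
                                mode, trace = NULL) {
  out_id <- model_outcome(model)
  fac_ids <- model_factors(model)
  sim <- vapply(fac_ids, function(id) {
    plts_similarity(steady[[id]], steady[[out_id]], z_form = z_form,
                    scalarization = scalarization)
  }, 1)
  build_ranking(model, fac_ids, sim, z_form, lam, mode, trace)
}

build_ranking <- function(model, fac_ids, sim, z_form, lam, mode,
                          trace = NULL) {
  rk <- rank(-sim, ties.method = "average")
  info <- model$nodes[match(fac_ids, model$nodes$id), ]
  ranking <- data.frame(id = fac_ids, label = info$label,
                        group = info$group, similarity = unname(sim),
                        rank = unname(rk), stringsAsFactors = FALSE)
  gs <- if (any(nzchar(ranking$group))) {
    agg <- tapply(ranking$rank, ranking$group, mean)
    data.frame(group = names(agg), score = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = character(0), score = numeric(0))
  }
  structure(list(ranking = ranking, group_scores = gs,
                 z_form = if (is.function(z_form)) "custom" else z_form,
                 lam = lam, mode = mode, trace = trace),
            class = "similarity_ranking")
}

#' @export
print.similarity_ranking <- function(x, digits = 4, ...) {
  cat(sprintf("<similarity_ranking> mode = %s, Z = %s, lambda = %g\n",
              x$mode, x$z_form, x$lam))
  df <- x$ranking[order(x$ranking$rank), ]
  df$similarity <- round(df$similarity, digits)
  print(df, row.names = FALSE)
  if (nrow(x$group_scores)) {
    cat("group scores (mean member rank; lower = more influential):\n")
    print(x$group_scores[order(x$group_scores$score), ], row.names = FALSE)
  }
  invisible(x)
}

#' Sensitivity of the ranking to the Z-mapping form
#'
#' The steady state does not depend on Z, so the map is run once and the
#' similarity list is recomputed under each requested Z form. Because every
#' supported Z is strictly decreasing, ranks depend only on the ordering of
#' the underlying distances and the rank vectors should agree across forms;
#' the result carries an explicit agreement flag.
#'
#' @inheritParams rank_factors
#' @param z_list character vector of Z forms to compare (default all four).
#' @return A list of class `"z_sensitivity"`: one `"similarity_ranking"` per
#'   Z form, a wide comparison table, and `ranks_agree`.
#' @export
sensitivity_z <- function(model, settings = plfcm_settings(),
                          z_list = z_form_names()) {
  trace <- plfcm_run(model, settings)
  if (trace$status != "fixed_point") {
    stop("model did not reach a fixed point (status: ", trace$status, ")",
         call. = FALSE)
  }
  steady <- steady_state_plts(trace, model)
  rankings <- lapply(z_list, function(z) {
    ranking_from_steady(model, steady, z, settings$lam,
                        "prob_weighted", "plfcm")
  })
  names(rankings) <- z_list
  tab <- rankings[[1]]$ranking[, c("id", "group")]
  for (z in z_list) {
    tab[[paste0("similarity_", z)]] <- rankings[[z]]$ranking$similarity
    tab[[paste0("rank_", z)]] <- rankings[[z]]$ranking$rank
  }
  rank_mat <- sapply(rankings, function(r) r$ranking$rank)
  agree <- all(apply(rank_mat, 1, function(v) length(unique(v)) == 1L))
  structure(list(rankings = rankings, table = tab, ranks_agree = agree),
            class = "z_sensitivity")
}

#' @export
print.z_sensitivity <- function(x, ...) {
  cat("<z_sensitivity> ranks agree across Z forms:", x$ranks_agree, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of the ranking to the threshold steepness
#'
#' Reruns the whole pipeline for each steepness value and reports, per
#' \eqn{\lambda}, the similarity list, ranks, and the similarity spread
#' (max minus min). Larger \eqn{\lambda} saturates the threshold harder, so
#' steady states crowd together and the spread shrinks — small
#' \eqn{\lambda} gives the sharpest discrimination between factors.
#'
#' @inheritParams rank_factors
#' @param lambdas numeric grid of steepness values (default
#'   `c(2, 3, 4, 6, 8, 10)`).
#' @return A list of class `"lambda_sensitivity"`: one
#'   `"similarity_ranking"` per lambda, a long table, and a data frame
#'   `spread` with the per-lambda similarity range.
#' @export
sensitivity_lambda <- function(model, lambdas = c(2, 3, 4, 6, 8, 10),
                               settings = plfcm_settings(),
                               z_form = "rational") {
  stopifnot(is.numeric(lambdas), length(lambdas) >= 1, all(lambdas > 0))
  rankings <- lapply(lambdas, function(lm) {
    s <- settings; s$lam <- lm
    rank_factors(model, s, z_form)
  })
  names(rankings) <- as.character(lambdas)
  tab <- do.call(rbind, lapply(seq_along(lambdas), function(i) {
    df <- rankings[[i]]$ranking
    df$lambda <- lambdas[i]
    df
  }))
  spread <- data.frame(
    lambda = lambdas,
    spread = vapply(rankings, function(r) {
      max(r$ranking$similarity) - min(r$ranking$similarity)
    }, 1)
  )
  structure(list(rankings = rankings, table = tab, spread = spread,
                 z_form = z_form),
            class = "lambda_sensitivity")
}

#' @export
print.lambda_sensitivity <- function(x, ...) {
  cat("<lambda_sensitivity> Z =", x$z_form, "\n")
  print(x$spread, row.names = FALSE)
  invisible(x)
}

#' Hesitant fuzzy linguistic baseline (probabilities disregarded)
#'
#' The degenerate model obtained by dropping the probabilities attached to
#' linguistic terms. The membership channel of the full model never reads
#' probabilities, so the baseline's iteration history is identical to the
#' membership channel of [plfcm_run()]; only the similarity step changes —
#' distances are computed on the bare membership vectors with uniform
#' position weights.
#'
#' @inheritParams rank_factors
#' @return A `"similarity_ranking"` with `mode = "hflcm"`.
#' @export
hflcm_run <- function(model, settings = plfcm_settings(),
                      z_form = "rational") {
  trace <- plfcm_run(model, settings)
  if (trace$status != "fixed_point") {
    stop("model did not reach a fixed point (status: ", trace$status, ")",
         call. = FALSE)
  }
  steady <- steady_state_plts(trace, model)
  ranking_from_steady(model, steady, z_form, settings$lam,
                      scalarization = "membership", mode = "hflcm",
                      trace = trace)
}

#' Classical crisp fuzzy-cognitive-map baseline
#'
#' The degenerate model obtained by score-defuzzifying every PLTS: a node's
#' initial activation is the equivalent transformation of its state score
#' (an unsigned value in \eqn{[0, 1]}), and each edge weight is its score on
#' the weight scale divided by \eqn{\tau} (a signed crisp weight in
#' \eqn{[-1, 1]}, preserving negative influences). The classical update
#' \deqn{x_i(t+1) = f\bigl(x_i(t) + \sum_{j \ne i} x_j(t)\, w_{ji}\bigr)}
#' uses the plain (unbounded) sum, so with \eqn{\lambda = 1} steady
#' activations can approach 1. Similarities use \eqn{|x_i - x_R|} as the
#' distance fed to the Z-mapping.
#'
#' @inheritParams rank_factors
#' @return A `"similarity_ranking"` with `mode = "fcm"`; its `trace` field
#'   is a (steps + 1) x nodes matrix of crisp activations.
#' @export
fcm_run <- function(model, settings = plfcm_settings(),
                    z_form = "rational") {
  stopifnot(inherits(model, "plfcm_model"))
  ids <- model$nodes$id
  n <- length(ids)
  x <- vapply(ids, function(id) {
    g_transform(plts_score(model$states[[id]]), model$state_scale)
  }, 1)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(model$edges) > 0) {
    for (e in seq_len(nrow(model$edges))) {
      w[model$edges$from[e], model$edges$to[e]] <-
        plts_score(model$weights[[e]]) / model$weight_scale$tau
    }
  }
  f <- settings$threshold
  if (is.null(f)) f <- function(v, lam) tanh(lam * v)

  hist <- matrix(NA_real_, settings$max_iter + 1L, n,
                 dimnames = list(NULL, ids))
  hist[1, ] <- x
  status <- "chaotic"; n_iter <- settings$max_iter; cycle_length <- NA_integer_
  for (t in seq_len(settings$max_iter)) {
    nxt <- f(x + drop(crossprod(w, x)), settings$lam)
    hist[t + 1, ] <- nxt
    delta <- max(abs(nxt - x))
    x <- nxt
    if (delta <= settings$tol) { status <- "fixed_point"; n_iter <- t; break }
    first <- max(1L, t + 1L - settings$cycle_window)
    if (t - 1L >= first) {
      for (s in first:(t - 1L)) {
        if (max(abs(hist[s, ] - x)) <= settings$tol) {
          status <- "limit_cycle"; n_iter <- t
          cycle_length <- (t + 1L) - s
          break
        }
      }
      if (status == "limit_cycle") break
    }
  }
  if (status != "fixed_point") {
    stop("crisp baseline did not reach a fixed point (status: ", status,
         ")", call. = FALSE)
  }
  out_id <- model_outcome(model)
  fac_ids <- model_factors(model)
  xs <- hist[n_iter + 1L, ]
  sim <- vapply(fac_ids, function(id) {
    similarity_from_distance(min(abs(xs[id] - xs[out_id]), 1), z_form)
  }, 1)
  res <- build_ranking(model, fac_ids, sim, z_form, settings$lam, "fcm")
  res$trace <- hist[seq_len(n_iter + 1L), , drop = FALSE]
  res$status <- status
  res
}
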