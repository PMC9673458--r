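# Shared fixtures and independent (naive) oracles used across test files.

rand_plts <- function(tau = 5, max_len = 4) {
  k <- sample(seq_len(max_len), 1)
  terms <- sort(sample(seq(-tau, tau), k))
  p <- runif(k)
  plts(terms, p / sum(p), pl_scale(tau))
}

expect_plts_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$term, b$term, tolerance = tol)
  expect_equal(a$prob, b$prob, tolerance = tol)
}

# Explicit double-loop enumeration of a Cartesian PLTS operator, merged the
# same way (sum probabilities of equal memberships); independent of the
# package's vectorised path.
naive_cartesian <- function(a, b, combine) {
  tau <- a$scale$tau
  eta <- c(); p <- c()
  for (i in seq_along(a$term)) {
    for (j in seq_along(b$term)) {
      e1 <- (a$term[i] + tau) / (2 * tau)
      e2 <- (b$term[j] + tau) / (2 * tau)
      eta <- c(eta, combine(e1, e2))
      p <- c(p, a$prob[i] * b$prob[j])
    }
  }
  o <- order(eta); eta <- eta[o]; p <- p[o]
  out_eta <- c(); out_p <- c()
  for (m in seq_along(eta)) {
    if (length(out_eta) && abs(eta[m] - out_eta[length(out_eta)]) <= 1e-12) {
      out_p[length(out_p)] <- out_p[length(out_p)] + p[m]
    } else {
      out_eta <- c(out_eta, eta[m]); out_p <- c(out_p, p[m])
    }
  }
  list(eta = out_eta, prob = out_p)
}

# Naive per-node, per-position double loop over the update rule.
naive_step <- function(eta, prob, layout, lam) {
  n <- nrow(eta); l <- ncol(eta)
  ne <- eta; np <- prob
  for (i in seq_len(n)) {
    for (k in seq_len(l)) {
      ae <- 1; ap <- 1
      for (j in seq_len(n)) {
        if (layout$adj[j, i]) {
          ae <- ae * (1 - eta[j, k] * layout$wm[j, i, k])
          ap <- ap * (1 - prob[j, k] * layout$wp[j, i, k])
        }
      }
      ae <- 1 - ae; ap <- 1 - ap
      ne[i, k] <- tanh(lam * (eta[i, k] + ae - eta[i, k] * ae))
      np[i, k] <- tanh(lam * (prob[i, k] + ap - prob[i, k] * ap))
    }
  }
  list(eta = ne, prob = np / rowSums(np))
}

# Small always-convergent models: complete positive digraphs. Weights carry
# positive probability at every template position so both channels settle.
saturating_model <- function(n = 5) {
  complete_positive(n, state = "{s-3:0.2, s0:0.3, s3:0.5}",
                    weight = "{s1:0.2, s2:0.3, s3:0.5}")
}

# Every initial membership below the eventual fixed point, so the orbit
# rises monotonically.
low_start_model <- function(n = 4) {
  complete_positive(n, state = "{s-3:0.5, s-1:0.5}",
                    weight = "{s2:0.5, s3:0.5}")
}

complete_positive <- function(n, state, weight) {
  nodes <- data.frame(
    id = c(paste0("C", seq_len(n - 1)), "R"),
    state = state,
    role = c(rep("factor", n - 1), "outcome"))
  pairs <- expand.grid(from = nodes$id, to = nodes$id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$weight <- weight
  plfcm_model(nodes, pairs)
}

demo_case_model <- function() {
  load_case_study(synthetic_matrix_path())
}
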