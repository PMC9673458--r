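test_that("threshold function is tanh(lambda x) with the expected shape", {
  expect_equal(pl_threshold(0, 5), 0)
  expect_equal(pl_threshold(1, 1), tanh(1))
  x <- seq(-2, 2, by = 0.25)
  expect_equal(pl_threshold(-x, 2), -pl_threshold(x, 2))
  expect_true(all(diff(pl_threshold(x, 0.7)) > 0))
  expect_error(pl_threshold(1, 0), "positive")
})

test_that("alignment builds the ascending union template over node states", {
  m <- demo_case_model()
  layout <- plfcm_align(m)
  expect_equal(layout$template, c(-3, 0, 3))
  expect_equal(unname(layout$eta0[1, ]), c(0.2, 0.5, 0.8))
  expect_true(all(apply(layout$eta0, 1, function(r)
    all(r == c(0.2, 0.5, 0.8)))))
  # probability rows carry each node's own triple
  expect_equal(unname(layout$prob0["C10", ]), c(0.6, 0.35, 0.05))
  expect_equal(unname(layout$prob0["R", ]), c(0.15, 0.4, 0.45))

  # all-singleton model collapses to one position
  m1 <- plfcm_model(data.frame(id = c("C1", "R"),
                               state = c("{s3:1}", "{s3:1}"),
                               role = c("factor", "outcome")))
  expect_equal(length(plfcm_align(m1)$template), 1)

  # mixed supports: template length = number of distinct indices
  m2 <- plfcm_model(data.frame(
    id = c("C1", "R"),
    state = c("{s-3:0.5, s1:0.5}", "{s0:0.4, s3:0.6}"),
    role = c("factor", "outcome")))
  expect_equal(plfcm_align(m2)$template, c(-3, 0, 1, 3))
})

test_that("edge weights align positionally with zero-probability padding", {
  m <- plfcm_model(
    nodes = data.frame(id = c("C1", "R"),
                       state = c("{s-3:0.3, s0:0.2, s3:0.5}",
                                 "{s-3:0.15, s0:0.4, s3:0.45}"),
                       role = c("factor", "outcome")),
    edges = data.frame(from = "C1", to = "R", weight = "{s1:0.4, s2:0.6}"))
  layout <- plfcm_align(m)
  # weight has 2 entries on a 3-slot template: smallest term repeats first
  expect_equal(layout$wm["C1", "R", ], g_transform(c(1, 1, 2), 3))
  expect_equal(layout$wp["C1", "R", ], c(0, 0.4, 0.6))
})

test_that("a node without incoming edges evolves by the bare threshold", {
  m <- plfcm_model(
    nodes = data.frame(id = c("C1", "R"),
                       state = c("{s-3:0.3, s0:0.2, s3:0.5}",
                                 "{s-3:0.15, s0:0.4, s3:0.45}"),
                       role = c("factor", "outcome")),
    edges = data.frame(from = "C1", to = "R", weight = "{s2:1}"))
  layout <- plfcm_align(m)
  s <- plfcm_step(layout$eta0, layout$prob0, m,
                  plfcm_settings(lam = 1.3))
  expect_equal(unname(s$eta["C1", ]), tanh(1.3 * c(0.2, 0.5, 0.8)))
})

test_that("a zero-edge map started at the scale bottom fixes at zero immediately", {
  m <- plfcm_model(data.frame(id = c("C1", "R"),
                              state = c("{s-5:1}", "{s-5:1}"),
                              role = c("factor", "outcome")))
  tr <- plfcm_run(m)
  expect_equal(tr$status, "fixed_point")
  expect_lte(tr$n_iter, 2)
  expect_equal(max(abs(tr$membership)), 0)
})

test_that("all-positive saturating map converges into the high-membership band", {
  m <- saturating_model(5)
  tr <- plfcm_run(m)
  expect_equal(tr$status, "fixed_point")
  last <- dim(tr$membership)[1]
  steady <- tr$membership[last, , ]
  expect_true(all(steady >= 0.75))
  expect_true(all(steady <= tanh(1) + 1e-9))
})

test_that("with positive weights and a low start memberships rise monotonically", {
  m <- low_start_model(4)
  tr <- plfcm_run(m)
  expect_equal(tr$status, "fixed_point")
  steps <- dim(tr$membership)[1]
  expect_true(all(vapply(2:steps, function(t) {
    all(tr$membership[t, , ] - tr$membership[t - 1, , ] >= -1e-9)
  }, TRUE)))
})

test_that("trace invariants hold on seeded random models", {
  for (seed in c(1, 4, 5)) {
    m <- generate_synthetic(n_nodes = 7, seed = seed)
    st <- plfcm_settings(lam = 1.5, max_iter = 40)
    tr <- plfcm_run(m, st)
    steps <- dim(tr$membership)[1]
    expect_true(all(tr$membership >= 0 & tr$membership <= 1))
    # after the first update every membership is capped by tanh(lambda)
    expect_true(all(tr$membership[-1, , ] <= tanh(st$lam) + 1e-9))
    for (t in seq_len(steps)) {
      expect_equal(unname(rowSums(matrix(tr$probability[t, , ],
                                         length(tr$ids)))),
                   rep(1, length(tr$ids)), tolerance = 1e-9)
    }
  }
})

test_that("vectorized step equals the naive per-node per-position loop", {
  set.seed(61)
  for (seed in 1:8) {
    m <- generate_synthetic(n_nodes = sample(3:6, 1), edge_density = 0.5,
                            seed = seed)
    layout <- plfcm_align(m)
    st <- plfcm_settings(lam = runif(1, 0.5, 3))
    got <- plfcm_step(layout$eta0, layout$prob0, m, st)
    want <- naive_step(layout$eta0, layout$prob0, layout, st$lam)
    expect_equal(got$eta, want$eta, tolerance = 1e-12)
    expect_equal(got$prob, want$prob, tolerance = 1e-12)
  }
})

test_that("a decreasing threshold hook produces a detected period-2 cycle", {
  m <- plfcm_model(data.frame(id = c("C1", "R"),
                              state = c("{s-3:0.3, s3:0.7}",
                                        "{s-2:0.6, s2:0.4}"),
                              role = c("factor", "outcome")))
  tr <- plfcm_run(m, plfcm_settings(threshold = function(x, lam) 1 - x))
  expect_equal(tr$status, "limit_cycle")
  expect_equal(tr$cycle_length, 2)
})

test_that("runs that settle neither way are classified chaotic at the cap", {
  m <- demo_case_model()
  tr <- plfcm_run(m, plfcm_settings(max_iter = 5))
  expect_equal(tr$status, "chaotic")
  expect_equal(tr$n_iter, 5)
  expect_error(steady_state_plts(tr, m), "did not converge")
})

test_that("steady-state PLTSs back-transform the final matrices exactly", {
  m <- demo_case_model()
  tr <- plfcm_run(m)
  steady <- steady_state_plts(tr, m)
  last <- dim(tr$membership)[1]
  for (i in seq_along(tr$ids)) {
    id <- tr$ids[i]
    expect_equal(g_transform(steady[[id]]$term, m$state_scale),
                 unname(tr$membership[last, i, ]), tolerance = 1e-12)
    expect_equal(steady[[id]]$prob, unname(tr$probability[last, i, ]))
    expect_equal(sum(steady[[id]]$prob), 1, tolerance = 1e-9)
  }
})

test_that("trace exports to long format with one row per step-node-position", {
  m <- saturating_model(3)
  tr <- plfcm_run(m)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), (tr$n_iter + 1) * 3 * length(tr$template))
  expect_named(df, c("step", "node", "position", "membership", "probability"))
  expect_equal(df$membership[df$step == 0 & df$node == "C1"],
               unname(tr$membership[1, "C1", ]))
})
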