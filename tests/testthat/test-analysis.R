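test_that("factor ranking orders by similarity with ranks a permutation", {
  m <- demo_case_model()
  rk <- rank_factors(m)
  expect_s3_class(rk, "similarity_ranking")
  expect_equal(sort(rk$ranking$rank), 1:12)
  expect_equal(rk$ranking$id[rk$ranking$rank == 1],
               rk$ranking$id[which.max(rk$ranking$similarity)])
  expect_true(all(rk$ranking$similarity >= 0 & rk$ranking$similarity <= 1))
  # group scores are hand-computable means of member ranks
  for (g in rk$group_scores$group) {
    members <- rk$ranking$rank[rk$ranking$group == g]
    expect_equal(rk$group_scores$score[rk$group_scores$group == g],
                 mean(members))
  }
  expect_error(rank_factors(m, plfcm_settings(max_iter = 4)), "chaotic")
})

test_that("identical factors tie and share the mean rank", {
  nodes <- data.frame(
    id = c("C1", "C2", "R"),
    state = c("{s-3:0.3, s3:0.7}", "{s-3:0.3, s3:0.7}",
              "{s-3:0.15, s0:0.4, s3:0.45}"),
    role = c("factor", "factor", "outcome"))
  edges <- data.frame(from = c("C1", "C2", "R", "R"),
                      to = c("R", "R", "C1", "C2"),
                      weight = "{s2:0.5, s3:0.5}")
  m <- plfcm_model(nodes, edges)
  rk <- rank_factors(m)
  expect_equal(rk$ranking$similarity[1], rk$ranking$similarity[2])
  expect_equal(rk$ranking$rank, c(1.5, 1.5))
})

test_that("ranks are invariant across the four Z-mapping forms", {
  m <- demo_case_model()
  sz <- sensitivity_z(m)
  expect_true(sz$ranks_agree)
  rank_cols <- grep("^rank_", names(sz$table))
  expect_equal(length(rank_cols), 4)
  for (col in rank_cols[-1]) {
    expect_equal(sz$table[[col]], sz$table[[rank_cols[1]]])
  }
  # similarities themselves differ between forms
  expect_false(isTRUE(all.equal(sz$table$similarity_linear,
                                sz$table$similarity_rational)))
})

test_that("similarity spread shrinks as the threshold steepens", {
  m <- demo_case_model()
  sl <- sensitivity_lambda(m, lambdas = c(2, 6, 10))
  expect_true(all(diff(sl$spread$spread) <= 1e-12))
  expect_gt(sl$spread$spread[1], sl$spread$spread[3])
  for (r in sl$rankings) expect_equal(sort(r$ranking$rank), 1:12)
})

test_that("hesitant baseline reuses the identical membership history", {
  for (seed in c(5, 13)) {
    m <- generate_synthetic(n_nodes = 8, seed = seed)
    main <- rank_factors(m)
    base <- hflcm_run(m)
    expect_identical(base$trace$membership, main$trace$membership)
    expect_true(all(base$ranking$similarity >= 0 &
                      base$ranking$similarity <= 1))
    expect_equal(base$mode, "hflcm")
  }
})

test_that("membership channel never reads probabilities", {
  # same support everywhere, different probabilities => same memberships
  m1 <- generate_synthetic(n_nodes = 6, seed = 9)
  m2 <- m1
  set.seed(99)
  m2$states <- lapply(m1$states, function(s) {
    p <- runif(length(s$term)); plts(s$term, p / sum(p), s$scale)
  })
  m2$weights <- lapply(m1$weights, function(w) {
    p <- runif(length(w$term)); plts(w$term, p / sum(p), w$scale)
  })
  st <- plfcm_settings(max_iter = 30)
  t1 <- plfcm_run(m1, st); t2 <- plfcm_run(m2, st)
  n <- min(dim(t1$membership)[1], dim(t2$membership)[1])
  expect_identical(t1$membership[seq_len(n), , ],
                   t2$membership[seq_len(n), , ])
})

test_that("crisp baseline defuzzifies states through score and g", {
  m <- load_case_study()
  x0 <- vapply(m$nodes$id, function(id) {
    g_transform(plts_score(m$states[[id]]), m$state_scale)
  }, 1)
  expect_equal(unname(x0),
               c(0.65, 0.65, 0.35, 0.62, 0.71, 0.56, 0.62, 0.395, 0.515,
                 0.335, 0.47, 0.62, 0.59))
})

test_that("crisp baseline iterates the plain-sum update to a fixed point", {
  m <- demo_case_model()
  rk <- fcm_run(m)
  expect_equal(rk$mode, "fcm")
  expect_equal(rk$status, "fixed_point")
  expect_equal(unname(rk$trace[1, ]),
               vapply(m$nodes$id, function(id) {
                 g_transform(plts_score(m$states[[id]]), m$state_scale)
               }, 1, USE.NAMES = FALSE))
  # plain sums can push activations past tanh(lambda * 1)
  expect_gt(max(rk$trace), tanh(1))
  expect_equal(sort(rk$ranking$rank), 1:12)

  # zero matrix: x(t+1) = tanh(x(t)), decaying towards 0
  m0 <- plfcm_model(data.frame(id = c("C1", "R"),
                               state = c("{s3:1}", "{s-3:0.5, s3:0.5}"),
                               role = c("factor", "outcome")))
  rk0 <- fcm_run(m0, plfcm_settings(tol = 1e-4, max_iter = 500))
  expect_lt(max(abs(rk0$trace[nrow(rk0$trace), ])), 0.15)
})
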