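test_that("normalization rescales probabilities proportionally and is idempotent", {
  sc <- pl_scale(5)
  a <- plts(c(-3, 0), c(0.5, 0.5), sc)
  expect_plts_equal(plts_normalize(a), a)

  b <- plts_normalize(plts(c(-1, 1), c(0.2, 0.2), pl_scale(3)))
  expect_equal(b$prob, c(0.5, 0.5))

  # divide by 0.9
  cc <- plts_normalize(plts(c(-3, 0, 3), c(0.45, 0.30, 0.15), sc))
  expect_equal(cc$prob, c(0.5, 1 / 3, 1 / 6))
  expect_plts_equal(plts_normalize(cc), cc)

  expect_error(plts_normalize(plts(0, 0, sc)), "all zero")
})

test_that("constructor and parser reject invalid input", {
  sc <- pl_scale(3)
  expect_error(plts(c(1, 1), c(0.5, 0.5), sc), "distinct")
  expect_error(plts(4, 1, sc), "outside")
  expect_error(plts(1.5, 1, sc), "integers")
  expect_error(plts(1, 1.2, sc), "\\[0, 1\\]")
  expect_error(plts(c(0, 1), c(0.8, 0.8), sc), "at most 1")
  expect_error(plts_parse("{s1-0.5}", sc), "malformed")
  expect_error(pl_scale(0), "positive integer")
  expect_error(pl_scale(2, labels = c("a", "b")), "2 \\* tau \\+ 1")
})

test_that("PLTS text syntax round-trips and accepts arbitrary entry order", {
  sc <- pl_scale(5)
  x <- plts_parse("{s3:0.45, s0:0.4, s-3:0.15}", sc)
  expect_equal(x$term, c(-3, 0, 3))
  expect_equal(x$prob, c(0.15, 0.4, 0.45))
  expect_identical(plts_format(x), "{s-3:0.15, s0:0.4, s3:0.45}")
  expect_plts_equal(plts_parse(plts_format(x), sc), x)
})

test_that("padding extends the shorter operand with zero-probability terms", {
  sc <- pl_scale(5)
  a <- plts(c(-3, 0, 3), c(0.2, 0.3, 0.5), sc)
  same <- plts_pad_pair(a, a)
  expect_plts_equal(same$a, a)
  expect_plts_equal(same$b, a)

  b <- plts(0, 1, sc)
  cc <- plts(c(-1, 1), c(0.5, 0.5), sc)
  p <- plts_pad_pair(b, cc)
  expect_equal(length(p$a), 2)
  expect_equal(p$a$prob, c(0, 1))
  expect_equal(p$a$term, c(0, 0))      # smallest term repeated
  expect_plts_equal(p$b, cc)
  # padded pair feeds the distance at common length l = 2
  expect_silent(d <- plts_distance(b, cc))
  expect_gte(d, 0); expect_lte(d, 1)

  expect_error(plts_pad_pair(b, plts(0, 1, pl_scale(3))), "different scales")
})

test_that("score is the probability-weighted expectation of term indices", {
  sc <- pl_scale(5)
  expect_equal(plts_score(plts(2, 1, sc)), 2)
  expect_equal(plts_score(plts(c(-1, 1), c(0.5, 0.5), sc)), 0)
  expect_equal(plts_score(plts(c(-3, 0, 3), c(0.15, 0.40, 0.45), sc)), 0.9)
  # computed on the standard form: raw sums rescale away
  expect_equal(plts_score(plts(c(-3, 3), c(0.2, 0.2), sc)), 0)
})

test_that("complement negates terms, keeps probabilities, and is an involution", {
  sc <- pl_scale(3)
  expect_plts_equal(plts_complement(plts(3, 1, sc)), plts(-3, 1, sc))
  expect_plts_equal(plts_complement(plts(0, 1, sc)), plts(0, 1, sc))
  set.seed(11)
  for (i in 1:50) {
    a <- rand_plts(tau = 4)
    expect_plts_equal(plts_complement(plts_complement(a)), a)
  }
})

test_that("expert pooling averages per-term probability mass", {
  sc <- pl_scale(3)
  e1 <- plts_parse("{s-3:0.6, s-1:0.3, s0:0.1}", sc)
  e2 <- plts_parse("{s-3:0.5, s0:0.5}", sc)
  e3 <- plts_parse("{s-3:0.4, s-2:0.3, s0:0.3}", sc)
  pooled <- plts_aggregate(list(e1, e2, e3))
  expect_equal(pooled$term, c(-3, -2, -1, 0))
  expect_equal(pooled$prob, c(0.5, 0.1, 0.1, 0.3))

  expect_plts_equal(plts_aggregate(list(e1)), plts_normalize(e1))
  expect_plts_equal(plts_aggregate(list(e2, e2)), plts_normalize(e2))

  expect_error(plts_aggregate(list()), "non-empty")
  expect_error(plts_aggregate(list(e1, e2), weights = c(1)), "one entry per")
  expect_error(plts_aggregate(list(e1, e2), weights = c(0.7, 0.7)), "sum to 1")
})
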