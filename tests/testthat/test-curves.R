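test_that("time normalization preserves constants, ramps and endpoints", {
  win <- list(start = 10, end = 110)
  const <- tibble::tibble(frame = 10:109, value = 3.5)
  out <- time_normalize(const, win)
  expect_equal(nrow(out), 101)
  expect_true(all(out$value == 3.5))

  ramp <- tibble::tibble(frame = 10:109, value = seq(0, 99))
  out2 <- time_normalize(ramp, win)
  expect_equal(out2$value[1], 0)
  expect_equal(out2$value[101], 99)
  expect_equal(out2$value, seq(0, 99, length.out = 101), tolerance = 1e-12)

  # renormalizing an already node-indexed series is the identity
  again <- time_normalize(
    tibble::tibble(frame = 0:100, value = out2$value),
    list(start = 0, end = 101))
  expect_equal(again$value, out2$value, tolerance = 1e-12)

  expect_error(time_normalize(tibble::tibble(frame = 1, value = 1),
                              list(start = 1, end = 2)), "short")
})

test_that("element aggregation sums forces and strength-weights
          activations", {
  act <- tibble::tibble(
    frame = 1,
    element = c("a1", "a2", "b1"),
    group = c("glut", "glut", "other"),
    side = "r",
    activation = c(0.4, 0.4, 0.9),
    force = c(30, 70, 10)
  )
  agg <- aggregate_elements(act)
  glut <- agg[agg$muscle == "glut", ]
  expect_equal(glut$activation, 0.4)
  expect_equal(glut$force, 100)
  # singleton groups are identities
  other <- agg[agg$muscle == "other", ]
  expect_equal(other$activation, 0.9)
  expect_equal(other$force, 10)
  # strength weighting bounded by element range
  agg2 <- aggregate_elements(act, strengths = c(a1 = 100, a2 = 900, b1 = 1))
  g2 <- agg2$activation[agg2$muscle == "glut"]
  expect_gte(g2, 0.4); expect_lte(g2, 0.4)

  act$group <- NULL
  expect_error(aggregate_elements(act, grouping = c(a1 = "glut")),
               "without a group")
})

test_that("body-weight normalization is exact and invertible", {
  cur <- tibble::tibble(force = 700, moment = 70)
  out <- normalize_loads(cur, 700)
  expect_equal(out$force, 1)
  expect_equal(out$moment, 0.1)
  back <- out
  back$force <- back$force * 700
  back$moment <- back$moment * 700
  expect_equal(back, cur)
  expect_error(normalize_loads(cur, 0), "positive")
})

test_that("left trials mirror the mediolateral axis only, idempotently", {
  cur <- tidyr::expand_grid(side = c("left", "right"),
                            axis = c("x", "y", "z"))
  cur$force <- c(1, 2, 3, 4, 5, 6)
  m1 <- mirror_left_to_right(cur)
  expect_equal(m1$force[m1$side == "left"], c(1, -2, 3))
  expect_equal(m1$force[m1$side == "right"], c(4, 5, 6))
  m2 <- mirror_left_to_right(m1)
  expect_equal(m2$force, m1$force)
  expect_error(mirror_left_to_right(dplyr::select(cur, -side)), "side")
})
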