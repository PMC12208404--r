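test_that("single-muscle and symmetric-agonist frames solve in closed form", {
  cfg <- redundancy_config()
  one <- solve_frame(matrix(0.05, 1, 1), 1000, 25, cfg)
  expect_equal(unname(one$activations), 0.5, tolerance = 1e-9)
  expect_equal(one$status, "ok")

  two <- solve_frame(matrix(0.05, 1, 2), c(1000, 1000), 25, cfg)
  expect_equal(unname(two$activations), c(0.25, 0.25), tolerance = 1e-9)
})

test_that("the cubic-criterion KKT solution a_i ~ sqrt(r_i F_i) holds and
          matches brute-force search", {
  cfg <- redundancy_config()
  set.seed(2)
  r <- runif(5, 0.02, 0.08)
  Fm <- runif(5, 500, 2000)
  sol <- solve_frame(matrix(r, 1, 5), Fm, 30, cfg)
  ratio <- sol$activations / sol$activations[1]
  pred <- sqrt(r * Fm) / sqrt(r[1] * Fm[1])
  expect_lt(max(abs(ratio - pred)), 1e-6)
  expect_lt(max(abs(sol$residual)), 1e-6 * 30)

  r3 <- c(0.05, 0.03, 0.06); F3 <- c(800, 1200, 600); M <- 20
  sol3 <- solve_frame(matrix(r3, 1, 3), F3, M, cfg)
  grid <- seq(0, 1, by = 0.004)
  best <- c(Inf, 0, 0, 0)
  for (a1 in grid) for (a2 in grid) {
    a3 <- (M - a1 * r3[1] * F3[1] - a2 * r3[2] * F3[2]) / (r3[3] * F3[3])
    if (a3 >= 0) {
      v <- a1^3 + a2^3 + a3^3
      if (v < best[1]) best <- c(v, a1, a2, a3)
    }
  }
  expect_lt(max(abs(sol3$activations - best[2:4])), 0.004)
})

test_that("degenerate and edge frames behave as specified", {
  cfg <- redundancy_config()
  # zero demand -> zero activation
  z <- solve_frame(matrix(c(0.05, -0.03), 1, 2), c(500, 500), 0, cfg)
  expect_equal(unname(z$activations), c(0, 0))
  # infeasible direction flagged, least-squares answer returned
  inf <- solve_frame(matrix(c(0.05, 0.03), 1, 2), c(1000, 1000), -10, cfg)
  expect_equal(inf$status, "infeasible")
  # doubling strengths strictly lowers every nonzero activation
  set.seed(3)
  r <- runif(6, 0.02, 0.08); Fm <- runif(6, 400, 1500)
  s1 <- solve_frame(matrix(r, 1, 6), Fm, 25, cfg)
  s2 <- solve_frame(matrix(r, 1, 6), 2 * Fm, 25, cfg)
  nz <- s1$activations > 1e-9
  expect_true(all(s2$activations[nz] < s1$activations[nz]))
  # overload is flagged but solved under the default policy
  ov <- solve_frame(matrix(0.05, 1, 1), 100, 25, cfg)
  expect_equal(ov$status, "overload")
  expect_equal(unname(ov$activations), 5, tolerance = 1e-9)
  # and capped under the cap policy
  cap <- solve_frame(matrix(0.05, 1, 2), c(1000, 1000), 80,
                     redundancy_config(bound_policy = "cap_at_1"))
  expect_true(all(cap$activations <= 1 + 1e-9))
})

test_that("the minimiser is unique: column permutations commute with the
          solve", {
  cfg <- redundancy_config()
  set.seed(4)
  A <- matrix(rnorm(10 * 60, sd = 0.04), 10, 60)
  st <- runif(60, 200, 2500)
  M <- rnorm(10, 0, 25)
  base <- solve_frame(A, st, M, cfg)
  perm <- sample(60)
  shuffled <- solve_frame(A[, perm], st[perm], M, cfg)
  expect_lt(max(abs(shuffled$activations[order(perm)] - base$activations)),
            1e-8)
})

test_that("stride solutions balance the demanded moments at every frame", {
  tr <- fix("trial_clean")
  kin <- fix("kin_clean")
  fr <- stride_frames(tr)
  loads_s <- fix("loads_clean")[fix("loads_clean")$frame %in% fr, ]
  sol <- solve_stride(fix("model_human"), kin, loads_s)
  expect_true(all(sol$frames$residual <=
                    1e-6 * pmax(sol$frames$max_moment, 1)))
  expect_true(all(sol$activations$activation >= 0))
  expect_false(any(sol$frames$status == "infeasible"))

  # zero net moments -> all zero activations
  zero_loads <- loads_s
  zero_loads$moment <- 0
  sol0 <- solve_stride(fix("model_human"), kin, zero_loads,
                       frames = fr[1:3])
  expect_equal(max(sol0$activations$activation), 0)
})

test_that("muscle-inclusive reactions reduce to intersegmental forces when
          nothing is active, and add single-muscle pulls vectorially", {
  tr <- fix("trial_clean")
  kin <- fix("kin_clean")
  fr <- stride_frames(tr)[1:4]
  loads_s <- fix("loads_clean")[fix("loads_clean")$frame %in% fr, ]
  sol <- solve_stride(fix("model_human"), kin, loads_s, frames = fr)

  quiet <- sol
  quiet$activations$activation <- 0
  quiet$activations$force <- 0
  jrf0 <- joint_reaction_with_muscles(fix("model_human"), kin, quiet,
                                      loads_s, side = "right")
  base <- loads_s[loads_s$joint == "hip" & loads_s$side == "right", ]
  expect_equal(jrf0$force,
               base$force[order(base$frame, match(base$axis, c("x", "y", "z")))],
               tolerance = 1e-9)

  # exactly one active muscle shifts the reaction by its pull vector
  single <- quiet
  el <- "gluteus_medius_r05"
  idx <- single$activations$element == el &
    single$activations$frame == fr[1]
  single$activations$force[idx] <- 500
  jrf1 <- joint_reaction_with_muscles(fix("model_human"), kin, single,
                                      loads_s, side = "right")
  dv <- jrf1$force[jrf1$frame == fr[1]] - jrf0$force[jrf0$frame == fr[1]]
  expect_equal(sqrt(sum(dv^2)), 500, tolerance = 1e-9)
  expect_gt(dv[3], 0)  # abductor pulls the pelvis down onto the head: +Z contact
})
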