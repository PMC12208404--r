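# Analytic single-pendulum hip moment: I_hip * thdd + m g d sin(th),
# with I_hip = I_com + m d^2, theta measured from straight-down.
test_that("the hip moment of a swinging thigh matches the pendulum closed
          form to near machine precision", {
  m1 <- 8.3; d1 <- 0.19; I1 <- 0.14; l1 <- 0.44
  toy <- toy_leg_model(m1 = m1, d1 = d1, I1 = I1, l1 = l1, m2 = 0, I2 = 0)
  fs <- 100
  t <- seq(0, 1.5, by = 1 / fs)
  th <- 0.4 * sin(2 * pi * 1.1 * t) + 0.1
  thd <- 0.4 * 2 * pi * 1.1 * cos(2 * pi * 1.1 * t)
  thdd <- -0.4 * (2 * pi * 1.1)^2 * sin(2 * pi * 1.1 * t)
  q <- coord_matrix(toy, length(t), list(hip_flexion_r = th))
  qd <- coord_matrix(toy, length(t), list(hip_flexion_r = thd))
  qdd <- coord_matrix(toy, length(t), list(hip_flexion_r = thdd))
  kin <- toy_kinematics(toy, q, qd, qdd, fs)
  loads <- net_joint_loads(toy, kin, toy_trial(kin$frames, fs))
  hip_y <- loads$moment[loads$joint == "hip" & loads$axis == "y"]
  # flexion is rotation about -Y: generalized torque = -M_y
  tau <- -hip_y
  g <- 9.80665
  expected <- (I1 + m1 * d1^2) * thdd + m1 * g * d1 * sin(th)
  expect_lt(max(abs(tau - expected)) / max(abs(expected)), 1e-8)
})

# Independent oracle: planar two-link equations of motion in absolute
# angles (standard double-pendulum dynamics), mapped to hip/knee torques
# through the virtual-work transform.
test_that("Newton-Euler agrees with the Lagrangian two-link derivation", {
  m1 <- 7.5; d1 <- 0.18; I1 <- 0.11; l1 <- 0.42
  m2 <- 3.2; d2 <- 0.16; I2 <- 0.05; l2 <- 0.40
  toy <- toy_leg_model(m1, d1, I1, l1, m2, d2, I2, l2)
  fs <- 100
  t <- seq(0, 1.2, by = 1 / fs)
  th1 <- 0.35 * sin(2 * pi * t) + 0.05          # hip flexion
  th1d <- 0.35 * 2 * pi * cos(2 * pi * t)
  th1dd <- -0.35 * (2 * pi)^2 * sin(2 * pi * t)
  thk <- 0.5 + 0.3 * sin(2 * pi * 1.3 * t + 1)  # knee flexion
  thkd <- 0.3 * 2 * pi * 1.3 * cos(2 * pi * 1.3 * t + 1)
  thkdd <- -0.3 * (2 * pi * 1.3)^2 * sin(2 * pi * 1.3 * t + 1)

  q <- coord_matrix(toy, length(t),
                    list(hip_flexion_r = th1, knee_flexion_r = thk))
  qd <- coord_matrix(toy, length(t),
                     list(hip_flexion_r = th1d, knee_flexion_r = thkd))
  qdd <- coord_matrix(toy, length(t),
                      list(hip_flexion_r = th1dd, knee_flexion_r = thkdd))
  kin <- toy_kinematics(toy, q, qd, qdd, fs)
  loads <- net_joint_loads(toy, kin, toy_trial(kin$frames, fs))

  # absolute link angles from vertical-down, positive forward
  a1 <- th1; a1d <- th1d; a1dd <- th1dd
  a2 <- th1 - thk; a2d <- th1d - thkd; a2dd <- th1dd - thkdd
  g <- 9.80665
  M11 <- I1 + m1 * d1^2 + m2 * l1^2
  M22 <- I2 + m2 * d2^2
  h <- m2 * l1 * d2
  Q1 <- M11 * a1dd + h * cos(a1 - a2) * a2dd + h * sin(a1 - a2) * a2d^2 +
    (m1 * d1 + m2 * l1) * g * sin(a1)
  Q2 <- M22 * a2dd + h * cos(a1 - a2) * a1dd - h * sin(a1 - a2) * a1d^2 +
    m2 * g * d2 * sin(a2)
  tau_hip <- Q1 + Q2
  tau_knee <- -Q2

  got_hip <- -loads$moment[loads$joint == "hip" & loads$axis == "y"]
  got_knee <- loads$moment[loads$joint == "knee" & loads$axis == "y"]
  expect_lt(max(abs(got_hip - tau_hip)) / max(abs(tau_hip)), 1e-8)
  expect_lt(max(abs(got_knee - tau_knee)) / max(abs(tau_knee)), 1e-8)
})

test_that("zero gravity, zero motion and zero external force give zero
          loads", {
  toy <- toy_leg_model()
  q <- coord_matrix(toy, 20)
  kin <- toy_kinematics(toy, q, q * 0, q * 0)
  loads <- net_joint_loads(toy, kin, toy_trial(kin$frames), gravity = 0)
  expect_lt(max(abs(loads$moment)), 1e-12)
  expect_lt(max(abs(loads$force)), 1e-12)
})

test_that("static stance transfers body weight minus the stance leg to the
          hip", {
  m <- fix("model_human")
  sub <- fix("subject")
  bw <- sub$body_mass * 9.80665
  q <- neutral_posture(m)
  n <- 30
  qmat <- matrix(rep(q, each = n), n, length(q),
                 dimnames = list(NULL, names(q)))
  kin <- toy_kinematics(m, qmat, qmat * 0, qmat * 0)
  trial <- toy_trial(kin$frames, fz1 = bw, cop1 = c(0.02, -sub$hip_breadth / 2, 0))
  loads <- net_joint_loads(m, kin, trial)
  leg_mass <- sum(vapply(m$segments[c("thigh_r", "shank_r", "talus_r",
                                      "foot_r")], `[[`, numeric(1), "mass"))
  hip_z <- loads$force[loads$joint == "hip" & loads$side == "right" &
                         loads$axis == "z"]
  expect_equal(mean(hip_z), bw - leg_mass * 9.80665, tolerance = 1e-6 * bw)
  expect_true(all(hip_z > 0))
})

test_that("whole-body residuals are small on consistent trials and scale
          linearly with a ground-force error", {
  res <- residual_loads(fix("model_human"), fix("kin_clean"),
                        fix("trial_clean"))
  fr <- stride_frames(fix("trial_clean"))
  bw <- fix("subject")$body_mass * 9.80665
  expect_lt(max(abs(res$force[res$frame %in% fr])) / bw, 0.01)

  inflated <- fix("trial_clean")
  inflated$grf$fz <- inflated$grf$fz * 1.1
  res2 <- residual_loads(fix("model_human"), fix("kin_clean"), inflated)
  keep_r <- res$axis == "z" & res$frame %in% fr
  keep_g <- fix("trial_clean")$grf$frame %in% fr
  dz <- res$force[keep_r] - res2$force[res2$axis == "z" & res2$frame %in% fr]
  gz <- tapply(fix("trial_clean")$grf$fz[keep_g],
               fix("trial_clean")$grf$frame[keep_g], sum)
  expect_equal(dz, as.numeric(0.1 * gz), tolerance = 1e-3)
})

test_that("residual magnitude is invariant to a rigid lab rotation", {
  tr <- fix("trial_clean")
  ang <- 0.6
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3)
  rot <- tr
  mkr <- as.matrix(tr$markers[, c("x", "y", "z")]) %*% t(Rz)
  rot$markers$x <- mkr[, 1]; rot$markers$y <- mkr[, 2]; rot$markers$z <- mkr[, 3]
  for (cols in list(c("fx", "fy", "fz"), c("copx", "copy", "copz"))) {
    v <- as.matrix(tr$grf[, cols]) %*% t(Rz)
    rot$grf[[cols[1]]] <- v[, 1]; rot$grf[[cols[2]]] <- v[, 2]
    rot$grf[[cols[3]]] <- v[, 3]
  }
  kin_rot <- fit_kinematics(rot, fix("model_human"))
  res0 <- residual_loads(fix("model_human"), fix("kin_clean"), tr)
  res1 <- residual_loads(fix("model_human"), kin_rot, rot)
  n0 <- tapply(res0$force, res0$frame, function(f) sqrt(sum(f^2)))
  n1 <- tapply(res1$force, res1$frame, function(f) sqrt(sum(f^2)))
  fr <- as.character(stride_frames(tr))
  expect_equal(n1[fr], n0[fr], tolerance = 1e-6)
})

test_that("a left-first trial mirrors the right-first loads", {
  tr_r <- fix("trial_clean")
  tr_l <- generate_gait_trial(fix("subject"), trial_seed = 7, noise_sd = 0,
                              jitter = 0, side = "left")
  kin_l <- fit_kinematics(tr_l, fix("model_human"))
  loads_r <- fix("loads_clean")
  loads_l <- net_joint_loads(fix("model_human"), kin_l, tr_l)
  fr <- stride_frames(tr_r)
  pick <- function(ld, side, axis) {
    ld$force[ld$joint == "hip" & ld$side == side & ld$axis == axis &
               ld$frame %in% fr]
  }
  expect_equal(pick(loads_l, "left", "z"), pick(loads_r, "right", "z"),
               tolerance = 1e-6)
  expect_equal(pick(loads_l, "left", "y"), -pick(loads_r, "right", "y"),
               tolerance = 1e-6)
  expect_equal(pick(loads_l, "left", "x"), pick(loads_r, "right", "x"),
               tolerance = 1e-6)
})

test_that("stride extraction returns the half-open event window", {
  tr <- fix("trial_clean")
  s <- extract_stride(tr)
  expect_equal(s$start, tr$events$ic)
  expect_equal(s$end, tr$events$ipsi_ic)
  expect_equal(s$n_frames, tr$events$ipsi_ic - tr$events$ic)
  expect_equal(s$side, "right")
  expect_equal(s$n_frames / tr$sample_rate, tr$stride_period,
               tolerance = 1.01 / tr$sample_rate)
  broken <- tr
  broken$events$ipsi_ic <- NULL
  expect_error(extract_stride(broken), "ipsilateral")
})
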