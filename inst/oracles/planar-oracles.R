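# Closed-form planar pendulum oracles for validating the inverse-dynamics
# pass. Each builds a minimal hand-specified rigid-segment model, drives
# it with analytic trajectories, and returns the maximum relative
# discrepancy between the package's Newton-Euler joint moments and the
# textbook Lagrangian solution.

planar_model <- function(m1, d1, I1, l1, m2, d2, I2, l2) {
  seg <- function(name, parent, joint_location, rotations, mass, com, I,
                  length) {
    list(name = name, parent = parent, joint_location = joint_location,
         rotations = rotations, mass = mass, com = com,
         inertia = diag(rep(I, 3)), length = length)
  }
  structure(list(
    segments = list(
      pelvis = seg("pelvis", NA, NULL,
                   list(list(axis = c(0, 0, 1), coord = "pelvis_rotation"),
                        list(axis = c(1, 0, 0), coord = "pelvis_list"),
                        list(axis = c(0, 1, 0), coord = "pelvis_tilt")),
                   0, c(0, 0, 0), 0, 0.1),
      thigh_r = seg("thigh_r", "pelvis", c(0, 0, 0),
                    list(list(axis = c(0, -1, 0), coord = "hip_flexion_r")),
                    m1, c(0, 0, -d1), I1, l1),
      shank_r = seg("shank_r", "thigh_r", c(0, 0, -l1),
                    list(list(axis = c(0, 1, 0), coord = "knee_flexion_r")),
                    m2, c(0, 0, -d2), I2, l2)
    ),
    order = c("pelvis", "thigh_r", "shank_r"),
    coord_names = c("pelvis_x", "pelvis_y", "pelvis_z", "pelvis_rotation",
                    "pelvis_list", "pelvis_tilt", "hip_flexion_r",
                    "knee_flexion_r"),
    muscles = tibble::tibble(element = character(), group = character(),
                             side = character(), max_strength = numeric(),
                             path = list()),
    markers = tibble::tibble(marker = character(), segment = character(),
                             point = list()),
    dims = list(), subject = tibble::tibble()
  ), class = "skeleton_model")
}

planar_kin <- function(model, values, fs = 100) {
  n <- length(values$q[[1]])
  mk <- function(part) {
    m <- matrix(0, n, length(model$coord_names),
                dimnames = list(NULL, model$coord_names))
    for (nm in names(part)) m[, nm] <- part[[nm]]
    m
  }
  structure(list(q = mk(values$q), q_filt = mk(values$q), qd = mk(values$qd),
                 qdd = mk(values$qdd), time = seq_len(n) / fs,
                 frames = seq_len(n) - 1, sample_rate = fs,
                 marker_rms = numeric(n), filter_cutoff = fs / 2.0001),
            class = "kinematics_trajectory")
}

zero_trial <- function(frames, fs = 100) {
  grf <- do.call(rbind, lapply(frames, function(f) {
    data.frame(frame = f, time = f / fs, plate = c(1L, 2L), fx = 0, fy = 0,
               fz = 0, copx = 0, copy = 0, copz = 0, tz = 0)
  }))
  structure(list(subject = tibble::tibble(), side = "right",
                 sample_rate = fs, walking_speed = 1, stride_period = 1,
                 markers = tibble::tibble(frame = frames),
                 grf = tibble::as_tibble(grf),
                 events = list(ic = frames[1],
                               ipsi_ic = frames[length(frames)]),
                 plate_sides = c(plate1 = "right", plate2 = "left")),
            class = "gait_trial")
}

pendulum_relative_error <- function() {
  m1 <- 8.3; d1 <- 0.19; I1 <- 0.14
  model <- planar_model(m1, d1, I1, 0.44, 0, 0.1, 0, 0.4)
  t <- seq(0, 1.5, by = 0.01)
  th <- 0.4 * sin(2 * pi * 1.1 * t) + 0.1
  thd <- 0.4 * 2 * pi * 1.1 * cos(2 * pi * 1.1 * t)
  thdd <- -0.4 * (2 * pi * 1.1)^2 * sin(2 * pi * 1.1 * t)
  kin <- planar_kin(model, list(q = list(hip_flexion_r = th),
                                qd = list(hip_flexion_r = thd),
                                qdd = list(hip_flexion_r = thdd)))
  loads <- hipmorph::net_joint_loads(model, kin, zero_trial(kin$frames))
  tau <- -loads$moment[loads$joint == "hip" & loads$axis == "y"]
  expected <- (I1 + m1 * d1^2) * thdd + m1 * 9.80665 * d1 * sin(th)
  max(abs(tau - expected)) / max(abs(expected))
}

two_link_relative_error <- function() {
  m1 <- 7.5; d1 <- 0.18; I1 <- 0.11; l1 <- 0.42
  m2 <- 3.2; d2 <- 0.16; I2 <- 0.05
  model <- planar_model(m1, d1, I1, l1, m2, d2, I2, 0.4)
  t <- seq(0, 1.2, by = 0.01)
  th1 <- 0.35 * sin(2 * pi * t) + 0.05
  th1d <- 0.35 * 2 * pi * cos(2 * pi * t)
  th1dd <- -0.35 * (2 * pi)^2 * sin(2 * pi * t)
  thk <- 0.5 + 0.3 * sin(2 * pi * 1.3 * t + 1)
  thkd <- 0.3 * 2 * pi * 1.3 * cos(2 * pi * 1.3 * t + 1)
  thkdd <- -0.3 * (2 * pi * 1.3)^2 * sin(2 * pi * 1.3 * t + 1)
  kin <- planar_kin(model, list(
    q = list(hip_flexion_r = th1, knee_flexion_r = thk),
    qd = list(hip_flexion_r = th1d, knee_flexion_r = thkd),
    qdd = list(hip_flexion_r = th1dd, knee_flexion_r = thkdd)))
  loads <- hipmorph::net_joint_loads(model, kin, zero_trial(kin$frames))
  a1 <- th1; a2 <- th1 - thk
  g <- 9.80665
  h <- m2 * l1 * d2
  Q1 <- (I1 + m1 * d1^2 + m2 * l1^2) * th1dd +
    h * cos(a1 - a2) * (th1dd - thkdd) +
    h * sin(a1 - a2) * (th1d - thkd)^2 + (m1 * d1 + m2 * l1) * g * sin(a1)
  Q2 <- (I2 + m2 * d2^2) * (th1dd - thkdd) + h * cos(a1 - a2) * th1dd -
    h * sin(a1 - a2) * th1d^2 + m2 * g * d2 * sin(a2)
  got_hip <- -loads$moment[loads$joint == "hip" & loads$axis == "y"]
  got_knee <- loads$moment[loads$joint == "knee" & loads$axis == "y"]
  max(max(abs(got_hip - (Q1 + Q2))) / max(abs(Q1 + Q2)),
      max(abs(got_knee + Q2)) / max(abs(Q2)))
}
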