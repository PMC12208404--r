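# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; no files are read.

fix_env <- new.env()

fix <- function(name) {
  if (!exists(name, fix_env)) {
    fix_env[[name]] <- switch(
      name,
      cohort = generate_cohort(10, 1),
      subject = fix("cohort")[1, ],
      model_human = build_subject_model(hip_shape_params("human_like"),
                                        fix("subject")),
      model_austral = build_subject_model(hip_shape_params("australopith_like"),
                                          fix("subject")),
      # dynamically consistent, measurement-noise-free trial for the
      # dynamics oracles
      trial_clean = generate_gait_trial(fix("subject"), trial_seed = 7,
                                        noise_sd = 0, jitter = 0),
      kin_clean = fit_kinematics(fix("trial_clean"), fix("model_human")),
      loads_clean = net_joint_loads(fix("model_human"), fix("kin_clean"),
                                    fix("trial_clean")),
      stop("unknown fixture: ", name)
    )
  }
  fix_env[[name]]
}

stride_frames <- function(trial) {
  s <- extract_stride(trial)
  seq(s$start, s$end - 1)
}

# Minimal hand-built planar models for analytic oracles. Segment masses,
# com offsets and inertias are chosen freely by the caller; the pelvis is
# a massless fixed base.
toy_leg_model <- function(m1 = 7, d1 = 0.18, I1 = 0.12, l1 = 0.42,
                          m2 = 0, d2 = 0.15, I2 = 0.05, l2 = 0.40,
                          muscles = NULL) {
  seg <- function(name, parent, joint_location, rotations, mass, com, I,
                  length) {
    list(name = name, parent = parent, joint_location = joint_location,
         rotations = rotations, mass = mass, com = com,
         inertia = diag(rep(I, 3)), length = length)
  }
  segments <- list(
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
  )
  if (is.null(muscles)) {
    muscles <- tibble::tibble(element = character(), group = character(),
                              side = character(), max_strength = numeric(),
                              path = list())
  }
  structure(list(
    segments = segments, order = names(segments),
    coord_names = c("pelvis_x", "pelvis_y", "pelvis_z", "pelvis_rotation",
                    "pelvis_list", "pelvis_tilt", "hip_flexion_r",
                    "knee_flexion_r"),
    muscles = muscles,
    markers = tibble::tibble(marker = character(), segment = character(),
                             point = list()),
    dims = list(), subject = tibble::tibble(),
    variant = hip_shape_params("human_like")
  ), class = "skeleton_model")
}

# Kinematics container for hand-specified coordinate trajectories.
toy_kinematics <- function(model, q, qd, qdd, fs = 100) {
  n <- nrow(q)
  structure(list(q = q, q_filt = q, qd = qd, qdd = qdd,
                 time = seq_len(n) / fs, frames = seq_len(n) - 1,
                 sample_rate = fs, marker_rms = numeric(n),
                 filter_cutoff = fs / 2.0001),
            class = "kinematics_trajectory")
}

# Trial stub carrying (optionally zero) plate records for toy models.
toy_trial <- function(frames, fs = 100, fz1 = 0, cop1 = c(0, 0, 0)) {
  grf <- dplyr::bind_rows(lapply(frames, function(f) {
    tibble::tibble(frame = f, time = f / fs, plate = c(1L, 2L),
                   fx = 0, fy = 0, fz = c(fz1, 0),
                   copx = cop1[1], copy = cop1[2], copz = cop1[3], tz = 0)
  }))
  structure(list(
    subject = tibble::tibble(), side = "right", sample_rate = fs,
    walking_speed = 1, stride_period = 1,
    markers = tibble::tibble(frame = frames),
    grf = grf, events = list(ic = frames[1], ipsi_ic = frames[length(frames)]),
    plate_sides = c(plate1 = "right", plate2 = "left")
  ), class = "gait_trial")
}

coord_matrix <- function(model, n, values = list()) {
  q <- matrix(0, n, length(model$coord_names),
              dimnames = list(NULL, model$coord_names))
  for (nm in names(values)) q[, nm] <- values[[nm]]
  q
}

null_curves <- function(n_sub = 10, n_tr = 3, seed = 1, effect = 0,
                        window = 40:60, n_nodes = 101) {
  set.seed(seed)
  nodes <- seq(0, 100, length.out = n_nodes)
  rows <- list()
  for (s in seq_len(n_sub)) {
    base <- cumsum(rnorm(n_nodes, sd = 0.05))
    for (cond in c("A", "B")) {
      for (tr in seq_len(n_tr)) {
        v <- base + rnorm(n_nodes, sd = 0.1) +
          0.3 * sin(2 * pi * nodes / 100 + rnorm(1, sd = 0.2))
        if (cond == "B" && effect != 0) {
          v[window + 1] <- v[window + 1] + effect
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sprintf("S%02d", s), trial = tr, condition = cond,
          node = nodes, value = v)
      }
    }
  }
  dplyr::bind_rows(rows)
}

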