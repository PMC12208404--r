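#' Parametric joint-angle program for synthetic walking
#'
#' The synthetic gait generator poses the skeleton with smooth periodic
#' joint-angle trajectories: each generalized coordinate is a truncated
#' Fourier series `q(t) = a0 + sum_k A_k cos(2 pi k (t/T - phi_k))` over
#' stride phase, so velocities and accelerations are available in closed
#' form and the generated ground reaction forces can be made exactly
#' consistent with the generated motion. Amplitudes are in radians (metres
#' for pelvis translations); phase 0 is the first-side initial contact.
#' The default program emulates level self-selected-speed walking: a
#' single-harmonic ~20 deg hip flexion-extension wave, a two-harmonic knee
#' wave with a small stance bump and a large swing bump, a push-off ankle
#' wave, a double-frequency vertical pelvis oscillation (inverted-pendulum
#' vault, highest at single support, amplitude 15 mm -> the classic
#' two-peaked vertical GRF), and small pelvis sway/tilt/rotation waves.
#' The left-side program is the right-side program shifted by half a
#' stride.
#'
#' @param jitter SD of the multiplicative amplitude perturbation (and a
#'   third of that SD, additive, on phases) applied per trial to emulate
#'   natural stride-to-stride variability; 0 gives the deterministic
#'   nominal gait.
#' @return named list of per-coordinate harmonic descriptions.
#' @export
gait_program <- function(jitter = 0) {
  h <- function(a0, ...) {
    terms <- list(...)
    list(a0 = a0, terms = lapply(terms, function(t) {
      list(k = t[1], A = t[2], phi = t[3])
    }))
  }
  right <- list(
    hip_flexion   = h(0.15, c(1, 0.35, -0.05)),
    hip_adduction = h(0.02, c(1, 0.07, 0.25)),
    hip_rotation  = h(-0.12, c(1, 0.04, 0.30)),  # -7 deg toe-out offset
    knee_flexion  = h(0.32, c(1, 0.30, 0.73), c(2, 0.12, 0.15)),
    ankle_flexion = h(0.02, c(1, 0.10, 0.32), c(2, 0.08, 0.45)),
    subtalar      = h(0.00)
  )
  prog <- list()
  for (nm in names(right)) {
    prog[[paste0(nm, "_r")]] <- right[[nm]]
    left <- right[[nm]]
    left$terms <- lapply(left$terms, function(t) {
      t$phi <- t$phi + 0.5; t
    })
    prog[[paste0(nm, "_l")]] <- left
  }
  # forward-speed fluctuation phased so single support brakes early and
  # propels late; vertical vault phased for the two-peak vertical GRF
  prog$pelvis_x <- h(0, c(2, 0.008, 0.20))   # + linear v*t added on top
  prog$pelvis_y <- h(0, c(1, 0.025, -0.25))
  prog$pelvis_z <- h(0, c(2, 0.015, 0.28))   # a0 set to standing height
  prog$pelvis_tilt <- h(0.08, c(2, 0.010, 0.00))
  prog$pelvis_list <- h(0, c(1, 0.030, 0.30))
  prog$pelvis_rotation <- h(0, c(1, 0.07, 0.50))
  if (jitter > 0) {
    for (nm in names(prog)) {
      prog[[nm]]$terms <- lapply(prog[[nm]]$terms, function(t) {
        t$A <- t$A * (1 + stats::rnorm(1, 0, jitter))
        t$phi <- t$phi + stats::rnorm(1, 0, jitter / 3)
        t
      })
    }
  }
  prog
}

# Evaluate a program at times t (s) for stride period T: q, qd, qdd
# matrices (rows = frames, cols = program coordinates).
eval_program <- function(prog, t, T) {
  nm <- names(prog)
  q <- qd <- qdd <- matrix(0, length(t), length(nm),
                           dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    p <- prog[[j]]
    q[, j] <- p$a0
    for (tm in p$terms) {
      w <- 2 * pi * tm$k / T
      arg <- w * t - 2 * pi * tm$k * tm$phi
      q[, j] <- q[, j] + tm$A * cos(arg)
      qd[, j] <- qd[, j] - tm$A * w * sin(arg)
      qdd[, j] <- qdd[, j] - tm$A * w^2 * cos(arg)
    }
  }
  list(q = q, qd = qd, qdd = qdd)
}

# Anteroposterior shear (fraction of body weight) added to the
# first-contact plate and subtracted from the other, nonzero only while
# both feet are grounded: braking (-X) when the first-contact foot leads,
# propulsion (+X) when it trails.
ds_shear <- function(phase, stance = 0.62, ds = 0.14, amp = 0.12) {
  ph <- phase %% 1
  e <- numeric(length(ph))
  lead <- ph < ds
  e[lead] <- -amp * sin(pi * ph[lead] / ds)
  trail <- ph >= stance - ds & ph < stance
  e[trail] <- amp * sin(pi * (stance - ph[trail]) / ds)
  e
}

# Quintic smoothstep on [0,1].
smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# Fraction of total ground force carried by the first-contact foot as a
# function of wrapped stride phase. Stance 62%, double support 14% at each
# transfer.
stance_weight <- function(phase, stance = 0.62, ds = 0.14) {
  ph <- phase %% 1
  w <- numeric(length(ph))
  w[ph < ds] <- smootherstep(ph[ph < ds] / ds)
  w[ph >= ds & ph < stance - ds] <- 1
  sel <- ph >= stance - ds & ph < stance
  w[sel] <- smootherstep((stance - ph[sel]) / ds)
  w
}

#' Generate one synthetic walking trial
#'
#' Poses the subject's skeleton with a (optionally jittered) periodic gait
#' program, samples 52 marker trajectories with optional measurement
#' noise, and derives two force-plate records that are dynamically
#' consistent with the generated motion: the total ground reaction force
#' equals the whole-body inertial plus gravitational force at every frame
#' (computed from the closed-form accelerations), apportioned between the
#' plates by a smooth double-support weight. Vertical force on each plate
#' is therefore nonnegative and two-peaked, and the time-average of the
#' summed vertical force over one stride equals body weight.
#'
#' The recording contains one full stride (initial contact of the
#' first-contact foot to its next initial contact) plus a quarter-stride
#' lead-in and lead-out on both sides.
#'
#' @param subject one-row tibble from [generate_cohort()].
#' @param walking_speed m/s; `NULL` picks a stature-scaled self-selected
#'   speed. Speeds outside the calibrated 0.5-2.5 m/s range are clamped
#'   with a warning.
#' @param trial_seed integer seed: drives the stride-to-stride program
#'   jitter and the marker noise.
#' @param noise_sd marker measurement noise SD (m).
#' @param jitter program variability passed to [gait_program()].
#' @param side first-contact foot.
#' @param sample_rate Hz.
#' @return object of class `gait_trial`: tibbles `markers` (frame, time,
#'   marker, x, y, z) and `grf` (frame, time, plate, fx, fy, fz, copx,
#'   copy, copz, tz), `events` (0-based `ic`, `ipsi_ic`), `plate_sides`,
#'   `subject`, `sample_rate`, `walking_speed`, `stride_period`. The
#'   generating coordinate trajectories are attached as attribute
#'   `"truth"` for validation studies.
#' @export
generate_gait_trial <- function(subject, walking_speed = NULL, trial_seed = 1,
                                noise_sd = 0.002, jitter = 0.03,
                                side = c("right", "left"),
                                sample_rate = 100) {
  side <- match.arg(side)
  if (is.null(walking_speed)) {
    walking_speed <- 1.33 * sqrt(subject$stature / 1.7)
  }
  if (walking_speed <= 0) stop("`walking_speed` must be > 0", call. = FALSE)
  if (walking_speed < 0.5 || walking_speed > 2.5) {
    warning("walking_speed ", walking_speed,
            " outside calibrated range [0.5, 2.5] m/s; clamping")
    walking_speed <- min(max(walking_speed, 0.5), 2.5)
  }
  model <- build_subject_model(hip_shape_params("human_like"), subject)
  stride_len <- 0.8 * subject$stature * (walking_speed / 1.3)^0.42
  T <- stride_len / walking_speed

  with_seed(trial_seed, {
    prog <- gait_program(jitter)
    n_stride <- round(T * sample_rate)
    pad <- round(0.25 * T * sample_rate)
    frames <- seq(-pad, n_stride + pad)
    t <- frames / sample_rate
    kin <- eval_program(prog, t, T)

    # mirror-convention: the program is right-stance-first; a left-first
    # trial swaps the side labels (symmetric program), i.e. relabels.
    q_all <- program_to_coords(kin$q, model, side, walking_speed, t)
    qd_all <- program_to_coords(kin$qd, model, side, walking_speed * 0 + 1, t,
                                deriv = 1, speed = walking_speed)
    qdd_all <- program_to_coords(kin$qdd, model, side, 0, t, deriv = 2)

    # standing height: place the lowest sole point 5 mm above the floor
    z_probe <- vapply(seq_along(t), function(i) {
      mp <- marker_positions(model, q_all[i, ])
      min(mp[c("RHEE", "RTOE", "LHEE", "LTOE"), "z"])
    }, numeric(1))
    q_all[, "pelvis_z"] <- q_all[, "pelvis_z"] - min(z_probe) + 0.005

    # pose, markers, and whole-body force from analytic accelerations
    g <- 9.80665
    masses <- vapply(model$segments, `[[`, numeric(1), "mass")
    F_tot <- matrix(0, length(t), 3)
    markers <- vector("list", length(t))
    for (i in seq_along(t)) {
      st <- fk_state(model, q_all[i, ], qd_all[i, ], qdd_all[i, ])
      acc <- vapply(st, `[[`, numeric(3), "a_com")
      F_tot[i, ] <- drop(acc %*% masses) + c(0, 0, sum(masses) * g)
      markers[[i]] <- marker_positions(model, q_all[i, ], st = st)
    }

    phase <- t / T
    w1 <- stance_weight(phase)
    # equal-and-opposite double-support shear exchange: the leading foot
    # brakes while the trailing foot propels; the pair cancels in the
    # whole-body balance, so dynamic consistency is untouched
    exch <- ds_shear(phase) * sum(masses) * g
    heel1 <- toupper(substr(side, 1, 1))
    heel2 <- if (side == "right") "L" else "R"
    grf <- dplyr::bind_rows(lapply(seq_along(t), function(i) {
      cop <- function(pfx, u) {
        hp <- markers[[i]][paste0(pfx, "HEE"), ]
        tp <- markers[[i]][paste0(pfx, "TOE"), ]
        p <- (1 - (0.1 + 0.75 * u)) * hp + (0.1 + 0.75 * u) * tp
        c(p[1], p[2], 0)
      }
      u1 <- pmin(pmax(phase[i] %% 1 / 0.62, 0), 1)
      ph2 <- (phase[i] - 0.5) %% 1
      u2 <- pmin(pmax(ph2 / 0.62, 0), 1)
      tibble::tibble(
        frame = frames[i] + pad, time = t[i],
        plate = c(1L, 2L),
        fx = c(w1[i], 1 - w1[i]) * F_tot[i, 1] + c(exch[i], -exch[i]),
        fy = c(w1[i], 1 - w1[i]) * F_tot[i, 2],
        fz = c(w1[i], 1 - w1[i]) * F_tot[i, 3],
        copx = c(cop(heel1, u1)[1], cop(heel2, u2)[1]),
        copy = c(cop(heel1, u1)[2], cop(heel2, u2)[2]),
        copz = 0, tz = 0
      )
    }))

    mk <- dplyr::bind_rows(lapply(seq_along(t), function(i) {
      m <- markers[[i]]
      if (noise_sd > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), 3)
      }
      tibble::tibble(frame = frames[i] + pad, time = t[i],
                     marker = rownames(m),
                     x = unname(m[, 1]), y = unname(m[, 2]),
                     z = unname(m[, 3]))
    }))

    trial <- structure(list(
      subject = tibble::as_tibble(as.list(subject)),
      side = side,
      sample_rate = sample_rate,
      walking_speed = walking_speed,
      stride_period = T,
      markers = mk,
      grf = grf,
      events = list(ic = pad, ipsi_ic = pad + n_stride),
      plate_sides = stats::setNames(c(side, setdiff(c("right", "left"), side)),
                                    c("plate1", "plate2"))
    ), class = "gait_trial")
    attr(trial, "truth") <- list(q = q_all, qd = qd_all, qdd = qdd_all,
                                 time = t, program = prog)
    trial
  })
}

# Map program coordinates onto model coordinate names, adding the linear
# forward progression. For a left-first trial the program's "_r" curves
# drive the left side (the program is bilaterally symmetric, so this is a
# pure relabelling).
program_to_coords <- function(mat, model, side, lin_coeff, t, deriv = 0,
                              speed = NULL) {
  out <- matrix(0, nrow(mat), length(model$coord_names),
                dimnames = list(NULL, model$coord_names))
  swap <- side == "left"
  for (nm in colnames(mat)) {
    target <- nm
    if (swap && grepl("_(r|l)$", nm)) {
      target <- ifelse(grepl("_r$", nm), sub("_r$", "_l", nm),
                       sub("_l$", "_r", nm))
    }
    if (target %in% colnames(out)) out[, target] <- mat[, nm]
  }
  if (deriv == 0) out[, "pelvis_x"] <- out[, "pelvis_x"] + lin_coeff * t
  if (deriv == 1) out[, "pelvis_x"] <- out[, "pelvis_x"] + speed
  if (swap) {
    # mirror the lateral coordinates so the left-first gait is the exact
    # mirror image of the right-first gait
    for (nm in c("pelvis_y", "pelvis_list", "pelvis_rotation")) {
      out[, nm] <- -out[, nm]
    }
  }
  out
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial> subject ", x$subject$subject_id, ", ", x$side,
      "-first stride, ", length(unique(x$markers$frame)), " frames @ ",
      x$sample_rate, " Hz, speed ", round(x$walking_speed, 2), " m/s\n",
      sep = "")
  invisible(x)
}
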