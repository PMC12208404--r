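#' Fit model kinematics to marker trajectories
#'
#' Per-frame weighted least-squares pose of the joint-constrained chain:
#' the pelvis (with its welded trunk segment) is posed by a rigid Kabsch
#' fit to its markers; each thigh by the rotation-only Procrustes fit about
#' the known hip centre; hinge angles (knee) by the closed-form planar
#' Procrustes angle; and the two-hinge ankle/subtalar complex by a small
#' 2-DOF least-squares refinement per frame. With noiseless markers the
#' recovery is exact to solver precision.
#'
#' Generalized velocities and accelerations are obtained by central
#' differences of the low-pass filtered coordinates (zero-lag 4th-order
#' Butterworth, default 6 Hz cutoff, reflection-padded).
#'
#' @param trial a [generate_gait_trial()] result (or compatible object).
#' @param model the subject's `skeleton_model`.
#' @param filter_cutoff low-pass cutoff (Hz).
#' @return object of class `kinematics_trajectory`: matrices `q` (raw
#'   fitted coordinates), `q_filt`, `qd`, `qdd` (frames x coordinates),
#'   `time`, `sample_rate`, `marker_rms` (per-frame fit residual, m).
#' @export
fit_kinematics <- function(trial, model, filter_cutoff = 6) {
  mk <- trial$markers
  frames <- sort(unique(mk$frame))
  n <- length(frames)
  marker_names <- model$markers$marker
  # world marker array
  W <- array(NA_real_, c(n, length(marker_names), 3),
             dimnames = list(NULL, marker_names, c("x", "y", "z")))
  idx_f <- match(mk$frame, frames)
  idx_m <- match(mk$marker, marker_names)
  W[cbind(idx_f, idx_m, 1)] <- mk$x
  W[cbind(idx_f, idx_m, 2)] <- mk$y
  W[cbind(idx_f, idx_m, 3)] <- mk$z
  if (anyNA(W)) {
    bad <- which(apply(W, 1, anyNA))
    stop("marker dropout at frames ", bad[1], "-", bad[length(bad)],
         call. = FALSE)
  }

  # local marker coordinates per rigid unit (hat is welded to the pelvis)
  local <- list()
  for (i in seq_len(nrow(model$markers))) {
    seg <- model$markers$segment[i]
    p <- model$markers$point[[i]]
    if (seg == "hat") {
      seg <- "pelvis"
      p <- p + model$segments$hat$joint_location
    }
    local[[seg]] <- rbind(local[[seg]],
                          stats::setNames(p, NULL))
    rownames(local[[seg]])[nrow(local[[seg]])] <- model$markers$marker[i]
  }
  for (s in names(local)) {
    if (nrow(local[[s]]) < 3) {
      stop("segment ", s, " has fewer than 3 markers", call. = FALSE)
    }
  }

  coords <- model$coord_names
  q <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  rms <- numeric(n)
  sl <- model$dims$shank_length
  fl <- model$subject$femur_length
  talus_h <- model$dims$talus_height
  hb <- model$subject$hip_breadth
  ankle_prev <- c(r = 0, l = 0); subt_prev <- c(r = 0, l = 0)

  for (i in seq_len(n)) {
    res2 <- 0; nm_used <- 0
    w_at <- function(seg) W[i, rownames(local[[seg]]), , drop = TRUE]

    # pelvis (+ trunk weld): full rigid fit
    wp <- w_at("pelvis")
    fitp <- rigid_fit(local$pelvis, wp)
    Rp <- fitp$rotation; tp <- fitp$translation
    pred <- apply_rigid(fitp, local$pelvis)
    res2 <- res2 + sum((pred - wp)^2); nm_used <- nm_used + nrow(wp)
    q[i, c("pelvis_x", "pelvis_y", "pelvis_z")] <- tp
    q[i, c("pelvis_rotation", "pelvis_list", "pelvis_tilt")] <-
      decompose_zxy(Rp)

    for (s in c("r", "l")) {
      la <- if (s == "l") 1 else -1
      hip_w <- tp + drop(Rp %*% c(0, la * hb / 2, 0))
      th <- paste0("thigh_", s)
      d <- sweep(w_at(th), 2, hip_w)
      Rt <- rotation_fit(local[[th]], d)
      res2 <- res2 + sum((local[[th]] %*% t(Rt) - d)^2)
      nm_used <- nm_used + nrow(d)
      ang <- decompose_hip(t(Rp) %*% Rt)
      q[i, paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_"), s)] <-
        c(ang[1], -la * ang[2], -la * ang[3])

      # knee hinge (about +Y in thigh frame)
      knee_w <- hip_w + drop(Rt %*% c(0, 0, -fl))
      sh <- paste0("shank_", s)
      dk <- sweep(w_at(sh), 2, knee_w) %*% Rt  # into thigh frame
      mk_l <- local[[sh]]
      theta <- atan2(sum(dk[, 1] * mk_l[, 3] - dk[, 3] * mk_l[, 1]),
                     sum(dk[, 1] * mk_l[, 1] + dk[, 3] * mk_l[, 3]))
      q[i, paste0("knee_flexion_", s)] <- theta
      Rs <- Rt %*% rot_axis(c(0, 1, 0), theta)
      res2 <- res2 + sum((mk_l %*% t(Rs) + rep(knee_w, each = nrow(mk_l)) -
                            w_at(sh))^2)
      nm_used <- nm_used + nrow(mk_l)

      # ankle + subtalar hinges from foot markers: alternating
      # closed-form single-hinge fits (coordinate descent; each step is
      # the exact planar Procrustes angle), deterministic and exact on
      # noiseless data
      ankle_w <- knee_w + drop(Rs %*% c(0, 0, -sl))
      ft <- paste0("foot_", s)
      wf <- w_at(ft); mf <- local[[ft]]
      alpha <- ankle_prev[[s]]; beta <- subt_prev[[s]]
      d_sh <- sweep(wf, 2, ankle_w) %*% Rs  # targets in shank frame
      t_off <- c(0, 0, -talus_h)
      for (it in 1:50) {
        # fit the ankle hinge given the subtalar angle
        m_ta <- sweep(mf %*% t(rot_axis(c(-la, 0, 0), beta)), 2, t_off, "+")
        a_new <- -hinge_y(m_ta, d_sh)
        # fit the subtalar hinge given the ankle angle
        d_ta <- sweep(d_sh %*% rot_axis(c(0, 1, 0), -a_new), 2, t_off)
        b_new <- -la * hinge_x(mf, d_ta)
        done <- abs(a_new - alpha) < 1e-14 && abs(b_new - beta) < 1e-14
        alpha <- a_new; beta <- b_new
        if (done) break
      }
      ankle_prev[[s]] <- alpha; subt_prev[[s]] <- beta
      q[i, paste0("ankle_flexion_", s)] <- alpha
      q[i, paste0("subtalar_", s)] <- beta
      Rf <- Rs %*% rot_axis(c(0, -1, 0), alpha) %*% rot_axis(c(-la, 0, 0), beta)
      of <- ankle_w + drop(Rs %*% rot_axis(c(0, -1, 0), alpha) %*% t_off)
      res2 <- res2 + sum((mf %*% t(Rf) + rep(of, each = nrow(mf)) - wf)^2)
      nm_used <- nm_used + nrow(mf)
    }
    rms[i] <- sqrt(res2 / nm_used)
  }

  fs <- trial$sample_rate
  q_filt <- apply(q, 2, filter_lowpass, fs = fs, fc = filter_cutoff)
  qd <- apply(q_filt, 2, central_diff, dt = 1 / fs)
  qdd <- apply(q_filt, 2, second_diff, dt = 1 / fs)
  structure(list(q = q, q_filt = q_filt, qd = qd, qdd = qdd,
                 time = frames / fs, frames = frames, sample_rate = fs,
                 marker_rms = rms, filter_cutoff = filter_cutoff),
            class = "kinematics_trajectory")
}

# Closed-form hinge angles: least-squares planar Procrustes rotation of
# paired points (rows of m onto rows of d) about the +Y / +X axis.
hinge_y <- function(m, d) {
  atan2(sum(m[, 3] * d[, 1] - m[, 1] * d[, 3]),
        sum(m[, 1] * d[, 1] + m[, 3] * d[, 3]))
}
hinge_x <- function(m, d) {
  atan2(sum(m[, 2] * d[, 3] - m[, 3] * d[, 2]),
        sum(m[, 2] * d[, 2] + m[, 3] * d[, 3]))
}

# Rotation-only Procrustes (translation fixed): R minimizing sum|R a - b|^2.
rotation_fit <- function(a, b) {
  sv <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# R = Rz(psi) Rx(phi) Ry(theta) -> c(psi, phi, theta)
decompose_zxy <- function(R) {
  phi <- asin(max(-1, min(1, R[3, 2])))
  psi <- atan2(-R[1, 2], R[2, 2])
  theta <- atan2(-R[3, 1], R[3, 3])
  c(psi, phi, theta)
}

# R = Ry(-f) Rx(a) Rz(r) -> c(f, a, r)  (right-side hip sequence)
decompose_hip <- function(R) {
  a <- asin(max(-1, min(1, -R[2, 3])))
  f <- atan2(-R[1, 3], R[3, 3])
  r <- atan2(R[2, 1], R[2, 2])
  c(f, a, r)
}

# Zero-lag 4th-order Butterworth low-pass with odd-reflection padding.
filter_lowpass <- function(x, fs, fc) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(x)
  bt <- signal::butter(4, fc / (fs / 2))
  pad <- min(n - 1, max(10, round(3 * fs / fc)))
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  # demean so the zero-state startup transient acts on deviations only
  mu <- mean(x)
  y <- signal::filtfilt(bt, c(head_pad, x, tail_pad) - mu) + mu
  y[(pad + 1):(pad + n)]
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

second_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}
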