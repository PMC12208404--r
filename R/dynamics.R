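#' Net joint moments and intersegmental forces over a trial
#'
#' Recursive Newton-Euler inverse dynamics from the feet upward. Segment
#' angular velocity/acceleration and centre-of-mass accelerations are
#' propagated analytically from the fitted generalized coordinates and
#' their filtered derivatives; ground reaction forces (filtered with the
#' same zero-lag low-pass as the kinematics) are applied to the feet at
#' their centres of pressure. Moments are reported in model axes (X =
#' travel, Y = mediolateral, Z = vertical) as the moment applied by the
#' parent segment on the distal segment at the joint; forces as the
#' intersegmental force transmitted to the *proximal* segment from the
#' distal one, so the stance-limb vertical hip force is positive.
#'
#' @param model a `skeleton_model`.
#' @param kin a [fit_kinematics()] result.
#' @param trial the matching `gait_trial` (source of GRFs).
#' @param gravity gravitational acceleration (m/s^2); exposed for
#'   validation studies on analytic toy systems.
#' @return tibble: frame, time, joint (`hip`/`knee`/`ankle`/`subtalar`),
#'   side, axis (`x`/`y`/`z`), moment (N m), force (N).
#' @export
net_joint_loads <- function(model, kin, trial, gravity = 9.80665) {
  comp <- compute_inverse_dynamics(model, kin, trial, gravity)
  comp$loads
}

compute_inverse_dynamics <- function(model, kin, trial, gravity = 9.80665) {
  n <- nrow(kin$q_filt)
  grf <- filtered_grf(trial, kin)
  g_vec <- c(0, 0, -gravity)
  segs <- model$segments
  kids <- lapply(names(segs), function(nm) {
    names(segs)[vapply(segs, function(s) {
      identical(s$parent, nm)
    }, logical(1))]
  })
  names(kids) <- names(segs)
  post <- rev(model$order)  # leaves first
  joint_name <- c(thigh = "hip", shank = "knee", talus = "ankle",
                  foot = "subtalar")

  acc_frame <- integer(0); acc_time <- numeric(0); acc_joint <- character(0)
  acc_side <- character(0)
  mlist <- list(); flist <- list()
  axes_all <- vector("list", n)
  states_cache <- vector("list", n)
  for (i in seq_len(n)) {
    st <- fk_state(model, kin$q_filt[i, ], kin$qd[i, ], kin$qdd[i, ])
    states_cache[[i]] <- st
    axes_all[[i]] <- attr(st, "axes")
    f_prox <- list(); m_prox <- list()
    for (nm in post) {
      sg <- segs[[nm]]
      s <- st[[nm]]
      Iw <- s$R %*% sg$inertia %*% t(s$R)
      f_ext <- c(0, 0, 0); m_ext_about_c <- c(0, 0, 0)
      side <- if (grepl("_l$", nm)) "left" else "right"
      if (grepl("^foot_", nm)) {
        plate <- which(trial$plate_sides == side)
        gr <- grf[[plate]]
        f_e <- c(gr$fx[i], gr$fy[i], gr$fz[i])
        p_e <- c(gr$copx[i], gr$copy[i], gr$copz[i])
        f_ext <- f_e
        m_ext_about_c <- c(0, 0, gr$tz[i]) + cross3(p_e - s$com, f_e)
      }
      f_ch <- c(0, 0, 0); m_ch_about_c <- c(0, 0, 0)
      for (ch in kids[[nm]]) {
        p_ch <- st[[ch]]$origin
        f_ch <- f_ch + f_prox[[ch]]
        m_ch_about_c <- m_ch_about_c + m_prox[[ch]] +
          cross3(p_ch - s$com, f_prox[[ch]])
      }
      fp <- sg$mass * s$a_com - sg$mass * g_vec - f_ext + f_ch
      mp <- drop(Iw %*% s$alpha) + cross3(s$omega, drop(Iw %*% s$omega)) -
        cross3(s$origin - s$com, fp) + m_ch_about_c - m_ext_about_c
      f_prox[[nm]] <- fp
      m_prox[[nm]] <- mp
      base <- sub("_(r|l)$", "", nm)
      if (base %in% names(joint_name)) {
        acc_frame <- c(acc_frame, kin$frames[i])
        acc_time <- c(acc_time, kin$time[i])
        acc_joint <- c(acc_joint, joint_name[[base]])
        acc_side <- c(acc_side, if (grepl("_l$", nm)) "left" else "right")
        mlist[[length(mlist) + 1]] <- mp
        flist[[length(flist) + 1]] <- -fp
      }
    }
  }
  k <- length(acc_frame)
  loads <- tibble::tibble(
    frame = rep(acc_frame, each = 3),
    time = rep(acc_time, each = 3),
    joint = rep(acc_joint, each = 3),
    side = rep(acc_side, each = 3),
    axis = rep(c("x", "y", "z"), k),
    moment = unlist(mlist),
    force = unlist(flist)
  )
  list(loads = loads, states = states_cache, axes = axes_all, grf = grf)
}

filtered_grf <- function(trial, kin) {
  fs <- trial$sample_rate
  fc <- kin$filter_cutoff
  lapply(1:2, function(p) {
    gr <- trial$grf[trial$grf$plate == p, ]
    gr <- gr[order(gr$frame), ]
    stopifnot(all(gr$frame == kin$frames))
    for (cl in c("fx", "fy", "fz")) {
      gr[[cl]] <- filter_lowpass(gr[[cl]], fs, fc)
    }
    gr
  })
}

#' Whole-body residual force and moment
#'
#' The dynamic imbalance between modelled segment inertia plus gravity and
#' the measured ground reaction forces, assigned at the pelvis origin:
#' `F_res = sum_i m_i a_i - sum_i m_i g - sum GRF`, with the analogous
#' moment about the pelvis origin. Residuals are diagnostic and never
#' silently corrected; on noiseless synthetic trials the residual force
#' stays below 1% of body weight.
#'
#' @inheritParams net_joint_loads
#' @return tibble: frame, time, axis, force (N), moment (N m).
#' @export
residual_loads <- function(model, kin, trial, gravity = 9.80665) {
  n <- nrow(kin$q_filt)
  grf <- filtered_grf(trial, kin)
  g_vec <- c(0, 0, -gravity)
  segs <- model$segments
  out <- vector("list", n)
  for (i in seq_len(n)) {
    st <- fk_state(model, kin$q_filt[i, ], kin$qd[i, ], kin$qdd[i, ])
    p0 <- st$pelvis$origin
    F <- c(0, 0, 0); M <- c(0, 0, 0)
    for (nm in names(segs)) {
      sg <- segs[[nm]]; s <- st[[nm]]
      Iw <- s$R %*% sg$inertia %*% t(s$R)
      F <- F + sg$mass * (s$a_com - g_vec)
      M <- M + drop(Iw %*% s$alpha) + cross3(s$omega, drop(Iw %*% s$omega)) +
        cross3(s$com - p0, sg$mass * (s$a_com - g_vec))
    }
    for (p in 1:2) {
      gr <- grf[[p]]
      fe <- c(gr$fx[i], gr$fy[i], gr$fz[i])
      pe <- c(gr$copx[i], gr$copy[i], gr$copz[i])
      F <- F - fe
      M <- M - cross3(pe - p0, fe) - c(0, 0, gr$tz[i])
    }
    out[[i]] <- tibble::tibble(frame = kin$frames[i], time = kin$time[i],
                               axis = c("x", "y", "z"), force = F, moment = M)
  }
  dplyr::bind_rows(out)
}

#' Extract the analysed stride window from a trial
#'
#' A complete stride runs from initial contact with the first force plate
#' to the ipsilateral initial contact; the returned window is half-open
#' `[ic, ipsi_ic)` in 0-based frames.
#'
#' @param trial a `gait_trial`.
#' @return list: `start`, `end` (exclusive), `n_frames`, `side` (stance
#'   side of the first contact).
#' @export
extract_stride <- function(trial) {
  ev <- trial$events
  if (is.null(ev$ic) || is.null(ev$ipsi_ic) || is.na(ev$ipsi_ic)) {
    stop("missing ipsilateral initial contact event", call. = FALSE)
  }
  frames <- sort(unique(trial$markers$frame))
  if (!(ev$ic %in% frames) || !(ev$ipsi_ic %in% frames)) {
    stop("stride events fall outside the recording", call. = FALSE)
  }
  list(start = ev$ic, end = ev$ipsi_ic, n_frames = ev$ipsi_ic - ev$ic,
       side = trial$side)
}
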