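#' Muscle recruitment settings
#'
#' The redundancy criterion minimises the sum of element activations
#' raised to an exponent (default 3) subject to the muscle moments
#' balancing the net joint moments at every frame, with nonnegative
#' activations. For exponent >= 2 the problem is strictly convex on the
#' feasible set, so the minimiser is unique.
#'
#' @param exponent criterion exponent p (>= 2).
#' @param bound_policy `"allow_overload_with_flag"` (activations may
#'   exceed 1 and frames where they do are flagged, keeping infeasibility
#'   visible) or `"cap_at_1"` (hard upper bound in the solve).
#' @param tolerance moment-balance residual tolerance, relative to
#'   `max(1, |M|)` per frame.
#' @param dofs generalized coordinates whose moments enter the constraint
#'   set; default bilateral hip (3 DOF), knee and ankle flexion.
#' @return list of class `redundancy_config`.
#' @export
redundancy_config <- function(exponent = 3,
                              bound_policy = c("allow_overload_with_flag",
                                               "cap_at_1"),
                              tolerance = 1e-9,
                              dofs = default_solve_dofs()) {
  if (exponent < 2) stop("`exponent` must be >= 2", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  structure(list(exponent = exponent, bound_policy = match.arg(bound_policy),
                 tolerance = tolerance, dofs = dofs),
            class = "redundancy_config")
}

#' @rdname redundancy_config
#' @export
default_solve_dofs <- function() {
  unlist(lapply(c("r", "l"), function(s) {
    paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_",
             "knee_flexion_", "ankle_flexion_"), s)
  }))
}

#' Resolve one frame of the muscle redundancy problem
#'
#' Solves `min sum_i a_i^p` subject to `R diag(strengths) a = M`, `a >= 0`
#' (optionally `a <= 1` under the `cap_at_1` policy) with a primal-dual
#' interior-point Newton method. The objective Hessian is diagonal, so
#' each Newton step reduces to a DOF x DOF Schur-complement solve; the
#' barrier parameter follows the complementarity gap down to the requested
#' tolerance, and the strict convexity of the criterion makes the returned
#' minimiser unique. Frames whose required moment direction lies outside
#' the muscles' nonnegative span are flagged `"infeasible"` and answered
#' with the nonnegative least-squares moment match instead.
#'
#' @param R moment-arm matrix, DOFs x elements (m).
#' @param strengths element maximum strengths (N).
#' @param net_moments required generalized moments per DOF (N m).
#' @param config a [redundancy_config()].
#' @return list: `activations`, `forces`, `residual` (moment balance,
#'   N m), `status` (`"ok"`, `"overload"` or `"infeasible"`).
#' @export
solve_frame <- function(R, strengths, net_moments, config = redundancy_config()) {
  R <- as.matrix(R)
  A <- sweep(R, 2, strengths, "*")
  M <- as.numeric(net_moments)
  p <- config$exponent
  cap <- config$bound_policy == "cap_at_1"
  n <- ncol(A)
  m <- nrow(A)

  finish <- function(a, status) {
    a <- pmax(a, 0)
    res <- drop(A %*% a) - M
    if (status == "ok" &&
        max(abs(res)) > config$tolerance * max(1, max(abs(M)))) {
      status <- "infeasible"
    }
    if (status == "ok" && !cap && any(a > 1 + 1e-12)) status <- "overload"
    list(activations = a, forces = a * strengths, residual = res,
         status = status)
  }
  if (max(abs(M)) == 0) return(finish(numeric(n), "ok"))

  # row equilibration: unit-norm constraint rows condition the Schur
  # complement without changing the solution
  rn <- pmax(sqrt(rowSums(A^2)), 1e-12 * max(abs(A), 1e-30))
  As <- A / rn
  Ms <- M / rn
  tol_rows <- 0.5 * config$tolerance * max(1, max(abs(M))) / rn
  a <- rep(0.2, n)
  lam <- rep(1, n)           # multiplier for a >= 0
  xi <- rep(1, n)            # multiplier for a <= 1 (cap policy)
  nu <- numeric(m)
  ok <- FALSE
  if (cap) a <- pmin(a, 0.5)
  for (it in 1:200) {
    grad <- p * a^(p - 1)
    H <- p * (p - 1) * pmax(a, 1e-12)^(p - 2)
    r_d <- grad - lam - drop(crossprod(As, nu)) + if (cap) xi else 0
    r_p <- drop(As %*% a) - Ms
    gap <- sum(lam * a) + if (cap) sum(xi * (1 - a)) else 0
    gap <- gap / if (cap) (2 * n) else n
    if (all(abs(r_p) < tol_rows) && max(abs(r_d)) < 1e-10 && gap < 1e-14) {
      ok <- TRUE
      break
    }
    mu <- 0.2 * gap
    W <- H + lam / a + if (cap) xi / (1 - a) else 0
    rhs <- -r_d + (mu / a - lam) - if (cap) (mu / (1 - a) - xi) else 0
    AW <- As * rep(1 / W, each = m)
    S <- AW %*% t(As)
    dnu <- tryCatch(
      solve(S + diag(1e-14 * max(diag(S)), m), -r_p - drop(AW %*% rhs)),
      error = function(e) NULL
    )
    if (is.null(dnu)) break
    da <- (drop(crossprod(As, dnu)) + rhs) / W
    dlam <- (mu - lam * a) / a - (lam / a) * da
    alpha <- 0.99 * min(1, suppressWarnings(min(-a[da < 0] / da[da < 0])),
                        suppressWarnings(min(-lam[dlam < 0] / dlam[dlam < 0])))
    if (cap) {
      dxi <- (mu - xi * (1 - a)) / (1 - a) + (xi / (1 - a)) * da
      alpha <- 0.99 * min(alpha,
                          suppressWarnings(min((1 - a)[da > 0] / da[da > 0])),
                          suppressWarnings(min(-xi[dxi < 0] / dxi[dxi < 0])))
      xi <- xi + alpha * dxi
    }
    if (!is.finite(alpha) || alpha <= 0) break
    a <- a + alpha * da
    lam <- lam + alpha * dlam
    nu <- nu + alpha * dnu
  }
  if (ok) return(finish(a, "ok"))
  # no convergence: the moment demand is (numerically) outside the
  # nonnegative span; answer with the nonnegative least-squares match
  ls <- tryCatch(pracma::lsqnonneg(A, M)$x, error = function(e) a)
  res <- drop(A %*% ls) - M
  if (max(abs(res)) <= config$tolerance * max(1, max(abs(M)))) {
    # feasible after all (interior path stalled): accept if optimal-ish,
    # else report the stalled interior point, whichever costs less
    cand <- if (sum(pmax(a, 0)^p) < sum(ls^p)) pmax(a, 0) else ls
    return(finish(cand, "ok"))
  }
  finish(ls, "infeasible")
}

#' Resolve muscle forces over a stride
#'
#' Frame-wise [solve_frame()] across the stride window: the moment-arm
#' matrix is evaluated at each frame's posture, the required generalized
#' moments are the inverse-dynamics joint moments projected on each
#' coordinate's instantaneous axis, and all included DOFs (both limbs) are
#' solved simultaneously.
#'
#' @param model a `skeleton_model`.
#' @param kin a [fit_kinematics()] result.
#' @param joint_loads result of [net_joint_loads()] on the same trial.
#' @param config a [redundancy_config()].
#' @param frames frames to solve (default: all frames in `joint_loads`).
#' @return object of class `redundancy_solution`: tibble `activations`
#'   (frame, element, group, side, activation, force), tibble `frames`
#'   (frame, status, residual), plus the config.
#' @export
solve_stride <- function(model, kin, joint_loads, config = redundancy_config(),
                         frames = NULL) {
  frames <- frames %||% sort(unique(joint_loads$frame))
  dofs <- config$dofs
  strengths <- model$muscles$max_strength
  coord_joint <- dof_joint_map(model)
  loads_by_frame <- split(joint_loads, joint_loads$frame)

  act_rows <- vector("list", length(frames))
  frame_rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    i <- match(fr, kin$frames)
    q <- kin$q_filt[i, ]
    st <- fk_state(model, q)
    axes <- attr(st, "axes")
    Rm <- moment_arm_matrix(model, q, dofs)
    ld <- loads_by_frame[[as.character(fr)]]
    M <- vapply(dofs, function(d) {
      jt <- coord_joint[[d]]
      sel <- ld$joint == jt$joint & ld$side == jt$side
      sum(ld$moment[sel][match(c("x", "y", "z"), ld$axis[sel])] * axes[[d]])
    }, numeric(1))
    sol <- solve_frame(Rm, strengths, M, config)
    act_rows[[fi]] <- tibble::tibble(
      frame = fr, element = model$muscles$element,
      group = model$muscles$group, side = model$muscles$side,
      activation = sol$activations, force = sol$forces
    )
    frame_rows[[fi]] <- tibble::tibble(frame = fr, status = sol$status,
                                       residual = max(abs(sol$residual)),
                                       max_moment = max(abs(M)))
  }
  structure(list(activations = dplyr::bind_rows(act_rows),
                 frames = dplyr::bind_rows(frame_rows),
                 config = config),
            class = "redundancy_solution")
}

dof_joint_map <- function(model) {
  out <- list()
  for (sg in model$segments) {
    base <- sub("_(r|l)$", "", sg$name)
    jt <- c(thigh = "hip", shank = "knee", talus = "ankle",
            foot = "subtalar")[base]
    if (is.na(jt)) next
    side <- if (grepl("_l$", sg$name)) "left" else "right"
    for (rot in sg$rotations) out[[rot$coord]] <- list(joint = jt, side = side)
  }
  out
}

#' @export
print.redundancy_solution <- function(x, ...) {
  cat("<redundancy_solution> ", nrow(x$frames), " frames, ",
      length(unique(x$activations$element)), " elements; status: ",
      paste(names(table(x$frames$status)), table(x$frames$status),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Muscle-inclusive joint reaction force
#'
#' The reaction force transmitted across a joint to the proximal segment,
#' including both the externally induced intersegmental force and the
#' vector sum of the muscle forces whose paths cross the joint (each
#' applied along its crossing path segment). With all activations zero
#' this reduces to the intersegmental force.
#'
#' @param model a `skeleton_model`.
#' @param kin a `kinematics_trajectory`.
#' @param solution a [solve_stride()] result.
#' @param joint_loads result of [net_joint_loads()].
#' @param joint joint name (`"hip"`).
#' @param side `"right"` or `"left"`.
#' @return tibble: frame, axis, force (N), positive = force pushed into
#'   the proximal segment (vertical hip force positive in stance).
#' @export
joint_reaction_with_muscles <- function(model, kin, solution, joint_loads,
                                        joint = "hip",
                                        side = c("right", "left")) {
  side <- match.arg(side)
  s_sfx <- if (side == "right") "r" else "l"
  child <- c(hip = "thigh", knee = "shank", ankle = "talus")[[joint]]
  child <- paste0(child, "_", s_sfx)
  below <- c(child, descendants(model)[[child]])
  # muscles crossing this joint and their crossing path segment
  cross <- list()
  for (j in seq_len(nrow(model$muscles))) {
    path <- model$muscles$path[[j]]
    segs <- vapply(path, `[[`, character(1), "segment")
    in_below <- segs %in% below
    if (!any(in_below) || all(in_below)) next
    k <- which(!in_below[-length(segs)] & in_below[-1])
    if (length(k) == 0) next
    cross[[model$muscles$element[j]]] <- c(j, k[1])
  }
  frames <- sort(unique(solution$activations$frame))
  act <- solution$activations
  base <- joint_loads[joint_loads$joint == joint & joint_loads$side == side, ]
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    i <- match(fr, kin$frames)
    st <- fk_state(model, kin$q_filt[i, ])
    f <- base$force[base$frame == fr][match(c("x", "y", "z"),
                                            base$axis[base$frame == fr])]
    af <- act[act$frame == fr, ]
    for (el in names(cross)) {
      j <- cross[[el]][1]; k <- cross[[el]][2]
      Fm <- af$force[match(el, af$element)]
      if (Fm == 0) next
      path <- model$muscles$path[[j]]
      pw <- function(a) {
        s <- st[[a$segment]]
        s$origin + drop(s$R %*% a$point)
      }
      ap <- pw(path[[k]]); ad <- pw(path[[k + 1]])
      u <- (ap - ad) / sqrt(sum((ap - ad)^2))
      f <- f + Fm * u
    }
    out[[fi]] <- tibble::tibble(frame = fr, axis = c("x", "y", "z"), force = f)
  }
  dplyr::bind_rows(out)
}
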