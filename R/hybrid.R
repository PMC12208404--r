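#' Build a hybrid femur: australopith proximal end, human distal end
#'
#' Reproduces the hybrid-bone construction used to graft a fossil-shaped
#' proximal femur onto a modern human distal femur while keeping the human
#' surface triangulation. Pipeline: (1) uniformly scale the australopith
#' femur to the human head-to-knee length; (2) rigidly align its proximal
#' region onto the human proximal region by ICP; (3) spread `n_proximal`
#' control vertices evenly (farthest-point sampling) over the human
#' proximal region; (4) find their geometrically homologous locations on
#' the australopith proximal surface by staged CPD; (5) spread `n_distal`
#' control vertices over the human distal region; (6) warp every human
#' femur vertex through the thin-plate spline that maps (human proximal +
#' human distal) controls to (australopith homologues + human distal)
#' controls. The shaft becomes the smooth TPS interpolation between the two
#' ends; the distal controls are interpolation targets, so the distal end
#' is unmoved.
#'
#' @param human_femur,austral_femur [landmarked_mesh()]es carrying
#'   `femoral_head_center` and `knee_center` landmarks.
#' @param proximal_fraction fraction of head-to-knee length (from the head)
#'   defining the proximal region.
#' @param n_proximal,n_distal control vertex counts (capped at the number
#'   of vertices available in each region).
#' @param cpd a [cpd_config()].
#' @param distal_fraction fraction of the length (from the knee) defining
#'   the distal region.
#' @return the hybrid `landmarked_mesh` (human topology) with an
#'   attribute `"report"`: tibble of stage diagnostics.
#' @export
build_hybrid_femur <- function(human_femur, austral_femur,
                               proximal_fraction = 0.2,
                               n_proximal = 237, n_distal = 2500,
                               cpd = cpd_config(),
                               distal_fraction = 0.3) {
  if (proximal_fraction <= 0 || proximal_fraction >= 1) {
    stop("`proximal_fraction` must be in (0, 1)", call. = FALSE)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("hybrid femur stage [", what, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  hum_len <- femur_axis_length(human_femur)

  aus <- stage("scale", scale_to_joint_centers(
    austral_femur,
    list(femur = c("femoral_head_center", "knee_center")),
    c(femur = hum_len)
  ))

  hum_prox <- femur_region(human_femur, proximal_fraction, from = "head")
  aus_prox <- femur_region(aus, proximal_fraction, from = "head")
  fit <- stage("icp", icp_align(aus_prox, hum_prox))
  aus <- transform_mesh(aus, function(p) apply_rigid(fit, p))
  aus_prox <- apply_rigid(fit, aus_prox)

  prox_ctrl <- hum_prox[farthest_point_sample(
    hum_prox, min(n_proximal, nrow(hum_prox))), , drop = FALSE]
  corr <- stage("cpd", cpd_correspond(prox_ctrl, aus_prox, cpd))
  # homologous locations live on the target surface: snap each deformed
  # control point to its nearest vertex of the australopith proximal cloud
  nn <- max.col(-pairwise_dist(corr$points, aus_prox), ties.method = "first")
  corr$points <- aus_prox[nn, , drop = FALSE]

  hum_dist <- femur_region(human_femur, distal_fraction, from = "knee")
  dist_ctrl <- hum_dist[farthest_point_sample(
    hum_dist, min(n_distal, nrow(hum_dist))), , drop = FALSE]

  warp <- stage("tps", fit_tps(rbind(prox_ctrl, dist_ctrl),
                               rbind(corr$points, dist_ctrl)))
  out <- warp_mesh(human_femur, warp)
  attr(out, "report") <- tibble::tibble(
    stage = c("icp_rms", "cpd_sigma", "tps_max_residual"),
    value = c(fit$rms, corr$sigma,
              max(sqrt(rowSums((apply_tps(warp, warp$source_landmarks) -
                                  warp$target_landmarks)^2))))
  )
  out
}

femur_axis_length <- function(mesh) {
  co <- landmark_coords(mesh, c("femoral_head_center", "knee_center"))
  sqrt(sum((co[1, ] - co[2, ])^2))
}

# Vertices within `fraction` of the head-to-knee length, measured along the
# shaft axis from the named end.
femur_region <- function(mesh, fraction, from = c("head", "knee")) {
  from <- match.arg(from)
  co <- landmark_coords(mesh, c("femoral_head_center", "knee_center"))
  axis <- co[2, ] - co[1, ]
  len <- sqrt(sum(axis^2))
  axis <- axis / len
  s <- drop(sweep(mesh$vertices, 2, co[1, ]) %*% axis) / len
  keep <- if (from == "head") s <= fraction else s >= 1 - fraction
  mesh$vertices[keep, , drop = FALSE]
}

#' Evenly distribute sample points by farthest-point sampling
#'
#' Greedy farthest-point subsampling of a point set: starts from the point
#' farthest from the centroid (deterministic) and repeatedly adds the point
#' farthest from the current sample.
#'
#' @param points N x 3 matrix.
#' @param n number of samples (<= N).
#' @return integer vector of row indices into `points`.
#' @export
farthest_point_sample <- function(points, n) {
  points <- as.matrix(points)
  if (n > nrow(points)) stop("`n` exceeds the number of points", call. = FALSE)
  centroid <- colMeans(points)
  idx <- integer(n)
  idx[1] <- which.max(rowSums(sweep(points, 2, centroid)^2))
  mind <- rowSums(sweep(points, 2, points[idx[1], ])^2)
  for (k in seq_len(n - 1)) {
    idx[k + 1] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(points, 2, points[idx[k + 1], ])^2))
  }
  idx
}
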