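#' Uniformly scale a mesh so named joint-centre distances hit targets
#'
#' Applies a single isometric scale about the midpoint of the first named
#' landmark pair so that every requested inter-landmark distance equals its
#' target. Because the scale is uniform, shape (all ratios of
#' inter-landmark distances) is preserved; if the requested targets imply
#' different scale factors no uniform scale exists and an error listing the
#' implied factors is raised.
#'
#' @param mesh a [landmarked_mesh()].
#' @param joint_landmark_pairs named list of length-2 character vectors,
#'   each naming the two landmarks whose distance is constrained.
#' @param target_distances named numeric vector (m), names matching
#'   `joint_landmark_pairs`.
#' @return the scaled `landmarked_mesh`.
#' @export
scale_to_joint_centers <- function(mesh, joint_landmark_pairs, target_distances) {
  nms <- names(joint_landmark_pairs)
  if (is.null(nms) || !all(nms %in% names(target_distances))) {
    stop("each landmark pair needs a matching named target distance",
         call. = FALSE)
  }
  if (any(target_distances[nms] <= 0)) {
    stop("target distances must be positive", call. = FALSE)
  }
  current <- vapply(joint_landmark_pairs, function(pair) {
    co <- landmark_coords(mesh, pair)
    sqrt(sum((co[1, ] - co[2, ])^2))
  }, numeric(1))
  if (any(current == 0)) stop("coincident joint landmarks", call. = FALSE)
  implied <- target_distances[nms] / current
  if (diff(range(implied)) > 1e-9 * mean(implied)) {
    stop("no single uniform scale satisfies the targets; implied scales: ",
         paste(sprintf("%s = %.9g", nms, implied), collapse = ", "),
         call. = FALSE)
  }
  s <- implied[[1]]
  centre <- colMeans(landmark_coords(mesh, joint_landmark_pairs[[1]]))
  transform_mesh(mesh, function(p) {
    sweep(sweep(p, 2, centre) * s, 2, centre, "+")
  })
}

#' Orient a pelvis to the anterior-pelvic-plane convention
#'
#' Rotates the pelvis about the inter-hip-centre (mediolateral) axis until
#' the anterior pelvic plane -- through the two anterior superior iliac
#' spines and the two pubic tubercles -- is parallel to the coronal plane
#' (ASIS vertically above the pubic tubercles). Rotations about the other
#' axes are fixed by left-right symmetry and are not altered. The achieved
#' anterior-pelvic-plane angle and the sacral slope (sagittal inclination of
#' the sacral endplate to the horizontal) are reported.
#'
#' Axis convention: X = direction of travel (anterior), Y = mediolateral,
#' Z = vertical.
#'
#' @param pelvis a [landmarked_mesh()] carrying `asis_l`, `asis_r`,
#'   `pubic_tubercle_l`, `pubic_tubercle_r`, `hip_center_l`, `hip_center_r`,
#'   `sacral_endplate_a`, `sacral_endplate_p` landmarks.
#' @param convention only `"anterior_pelvic_plane_vertical"` is defined.
#' @return list with `mesh` (reoriented pelvis) and `achieved_angles`
#'   (tibble: `app_angle_deg`, `sacral_slope_deg`).
#' @export
orient_pelvis <- function(pelvis, convention = "anterior_pelvic_plane_vertical") {
  convention <- match.arg(convention)
  needed <- c("asis_l", "asis_r", "pubic_tubercle_l", "pubic_tubercle_r",
              "hip_center_l", "hip_center_r",
              "sacral_endplate_a", "sacral_endplate_p")
  co <- landmark_coords(pelvis, needed)  # schema error if missing

  tilt <- app_angle(co)
  centre <- colMeans(co[c("hip_center_l", "hip_center_r"), ])
  R <- rot_y(tilt)
  out <- transform_mesh(pelvis, function(p) {
    sweep(sweep(p, 2, centre) %*% t(R), 2, centre, "+")
  })
  co2 <- landmark_coords(out, needed)
  sac <- co2["sacral_endplate_a", ] - co2["sacral_endplate_p", ]
  list(
    mesh = out,
    achieved_angles = tibble::tibble(
      app_angle_deg = app_angle(co2) * 180 / pi,
      sacral_slope_deg = atan2(sac[["z"]], sac[["x"]]) * 180 / pi
    )
  )
}

# Sagittal inclination of the anterior pelvic plane: angle of the
# (mid pubic tubercle -> mid ASIS) line from vertical, positive = ASIS
# anterior of the tubercles.
app_angle <- function(co) {
  v <- colMeans(co[c("asis_l", "asis_r"), ]) -
    colMeans(co[c("pubic_tubercle_l", "pubic_tubercle_r"), ])
  atan2(v[["x"]], v[["z"]])
}

rot_y <- function(a) {
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}
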