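#' Hip shape parameters
#'
#' Dimensionless shape descriptors of the hip functional complex that the
#' two study variants contrast: relative biacetabular breadth (inter-hip
#' spacing relative to the rest of the pelvis), femoral neck length, the
#' anterior wrap of the iliac blade (which places the anterior abductor
#' origins), and anteroposterior pelvic depth.
#'
#' The two presets encode the study contrast at equal inter-hip-centre
#' distance: the australopith-like form has relatively greater
#' biacetabular breadth (so the blades sit relatively closer to the hip
#' centres), a longer femoral neck, much less anterior iliac wrap (abductor
#' origins more posterior/lateral), and an anteroposteriorly compressed
#' pelvis.
#'
#' @param variant `"human_like"` or `"australopith_like"`, or pass the
#'   ratios explicitly.
#' @param biacetabular_breadth_ratio,neck_length_ratio,ap_depth_ratio
#'   positive dimensionless ratios relative to the human-like form.
#' @param iliac_flare_angle anterior wrap of the iliac blade in degrees,
#'   strictly between 0 and 90.
#' @return list of class `hip_shape_params`.
#' @export
hip_shape_params <- function(variant = c("human_like", "australopith_like"),
                             biacetabular_breadth_ratio = NULL,
                             neck_length_ratio = NULL,
                             iliac_flare_angle = NULL,
                             ap_depth_ratio = NULL) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    human_like = list(biacetabular_breadth_ratio = 1, neck_length_ratio = 1,
                      iliac_flare_angle = 40, ap_depth_ratio = 1),
    australopith_like = list(biacetabular_breadth_ratio = 1.25,
                             neck_length_ratio = 1.06,
                             iliac_flare_angle = 25, ap_depth_ratio = 0.75)
  )
  p <- list(
    variant = variant,
    biacetabular_breadth_ratio =
      biacetabular_breadth_ratio %||% preset$biacetabular_breadth_ratio,
    neck_length_ratio = neck_length_ratio %||% preset$neck_length_ratio,
    iliac_flare_angle = iliac_flare_angle %||% preset$iliac_flare_angle,
    ap_depth_ratio = ap_depth_ratio %||% preset$ap_depth_ratio
  )
  if (p$biacetabular_breadth_ratio <= 0 || p$neck_length_ratio <= 0 ||
      p$ap_depth_ratio <= 0) {
    stop("shape ratios must be positive", call. = FALSE)
  }
  if (p$iliac_flare_angle <= 0 || p$iliac_flare_angle >= 90) {
    stop("`iliac_flare_angle` must lie in (0, 90) degrees", call. = FALSE)
  }
  structure(p, class = "hip_shape_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parametric pelvis dimensions shared by the mesh generator and the
# musculoskeletal model builder. All lengths scale with the subject's
# inter-hip-centre distance `hb`.
pelvis_dims <- function(params, hb) {
  # The ilium's height/breadth proportion falls with the square of the
  # relative biacetabular breadth: a relatively broad-hipped (short,
  # wide-bladed) pelvis carries its abductor origins markedly lower over
  # the hip, while the lateral extent of the blade tracks the (fixed)
  # inter-hip distance.
  list(
    hb = hb,
    blade_radius = 0.55 * hb,
    blade_height = 0.45 * hb / params$biacetabular_breadth_ratio^2,
    ap = params$ap_depth_ratio,
    flare = params$iliac_flare_angle * pi / 180,
    neck_length = 0.29 * hb * params$neck_length_ratio
  )
}

# Abductor / hip-muscle attachment sites in the pelvis frame (origin at the
# midpoint of the hip centres; X anterior, Y left, Z up) and femur sites in
# the thigh frame (origin at the hip centre). `side` is "l" or "r";
# `lat` is the lateral sign (+1 left, -1 right).
#
# Gluteal origin fans span azimuth phi measured from anterior (+X) toward
# lateral (90 deg) and posterior (180 deg): the fan's anterior limit is
# (90 - flare) deg, so a strongly wrapped (human-like) blade carries
# origins far anterior and a weakly wrapped one does not.
hip_attachment_sites <- function(params, subject, side = c("r", "l"),
                                 n_per_gluteal = 12) {
  side <- match.arg(side)
  lat <- if (side == "l") 1 else -1
  d <- pelvis_dims(params, subject$hip_breadth)
  hip <- c(0, lat * d$hb / 2, 0)

  # the fan azimuth is governed solely by the flare parameter (anterior
  # wrap); anteroposterior inlet compression acts on the pelvis body, not
  # on the blade fan placement
  fan <- function(phi, radius, height) {
    cbind(radius * cos(phi), hip[2] + lat * radius * sin(phi),
          hip[3] + height)
  }
  phi_med <- seq(pi / 2 - d$flare, 150 * pi / 180, length.out = n_per_gluteal)
  phi_min <- seq(pi / 2 - 1.1 * d$flare, 140 * pi / 180,
                 length.out = n_per_gluteal)
  phi_max <- seq(150 * pi / 180, 205 * pi / 180, length.out = n_per_gluteal)

  origins <- rbind(
    fan(phi_med, d$blade_radius, d$blade_height),
    fan(phi_min, 0.8 * d$blade_radius, 0.65 * d$blade_height),
    fan(phi_max, 0.85 * d$blade_radius,
        seq(0.5 * d$blade_height, -0.25 * d$blade_height,
            length.out = n_per_gluteal))
  )
  groups <- rep(c("gluteus_medius", "gluteus_minimus", "gluteus_maximus"),
                each = n_per_gluteal)

  # Femoral insertions, thigh frame (origin = hip centre). The greater
  # trochanter sits one neck length lateral of the hip centre.
  nl <- d$neck_length
  troch <- c(0, lat * (nl + 0.01 * d$hb / 0.17), -0.015)
  ins_med <- cbind(seq(0.012, -0.012, length.out = n_per_gluteal),
                   troch[2] - lat * 0.004, troch[3] + 0.01)
  # minimus inserts on the anterior facet of the greater trochanter
  ins_min <- cbind(seq(0.024, 0.004, length.out = n_per_gluteal),
                   troch[2] - lat * 0.002, troch[3] + 0.018)
  ins_max <- cbind(seq(-0.012, -0.022, length.out = n_per_gluteal),
                   lat * (0.55 * nl + 0.012),
                   seq(-0.05, -0.09, length.out = n_per_gluteal))

  tibble::tibble(
    group = groups,
    element = paste0(groups, "_", side, sprintf("%02d", sequence(
      rep(n_per_gluteal, 3)))),
    side = side,
    origin = lapply(seq_len(nrow(origins)), function(i) origins[i, ]),
    insertion = lapply(seq_len(nrow(origins)), function(i) {
      rbind(ins_med, ins_min, ins_max)[i, ]
    })
  )
}

#' Generate parametric two-variant pelvis and femur geometry
#'
#' Builds stylised but fully landmarked pelvis and femur surface meshes for
#' a subject under a given hip shape. Both variants share the landmark
#' schema (names and counts), so any two variants form a valid source /
#' target pair for thin-plate-spline warping. The inter-hip-centre distance
#' equals the subject's `hip_breadth` regardless of variant; shape
#' parameters redistribute everything else around the fixed hip centres.
#'
#' @param params a [hip_shape_params()].
#' @param subject one-row tibble from [generate_cohort()] (or a list with
#'   `hip_breadth`, `femur_length`).
#' @return list with `pelvis` and `femur` [landmarked_mesh()]es. Pelvis
#'   frame: origin midway between hip centres, X anterior, Y left, Z up.
#'   Femur frame: origin at the hip centre (right side).
#' @export
generate_hip_geometry <- function(params, subject) {
  if (!inherits(params, "hip_shape_params")) {
    stop("`params` must be a `hip_shape_params` object", call. = FALSE)
  }
  d <- pelvis_dims(params, subject$hip_breadth)
  if (d$blade_radius < 0.05 * d$hb || d$neck_length > subject$femur_length) {
    stop("degenerate shape ratios for this subject", call. = FALSE)
  }
  list(pelvis = pelvis_mesh(params, subject, d),
       femur = femur_mesh(params, subject, d))
}

pelvis_mesh <- function(params, subject, d) {
  # Deformed ellipsoid shell: lateral half-width tracks the blade radius,
  # AP half-depth is compressed by the shape parameter.
  sphere <- unit_sphere_mesh(18, 12)
  half_w <- d$hb / 2 + d$blade_radius * 0.8
  half_d <- 0.75 * d$hb * d$ap
  half_h <- d$blade_height + 0.35 * d$hb
  verts <- cbind(sphere$v[, 1] * half_d, sphere$v[, 2] * half_w,
                 sphere$v[, 3] * half_h)

  flare <- d$flare
  asis_r <- 1.05 * d$blade_radius
  sac_x <- -0.55 * d$hb * d$ap
  lms <- list(
    hip_center_l = c(0, d$hb / 2, 0),
    hip_center_r = c(0, -d$hb / 2, 0),
    asis_l = c(asis_r * cos(pi / 2 - flare) * d$ap,
               d$hb / 2 + asis_r * sin(pi / 2 - flare), d$blade_height),
    asis_r = c(asis_r * cos(pi / 2 - flare) * d$ap,
               -d$hb / 2 - asis_r * sin(pi / 2 - flare), d$blade_height),
    psis_l = c(sac_x, 0.16 * d$hb, d$blade_height * 0.95),
    psis_r = c(sac_x, -0.16 * d$hb, d$blade_height * 0.95),
    pubic_tubercle_l = c(asis_r * cos(pi / 2 - flare) * d$ap, 0.1 * d$hb,
                         -0.28 * d$hb),
    pubic_tubercle_r = c(asis_r * cos(pi / 2 - flare) * d$ap, -0.1 * d$hb,
                         -0.28 * d$hb),
    iliac_crest_l = c(0, d$hb / 2 + d$blade_radius, d$blade_height * 1.1),
    iliac_crest_r = c(0, -d$hb / 2 - d$blade_radius, d$blade_height * 1.1),
    ischial_tuberosity_l = c(-0.12 * d$hb * d$ap, 0.33 * d$hb, -0.35 * d$hb),
    ischial_tuberosity_r = c(-0.12 * d$hb * d$ap, -0.33 * d$hb, -0.35 * d$hb),
    # Sacral endplate built so that the oriented pelvis shows a sacral
    # slope of about 30 degrees (anterior rim higher... anterior rim of S1
    # is anterior and above the posterior rim along a 30 deg incline).
    sacral_endplate_a = c(sac_x + 0.04 * cos(30 * pi / 180), 0,
                          0.75 * d$blade_height + 0.04 * sin(30 * pi / 180)),
    sacral_endplate_p = c(sac_x - 0.04 * cos(30 * pi / 180), 0,
                          0.75 * d$blade_height - 0.04 * sin(30 * pi / 180))
  )
  # Abductor-origin landmarks from the shared parametric site map: the
  # full 12-point medius fan plus three points each for minimus and
  # maximus, so the landmark set densely constrains warps over the blade.
  for (side in c("l", "r")) {
    sites <- hip_attachment_sites(params, subject, side)
    med <- sites[sites$group == "gluteus_medius", ]
    for (k in seq_len(nrow(med))) {
      lms[[sprintf("glut_med_origin_%02d_%s", k, side)]] <- med$origin[[k]]
    }
    for (grp in c("gluteus_minimus", "gluteus_maximus")) {
      gs <- sites[sites$group == grp, ]
      sel <- c(1, ceiling(nrow(gs) / 2), nrow(gs))
      tag <- if (grp == "gluteus_minimus") "glut_min" else "glut_max"
      for (k in seq_along(sel)) {
        lms[[sprintf("%s_origin_%02d_%s", tag, sel[k], side)]] <-
          gs$origin[[sel[k]]]
      }
    }
    # acetabular rim points tie the warp down around the (fixed) hip
    lat <- if (side == "l") 1 else -1
    hip <- c(0, lat * d$hb / 2, 0)
    r_acet <- 0.16 * d$hb
    lms[[paste0("acetab_rim_ant_", side)]] <- hip + c(r_acet, 0, 0)
    lms[[paste0("acetab_rim_sup_", side)]] <- hip + c(0, 0, r_acet)
    lms[[paste0("acetab_rim_post_", side)]] <- hip + c(-r_acet, 0, 0)
  }
  landmarked_mesh(verts, sphere$f, lms)
}

femur_mesh <- function(params, subject, d) {
  fl <- subject$femur_length
  nl <- d$neck_length
  # Shaft tube from just below the neck to the knee, hip centre at origin
  # (right-side convention: lateral = -Y).
  n_ring <- 12; n_len <- 14
  shaft_top <- c(0, -(nl + 0.01), -0.03)
  knee <- c(0, 0, -fl)
  tt <- seq(0, 1, length.out = n_len)
  axis_pts <- outer(1 - tt, shaft_top) + outer(tt, knee)
  radius <- 0.016 + 0.012 * exp(-((tt - 0) / 0.25)^2)  # flares proximally
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  verts <- do.call(rbind, lapply(seq_len(n_len), function(i) {
    cbind(axis_pts[i, 1] + radius[i] * cos(ang),
          axis_pts[i, 2] + radius[i] * sin(ang),
          axis_pts[i, 3])
  }))
  # head sphere vertices around the hip centre
  head <- unit_sphere_mesh(8, 6)
  head_v <- head$v * 0.024
  faces <- rbind(tube_faces(n_len, n_ring),
                 head$f + nrow(verts))
  verts <- rbind(verts, head_v)

  lms <- list(
    femoral_head_center = c(0, 0, 0),
    knee_center = knee,
    knee_axis_medial = knee + c(0, 0.045, 0),
    knee_axis_lateral = knee + c(0, -0.045, 0),
    greater_trochanter = c(0, -(nl + 0.01), -0.015),
    lesser_trochanter = c(-0.01, 0.012, -0.05)
  )
  landmarked_mesh(verts, faces, lms)
}

# Latitude/longitude triangulated unit sphere.
unit_sphere_mesh <- function(n_lon, n_lat) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(lon = lon, lat = lat)
  v <- rbind(
    cbind(cos(grid$lat) * cos(grid$lon), cos(grid$lat) * sin(grid$lon),
          sin(grid$lat)),
    c(0, 0, -1), c(0, 0, 1)
  )
  idx <- function(i, j) (j - 1) * n_lon + (i - 1) %% n_lon + 1
  f <- list()
  for (j in seq_len(n_lat - 1)) {
    for (i in seq_len(n_lon)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  south <- n_lon * n_lat + 1; north <- n_lon * n_lat + 2
  for (i in seq_len(n_lon)) {
    f[[length(f) + 1]] <- c(south, idx(i + 1, 1), idx(i, 1))
    f[[length(f) + 1]] <- c(north, idx(i, n_lat), idx(i + 1, n_lat))
  }
  list(v = v, f = do.call(rbind, f))
}

tube_faces <- function(n_len, n_ring) {
  f <- list()
  for (j in seq_len(n_len - 1)) {
    for (i in seq_len(n_ring)) {
      a <- (j - 1) * n_ring + i
      b <- (j - 1) * n_ring + i %% n_ring + 1
      f[[length(f) + 1]] <- c(a, b, a + n_ring)
      f[[length(f) + 1]] <- c(b, b + n_ring, a + n_ring)
    }
  }
  do.call(rbind, f)
}
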