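sym_test_mesh <- function(perturb = NULL) {
  geom <- generate_hip_geometry(hip_shape_params("human_like"),
                                fix("subject"))
  mesh <- geom$pelvis
  if (!is.null(perturb)) {
    for (nm in names(perturb)) {
      mesh$landmarks[[nm]] <- mesh$landmarks[[nm]] + perturb[[nm]]
    }
  }
  mesh
}

pelvis_pairs <- rbind(
  c("asis_l", "asis_r"), c("psis_l", "psis_r"),
  c("pubic_tubercle_l", "pubic_tubercle_r"),
  c("hip_center_l", "hip_center_r"),
  c("iliac_crest_l", "iliac_crest_r"),
  c("ischial_tuberosity_l", "ischial_tuberosity_r")
)
pelvis_midline <- c("sacral_endplate_a", "sacral_endplate_p")

test_that("an already symmetric pelvis is a fixed point of symmetrisation", {
  mesh <- sym_test_mesh()
  out <- reduce_asymmetry(mesh, pelvis_pairs, pelvis_midline)
  expect_lt(max(abs(out$vertices - mesh$vertices)), 1e-9)
  expect_lt(asymmetry_score(out, pelvis_pairs, pelvis_midline), 1e-10)
})

test_that("a one-sided landmark offset is split evenly across sides", {
  delta <- c(0.004, 0.002, -0.003)
  mesh <- sym_test_mesh(perturb = list(iliac_crest_l = delta))
  out <- reduce_asymmetry(mesh, pelvis_pairs, pelvis_midline)
  orig <- landmark_coords(sym_test_mesh())
  res <- landmark_coords(out)
  moved_l <- res["iliac_crest_l", ] - orig["iliac_crest_l", ]
  # the ideal averaging answer is delta/2; the rigid re-alignment before
  # averaging spreads a small part of the offset over the configuration
  expect_equal(as.numeric(moved_l), delta / 2,
               tolerance = 0.45 * max(abs(delta)))
  expect_lt(asymmetry_score(out, pelvis_pairs, pelvis_midline),
            asymmetry_score(mesh, pelvis_pairs, pelvis_midline) / 20)
})

test_that("random asymmetric perturbations strictly lose asymmetry", {
  for (seed in 1:5) {
    set.seed(seed)
    nm <- sample(c(pelvis_pairs), 3)
    pert <- stats::setNames(
      lapply(nm, function(x) rnorm(3, sd = 0.004)), nm)
    mesh <- sym_test_mesh(perturb = pert)
    before <- asymmetry_score(mesh, pelvis_pairs, pelvis_midline)
    out <- reduce_asymmetry(mesh, pelvis_pairs, pelvis_midline)
    after <- asymmetry_score(out, pelvis_pairs, pelvis_midline)
    expect_lt(after, before)
  }
  expect_error(
    reduce_asymmetry(sym_test_mesh(), rbind(c("nope_l", "nope_r")),
                     pelvis_midline),
    "not present"
  )
})

test_that("joint-centre scaling hits targets exactly and preserves shape", {
  mesh <- sym_test_mesh()
  pair <- list(hips = c("hip_center_l", "hip_center_r"))
  cur <- dist(landmark_coords(mesh, pair$hips))[1]

  out <- scale_to_joint_centers(mesh, pair, c(hips = 0.170))
  expect_equal(dist(landmark_coords(out, pair$hips))[1], 0.170,
               tolerance = 1e-12)
  # shape preserved: ratios of inter-landmark distances unchanged
  d0 <- dist(landmark_coords(mesh)); d1 <- dist(landmark_coords(out))
  expect_lt(max(abs(d1 / d0 - 0.170 / cur)), 1e-9)

  ident <- scale_to_joint_centers(mesh, pair, c(hips = cur))
  expect_equal(ident$vertices, mesh$vertices, tolerance = 1e-12)
  # idempotent at the same target
  twice <- scale_to_joint_centers(out, pair, c(hips = 0.170))
  expect_equal(twice$vertices, out$vertices, tolerance = 1e-12)

  expect_error(
    scale_to_joint_centers(mesh, list(
      hips = c("hip_center_l", "hip_center_r"),
      asis = c("asis_l", "asis_r")
    ), c(hips = 0.170, asis = 0.129)),
    "implied scales"
  )
})

test_that("a 0.277 m fossil-scale femur rescales exactly to a subject femur", {
  geom <- generate_hip_geometry(hip_shape_params("australopith_like"),
                                fix("subject"))
  femur <- geom$femur
  pair <- list(femur = c("femoral_head_center", "knee_center"))
  small <- scale_to_joint_centers(femur, pair, c(femur = 0.277))
  expect_equal(dist(landmark_coords(small, pair$femur))[1], 0.277,
               tolerance = 1e-12)
  target <- fix("subject")$femur_length
  scaled <- scale_to_joint_centers(small, pair, c(femur = target))
  expect_equal(dist(landmark_coords(scaled, pair$femur))[1], target,
               tolerance = 1e-12)
})

test_that("pelvis orientation zeroes the anterior pelvic plane angle", {
  mesh <- sym_test_mesh()
  res0 <- orient_pelvis(mesh)
  expect_lt(abs(res0$achieved_angles$app_angle_deg), 1e-9)

  # pre-tilt by 12 degrees and recover
  centre <- colMeans(landmark_coords(mesh, c("hip_center_l", "hip_center_r")))
  tilted <- hipmorph:::transform_mesh(mesh, function(p) {
    sweep(sweep(p, 2, centre) %*% t(hipmorph:::rot_y(12 * pi / 180)),
          2, centre, "+")
  })
  res <- orient_pelvis(tilted)
  expect_lt(abs(res$achieved_angles$app_angle_deg), 1e-9)
  expect_lt(max(abs(res$mesh$vertices - res0$mesh$vertices)), 1e-9)
})

test_that("the oriented australopith pelvis shows a ~30 degree sacral slope", {
  geom <- generate_hip_geometry(hip_shape_params("australopith_like"),
                                fix("subject"))
  res <- orient_pelvis(geom$pelvis)
  expect_equal(res$achieved_angles$sacral_slope_deg, 30, tolerance = 3)
  expect_error(
    orient_pelvis(landmarked_mesh(matrix(rnorm(30), 10, 3))),
    "not present"
  )
})

test_that("hybrid femur of identical parents reproduces the human femur", {
  geom <- generate_hip_geometry(hip_shape_params("human_like"), fix("subject"))
  hybrid <- build_hybrid_femur(geom$femur, geom$femur,
                               n_proximal = 40, n_distal = 60)
  expect_lt(max(abs(hybrid$vertices - geom$femur$vertices)), 1e-6)
  expect_identical(hybrid$faces, geom$femur$faces)
})

test_that("hybrid femur defaults follow the published construction", {
  expect_equal(formals(build_hybrid_femur)$proximal_fraction, 0.2)
  expect_equal(formals(build_hybrid_femur)$n_proximal, 237)
  expect_equal(formals(build_hybrid_femur)$n_distal, 2500)
})

test_that("distal control vertices are unmoved by the hybrid warp", {
  hg <- generate_hip_geometry(hip_shape_params("human_like"), fix("subject"))
  ag <- generate_hip_geometry(hip_shape_params("australopith_like"),
                              fix("subject"))
  hybrid <- build_hybrid_femur(hg$femur, ag$femur,
                               n_proximal = 40, n_distal = 60)
  report <- attr(hybrid, "report")
  expect_lt(report$value[report$stage == "tps_max_residual"], 1e-8)
  # distal region vertices essentially unchanged
  dist_reg <- hipmorph:::femur_region(hg$femur, 0.15, from = "knee")
  keep <- apply(hg$femur$vertices, 1, function(v) {
    any(colSums(abs(t(dist_reg) - v)) < 1e-12)
  })
  expect_lt(max(abs(hybrid$vertices[keep, ] - hg$femur$vertices[keep, ])),
            5e-4)
})

test_that("a human->australopith->human landmark round trip is smooth", {
  hg <- generate_hip_geometry(hip_shape_params("human_like"), fix("subject"))
  ag <- generate_hip_geometry(hip_shape_params("australopith_like"),
                              fix("subject"))
  src <- landmark_coords(hg$pelvis)
  tgt <- landmark_coords(ag$pelvis)[rownames(src), ]
  there <- fit_tps(src, tgt)
  back <- fit_tps(tgt, src)
  set.seed(8)
  probe <- src[sample(nrow(src), 8), ] +
    matrix(rnorm(24, sd = 0.01), 8, 3)
  round_trip <- apply_tps(back, apply_tps(there, probe))
  expect_lt(max(sqrt(rowSums((round_trip - probe)^2))),
            0.01 * bbox_diagonal(hg$pelvis))
})

test_that("farthest-point sampling spreads points and is deterministic", {
  set.seed(9)
  pts <- matrix(runif(600), 200, 3)
  i1 <- farthest_point_sample(pts, 20)
  i2 <- farthest_point_sample(pts, 20)
  expect_identical(i1, i2)
  expect_equal(length(unique(i1)), 20)
  expect_error(farthest_point_sample(pts, 201), "exceeds")
})
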