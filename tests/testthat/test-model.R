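test_that("model mass, gluteal fan sizes and proportional scaling hold", {
  m <- fix("model_human")
  sub <- fix("subject")
  masses <- vapply(m$segments, `[[`, numeric(1), "mass")
  expect_equal(sum(masses), sub$body_mass, tolerance = 1e-9)

  counts <- table(m$muscles$group[m$muscles$side == "r"])
  expect_equal(unname(counts[["gluteus_medius"]]), 12L)
  expect_equal(unname(counts[["gluteus_minimus"]]), 12L)
  expect_equal(unname(counts[["gluteus_maximus"]]), 12L)

  sub2 <- sub
  sub2$body_mass <- 2 * sub$body_mass
  m2 <- build_subject_model(hip_shape_params("human_like"), sub2)
  masses2 <- vapply(m2$segments, `[[`, numeric(1), "mass")
  expect_equal(masses2, 2 * masses, tolerance = 1e-12)
})

test_that("both variants share hip-to-hip and hip-to-knee distances", {
  mh <- fix("model_human"); ma <- fix("model_austral")
  q <- neutral_posture(mh)
  for (m in list(mh, ma)) {
    st <- fk_state(m, q)
    hh <- sqrt(sum((st$thigh_r$origin - st$thigh_l$origin)^2))
    hk <- sqrt(sum((st$thigh_r$origin - st$shank_r$origin)^2))
    expect_equal(hh, fix("subject")$hip_breadth, tolerance = 1e-9)
    expect_equal(hk, fix("subject")$femur_length, tolerance = 1e-9)
  }
})

test_that("a straight-line muscle's arm equals its perpendicular distance", {
  d <- 0.07
  toy <- toy_leg_model(muscles = tibble::tibble(
    element = c("vert", "through"),
    group = c("toy", "toy"), side = "r", max_strength = 100,
    path = list(
      list(list(segment = "pelvis", point = c(d, 0, 0.2)),
           list(segment = "thigh_r", point = c(d, 0, -0.2))),
      list(list(segment = "pelvis", point = c(0, 0, 0.2)),
           list(segment = "thigh_r", point = c(0, 0, -0.2)))
    )
  ))
  q <- stats::setNames(numeric(8), toy$coord_names)
  expect_equal(abs(moment_arm(toy, q, "vert", "hip_flexion_r")), d,
               tolerance = 1e-6)
  # a path through the joint centre has no leverage
  expect_lt(abs(moment_arm(toy, q, "through", "hip_flexion_r")), 1e-6)
})

test_that("finite-difference arms match the law-of-cosines derivative", {
  a <- 0.12; b <- 0.23
  toy <- toy_leg_model(muscles = tibble::tibble(
    element = "lc", group = "toy", side = "r", max_strength = 100,
    path = list(list(list(segment = "pelvis", point = c(0, 0, a)),
                     list(segment = "thigh_r", point = c(0, 0, -b))))
  ))
  for (theta in c(-0.5, 0.2, 0.9)) {
    q <- stats::setNames(numeric(8), toy$coord_names)
    q["hip_flexion_r"] <- theta
    L <- sqrt(a^2 + b^2 + 2 * a * b * cos(theta))
    expect_equal(unname(muscle_lengths(toy, q, "lc")), L, tolerance = 1e-9)
    analytic <- a * b * sin(theta) / L
    expect_equal(unname(moment_arm(toy, q, "lc", "hip_flexion_r")), analytic,
                 tolerance = 1e-6)
  }
})

test_that("moment arms are invariant to rigid whole-body displacement", {
  m <- fix("model_human")
  q <- neutral_posture(m)
  q2 <- q
  q2[c("pelvis_x", "pelvis_y", "pelvis_z")] <- c(3.1, -0.8, 1.4)
  q2["pelvis_rotation"] <- 0.7
  for (el in c("gluteus_medius_r05", "hamstrings_l02")) {
    dof <- if (grepl("_r", el)) "hip_adduction_r" else "hip_flexion_l"
    expect_equal(moment_arm(m, q, el, dof), moment_arm(m, q2, el, dof),
                 tolerance = 1e-9)
  }
})

test_that("morphing attachments preserves joint centres, masses and applies
          only to affected segments", {
  m <- fix("model_human")
  src <- landmark_coords(
    generate_hip_geometry(hip_shape_params("human_like"), fix("subject"))$pelvis)
  ident <- fit_tps(src, src)
  m_id <- morph_attachments(m, ident, "pelvis")
  expect_equal(muscle_lengths(m_id, neutral_posture(m)),
               muscle_lengths(m, neutral_posture(m)), tolerance = 1e-9)

  tgt <- landmark_coords(
    generate_hip_geometry(hip_shape_params("australopith_like"),
                          fix("subject"))$pelvis)[rownames(src), ]
  warp <- fit_tps(src, tgt)
  m_w <- morph_attachments(m, warp, "pelvis")
  # joint centres and inertial properties untouched
  st0 <- fk_state(m, neutral_posture(m)); st1 <- fk_state(m_w, neutral_posture(m))
  expect_lt(max(abs(st0$thigh_r$origin - st1$thigh_r$origin)), 1e-9)
  expect_identical(vapply(m_w$segments, `[[`, numeric(1), "mass"),
                   vapply(m$segments, `[[`, numeric(1), "mass"))
  # thigh-side insertions untouched, pelvis-side origins moved
  path0 <- m$muscles$path[[1]]; path1 <- m_w$muscles$path[[1]]
  expect_false(isTRUE(all.equal(path0[[1]]$point, path1[[1]]$point)))
  expect_equal(path0[[2]]$point, path1[[2]]$point)
})

test_that("the anterior gluteus medius origin moves posteriorly under the
          australopith warp", {
  src <- landmark_coords(
    generate_hip_geometry(hip_shape_params("human_like"), fix("subject"))$pelvis)
  tgt <- landmark_coords(
    generate_hip_geometry(hip_shape_params("australopith_like"),
                          fix("subject"))$pelvis)[rownames(src), ]
  warp <- fit_tps(src, tgt)
  m_w <- morph_attachments(fix("model_human"), warp, "pelvis")
  ant <- which(fix("model_human")$muscles$element == "gluteus_medius_r01")
  before <- fix("model_human")$muscles$path[[ant]][[1]]$point
  after <- m_w$muscles$path[[ant]][[1]]$point
  expect_lt(after[1], before[1])
})

test_that("path checks are clean on the stock model and flag constructed
          failures deterministically", {
  tr <- fix("trial_clean")
  kin <- fix("kin_clean")
  fr <- stride_frames(tr)
  postures <- lapply(fr[seq(1, length(fr), by = 12)], function(f) {
    kin$q_filt[match(f, kin$frames), ]
  })
  rep1 <- check_muscle_paths(fix("model_human"), postures)
  expect_equal(nrow(rep1), 0L)
  expect_identical(rep1, check_muscle_paths(fix("model_human"), postures))

  bad <- fix("model_human")
  j <- which(bad$muscles$element == "gluteus_medius_r06")
  # drag the origin onto the hip joint centre: no leverage about the hip
  bad$muscles$path[[j]][[1]]$point <- c(0, -fix("subject")$hip_breadth / 2, 0)
  bad$muscles$path[[j]][[2]]$point <- c(0, 0.001, -0.001)
  attr(bad, "path_cache") <- NULL
  attr(bad, "path_cache") <- hipmorph:::path_cache(bad)
  rep2 <- check_muscle_paths(bad, postures)
  expect_true("path_through_joint_center" %in% rep2$flag)
})
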