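test_that("cohorts are balanced, bounded and seed-deterministic", {
  coh <- generate_cohort(10, seed = 1)
  expect_equal(as.integer(table(coh$sex)[c("F", "M")]), c(5L, 5L))
  expect_identical(coh, generate_cohort(10, seed = 1))
  expect_false(identical(coh, generate_cohort(10, seed = 2)))
  expect_error(generate_cohort(0), "positive")

  b <- cohort_bounds()
  one <- generate_cohort(1, seed = 7)
  expect_true(one$stature >= b$stature_F[1] && one$stature <= b$stature_F[2])
  expect_true(one$body_mass / one$stature^2 >= b$bmi[1] &&
                one$body_mass / one$stature^2 <= b$bmi[2])
  expect_true(all(coh$hip_breadth > 0 & coh$hip_breadth < coh$stature))
  expect_true(all(coh$femur_length > 0 & coh$femur_length < coh$stature))
})

test_that("hip geometry variants share schema and hip spacing, and the
          australopith form is anteroposteriorly compressed", {
  sub <- fix("subject")
  hg <- generate_hip_geometry(hip_shape_params("human_like"), sub)
  ag <- generate_hip_geometry(hip_shape_params("australopith_like"), sub)

  expect_setequal(names(hg$pelvis$landmarks), names(ag$pelvis$landmarks))
  expect_setequal(names(hg$femur$landmarks), names(ag$femur$landmarks))

  hip_dist <- function(g) {
    dist(landmark_coords(g$pelvis, c("hip_center_l", "hip_center_r")))[1]
  }
  expect_equal(hip_dist(hg), sub$hip_breadth, tolerance = 1e-12)
  expect_equal(hip_dist(hg), hip_dist(ag), tolerance = 1e-12)

  depth <- function(g) diff(range(g$pelvis$vertices[, 1]))
  expect_lt(depth(ag), depth(hg))

  expect_error(
    generate_hip_geometry(
      hip_shape_params("human_like", neck_length_ratio = 50), sub),
    "degenerate"
  )
})

test_that("more iliac flare moves the anterior abductor origin anteriorly", {
  sub <- fix("subject")
  xs <- vapply(c(15, 30, 45), function(fl) {
    g <- generate_hip_geometry(
      hip_shape_params("human_like", iliac_flare_angle = fl), sub)
    landmark_coords(g$pelvis, "glut_med_origin_01_l")[1, "x"]
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("trials are bit-identical under the same seed", {
  t1 <- generate_gait_trial(fix("subject"), trial_seed = 42)
  t2 <- generate_gait_trial(fix("subject"), trial_seed = 42)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$grf, t2$grf)
  expect_false(identical(
    t1$markers, generate_gait_trial(fix("subject"), trial_seed = 43)$markers))
})

test_that("vertical plate forces are nonnegative and average body weight", {
  tr <- fix("trial_clean")
  expect_true(all(tr$grf$fz >= 0))
  fr <- stride_frames(tr)
  tot <- tapply(tr$grf$fz[tr$grf$frame %in% fr],
                tr$grf$frame[tr$grf$frame %in% fr], sum)
  bw <- fix("subject")$body_mass * 9.80665
  expect_equal(mean(tot) / bw, 1, tolerance = 0.01)
})

test_that("the symmetric program makes left curves a half-stride shift of
          right curves", {
  tr <- fix("trial_clean")
  truth <- attr(tr, "truth")
  T_frames <- tr$events$ipsi_ic - tr$events$ic
  shift <- round(T_frames / 2)
  n <- nrow(truth$q)
  idx <- seq_len(n - shift)
  for (cn in c("hip_flexion", "knee_flexion", "ankle_flexion")) {
    r <- truth$q[idx + shift, paste0(cn, "_r")]
    l <- truth$q[idx, paste0(cn, "_l")]
    # the event grid rounds the half-period to whole frames
    expect_lt(max(abs(r - l)), 0.05)
  }
})

test_that("all marker trajectories share the frame grid and events lie
          within the recording", {
  tr <- fix("trial_clean")
  counts <- table(tr$markers$marker)
  expect_equal(length(unique(counts)), 1L)
  frames <- sort(unique(tr$markers$frame))
  expect_true(tr$events$ic %in% frames && tr$events$ipsi_ic %in% frames)
  expect_equal(length(unique(table(tr$markers$frame))), 1L)
})

test_that("out-of-range speeds are clamped with a warning", {
  expect_warning(tr <- generate_gait_trial(fix("subject"), walking_speed = 5,
                                           trial_seed = 1),
                 "clamp")
  expect_equal(tr$walking_speed, 2.5)
  expect_error(generate_gait_trial(fix("subject"), walking_speed = -1),
               "> 0")
})
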