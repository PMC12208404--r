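test_that("the default balanced design runs and is seed-deterministic", {
  cur <- null_curves(10, 3, seed = 2)
  r1 <- spm_rm_anova(cur, n_permutations = 200, seed = 9)
  r2 <- spm_rm_anova(cur, n_permutations = 200, seed = 9)
  expect_identical(r1$field, r2$field)
  expect_identical(r1$threshold, r2$threshold)
  expect_equal(r1$n_subjects, 10)
  expect_equal(nrow(r1$field), 101)
  expect_true(all(r1$field$F >= 0))
})

test_that("unbalanced designs are rejected with subsetting advice", {
  cur <- null_curves(5, 3, seed = 3)
  cur <- cur[!(cur$subject == "S01" & cur$condition == "A" & cur$trial == 3), ]
  expect_error(spm_rm_anova(cur, n_permutations = 50), "subset")
})

test_that("the critical threshold is monotone non-increasing in alpha", {
  cur <- null_curves(8, 3, seed = 4)
  thrs <- vapply(c(0.01, 0.05, 0.2), function(a) {
    spm_rm_anova(cur, alpha = a, n_permutations = 300, seed = 5)$threshold
  }, numeric(1))
  expect_true(all(diff(thrs) <= 0))
})

test_that("the F-field is invariant to relabelling subjects", {
  cur <- null_curves(6, 3, seed = 6)
  r1 <- spm_rm_anova(cur, n_permutations = 100, seed = 7)
  relab <- cur
  map <- stats::setNames(sample(unique(cur$subject)), unique(cur$subject))
  relab$subject <- unname(map[relab$subject])
  r2 <- spm_rm_anova(relab, n_permutations = 100, seed = 7)
  expect_equal(r2$field$F, r1$field$F, tolerance = 1e-12)
})

test_that("a strong injected offset is detected exactly where it was
          injected", {
  cur <- null_curves(10, 3, seed = 8, effect = 1.5, window = 40:60)
  r <- spm_rm_anova(cur, n_permutations = 500, seed = 9)
  expect_gt(nrow(r$clusters), 0)
  hit <- any(r$clusters$start_node <= 60 & r$clusters$end_node >= 40)
  expect_true(hit)
  expect_true(all(r$clusters$p_value > 0 & r$clusters$p_value <= 1))
})

test_that("family-wise false positives stay near the nominal level on null
          data (reduced Monte Carlo)", {
  hits <- vapply(1:60, function(i) {
    cur <- null_curves(10, 3, seed = 100 + i)
    r <- spm_rm_anova(cur, n_permutations = 300, seed = i)
    nrow(r$clusters) > 0
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.07)
})

test_that("tidy and glance summarise SPM results", {
  cur <- null_curves(6, 3, seed = 11, effect = 2)
  r <- spm_rm_anova(cur, n_permutations = 200, seed = 2)
  expect_identical(tidy(r), r$clusters)
  g <- glance(r)
  expect_equal(g$n_clusters, nrow(r$clusters))
  expect_s3_class(autoplot(r), "gg")
})
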