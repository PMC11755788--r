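two_groups <- function(...) {
  cohort_config(groups = default_groups()[c(1, 4), ], n_per_group = 1,
                hours = 2, ...)
}

test_that("the generators are fully seed-deterministic", {
  a <- simulate_homecage(two_groups(seed = 3))
  b <- simulate_homecage(two_groups(seed = 3))
  expect_identical(a, b)
  c <- simulate_homecage(two_groups(seed = 4))
  expect_false(identical(a[[1]]$keypoints$center$x,
                         c[[1]]$keypoints$center$x))
  s1 <- simulate_syllables(two_groups(seed = 3))
  s2 <- simulate_syllables(two_groups(seed = 3))
  expect_identical(s1, s2)
  g1 <- simulate_gait_runs(two_groups(seed = 3))
  g2 <- simulate_gait_runs(two_groups(seed = 3))
  expect_identical(g1, g2)
})

test_that("zero activity freezes the centroid completely", {
  cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                      n_per_group = 1, hours = 2, seed = 5,
                      keypoint_noise_px = 0)
  cc$effects$WT_Y$activity <- 0
  rec <- simulate_homecage(cc)[[1]]
  expect_equal(max(centroid_speed(rec)), 0)
  expect_equal(percent_moved(rec), 0)
})

test_that("night activity is twice day activity at the default knobs", {
  ratios <- vapply(1:4, function(s) {
    cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                        n_per_group = 2, hours = 22, seed = s)
    recs <- simulate_homecage(cc)
    mean(vapply(recs, function(r) {
      night <- phase_interval(r$timeline, "night")
      day <- phase_interval(r$timeline, "day")
      # skip the acclimation transient at the start of the day phase
      percent_moved(r, night) /
        percent_moved(r, c(day[1] + 2 * 3600, day[2]))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(min(ratios), 1.4)         # direction, every seed
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("simulated recordings carry the assay structure", {
  cc <- two_groups(seed = 6)
  recs <- simulate_homecage(cc)
  rec <- recs[[1]]
  expect_length(recs, 2L)
  expect_equal(n_frames(rec), 2 * 3600)
  expect_setequal(names(rec$keypoints), mouse_bodyparts)
  g <- rec$geometry
  for (bp in names(rec$keypoints)) {
    lik <- rec$keypoints[[bp]]$likelihood
    expect_true(all(lik >= 0 & lik <= 1))
  }
  # dropout rate close to its target across all keypoints
  drop_rate <- mean(vapply(rec$keypoints, function(k)
    mean(k$likelihood < 0.90), numeric(1)))
  expect_lt(abs(drop_rate - cc$dropout), 0.01)
  # group labels propagate
  expect_equal(recs[[2]]$genotype, "AD")
  expect_equal(recs[[2]]$age, "old")
})

test_that("syllable generation follows the codebook", {
  one <- syllable_codebook(1)
  cc <- two_groups(seed = 7)
  s <- simulate_syllables(cc, one)[[1]]
  expect_true(all(s$labels == 0L))

  bad <- syllable_codebook(3)
  bad$transition[1, ] <- c(0, 2, 2)
  expect_error(syllable_codebook(3, transition = bad$transition),
               "sum to 1")
  expect_error(syllable_codebook(3, mean_duration_s = c(1, -1, 2)),
               "positive")

  # uniform codebook: empirical usage uniform within CI
  cb <- syllable_codebook(5, mean_duration_s = rep(2, 5))
  cc2 <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                       n_per_group = 1, hours = 22, seed = 8)
  s <- simulate_syllables(cc2, cb)[[1]]
  fd <- frequency_duration(s)
  expect_true(all(abs(fd$frequency - 0.2) < 0.03))
  expect_equal(mean(fd$mean_duration_s), 2, tolerance = 0.15)

  # empirical bout transition matrix recovers the generating chain
  m <- transition_matrix(s)
  expect_lt(max(abs(m - cb$transition)), 0.05)
})

test_that("the usage tilt is recovered by the frequency estimate", {
  cb <- syllable_codebook(10, mean_duration_s = rep(2, 10))
  cc <- cohort_config(groups = default_groups()[c(1, 4), ],
                      n_per_group = 1, hours = 22, seed = 9,
                      tilt_syllable = 6L)
  seqs <- simulate_syllables(cc, cb)
  f_wt <- frequency_duration(seqs[[1]])$frequency[6]
  f_ad <- frequency_duration(seqs[[2]])$frequency[6]
  expect_gt(f_ad / f_wt, 1.4)
  # oracle: stationary distribution of the tilted bout chain
  P <- cagewalk:::tilted_transition(cb, 2, 6L)
  ev <- eigen(t(P))
  pi_ <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_ <- pi_ / sum(pi_)
  expect_equal(f_ad, pi_[6], tolerance = 0.15 * pi_[6])
})

test_that("gait generation exposes the planted group effects", {
  cc <- two_groups(seed = 10)
  cc$effects$WT_Y$nssp_corruption <- 0
  runs <- simulate_gait_runs(cc)
  wt <- runs[vapply(runs, function(r) r$animal, "") == "WT_Y_1"]
  expect_true(all(vapply(wt, nssp_percent, numeric(1)) == 100))

  # hindpaw intensity gain 1.3 recovered as a ratio against baseline
  rs <- run_summary(runs, dt = 0.01)$per_animal
  hind <- (rs$mean_intensity_RH + rs$mean_intensity_LH) / 2
  names(hind) <- rs$animal
  expect_equal(unname(hind["AD_O_1"] / hind["WT_Y_1"]), 1.3,
               tolerance = 0.05)

  # injected non-compliant runs are excluded by the filter
  runs_nc <- simulate_gait_runs(cc, include_noncompliant = TRUE)
  out <- compliance_filter(runs_nc)
  expect_equal(nrow(out$excluded), 2L)
  expect_setequal(out$excluded$reason, c("duration", "bidirectional"))

  expect_error({
    bad <- two_groups(seed = 1,
                      effects = list(WT_Y = list(nssp_corruption = 1.5)))
  }, "nssp_corruption")
  expect_error(cohort_config(n_per_group = 0), "positive")
  expect_error(cohort_config(dropout = 1), "dropout")
  expect_error(cohort_config(hours = -2), "duration")
})
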