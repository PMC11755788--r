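paws4 <- c("RF", "RH", "LF", "LH")

test_that("compliance is strict at 10 s and one-directionality", {
  ok <- run_from_schedule(rep(paws4, 4), seq(0, 9.0, length.out = 16),
                          stands = 0.5)
  expect_lt(run_duration <- max(ok$footfalls$release), 10)
  boundary <- run_from_schedule(rep(paws4, 4),
                                seq(0, 9.8, length.out = 16),
                                stands = 0.2)
  expect_equal(max(boundary$footfalls$release) -
                 min(boundary$footfalls$contact), 10)
  rev_ff <- data.frame(paw = rep(paws4, 4),
                       contact = seq(0, 3, length.out = 16),
                       release = seq(0, 3, length.out = 16) + 0.1,
                       heel_x = c(seq(10, 80, length.out = 8),
                                  seq(80, 10, length.out = 8)),
                       heel_y = 60)
  reversal <- gait_run(rev_ff)
  out <- compliance_filter(list(ok, boundary, reversal))
  expect_length(out$compliant, 1L)
  expect_equal(out$excluded$reason, c("duration", "bidirectional"))
  # fewer than 3 compliant runs flags the animal
  expect_true(out$report$flagged[out$report$animal == "a1"])
  ok3 <- lapply(1:3, function(i)
    run_from_schedule(rep(paws4, 2), seq(0, 2, length.out = 8),
                      run_id = i))
  expect_false(compliance_filter(ok3)$report$flagged)
})

test_that("paw parameters follow the print geometry and timing", {
  # heel (0,0), third toe (0,30) at 10 px/mm -> print length 3 mm
  ff <- data.frame(paw = "RF", contact = 0, release = 0.2,
                   heel_x = 0, heel_y = 0, toe3_x = 0, toe3_y = 30)
  run <- gait_run(ff, px_per_mm = 10)
  expect_equal(paw_parameters(run)$print_length_mm, 3)

  # paw axis parallel to the body axis -> angle 0; perpendicular -> 90
  ff2 <- data.frame(paw = c("RF", "LF"), contact = c(0, 0.5),
                    release = c(0.2, 0.7),
                    heel_x = c(0, 10), heel_y = c(0, 0),
                    toe3_x = c(12, 10), toe3_y = c(0, 8))
  pp2 <- paw_parameters(gait_run(ff2))
  expect_equal(pp2$paw_angle_deg[1], 0)
  expect_equal(abs(pp2$paw_angle_deg[2]), 90)

  # stand / step cycle / swing arithmetic
  ff3 <- data.frame(paw = c("RF", "RF"), contact = c(1.0, 1.5),
                    release = c(1.3, 1.8))
  pp3 <- paw_parameters(gait_run(ff3))
  expect_equal(pp3$stand_s[1], 0.3)
  expect_equal(pp3$step_cycle_s[1], 0.5)
  expect_equal(pp3$swing_s[1], 0.2)
  expect_true(is.na(pp3$step_cycle_s[2]))  # last contact: no cycle
  # step cycle is never shorter than stand on simulated runs
  cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                      n_per_group = 1, seed = 2)
  run <- simulate_gait_runs(cc)[[1]]
  pp <- paw_parameters(run)
  ok <- !is.na(pp$step_cycle_s)
  expect_true(all(pp$step_cycle_s[ok] >= pp$stand_s[ok] - 1e-9))
})

test_that("support categories partition the run and match the oracle", {
  # all four paws down throughout
  four <- gait_run(data.frame(paw = paws4, contact = 0:3 * 1e-9,
                              release = 5))
  sup <- support_fractions(four, exact = TRUE)
  expect_equal(sup[["four"]], 100, tolerance = 1e-6)

  # perfect trot: diagonal pairs alternating, tiling the run
  trot <- gait_run(data.frame(
    paw = rep(c("RF", "LH", "LF", "RH"), 2),
    contact = rep(0:3, each = 2),
    release = rep(0:3, each = 2) + 1
  ))
  sup_trot <- support_fractions(trot, exact = TRUE)
  expect_equal(sup_trot[["diagonal"]], 100, tolerance = 1e-6)

  set.seed(51)
  for (i in 1:50) {
    run <- random_schedule()
    expect_equal(sum(support_fractions(run, exact = TRUE)), 100,
                 tolerance = 1e-9)
    expect_equal(sum(support_fractions(run, dt = 0.01)), 100,
                 tolerance = 1e-9)
  }
})

test_that("discretized support converges to the event-driven oracle", {
  set.seed(52)
  run <- random_schedule(n = 16, span = 4)
  exact <- support_fractions(run, exact = TRUE)
  err <- vapply(c(0.05, 0.01, 0.002), function(dt)
    max(abs(support_fractions(run, dt = dt) - exact)), numeric(1))
  expect_lt(err[3], err[1] + 1e-9)
  expect_lt(err[3], 0.5)
})

test_that("base of support averages lateral widths of the girdle pairs", {
  ff <- data.frame(paw = rep(c("RH", "LH"), 3),
                   contact = seq(0, 2.5, by = 0.5),
                   release = seq(0, 2.5, by = 0.5) + 0.3,
                   heel_x = seq(10, 60, by = 10),
                   heel_y = rep(c(65, 55), 3))
  bos <- base_of_support(gait_run(ff, px_per_mm = 2))
  expect_equal(bos[["hind"]], 5)      # 10 px / 2 px-per-mm
  expect_true(is.na(bos[["front"]]))
  ff0 <- ff; ff0$heel_y <- 60
  expect_equal(base_of_support(gait_run(ff0, px_per_mm = 2))[["hind"]], 0)
  # brute-force pairing oracle on a random run
  set.seed(53)
  run <- random_schedule(n = 20, span = 5)
  got <- base_of_support(run)
  brute_one <- function(pair) {
    d <- run$footfalls[run$footfalls$paw %in% pair, , drop = FALSE]
    w <- c()
    if (nrow(d) > 1) for (i in seq_len(nrow(d) - 1))
      if (d$paw[i] != d$paw[i + 1])
        w <- c(w, abs(d$heel_y[i + 1] - d$heel_y[i]))
    if (length(w)) mean(w) / run$px_per_mm else NA_real_
  }
  expect_equal(got[["front"]], brute_one(c("RF", "LF")))
  expect_equal(got[["hind"]], brute_one(c("RH", "LH")))
})

test_that("NSSP matches the exhaustive window oracle", {
  # pure alternate pattern scores 100
  aa <- run_from_schedule(rep(paws4, 5), seq(0, 4.75, by = 0.25))
  expect_equal(nssp_percent(aa), 100)
  # a single paw never completes a pattern
  rf <- run_from_schedule(rep("RF", 8), seq(0, 1.75, by = 0.25))
  expect_equal(nssp_percent(rf), 0)
  # fewer than 4 steps: undefined and flagged
  short <- run_from_schedule(c("RF", "LF", "RH"), c(0, 0.2, 0.4))
  expect_true(is.na(nssp_percent(short)))
  expect_match(attr(nssp_percent(short), "reason"), "4 steps")

  # oracle: the six canonical patterns and their rotations, built
  # independently; every 4-step window is checked against this set
  pats <- list(c("RF", "RH", "LF", "LH"), c("LF", "RH", "RF", "LH"),
               c("RF", "LF", "RH", "LH"), c("LF", "RF", "LH", "RH"),
               c("RF", "LF", "LH", "RH"), c("LF", "RF", "RH", "LH"))
  normal_set <- unique(unlist(lapply(pats, function(p)
    lapply(0:3, function(k)
      paste(p[((seq_len(4) - 1 + k) %% 4) + 1], collapse = "-"))),
    recursive = FALSE))
  oracle_window <- function(w) paste(w, collapse = "-") %in% normal_set
  # the rotation closure of the six patterns is all 24 permutations
  expect_length(normal_set, 24L)

  set.seed(54)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    paws <- sample(paws4, n, replace = TRUE)
    run <- run_from_schedule(paws, seq(0, by = 0.25, length.out = n))
    windows <- vapply(seq_len(n - 3), function(j)
      oracle_window(paws[j:(j + 3)]), logical(1))
    expect_equal(nssp_percent(run), 100 * mean(windows))
  }
})

test_that("run summaries aggregate steps, cadence and paw means", {
  # 20 steps over 5 s (first contact 0, last release 5) -> cadence 4
  contacts <- seq(0, 4.75, by = 0.25)
  run <- gait_run(data.frame(paw = rep(paws4, 5), contact = contacts,
                             release = contacts + c(rep(0.2, 19), 0.25)))
  rs <- run_summary(list(run), dt = 0.01)
  expect_equal(rs$per_run$duration_s, 5)
  expect_equal(rs$per_run$n_steps, 20L)
  expect_equal(rs$per_run$cadence, 4)
  # averaging two identical runs changes nothing
  run2 <- run; run2$run_id <- 2L
  rs2 <- run_summary(list(run, run2), dt = 0.01)
  expect_equal(rs2$per_animal$cadence, rs$per_run$cadence)
  expect_equal(rs2$per_animal$nssp_pct, rs$per_run$nssp_pct)
  # per-animal mean equals the brute-force mean over the run table
  cc <- cohort_config(groups = default_groups()[1:2, ], n_per_group = 2,
                      seed = 9)
  runs <- simulate_gait_runs(cc)
  rs3 <- run_summary(runs, dt = 0.01)
  for (an in unique(rs3$per_run$animal)) {
    sel <- rs3$per_run$animal == an
    expect_equal(
      rs3$per_animal$n_steps[rs3$per_animal$animal == an],
      mean(rs3$per_run$n_steps[sel]))
  }
})

test_that("gait_run validates footfall records", {
  expect_error(gait_run(data.frame(paw = "XX", contact = 0,
                                   release = 1)), "paw")
  expect_error(gait_run(data.frame(paw = "RF", contact = 1,
                                   release = 1)), "release")
  expect_error(gait_run(data.frame(paw = "RF", contact = 0, release = 1,
                                   mean_intensity = 300)), "255")
})
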