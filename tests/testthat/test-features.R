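test_that("percent moved counts threshold crossings exactly", {
  frozen <- rec_from_moves(rep(FALSE, 100))
  expect_equal(percent_moved(frozen), 0)
  mover <- rec_from_moves(c(FALSE, rep(TRUE, 99)))  # frame 1 has speed 0
  expect_equal(percent_moved(mover, c(1, 100)), 100)
  # 37 moving frames out of 600
  move <- rep(FALSE, 600)
  move[sample.int(599, 37) + 1L] <- TRUE
  rec <- rec_from_moves(move)
  expect_equal(percent_moved(rec, c(0, 600)), 100 * 37 / 600,
               tolerance = 1e-12)
})

test_that("speed classes match a hand count and nest correctly", {
  # speeds (cm/s): 0, 1, 1, 1, 5 at 6 px/cm -> steps 6, 6, 6, 30 px
  xy <- cbind(100 + cumsum(c(0, 6, -6, 6, 30)), rep(120, 5))
  rec <- make_track_rec(xy)
  sf <- speed_class_fractions(rec, c(0, 5))
  expect_equal(sf[["moved"]], 80)
  expect_equal(sf[["scoot"]], 60)
  expect_equal(sf[["burst"]], 20)
  expect_equal(sf[["speed"]], mean(c(1, 1, 1, 5)))

  still <- rec_from_moves(rep(FALSE, 20))
  sf0 <- speed_class_fractions(still, c(0, 20))
  expect_equal(unname(sf0[c("moved", "scoot", "burst", "escape")]),
               rep(0, 4))
  expect_equal(sf0[["speed"]], 0)
  expect_true(isTRUE(attr(sf0, "no_movement")))

  set.seed(21)
  for (i in 1:10) {
    rec <- make_track_rec(cbind(160 + cumsum(rnorm(200, 0, 8)) %% 50,
                                120 + cumsum(rnorm(200, 0, 8)) %% 50))
    sf <- speed_class_fractions(rec)
    expect_lte(sf[["escape"]], sf[["burst"]] + 1e-12)
    expect_lte(sf[["burst"]], sf[["moved"]] + 1e-12)
    expect_lte(sf[["scoot"]] + sf[["burst"]], sf[["moved"]] + 1e-12)
    expect_lte(sf[["moved"]], 100)
  }
})

test_that("stretch-attend requires elongation and low speed", {
  never <- make_track_rec(cbind(rep(100, 50), rep(100, 50)))
  expect_equal(sap_fraction(never), 0)

  # elongation must coincide with low speed to count as SAP
  n <- 100
  move <- rep(FALSE, n)
  move[seq(6, 96, 5)] <- TRUE                      # 19 moving frames
  elong <- rep(1, n)
  elong[move] <- 1.4                               # elongated but fast
  slow_elongated <- c(2, 3, 4, 8, 9, 12, 13, 14, 17, 18)
  elong[slow_elongated] <- 1.4                     # 10 SAP frames
  rec <- rec_from_moves(move, elong = elong)
  sap <- sap_fraction(rec)
  expect_lt(sap, 100 * mean(elong > 1.2))
  expect_equal(sap, 10)
})

test_that("acclimation is the period-1 minus period-6 difference", {
  # frame 1 always has speed 0, so the flat pattern starts at frame 2
  flat <- rec_from_moves(rep(c(FALSE, TRUE), 1800))
  expect_equal(acclimation(flat, "movement"), 0)
  # 30% moving in period 1, 10% in period 6 (600-frame periods)
  move <- rep(FALSE, 3600)
  move[which(seq_len(600) %% 10 %in% 2:4)] <- TRUE           # period 1: 30%
  move[3000 + which(seq_len(600) %% 10 == 2)] <- TRUE        # period 6: 10%
  rec <- rec_from_moves(move)
  expect_equal(acclimation(rec, "movement"), 20, tolerance = 1e-9)
})

test_that("habituation indices follow the per-presentation responses", {
  tl <- assay_timeline()
  onsets <- stimulus_onsets(tl)
  n <- as.integer(onsets[3] + 1200)
  resp <- c(40, 25, 10)
  # each post-onset period gets exactly resp% moving frames; pre 0%
  move <- rep(FALSE, n)
  for (k in 1:3) {
    idx <- onsets[k] + seq_len(600)
    move[idx[seq_len(resp[k] * 6)]] <- TRUE
  }
  rec <- rec_from_moves(move)
  r <- habituation_responses(rec, "moved")
  expect_equal(r, resp, tolerance = 1e-9)
  expect_equal(habituation(rec, "moth", "moved"), 30, tolerance = 1e-9)
  expect_equal(habituation(rec, "lines1", "moved"), 15, tolerance = 1e-9)

  quiet <- rec_from_moves(rep(FALSE, n))
  expect_equal(habituation(quiet, "moth", "moved"), 0)
  # an onset within one period of the assay start has no pre-window
  early <- assay_timeline(
    phases = data.frame(phase = c("night_stimuli", "day"),
                        start_h = c(0, 6), end_h = c(6, 22)),
    stimulus_onsets_h = c(1 / 120, 2, 4))
  rec2 <- rec_from_moves(rep(FALSE, 6 * 3600))
  rec2$timeline <- early
  expect_error(habituation_responses(rec2, "moved"), "edge")
})

test_that("quadrant occupancy partitions to 100", {
  parked <- make_track_rec(cbind(rep(80, 60), rep(60, 60)))
  expect_equal(unname(quadrant_occupancy(parked)), c(100, 0, 0, 0))
  set.seed(31)
  for (i in 1:10) {
    rec <- make_track_rec(cbind(runif(100, 0, 320), runif(100, 0, 240)))
    expect_equal(sum(quadrant_occupancy(rec)), 100, tolerance = 1e-9)
  }
})

test_that("wall distance matches geometry and a brute-force oracle", {
  wall <- make_track_rec(cbind(rep(0, 10), rep(100, 10)))
  expect_equal(distance_from_wall(wall), 0)
  centre <- make_track_rec(cbind(rep(160, 10), rep(120, 10)))
  expect_equal(distance_from_wall(centre), 120)  # min(W, H) / 2
  set.seed(32)
  xy <- cbind(runif(50, 0, 320), runif(50, 0, 240))
  rec <- make_track_rec(xy)
  brute <- mean(apply(xy, 1, function(p)
    min(p[1], 320 - p[1], p[2], 240 - p[2])))
  expect_equal(distance_from_wall(rec), brute)
})

test_that("window time uses the nose and conjuncts with the partner", {
  geom <- cage_geometry()
  wc <- geom$window_center
  at_window <- make_track_rec(cbind(rep(wc[1] - 22.5, 40), rep(wc[2], 40)),
                              geometry = geom)
  expect_equal(time_near_window(at_window), 100)
  away <- make_track_rec(cbind(rep(50, 40), rep(50, 40)), geometry = geom)
  expect_equal(time_near_window(away), 0)
  # zero radius: nothing counts
  g0 <- cage_geometry(window_radius_px = 0)
  expect_equal(time_near_window(make_track_rec(
    cbind(rep(100, 10), rep(100, 10)), geometry = g0)), 0)
  # one-sided presence can only shrink the conjunction
  partner <- rep(c(TRUE, FALSE), 20)
  expect_lte(time_near_window(at_window, partner = partner),
             time_near_window(at_window))
  expect_equal(time_near_window(at_window, partner = at_window), 100)
  expect_error(time_near_window(at_window, partner = rep(TRUE, 3)),
               "frame count")
})

test_that("batteries have fixed width, are deterministic, flag missing", {
  cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                      n_per_group = 1, hours = 2, seed = 5)
  rec <- filter_low_likelihood(simulate_homecage(cc)[[1]])
  b1 <- battery_track15(rec)
  b2 <- battery_pose52(rec)
  expect_equal(nrow(b1), 15L)
  expect_equal(nrow(b2), 52L)
  # per-phase entries are computed on their own intervals: the night
  # phase (doubled activity) must differ from the day phase
  v <- function(p) b2$value[b2$parameter == p]
  expect_false(isTRUE(all.equal(v("moved_day_pct"),
                                v("moved_night_pct"))))
  expect_gt(v("moved_night_pct"), v("moved_day_pct"))
  expect_false(any(duplicated(b1$parameter)))
  expect_false(any(duplicated(b2$parameter)))
  expect_equal(battery_track15(rec), b1)

  # missing nose: SAP/window entries flagged, width preserved
  noseless <- rec
  noseless$keypoints$nose <- NULL
  noseless$mask <- noseless$mask[, colnames(noseless$mask) != "nose"]
  b3 <- battery_pose52(noseless)
  expect_equal(nrow(b3), 52L)
  expect_true(any(b3$missing))
  expect_true(all(is.na(b3$value[b3$missing])))
  expect_true("acclimation_sap" %in% b3$parameter[b3$missing])
})

test_that("battery quadrant block partitions to 100", {
  cc <- cohort_config(groups = default_groups()[1, , drop = FALSE],
                      n_per_group = 1, hours = 2, seed = 6)
  rec <- simulate_homecage(cc)[[1]]
  b <- battery_track15(rec)
  q <- b$value[grepl("^quadrant_", b$parameter)]
  expect_equal(sum(q), 100, tolerance = 1e-6)
})
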