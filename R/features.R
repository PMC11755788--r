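#' Speed-class configuration
#'
#' Thresholds classifying per-frame centroid speed into movement
#' classes. Thresholds are given in cm/s and converted to px/s through
#' the recording's `px_per_cm` scale at computation time. A frame is
#' "moved" when its speed exceeds `move_cms`; "scoot" is low-speed
#' movement in `(move_cms, scoot_hi_cms)`; "burst" is speed at or above
#' `burst_lo_cms`. "Escape" frames are burst frames within
#' `escape_window_s` seconds after a stimulus onset whose displacement
#' is directed toward the hut. No instrument thresholds are published
#' for this assay; the defaults are chosen so the three classes are
#' non-degenerate on the synthetic baseline and are fully configurable.
#'
#' @param move_cms Movement threshold (cm/s), default 0.5.
#' @param scoot_hi_cms Upper edge of the scoot band (cm/s), default 4.
#' @param burst_lo_cms Lower edge of the burst band (cm/s), default 4.
#' @param escape_window_s Post-onset window for escape frames (s),
#'   default 600.
#' @param sap_elongation Body-elongation threshold for stretch-attend
#'   posture, as a multiple of the animal's median nose-to-tail-base
#'   length; default 1.2.
#' @return An object of class `speed_class_config`.
#' @export
speed_class_config <- function(move_cms = 0.5, scoot_hi_cms = 4,
                               burst_lo_cms = 4, escape_window_s = 600,
                               sap_elongation = 1.2) {
  stopifnot(move_cms > 0, move_cms < scoot_hi_cms,
            scoot_hi_cms <= burst_lo_cms, escape_window_s > 0,
            sap_elongation > 1)
  structure(list(move_cms = move_cms, scoot_hi_cms = scoot_hi_cms,
                 burst_lo_cms = burst_lo_cms,
                 escape_window_s = escape_window_s,
                 sap_elongation = sap_elongation),
            class = "speed_class_config")
}

#' Per-frame centroid speed
#'
#' Speed at frame t is the displacement of the `center` keypoint from
#' frame t-1 multiplied by the frame rate (px/s); the first frame has
#' speed 0.
#'
#' @param rec A [pose_recording()].
#' @return Numeric vector of speeds (px/s), one per frame.
#' @export
centroid_speed <- function(rec) {
  xy <- kp_xy(rec, "center")
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, d) * rec$timeline$frame_rate
}

# logical frame selector for a half-open interval [start, end) in seconds
frames_in <- function(rec, interval) {
  if (is.null(interval)) return(rep(TRUE, n_frames(rec)))
  if (length(interval) != 2L || interval[2] <= interval[1])
    stop("interval must be c(start, end) with end > start")
  t <- frame_times(rec$timeline, n_frames(rec))
  t >= interval[1] & t < interval[2]
}

# per-frame speed-class channels, memoized on the recording (battery
# runs stash them under rec$.channels so the ~30 registry entries per
# battery share one pass over the frames)
speed_channels <- function(rec, cfg) {
  ch <- rec$.channels
  if (!is.null(ch) && identical(ch$cfg, cfg)) return(ch)
  sp <- centroid_speed(rec) / rec$geometry$px_per_cm   # cm/s
  moved <- sp > cfg$move_cms
  scoot <- moved & sp < cfg$scoot_hi_cms
  burst <- sp >= cfg$burst_lo_cms
  hutc <- c(mean(rec$geometry$hut[c("x0", "x1")]),
            mean(rec$geometry$hut[c("y0", "y1")]))
  xy <- kp_xy(rec, "center")
  dh <- sqrt((xy[, 1] - hutc[1])^2 + (xy[, 2] - hutc[2])^2)
  approaching <- c(FALSE, diff(dh) < 0)
  t <- frame_times(rec$timeline, n_frames(rec))
  post <- rep(FALSE, length(t))
  for (on in stimulus_onsets(rec$timeline))
    post <- post | (t >= on & t < on + cfg$escape_window_s)
  list(cfg = cfg, speed = sp, moved = moved, scoot = scoot,
       burst = burst, escape = burst & post & approaching)
}

# per-frame SAP state (elongated and slow), memoized like the above
sap_channel <- function(rec, cfg) {
  ch <- rec$.sap
  if (!is.null(ch) && identical(ch$cfg, cfg)) return(ch)
  nose <- kp_xy(rec, "nose")
  tb <- kp_xy(rec, "tail_base")
  blen <- sqrt((nose[, 1] - tb[, 1])^2 + (nose[, 2] - tb[, 2])^2)
  med <- stats::median(blen)
  if (!is.finite(med) || med <= 0) stop("degenerate body length")
  list(cfg = cfg,
       sap = (blen / med > cfg$sap_elongation) &
         !speed_channels(rec, cfg)$moved)
}

# per-frame logical: speed above the move threshold
moved_frames <- function(rec, cfg) {
  speed_channels(rec, cfg)$moved
}

#' Percentage of frames with movement
#'
#' @param rec A [pose_recording()].
#' @param interval `c(start, end)` in seconds (half-open), or `NULL` for
#'   the whole recording.
#' @param cfg A [speed_class_config()].
#' @return Percentage of frames in the interval whose centroid speed
#'   exceeds the movement threshold.
#' @export
percent_moved <- function(rec, interval = NULL,
                          cfg = speed_class_config()) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  100 * mean(moved_frames(rec, cfg)[idx])
}

#' Speed-class fractions and mean speed
#'
#' Classifies each frame of the interval by centroid speed and returns
#' the percentage of moved, scoot, burst and escape frames plus the mean
#' speed (cm/s) over moving frames. Escape frames are burst frames that
#' occur within the post-onset escape window and whose displacement is
#' directed toward the hut (distance to the hut centre decreasing).
#' When no frame moves, mean speed is reported as 0 and the result
#' carries attribute `no_movement = TRUE`.
#'
#' @inheritParams percent_moved
#' @return Named numeric vector `moved`, `scoot`, `burst`, `escape`
#'   (percent of frames) and `speed` (mean cm/s over moving frames).
#' @export
speed_class_fractions <- function(rec, interval = NULL,
                                  cfg = speed_class_config()) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  ch <- speed_channels(rec, cfg)
  moved <- ch$moved
  mean_speed <- if (any(moved[idx])) mean(ch$speed[idx & moved]) else 0
  out <- c(moved = 100 * mean(moved[idx]),
           scoot = 100 * mean(ch$scoot[idx]),
           burst = 100 * mean(ch$burst[idx]),
           escape = 100 * mean(ch$escape[idx]),
           speed = mean_speed)
  if (!any(moved[idx])) attr(out, "no_movement") <- TRUE
  out
}

#' Stretch-attend posture fraction
#'
#' A frame is in stretch-attend posture (SAP) when the body is elongated
#' (nose-to-tail-base distance above `sap_elongation` times the
#' animal's median body length) while the centroid is near-stationary
#' (speed below the movement threshold).
#'
#' @inheritParams percent_moved
#' @return Percentage of SAP frames in the interval.
#' @export
sap_fraction <- function(rec, interval = NULL,
                         cfg = speed_class_config()) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  100 * mean(sap_channel(rec, cfg)$sap[idx])
}

#' Acclimation index
#'
#' Decline of exploratory behavior over the first assay hour: the metric
#' in the first analysis period minus the metric in the sixth period
#' (the last period of hour one at the default 10-minute period length).
#' Positive values mean the behavior declines as the animal acclimates.
#'
#' @param rec A [pose_recording()].
#' @param metric `"movement"` (% moved) or `"sap"` (% stretch-attend).
#' @param cfg A [speed_class_config()].
#' @return Acclimation index (percentage-point difference).
#' @export
acclimation <- function(rec, metric = c("movement", "sap"),
                        cfg = speed_class_config()) {
  metric <- match.arg(metric)
  f <- switch(metric, movement = percent_moved, sap = sap_fraction)
  p1 <- period_interval(rec$timeline, 1L)
  p6 <- period_interval(rec$timeline, 6L)
  f(rec, p1, cfg) - f(rec, p6, cfg)
}

#' Per-presentation stimulus responses
#'
#' For each stimulus onset, the metric over the first analysis period
#' after onset minus the metric over the period immediately before onset
#' (a within-animal response, in percentage points).
#'
#' @param rec A [pose_recording()].
#' @param metric `"moved"` or `"scoot"`.
#' @param cfg A [speed_class_config()].
#' @return Numeric vector, one response per stimulus presentation.
#' @export
habituation_responses <- function(rec, metric = c("moved", "scoot"),
                                  cfg = speed_class_config()) {
  metric <- match.arg(metric)
  tl <- rec$timeline
  plen <- tl$period_min * 60
  tmax <- tl$hours * 3600
  val <- function(iv) {
    sf <- speed_class_fractions(rec, iv, cfg)
    sf[[if (metric == "moved") "moved" else "scoot"]]
  }
  vapply(stimulus_onsets(tl), function(on) {
    if (on - plen < 0 || on + plen > tmax)
      stop("stimulus onset at ", on,
           " s too close to the recording edge for a pre/post period")
    val(c(on, on + plen)) - val(c(on - plen, on))
  }, numeric(1))
}

#' Habituation index
#'
#' Decline of the stimulus-evoked response across repeated
#' presentations. For the moth stimulus the index is the response to
#' presentation 1 minus the response to presentation 3; for the first
#' set of moving lines it is the response to presentation 1 minus the
#' response to presentation 2. Positive values indicate habituation.
#'
#' @param rec A [pose_recording()].
#' @param stimulus `"moth"` or `"lines1"`.
#' @param metric `"moved"` or `"scoot"`.
#' @param cfg A [speed_class_config()].
#' @return Habituation index (percentage-point difference).
#' @export
habituation <- function(rec, stimulus = c("moth", "lines1"),
                        metric = c("moved", "scoot"),
                        cfg = speed_class_config()) {
  stimulus <- match.arg(stimulus)
  r <- habituation_responses(rec, metric, cfg)
  if (length(r) < 3L)
    stop("habituation indices need three stimulus presentations")
  switch(stimulus, moth = r[1] - r[3], lines1 = r[1] - r[2])
}

#' Quadrant occupancy
#'
#' Percentage of frames the centroid spends in each cage quadrant (see
#' [quadrant_of()] for numbering). The four percentages sum to 100.
#'
#' @inheritParams percent_moved
#' @return Named numeric vector `q1`..`q4` summing to 100.
#' @export
quadrant_occupancy <- function(rec, interval = NULL) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  xy <- kp_xy(rec, "center")
  q <- quadrant_of(xy[idx, 1], xy[idx, 2], rec$geometry)
  out <- 100 * tabulate(q, nbins = 4L) / sum(idx)
  names(out) <- paste0("q", 1:4)
  out
}

#' Mean distance from the nearest cage wall
#'
#' @inheritParams percent_moved
#' @return Mean over frames of the minimum centroid distance to the four
#'   cage walls (px).
#' @export
distance_from_wall <- function(rec, interval = NULL) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  xy <- kp_xy(rec, "center")
  mean(wall_distance_px(xy[idx, 1], xy[idx, 2], rec$geometry))
}

#' Time spent near the social window
#'
#' Percentage of frames with the nose (fallback: centroid) within the
#' window radius. With `partner` given, a frame only counts when the
#' partner is simultaneously near its own window: `partner` may be the
#' paired cage's [pose_recording()] (same frame count) or a per-frame
#' logical presence vector.
#'
#' @inheritParams percent_moved
#' @param partner Optional partner recording or logical vector.
#' @return Percentage of frames.
#' @export
time_near_window <- function(rec, interval = NULL, partner = NULL) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  probe <- if ("nose" %in% names(rec$keypoints)) "nose" else "center"
  xy <- kp_xy(rec, probe)
  here <- near_window(xy[, 1], xy[, 2], rec$geometry)
  if (!is.null(partner)) {
    there <- if (inherits(partner, "pose_recording")) {
      pprobe <- if ("nose" %in% names(partner$keypoints)) "nose" else "center"
      pxy <- kp_xy(partner, pprobe)
      near_window(pxy[, 1], pxy[, 2], partner$geometry)
    } else as.logical(partner)
    if (length(there) != length(here))
      stop("partner channel must match the recording frame count")
    here <- here & there
  }
  100 * mean(here[idx])
}

#' Hut occupancy
#'
#' @inheritParams percent_moved
#' @return Percentage of frames with the centroid inside the hut region.
#' @export
hut_occupancy <- function(rec, interval = NULL) {
  idx <- frames_in(rec, interval)
  if (!any(idx)) stop("empty interval")
  xy <- kp_xy(rec, "center")
  100 * mean(in_hut(xy[idx, 1], xy[idx, 2], rec$geometry))
}

# canonical analysis intervals; an "assay hour" is 1/22 of the assay so
# that scaled timelines keep the assay topology
assay_intervals <- function(timeline) {
  h <- timeline$hours * 3600 / 22
  night <- phase_interval(timeline, "night")
  list(
    hour1 = c(0, h),
    night_hour1 = c(night[1], night[1] + h),
    day = phase_interval(timeline, "day"),
    night = night,
    night_stimuli = phase_interval(timeline, "night_stimuli"),
    day2 = phase_interval(timeline, "day2"),
    assay = c(0, timeline$hours * 3600)
  )
}
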