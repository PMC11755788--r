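# Feature batteries: the 15-parameter track battery (centroid tracking)
# and the 52-parameter pose battery (full keypoint pose estimation).
#
# Parameters named in the published analyses (movement in the 1st hour
# and 1st night hour; speed classes; acclimation in % movement and
# % SAP; habituation to the moth and to the first moving lines;
# quadrant occupancy; distance from any wall; time near the window with
# partner) are fixed verbatim; the remaining slots are documented
# registry extensions (per-phase activity, SAP and hut occupancy,
# per-presentation stimulus responses) filling the batteries to exactly
# 15 and 52 entries.

registry_version <- "cagewalk-registry-1"

# one registry entry
re <- function(name, units, fn, extension = FALSE) {
  list(name = name, units = units, fn = fn, extension = extension)
}

track15_registry <- function() {
  iv <- function(which) {
    force(which)
    function(rec, cfg, partner)
      percent_moved(rec, assay_intervals(rec$timeline)[[which]], cfg)
  }
  list(
    re("movement_hour1_pct", "% frames", iv("hour1")),
    re("movement_night_hour1_pct", "% frames", iv("night_hour1")),
    re("acclimation_movement", "pp", function(rec, cfg, partner)
      acclimation(rec, "movement", cfg)),
    re("acclimation_sap", "pp", function(rec, cfg, partner)
      acclimation(rec, "sap", cfg)),
    re("habituation_moth_moved", "pp", function(rec, cfg, partner)
      habituation(rec, "moth", "moved", cfg)),
    re("quadrant_q1_pct", "% frames", function(rec, cfg, partner)
      quadrant_occupancy(rec)[["q1"]]),
    re("quadrant_q2_pct", "% frames", function(rec, cfg, partner)
      quadrant_occupancy(rec)[["q2"]]),
    re("quadrant_q3_pct", "% frames", function(rec, cfg, partner)
      quadrant_occupancy(rec)[["q3"]]),
    re("quadrant_q4_pct", "% frames", function(rec, cfg, partner)
      quadrant_occupancy(rec)[["q4"]]),
    re("mean_speed_hour1_cms", "cm/s", function(rec, cfg, partner)
      speed_class_fractions(rec, assay_intervals(rec$timeline)$hour1,
                            cfg)[["speed"]]),
    re("sap_hour1_pct", "% frames", function(rec, cfg, partner)
      sap_fraction(rec, assay_intervals(rec$timeline)$hour1, cfg),
      extension = TRUE),
    re("hut_occupancy_pct", "% frames", function(rec, cfg, partner)
      hut_occupancy(rec), extension = TRUE),
    re("movement_day_pct", "% frames", iv("day"), extension = TRUE),
    re("movement_night_pct", "% frames", iv("night"), extension = TRUE),
    re("movement_assay_pct", "% frames", iv("assay"), extension = TRUE)
  )
}

pose52_registry <- function() {
  # force() the factory arguments: these are called with loop
  # variables, and an unforced promise would collapse every closure
  # onto the last loop value
  sc <- function(which, what) {
    force(which); force(what)
    function(rec, cfg, partner)
      speed_class_fractions(rec, assay_intervals(rec$timeline)[[which]],
                            cfg)[[what]]
  }
  sap_iv <- function(which) {
    force(which)
    function(rec, cfg, partner)
      sap_fraction(rec, assay_intervals(rec$timeline)[[which]], cfg)
  }
  hut_iv <- function(which) {
    force(which)
    function(rec, cfg, partner)
      hut_occupancy(rec, assay_intervals(rec$timeline)[[which]])
  }
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  for (w in c("hour1", "night_hour1"))
    for (what in c("moved", "scoot", "burst", "escape", "speed"))
      add(re(paste0(what, "_", w, if (what == "speed") "_cms" else "_pct"),
             if (what == "speed") "cm/s" else "% frames", sc(w, what)))
  add(re("acclimation_movement", "pp", function(rec, cfg, partner)
    acclimation(rec, "movement", cfg)))
  add(re("acclimation_sap", "pp", function(rec, cfg, partner)
    acclimation(rec, "sap", cfg)))
  for (stim in c("moth", "lines1"))
    for (m in c("moved", "scoot"))
      add(re(paste0("habituation_", stim, "_", m), "pp",
             local({
               s <- stim; mm <- m
               function(rec, cfg, partner) habituation(rec, s, mm, cfg)
             })))
  add(re("wall_distance_px", "px", function(rec, cfg, partner)
    distance_from_wall(rec)))
  add(re("wall_distance_night_px", "px", function(rec, cfg, partner)
    distance_from_wall(rec, assay_intervals(rec$timeline)$night),
    extension = TRUE))
  add(re("near_window_pct", "% frames", function(rec, cfg, partner)
    time_near_window(rec), extension = TRUE))
  add(re("near_window_partner_pct", "% frames", function(rec, cfg, partner) {
    if (is.null(partner)) partner <- rec$partner_near_window
    if (is.null(partner)) stop("no partner channel available")
    time_near_window(rec, partner = partner)
  }))
  for (w in c("day", "night", "night_stimuli", "day2")) {
    for (what in c("moved", "scoot", "burst", "speed"))
      add(re(paste0(what, "_", w, if (what == "speed") "_cms" else "_pct"),
             if (what == "speed") "cm/s" else "% frames", sc(w, what),
             extension = TRUE))
  }
  for (w in c("day", "night", "night_stimuli", "day2"))
    add(re(paste0("sap_", w, "_pct"), "% frames", sap_iv(w),
           extension = TRUE))
  for (w in c("day", "night", "night_stimuli", "day2"))
    add(re(paste0("hut_", w, "_pct"), "% frames", hut_iv(w),
           extension = TRUE))
  for (q in paste0("q", 1:4))
    add(re(paste0("quadrant_", q, "_pct"), "% frames",
           local({
             qq <- q
             function(rec, cfg, partner) quadrant_occupancy(rec)[[qq]]
           })))
  for (k in 1:3)
    add(re(paste0("stimulus_response", k, "_moved"), "pp",
           local({
             kk <- k
             function(rec, cfg, partner)
               habituation_responses(rec, "moved", cfg)[kk]
           }), extension = TRUE))
  add(re("movement_assay_pct", "% frames", function(rec, cfg, partner)
    percent_moved(rec, NULL, cfg), extension = TRUE))
  entries
}

run_battery <- function(rec, registry, battery, cfg, partner = NULL) {
  # one pass over the frames, shared by every registry entry
  rec$.channels <- speed_channels(rec, cfg)
  rec$.sap <- tryCatch(sap_channel(rec, cfg), error = function(e) NULL)
  vals <- numeric(length(registry))
  miss <- logical(length(registry))
  for (i in seq_along(registry)) {
    v <- tryCatch(registry[[i]]$fn(rec, cfg, partner),
                  error = function(e) NA_real_)
    if (is.null(v) || !is.finite(v)) {
      vals[i] <- NA_real_
      miss[i] <- TRUE
    } else vals[i] <- v
  }
  out <- data.frame(
    animal = rec$animal,
    battery = battery,
    parameter = vapply(registry, `[[`, character(1), "name"),
    value = vals,
    units = vapply(registry, `[[`, character(1), "units"),
    missing = miss,
    stringsAsFactors = FALSE
  )
  attr(out, "registry_version") <- registry_version
  out
}

#' Track feature battery (15 parameters)
#'
#' Computes the 15-parameter centroid-tracking battery: movement in the
#' first assay hour and the first night hour, acclimation indices (%
#' movement and % SAP), habituation to the moth stimulus, quadrant
#' occupancy, mean speed, and documented registry extensions (SAP in
#' hour one, hut occupancy, per-phase and assay-wide movement). Entries
#' that cannot be computed are flagged missing; the battery always has
#' exactly 15 rows.
#'
#' @param rec A filtered [pose_recording()].
#' @param cfg A [speed_class_config()].
#' @return A data frame with columns `animal`, `battery`, `parameter`,
#'   `value`, `units`, `missing` (15 rows), carrying the registry
#'   version as an attribute.
#' @export
battery_track15 <- function(rec, cfg = speed_class_config()) {
  run_battery(rec, track15_registry(), "track15", cfg)
}

#' Pose feature battery (52 parameters)
#'
#' Computes the 52-parameter pose-estimation battery: speed classes
#' (moved, scoot, burst, escape, mean speed) over the first assay hour
#' and first night hour, acclimation and habituation indices, distance
#' from the cage walls, time near the social window (alone and with
#' partner), and documented registry extensions (per-phase speed
#' classes, SAP, hut occupancy, quadrant occupancy, per-presentation
#' stimulus responses). Always exactly 52 rows; uncomputable entries
#' are flagged missing.
#'
#' @param rec A filtered [pose_recording()].
#' @param cfg A [speed_class_config()].
#' @param partner Optional partner recording or per-frame logical
#'   presence vector for the with-partner window parameter (defaults to
#'   the recording's own `partner_near_window` channel when present).
#' @return A 52-row data frame as in [battery_track15()].
#' @export
battery_pose52 <- function(rec, cfg = speed_class_config(),
                           partner = NULL) {
  run_battery(rec, pose52_registry(), "pose52", cfg, partner)
}
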