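#' Assay timeline
#'
#' Describes the temporal structure of a home-cage recording: the frame
#' rate, the ordered light/dark phases tiling the assay, the stimulus
#' onsets, and the fixed-length analysis periods used for acclimation,
#' habituation and syllable summaries.
#'
#' The default 22-hour assay consists of a 6-hour daytime phase, a 6-hour
#' nighttime phase, a 6-hour nighttime phase with three stimulus
#' presentations, and a final 4-hour daytime phase. Stimuli are presented
#' at elapsed hours 12, 14 and 16 (the starts of assay hours 13, 15 and
#' 17), which fall at the starts of 10-minute periods 73, 85 and 97.
#'
#' Passing `hours` different from 22 rescales the whole structure
#' (phase boundaries, onsets and period length) proportionally, so that
#' period arithmetic — including the period indices of the three stimulus
#' onsets — is preserved at reduced duration. This is the mechanism used
#' to run desk-scale simulations with the full assay topology.
#'
#' @param hours Total assay duration in hours (default 22).
#' @param frame_rate Frames per second (default 1, i.e. a 1-s snapshot
#'   interval).
#' @param phases Optional data frame with columns `phase`, `start_h`,
#'   `end_h` tiling `[0, hours)` without gap or overlap. Defaults to the
#'   day/night/night+stimuli/day structure described above (rescaled).
#' @param stimulus_onsets_h Elapsed hours of stimulus onsets; must lie
#'   inside a phase whose name contains `"stimul"`. Default
#'   `c(12, 14, 16) * hours / 22`.
#' @param period_min Length of an analysis period in minutes. Default
#'   `10 * hours / 22`.
#' @return An object of class `assay_timeline`.
#' @examples
#' tl <- assay_timeline()
#' period_index(12 * 3600, tl)  # 73: first stimulus presentation
#' phase_of(6 * 3600, tl)       # "night"
#' @export
assay_timeline <- function(hours = 22, frame_rate = 1, phases = NULL,
                           stimulus_onsets_h = NULL, period_min = NULL) {
  stopifnot(is.numeric(hours), length(hours) == 1L, hours > 0,
            is.numeric(frame_rate), frame_rate > 0)
  f <- hours / 22
  if (is.null(phases)) {
    phases <- data.frame(
      phase   = c("day", "night", "night_stimuli", "day2"),
      start_h = c(0, 6, 12, 18) * f,
      end_h   = c(6, 12, 18, 22) * f,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(stimulus_onsets_h)) stimulus_onsets_h <- c(12, 14, 16) * f
  if (is.null(period_min)) period_min <- 10 * f

  phases <- phases[order(phases$start_h), , drop = FALSE]
  if (!isTRUE(all.equal(phases$start_h[1], 0)) ||
      !isTRUE(all.equal(phases$end_h[nrow(phases)], hours)) ||
      (nrow(phases) > 1 &&
       !isTRUE(all.equal(phases$start_h[-1], phases$end_h[-nrow(phases)]))))
    stop("phases must tile [0, ", hours, ") hours without gap or overlap")
  if (any(phases$end_h <= phases$start_h))
    stop("each phase must have positive duration")
  if (period_min <= 0) stop("period_min must be positive")

  stim_phase <- grepl("stimul", phases$phase)
  if (length(stimulus_onsets_h)) {
    if (!any(stim_phase))
      stop("stimulus onsets given but no phase is marked as a stimulus phase")
    lo <- phases$start_h[stim_phase][1]
    hi <- phases$end_h[stim_phase][length(which(stim_phase))]
    if (any(stimulus_onsets_h < lo | stimulus_onsets_h >= hi))
      stop("stimulus onsets must lie inside the stimulus phase [",
           lo, ", ", hi, ") h")
  }

  structure(
    list(hours = hours, frame_rate = frame_rate, phases = phases,
         stimulus_onsets_h = sort(stimulus_onsets_h),
         period_min = period_min),
    class = "assay_timeline"
  )
}

#' @export
print.assay_timeline <- function(x, ...) {
  cat("<assay_timeline> ", x$hours, " h @ ", x$frame_rate, " fps, ",
      n_periods(x), " periods of ", signif(x$period_min, 4), " min\n",
      sep = "")
  cat("  phases: ",
      paste0(x$phases$phase, "[", signif(x$phases$start_h, 4), ",",
             signif(x$phases$end_h, 4), ")", collapse = " "), "\n", sep = "")
  cat("  stimulus onsets (h): ",
      paste(signif(x$stimulus_onsets_h, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of analysis periods in a timeline
#'
#' @param timeline An [assay_timeline()].
#' @return Integer count of whole periods (132 at defaults).
#' @export
n_periods <- function(timeline) {
  as.integer(floor(timeline$hours * 60 / timeline$period_min + 1e-9))
}

#' Analysis-period index of a time point
#'
#' Periods are half-open, fixed-length windows numbered from 1. At the
#' default 10-minute period length the first stimulus onset (elapsed hour
#' 12, start of assay hour 13) falls at the start of period 73, and the
#' later onsets at periods 85 and 97.
#'
#' @param t_seconds Elapsed time(s) in seconds, in `[0, hours * 3600)`.
#' @param timeline An [assay_timeline()].
#' @return Integer vector of 1-based period indices.
#' @export
period_index <- function(t_seconds, timeline) {
  stopifnot(inherits(timeline, "assay_timeline"))
  tmax <- timeline$hours * 3600
  if (any(t_seconds < 0 | t_seconds >= tmax))
    stop("time out of assay range [0, ", tmax, ") s")
  as.integer(floor(t_seconds / (timeline$period_min * 60))) + 1L
}

#' Time interval covered by an analysis period
#'
#' @param timeline An [assay_timeline()].
#' @param period 1-based period index.
#' @return `c(start, end)` in seconds, half-open.
#' @export
period_interval <- function(timeline, period) {
  stopifnot(period >= 1, period <= n_periods(timeline))
  plen <- timeline$period_min * 60
  c((period - 1) * plen, period * plen)
}

#' Phase containing a time point
#'
#' Phase intervals are half-open: a boundary instant belongs to the later
#' phase.
#'
#' @inheritParams period_index
#' @return Character vector of phase names.
#' @export
phase_of <- function(t_seconds, timeline) {
  stopifnot(inherits(timeline, "assay_timeline"))
  tmax <- timeline$hours * 3600
  if (any(t_seconds < 0 | t_seconds >= tmax))
    stop("time out of assay range [0, ", tmax, ") s")
  th <- t_seconds / 3600
  idx <- findInterval(th, timeline$phases$start_h)
  timeline$phases$phase[idx]
}

#' Time interval of a named phase
#'
#' @param timeline An [assay_timeline()].
#' @param phase Phase name (must match one phase).
#' @return `c(start, end)` in seconds.
#' @export
phase_interval <- function(timeline, phase) {
  i <- which(timeline$phases$phase == phase)
  if (length(i) != 1L) stop("unknown phase '", phase, "'")
  c(timeline$phases$start_h[i], timeline$phases$end_h[i]) * 3600
}

#' Stimulus onset times in seconds
#'
#' @param timeline An [assay_timeline()].
#' @return Numeric vector of onset times (s).
#' @export
stimulus_onsets <- function(timeline) {
  timeline$stimulus_onsets_h * 3600
}

# frame timestamps (s) for an n-frame recording on this timeline
frame_times <- function(timeline, n) {
  (seq_len(n) - 1) / timeline$frame_rate
}

# number of frames in a full recording on this timeline
n_frames_full <- function(timeline) {
  as.integer(round(timeline$hours * 3600 * timeline$frame_rate))
}
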