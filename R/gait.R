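#' Gait run
#'
#' An ordered set of footfall records from one walkway crossing.
#' Footfalls are timestamped paw contacts with print geometry and
#' intensity. The walkway axis is x (px); y is the lateral axis.
#'
#' @param footfalls Data frame with one row per print. Required
#'   columns: `paw` (RF/LF/RH/LH), `contact`, `release` (s). Optional
#'   geometry/intensity columns used by [paw_parameters()]: `heel_x`,
#'   `heel_y`, `toe3_x`, `toe3_y` (third toe), `toe_a_x`, `toe_a_y`,
#'   `toe_b_x`, `toe_b_y` (outer toe pair 1/5 for toe spread and
#'   intermediate pair 2/4 for intermediate toe spread are both passed
#'   through this pair-of-points schema: `toe_a`/`toe_b` = toes 1 and 5,
#'   `itoe_a_*`/`itoe_b_*` = toes 2 and 4), `print_area`,
#'   `max_contact_area` (px^2), `mean_intensity`, `min_intensity`
#'   (0-255 a.u.).
#' @param animal Animal identifier.
#' @param run_id Run identifier within animal.
#' @param px_per_mm Pixel-to-millimetre scale (default 2).
#' @return An object of class `gait_run`. The run direction (+1/-1
#'   along the walkway) is inferred from the overall heel-x
#'   displacement (falling back to +1 when geometry is absent).
#' @export
gait_run <- function(footfalls, animal = "animal1", run_id = 1L,
                     px_per_mm = 2) {
  if (!is.data.frame(footfalls) ||
      !all(c("paw", "contact", "release") %in% names(footfalls)))
    stop("footfalls must be a data frame with paw, contact, release")
  if (nrow(footfalls) == 0L) stop("run has no footfalls")
  if (!all(footfalls$paw %in% c("RF", "LF", "RH", "LH")))
    stop("paw labels must be RF, LF, RH or LH")
  if (any(footfalls$release <= footfalls$contact))
    stop("every print must have release > contact")
  for (col in c("mean_intensity", "min_intensity")) {
    v <- footfalls[[col]]
    if (!is.null(v) && any(v < 0 | v > 255, na.rm = TRUE))
      stop(col, " must lie in [0, 255]")
  }
  footfalls <- footfalls[order(footfalls$contact), , drop = FALSE]
  rownames(footfalls) <- NULL
  direction <- if ("heel_x" %in% names(footfalls) && nrow(footfalls) > 1) {
    d <- footfalls$heel_x[nrow(footfalls)] - footfalls$heel_x[1]
    if (d < 0) -1L else 1L
  } else 1L
  structure(list(animal = animal, run_id = run_id,
                 footfalls = footfalls, direction = direction,
                 px_per_mm = px_per_mm),
            class = "gait_run")
}

#' @export
print.gait_run <- function(x, ...) {
  cat("<gait_run> ", x$animal, " run ", x$run_id, ": ",
      nrow(x$footfalls), " footfalls, direction ",
      if (x$direction > 0) "+x" else "-x", "\n", sep = "")
  invisible(x)
}

run_duration <- function(run) {
  max(run$footfalls$release) - min(run$footfalls$contact)
}

# maximum counter-directional excursion of the heel track (px)
run_drawdown <- function(run) {
  ff <- run$footfalls
  if (!"heel_x" %in% names(ff) || nrow(ff) < 2L) return(0)
  x <- ff$heel_x * run$direction
  max(cummax(x) - x)
}

#' Run-compliance filter
#'
#' A compliant run is a one-directional walkway crossing completed in
#' strictly less than `max_duration_s` seconds (default 10; a run of
#' exactly 10.0 s is excluded). One-directionality is violated when the
#' heel track backtracks by more than `reversal_tol_px` against the run
#' direction. Animals are expected to contribute at least `min_runs`
#' compliant runs and are flagged otherwise.
#'
#' @param runs List of [gait_run()] objects.
#' @param max_duration_s Strict upper duration bound (s).
#' @param reversal_tol_px Allowed counter-directional excursion (px).
#' @param min_runs Required compliant runs per animal (default 3).
#' @return List with `compliant` (the kept runs), `excluded` (data
#'   frame of run id and reason: `"duration"` or `"bidirectional"`) and
#'   `report` (per-animal compliant-run counts with a `flagged` column
#'   for animals below `min_runs`).
#' @export
compliance_filter <- function(runs, max_duration_s = 10,
                              reversal_tol_px = 30, min_runs = 3L) {
  stopifnot(length(runs) > 0)
  reasons <- character(0)
  which_runs <- integer(0)
  keep <- logical(length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    reason <- NULL
    if (!(run_duration(run) < max_duration_s)) reason <- "duration"
    else if (run_drawdown(run) > reversal_tol_px) reason <- "bidirectional"
    if (is.null(reason)) keep[i] <- TRUE
    else {
      reasons <- c(reasons, reason)
      which_runs <- c(which_runs, i)
    }
  }
  compliant <- runs[keep]
  excluded <- data.frame(
    index = which_runs,
    animal = vapply(runs[which_runs], `[[`, character(1), "animal"),
    run_id = vapply(runs[which_runs], function(r) as.integer(r$run_id),
                    integer(1)),
    reason = reasons,
    stringsAsFactors = FALSE
  )
  animals <- vapply(runs, `[[`, character(1), "animal")
  kept_by <- table(factor(animals[keep], levels = unique(animals)))
  report <- data.frame(animal = names(kept_by),
                       n_compliant = as.integer(kept_by),
                       flagged = as.integer(kept_by) < min_runs,
                       stringsAsFactors = FALSE)
  list(compliant = compliant, excluded = excluded, report = report)
}

fold_angle <- function(deg) ((deg + 90) %% 180) - 90

#' Per-paw print parameters
#'
#' Computes the paw-level gait parameters for every print of a run:
#' manual print length (third toe to heel), toe spread (outer toe
#' pair), intermediate toe spread (toes 2/4), print and maximum contact
#' areas, mean and minimum intensity, stand (release - contact), step
#' cycle (time to the next initial contact of the same paw; the last
#' contact of each paw has none), swing (step cycle - stand), and the
#' paw angle relative to the body axis (the signed angle between the
#' heel-to-third-toe vector and the run direction, folded to
#' [-90, 90] degrees). Distances are reported in mm via the run scale.
#' Prints missing a landmark get `NA` for the affected metric.
#'
#' @param run A [gait_run()].
#' @return Data frame, one row per print.
#' @export
paw_parameters <- function(run) {
  ff <- run$footfalls
  s <- run$px_per_mm
  n <- nrow(ff)
  col <- function(nm) if (nm %in% names(ff)) ff[[nm]] else rep(NA_real_, n)
  seglen <- function(ax, ay, bx, by) sqrt((bx - ax)^2 + (by - ay)^2) / s
  print_length <- seglen(col("heel_x"), col("heel_y"),
                         col("toe3_x"), col("toe3_y"))
  toe_spread <- seglen(col("toe_a_x"), col("toe_a_y"),
                       col("toe_b_x"), col("toe_b_y"))
  itoe_spread <- seglen(col("itoe_a_x"), col("itoe_a_y"),
                        col("itoe_b_x"), col("itoe_b_y"))
  vx <- (col("toe3_x") - col("heel_x")) * run$direction
  vy <- (col("toe3_y") - col("heel_y")) * run$direction
  paw_angle <- fold_angle(atan2(vy, vx) * 180 / pi)
  stand <- ff$release - ff$contact
  step_cycle <- rep(NA_real_, n)
  for (p in unique(ff$paw)) {
    i <- which(ff$paw == p)
    if (length(i) > 1L)
      step_cycle[i[-length(i)]] <- diff(ff$contact[i])
  }
  data.frame(
    paw = ff$paw, contact = ff$contact,
    print_length_mm = print_length, toe_spread_mm = toe_spread,
    intermediate_toe_spread_mm = itoe_spread,
    print_area = col("print_area"),
    max_contact_area = col("max_contact_area"),
    mean_intensity = col("mean_intensity"),
    min_intensity = col("min_intensity"),
    stand_s = stand, step_cycle_s = step_cycle,
    swing_s = step_cycle - stand,
    paw_angle_deg = paw_angle,
    stringsAsFactors = FALSE
  )
}

support_categories <- c("zero", "single", "girdle", "lateral",
                        "diagonal", "three", "four")

classify_support <- function(paws) {
  n <- length(paws)
  if (n == 0L) return("zero")
  if (n == 1L) return("single")
  if (n == 3L) return("three")
  if (n == 4L) return("four")
  pair <- paste(sort(paws), collapse = "-")
  if (pair %in% c("LF-RF", "LH-RH")) "girdle"
  else if (pair %in% c("RF-RH", "LF-LH")) "lateral"
  else "diagonal"
}

#' Support-category decomposition of a run
#'
#' Classifies every instant of the run (first contact to last release)
#' by the set of paws in contact with the walkway: zero, single, girdle
#' pair (RF-LF or RH-LH), lateral pair (RF-RH or LF-LH), diagonal pair
#' (RF-LH or LF-RH), three or four paws. The seven categories are
#' exhaustive and mutually exclusive and their percentages sum to 100.
#'
#' Two computations are available: an exact event-driven decomposition
#' over the contact/release breakpoints (`exact = TRUE`), and a
#' discretization at step `dt` that converges to it as `dt` shrinks.
#'
#' @param run A [gait_run()].
#' @param dt Discretization step in seconds (default 0.001).
#' @param exact Use the event-driven computation instead.
#' @return Named numeric vector of percentages over the seven
#'   categories.
#' @export
support_fractions <- function(run, dt = 0.001, exact = FALSE) {
  ff <- run$footfalls
  t0 <- min(ff$contact)
  t1 <- max(ff$release)
  out <- stats::setNames(numeric(7), support_categories)
  if (exact) {
    bp <- sort(unique(c(ff$contact, ff$release, t0, t1)))
    for (i in seq_len(length(bp) - 1L)) {
      mid <- (bp[i] + bp[i + 1L]) / 2
      down <- unique(ff$paw[ff$contact <= mid & ff$release > mid])
      cat_ <- classify_support(down)
      out[cat_] <- out[cat_] + (bp[i + 1L] - bp[i])
    }
    return(100 * out / (t1 - t0))
  }
  stopifnot(dt > 0)
  mids <- seq(t0 + dt / 2, t1, by = dt)
  down_mat <- vapply(c("RF", "LF", "RH", "LH"), function(p) {
    fp <- ff[ff$paw == p, , drop = FALSE]
    down <- rep(FALSE, length(mids))
    # prints of one paw may overlap (e.g. double placements), so OR
    # over intervals rather than parity-counting boundaries
    for (j in seq_len(nrow(fp)))
      down <- down | (mids >= fp$contact[j] & mids < fp$release[j])
    down
  }, logical(length(mids)))
  if (!is.matrix(down_mat)) down_mat <- matrix(down_mat, nrow = 1)
  npaws <- rowSums(down_mat)
  cats <- character(length(mids))
  cats[npaws == 0] <- "zero"
  cats[npaws == 1] <- "single"
  cats[npaws == 3] <- "three"
  cats[npaws == 4] <- "four"
  two <- which(npaws == 2)
  if (length(two)) {
    paws <- c("RF", "LF", "RH", "LH")
    cats[two] <- vapply(two, function(i)
      classify_support(paws[down_mat[i, ]]), character(1))
  }
  tab <- table(factor(cats, levels = support_categories))
  100 * as.vector(tab) / length(mids) -> pct
  stats::setNames(pct, support_categories)
}

#' Base of support
#'
#' Average lateral width between left and right paw placements of the
#' front and hind girdle pairs: successive opposite-side prints of a
#' pair contribute the absolute lateral (y) distance between their heel
#' positions.
#'
#' @param run A [gait_run()].
#' @return Named numeric vector `c(front, hind)` in mm (`NA` when a
#'   pair has no opposite-side succession).
#' @export
base_of_support <- function(run) {
  ff <- run$footfalls
  one <- function(paws) {
    d <- ff[ff$paw %in% paws, , drop = FALSE]
    if (nrow(d) < 2L || !"heel_y" %in% names(d)) return(NA_real_)
    w <- numeric(0)
    for (i in seq_len(nrow(d) - 1L))
      if (d$paw[i] != d$paw[i + 1L])
        w <- c(w, abs(d$heel_y[i + 1L] - d$heel_y[i]))
    if (length(w)) mean(w) / run$px_per_mm else NA_real_
  }
  c(front = one(c("RF", "LF")), hind = one(c("RH", "LH")))
}

# the six canonical normal step sequence patterns: alternate (Aa, Ab),
# cruciate (Ca, Cb) and rotary (Ra, Rb)
nssp_patterns <- list(
  Aa = c("RF", "RH", "LF", "LH"),
  Ab = c("LF", "RH", "RF", "LH"),
  Ca = c("RF", "LF", "RH", "LH"),
  Cb = c("LF", "RF", "LH", "RH"),
  Ra = c("RF", "LF", "LH", "RH"),
  Rb = c("LF", "RF", "RH", "LH")
)

rotate4 <- function(p, k) p[((seq_len(4) - 1L + k) %% 4L) + 1L]

# is a 4-step window one of the six patterns, invariant to which paw
# starts the window
is_nssp_window <- function(w) {
  if (length(unique(w)) != 4L) return(FALSE)
  for (p in nssp_patterns)
    for (k in 0:3)
      if (all(w == rotate4(p, k))) return(TRUE)
  FALSE
}

#' Percentage of normal step sequence patterns
#'
#' Slides a 4-step window (advancing one step at a time) over the
#' initial-contact order of the paws. A window is normal when it
#' contains all four paws once and matches one of the six canonical
#' step sequence patterns (alternate Aa/Ab, cruciate Ca/Cb, rotary
#' Ra/Rb) up to rotation of the starting paw. By default each window
#' counts equally (per-step attribution); with `weighted = TRUE`
#' windows are weighted by the time to the next window start, giving a
#' duration-weighted percentage.
#'
#' @param run A [gait_run()].
#' @param weighted Duration-weight the windows.
#' @return NSSP percentage in [0, 100]; `NA` (flagged via attribute
#'   `reason`) for runs with fewer than 4 steps.
#' @export
nssp_percent <- function(run, weighted = FALSE) {
  ff <- run$footfalls
  n <- nrow(ff)
  if (n < 4L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 4 steps"
    return(out)
  }
  starts <- seq_len(n - 3L)
  normal <- vapply(starts, function(i)
    is_nssp_window(ff$paw[i:(i + 3L)]), logical(1))
  if (!weighted) return(100 * mean(normal))
  w <- diff(ff$contact)[starts]          # time to next window start
  w[w <= 0 | !is.finite(w)] <- min(w[w > 0], 1e-6)
  100 * sum(w * normal) / sum(w)
}

#' Per-run and per-animal gait summary
#'
#' Computes the full gait parameter set for each compliant run and
#' averages within animal: duration (first contact to last release of
#' the identified steps), cadence (steps per second), number of steps,
#' NSSP percentage, the seven support fractions, base of support, and
#' the per-paw means of every print parameter.
#'
#' @param runs List of [gait_run()] objects (typically the `compliant`
#'   element of [compliance_filter()]).
#' @param dt Discretization step for [support_fractions()].
#' @return List with `per_run` and `per_animal` data frames.
#' @export
run_summary <- function(runs, dt = 0.001) {
  stopifnot(length(runs) > 0)
  rows <- lapply(runs, function(run) {
    ff <- run$footfalls
    dur <- run_duration(run)
    sup <- support_fractions(run, dt = dt)
    bos <- base_of_support(run)
    pp <- paw_parameters(run)
    row <- data.frame(animal = run$animal, run_id = run$run_id,
                      duration_s = dur, n_steps = nrow(ff),
                      cadence = nrow(ff) / dur,
                      nssp_pct = as.numeric(nssp_percent(run)),
                      stringsAsFactors = FALSE)
    for (cat_ in support_categories)
      row[[paste0("support_", cat_, "_pct")]] <- sup[[cat_]]
    row$bos_front_mm <- bos[["front"]]
    row$bos_hind_mm <- bos[["hind"]]
    metrics <- c("print_length_mm", "toe_spread_mm",
                 "intermediate_toe_spread_mm", "print_area",
                 "max_contact_area", "mean_intensity", "min_intensity",
                 "stand_s", "step_cycle_s", "paw_angle_deg")
    for (p in c("RF", "LF", "RH", "LH"))
      for (m in metrics)
        row[[paste0(m, "_", p)]] <-
          mean(pp[[m]][pp$paw == p], na.rm = TRUE)
    row
  })
  per_run <- do.call(rbind, rows)
  num <- names(per_run)[vapply(per_run, is.numeric, logical(1))]
  num <- setdiff(num, "run_id")
  per_animal <- stats::aggregate(per_run[num],
                                 by = list(animal = per_run$animal),
                                 FUN = function(v) mean(v, na.rm = TRUE))
  list(per_run = per_run, per_animal = per_animal)
}
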