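#' Default experimental design
#'
#' The ten experimental groups of the full drug-treatment design:
#' wild-type and AD-model mice, untreated or chronically treated with
#' cyclosporine A (CSA), nebivolol (NEB) or cabozantinib (XL), each at
#' two ages.
#'
#' @return Data frame with columns `group`, `genotype`, `age`,
#'   `treatment`.
#' @export
default_groups <- function() {
  data.frame(
    group = c("WT_Y", "WT_O", "AD_Y", "AD_O", "AD_CSA_Y", "AD_CSA_O",
              "AD_NEB_Y", "AD_NEB_O", "AD_XL_Y", "AD_XL_O"),
    genotype = c("WT", "WT", rep("AD", 8)),
    age = rep(c("young", "old"), 5),
    treatment = c("none", "none", "none", "none", "CsA", "CsA",
                  "Neb", "Neb", "Cab", "Cab"),
    stringsAsFactors = FALSE
  )
}

# every generator knob, at its wild-type-young baseline; all group
# effects are expressed as ratios (or probabilities) against this row
baseline_effects <- function() {
  list(
    activity = 1,          # multiplier on active-time occupancy
    sap = 1,               # multiplier on stretch-attend propensity
    stim_gain = 1,         # multiplier on stimulus-response amplitude
    hind_intensity = 1,    # multiplier on hindpaw print intensity
    nssp_corruption = 0.05,# probability a step breaks the paw pattern
    steps = 1,             # multiplier on steps per run
    print_length = 1,      # multiplier on print length
    bos_hind = 1,          # multiplier on hind base of support
    stand = 1,             # multiplier on stand / step-cycle durations
    syllable_tilt = 1      # usage tilt on the tilted syllable
  )
}

#' Default group effect table
#'
#' Generator knob settings per experimental group, expressed as ratios
#' against the wild-type-young baseline. The directions mirror the
#' published gait and home-cage contrasts: AD animals are hypoactive and
#' show more stretch-attend posture, blunted stimulus responses, fewer
#' steps with more step-pattern corruption and shorter front prints when
#' young, and heavier hindpaw loading (intensity, stand, hind base of
#' support) plus a tilted syllable repertoire when old. Treated groups
#' sit between the AD and WT rows: cyclosporine-treated old animals
#' resemble old wild types, while nebivolol- and cabozantinib-treated
#' old animals resemble young AD animals.
#'
#' @return Named list (one entry per group) of knob lists.
#' @export
default_effects <- function() {
  b <- baseline_effects()
  m <- function(...) utils::modifyList(b, list(...))
  list(
    WT_Y = b,
    WT_O = m(activity = 0.85, steps = 0.8, nssp_corruption = 0.15),
    AD_Y = m(activity = 0.8, sap = 1.3, stim_gain = 0.7, steps = 0.8,
             nssp_corruption = 0.25, print_length = 0.9),
    AD_O = m(activity = 0.7, sap = 1.4, stim_gain = 0.6, steps = 0.8,
             nssp_corruption = 0.25, hind_intensity = 1.3,
             bos_hind = 1.15, stand = 1.15, syllable_tilt = 2),
    AD_CSA_Y = m(activity = 0.9, stim_gain = 0.9, nssp_corruption = 0.2),
    AD_CSA_O = m(activity = 0.85, steps = 0.8, nssp_corruption = 0.15),
    AD_NEB_Y = m(activity = 0.8, sap = 1.3, stim_gain = 0.8,
                 nssp_corruption = 0.25, print_length = 0.9),
    AD_NEB_O = m(activity = 0.8, sap = 1.3, stim_gain = 0.8,
                 nssp_corruption = 0.2),
    AD_XL_Y = m(activity = 0.9, stand = 1.2, nssp_corruption = 0.2),
    AD_XL_O = m(activity = 0.8, sap = 1.25, nssp_corruption = 0.2)
  )
}

#' Synthetic cohort configuration
#'
#' Fully determines (together with the seed) every output of the
#' synthetic-data generators. All group effects are ratios against the
#' wild-type-young baseline.
#'
#' @param groups Data frame as [default_groups()] (subsettable).
#' @param n_per_group Animals per group (default 8).
#' @param seed Integer seed; fully determines all outputs.
#' @param hours Recording duration in hours (default 22; reduced
#'   durations rescale the assay timeline, see [assay_timeline()]).
#' @param frame_rate Frames per second (default 1).
#' @param effects Named list of per-group knob lists, merged over the
#'   baseline; see [default_effects()].
#' @param night_activity_mult Night/day activity ratio (default 2).
#' @param base_activity Baseline daytime active-time fraction (default
#'   0.12).
#' @param bout_len_s Mean activity-bout length, seconds (default 6).
#' @param sap_base Baseline stretch-attend occupancy (default 0.05).
#' @param acclim_amp Amplitude of the first-hour exploratory excess
#'   (default 1.5); decays with time constant `acclim_tau_s`.
#' @param acclim_tau_s Acclimation decay time constant in seconds
#'   (default: one fifth of the first assay hour).
#' @param stim_amp Activity boost at a full-gain stimulus response
#'   (default 1.5).
#' @param hab_decay Multiplicative decay of the stimulus response per
#'   presentation (default 0.5).
#' @param dropout Likelihood-dropout rate in `[0, 1)` (default 0.03):
#'   fraction of keypoint frames pushed below the 0.90 filter.
#' @param keypoint_noise_px Gaussian observation noise on every
#'   keypoint coordinate (px, default 0.5).
#' @param tilt_syllable Codebook index (1-based position) of the
#'   syllable whose usage the `syllable_tilt` knob scales (default 6).
#' @param runs_per_animal Compliant walkway runs per animal (default 4).
#' @param steps_per_run Baseline steps per run (default 20).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_groups(), n_per_group = 8,
                          seed = 1, hours = 22, frame_rate = 1,
                          effects = default_effects(),
                          night_activity_mult = 2, base_activity = 0.12,
                          bout_len_s = 6, sap_base = 0.05,
                          acclim_amp = 1.5, acclim_tau_s = NULL,
                          stim_amp = 1.5, hab_decay = 0.5,
                          dropout = 0.03, keypoint_noise_px = 0.5,
                          tilt_syllable = 6L,
                          runs_per_animal = 4L, steps_per_run = 20L) {
  if (!is.numeric(n_per_group) || n_per_group < 1)
    stop("config error: n_per_group must be a positive count")
  if (!is.numeric(hours) || hours <= 0)
    stop("config error: recording duration must be positive")
  if (dropout < 0 || dropout >= 1)
    stop("config error: dropout must lie in [0, 1)")
  if (is.null(acclim_tau_s)) acclim_tau_s <- hours * 3600 / 22 / 5
  b <- baseline_effects()
  eff <- stats::setNames(
    lapply(groups$group, function(g) {
      e <- utils::modifyList(b, if (is.null(effects[[g]])) list()
                             else effects[[g]])
      if (e$nssp_corruption < 0 || e$nssp_corruption > 1)
        stop("config error: nssp_corruption for group ", g,
             " must lie in [0, 1]")
      e
    }), groups$group)
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         seed = as.integer(seed), hours = hours, frame_rate = frame_rate,
         effects = eff, night_activity_mult = night_activity_mult,
         base_activity = base_activity, bout_len_s = bout_len_s,
         sap_base = sap_base, acclim_amp = acclim_amp,
         acclim_tau_s = acclim_tau_s, stim_amp = stim_amp,
         hab_decay = hab_decay, dropout = dropout,
         keypoint_noise_px = keypoint_noise_px,
         tilt_syllable = as.integer(tilt_syllable),
         runs_per_animal = as.integer(runs_per_animal),
         steps_per_run = as.integer(steps_per_run)),
    class = "cohort_config"
  )
}

# iterate (group, animal index) -> animal id
cohort_animals <- function(config) {
  do.call(rbind, lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    data.frame(animal = paste0(g$group, "_", seq_len(config$n_per_group)),
               group = g$group, genotype = g$genotype, age = g$age,
               treatment = g$treatment, stringsAsFactors = FALSE)
  }))
}

#' Simulate home-cage pose recordings
#'
#' Per animal: a two-state (rest/active) semi-Markov activity process
#' whose active-time occupancy is phase-modulated (night above day by
#' `night_activity_mult`), group-modulated (`activity` knob), inflated
#' during the first hour by an exponentially decaying acclimation
#' excess, and transiently boosted after each stimulus onset with
#' group-dependent gain and between-presentation habituation decay.
#' Active frames advance the centroid along a correlated random walk
#' confined to the cage with soft wall avoidance and a weak homing bias
#' toward the hut corner (producing hut dwell episodes during rest).
#' Stretch-attend postures are generated as a second occupancy process
#' expressed during rest via an elongated body template. The 12
#' keypoints are placed on a rigid head+trunk template oriented along
#' the direction of motion, and likelihoods are drawn near 1 with
#' dropout below the 0.90 filter at the configured rate. A synthetic
#' partner-presence channel (`partner_near_window`) is attached for the
#' sociability parameter.
#'
#' The transition hazards are parameterized so that the stationary
#' active-time fraction equals the target occupancy exactly, making the
#' percentage of moved frames linear in the activity knobs.
#'
#' @param config A [cohort_config()].
#' @param geometry A [cage_geometry()].
#' @return List of [pose_recording()] objects, one per animal.
#' @export
simulate_homecage <- function(config, geometry = cage_geometry()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  tl <- assay_timeline(hours = config$hours,
                       frame_rate = config$frame_rate)
  manifest <- cohort_animals(config)
  lapply(seq_len(nrow(manifest)), function(i) {
    a <- manifest[i, ]
    simulate_one_recording(config, tl, geometry, a)
  })
}

simulate_one_recording <- function(config, tl, geometry, a) {
  eff <- config$effects[[a$group]]
  n <- n_frames_full(tl)
  if (n < 2L) stop("config error: recording too short")
  t <- frame_times(tl, n)
  fr <- tl$frame_rate

  # target active-time occupancy per frame
  night <- grepl("night", phase_of(t, tl))
  occ <- config$base_activity * eff$activity *
    ifelse(night, config$night_activity_mult, 1)
  occ <- occ * (1 + config$acclim_amp * exp(-t / config$acclim_tau_s))
  plen <- tl$period_min * 60
  onsets <- stimulus_onsets(tl)
  for (k in seq_along(onsets)) {
    w <- t >= onsets[k] & t < onsets[k] + plen
    occ[w] <- occ[w] *
      (1 + config$stim_amp * eff$stim_gain * config$hab_decay^(k - 1))
  }
  occ <- pmin(occ, 0.85)

  lb <- config$bout_len_s * fr               # mean active-bout frames
  p_on <- pmin(occ / pmax(1 - occ, 1e-9) / lb, 1)
  p_off <- 1 / lb

  # stretch-attend occupancy (expressed during rest)
  sap_occ <- pmin(config$sap_base * eff$sap *
                    (1 + 2 * exp(-t / config$acclim_tau_s)), 0.6)
  ls <- 3 * fr                               # mean SAP-bout frames
  ps_on <- pmin(sap_occ / pmax(1 - sap_occ, 1e-9) / ls, 1)
  ps_off <- 1 / ls

  ppcm <- geometry$px_per_cm
  hutc <- c(mean(geometry$hut[c("x0", "x1")]),
            mean(geometry$hut[c("y0", "y1")]))
  margin <- 6
  pos <- matrix(0, n, 2)
  pos[1, ] <- c(geometry$width_px / 2, geometry$height_px / 2)
  theta <- numeric(n)
  theta[1] <- stats::runif(1, 0, 2 * pi)
  active <- logical(n)
  sap <- logical(n)

  u_act <- stats::runif(n)
  u_sap <- stats::runif(n)
  turn <- stats::rnorm(n, 0, 0.5)
  steplen <- pmax(0.6 * ppcm + stats::rgamma(n, shape = 1.2,
                                             scale = 2 * ppcm), 0)

  st <- FALSE
  ss <- FALSE
  for (i in seq_len(n)) {
    st <- if (st) u_act[i] >= p_off else u_act[i] < p_on[i]
    active[i] <- st
    ss <- if (ss) u_sap[i] >= ps_off else u_sap[i] < ps_on[i]
    sap[i] <- ss && !st
    if (i == 1L) next
    if (active[i]) {
      th <- theta[i - 1] + turn[i]
      # weak homing bias toward the hut corner
      home <- atan2(hutc[2] - pos[i - 1, 2], hutc[1] - pos[i - 1, 1])
      dth <- ((home - th + pi) %% (2 * pi)) - pi
      th <- th + 0.05 * dth
      p <- pos[i - 1, ] + steplen[i] * c(cos(th), sin(th))
      # soft wall avoidance: reflect into the margin
      p[1] <- reflect_into(p[1], margin, geometry$width_px - margin)
      p[2] <- reflect_into(p[2], margin, geometry$height_px - margin)
      pos[i, ] <- p
      theta[i] <- th
    } else {
      # resting frames hold position exactly (dwell episodes)
      pos[i, ] <- pos[i - 1, ]
      theta[i] <- theta[i - 1]
    }
  }

  rec <- pose_recording(
    make_keypoints(pos, theta, sap, n, ppcm, config$dropout,
                   config$keypoint_noise_px),
    timeline = tl, geometry = geometry, animal = a$animal,
    genotype = a$genotype, age = a$age, treatment = a$treatment
  )
  rec$group <- a$group
  rec$partner_near_window <- simulate_presence(n, occ_target = 0.15,
                                               mean_len = 30 * fr)
  rec
}

reflect_into <- function(x, lo, hi) {
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo), hi)
}

# two-state presence channel with exact stationary occupancy
simulate_presence <- function(n, occ_target, mean_len) {
  p_on <- min(occ_target / (1 - occ_target) / mean_len, 1)
  p_off <- 1 / mean_len
  u <- stats::runif(n)
  out <- logical(n)
  st <- FALSE
  for (i in seq_len(n)) {
    st <- if (st) u[i] >= p_off else u[i] < p_on
    out[i] <- st
  }
  out
}

# rigid two-segment body template, oriented along motion; SAP frames
# stretch the nose/tail-base axial offsets
make_keypoints <- function(pos, theta, sap, n, ppcm, dropout,
                           noise_px = 0.5) {
  len <- 8 * ppcm                            # body length, px
  elong <- 1 + 0.35 * sap
  ux <- cos(theta); uy <- sin(theta)
  nx <- -uy; ny <- ux
  offsets <- list(                           # c(axial, lateral) in body lengths
    nose = c(0.50, 0), head = c(0.35, 0),
    right_ear = c(0.30, 0.12), left_ear = c(0.30, -0.12),
    neck = c(0.25, 0), center = c(0, 0),
    right_shoulder = c(0.15, 0.15), left_shoulder = c(0.15, -0.15),
    hip = c(-0.25, 0), tail_base = c(-0.45, 0),
    tail_mid = c(-0.70, 0), tail_tip = c(-0.95, 0)
  )
  kps <- lapply(names(offsets), function(bp) {
    o <- offsets[[bp]]
    ax <- o[1] * len * (if (bp %in% c("nose", "tail_base")) elong else 1)
    x <- pos[, 1] + ax * ux + o[2] * len * nx +
      stats::rnorm(n, 0, noise_px)
    y <- pos[, 2] + ax * uy + o[2] * len * ny +
      stats::rnorm(n, 0, noise_px)
    lik <- pmin(1 - abs(stats::rnorm(n, 0, 0.01)), 1)
    drop <- stats::runif(n) < dropout
    lik[drop] <- stats::runif(sum(drop), 0.3, 0.899)
    data.frame(x = x, y = y, likelihood = lik)
  })
  stats::setNames(kps, names(offsets))
}

#' Syllable codebook
#'
#' The codebook of a fitted unsupervised segmentation: label ids, mean
#' bout durations, and a row-stochastic, zero-diagonal bout transition
#' matrix. The default emulates a 29-syllable model with mean bout
#' lengths between 2 and 5 seconds and uniform off-diagonal
#' transitions.
#'
#' @param n_syllables Codebook size (default 29).
#' @param labels Label ids (default `0:(n_syllables - 1)`; arbitrary
#'   non-contiguous ids are allowed).
#' @param mean_duration_s Per-syllable mean bout duration (s).
#' @param transition Row-stochastic transition matrix with zero
#'   diagonal.
#' @return An object of class `syllable_codebook`.
#' @export
syllable_codebook <- function(n_syllables = 29, labels = NULL,
                              mean_duration_s = NULL,
                              transition = NULL) {
  stopifnot(n_syllables >= 1)
  if (is.null(labels)) labels <- 0:(n_syllables - 1)
  stopifnot(length(labels) == n_syllables)
  if (is.null(mean_duration_s))
    mean_duration_s <- 2 + 3 * (seq_len(n_syllables) - 1) /
      max(1, n_syllables - 1)
  if (any(mean_duration_s <= 0))
    stop("config error: mean bout durations must be positive")
  if (is.null(transition)) {
    transition <- matrix(1, n_syllables, n_syllables)
    diag(transition) <- 0
    if (n_syllables > 1) transition <- transition / (n_syllables - 1)
  }
  if (!isTRUE(all.equal(dim(transition), rep(n_syllables, 2))))
    stop("config error: transition matrix must be ",
         n_syllables, " x ", n_syllables)
  if (n_syllables > 1 &&
      !isTRUE(all.equal(unname(rowSums(transition)),
                        rep(1, n_syllables))))
    stop("config error: transition matrix rows must sum to 1")
  if (any(diag(transition) != 0))
    stop("config error: transition matrix must have zero diagonal")
  structure(list(n_syllables = n_syllables, labels = as.integer(labels),
                 mean_duration_s = mean_duration_s,
                 transition = transition),
            class = "syllable_codebook")
}

# the group-tilted bout transition matrix actually used by the
# generator: incoming probabilities to the tilted syllable scaled, rows
# renormalized, diagonal kept zero
tilted_transition <- function(codebook, tilt, tilt_index) {
  P <- codebook$transition
  if (tilt != 1 && codebook$n_syllables > 1) {
    P[, tilt_index] <- P[, tilt_index] * tilt
    P <- P / rowSums(P)
  }
  P
}

#' Simulate syllable label sequences
#'
#' Per animal: a semi-Markov bout sequence — bout labels drawn from the
#' codebook transition matrix (with the group's usage tilt applied to
#' incoming transition probabilities and rows renormalized), bout
#' lengths geometric around the per-syllable mean durations.
#'
#' @param config A [cohort_config()].
#' @param codebook A [syllable_codebook()].
#' @return List of [syllable_sequence()] objects, one per animal.
#' @export
simulate_syllables <- function(config, codebook = syllable_codebook()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(codebook, "syllable_codebook"))
  set.seed(config$seed + 1L)
  n <- as.integer(round(config$hours * 3600 * config$frame_rate))
  if (n < 1L) stop("config error: recording too short")
  manifest <- cohort_animals(config)
  k <- codebook$n_syllables
  lapply(seq_len(nrow(manifest)), function(i) {
    a <- manifest[i, ]
    tilt <- config$effects[[a$group]]$syllable_tilt
    P <- tilted_transition(codebook, tilt, config$tilt_syllable)
    labels <- integer(n)
    cur <- sample.int(k, 1)
    pos <- 1L
    while (pos <= n) {
      mlen <- codebook$mean_duration_s[cur] * config$frame_rate
      len <- 1L + stats::rgeom(1, prob = min(1, 1 / mlen))
      end <- min(n, pos + len - 1L)
      labels[pos:end] <- codebook$labels[cur]
      pos <- end + 1L
      cur <- if (k > 1) sample.int(k, 1, prob = P[cur, ]) else cur
    }
    syllable_sequence(labels, frame_rate = config$frame_rate,
                      codebook = codebook$labels, animal = a$animal)
  })
}

#' Simulate walkway gait runs
#'
#' Per animal: `runs_per_animal` runs of footfalls laid down along a
#' one-dimensional walkway in the canonical alternate pattern
#' (RF-RH-LF-LH), with each step independently replaced by a random paw
#' with the group's `nssp_corruption` probability. Print geometry
#' follows a per-paw template with group-scaled print length and hind
#' base of support; print intensities carry the group's hindpaw gain;
#' stand and step-cycle durations scale with the `stand` knob; steps per
#' run scale with the `steps` knob. With `include_noncompliant = TRUE`
#' each animal additionally contributes one non-compliant run
#' (alternating between an over-10-second crossing and a mid-run
#' direction reversal) to exercise the compliance filter.
#'
#' @param config A [cohort_config()].
#' @param include_noncompliant Inject one non-compliant run per animal.
#' @param px_per_mm Walkway camera scale (default 2).
#' @return List of [gait_run()] objects.
#' @export
simulate_gait_runs <- function(config, include_noncompliant = FALSE,
                               px_per_mm = 2) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)
  manifest <- cohort_animals(config)
  runs <- list()
  for (i in seq_len(nrow(manifest))) {
    a <- manifest[i, ]
    eff <- config$effects[[a$group]]
    for (r in seq_len(config$runs_per_animal)) {
      runs[[length(runs) + 1L]] <-
        simulate_one_run(config, eff, a$animal, r, px_per_mm)
    }
    if (include_noncompliant) {
      kind <- if (i %% 2L == 1L) "slow" else "reverse"
      runs[[length(runs) + 1L]] <-
        simulate_one_run(config, eff, a$animal,
                         config$runs_per_animal + 1L, px_per_mm,
                         noncompliant = kind)
    }
  }
  runs
}

simulate_one_run <- function(config, eff, animal, run_id, px_per_mm,
                             noncompliant = NULL) {
  n_steps <- max(8L, as.integer(round(config$steps_per_run * eff$steps +
                                        stats::rnorm(1, 0, 1))))
  paws <- c("RF", "RH", "LF", "LH")
  order_ <- rep(paws, length.out = n_steps)
  corrupt <- stats::runif(n_steps) < eff$nssp_corruption
  order_[corrupt] <- sample(paws, sum(corrupt), replace = TRUE)

  step_dt <- 0.22 * eff$stand
  if (identical(noncompliant, "slow")) step_dt <- 12 / n_steps
  contact <- cumsum(c(0.1, pmax(stats::rnorm(n_steps - 1L, step_dt,
                                             0.015 * eff$stand),
                                0.03)))
  # duty factor ~0.43: each paw stays down across ~2 other steps, so
  # the support decomposition populates the multi-paw categories
  stand <- pmax(stats::rnorm(n_steps, 1.7 * step_dt,
                             0.1 * step_dt), 0.01)
  release <- contact + stand

  speed_px <- 5 * px_per_mm * 10 / (4 * step_dt)   # ~5 cm per stride
  x <- speed_px * contact
  if (identical(noncompliant, "reverse")) {
    half <- seq_len(n_steps) > n_steps / 2
    x[half] <- 2 * x[sum(!half)] - x[half]
  }
  front <- order_ %in% c("RF", "LF")
  x <- x + ifelse(front, 15, 0) + stats::rnorm(n_steps, 0, 1)

  width_front <- 10 * px_per_mm
  width_hind <- 14 * px_per_mm * eff$bos_hind
  side <- ifelse(order_ %in% c("RF", "RH"), 1, -1)
  y <- 60 + side * ifelse(front, width_front, width_hind) / 2 +
    stats::rnorm(n_steps, 0, 0.8)

  plen <- ifelse(front, 5.5, 6.5) * px_per_mm *
    ifelse(front, eff$print_length, 1)
  spread <- ifelse(front, 4, 7) * px_per_mm
  ispread <- ifelse(front, 3, 5) * px_per_mm
  mean_int <- ifelse(front, 115, 125 * eff$hind_intensity) +
    stats::rnorm(n_steps, 0, 2)
  mean_int <- pmin(pmax(mean_int, 1), 255)
  min_int <- pmin(pmax(mean_int - 25, 0), 255)

  footfalls <- data.frame(
    paw = order_, contact = contact, release = release,
    heel_x = x, heel_y = y, toe3_x = x + plen, toe3_y = y,
    toe_a_x = x + plen, toe_a_y = y - spread / 2,
    toe_b_x = x + plen, toe_b_y = y + spread / 2,
    itoe_a_x = x + plen * 0.9, itoe_a_y = y - ispread / 2,
    itoe_b_x = x + plen * 0.9, itoe_b_y = y + ispread / 2,
    print_area = plen * spread * 0.6,
    max_contact_area = plen * spread * 0.75,
    mean_intensity = mean_int, min_intensity = min_int,
    stringsAsFactors = FALSE
  )
  gait_run(footfalls, animal = animal, run_id = run_id,
           px_per_mm = px_per_mm)
}
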