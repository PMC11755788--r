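# Fixture builders shared across the suite. All fixtures are built in
# code; nothing is read from disk except round-trip temporaries.

# recording with an explicit centroid track; nose/tail_base sit along
# +x at half a body length, optionally elongated per frame
make_track_rec <- function(xy, hours = 22, frame_rate = 1,
                           geometry = cage_geometry(), lik = 1,
                           body_len = 45, elong = NULL) {
  n <- nrow(xy)
  if (is.null(elong)) elong <- rep(1, n)
  tl <- assay_timeline(hours = hours, frame_rate = frame_rate)
  lik <- rep(lik, length.out = n)
  pose_recording(
    list(
      center = data.frame(x = xy[, 1], y = xy[, 2], likelihood = lik),
      nose = data.frame(x = xy[, 1] + elong * body_len / 2, y = xy[, 2],
                        likelihood = lik),
      tail_base = data.frame(x = xy[, 1] - elong * body_len / 2,
                             y = xy[, 2], likelihood = lik)
    ),
    timeline = tl, geometry = geometry
  )
}

# recording whose per-frame "moved" status is exactly the given logical
# vector: moving frames displace by step_px (bouncing in place so the
# track stays inside the cage)
rec_from_moves <- function(move, hours = 22, frame_rate = 1,
                           step_px = 10, geometry = cage_geometry(),
                           elong = NULL) {
  n <- length(move)
  dx <- numeric(n)
  sign <- 1
  for (i in seq_len(n)) if (move[i]) {
    dx[i] <- sign * step_px
    sign <- -sign
  }
  x <- 160 + cumsum(dx)
  make_track_rec(cbind(x, rep(120, n)), hours = hours,
                 frame_rate = frame_rate, geometry = geometry,
                 elong = elong)
}

# minimal gait run from a schedule; heel geometry laid along +x
run_from_schedule <- function(paws, contacts, stands = 0.2,
                              heel_y = NULL, px_per_mm = 2,
                              animal = "a1", run_id = 1L) {
  n <- length(paws)
  stands <- rep(stands, length.out = n)
  if (is.null(heel_y))
    heel_y <- ifelse(paws %in% c("RF", "RH"), 65, 55)
  x <- 10 * seq_len(n)
  gait_run(data.frame(paw = paws, contact = contacts,
                      release = contacts + stands,
                      heel_x = x, heel_y = heel_y,
                      toe3_x = x + 12, toe3_y = heel_y,
                      stringsAsFactors = FALSE),
           animal = animal, run_id = run_id, px_per_mm = px_per_mm)
}

# random footfall schedule (arbitrary overlaps) for partition checks
random_schedule <- function(n = 12, span = 3) {
  paws <- sample(c("RF", "LF", "RH", "LH"), n, replace = TRUE)
  contact <- sort(stats::runif(n, 0, span))
  gait_run(data.frame(paw = paws, contact = contact,
                      release = contact + stats::runif(n, 0.05, 1),
                      stringsAsFactors = FALSE))
}

# random pose keypoint table for IO round-trips
random_pose_fixture <- function(n = 5, bodyparts = c("nose", "center")) {
  kps <- lapply(bodyparts, function(bp)
    data.frame(x = stats::runif(n, 0, 320), y = stats::runif(n, 0, 240),
               likelihood = stats::runif(n)))
  pose_recording(stats::setNames(kps, bodyparts))
}

# exact two-sided rank-sum p by exhaustive enumeration over all
# assignments of the pooled sample (tie-free inputs)
perm_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  U_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- U_of(seq_len(na))
  lo <- min(u_obs, na * length(b) - u_obs)
  hi <- max(u_obs, na * length(b) - u_obs)
  all_idx <- utils::combn(length(pooled), na)
  u_all <- apply(all_idx, 2, U_of)
  mean(u_all <= lo | u_all >= hi)
}
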