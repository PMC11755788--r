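#' Parameter-recovery check on one synthetic cohort
#'
#' Simulates one full cohort (all ten experimental groups at the
#' default planted effects) and measures whether each generator knob is
#' recovered by the pipeline stage it targets: the night/day activity
#' ratio (planted x2), the hindpaw print-intensity ratio of the old AD
#' group against the young wild-type baseline (planted x1.3), the step
#' sequence deficit of young AD animals (planted pattern corruption),
#' the usage ratio of the tilted syllable (planted x2), and whether the
#' k = 3 cut of the PCA-weighted Ward dendrogram separates the old
#' wild-type from the old AD group.
#'
#' @param seed Integer seed for the cohort.
#' @param hours Recording duration (default 2; the full assay topology
#'   is preserved by timeline rescaling).
#' @param n_per_group Animals per group (default 8, the wild-type
#'   cohort size of the design being emulated). Group profiles are
#'   means over animals; a cohort of one animal per group degenerates
#'   to single-animal profiles whose sampling noise at desk scale
#'   swamps the planted group structure.
#' @return One-row data frame with the measured quantities:
#'   `night_day_ratio`, `hind_intensity_ratio`, `nssp_wt`, `nssp_ad`,
#'   `tilt_ratio`, `separated` (logical).
#' @export
recovery_check <- function(seed, hours = 2, n_per_group = 8) {
  cc <- cohort_config(n_per_group = n_per_group, hours = hours,
                      seed = seed)
  recs <- lapply(simulate_homecage(cc), filter_low_likelihood)
  seqs <- simulate_syllables(cc)
  runs <- simulate_gait_runs(cc)
  manifest <- cohort_animals(cc)

  by_group <- function(vals, animals) {
    g <- manifest$group[match(animals, manifest$animal)]
    tapply(vals, g, mean)
  }

  # night/day activity from the wild-type-young recordings
  wt <- recs[manifest$group == "WT_Y"]
  h <- hours * 3600 / 22
  nd <- mean(vapply(wt, function(r) {
    night <- phase_interval(r$timeline, "night")
    day <- phase_interval(r$timeline, "day")
    percent_moved(r, night) / percent_moved(r, c(day[1] + 2 * h, day[2]))
  }, numeric(1)))

  # gait: hindpaw intensity and step sequence patterns per group
  gs <- run_summary(compliance_filter(runs)$compliant,
                    dt = 0.01)$per_animal
  hind <- by_group((gs$mean_intensity_RH + gs$mean_intensity_LH) / 2,
                   gs$animal)
  nssp <- by_group(gs$nssp_pct, gs$animal)

  # syllable usage of the tilted syllable
  tilt_label <- syllable_codebook()$labels[cc$tilt_syllable]
  freq <- vapply(seqs, function(s) {
    fd <- frequency_duration(s)
    fd$frequency[fd$syllable == tilt_label]
  }, numeric(1))
  tf <- by_group(freq, vapply(seqs, `[[`, character(1), "animal"))

  # profiles and the k = 3 weighted Ward cut
  rows <- t(vapply(seq_along(recs), function(i) {
    profile_row(battery_track15(recs[[i]]), battery_pose52(recs[[i]]),
                frequency_duration(seqs[[i]]))
  }, numeric(125)))
  rownames(rows) <- manifest$animal
  profiles <- assemble_profiles(rows, manifest$group)
  cl <- profile_cluster(profiles, k = 3)$clusters

  data.frame(
    seed = seed,
    night_day_ratio = nd,
    hind_intensity_ratio = unname(hind["AD_O"] / hind["WT_Y"]),
    nssp_wt = unname(nssp["WT_Y"]),
    nssp_ad = unname(nssp["AD_Y"]),
    tilt_ratio = unname(tf["AD_O"] / tf["WT_Y"]),
    separated = cl[["WT_O"]] != cl[["AD_O"]]
  )
}
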