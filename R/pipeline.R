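# End-to-end orchestration: validated run configuration, dataset
# simulation to disk, feature/syllable/gait extraction, profile
# clustering and statistics, with per-stage logging and a config hash
# stamped into every output for reproducibility audit.

run_config_keys <- c(
  "outdir", "seed", "hours", "frame_rate", "n_per_group", "groups",
  "likelihood_threshold", "move_cms", "scoot_hi_cms", "burst_lo_cms",
  "sap_elongation", "k_clusters", "registry_version", "dropout",
  "runs_per_animal", "steps_per_run"
)

#' Run configuration
#'
#' Builds and validates the configuration driving the pipeline
#' commands. Unknown keys are rejected; the configuration hash is
#' recorded in every output file header.
#'
#' @param config Named list of settings, or a path to a YAML file
#'   containing one. Recognized keys: `outdir`, `seed`, `hours`,
#'   `frame_rate`, `n_per_group`, `groups` (subset of
#'   [default_groups()] labels), `likelihood_threshold`, `move_cms`,
#'   `scoot_hi_cms`, `burst_lo_cms`, `sap_elongation`, `k_clusters`,
#'   `dropout`, `runs_per_animal`, `steps_per_run`,
#'   `registry_version`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: file not found: ",
                                   config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  defaults <- list(outdir = "cagewalk_out", seed = 1L, hours = 22,
                   frame_rate = 1, n_per_group = 8,
                   groups = default_groups()$group,
                   likelihood_threshold = 0.90, move_cms = 0.5,
                   scoot_hi_cms = 4, burst_lo_cms = 4,
                   sap_elongation = 1.2, k_clusters = 3,
                   dropout = 0.03, runs_per_animal = 4,
                   steps_per_run = 20,
                   registry_version = registry_version)
  cfg <- utils::modifyList(defaults, config)
  if (!all(cfg$groups %in% default_groups()$group))
    stop("config error: unknown group label(s): ",
         paste(setdiff(cfg$groups, default_groups()$group),
               collapse = ", "))
  if (cfg$likelihood_threshold <= 0 || cfg$likelihood_threshold > 1)
    stop("config error: likelihood_threshold must lie in (0, 1]")
  if (!identical(cfg$registry_version, registry_version))
    stop("config error: registry version mismatch (have ",
         registry_version, ")")
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# FNV-1a hash over the deparsed configuration (hex string); the output
# path is excluded so the hash identifies the scientific settings
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$outdir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]),
                           collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) ## keep in range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

as_cohort_config <- function(cfg) {
  groups <- default_groups()
  cohort_config(groups = groups[groups$group %in% cfg$groups, ,
                                drop = FALSE],
                n_per_group = cfg$n_per_group, seed = cfg$seed,
                hours = cfg$hours, frame_rate = cfg$frame_rate,
                dropout = cfg$dropout,
                runs_per_animal = cfg$runs_per_animal,
                steps_per_run = cfg$steps_per_run)
}

as_speed_config <- function(cfg) {
  speed_class_config(move_cms = cfg$move_cms,
                     scoot_hi_cms = cfg$scoot_hi_cms,
                     burst_lo_cms = cfg$burst_lo_cms,
                     sap_elongation = cfg$sap_elongation)
}

stamp <- function(cfg) {
  paste0("# cagewalk ", as.character(utils::packageVersion("cagewalk")),
         " config=", cfg$hash, " registry=", cfg$registry_version)
}

write_stamped_table <- function(df, path, cfg, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp(cfg), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_stamped_table <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

log_stage <- function(quiet, ...) if (!quiet) message("[cagewalk] ", ...)

#' Simulate a cohort dataset to disk
#'
#' Generates the synthetic cohort defined by the configuration and
#' writes the same file formats the extraction stage consumes: one
#' DLC-dialect pose CSV per animal, per-frame syllable label CSVs, a
#' footfall CSV, and a cohort manifest TSV mapping animal ids to
#' groups.
#'
#' @param config A [run_config()] (or list/path accepted by it).
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config = list(), quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(file.path(cfg$outdir, "pose"), recursive = TRUE,
             showWarnings = FALSE)
  cc <- as_cohort_config(cfg)
  recs <- simulate_homecage(cc)
  log_stage(quiet, "simulated ", length(recs), " pose recordings")
  for (rec in recs)
    write_pose_table(rec, file.path(cfg$outdir, "pose",
                                    paste0(rec$animal, ".csv")))
  seqs <- simulate_syllables(cc)
  syl <- do.call(rbind, lapply(seqs, function(s)
    data.frame(animal = s$animal,
               frame = seq_along(s$labels) - 1L,
               syllable = s$labels)))
  write_stamped_table(syl, file.path(cfg$outdir, "syllables.csv"), cfg,
                      sep = ",")
  runs <- simulate_gait_runs(cc)
  ft <- do.call(rbind, lapply(runs, function(r)
    cbind(animal = r$animal, run_id = r$run_id, r$footfalls)))
  write_stamped_table(ft, file.path(cfg$outdir, "footfalls.csv"), cfg,
                      sep = ",")
  manifest <- cohort_animals(cc)
  write_stamped_table(manifest, file.path(cfg$outdir, "manifest.tsv"),
                      cfg)
  log_stage(quiet, "wrote dataset to ", cfg$outdir)
  invisible(cfg$outdir)
}

#' Extract feature, syllable and gait tables
#'
#' Reads the dataset written by [cmd_simulate()] (or real data in the
#' same layout), applies the likelihood filter, and writes tidy tables:
#' the track and pose feature batteries, assay-wide syllable summaries,
#' and per-animal gait metrics, plus a log of masked-frame counts and
#' excluded non-compliant runs.
#'
#' @inheritParams cmd_simulate
#' @return Named list of the output tables, invisibly.
#' @export
cmd_extract <- function(config = list(), quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  manifest <- read_stamped_table(file.path(cfg$outdir, "manifest.tsv"))
  if (nrow(manifest) == 0L) stop("data error: empty cohort manifest")
  scfg <- as_speed_config(cfg)
  tl <- assay_timeline(hours = cfg$hours, frame_rate = cfg$frame_rate)

  feats <- list(); masked <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    an <- manifest$animal[i]
    path <- file.path(cfg$outdir, "pose", paste0(an, ".csv"))
    if (!file.exists(path)) stop("data error: missing pose table ", path)
    rec <- read_pose_table(path, timeline = tl, animal = an,
                           genotype = manifest$genotype[i],
                           age = manifest$age[i],
                           treatment = manifest$treatment[i])
    rec <- filter_low_likelihood(rec, cfg$likelihood_threshold)
    masked[an] <- rec$n_masked
    feats[[an]] <- rbind(battery_track15(rec, scfg),
                         battery_pose52(rec, scfg))
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  write_stamped_table(features, file.path(cfg$outdir, "features.tsv"),
                      cfg)

  syl <- read_stamped_table(file.path(cfg$outdir, "syllables.csv"),
                            sep = ",")
  codebook <- sort(unique(syl$syllable))
  syll_tab <- do.call(rbind, lapply(split(syl, syl$animal), function(d) {
    s <- syllable_sequence(d$syllable[order(d$frame)],
                           frame_rate = cfg$frame_rate,
                           codebook = codebook, animal = d$animal[1])
    cbind(animal = d$animal[1], frequency_duration(s))
  }))
  rownames(syll_tab) <- NULL
  write_stamped_table(syll_tab, file.path(cfg$outdir, "syllable_summary.tsv"),
                      cfg)

  ft <- read_stamped_table(file.path(cfg$outdir, "footfalls.csv"),
                           sep = ",")
  runs <- lapply(split(ft, list(ft$animal, ft$run_id), drop = TRUE),
                 function(d) gait_run(d[setdiff(names(d),
                                                c("animal", "run_id"))],
                                      animal = d$animal[1],
                                      run_id = d$run_id[1]))
  filt <- compliance_filter(runs)
  gait <- run_summary(filt$compliant)
  write_stamped_table(gait$per_animal,
                      file.path(cfg$outdir, "gait_per_animal.tsv"), cfg)
  write_stamped_table(gait$per_run,
                      file.path(cfg$outdir, "gait_per_run.tsv"), cfg)
  logdf <- data.frame(animal = names(masked),
                      masked_entries = as.integer(masked))
  write_stamped_table(logdf, file.path(cfg$outdir, "extract_log.tsv"),
                      cfg)
  log_stage(quiet, "extracted ", nrow(manifest), " animals; excluded ",
            nrow(filt$excluded), " non-compliant runs")
  invisible(list(features = features, syllables = syll_tab,
                 gait = gait, excluded = filt$excluded))
}

#' Assemble and cluster behavioral profiles
#'
#' Builds the per-animal 125-parameter profile rows from the extracted
#' tables, averages within group, computes PCA-loading weights and the
#' weighted Ward dendrogram, and writes the profiles (wide CSV),
#' loadings/weights (TSV), flat cluster assignments (TSV) and the
#' dendrogram (Newick).
#'
#' @inheritParams cmd_simulate
#' @return List with `profiles`, `result` (the `cluster_result`),
#'   invisibly.
#' @export
cmd_profile_cluster <- function(config = list(), quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  features <- read_stamped_table(file.path(cfg$outdir, "features.tsv"))
  syll <- read_stamped_table(file.path(cfg$outdir,
                                       "syllable_summary.tsv"))
  manifest <- read_stamped_table(file.path(cfg$outdir, "manifest.tsv"))
  animals <- manifest$animal
  rows <- t(vapply(animals, function(an) {
    f <- features[features$animal == an, , drop = FALSE]
    s <- syll[syll$animal == an, , drop = FALSE]
    profile_row(f[f$battery == "track15", , drop = FALSE],
                f[f$battery == "pose52", , drop = FALSE],
                data.frame(syllable = s$syllable,
                           frequency = s$frequency,
                           mean_duration_s = s$mean_duration_s))
  }, numeric(67L + 2L * length(unique(syll$syllable)))))
  profiles <- assemble_profiles(rows, manifest$group,
                                levels = cfg$groups)
  res <- profile_cluster(profiles, k = cfg$k_clusters)
  pr <- data.frame(group = rownames(profiles), profiles,
                   check.names = FALSE)
  write_stamped_table(pr, file.path(cfg$outdir, "profiles.csv"), cfg,
                      sep = ",")
  wt <- data.frame(parameter = names(res$pca$weights),
                   weight = res$pca$weights,
                   pc1_loading = res$pca$loadings[
                     match(names(res$pca$weights),
                           rownames(res$pca$loadings)), 1])
  write_stamped_table(wt, file.path(cfg$outdir, "weights.tsv"), cfg)
  cl <- data.frame(group = names(res$clusters),
                   cluster = as.integer(res$clusters))
  write_stamped_table(cl, file.path(cfg$outdir, "clusters.tsv"), cfg)
  export_dendrogram(res, file.path(cfg$outdir, "dendrogram.nwk"))
  log_stage(quiet, "clustered ", nrow(profiles), " group profiles (k = ",
            res$k, ")")
  invisible(list(profiles = profiles, result = res))
}

#' Group statistics and significance tables
#'
#' Runs the statistical battery over the extracted tables: two-way
#' ANOVA (age x genotype, Tukey HSD when the interaction gates open)
#' per gait parameter, rank-sum tests per home-cage feature between
#' genotypes within age, and Kruskal-Wallis with Dunn's post hoc per
#' syllable frequency; writes a tidy results TSV and an annotated
#' significance matrix.
#'
#' @inheritParams cmd_simulate
#' @param adjust Multiple-testing adjustment for the significance
#'   matrix (default `"none"`).
#' @return The tidy results data frame, invisibly.
#' @export
cmd_stats <- function(config = list(), adjust = "none", quiet = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  manifest <- read_stamped_table(file.path(cfg$outdir, "manifest.tsv"))
  gait <- read_stamped_table(file.path(cfg$outdir,
                                       "gait_per_animal.tsv"))
  features <- read_stamped_table(file.path(cfg$outdir, "features.tsv"))
  syll <- read_stamped_table(file.path(cfg$outdir,
                                       "syllable_summary.tsv"))
  mrow <- match(gait$animal, manifest$animal)
  res <- list()
  add <- function(parameter, contrast, p, direction)
    res[[length(res) + 1L]] <<- data.frame(
      parameter = parameter, contrast = contrast, p = p,
      direction = direction, stringsAsFactors = FALSE)

  if (length(unique(manifest$age[mrow])) > 1 &&
      length(unique(manifest$genotype[mrow])) > 1) {
    for (param in c("n_steps", "nssp_pct", "mean_intensity_RH",
                    "print_length_RF", "stand_s_RH", "bos_hind_mm")) {
      if (!param %in% names(gait)) next
      r <- gait_anova(gait[[param]], manifest$age[mrow],
                      manifest$genotype[mrow])
      ip <- r$effects$p[r$effects$term == "age:genotype"]
      if (length(ip) != 1L || is.na(ip)) next
      add(param, "age:genotype", ip,
          if (is.na(r$direction)) "up" else r$direction)
    }
  }
  for (param in unique(features$parameter)) {
    for (ag in unique(manifest$age)) {
      sel <- features$parameter == param &
        features$animal %in% manifest$animal[manifest$age == ag]
      f <- features[sel, , drop = FALSE]
      gt <- manifest$genotype[match(f$animal, manifest$animal)]
      if (length(unique(gt)) != 2L) next
      a <- f$value[gt == "AD"]; b <- f$value[gt == "WT"]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) next
      r <- homecage_wilcoxon(a, b)
      add(param, paste0("AD-WT/", ag), r$p,
          if (stats::median(a, na.rm = TRUE) >
              stats::median(b, na.rm = TRUE)) "up" else "down")
    }
  }
  gsy <- manifest$group[match(syll$animal, manifest$animal)]
  if (length(unique(gsy)) > 1) {
    for (s in unique(syll$syllable)) {
      sel <- syll$syllable == s
      if (sum(sel) < 3) next
      r <- tryCatch(syllable_kw_dunn(syll$frequency[sel], gsy[sel]),
                    error = function(e) NULL)
      if (is.null(r)) next
      add(paste0("syllfreq.", s), "groups", r$p, "up")
    }
  }
  res <- do.call(rbind, res)
  write_stamped_table(res, file.path(cfg$outdir, "stats.tsv"), cfg)
  mat <- significance_matrix(res, adjust = adjust)
  write_significance_matrix(mat, file.path(cfg$outdir,
                                           "significance_matrix.tsv"))
  log_stage(quiet, "wrote ", nrow(res), " test results")
  invisible(res)
}
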