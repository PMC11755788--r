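# Behavioral profiles: 125 named, ordered parameters per experimental
# group (15 track + 52 pose + 29 syllable frequencies + 29 syllable
# durations), and the PCA-loading-weighted Ward clustering of the
# group profiles.

#' Canonical profile column names
#'
#' @param codebook A [syllable_codebook()] (only the labels are used).
#' @return Character vector of the 125 ordered profile column names:
#'   `track.*` (15), `pose.*` (52), `syllfreq.<id>` (one per codebook
#'   syllable) and `sylldur.<id>`.
#' @export
profile_columns <- function(codebook = syllable_codebook()) {
  track <- vapply(track15_registry(), `[[`, character(1), "name")
  pose <- vapply(pose52_registry(), `[[`, character(1), "name")
  c(paste0("track.", track), paste0("pose.", pose),
    paste0("syllfreq.", codebook$labels),
    paste0("sylldur.", codebook$labels))
}

#' Per-animal profile row
#'
#' Concatenates one animal's feature batteries and assay-wide syllable
#' summary into a named numeric vector over the canonical profile
#' columns.
#'
#' @param track15 The animal's [battery_track15()] table.
#' @param pose52 The animal's [battery_pose52()] table.
#' @param syll The animal's assay-wide [frequency_duration()] table.
#' @return Named numeric vector of length `15 + 52 + 2 * codebook size`
#'   (125 at the default 29-syllable codebook). Undefined durations of
#'   unexpressed syllables and missing battery entries are `NA` (later
#'   imputed by [assemble_profiles()]).
#' @export
profile_row <- function(track15, pose52, syll) {
  stopifnot(nrow(track15) == 15L, nrow(pose52) == 52L)
  c(stats::setNames(track15$value, paste0("track.", track15$parameter)),
    stats::setNames(pose52$value, paste0("pose.", pose52$parameter)),
    stats::setNames(syll$frequency, paste0("syllfreq.", syll$syllable)),
    stats::setNames(syll$mean_duration_s,
                    paste0("sylldur.", syll$syllable)))
}

#' Assemble group behavioral profiles
#'
#' Averages per-animal profile rows within experimental group, giving
#' one 125-parameter profile per group. Missing entries (flagged
#' battery parameters, undefined syllable durations) are imputed by the
#' column median across animals, with the imputed cells recorded in the
#' `imputed` attribute for audit.
#'
#' @param rows Matrix (or data frame) of per-animal profile rows, with
#'   row names = animal ids and the canonical profile column names.
#' @param groups Character vector of group labels, one per animal row.
#' @param levels Optional full set of expected groups; an expected
#'   group with zero animals is an error.
#' @return Numeric matrix, one row per group (lexicographic order),
#'   with attribute `imputed` (count of imputed cells).
#' @export
assemble_profiles <- function(rows, groups, levels = NULL) {
  if (!is.null(levels)) {
    empty <- setdiff(levels, groups)
    if (length(empty))
      stop("group(s) with zero animals: ",
           paste(empty, collapse = ", "))
  }
  rows <- as.matrix(rows)
  if (is.null(rownames(rows)))
    rownames(rows) <- paste0("animal", seq_len(nrow(rows)))
  if (anyDuplicated(rownames(rows)))
    stop("duplicate animal ids in profile rows")
  if (length(groups) != nrow(rows))
    stop("groups must have one label per animal row")
  if (any(is.na(groups)) || any(!nzchar(groups)))
    stop("every animal must carry a group label")
  n_imputed <- 0L
  if (anyNA(rows)) {
    for (j in seq_len(ncol(rows))) {
      na <- is.na(rows[, j])
      if (any(na)) {
        med <- stats::median(rows[!na, j])
        if (!length(rows[!na, j]) || is.na(med)) med <- 0
        rows[na, j] <- med
        n_imputed <- n_imputed + sum(na)
      }
    }
  }
  glev <- sort(unique(groups))
  out <- t(vapply(glev, function(g) {
    colMeans(rows[groups == g, , drop = FALSE])
  }, numeric(ncol(rows))))
  rownames(out) <- glev
  attr(out, "imputed") <- n_imputed
  out
}

#' PCA-derived column weights
#'
#' Z-scores the profile columns, runs principal component analysis, and
#' assigns each column the absolute value of its loading on the first
#' principal component, renormalized to mean 1 over the retained
#' columns. Zero-variance columns are excluded from the PCA and get
#' weight 0 (flagged in `dropped`).
#'
#' @param profiles Numeric matrix of group profiles (rows = groups).
#' @return List with `loadings` (PC rotation matrix of retained
#'   columns), `explained` (explained-variance ratios, non-increasing),
#'   `weights` (named, one per profile column) and `dropped`
#'   (zero-variance column names).
#' @export
pca_weights <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3L)
    stop("PCA weighting needs at least 3 profile rows")
  sds <- apply(profiles, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all profile columns are constant")
  z <- scale(profiles[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  w_kept <- abs(pc$rotation[, 1])
  w_kept <- w_kept / mean(w_kept)
  weights <- stats::setNames(numeric(ncol(profiles)),
                             colnames(profiles))
  weights[names(w_kept)] <- w_kept
  list(loadings = pc$rotation, explained = explained,
       weights = weights, dropped = colnames(profiles)[!keep])
}

#' Weighted Ward clustering of group profiles
#'
#' Z-scores the profile columns, multiplies each by the square root of
#' its weight (so squared Euclidean distance is linear in the weights),
#' and clusters the groups by Ward's method on Euclidean distances.
#' Rows are ordered lexicographically by group label before clustering
#' so tie-breaking is deterministic. Equal weights reproduce unweighted
#' Ward linkage exactly.
#'
#' @param profiles Numeric matrix of group profiles (rows = groups).
#' @param weights Non-negative weight per column (e.g. from
#'   [pca_weights()]); recycled scalar allowed.
#' @param k Number of flat clusters to cut (default 3).
#' @return An object of class `cluster_result`: `hclust` (the linkage),
#'   `clusters` (flat assignment at `k`), `weights`, and the z-scored
#'   weighted matrix `x`.
#' @export
weighted_ward <- function(profiles, weights = 1, k = 3) {
  profiles <- as.matrix(profiles)
  if (length(weights) == 1L) weights <- rep(weights, ncol(profiles))
  if (length(weights) != ncol(profiles))
    stop("weights must have one entry per profile column")
  if (any(weights < 0)) stop("weights must be non-negative")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  sds <- apply(profiles, 2, stats::sd)
  z <- profiles
  ok <- sds > 0
  z[, ok] <- scale(profiles[, ok, drop = FALSE])
  z[, !ok] <- 0
  x <- sweep(z, 2, sqrt(weights), "*")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  k <- min(k, nrow(profiles))
  structure(list(hclust = hc,
                 clusters = stats::cutree(hc, k = k),
                 k = k, weights = weights, x = x),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$hclust$order), " leaves, k = ",
      x$k, "\n", sep = "")
  print(split(names(x$clusters), x$clusters))
  invisible(x)
}

#' Full profile clustering
#'
#' Convenience wrapper: PCA-loading weights followed by weighted Ward
#' clustering.
#'
#' @inheritParams weighted_ward
#' @return A `cluster_result` with the [pca_weights()] output attached
#'   as `$pca`.
#' @export
profile_cluster <- function(profiles, k = 3) {
  pw <- pca_weights(profiles)
  res <- weighted_ward(profiles, pw$weights, k = k)
  res$pca <- pw
  res
}

#' Export a dendrogram as Newick
#'
#' Writes the clustering dendrogram as a Newick tree with merge heights
#' as branch lengths; re-parsing reproduces the topology.
#'
#' @param result A `cluster_result` (or `hclust`).
#' @param path Output file path.
#' @return The Newick string, invisibly.
#' @export
export_dendrogram <- function(result, path) {
  hc <- if (inherits(result, "cluster_result")) result$hclust else result
  if (!inherits(hc, "hclust")) stop("need a cluster_result or hclust")
  if (length(hc$labels) < 2L)
    stop("cannot export a dendrogram with fewer than 2 leaves")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
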