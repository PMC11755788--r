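#' Standard mouse body parts
#'
#' The 12 keypoints tracked by the pose model: the 8 core parts used for
#' syllable segmentation (nose, ears, head, neck, centre, hip, tail
#' base) plus shoulders and two tail points.
#'
#' @export
mouse_bodyparts <- c(
  "nose", "left_ear", "right_ear", "head", "neck", "center",
  "left_shoulder", "right_shoulder", "hip", "tail_base",
  "tail_mid", "tail_tip"
)

#' Pose recording
#'
#' A per-animal time series of named keypoints on an assay timeline with
#' cage geometry. Each keypoint carries per-frame x, y (px, image
#' coordinates) and a tracking likelihood in [0, 1]. A logical mask (one
#' column per keypoint) records which entries were invalidated by the
#' likelihood filter; entries are only masked by
#' [filter_low_likelihood()].
#'
#' @param keypoints Named list of data frames, each with columns `x`,
#'   `y`, `likelihood` and a common number of rows (frames).
#' @param timeline An [assay_timeline()].
#' @param geometry A [cage_geometry()].
#' @param animal Animal identifier.
#' @param genotype,age,treatment Group labels (free-form; conventionally
#'   genotype in WT/AD, age in young/old/aged, treatment in
#'   none/CsA/Neb/Cab).
#' @return An object of class `pose_recording`.
#' @export
pose_recording <- function(keypoints, timeline = assay_timeline(),
                           geometry = cage_geometry(), animal = "animal1",
                           genotype = "WT", age = "young",
                           treatment = "none") {
  stopifnot(is.list(keypoints), length(keypoints) > 0,
            !is.null(names(keypoints)), all(nzchar(names(keypoints))))
  nf <- unique(vapply(keypoints, nrow, integer(1)))
  if (length(nf) != 1L)
    stop("all keypoint series must share one frame index")
  for (bp in names(keypoints)) {
    kp <- keypoints[[bp]]
    if (!all(c("x", "y", "likelihood") %in% names(kp)))
      stop("keypoint '", bp, "' must have columns x, y, likelihood")
    lik <- kp$likelihood
    if (any(!is.na(lik) & (lik < 0 | lik > 1)))
      stop("keypoint '", bp, "' has likelihood outside [0, 1]")
    keypoints[[bp]] <- kp[c("x", "y", "likelihood")]
  }
  mask <- matrix(FALSE, nrow = nf, ncol = length(keypoints),
                 dimnames = list(NULL, names(keypoints)))
  structure(
    list(animal = animal, genotype = genotype, age = age,
         treatment = treatment, timeline = timeline, geometry = geometry,
         keypoints = keypoints, mask = mask, n_masked = 0L),
    class = "pose_recording"
  )
}

#' @export
print.pose_recording <- function(x, ...) {
  cat("<pose_recording> ", x$animal, " (", x$genotype, "/", x$age, "/",
      x$treatment, "): ", n_frames(x), " frames, ",
      length(x$keypoints), " keypoints, ", x$n_masked,
      " masked entries\n", sep = "")
  invisible(x)
}

#' Number of frames in a pose recording
#' @param rec A [pose_recording()].
#' @export
n_frames <- function(rec) nrow(rec$keypoints[[1]])

# x/y matrix (n x 2) for one keypoint
kp_xy <- function(rec, bodypart) {
  kp <- rec$keypoints[[bodypart]]
  if (is.null(kp)) stop("recording has no keypoint '", bodypart, "'")
  cbind(kp$x, kp$y)
}

#' Read a pose-estimation table
#'
#' Reads per-frame keypoint coordinates and likelihoods. Two dialects
#' are supported: the DeepLabCut wide CSV (three header rows
#' scorer/bodyparts/coords, then one row per frame with a leading frame
#' index and x, y, likelihood columns per body part) and a flat CSV with
#' columns `frame, bodypart, x, y, likelihood`. The dialect is
#' auto-detected from the first header field.
#'
#' @param path Path to the CSV file.
#' @param dialect `"auto"` (default), `"dlc"` or `"flat"`.
#' @param timeline,geometry,animal,genotype,age,treatment Passed to
#'   [pose_recording()].
#' @return A [pose_recording()].
#' @export
read_pose_table <- function(path, dialect = c("auto", "dlc", "flat"),
                            timeline = assay_timeline(),
                            geometry = cage_geometry(),
                            animal = NULL, genotype = "WT", age = "young",
                            treatment = "none") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("format error: empty pose table '", path, "'")
  if (dialect == "auto") {
    lead <- strsplit(first, ",")[[1]][1]
    dialect <- if (identical(tolower(trimws(lead)), "scorer")) "dlc" else "flat"
  }
  if (is.null(animal))
    animal <- sub("\\.[^.]*$", "", basename(path))
  kp <- if (dialect == "dlc") read_pose_dlc(path) else read_pose_flat(path)
  pose_recording(kp, timeline = timeline, geometry = geometry,
                 animal = animal, genotype = genotype, age = age,
                 treatment = treatment)
}

read_pose_dlc <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 4L) stop("format error: DLC table '", path,
                           "' has no data rows")
  bodyparts <- as.character(raw[2, -1])
  coords <- tolower(trimws(as.character(raw[3, -1])))
  dat <- raw[-(1:3), , drop = FALSE]
  frames <- suppressWarnings(as.numeric(dat[[1]]))
  if (any(is.na(frames)) || any(diff(frames) <= 0))
    stop("format error: non-monotone frame index in '", path, "'")
  keypoints <- list()
  for (bp in unique(bodyparts)) {
    cols <- which(bodyparts == bp)
    get <- function(what) {
      j <- cols[coords[cols] == what]
      if (length(j) != 1L)
        stop("format error: missing '", what, "' column for body part '",
             bp, "' in '", path, "'")
      as.numeric(dat[[j + 1L]])
    }
    # likelihood checked first so its absence is the named error
    lik <- {
      j <- cols[coords[cols] == "likelihood"]
      if (length(j) != 1L)
        stop("format error: missing 'likelihood' column for body part '",
             bp, "' in '", path, "'")
      as.numeric(dat[[j + 1L]])
    }
    keypoints[[bp]] <- data.frame(x = get("x"), y = get("y"),
                                  likelihood = lik)
  }
  keypoints
}

read_pose_flat <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "bodypart", "x", "y", "likelihood")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("format error: missing column(s) ", paste0("'", miss, "'",
         collapse = ", "), " in '", path, "'")
  if (nrow(dat) == 0L) stop("format error: empty pose table '", path, "'")
  keypoints <- list()
  for (bp in unique(dat$bodypart)) {
    d <- dat[dat$bodypart == bp, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    if (any(duplicated(d$frame)))
      stop("format error: non-monotone frame index for body part '", bp,
           "' in '", path, "'")
    keypoints[[bp]] <- data.frame(x = d$x, y = d$y,
                                  likelihood = d$likelihood)
  }
  nf <- vapply(keypoints, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("format error: body parts have unequal frame counts in '",
         path, "'")
  keypoints
}

#' Write a pose recording to a CSV pose table
#'
#' Inverse of [read_pose_table()]; values round-trip up to float
#' formatting (17 significant digits are written).
#'
#' @param rec A [pose_recording()].
#' @param path Output path.
#' @param dialect `"dlc"` (default) or `"flat"`.
#' @param scorer Scorer label written in the DLC header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(rec, path, dialect = c("dlc", "flat"),
                             scorer = "cagewalk") {
  dialect <- match.arg(dialect)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  bps <- names(rec$keypoints)
  nf <- n_frames(rec)
  if (dialect == "dlc") {
    header1 <- c("scorer", rep(scorer, 3L * length(bps)))
    header2 <- c("bodyparts", rep(bps, each = 3L))
    header3 <- c("coords", rep(c("x", "y", "likelihood"), length(bps)))
    body <- do.call(cbind, lapply(rec$keypoints, function(kp)
      cbind(fmt(kp$x), fmt(kp$y), fmt(kp$likelihood))))
    lines <- c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ","),
               apply(cbind(seq_len(nf) - 1L, body), 1L, paste,
                     collapse = ","))
    writeLines(lines, path)
  } else {
    dat <- do.call(rbind, lapply(bps, function(bp) {
      kp <- rec$keypoints[[bp]]
      data.frame(frame = seq_len(nf) - 1L, bodypart = bp,
                 x = fmt(kp$x), y = fmt(kp$y),
                 likelihood = fmt(kp$likelihood))
    }))
    utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Filter low-likelihood pose estimates
#'
#' Masks every (frame, keypoint) entry whose tracking likelihood falls
#' below `threshold` (default 0.90, strict `<`). Masked coordinates are
#' linearly interpolated from the nearest valid neighbours; at the
#' recording edges the nearest valid value is carried over. The mask is
#' retained on the returned recording for audit, and the count of masked
#' entries is recorded in `$n_masked`. The operation is idempotent.
#'
#' @param rec A [pose_recording()].
#' @param threshold Likelihood threshold in (0, 1].
#' @return The filtered [pose_recording()].
#' @export
filter_low_likelihood <- function(rec, threshold = 0.90) {
  stopifnot(inherits(rec, "pose_recording"),
            threshold > 0, threshold <= 1)
  n_masked <- 0L
  for (bp in names(rec$keypoints)) {
    kp <- rec$keypoints[[bp]]
    bad <- is.na(kp$likelihood) | kp$likelihood < threshold
    if (all(bad))
      stop("keypoint '", bp, "' has no frames at likelihood >= ",
           threshold)
    if (any(bad)) {
      good <- which(!bad)
      badi <- which(bad)
      kp$x[badi] <- stats::approx(good, kp$x[good], xout = badi,
                                  method = "linear", rule = 2)$y
      kp$y[badi] <- stats::approx(good, kp$y[good], xout = badi,
                                  method = "linear", rule = 2)$y
      rec$keypoints[[bp]] <- kp
    }
    rec$mask[, bp] <- bad
    n_masked <- n_masked + sum(bad)
  }
  rec$n_masked <- n_masked
  rec
}
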