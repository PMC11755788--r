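#' Syllable label sequence
#'
#' A per-frame sequence of integer behavioral syllable labels emitted by
#' an unsupervised segmentation of the pose time series. Labels are
#' arbitrary non-negative integers drawn from a fixed codebook; ids need
#' not be contiguous (unsupervised pipelines commonly emit sparse id
#' sets).
#'
#' @param labels Integer vector of per-frame labels.
#' @param frame_rate Frames per second (default 1).
#' @param codebook Sorted vector of allowed label ids. Defaults to the
#'   distinct labels present; pass the full codebook explicitly so that
#'   unused syllables appear with zero frequency (default fitted
#'   codebook size in this assay: 29 syllables).
#' @param animal Animal identifier.
#' @return An object of class `syllable_sequence`.
#' @export
syllable_sequence <- function(labels, frame_rate = 1, codebook = NULL,
                              animal = "animal1") {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label sequence")
  if (any(is.na(labels))) stop("labels must not contain NA")
  if (is.null(codebook)) codebook <- sort(unique(labels))
  codebook <- sort(unique(as.integer(codebook)))
  if (!all(labels %in% codebook))
    stop("labels outside the codebook: ",
         paste(utils::head(setdiff(unique(labels), codebook)),
               collapse = ", "))
  structure(list(animal = animal, labels = labels,
                 frame_rate = frame_rate, codebook = codebook),
            class = "syllable_sequence")
}

#' @export
print.syllable_sequence <- function(x, ...) {
  cat("<syllable_sequence> ", x$animal, ": ", length(x$labels),
      " frames, codebook of ", length(x$codebook), " syllables\n",
      sep = "")
  invisible(x)
}

#' Syllable bouts (run-length encoding)
#'
#' A bout is a maximal run of constant label. Concatenating the bouts
#' reconstructs the sequence exactly.
#'
#' @param seq A [syllable_sequence()].
#' @return Data frame with columns `label`, `start` (1-based frame
#'   index of the bout start) and `length` (frames).
#' @export
bouts <- function(seq) {
  r <- rle(seq$labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths)
}

# bouts whose start frame falls in [window[1], window[2]) seconds;
# window NULL = whole sequence
bouts_in_window <- function(seq, window = NULL) {
  b <- bouts(seq)
  if (is.null(window)) return(b)
  t0 <- (b$start - 1L) / seq$frame_rate
  b[t0 >= window[1] & t0 < window[2], , drop = FALSE]
}

#' Per-syllable frequency and duration
#'
#' Bout-based usage summaries over a time window. Frequency of a
#' syllable is its share of all bouts starting in the window (a bout is
#' attributed to the window containing its start frame, which makes
#' per-period bout counts additive). Duration is the mean bout length in
#' seconds. A frame-based occupancy column is also emitted, since both
#' conventions are in use. Syllables without bouts get frequency 0 and
#' `NA` duration.
#'
#' @param seq A [syllable_sequence()].
#' @param window `c(start, end)` seconds (half-open) or `NULL` for the
#'   whole sequence.
#' @return Data frame with one row per codebook syllable: `syllable`,
#'   `n_bouts`, `frequency`, `mean_duration_s`, `occupancy`.
#' @export
frequency_duration <- function(seq, window = NULL) {
  b <- bouts_in_window(seq, window)
  cb <- seq$codebook
  n_bouts <- vapply(cb, function(s) sum(b$label == s), integer(1))
  total <- sum(n_bouts)
  freq <- if (total > 0) n_bouts / total else rep(0, length(cb))
  dur <- vapply(cb, function(s) {
    len <- b$length[b$label == s]
    if (length(len)) mean(len) / seq$frame_rate else NA_real_
  }, numeric(1))
  # frame-based occupancy over the same window
  idx <- if (is.null(window)) rep(TRUE, length(seq$labels)) else {
    t <- (seq_along(seq$labels) - 1L) / seq$frame_rate
    t >= window[1] & t < window[2]
  }
  occ <- if (any(idx)) {
    tab <- table(factor(seq$labels[idx], levels = cb))
    as.numeric(tab) / sum(idx)
  } else rep(0, length(cb))
  out <- data.frame(syllable = cb, n_bouts = n_bouts, frequency = freq,
                    mean_duration_s = dur, occupancy = occ)
  attr(out, "empty_window") <- total == 0L
  out
}

#' Number of distinct syllables expressed in a window
#'
#' @inheritParams frequency_duration
#' @return Count of syllables with at least one bout starting in the
#'   window.
#' @export
distinct_syllables <- function(seq, window = NULL) {
  b <- bouts_in_window(seq, window)
  length(unique(b$label))
}

#' Bout-to-bout transition matrix
#'
#' Counts transitions between consecutive bout labels (self-transitions
#' are impossible by bout construction, so the diagonal is zero) and
#' row-normalizes. Rows without outgoing transitions are left at zero
#' and flagged in the `empty_rows` attribute.
#'
#' @param seq A [syllable_sequence()].
#' @return Row-stochastic square matrix over the codebook, with an
#'   `empty_rows` attribute naming rows with no outgoing transitions.
#' @export
transition_matrix <- function(seq) {
  b <- bouts(seq)
  cb <- seq$codebook
  k <- length(cb)
  m <- matrix(0, k, k, dimnames = list(as.character(cb),
                                       as.character(cb)))
  if (nrow(b) > 1L) {
    from <- match(b$label[-nrow(b)], cb)
    to <- match(b$label[-1L], cb)
    for (i in seq_along(from)) m[from[i], to[i]] <- m[from[i], to[i]] + 1
  }
  rs <- rowSums(m)
  empty <- rownames(m)[rs == 0]
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(m, "empty_rows") <- empty
  m
}

#' Syllable summaries at each stimulus onset
#'
#' Applies [frequency_duration()] to the first analysis period after
#' each stimulus onset (the 10-minute periods starting at onsets; at
#' timeline defaults these are periods 73, 85 and 97). Windows are
#' half-open: the frame at exactly onset + one period is excluded.
#'
#' @param seq A [syllable_sequence()].
#' @param timeline An [assay_timeline()].
#' @return Named list, one [frequency_duration()] table per onset,
#'   names `period<index>`.
#' @export
stimulus_onset_summaries <- function(seq, timeline) {
  plen <- timeline$period_min * 60
  out <- list()
  for (on in stimulus_onsets(timeline)) {
    p <- period_index(on, timeline)
    out[[paste0("period", p)]] <- frequency_duration(seq, c(on, on + plen))
  }
  out
}
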