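# Frame-wise conformational-state classifier.
#
# State 1 is recognised by the broken Thr35--Mg2+ bond (large OG35--Mg
# distance). Within state 2 the three Tyr32-orientation substates are
# resolved by a fixed decision cascade on the OH32--Ogamma and OH32--O18
# distances; frames matching no signature are reported UNASSIGNED, never
# silently merged.

#' Classifier configuration
#'
#' Thresholds are derived from the characteristic distance centers of the
#' (sub)states: the intact OG35--Mg bond sits near 2.0 A (so `t_mg` adds a
#' thermal margin and broken-bond trajectories jump far above 3 A), the
#' OH32--Ogamma centers are 2.7 A (OX), 7.5 A (OZ, broad) and 11.3 A (OY),
#' and the OY-defining OH32--O18 contact is 4.3 A against more than 12 A in
#' the other substates. The centers are state signatures, not sharp cutoffs;
#' every threshold is configurable.
#'
#' @param t_mg OG35--Mg cutoff (A) above which the Thr35 bond counts as
#'   broken (state 1). Default 2.6.
#' @param t_ox OH32--Ogamma cutoff (A) for substate OX. Default 4.5.
#' @param t_oy OH32--O18 cutoff (A) for substate OY. Default 6.5.
#' @param t_oz_max OH32--Ogamma upper bound (A) for substate OZ. Default 10.
#' @param smoothing_window Odd window (frames) of the label mode filter;
#'   1 disables smoothing. Default 5.
#' @return A `ras_classifier_config` list.
#' @export
classifier_config <- function(t_mg = 2.6, t_ox = 4.5, t_oy = 6.5,
                              t_oz_max = 10.0, smoothing_window = 5L) {
  if (!(t_mg < t_ox && t_ox < t_oz_max)) {
    abort("thresholds must satisfy t_mg < t_ox < t_oz_max")
  }
  if (t_oy <= 0) abort("t_oy must be positive")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    abort("smoothing_window must be an odd integer >= 1")
  }
  structure(list(t_mg = t_mg, t_ox = t_ox, t_oy = t_oy, t_oz_max = t_oz_max,
                 smoothing_window = smoothing_window),
            class = "ras_classifier_config")
}

#' Classify frames by the decision cascade
#'
#' The cascade: state 1 if the OG35--Mg distance exceeds `t_mg`; otherwise
#' OX if OH32--Ogamma is within `t_ox`; otherwise OY if OH32--O18 is within
#' `t_oy`; otherwise OZ if OH32--Ogamma is within `t_oz_max`; otherwise
#' UNASSIGNED. Total on finite input: every frame receives exactly one
#' label.
#'
#' @param features A `ras_features` tibble (or any data frame with the three
#'   cascade distance columns).
#' @param cfg A [classifier_config()].
#' @return Character vector of raw labels, one per row.
#' @export
classify_frame <- function(features, cfg = classifier_config()) {
  d_mg <- features$d_OG35_Mg
  d_ox <- features$d_OH32_Og
  d_o18 <- features$d_OH32_O18
  if (any(!is.finite(d_mg) | !is.finite(d_ox) | !is.finite(d_o18))) {
    abort("classifier requires finite cascade distances")
  }
  ifelse(d_mg > cfg$t_mg, "S1",
    ifelse(d_ox <= cfg$t_ox, "S2_OX",
      ifelse(d_o18 <= cfg$t_oy, "S2_OY",
        ifelse(d_ox <= cfg$t_oz_max, "S2_OZ", "UNASSIGNED"))))
}

# Centered mode filter on integer-coded labels; ties broken toward the
# previous frame's *smoothed* label, else toward the earliest tied label in
# the window. Window truncates at the series edges.
mode_filter <- function(code, window) {
  n <- length(code)
  if (window <= 1L || n == 1L) return(code)
  half <- window %/% 2L
  out <- integer(n)
  prev <- code[1]
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    cnt <- tabulate(code[lo:hi], nbins = 5L)
    m <- max(cnt)
    tied <- which(cnt == m)
    if (length(tied) == 1L) {
      out[i] <- tied
    } else if (prev %in% tied) {
      out[i] <- prev
    } else {
      w <- code[lo:hi]
      out[i] <- w[which(w %in% tied)[1]]
    }
    prev <- out[i]
  }
  out
}

#' Classify a feature series into a label series
#'
#' Applies the per-frame cascade, then a centered label mode filter (a
#' debouncer: representative trajectories dwell in a state for many frames,
#' so isolated single-frame flickers are treated as classification noise).
#' Segments and transitions are rebuilt from the smoothed labels.
#'
#' @param features A `ras_features` tibble (non-empty).
#' @param cfg A [classifier_config()].
#' @return A `ras_labels` tibble with columns `frame`, `raw_label`, `label`;
#'   attributes `segments` (tibble: `label`, `start`, `end`, `length`) and
#'   `config`. See [label_segments()], [transition_matrix()].
#' @export
classify_series <- function(features, cfg = classifier_config()) {
  if (nrow(features) == 0) abort("cannot classify an empty feature series")
  raw <- classify_frame(features, cfg)
  code <- match(raw, STATE_LEVELS)
  sm <- mode_filter(code, cfg$smoothing_window)
  lab <- STATE_LEVELS[sm]
  out <- tibble(frame = features$frame, raw_label = raw, label = lab)
  attr(out, "segments") <- rle_segments(lab, features$frame)
  attr(out, "config") <- cfg
  class(out) <- c("ras_labels", class(out))
  out
}

rle_segments <- function(lab, frame) {
  r <- rle(lab)
  end <- cumsum(r$lengths)
  start <- c(1L, head(end, -1L) + 1L)
  tibble(label = r$values, start = frame[start], end = frame[end],
         length = r$lengths)
}

#' Run-length segments of a label series
#' @param labels A `ras_labels` object.
#' @return Tibble with one row per dwell segment.
#' @export
label_segments <- function(labels) {
  seg <- attr(labels, "segments")
  if (is.null(seg)) seg <- rle_segments(labels$label, labels$frame)
  seg
}

#' Transition count matrix
#'
#' Counts boundary crossings between consecutive smoothed labels: entry
#' (i, j) is the number of i -> j transitions; the diagonal is zero. Total
#' transitions equal segments - 1 for a single trajectory.
#'
#' @param labels A `ras_labels` object.
#' @return 5 x 5 integer matrix over [state_levels()].
#' @export
transition_matrix <- function(labels) {
  lab <- labels$label
  m <- matrix(0L, 5, 5, dimnames = list(STATE_LEVELS, STATE_LEVELS))
  if (length(lab) >= 2) {
    a <- match(lab[-length(lab)], STATE_LEVELS)
    b <- match(lab[-1], STATE_LEVELS)
    keep <- a != b
    if (any(keep)) {
      t2 <- table(factor(a[keep], 1:5), factor(b[keep], 1:5))
      m <- m + matrix(as.integer(t2), 5, 5,
                      dimnames = list(STATE_LEVELS, STATE_LEVELS))
    }
  }
  m
}

#' Pooled (sub)state occupancies
#'
#' Occupancies over one label series or several pooled trajectories,
#' weighted by frame counts (a 300-frame trajectory counts three times a
#' 100-frame one), mirroring distributions calculated over all performed
#' simulations. UNASSIGNED is reported like any other label.
#'
#' @param labels A `ras_labels` object or a list of them.
#' @return A `ras_occupancy` tibble with columns `label`, `n_frames`,
#'   `fraction`, `mean_dwell` (frames; `NA` for labels never observed) and
#'   attribute `n_trajectories`. Fractions sum to 1.
#' @export
occupancy <- function(labels) {
  if (inherits(labels, "ras_labels")) labels <- list(labels)
  if (!length(labels) || sum(vapply(labels, nrow, integer(1))) == 0) {
    abort("occupancy requires at least one labeled frame")
  }
  lab_all <- unlist(lapply(labels, function(x) x$label))
  counts <- table(state_factor(lab_all))
  segs <- dplyr::bind_rows(lapply(labels, label_segments))
  dwell <- segs |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mean_dwell = mean(.data$length), .groups = "drop")
  out <- tibble(
    label = STATE_LEVELS,
    n_frames = as.integer(counts[STATE_LEVELS]),
    fraction = as.numeric(counts[STATE_LEVELS]) / length(lab_all)
  ) |>
    dplyr::left_join(dwell, by = "label")
  attr(out, "n_trajectories") <- length(labels)
  class(out) <- c("ras_occupancy", class(out))
  out
}
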