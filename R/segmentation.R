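# Activity segmentation: the nocturnal study animals consolidate rest into
# one diurnal inactive phase per day. Epochs are thresholded into
# resting/active, short activity bouts inside long rest are smoothed away,
# and the longest merged rest run overlapping daylight becomes the day's
# phase.

#' Segmentation parameters
#'
#' @param act_threshold Epochs with activity at or below this value are
#'   "resting" (collar units, 0-255; default 40).
#' @param min_rest_run_minutes Minimum duration of a merged rest segment
#'   for it to qualify as a candidate inactive phase (default 120).
#' @param max_gap_minutes Activity bouts shorter than this, with long rest
#'   on both sides, are treated as part of the rest phase (default 60).
#' @param epoch_minutes Nominal epoch length (default 5).
#' @return List of class `seg_params`.
#' @export
seg_params <- function(act_threshold = 40, min_rest_run_minutes = 120,
                       max_gap_minutes = 60, epoch_minutes = 5) {
  stopifnot(act_threshold >= 0, act_threshold <= 255,
            min_rest_run_minutes > 0, max_gap_minutes > 0)
  structure(list(act_threshold = act_threshold,
                 min_rest_run_minutes = min_rest_run_minutes,
                 max_gap_minutes = max_gap_minutes,
                 epoch_minutes = epoch_minutes), class = "seg_params")
}

#' Classify 5-min epochs as resting or active
#'
#' A pure per-epoch threshold: resting iff activity <= threshold.
#'
#' @param act Integer vector of activity values (0-255).
#' @param params A [seg_params()].
#' @return Character vector, `"resting"` or `"active"`, same length.
#' @export
classify_epochs <- function(act, params = seg_params()) {
  ifelse(act <= params$act_threshold, "resting", "active")
}

#' Merge rest runs across short activity bouts
#'
#' Scans the label sequence left to right. An active run is absorbed into
#' the surrounding rest when it is shorter than `max_gap_minutes` *and*
#' shorter than both adjacent rest runs (the left one taken after any
#' merges so far) - so isolated night-time rest blips never capture real
#' activity between them, while brief activity bouts inside a long rest
#' phase are smoothed away. Returns maximal merged rest segments.
#'
#' @param labels Output of [classify_epochs()].
#' @param timestamps POSIXct epoch start times (strictly increasing).
#' @param params A [seg_params()].
#' @return Data frame with `start`, `end` (POSIXct; end is exclusive, i.e.
#'   last epoch start + epoch length), and `epochs` (rest epochs contained).
#' @export
merge_rest_runs <- function(labels, timestamps, params = seg_params()) {
  stopifnot(length(labels) == length(timestamps))
  ep <- params$epoch_minutes * 60
  # despeckle: a single resting epoch wedged between active runs is sensor
  # noise (or an irrelevant catnap) and would otherwise break up genuine
  # activity bouts; relabel it active
  r <- rle(labels)
  if (length(r$lengths) > 2) {
    interior <- 2:(length(r$lengths) - 1L)
    flip <- interior[r$values[interior] == "resting" & r$lengths[interior] == 1L]
    if (length(flip)) {
      r$values[flip] <- "active"
      labels <- inverse.rle(r)
      r <- rle(labels)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  cur <- NULL  # c(start_idx, end_idx, rest_epochs)
  pending_gap <- Inf
  cur_min_of <- function(cur)
    (as.numeric(timestamps[cur[2]]) - as.numeric(timestamps[cur[1]])) / 60 +
      params$epoch_minutes
  for (k in seq_along(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    run_min <- (as.numeric(timestamps[i1]) - as.numeric(timestamps[i0])) / 60 +
      params$epoch_minutes
    if (r$values[k] == "resting") {
      if (is.null(cur)) {
        cur <- c(i0, i1, i1 - i0 + 1L)
      } else if (pending_gap < params$max_gap_minutes &&
                 pending_gap < run_min) {
        cur <- c(cur[1], i1, cur[3] + i1 - i0 + 1L)
      } else {
        segs[[length(segs) + 1L]] <- cur
        cur <- c(i0, i1, i1 - i0 + 1L)
      }
      pending_gap <- Inf
    } else {
      if (!is.null(cur)) {
        # true elapsed gap: from bout onset to the next run's first epoch,
        # so sensor dropouts hidden inside the bout count as gap time
        gap_min <- if (k < length(r$values))
          (as.numeric(timestamps[ends[k] + 1L]) - as.numeric(timestamps[i0])) / 60
        else Inf
        if (gap_min < params$max_gap_minutes && gap_min < cur_min_of(cur)) {
          pending_gap <- gap_min
        } else {
          segs[[length(segs) + 1L]] <- cur
          cur <- NULL
          pending_gap <- Inf
        }
      }
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
  if (!length(segs))
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"), epochs = integer()))
  m <- do.call(rbind, segs)
  out <- data.frame(start = timestamps[m[, 1]], end = timestamps[m[, 2]] + ep,
                    epochs = m[, 3])
  # second stage: the greedy pass can leave a mergeable gap behind when a
  # short rest run only grows into a long segment later; iterate the same
  # absorption rule at the segment level until stable
  repeat {
    if (nrow(out) < 2) break
    dur <- (as.numeric(out$end) - as.numeric(out$start)) / 60
    gap <- (as.numeric(out$start[-1]) - as.numeric(out$end[-nrow(out)])) / 60
    j <- which(gap < params$max_gap_minutes & gap < dur[-nrow(out)] &
                 gap < dur[-1])[1]
    if (is.na(j)) break
    out$end[j] <- out$end[j + 1]
    out$epochs[j] <- out$epochs[j] + out$epochs[j + 1]
    out <- out[-(j + 1), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Extract one diurnal inactive phase per animal-day
#'
#' For each calendar day, the phase is the longest merged rest segment
#' overlapping the day's `[sunrise, sunset]` window (ties broken by
#' earliest start; each segment serves only the day whose daylight it
#' overlaps most). Days without a qualifying segment emit no phase.
#'
#' @param act ACT table (`animal_id`, `timestamp`, `act`), one or many
#'   animals.
#' @param lat,lon Study-area coordinates for sunrise/sunset (degrees).
#' @param params A [seg_params()].
#' @param gap_days Optional data frame from [flag_gap_days()]; phases on
#'   flagged animal-days are marked low-confidence.
#' @return Data frame with `animal_id`, `date`, `start`, `end`,
#'   `epoch_count`, `low_confidence`.
#' @export
extract_inactive_phases <- function(act, lat, lon, params = seg_params(),
                                    gap_days = NULL) {
  out <- list()
  for (id in unique(act$animal_id)) {
    a <- act[act$animal_id == id, ]
    labels <- classify_epochs(a$act, params)
    segs <- merge_rest_runs(labels, a$timestamp, params)
    if (!nrow(segs)) next
    days <- seq(as.Date(min(a$timestamp)), as.Date(max(a$timestamp)), by = "day")
    sun <- sun_times(lat, lon, days)
    # overlap (seconds) of every segment with every day's daylight
    ov <- outer(seq_len(nrow(segs)), seq_along(days), function(i, j) {
      pmax(0, pmin(as.numeric(segs$end[i]), as.numeric(sun$sunset[j])) -
             pmax(as.numeric(segs$start[i]), as.numeric(sun$sunrise[j])))
    })
    seg_min <- (as.numeric(segs$end) - as.numeric(segs$start)) / 60
    day_of_seg <- apply(ov, 1, function(v) if (max(v) > 0) which.max(v) else NA_integer_)
    day_of_seg[seg_min < params$min_rest_run_minutes] <- NA_integer_
    for (j in seq_along(days)) {
      cand <- which(day_of_seg == j)
      if (!length(cand)) next
      len <- as.numeric(segs$end[cand]) - as.numeric(segs$start[cand])
      best <- cand[order(-len, as.numeric(segs$start[cand]))][1]
      out[[length(out) + 1L]] <- data.frame(
        animal_id = id, date = days[j], start = segs$start[best],
        end = segs$end[best], epoch_count = segs$epochs[best],
        low_confidence = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      epoch_count = integer(), low_confidence = logical()))
  ph <- do.call(rbind, out)
  if (!is.null(gap_days) && nrow(gap_days)) {
    key <- paste(ph$animal_id, ph$date)
    ph$low_confidence <- key %in% paste(gap_days$animal_id, gap_days$date)
  }
  ph
}

#' Anchoring of phase bounds to sunrise and sunset
#'
#' For each window half-width, the fraction of phases ending within that
#' window around sunset, and starting within it around sunrise (symmetric
#' windows).
#'
#' @param phases Output of [extract_inactive_phases()].
#' @param lat,lon Coordinates used for the sun times.
#' @param windows Half-widths in minutes (default 30 and 90).
#' @return Data frame `window_min`, `frac_end_near_sunset`,
#'   `frac_start_near_sunrise`.
#' @export
phase_timing_stats <- function(phases, lat, lon, windows = c(30, 90)) {
  if (!nrow(phases)) stop("no phases supplied")
  sun <- sun_times(lat, lon, sort(unique(phases$date)))
  i <- match(phases$date, sun$date)
  d_end <- abs(as.numeric(phases$end) - as.numeric(sun$sunset[i])) / 60
  d_start <- abs(as.numeric(phases$start) - as.numeric(sun$sunrise[i])) / 60
  data.frame(window_min = windows,
             frac_end_near_sunset = vapply(windows, function(w) mean(d_end <= w), 0),
             frac_start_near_sunrise = vapply(windows, function(w) mean(d_start <= w), 0))
}

#' Fraction of the time budget spent in the inactive phase
#'
#' Total phase duration divided by the number of covered animal-days times
#' 24 h.
#'
#' @param phases Output of [extract_inactive_phases()].
#' @return A single proportion.
#' @export
inactive_time_fraction <- function(phases) {
  sum(as.numeric(phases$end) - as.numeric(phases$start)) /
    (nrow(phases) * 86400)
}
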