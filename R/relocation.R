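# Within-phase relocation detection. A resting animal occasionally moves to
# a second site during its inactive phase; the signature is a sustained
# activity bout in the ACT series combined with a shift of the mean GPS
# position of more than 100 m between the fixes before and after the bout.

#' Relocation-detection parameters
#'
#' @param min_displacement_m Strict displacement threshold between pre- and
#'   post-bout mean positions (default 100; an event needs *more* than
#'   this).
#' @param min_active_bout_minutes Minimum length of a supra-threshold
#'   activity run inside the phase to count as a candidate (default 10,
#'   i.e. two 5-min epochs, rejecting single-epoch noise).
#' @param min_fixes Minimum GPS fixes on each side of a candidate
#'   (default 2).
#' @param act_threshold Activity threshold shared with segmentation
#'   (default 40).
#' @param edge_guard_minutes Fixes within this margin of the phase bounds
#'   are excluded from centroids (default 5): phase bounds are only
#'   epoch-accurate, so a fix in the first/last epoch can catch the animal
#'   still walking in or out.
#' @return List of class `reloc_params`.
#' @export
reloc_params <- function(min_displacement_m = 100, min_active_bout_minutes = 10,
                         min_fixes = 2, act_threshold = 40,
                         edge_guard_minutes = 5) {
  stopifnot(min_displacement_m > 0, min_active_bout_minutes > 0, min_fixes >= 1)
  structure(list(min_displacement_m = min_displacement_m,
                 min_active_bout_minutes = min_active_bout_minutes,
                 min_fixes = min_fixes, act_threshold = act_threshold,
                 edge_guard_minutes = edge_guard_minutes),
            class = "reloc_params")
}

# candidate activity bouts inside [start, end): maximal supra-threshold runs
.candidate_bouts <- function(act_t, act_v, start, end, params, epoch_s = 300) {
  sel <- act_t >= start & act_t < end
  tt <- act_t[sel]; vv <- act_v[sel]
  if (!length(tt)) return(NULL)
  r <- rle(vv > params$act_threshold)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * epoch_s / 60 >= params$min_active_bout_minutes)
  if (!length(keep)) return(NULL)
  data.frame(bout_start = tt[starts[keep]], bout_end = tt[ends[keep]] + epoch_s)
}

#' Detect relocations within inactive phases
#'
#' For each phase, candidate bouts are maximal runs of supra-threshold ACT
#' epochs lasting at least `min_active_bout_minutes`. Processed in time
#' order, the pre-bout centroid is the mean of fixes from the phase start
#' (or the previous event's bout end) to the bout start, and the post-bout
#' centroid the mean of fixes from the bout end to the next candidate (or
#' the phase end). An event is emitted iff the centroids are strictly more
#' than `min_displacement_m` apart; several events per phase are allowed.
#'
#' @param phases Output of [extract_inactive_phases()].
#' @param act ACT table. @param gps GPS table (planar meters).
#' @param params A [reloc_params()].
#' @param calendar Optional [hunting_calendar()] for season labels.
#' @return Data frame with `animal_id`, `date`, `event_time`, `pre_x`,
#'   `pre_y`, `post_x`, `post_y`, `distance_m`, `season` (3-level factor,
#'   `NA` when no calendar given).
#' @export
detect_relocations <- function(phases, act, gps, params = reloc_params(),
                               calendar = NULL) {
  out <- list()
  act_by <- split(act[, c("timestamp", "act")], act$animal_id)
  gps_by <- split(gps[, c("timestamp", "x", "y")], gps$animal_id)
  guard <- params$edge_guard_minutes * 60
  for (i in seq_len(nrow(phases))) {
    ph <- phases[i, ]
    a <- act_by[[ph$animal_id]]
    ga <- gps_by[[ph$animal_id]]
    g <- ga[ga$timestamp >= ph$start + guard & ga$timestamp < ph$end - guard, ]
    if (nrow(g) < 2 * params$min_fixes) next
    bouts <- .candidate_bouts(a$timestamp, a$act, ph$start, ph$end, params)
    if (is.null(bouts)) next
    seg_start <- ph$start
    for (b in seq_len(nrow(bouts))) {
      pre <- g[g$timestamp >= seg_start & g$timestamp < bouts$bout_start[b], ]
      post_lim <- if (b < nrow(bouts)) bouts$bout_start[b + 1] else ph$end
      post <- g[g$timestamp >= bouts$bout_end[b] & g$timestamp < post_lim, ]
      if (nrow(pre) < params$min_fixes || nrow(post) < params$min_fixes) next
      d <- sqrt((mean(post$x) - mean(pre$x))^2 + (mean(post$y) - mean(pre$y))^2)
      if (d > params$min_displacement_m) {
        out[[length(out) + 1L]] <- data.frame(
          animal_id = ph$animal_id, date = ph$date,
          event_time = bouts$bout_start[b],
          pre_x = mean(pre$x), pre_y = mean(pre$y),
          post_x = mean(post$x), post_y = mean(post$y), distance_m = d)
        seg_start <- bouts$bout_end[b]
      }
    }
  }
  if (!length(out)) {
    ev <- data.frame(animal_id = character(), date = as.Date(character()),
                     event_time = as.POSIXct(character(), tz = "UTC"),
                     pre_x = numeric(), pre_y = numeric(), post_x = numeric(),
                     post_y = numeric(), distance_m = numeric())
  } else ev <- do.call(rbind, out)
  ev$season <- if (!is.null(calendar)) season_label(ev$date, calendar)
               else factor(rep(NA_character_, nrow(ev)),
                           levels = levels(season_label(Sys.Date())))
  ev
}

#' Per-season relocation summary
#'
#' Share of phases with at least one relocation event, by season, plus the
#' split of event distances at 500 m.
#'
#' @param events Output of [detect_relocations()].
#' @param phases Output of [extract_inactive_phases()].
#' @param calendar A [hunting_calendar()].
#' @return Data frame per season: `n_phases`, `n_relocated`, `p_relocation`,
#'   `n_short` (<= 500 m), `n_long` (> 500 m).
#' @export
relocation_summary <- function(events, phases, calendar = hunting_calendar()) {
  s3 <- season_label(phases$date, calendar)
  has_ev <- paste(phases$animal_id, phases$date) %in%
    paste(events$animal_id, events$date)
  ev_season <- season_label(events$date, calendar)
  res <- lapply(levels(s3), function(lv) {
    n <- sum(s3 == lv)
    data.frame(season = lv, n_phases = n,
               n_relocated = sum(has_ev & s3 == lv),
               p_relocation = if (n) sum(has_ev & s3 == lv) / n else NA_real_,
               n_short = sum(ev_season == lv & events$distance_m <= 500),
               n_long = sum(ev_season == lv & events$distance_m > 500))
  })
  do.call(rbind, res)
}
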