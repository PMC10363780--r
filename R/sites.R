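# Daily resting locations and resting sites. Each inactive phase yields one
# daily resting location (mean of the fixes acquired before any relocation,
# so the location reflects the dawn choice of where to settle); per animal,
# those locations are clustered by average-linkage agglomeration cut at
# 50 m into resting sites, whose revisits are then counted by season.

#' Daily resting locations
#'
#' Mean GPS position of each inactive phase, ignoring every fix acquired at
#' or after the first relocation event's bout onset. Phases without a
#' qualifying fix emit nothing.
#'
#' @param phases Output of [extract_inactive_phases()].
#' @param gps GPS table (planar meters).
#' @param events Output of [detect_relocations()] (may be empty).
#' @return Data frame `animal_id`, `date`, `x`, `y`, `n_fixes`.
#' @export
daily_resting_locations <- function(phases, gps, events = NULL) {
  out <- list()
  gps_by <- split(gps[, c("timestamp", "x", "y")], gps$animal_id)
  ev_key <- if (!is.null(events) && nrow(events))
    paste(events$animal_id, events$date) else character()
  for (i in seq_len(nrow(phases))) {
    ph <- phases[i, ]
    lim <- ph$end
    if (length(ev_key)) {
      hit <- ev_key == paste(ph$animal_id, ph$date)
      if (any(hit)) lim <- min(events$event_time[hit])
    }
    ga <- gps_by[[ph$animal_id]]
    g <- ga[ga$timestamp >= ph$start & ga$timestamp < lim, ]
    if (!nrow(g)) next
    out[[length(out) + 1L]] <- data.frame(
      animal_id = ph$animal_id, date = ph$date,
      x = mean(g$x), y = mean(g$y), n_fixes = nrow(g))
  }
  if (!length(out))
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      x = numeric(), y = numeric(), n_fixes = integer()))
  do.call(rbind, out)
}

#' Cluster daily resting locations into resting sites
#'
#' Strictly per animal: average-linkage hierarchical clustering of the
#' daily locations, dendrogram cut at `cutoff_m` (clusters merging at
#' exactly the cutoff are joined). Singleton sites are allowed.
#'
#' @param locations Output of [daily_resting_locations()].
#' @param cutoff_m Dendrogram cut height in meters (default 50).
#' @return `locations` with an added `site` column (`animal_id:index`,
#'   indices ordered by first visit date within animal).
#' @export
cluster_resting_sites <- function(locations, cutoff_m = 50) {
  locations$site <- NA_character_
  for (id in unique(locations$animal_id)) {
    sel <- which(locations$animal_id == id)
    if (length(sel) == 1L) {
      locations$site[sel] <- paste0(id, ":1")
      next
    }
    hc <- stats::hclust(stats::dist(locations[sel, c("x", "y")]), method = "average")
    grp <- stats::cutree(hc, h = cutoff_m)
    # relabel in order of first appearance (date order) for determinism
    first <- tapply(seq_along(grp), grp, min)
    relab <- match(grp, as.integer(names(sort(first))))
    locations$site[sel] <- paste0(id, ":", relab)
  }
  locations
}

#' Summarise resting sites with per-season visit counts
#'
#' One row per site: centroid (mean of member daily locations), member
#' count, and visits split into non-hunting vs hunting season by the date
#' of each member visit. A site visited in both seasons appears with
#' positive counts in both columns (and will enter both seasonal models).
#'
#' @param locations Output of [cluster_resting_sites()].
#' @param calendar A [hunting_calendar()].
#' @return Data frame `site`, `animal_id`, `x`, `y`, `n_visits`,
#'   `n_visits_NHS`, `n_visits_HS`.
#' @export
summarise_sites <- function(locations, calendar = hunting_calendar()) {
  stopifnot("site" %in% names(locations))
  s2 <- season2(season_label(locations$date, calendar))
  agg <- lapply(split(seq_len(nrow(locations)), locations$site), function(idx) {
    data.frame(site = locations$site[idx[1]],
               animal_id = locations$animal_id[idx[1]],
               x = mean(locations$x[idx]), y = mean(locations$y[idx]),
               n_visits = length(idx),
               n_visits_NHS = sum(s2[idx] == "NHS"),
               n_visits_HS = sum(s2[idx] == "HS"))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$animal_id, out$site), , drop = FALSE]
}

#' Fraction of resting sites visited more than once
#' @param sites Output of [summarise_sites()].
#' @return A single proportion.
#' @export
revisited_fraction <- function(sites) mean(sites$n_visits > 1)
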