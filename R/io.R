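# Sensor-table and vector-layer ingest. Collar data arrive as two delimited
# tables per study: a 5-min activity (ACT) series and a 30-min GPS series.
# Everything is reprojected to one planar metric CRS on the way in, and the
# post-capture exclusion window is applied here so no downstream stage ever
# sees disturbed post-handling behaviour.

.parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read an activity (ACT) table
#'
#' Expects a CSV with header `animal_id, timestamp, act`: one integer
#' activity summary (0-255) per 5-min epoch per animal, timestamps in UTC
#' ISO-8601. Rows with unparseable timestamps are dropped with a count;
#' activity outside 0-255 is an error.
#'
#' @param path CSV file path.
#' @return A data frame with columns `animal_id`, `timestamp` (POSIXct UTC),
#'   `act` (integer), sorted by animal and time.
#' @export
read_act <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "timestamp", "act"), "ACT")
  ts <- .parse_utc(df$timestamp)
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sprintf("dropped %d ACT row(s) with unparseable timestamps", sum(bad)))
    df <- df[!bad, ]; ts <- ts[!bad]
  }
  if (any(df$act < 0 | df$act > 255, na.rm = TRUE))
    stop("ACT values outside [0, 255]", call. = FALSE)
  out <- data.frame(animal_id = as.character(df$animal_id), timestamp = ts,
                    act = as.integer(df$act))
  out[order(out$animal_id, out$timestamp), , drop = FALSE]
}

#' Read a GPS fix table and project it
#'
#' Expects a CSV with header `animal_id, timestamp, lon, lat` (UTC ISO-8601,
#' degrees). Fixes are reprojected to the planar CRS; `x`/`y` are meters.
#'
#' @param path CSV file path.
#' @param proj An [lcc_projection()].
#' @return Data frame `animal_id`, `timestamp`, `x`, `y` sorted by animal
#'   and time, with the projection attached as attribute `"projection"`.
#' @export
read_gps <- function(path, proj = lcc_projection()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "timestamp", "lon", "lat"), "GPS")
  ts <- .parse_utc(df$timestamp)
  bad <- is.na(ts) | !is.finite(df$lon) | !is.finite(df$lat)
  if (any(bad)) {
    warning(sprintf("dropped %d GPS row(s) with unparseable fields", sum(bad)))
    df <- df[!bad, ]; ts <- ts[!bad]
  }
  xy <- lcc_project(df$lon, df$lat, proj)
  out <- data.frame(animal_id = as.character(df$animal_id), timestamp = ts,
                    x = xy[, "x"], y = xy[, "y"])
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  attr(out, "projection") <- proj
  out
}

#' Build per-animal survey records
#'
#' The survey window starts `exclusion_days` after capture (animals show
#' depressed activity for a few days after handling) and ends at the last
#' observation.
#'
#' @param captures Data frame with `animal_id`, `study_site`, `capture_time`
#'   (POSIXct UTC); optional `sex`.
#' @param act,gps Sensor tables (used to locate each animal's last record).
#' @param exclusion_days Days dropped after each capture (default 3).
#' @return Data frame with `animal_id`, `study_site`, `sex`, `capture_time`,
#'   `survey_start`, `survey_end`, `survey_length_days`.
#' @export
animal_records <- function(captures, act, gps, exclusion_days = 3) {
  .require_cols(captures, c("animal_id", "study_site", "capture_time"), "captures")
  ids <- as.character(captures$animal_id)
  last_t <- vapply(ids, function(id) {
    tt <- c(act$timestamp[act$animal_id == id], gps$timestamp[gps$animal_id == id])
    if (!length(tt)) NA_real_ else as.numeric(max(tt))
  }, numeric(1))
  start <- captures$capture_time + exclusion_days * 86400
  end <- as.POSIXct(last_t, origin = "1970-01-01", tz = "UTC")
  len <- as.numeric(difftime(end, start, units = "days"))
  if (any(!is.na(len) & len <= 0))
    warning("some animals have non-positive survey length after exclusion")
  data.frame(animal_id = ids, study_site = as.character(captures$study_site),
             sex = if ("sex" %in% names(captures)) captures$sex else NA_character_,
             capture_time = captures$capture_time, survey_start = start,
             survey_end = end, survey_length_days = len)
}

#' Drop sensor rows before each animal's survey start
#'
#' @param tab ACT or GPS table.
#' @param records Output of [animal_records()].
#' @return The filtered table; the number of dropped rows is reported.
#' @export
filter_survey_window <- function(tab, records) {
  start <- records$survey_start[match(tab$animal_id, records$animal_id)]
  keep <- !is.na(start) & tab$timestamp >= start
  dropped <- sum(!keep)
  if (dropped) message(sprintf("survey-window filter dropped %d row(s)", dropped))
  tab[keep, , drop = FALSE]
}

#' Flag days with sensor gaps
#'
#' Gaps of up to `tol_intervals` nominal sampling intervals are tolerated
#' silently; any longer gap flags every UTC day it overlaps, and phases on
#' those days are later marked low-confidence.
#'
#' @param tab ACT or GPS table (one animal or many).
#' @param nominal_s Nominal cadence in seconds (300 for ACT, 1800 for GPS).
#' @param tol_intervals Tolerated gap length in intervals (default 3).
#' @return Data frame `animal_id`, `date` of flagged days (possibly empty).
#' @export
flag_gap_days <- function(tab, nominal_s, tol_intervals = 3) {
  out <- list()
  for (id in unique(tab$animal_id)) {
    tt <- sort(tab$timestamp[tab$animal_id == id])
    if (length(tt) < 2) next
    dt <- diff(as.numeric(tt))
    gi <- which(dt > tol_intervals * nominal_s)
    for (g in gi) {
      days <- seq(as.Date(tt[g]), as.Date(tt[g + 1]), by = "day")
      out[[length(out) + 1L]] <- data.frame(animal_id = id, date = days)
    }
  }
  if (!length(out)) return(data.frame(animal_id = character(), date = as.Date(character())))
  unique(do.call(rbind, out))
}

#' Load a full sensor dataset in one call
#'
#' Reads the ACT and GPS tables, builds the per-animal survey records from
#' a capture table, and applies the post-capture exclusion window to both
#' sensor streams.
#'
#' @param act_path,gps_path Sensor CSV paths (see [read_act()],
#'   [read_gps()]).
#' @param captures Capture data frame (see [animal_records()]).
#' @param proj An [lcc_projection()].
#' @param exclusion_days Days dropped after each capture (default 3).
#' @return List with `act`, `gps` (survey-window filtered) and `records`.
#' @export
load_sensor_tables <- function(act_path, gps_path, captures,
                               proj = lcc_projection(), exclusion_days = 3) {
  act <- read_act(act_path)
  gps <- read_gps(gps_path, proj)
  records <- animal_records(captures, act, gps, exclusion_days)
  list(act = filter_survey_window(act, records),
       gps = filter_survey_window(gps, records),
       records = records)
}

# ---- vector layers (GeoJSON) -----------------------------------------------

#' Read a GeoJSON FeatureCollection
#'
#' Minimal reader covering Polygon, MultiPolygon and LineString features
#' with scalar properties, which is all the landscape layers of this
#' pipeline use (building footprints, road lines, vegetation patches).
#'
#' @param path GeoJSON file.
#' @return List with `geometries` (list of n x 2 coordinate matrices; outer
#'   rings only), `types` (character), and `properties` (data frame).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path, call. = FALSE)
  geoms <- list(); types <- character(); props <- list()
  for (ft in gj$features) {
    g <- ft$geometry
    coord_mat <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    polys <- switch(g$type,
      Polygon = list(coord_mat(g$coordinates[[1]])),
      MultiPolygon = lapply(g$coordinates, function(pp) coord_mat(pp[[1]])),
      LineString = list(coord_mat(g$coordinates)),
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    for (p in polys) {
      # drop the explicit closing vertex of GeoJSON rings
      if (g$type != "LineString" && nrow(p) > 1 &&
          all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
      geoms[[length(geoms) + 1L]] <- p
      types <- c(types, if (g$type == "LineString") "line" else "polygon")
      pr <- ft$properties
      pr <- pr[!vapply(pr, is.null, TRUE)]
      props[[length(props) + 1L]] <-
        if (length(pr)) as.data.frame(pr, stringsAsFactors = FALSE)
        else data.frame(row.names = 1L)
    }
  }
  properties <- do.call(rbind, lapply(props, function(p) {
    all_names <- unique(unlist(lapply(props, names)))
    for (nm in setdiff(all_names, names(p))) p[[nm]] <- NA
    p[, all_names, drop = FALSE]
  }))
  list(geometries = geoms, types = types, properties = properties)
}

#' Write geometries to GeoJSON
#'
#' @param geometries List of n x 2 coordinate matrices.
#' @param types Character vector, "polygon" or "line", recycled.
#' @param properties Optional data frame, one row per geometry.
#' @param path Output file.
#' @export
write_geojson <- function(geometries, types = "polygon", properties = NULL, path) {
  types <- rep_len(types, length(geometries))
  feats <- lapply(seq_along(geometries), function(i) {
    m <- geometries[[i]]
    coords <- lapply(seq_len(nrow(m)), function(r) c(m[r, 1], m[r, 2]))
    geom <- if (types[i] == "line") {
      list(type = "LineString", coordinates = coords)
    } else {
      list(type = "Polygon", coordinates = list(c(coords, coords[1])))
    }
    pr <- if (!is.null(properties)) as.list(properties[i, , drop = FALSE]) else structure(list(), names = character())
    list(type = "Feature", geometry = geom, properties = pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Load and validate the three landscape layers
#'
#' Reads `buildings` (polygons), `roads` (lines with a `category`
#' property), and `vegetation` (polygons) from GeoJSON files, reprojects
#' lon/lat coordinates to the planar CRS, and repairs self-intersecting
#' rings (with a log message).
#'
#' @param paths Named list/vector with entries `buildings`, `roads`,
#'   `vegetation`.
#' @param proj An [lcc_projection()], or `NULL` if coordinates are already
#'   planar meters.
#' @return A list of class `landscape_layers` with elements `buildings`
#'   (list of polygons), `roads` (list of `list(coords, category)`), and
#'   `vegetation` (list of polygons).
#' @export
load_landscape_layers <- function(paths, proj = lcc_projection()) {
  reproject <- function(m) {
    if (is.null(proj)) return(m)
    lcc_project(m[, 1], m[, 2], proj)
  }
  grab <- function(key, want_type) {
    gj <- read_geojson(paths[[key]])
    if (!length(gj$geometries)) {
      warning(sprintf("layer '%s' is empty", key))
      return(gj)
    }
    if (!all(gj$types == want_type))
      stop(sprintf("layer '%s' mixes geometry types", key), call. = FALSE)
    gj
  }
  b <- grab("buildings", "polygon")
  n_rep <- 0L
  buildings <- lapply(b$geometries, function(p) {
    r <- repair_ring(p)
    if (r$repaired) n_rep <<- n_rep + 1L
    reproject(r$poly)
  })
  if (n_rep) message(sprintf("repaired %d invalid building ring(s)", n_rep))
  r <- grab("roads", "line")
  cats <- if (!is.null(r$properties$category)) as.character(r$properties$category)
          else rep(NA_character_, length(r$geometries))
  roads <- Map(function(g, cat) list(coords = reproject(g), category = cat),
               r$geometries, cats)
  v <- grab("vegetation", "polygon")
  vegetation <- lapply(v$geometries, function(p) reproject(repair_ring(p)$poly))
  structure(list(buildings = buildings, roads = roads, vegetation = vegetation),
            class = "landscape_layers")
}
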