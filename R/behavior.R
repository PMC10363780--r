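# Behavioural response models: how often a resting site is revisited
# (zero-truncated Poisson - a site exists in the data only because it was
# visited at least once), and whether/how far the animal relocates during
# an inactive phase (binomial + gamma-log mixed models with the 3-level
# hunting-season factor).

#' Assemble the seasonal revisitation dataset
#'
#' One row per resting site with at least one visit in the season:
#' visit count, covariates, and the log survey length of the owning animal
#' as a control for unequal monitoring duration.
#'
#' @param sites [summarise_sites()] output carrying `veg`, `d_village`,
#'   `d_road` covariate columns.
#' @param records [animal_records()] output (for survey lengths and study
#'   sites).
#' @param season `"NHS"` or `"HS"`.
#' @return Data frame with `n_visits`, `veg`, `d_village_s`, `d_road_s`,
#'   `log_survey`, `animal_id`, `study_site`; standardization attributes
#'   attached.
#' @export
build_revisit_dataset <- function(sites, records, season = c("NHS", "HS")) {
  season <- match.arg(season)
  cnt <- if (season == "NHS") sites$n_visits_NHS else sites$n_visits_HS
  d <- sites[cnt >= 1, , drop = FALSE]
  if (!nrow(d)) stop("no visited sites in season ", season)
  d$n_visits <- if (season == "NHS") d$n_visits_NHS else d$n_visits_HS
  m <- match(d$animal_id, records$animal_id)
  if (anyNA(m)) stop("sites reference animals missing from the survey records")
  d$log_survey <- log(records$survey_length_days[m])
  d$study_site <- as.character(records$study_site[m])
  d$d_village_s <- as.numeric(scale(d$d_village))
  d$d_road_s <- as.numeric(scale(d$d_road))
  attr(d, "season") <- season
  d
}

#' Fit the revisitation model
#'
#' Zero-truncated Poisson GLMM: visits ~ vegetation x distance-to-village
#' + vegetation x distance-to-road + log survey length, with
#' animal-within-study-site random intercepts.
#'
#' @param rows [build_revisit_dataset()] output.
#' @return A `glmm_fit`.
#' @export
fit_revisitation <- function(rows) {
  fit_glmm(n_visits ~ veg * d_village_s + veg * d_road_s + log_survey, rows,
           family = "zt_poisson", random = ~ study_site / animal_id)
}

#' Assemble the per-phase relocation dataset
#'
#' One row per inactive phase: whether at least one relocation event
#' occurred, covariates of the initial (pre-relocation) resting location,
#' the 3-level season factor, and the first event's distance (km) when
#' relocated.
#'
#' @param phases [extract_inactive_phases()] output.
#' @param events [detect_relocations()] output.
#' @param locations [daily_resting_locations()] output (pre-relocation
#'   means).
#' @param covariate_fun Function (`px`, `py`) -> data frame `veg`,
#'   `d_village`, `d_road`.
#' @param records [animal_records()] output.
#' @param calendar A [hunting_calendar()].
#' @return Data frame with `relocated`, `distance_km`, covariates (raw and
#'   standardized), `season3`, `animal_id`, `study_site`.
#' @export
build_relocation_dataset <- function(phases, events, locations, covariate_fun,
                                     records, calendar = hunting_calendar()) {
  key <- paste(phases$animal_id, phases$date)
  lk <- paste(locations$animal_id, locations$date)
  m <- match(key, lk)
  skipped <- sum(is.na(m))
  if (skipped) message(sprintf("%d phase(s) without a resting location skipped", skipped))
  ph <- phases[!is.na(m), , drop = FALSE]
  loc <- locations[m[!is.na(m)], , drop = FALSE]
  cv <- covariate_fun(loc$x, loc$y)
  ek <- paste(events$animal_id, events$date)
  first_dist <- vapply(paste(ph$animal_id, ph$date), function(k) {
    dd <- events$distance_m[ek == k]
    if (length(dd)) dd[1] / 1000 else NA_real_
  }, numeric(1))
  m2 <- match(ph$animal_id, records$animal_id)
  out <- data.frame(
    animal_id = ph$animal_id, date = ph$date,
    relocated = as.integer(!is.na(first_dist)),
    distance_km = first_dist,
    veg = cv$veg, d_village = cv$d_village, d_road = cv$d_road,
    season3 = season_label(ph$date, calendar),
    study_site = as.character(records$study_site[m2]))
  out$d_village_s <- as.numeric(scale(out$d_village))
  out$d_road_s <- as.numeric(scale(out$d_road))
  out
}

#' Fit the relocation-probability model
#'
#' Binomial GLMM: relocated ~ veg x d(road) + veg x d(village) + season
#' (3-level), animal-within-study-site random intercepts.
#'
#' @param rows [build_relocation_dataset()] output.
#' @return A `glmm_fit`.
#' @export
fit_relocation <- function(rows) {
  fit_glmm(relocated ~ veg * d_road_s + veg * d_village_s + season3, rows,
           family = "binomial", random = ~ study_site / animal_id)
}

#' Fit the relocation-distance model
#'
#' Gamma (log link) GLMM on the distances (km) of phases with a
#' relocation, same predictors as the probability model.
#'
#' @param rows [build_relocation_dataset()] output.
#' @return A `glmm_fit`.
#' @export
fit_relocation_distance <- function(rows) {
  d <- rows[rows$relocated == 1L, , drop = FALSE]
  if (nrow(d) < 10) warning("very few relocation events; distance model unstable")
  fit_glmm(distance_km ~ veg * d_road_s + veg * d_village_s + season3, d,
           family = "gamma_log", random = ~ study_site / animal_id)
}

#' Per-season predicted relocation probabilities
#'
#' Response-scale predictions of the relocation-probability model at a
#' reference covariate profile (vegetated site, distances at their data
#' means, i.e. standardized 0), one per season level.
#'
#' @param fit [fit_relocation()] output.
#' @param veg Reference vegetation class (default 1).
#' @return Data frame `season3`, `fit`, `lwr`, `upr`.
#' @export
relocation_probability_by_season <- function(fit, veg = 1) {
  nd <- data.frame(veg = veg, d_road_s = 0, d_village_s = 0,
                   season3 = factor(c("NHS", "HS_nonhunting", "HS_hunting_day"),
                                    levels = c("NHS", "HS_nonhunting",
                                               "HS_hunting_day")))
  cbind(season3 = nd$season3, predict(fit, nd, type = "response"))
}
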