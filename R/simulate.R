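# Synthetic landscape and collar-data generator. Emulates the statistical
# structure the analysis assumes - a village/road/vegetation mosaic, a
# nocturnal activity rhythm with one consolidated diurnal rest phase,
# site-faithful resting with distance-to-village-dependent revisitation,
# and rare within-rest relocations that are more frequent on hunting days -
# while recording the ground truth of every stage (phase bounds, bouts,
# site identities, relocation events, selection coefficients).

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline was built for:
#' 5-min ACT epochs with rest at a mean of 15 collar units and activity at
#' 120; an inactive phase covering 58.5% of the day anchored on sunset
#' (sd 45 min) and loosely on sunrise (sd 90 min, mean in the last hours
#' of the night); 30-min GPS with 15 m rest noise; per-season relocation
#' probabilities 0.08 (non-hunting season), 0.12 (open season, non-hunting
#' day) and 0.17 (hunting day); lognormal relocation distances with a
#' 237 m median, heavier-tailed on hunting days, truncated below at 150 m.
#'
#' @param n_animals Number of animals (default 5).
#' @param survey_days Mean days per animal (default 120); per-animal
#'   durations are drawn with sd `survey_days_sd` (default 30, floor 45)
#'   to mirror unequal collar deployments.
#' @param start_dates Optional `Date` vector (recycled) of survey starts;
#'   by default staggered through 2020 so both seasons are covered.
#' @param ... Overrides for any default component (see the returned list).
#' @return Nested list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 5, survey_days = 120, start_dates = NULL, ...) {
  cfg <- list(
    n_animals = n_animals, survey_days = survey_days,
    survey_days_sd = 30, start_dates = start_dates,
    proj = lcc_projection(),
    landscape = list(extent = 8000, n_villages = 3, buildings_per_village = 35,
                     building_size = c(12, 22), cluster_radius = 110,
                     n_roads = 3, veg_fraction = 0.40,
                     veg_patch_size = c(400, 1200), village_res = 2),
    activity = list(act_rest_mean = 15, act_rest_sd = 10,
                    act_active_mean = 125, act_active_sd = 38,
                    inactive_fraction = 0.585, start_sd_min = 90,
                    end_sd_min = 45, bouts_per_phase = 2,
                    bout_len_min = c(5, 15), event_margin_min = 120),
    gps = list(rest_noise_sd = 15, night_rho = 0.7, night_sd = 800,
               fix_minutes = 30, epoch_minutes = 5),
    sites = list(pool_size = 60, pool_radius = 1500, min_separation = 120,
                 p_new = 0.37, revisit_pref_exp = 0.5,
                 revisit_dist_coef = 0.5, explore_veg_coef = 1.3),
    relocation = list(p_reloc = c(NHS = 0.08, HS_nonhunting = 0.12,
                                  HS_hunting_day = 0.17),
                      dist_median_m = 237,
                      dist_sdlog = c(NHS = 0.6, HS_nonhunting = 0.8,
                                     HS_hunting_day = 1.0),
                      min_dist_m = 150, max_dist_m = 6000,
                      bout_len_min = c(15, 25)),
    calendar = hunting_calendar())
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  stopifnot(cfg$landscape$veg_fraction <= 0.9,
            all(cfg$relocation$p_reloc >= 0 & cfg$relocation$p_reloc <= 1),
            cfg$activity$act_rest_mean >= 0, cfg$activity$act_rest_mean <= 255)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a landscape mosaic
#'
#' Villages are clusters of rectangular buildings (dense enough that the
#' 50 m closing merges each cluster into one >1.5 ha polygon), roads are
#' jittered polylines crossing the extent (main categories plus a
#' residential road and a track, which the road filter must drop), and
#' dense vegetation is a set of rectangular patches grown until the target
#' cover fraction is reached.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_landscape` with `buildings`, `roads`,
#'   `vegetation` (the [load_landscape_layers()] structure), `extent` and
#'   `veg_fraction_realized`.
#' @export
sim_landscape <- function(config = sim_config()) {
  lc <- config$landscape
  ext <- lc$extent
  margin <- 900
  centers <- matrix(NA_real_, 0, 2)
  while (nrow(centers) < lc$n_villages) {
    p <- stats::runif(2, margin, ext - margin)
    if (!nrow(centers) || min(sqrt((centers[, 1] - p[1])^2 +
                                   (centers[, 2] - p[2])^2)) > 2000)
      centers <- rbind(centers, p)
  }
  buildings <- list()
  for (v in seq_len(lc$n_villages)) {
    for (b in seq_len(lc$buildings_per_village)) {
      ang <- stats::runif(1, 0, pi)
      r <- lc$cluster_radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      buildings[[length(buildings) + 1L]] <- rect_poly(
        centers[v, 1] + r * cos(th), centers[v, 2] + r * sin(th),
        stats::runif(1, lc$building_size[1], lc$building_size[2]),
        stats::runif(1, lc$building_size[1], lc$building_size[2]), ang)
    }
  }
  mk_road <- function(category) {
    th <- stats::runif(1, 0, pi)
    p0 <- c(stats::runif(1, 0.2, 0.8) * ext, stats::runif(1, 0.2, 0.8) * ext)
    tt <- seq(-ext, ext, by = 400)
    wob <- cumsum(stats::rnorm(length(tt), 0, 60))
    pts <- cbind(p0[1] + tt * cos(th) - wob * sin(th),
                 p0[2] + tt * sin(th) + wob * cos(th))
    keep <- pts[, 1] > -200 & pts[, 1] < ext + 200 &
      pts[, 2] > -200 & pts[, 2] < ext + 200
    list(coords = pts[keep, , drop = FALSE], category = category)
  }
  main_cats <- sample(c("primary", "secondary", "tertiary"), lc$n_roads,
                      replace = TRUE)
  roads <- c(lapply(main_cats, mk_road), list(mk_road("residential"), mk_road("track")))
  vegetation <- list(); grid <- 50
  gx <- seq(grid / 2, ext, by = grid)
  cov_grid <- matrix(FALSE, length(gx), length(gx))
  frac <- 0
  while (frac < lc$veg_fraction && length(vegetation) < 400) {
    w <- stats::runif(1, lc$veg_patch_size[1], lc$veg_patch_size[2])
    h <- stats::runif(1, lc$veg_patch_size[1], lc$veg_patch_size[2])
    p <- rect_poly(stats::runif(1, 0, ext), stats::runif(1, 0, ext), w, h,
                   stats::runif(1, 0, pi))
    vegetation[[length(vegetation) + 1L]] <- p
    ix <- which(gx >= min(p[, 1]) & gx <= max(p[, 1]))
    iy <- which(gx >= min(p[, 2]) & gx <= max(p[, 2]))
    if (length(ix) && length(iy)) {
      pts_x <- rep(gx[ix], times = length(iy)); pts_y <- rep(gx[iy], each = length(ix))
      cov_grid[ix, iy] <- cov_grid[ix, iy] |
        matrix(point_in_polygon(pts_x, pts_y, p), length(ix), length(iy))
    }
    frac <- mean(cov_grid)
  }
  structure(list(buildings = buildings, roads = roads, vegetation = vegetation,
                 extent = ext, veg_fraction_realized = frac),
            class = c("sim_landscape", "landscape_layers"))
}

.truncated_lognorm <- function(n, median_m, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, log(median_m), sdlog)
    out <- c(out, d[d > lower & d < upper])
  }
  out[seq_len(n)]
}

#' Simulate one animal's collar data with ground truth
#'
#' Daily schedule: the inactive phase ends at `sunset + N(0, 45 min)` and
#' starts at `end - 0.585 * 24 h + N(0, 90 min)` (so its expected length
#' matches the configured inactive fraction and its start falls in the
#' last hours of the night). Each dawn the animal either explores a new
#' site from its pool (probability `p_new`, vegetation-weighted) or
#' revisits a known one (weights proportional to past visits times
#' `exp(-coef * d_village / 1000)`). Rest-phase GPS jitters around the
#' site; nights are a correlated walk around the home-range centre. With
#' the seasonal probability the animal relocates once, mid-phase, by a
#' truncated-lognormal displacement announced by a 15-25 min activity
#' bout; short no-displacement bouts are sprinkled through every phase.
#' Bouts and relocations are placed at least `event_margin_min` from the
#' phase bounds so the true bounds stay well defined.
#'
#' @param config A [sim_config()].
#' @param landscape A [sim_landscape()].
#' @param villages [derive_villages()] of the landscape's buildings.
#' @param animal_id,study_site Identifiers.
#' @param start_date First survey day.
#' @return List with `act`, `gps` (io-format data frames), and `truth`
#'   (`days`: per-day phase bounds, site id/position, relocation;
#'   `bouts`: all no-displacement bouts; `pool`: the site pool with
#'   covariates).
#' @export
sim_animal <- function(config, landscape, villages, animal_id = "a1",
                       study_site = "site1", start_date = as.Date("2020-03-01")) {
  ac <- config$activity; gp <- config$gps; st <- config$sites
  rl <- config$relocation; ext <- landscape$extent
  roads_f <- suppressMessages(filter_roads(landscape$roads))
  center <- stats::runif(2, st$pool_radius + 300, ext - st$pool_radius - 300)
  pool <- matrix(NA_real_, 0, 2)
  while (nrow(pool) < st$pool_size) {
    th <- stats::runif(1, 0, 2 * pi); r <- st$pool_radius * sqrt(stats::runif(1))
    p <- center + r * c(cos(th), sin(th))
    if (!nrow(pool) || min(sqrt((pool[, 1] - p[1])^2 + (pool[, 2] - p[2])^2)) >
        st$min_separation)
      pool <- rbind(pool, p)
  }
  pool_cov <- landscape_covariates(pool[, 1], pool[, 2], villages, roads_f,
                                   landscape$vegetation)
  w_explore <- exp(st$explore_veg_coef * pool_cov$veg)
  ll <- lcc_unproject(center[1], center[2], config$proj)
  days <- seq(start_date, by = "day", length.out = config$survey_days)
  sun <- sun_times(ll[1, "lat"], ll[1, "lon"], days)
  s3 <- season_label(days, config$calendar)
  visits <- integer(st$pool_size)
  margin <- ac$event_margin_min * 60
  day_rows <- vector("list", config$survey_days)
  bout_rows <- list()
  for (d in seq_along(days)) {
    end_t <- as.numeric(sun$sunset[d]) + stats::rnorm(1, 0, ac$end_sd_min * 60)
    start_t <- end_t - ac$inactive_fraction * 86400 +
      stats::rnorm(1, 0, ac$start_sd_min * 60)
    # choose the day's site
    unvisited <- which(visits == 0L)
    if (length(unvisited) == st$pool_size ||
        (length(unvisited) && stats::runif(1) < st$p_new)) {
      site <- unvisited[sample.int(length(unvisited), 1,
                                   prob = w_explore[unvisited])]
    } else {
      w <- (visits^st$revisit_pref_exp) * (visits > 0) *
        exp(-st$revisit_dist_coef * pool_cov$d_village / 1000)
      site <- sample.int(st$pool_size, 1, prob = w)
    }
    visits[site] <- visits[site] + 1L
    # relocation?
    p <- rl$p_reloc[[as.character(s3[d])]]
    reloc <- stats::runif(1) < p
    reloc_time <- reloc_len <- reloc_dist <- NA_real_
    post <- c(NA_real_, NA_real_)
    if (reloc && (end_t - start_t) > 2 * margin + 3600) {
      reloc_time <- stats::runif(1, start_t + margin, end_t - margin - 1800)
      reloc_len <- 60 * sample(seq(rl$bout_len_min[1], rl$bout_len_min[2], by = 5), 1)
      reloc_dist <- .truncated_lognorm(1, rl$dist_median_m,
                                       rl$dist_sdlog[[as.character(s3[d])]],
                                       rl$min_dist_m, rl$max_dist_m)
      th <- stats::runif(1, 0, 2 * pi)
      post <- pool[site, ] + reloc_dist * c(cos(th), sin(th))
    } else reloc <- FALSE
    # short no-displacement bouts in the phase interior
    nb <- stats::rpois(1, ac$bouts_per_phase)
    if (nb > 0 && (end_t - start_t) > 2 * margin + 3600) {
      # events spaced >= 45 min apart: overlapping/abutting bouts would
      # make the true event structure itself ambiguous
      taken <- if (reloc) cbind(reloc_time, reloc_time + reloc_len) else
        matrix(numeric(0), 0, 2)
      bt <- numeric(0); bl <- numeric(0)
      for (k in seq_len(nb)) {
        for (try in 1:20) {
          cand_t <- stats::runif(1, start_t + margin, end_t - margin - 900)
          cand_l <- 60 * sample(seq(ac$bout_len_min[1], ac$bout_len_min[2],
                                    by = 5), 1)
          clear <- !nrow(taken) ||
            all(cand_t > taken[, 2] + 2700 | cand_t + cand_l < taken[, 1] - 2700)
          if (clear) {
            taken <- rbind(taken, c(cand_t, cand_t + cand_l))
            bt <- c(bt, cand_t); bl <- c(bl, cand_l)
            break
          }
        }
      }
      if (length(bt))
        bout_rows[[length(bout_rows) + 1L]] <- data.frame(
          animal_id = animal_id, date = days[d], bout_start = bt, bout_len = bl)
    }
    day_rows[[d]] <- data.frame(
      animal_id = animal_id, date = days[d], season3 = s3[d],
      phase_start = start_t, phase_end = end_t, site_id = site,
      site_x = pool[site, 1], site_y = pool[site, 2],
      relocated = reloc, reloc_time = reloc_time, reloc_len = reloc_len,
      reloc_dist = reloc_dist, post_x = post[1], post_y = post[2])
  }
  truth_days <- do.call(rbind, day_rows)
  truth_bouts <- if (length(bout_rows)) do.call(rbind, bout_rows) else
    data.frame(animal_id = character(), date = as.Date(character()),
               bout_start = numeric(), bout_len = numeric())
  # ---- emit ACT -------------------------------------------------------------
  t0 <- as.numeric(as.POSIXct(days[1], tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(days[config$survey_days], tz = "UTC")) + 86400
  ep <- gp$epoch_minutes * 60
  tt <- seq(t0, t1 - ep, by = ep)
  in_phase <- rep(FALSE, length(tt))
  for (d in seq_len(nrow(truth_days))) {
    in_phase <- in_phase | (tt >= truth_days$phase_start[d] &
                              tt < truth_days$phase_end[d])
  }
  in_bout <- rep(FALSE, length(tt))
  for (b in seq_len(nrow(truth_bouts))) {
    in_bout <- in_bout | (tt >= truth_bouts$bout_start[b] &
                            tt < truth_bouts$bout_start[b] + truth_bouts$bout_len[b])
  }
  rel <- truth_days[truth_days$relocated, , drop = FALSE]
  for (d in seq_len(nrow(rel))) {
    in_bout <- in_bout | (tt >= rel$reloc_time[d] &
                            tt < rel$reloc_time[d] + rel$reloc_len[d])
  }
  resting <- in_phase & !in_bout
  act_v <- ifelse(resting,
                  stats::rnorm(length(tt), ac$act_rest_mean, ac$act_rest_sd),
                  stats::rnorm(length(tt), ac$act_active_mean, ac$act_active_sd))
  act_v <- as.integer(pmin(255, pmax(0, round(act_v))))
  act <- data.frame(animal_id = animal_id,
                    timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                    act = act_v)
  # ---- emit GPS -------------------------------------------------------------
  fs <- gp$fix_minutes * 60
  ft <- seq(t0, t1 - fs, by = fs)
  fx <- numeric(length(ft)); fy <- numeric(length(ft))
  cur <- center
  # phase membership by interval (phases may start before midnight)
  day_idx <- findInterval(ft, truth_days$phase_start)
  for (i in seq_along(ft)) {
    d <- day_idx[i]
    td <- truth_days[d, ]
    phase_here <- d >= 1 && ft[i] >= td$phase_start && ft[i] < td$phase_end
    if (phase_here) {
      at_post <- td$relocated && ft[i] >= td$reloc_time + td$reloc_len
      base <- if (at_post) c(td$post_x, td$post_y) else c(td$site_x, td$site_y)
      pos <- base + stats::rnorm(2, 0, gp$rest_noise_sd)
      cur <- base
    } else {
      cur <- center + gp$night_rho * (cur - center) +
        stats::rnorm(2, 0, gp$night_sd * sqrt(1 - gp$night_rho^2))
      pos <- cur
    }
    fx[i] <- pos[1]; fy[i] <- pos[2]
  }
  gps <- data.frame(animal_id = animal_id,
                    timestamp = as.POSIXct(ft, origin = "1970-01-01", tz = "UTC"),
                    x = fx, y = fy)
  truth_days$phase_start <- as.POSIXct(truth_days$phase_start,
                                       origin = "1970-01-01", tz = "UTC")
  truth_days$phase_end <- as.POSIXct(truth_days$phase_end,
                                     origin = "1970-01-01", tz = "UTC")
  truth_days$reloc_time <- as.POSIXct(truth_days$reloc_time,
                                      origin = "1970-01-01", tz = "UTC")
  list(act = act, gps = gps,
       truth = list(days = truth_days, bouts = truth_bouts,
                    pool = cbind(as.data.frame(pool), pool_cov,
                                 site_id = seq_len(st$pool_size)),
                    center = center, study_site = study_site))
}

#' Simulate a full multi-animal study
#'
#' Landscape, derived villages, per-animal collar series and ground truth,
#' plus io-style survey records. All randomness comes from R's RNG: set a
#' seed first for reproducibility.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `config`, `landscape`, `villages`,
#'   `act`, `gps` (all animals stacked), `records`, `truth` (per-animal
#'   list).
#' @export
sim_study <- function(config = sim_config()) {
  landscape <- sim_landscape(config)
  villages <- derive_villages(landscape$buildings,
                              res = config$landscape$village_res)
  starts <- if (is.null(config$start_dates))
    as.Date("2020-01-01") + sort(sample(0:330, config$n_animals, replace = TRUE))
  else rep_len(as.Date(config$start_dates), config$n_animals)
  ids <- sprintf("a%02d", seq_len(config$n_animals))
  ss <- rep_len(c("siteA", "siteB"), config$n_animals)
  # unequal monitoring durations, as in real deployments
  days_i <- pmax(45, round(stats::rnorm(config$n_animals, config$survey_days,
                                        config$survey_days_sd)))
  sims <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    cfg_i <- config; cfg_i$survey_days <- days_i[i]
    sims[[i]] <- sim_animal(cfg_i, landscape, villages, ids[i], ss[i], starts[i])
  }
  act <- do.call(rbind, lapply(sims, `[[`, "act"))
  gps <- do.call(rbind, lapply(sims, `[[`, "gps"))
  records <- data.frame(
    animal_id = ids, study_site = ss, sex = "M",
    capture_time = as.POSIXct(starts, tz = "UTC") - 3 * 86400,
    survey_start = as.POSIXct(starts, tz = "UTC"),
    survey_end = as.POSIXct(starts + days_i, tz = "UTC"),
    survey_length_days = days_i)
  truth <- stats::setNames(lapply(sims, `[[`, "truth"), ids)
  structure(list(config = config, landscape = landscape, villages = villages,
                 act = act, gps = gps, records = records, truth = truth),
            class = "sim_study")
}

#' Simulate a used/available dataset with known selection coefficients
#'
#' Direct resource-selection simulation for parameter-recovery checks:
#' availability covariates are drawn from simple distributions, used
#' points are sampled from a large candidate pool with weights
#' `exp(X beta)` (the exponential RSF form), so a binomial used/available
#' model must recover `beta`'s slopes.
#'
#' @param beta Named coefficients on the standardized scale; any of
#'   `veg`, `d_road_s`, `d_village_s`, `veg:d_road_s`, `veg:d_village_s`.
#' @param n_used Used points. @param n_avail Availability points.
#' @param n_animals Animals to spread rows over (random intercepts sd
#'   `animal_sd`). @param animal_sd Between-animal sd on the log weight.
#' @param veg_prob Bernoulli probability of the vegetation class.
#' @return Data frame shaped like [build_rsf_dataset()] output.
#' @export
sim_rsf_dataset <- function(beta = c(veg = 1.0, d_road_s = 0.5, d_village_s = -0.3,
                                     `veg:d_road_s` = 0, `veg:d_village_s` = 0),
                            n_used = 200, n_avail = 20000, n_animals = 5,
                            animal_sd = 0, veg_prob = 0.45) {
  draw_cov <- function(n) {
    data.frame(veg = stats::rbinom(n, 1, veg_prob),
               d_road_s = stats::rnorm(n), d_village_s = stats::rnorm(n))
  }
  eta_of <- function(d, b_animal = 0) {
    full <- c(veg = 0, d_road_s = 0, d_village_s = 0,
              `veg:d_road_s` = 0, `veg:d_village_s` = 0)
    full[names(beta)] <- beta
    full["veg"] * d$veg + full["d_road_s"] * d$d_road_s +
      full["d_village_s"] * d$d_village_s +
      full["veg:d_road_s"] * d$veg * d$d_road_s +
      full["veg:d_village_s"] * d$veg * d$d_village_s + b_animal
  }
  animals <- sprintf("a%02d", seq_len(n_animals))
  b_animal <- stats::rnorm(n_animals, 0, animal_sd)
  rows <- list()
  for (i in seq_len(n_animals)) {
    # the animal intercept of a use-availability model is the per-animal
    # used:available ratio, so heterogeneity enters through the used counts
    nu <- max(2L, stats::rpois(1, n_used / n_animals * exp(b_animal[i])))
    na <- round(n_avail / n_animals)
    # a large candidate pool keeps the weighted draw close to the true
    # tilted distribution (a small pool adds variance the model cannot see)
    cand <- draw_cov(max(100 * nu, 5000))
    w <- exp(eta_of(cand))
    used <- cand[sample(nrow(cand), nu, replace = TRUE, prob = w), , drop = FALSE]
    avail <- draw_cov(na)
    rows[[i]] <- rbind(
      data.frame(used = 1L, used, animal_id = animals[i]),
      data.frame(used = 0L, avail, animal_id = animals[i]))
  }
  out <- do.call(rbind, rows)
  out$study_site <- rep_len(c("siteA", "siteB"),
                            n_animals)[match(out$animal_id, animals)]
  out
}
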