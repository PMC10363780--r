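.mk_sites <- function(n = 40, seed = 81) {
  set.seed(seed)
  data.frame(site = paste0("a1:", seq_len(n)),
             animal_id = rep(c("a1", "a2"), length.out = n),
             x = runif(n, 0, 1000), y = runif(n, 0, 1000),
             n_visits_NHS = rpois(n, 1.2), n_visits_HS = rpois(n, 0.8),
             veg = rbinom(n, 1, 0.5), d_village = runif(n, -50, 3000),
             d_road = runif(n, 0, 1500))
}

.mk_records <- function() data.frame(
  animal_id = c("a1", "a2"), study_site = c("S1", "S2"),
  survey_length_days = c(100, 160))

test_that("revisitation rows are zero-truncated with survey-length control", {
  sites <- .mk_sites()
  sites$n_visits <- sites$n_visits_NHS + sites$n_visits_HS
  rec <- .mk_records()
  rows <- build_revisit_dataset(sites, rec, "NHS")
  expect_true(all(rows$n_visits >= 1))
  expect_equal(nrow(rows), sum(sites$n_visits_NHS >= 1))
  expect_equal(unique(rows$log_survey[rows$animal_id == "a2"]), log(160))
  # a site visited in both seasons appears in both seasonal tables
  both <- sites$site[sites$n_visits_NHS >= 1 & sites$n_visits_HS >= 1][1]
  rows_hs <- build_revisit_dataset(sites, rec, "HS")
  expect_true(both %in% rows$site && both %in% rows_hs$site)
  expect_error(build_revisit_dataset(sites, rec[1, ], "NHS"), "missing")
})

test_that("revisitation model recovers a village-distance effect", {
  set.seed(82)
  n <- 400
  d <- data.frame(animal_id = sample(sprintf("a%d", 1:8), n, TRUE),
                  veg = rbinom(n, 1, 0.5), d_village_s = rnorm(n),
                  d_road_s = rnorm(n))
  d$study_site <- ifelse(d$animal_id %in% sprintf("a%d", 1:4), "S1", "S2")
  d$log_survey <- log(sample(c(90, 120, 180), n, TRUE))
  lam <- exp(-1.2 - 0.5 * d$d_village_s + 0.6 * d$log_survey / 2)
  d$n_visits <- qpois(runif(n, dpois(0, lam), 1), lam)
  f <- suppressWarnings(fit_revisitation(d))
  co <- f$coefficients
  expect_lt(co["d_village_s", "estimate"], 0)
  expect_lt(abs(co["d_village_s", "estimate"] + 0.5), 2 * co["d_village_s", "se"])
  r2 <- marginal_r2(f)
  expect_true(r2 > 0 && r2 <= 1)
  # constant-intensity data: slopes within 2 SE of zero
  d0 <- d
  lam0 <- exp(0.3)
  d0$n_visits <- qpois(runif(n, dpois(0, lam0), 1), lam0)
  f0 <- suppressWarnings(fit_revisitation(d0))
  sl <- f0$coefficients[c("veg", "d_village_s", "d_road_s"), ]
  expect_true(all(abs(sl[, "estimate"]) <= 2.5 * sl[, "se"]))
})

test_that("relocation rows carry pre-event covariates, season and distance", {
  cal <- hunting_calendar()
  dates <- as.Date("2020-08-13") + 0:2  # Thu NHS, Fri NHS, Sat 15 Aug = HS hunting
  phases <- data.frame(animal_id = "a1", date = dates,
                       start = as.POSIXct(dates, tz = "UTC") + 4 * 3600,
                       end = as.POSIXct(dates, tz = "UTC") + 18 * 3600,
                       epoch_count = 168L, low_confidence = FALSE)
  locations <- data.frame(animal_id = "a1", date = dates,
                          x = c(0, 100, 200), y = 0, n_fixes = 20L)
  events <- data.frame(animal_id = "a1", date = dates[3],
                       event_time = phases$start[3] + 5 * 3600,
                       distance_m = 250)
  cov_fun <- function(px, py) data.frame(veg = as.integer(px < 150),
                                         d_village = px + 10, d_road = 500 - px)
  rec <- data.frame(animal_id = "a1", study_site = "S1",
                    survey_length_days = 120)
  rows <- build_relocation_dataset(phases, events, locations, cov_fun, rec, cal)
  expect_equal(rows$relocated, c(0L, 0L, 1L))
  expect_equal(rows$distance_km, c(NA, NA, 0.25))
  expect_equal(as.character(rows$season3),
               c("NHS", "NHS", "HS_hunting_day"))
  expect_equal(rows$veg, c(1L, 1L, 0L))
  # a phase without a resting location is skipped with a message
  expect_message(
    rows2 <- build_relocation_dataset(phases, events, locations[-2, ],
                                      cov_fun, rec, cal),
    "skipped")
  expect_equal(nrow(rows2), 2)
})

test_that("relocation probability model recovers per-season rates", {
  set.seed(83)
  n_per <- 700
  p <- c(NHS = 0.08, HS_nonhunting = 0.12, HS_hunting_day = 0.17)
  d <- data.frame(
    season3 = factor(rep(names(p), each = n_per), levels = names(p)),
    veg = rbinom(3 * n_per, 1, 0.6), d_village_s = rnorm(3 * n_per),
    d_road_s = rnorm(3 * n_per),
    animal_id = sample(sprintf("a%d", 1:8), 3 * n_per, TRUE))
  d$study_site <- ifelse(d$animal_id %in% sprintf("a%d", 1:4), "S1", "S2")
  d$relocated <- rbinom(3 * n_per, 1, p[as.character(d$season3)])
  f <- suppressWarnings(fit_relocation(d))
  pr <- relocation_probability_by_season(f)
  for (s in names(p))
    expect_lt(abs(pr$fit[pr$season3 == s] - p[[s]]), 0.03)
  # reference-level invariance: relevelling does not change predictions
  d2 <- d; d2$season3 <- relevel(d2$season3, "HS_hunting_day")
  f2 <- suppressWarnings(fit_relocation(d2))
  pr2 <- relocation_probability_by_season(f2)
  m <- match(pr$season3, pr2$season3)
  expect_equal(pr$fit, pr2$fit[m], tolerance = 1e-4)
})

test_that("relocation distance model recovers the lognormal-scale intercept", {
  set.seed(84)
  n <- 400
  d <- data.frame(season3 = factor(sample(c("NHS", "HS_hunting_day"), n, TRUE),
                                   levels = c("NHS", "HS_nonhunting",
                                              "HS_hunting_day")),
                  veg = rbinom(n, 1, 0.5), d_village_s = rnorm(n),
                  d_road_s = rnorm(n),
                  animal_id = sample(sprintf("a%d", 1:6), n, TRUE),
                  relocated = 1L)
  d$study_site <- ifelse(d$animal_id %in% sprintf("a%d", 1:3), "S1", "S2")
  # median 237 m = 0.237 km on the log scale
  d$distance_km <- exp(rnorm(n, log(0.237), 0.5))
  f <- suppressWarnings(fit_relocation_distance(d))
  co <- f$coefficients
  # gamma-log intercept estimates the log MEAN: log(median) + sdlog^2/2
  target <- log(0.237) + 0.5^2 / 2
  expect_lt(abs(co["(Intercept)", "estimate"] - target),
            2 * co["(Intercept)", "se"] + 0.05)
  # degenerate: no relocations at all -> penalized flagged binomial fit
  d0 <- d; d0$relocated <- 0L
  f0 <- fit_relocation(d0)
  expect_true(f0$penalized)
  expect_false(f0$converged)
})
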