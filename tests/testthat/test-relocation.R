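# constructed phase: rest 04:00-18:00 with an activity bout, GPS every 30 min
.mk_phase_day <- function(bout_hm = c("10:00", "10:15"), pre_xy = c(0, 0),
                          post_xy = c(0, 0), bout_act = 180L) {
  tt <- epoch_times("2020-03-20 00:00", 288)
  hm <- format(tt, "%H:%M")
  act <- ifelse(hm >= "04:00" & hm < "18:00", 10L, 120L)
  act[hm >= bout_hm[1] & hm < bout_hm[2]] <- bout_act
  ft <- as.POSIXct("2020-03-20 00:00", tz = "UTC") + seq(0, 86400 - 1800, 1800)
  fhm <- format(ft, "%H:%M")
  x <- ifelse(fhm < bout_hm[1], pre_xy[1], post_xy[1])
  y <- ifelse(fhm < bout_hm[1], pre_xy[2], post_xy[2])
  list(act = data.frame(animal_id = "b1", timestamp = tt, act = act),
       gps = data.frame(animal_id = "b1", timestamp = ft, x = x, y = y),
       phases = data.frame(animal_id = "b1", date = as.Date("2020-03-20"),
                           start = tt[hm == "04:00"],
                           end = tt[hm == "18:00"][1],
                           epoch_count = 168L, low_confidence = FALSE))
}

test_that("displacement must strictly exceed 100 m", {
  d100 <- .mk_phase_day(post_xy = c(100, 0))
  expect_equal(nrow(detect_relocations(d100$phases, d100$act, d100$gps)), 0)
  d101 <- .mk_phase_day(post_xy = c(101, 0))
  ev <- detect_relocations(d101$phases, d101$act, d101$gps)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance_m, 101)
  # event distance is exactly the Euclidean norm between reported centroids
  expect_equal(ev$distance_m,
               sqrt((ev$post_x - ev$pre_x)^2 + (ev$post_y - ev$pre_y)^2))
  expect_equal(ev$event_time, d101$phases$start + 6 * 3600)
})

test_that("an activity bout with no displacement is not a relocation", {
  d0 <- .mk_phase_day(post_xy = c(0, 0))
  expect_equal(nrow(detect_relocations(d0$phases, d0$act, d0$gps)), 0)
  # single-epoch supra-threshold noise is not a candidate bout
  d1 <- .mk_phase_day(bout_hm = c("10:00", "10:05"), post_xy = c(500, 0))
  expect_equal(nrow(detect_relocations(d1$phases, d1$act, d1$gps)), 0)
})

test_that("chained events recompute centroids between candidates", {
  day <- .mk_phase_day(bout_hm = c("09:00", "09:15"))
  hm <- format(day$act$timestamp, "%H:%M")
  day$act$act[hm >= "13:00" & hm < "13:15"] <- 180L
  fhm <- format(day$gps$timestamp, "%H:%M")
  day$gps$x <- ifelse(fhm < "09:00", 0, ifelse(fhm < "13:00", 200, 650))
  day$gps$y <- 0
  ev <- detect_relocations(day$phases, day$act, day$gps)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$distance_m, c(200, 450))
})

test_that("too few fixes on either side skips the candidate", {
  day <- .mk_phase_day(bout_hm = c("04:30", "04:45"), post_xy = c(500, 0))
  # only one fix (04:00) before the bout, after the 5-min edge guard
  expect_equal(nrow(detect_relocations(day$phases, day$act, day$gps)), 0)
})

test_that("relocation summary counts phases and splits distances at 500 m", {
  cal <- hunting_calendar()
  phases <- data.frame(animal_id = "b1",
                       date = as.Date("2020-06-01") + 0:9,
                       start = as.POSIXct("2020-06-01 04:00", tz = "UTC") + (0:9) * 86400,
                       end = as.POSIXct("2020-06-01 18:00", tz = "UTC") + (0:9) * 86400)
  events <- data.frame(animal_id = "b1", date = as.Date(c("2020-06-02", "2020-06-05")),
                       event_time = phases$start[c(2, 5)] + 3600,
                       pre_x = 0, pre_y = 0, post_x = c(200, 800), post_y = 0,
                       distance_m = c(200, 800))
  sm <- relocation_summary(events, phases, cal)
  nhs <- sm[sm$season == "NHS", ]
  expect_equal(nhs$p_relocation, 0.2)
  expect_equal(nhs$n_short, 1)
  expect_equal(nhs$n_long, 1)
  # no events at all: probability zero in covered seasons
  sm0 <- relocation_summary(events[0, ], phases, cal)
  expect_equal(sm0$p_relocation[sm0$season == "NHS"], 0)
})

test_that("detected per-season relocation share matches binomial expectation", {
  ss <- small_study()
  ll <- study_latlon(ss)
  ph <- extract_inactive_phases(ss$act, ll$lat, ll$lon)
  ev <- detect_relocations(ph, ss$act, ss$gps, calendar = ss$config$calendar)
  td <- study_truth_days(ss)
  # every detected event day is a true relocation day and vice versa
  evk <- unique(paste(ev$animal_id, ev$date))
  truek <- paste(td$animal_id, td$date)[td$relocated]
  expect_setequal(evk, truek)
  sm <- relocation_summary(ev, ph, ss$config$calendar)
  p_cfg <- ss$config$relocation$p_reloc
  for (s in sm$season[sm$n_phases > 30]) {
    ci <- stats::binom.test(sm$n_relocated[sm$season == s],
                            sm$n_phases[sm$season == s])$conf.int
    expect_true(p_cfg[[s]] >= ci[1] && p_cfg[[s]] <= ci[2])
  }
})
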