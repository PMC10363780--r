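# Shared fixtures, built in code. The medium simulated study is expensive
# enough to build once and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

# full-scale study at default noise (5 animals x 120 days), segmented and
# with relocations detected: built once, reused by the acceptance checks
full_study_run <- function() {
  if (is.null(.fixture_env$full)) {
    set.seed(20240815)
    study <- sim_study(sim_config(n_animals = 5, survey_days = 120,
                                  survey_days_sd = 0))
    ll <- study_latlon(study)
    phases <- extract_inactive_phases(study$act, ll$lat, ll$lon)
    events <- detect_relocations(phases, study$act, study$gps,
                                 calendar = study$config$calendar)
    .fixture_env$full <- list(study = study, phases = phases, events = events,
                              latlon = ll)
  }
  .fixture_env$full
}

# a small two-animal study (noisy defaults) used by several files
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    set.seed(4021)
    .fixture_env$small <- sim_study(sim_config(n_animals = 2, survey_days = 60))
  }
  .fixture_env$small
}

study_latlon <- function(study) {
  ctr <- colMeans(study$gps[, c("x", "y")])
  ll <- lcc_unproject(ctr[1], ctr[2], study$config$proj)
  list(lat = ll[1, "lat"], lon = ll[1, "lon"])
}

study_truth_days <- function(study) {
  do.call(rbind, lapply(study$truth, function(t) t$days))
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  A <- sum_comb(as.vector(tab))
  B <- sum_comb(rowSums(tab)); C <- sum_comb(colSums(tab))
  n <- sum(tab)
  expected <- B * C / choose(n, 2)
  (A - expected) / ((B + C) / 2 - expected)
}

# regular 5-min epoch timestamps starting at a given UTC time
epoch_times <- function(start = "2020-03-20 00:00", n = 288) {
  as.POSIXct(start, tz = "UTC") + seq(0, by = 300, length.out = n)
}

# hand-rolled IRLS for a binomial GLM: the independent oracle for the
# mixed-model front-end at zero random-effect variance
irls_binomial <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}
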