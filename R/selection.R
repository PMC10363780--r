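# Resource selection for resting sites: home ranges from a 90% kernel
# utilization distribution of active-phase fixes, uniform availability
# samples inside them, a used/available binomial GLMM per season,
# selection-ratio curves, and Boyce-style k-fold cross-validation.

#' Kernel home range (90% utilization distribution)
#'
#' Bivariate normal-kernel density of the active-phase fixes on a metric
#' grid (normal-reference bandwidth per axis), thresholded at the density
#' level enclosing `level` of the probability mass.
#'
#' @param x,y Active-phase fix coordinates (planar meters).
#' @param level Utilization level (default 0.90).
#' @param grid_res Target grid cell size in meters (default 50).
#' @param bw Optional bandwidth override (length-2, meters).
#' @return Object of class `home_range`: grid vectors `xs`, `ys`, logical
#'   `mask`, `area_m2`, `bw`, `level`, and `contours` (polygons for
#'   plotting).
#' @export
home_range_kde <- function(x, y, level = 0.90, grid_res = 50, bw = NULL) {
  if (length(x) < 50) stop("need at least 50 fixes for a home range")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("degenerate fixes: zero spread")
  if (is.null(bw)) bw <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  if (any(bw <= 0)) stop("degenerate bandwidth")
  pad <- 2 * max(bw)
  lims <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  n_grid <- c(max(64L, ceiling((lims[2] - lims[1]) / grid_res)),
              max(64L, ceiling((lims[4] - lims[3]) / grid_res)))
  kd <- MASS::kde2d(x, y, h = bw, n = n_grid, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  mass <- kd$z * dx * dy
  mass <- mass / sum(mass)
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  cut_idx <- which(cum >= level)[1]
  zcut <- kd$z[ord[cut_idx]]
  mask <- kd$z >= zcut
  inside_frac <- mean(.hr_contains(list(xs = kd$x, ys = kd$y, mask = mask), x, y))
  if (inside_frac < 0.85)
    warning(sprintf("home range contains only %.0f%% of input fixes", 100 * inside_frac))
  cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = zcut)
  contours <- lapply(cl, function(c) cbind(x = c$x, y = c$y))
  structure(list(xs = kd$x, ys = kd$y, mask = mask, bw = bw, level = level,
                 area_m2 = sum(mask) * dx * dy, contours = contours,
                 mass_inside = sum(mass[mask])), class = "home_range")
}

.hr_contains <- function(hr, px, py) {
  ix <- round((px - hr$xs[1]) / diff(hr$xs[1:2])) + 1
  iy <- round((py - hr$ys[1]) / diff(hr$ys[1:2])) + 1
  ok <- ix >= 1 & ix <= length(hr$xs) & iy >= 1 & iy <= length(hr$ys)
  out <- logical(length(px))
  out[ok] <- hr$mask[cbind(ix[ok], iy[ok])]
  out
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("%.0f%% kernel home range: %.1f ha (bw %.0f/%.0f m)\n",
              100 * x$level, x$area_m2 / 1e4, x$bw[1], x$bw[2]))
  invisible(x)
}

#' Uniform availability sample inside a home range
#'
#' Rejection sampling from the bounding box of the home-range mask.
#'
#' @param hr A [home_range_kde()] object.
#' @param n Number of points.
#' @return n x 2 matrix of coordinates.
#' @export
sample_available <- function(hr, n) {
  xr <- range(hr$xs); yr <- range(hr$ys)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / max(1e-6, sum(hr$mask) / length(hr$mask)))
    px <- stats::runif(m, xr[1], xr[2]); py <- stats::runif(m, yr[1], yr[2])
    keep <- .hr_contains(hr, px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Assemble a seasonal used/available RSF dataset
#'
#' One row per used resting site (sites with at least one visit in the
#' season) and `n_avail_per_used` uniform availability points per used
#' site, drawn from the owning animal's home range. Distances are
#' standardized (z-score over the assembled dataset); the scaling is kept
#' as an attribute so selection-ratio curves can be reported in meters.
#'
#' @param sites Output of [summarise_sites()] (after covariates are merged
#'   via [landscape_covariates()], i.e. with `veg`, `d_village`, `d_road`).
#' @param home_ranges Named list of `home_range` objects keyed by animal.
#' @param season `"NHS"` or `"HS"`.
#' @param covariate_fun Function (`px`, `py`) -> data frame with `veg`,
#'   `d_village`, `d_road` used for the availability points.
#' @param n_avail_per_used Availability ratio (default 1000).
#' @param study_sites Optional named vector mapping animal -> study site
#'   (defaults to one site).
#' @return Data frame of class `rsf_data` with `used`, covariates (raw and
#'   standardized `d_village_s`, `d_road_s`), `animal_id`, `study_site`.
#' @export
build_rsf_dataset <- function(sites, home_ranges, season = c("NHS", "HS"),
                              covariate_fun, n_avail_per_used = 1000,
                              study_sites = NULL) {
  season <- match.arg(season)
  cnt <- if (season == "NHS") sites$n_visits_NHS else sites$n_visits_HS
  used <- sites[cnt >= 1, , drop = FALSE]
  if (!nrow(used)) stop("no used sites in season ", season)
  rows <- list()
  for (id in unique(used$animal_id)) {
    u <- used[used$animal_id == id, ]
    rows[[length(rows) + 1L]] <- data.frame(
      used = 1L, veg = u$veg, d_village = u$d_village, d_road = u$d_road,
      animal_id = id)
    av <- sample_available(home_ranges[[id]], n_avail_per_used * nrow(u))
    cv <- covariate_fun(av[, 1], av[, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      used = 0L, veg = cv$veg, d_village = cv$d_village, d_road = cv$d_road,
      animal_id = id)
  }
  out <- do.call(rbind, rows)
  out$study_site <- if (is.null(study_sites)) "site1"
                    else as.character(study_sites[out$animal_id])
  sc <- list(d_village = c(mean = mean(out$d_village), sd = stats::sd(out$d_village)),
             d_road = c(mean = mean(out$d_road), sd = stats::sd(out$d_road)))
  out$d_village_s <- (out$d_village - sc$d_village["mean"]) / sc$d_village["sd"]
  out$d_road_s <- (out$d_road - sc$d_road["mean"]) / sc$d_road["sd"]
  attr(out, "scaling") <- sc
  attr(out, "season") <- season
  class(out) <- c("rsf_data", class(out))
  out
}

#' Fit the seasonal resource-selection function
#'
#' Binomial GLMM of used vs available with vegetation-by-distance
#' interactions and animal-within-study-site random intercepts.
#'
#' @param rsf A [build_rsf_dataset()] data frame.
#' @param random Random-intercept nesting (default animal within study
#'   site).
#' @return A `glmm_fit`.
#' @export
fit_rsf <- function(rsf, random = ~ study_site / animal_id) {
  fit_glmm(used ~ veg * d_road_s + veg * d_village_s, rsf,
           family = "binomial", random = random)
}

#' Selection-ratio curve from a fitted RSF
#'
#' `SR(x) = (n_available / n_used) * exp(eta(x))` with `eta` the fitted
#' linear predictor including the intercept: the ratio of use density to
#' availability density, 1 = neutrality. The 95% CI comes from the Wald
#' interval on the link scale.
#'
#' @param fit A converged RSF `glmm_fit`.
#' @param newdata Covariate grid (standardized columns as in the fit).
#' @param n_used,n_available Row counts of the fitted dataset.
#' @return `newdata` with `sr`, `lwr`, `upr`.
#' @export
selection_ratio <- function(fit, newdata, n_used, n_available) {
  if (!fit$converged) stop("refusing to compute selection ratios from a non-converged fit")
  pr <- predict(fit, newdata, type = "link")
  k <- n_available / n_used
  cbind(newdata, sr = k * exp(pr$fit), lwr = k * exp(pr$lwr), upr = k * exp(pr$upr))
}

#' Cross-validation configuration
#' @param n_folds,n_bins,n_reps Folds, score bins and replicates
#'   (defaults 5, 10, 20).
#' @param n_avail_refit Availability points per used point in each CV
#'   refit (thinned for tractability; held-out scoring uses all points).
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5, n_bins = 10, n_reps = 20, n_avail_refit = 100) {
  stopifnot(n_folds >= 2, n_bins >= 3, n_reps >= 1)
  structure(list(n_folds = n_folds, n_bins = n_bins, n_reps = n_reps,
                 n_avail_refit = n_avail_refit), class = "cv_config")
}

# Spearman correlation of area-adjusted bin frequencies vs bin rank for one
# fold. Scores are binned equal-interval on the log (link) scale: RSF
# scores span orders of magnitude, and raw-scale bins would put almost all
# mass in the lowest bin. Bins with no availability mass are merged
# leftward.
.boyce_fold <- function(score_used, score_avail, n_bins, min_share = 0.01) {
  rng <- range(c(score_used, score_avail))
  if (diff(rng) == 0) return(NA_real_)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bu <- findInterval(score_used, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ba <- findInterval(score_avail, brk, rightmost.closed = TRUE, all.inside = TRUE)
  cu <- tabulate(bu, n_bins); ca <- tabulate(ba, n_bins)
  # merge bins carrying (almost) no availability mass into their left
  # neighbour: a frequency ratio from a near-empty bin is pure noise
  thin <- ca < min_share * sum(ca)
  if (all(thin)) return(NA_real_)
  grp <- seq_len(n_bins)
  for (j in seq_len(n_bins)) if (thin[j] && j > 1) grp[grp == j] <- grp[j - 1]
  if (thin[1]) grp[grp == 1] <- grp[min(which(!thin))]
  grp <- factor(grp, levels = unique(grp))  # keep bin order
  cu <- tapply(cu, grp, sum); ca <- tapply(ca, grp, sum)
  keep <- ca > 0
  if (sum(keep) < 3) return(NA_real_)
  fr <- (cu[keep] / max(1, sum(cu))) / (ca[keep] / sum(ca))
  suppressWarnings(stats::cor(fr, seq_along(fr), method = "spearman"))
}

#' Boyce-style k-fold cross-validation of an RSF
#'
#' Per replicate, used points are split into `n_folds` folds; each fold's
#' model is refit on the remaining used points (with a thinned availability
#' sample), then held-out used points and all availability points are
#' scored with the RSF score (binned equal-width on its log scale, where
#' the score distribution is well spread), and
#' the Spearman rank correlation between bin rank and area-adjusted
#' frequency (held-out used fraction / availability fraction) is averaged
#' over folds. Reports the mean and standard error over replicates.
#'
#' @param rsf A [build_rsf_dataset()] data frame.
#' @param config A [cv_config()].
#' @param fit_fun Refit procedure taking a data frame and returning an
#'   object whose `predict(..., type = "link")` works, or a plain scoring
#'   function of a data frame (e.g. the true simulated selection
#'   intensity, for consistency checks); default refits the RSF fixed
#'   effects by ML (random intercepts at 0 for scoring).
#' @return List `mean`, `se`, `per_rep` (replicate means).
#' @export
boyce_cv <- function(rsf, config = cv_config(), fit_fun = NULL) {
  used_idx <- which(rsf$used == 1L)
  avail_idx <- which(rsf$used == 0L)
  if (length(used_idx) < config$n_folds) stop("fewer used points than folds")
  form <- used ~ veg * d_road_s + veg * d_village_s
  if (is.null(fit_fun))
    fit_fun <- function(d) stats::glm(form, data = d, family = stats::binomial())
  score <- function(fit, d) {
    if (is.function(fit)) fit(d)
    else if (inherits(fit, "glmm_fit")) predict(fit, d, type = "link")$fit
    else stats::predict(fit, d, type = "link")
  }
  per_rep <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    fold <- sample(rep_len(seq_len(config$n_folds), length(used_idx)))
    cors <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      train_used <- used_idx[fold != f]
      test_used <- used_idx[fold == f]
      n_av <- min(length(avail_idx), config$n_avail_refit * length(train_used))
      train <- rsf[c(train_used, sample(avail_idx, n_av)), , drop = FALSE]
      fit <- fit_fun(train)
      cors[f] <- .boyce_fold(score(fit, rsf[test_used, , drop = FALSE]),
                             score(fit, rsf[avail_idx, , drop = FALSE]),
                             config$n_bins)
    }
    per_rep[r] <- mean(cors, na.rm = TRUE)
  }
  list(mean = mean(per_rep), se = stats::sd(per_rep) / sqrt(config$n_reps),
       per_rep = per_rep)
}
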