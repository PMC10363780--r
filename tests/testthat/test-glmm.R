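test_that("closed-form checks: logit intercept and zero-truncated mean", {
  d <- data.frame(y = c(1L, rep(0L, 1000)))
  f <- fit_glmm(y ~ 1, d, family = "binomial")
  expect_equal(unname(coef(f)), qlogis(1 / 1001), tolerance = 1e-6)
  # mean of a zero-truncated Poisson at lambda = 1 is 1/(1 - e^-1) ~ 1.582
  f0 <- structure(list(coefficients = matrix(0, 1, 4,
                         dimnames = list("(Intercept)",
                                         c("estimate", "se", "z", "p_value"))),
                       family = "zt_poisson"), class = "glmm_fit")
  set.seed(8)
  y <- qpois(runif(4000, dpois(0, 1), 1), 1)
  fz <- fit_glmm(y ~ 1, data.frame(y = y), family = "zt_poisson")
  expect_equal(unname(coef(fz)), 0, tolerance = 0.08)
  lam <- exp(coef(fz))
  expect_equal(unname(lam / (1 - exp(-lam))), mean(y), tolerance = 1e-3)
})

test_that("fixed effects match a hand-rolled IRLS oracle at zero random variance", {
  set.seed(21)
  d <- data.frame(x = rnorm(400), g = "only_group")
  d$y <- rbinom(400, 1, plogis(-0.4 + 0.9 * d$x))
  f <- suppressWarnings(fit_glmm(y ~ x, d, family = "binomial", random = ~ g))
  X <- cbind(1, d$x)
  oracle <- irls_binomial(X, d$y)
  expect_lt(max(abs(unname(coef(f)) - oracle)), 1e-6)
  # the single-level random factor was dropped with a warning
  expect_warning(fit_glmm(y ~ x, d, family = "binomial", random = ~ g),
                 "single level")
})

test_that("zero-truncated fit converges to plain Poisson when truncation is negligible", {
  set.seed(22)
  d <- data.frame(x = rnorm(800))
  d$y <- rpois(800, exp(3 + 0.3 * d$x))  # lambda ~ 20: P(0) < 1e-8
  stopifnot(all(d$y >= 1))
  fz <- fit_glmm(y ~ x, d, family = "zt_poisson")
  fp <- glm(y ~ x, poisson, d)
  expect_lt(max(abs(coef(fz) - coef(fp))), 1e-4)
})

test_that("parameter recovery within 2 SE per family at nominal coverage", {
  set.seed(23)
  n <- 400; n_rep <- 30
  hit <- matrix(0, n_rep, 3,
                dimnames = list(NULL, c("binomial", "zt_poisson", "gamma_log")))
  for (r in seq_len(n_rep)) {
    g <- sprintf("a%02d", sample(10, n, replace = TRUE))
    site <- ifelse(g %in% sprintf("a%02d", 1:5), "S1", "S2")
    b <- rnorm(10, 0, 0.4)[as.integer(factor(g))]
    x <- rnorm(n)
    d <- data.frame(x = x, g = g, site = site)
    # binomial, slope 0.8
    d$yb <- rbinom(n, 1, plogis(-0.2 + 0.8 * x + b))
    fb <- suppressWarnings(fit_glmm(yb ~ x, d, "binomial", ~ site / g))
    hit[r, 1] <- abs(fb$coefficients["x", "estimate"] - 0.8) <=
      2 * fb$coefficients["x", "se"]
    # zero-truncated Poisson, slope 0.4
    lam <- exp(0.3 + 0.4 * x + b)
    d$yz <- qpois(runif(n, dpois(0, lam), 1), lam)
    fz <- suppressWarnings(fit_glmm(yz ~ x, d, "zt_poisson", ~ site / g))
    hit[r, 2] <- abs(fz$coefficients["x", "estimate"] - 0.4) <=
      2 * fz$coefficients["x", "se"]
    # gamma log, slope -0.5, shape 3
    mu <- exp(0.5 - 0.5 * x + b)
    d$yg <- rgamma(n, shape = 3, rate = 3 / mu)
    fg <- suppressWarnings(fit_glmm(yg ~ x, d, "gamma_log", ~ site / g))
    hit[r, 3] <- abs(fg$coefficients["x", "estimate"] + 0.5) <=
      2 * fg$coefficients["x", "se"]
  }
  expect_true(all(colMeans(hit) >= 0.9))
})

test_that("degenerate binomial responses trigger the penalized fallback", {
  d <- data.frame(y = rep(0L, 60), x = rnorm(60))
  f <- fit_glmm(y ~ x, d, family = "binomial")
  expect_true(f$penalized)
  expect_false(f$converged)
  expect_true(is.finite(coef(f)[1]))
  expect_equal(unname(coef(f)[1]), qlogis(0.5 / 61), tolerance = 1e-8)
})

test_that("population-level predictions invert the link with ordered intervals", {
  set.seed(24)
  d <- data.frame(x = rnorm(300))
  d$y <- rbinom(300, 1, plogis(0.2 + d$x))
  f <- fit_glmm(y ~ x, d, family = "binomial")
  p0 <- predict(f, data.frame(x = -coef(f)[1] / coef(f)[2]))
  expect_equal(p0$fit, 0.5, tolerance = 1e-8)  # linear predictor 0
  pr <- predict(f, data.frame(x = c(-2, 0, 2)))
  expect_true(all(pr$lwr < pr$fit & pr$fit < pr$upr))
  expect_true(all(pr$fit > 0 & pr$fit < 1))
  expect_error(predict(f, data.frame(z = 1)))
  # mean prediction close to mean response at the data profile
  pm <- predict(f, d)
  expect_lt(abs(mean(pm$fit) - mean(d$y)), 0.05)
})

test_that("marginal R2 is 0 for a null model, bounded, and matches the plug-in", {
  set.seed(25)
  d <- data.frame(x = rnorm(3000), g = sprintf("g%d", sample(15, 3000, TRUE)))
  b <- rnorm(15, 0, sqrt(0.5))[as.integer(factor(d$g))]
  beta_x <- 1.0
  d$y <- rbinom(3000, 1, plogis(0.1 + beta_x * d$x + b))
  f <- fit_glmm(y ~ x, d, "binomial", ~ g)
  r2 <- marginal_r2(f)
  truth <- beta_x^2 / (beta_x^2 + 0.5 + pi^2 / 3)  # var(x) = 1
  expect_lt(abs(r2 - truth), 0.05)
  # intercept-only: no fixed-effect variance
  f0 <- fit_glmm(y ~ 1, d, "binomial", ~ g)
  expect_equal(marginal_r2(f0), 0)
  for (fam in c("binomial", "zt_poisson")) {
    dd <- data.frame(x = rnorm(150))
    dd$y <- if (fam == "binomial") rbinom(150, 1, plogis(dd$x)) else
      qpois(runif(150, dpois(0, exp(0.2 * dd$x)), 1), exp(0.2 * dd$x))
    ff <- suppressWarnings(fit_glmm(y ~ x, dd, fam))
    expect_true(marginal_r2(ff) >= 0 && marginal_r2(ff) <= 1)
  }
})
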