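# Mixed-model core shared by the resource-selection, revisitation and
# relocation analyses: one fitting front-end for the three response
# families the pipeline needs (binomial, zero-truncated Poisson, gamma
# with log link), each with animal-within-study-site nested random
# intercepts. Estimation is Laplace-approximate maximum likelihood via
# glmmTMB; this file owns the model surface, the degenerate-data guards,
# Wald machinery and Nakagawa's marginal R2.

#' Fit a generalized linear mixed model
#'
#' Fits `formula` by maximum likelihood with optional nested random
#' intercepts. Families: `"binomial"` (logit), `"zt_poisson"`
#' (zero-truncated Poisson, log link, P(Y=k | k>=1) = lambda^k
#' exp(-lambda) / (k! (1 - exp(-lambda)))), and `"gamma_log"` (gamma,
#' log link) for positive continuous responses.
#'
#' Random factors with fewer than 2 levels are dropped (variance pinned at
#' 0, with a warning). A binomial response with no variation (all 0 or
#' all 1) triggers a penalized intercept-only fallback (Laplace-smoothed
#' counts) instead of a divergent fit, flagged in the result.
#'
#' @param formula Fixed-effects formula, e.g.
#'   `used ~ veg * d_road + veg * d_village`.
#' @param data Model data frame.
#' @param family One of `"binomial"`, `"zt_poisson"`, `"gamma_log"`.
#' @param random One-sided nesting formula, e.g. `~ study_site / animal_id`
#'   (outer / inner grouping), or `NULL` for none.
#' @param weights Optional case weights.
#' @return Object of class `glmm_fit` with coefficient table, variance
#'   components, log-likelihood, convergence flag and the fitted engine
#'   object. Methods: `print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `predict`, `residuals`.
#' @export
fit_glmm <- function(formula, data, family = c("binomial", "zt_poisson", "gamma_log"),
                     random = NULL, weights = NULL) {
  family <- match.arg(family)
  fam_obj <- switch(family,
                    binomial = stats::binomial(),
                    zt_poisson = glmmTMB::truncated_poisson(link = "log"),
                    gamma_log = stats::Gamma(link = "log"))
  re_terms <- character()
  if (!is.null(random)) {
    vars <- all.vars(random)
    vars <- vars[vapply(vars, function(v) length(unique(data[[v]])) > 1, TRUE)]
    dropped <- setdiff(all.vars(random), vars)
    if (length(dropped))
      warning("random factor(s) with a single level dropped (variance pinned at 0): ",
              paste(dropped, collapse = ", "))
    if (length(vars) >= 1) re_terms <- paste0("(1 | ", vars[1], ")")
    if (length(vars) >= 2)
      re_terms <- c(re_terms, paste0("(1 | ", vars[1], ":", vars[2], ")"))
  }
  resp <- stats::model.response(stats::model.frame(formula, data))
  if (family == "binomial" && length(unique(resp)) < 2) {
    # degenerate response: penalized (add-half) intercept-only estimate
    k <- sum(resp); n <- length(resp)
    p <- (k + 0.5) / (n + 1)
    co <- matrix(c(stats::qlogis(p), sqrt(1 / (n * p * (1 - p))),
                   NA, NA), 1, 4,
                 dimnames = list("(Intercept)",
                                 c("estimate", "se", "z", "p_value")))
    co[1, 3] <- co[1, 1] / co[1, 2]
    co[1, 4] <- 2 * stats::pnorm(-abs(co[1, 3]))
    return(structure(list(coefficients = co, varcomp = numeric(0),
                          family = family, formula = formula, random = random,
                          logLik = NA_real_, converged = FALSE,
                          penalized = TRUE, n_obs = n, data = data,
                          engine = NULL), class = "glmm_fit"))
  }
  fe_labels <- attr(stats::terms(formula), "term.labels")
  fit_once <- function(re) {
    lab <- c(fe_labels, re)
    if (!length(lab)) lab <- "1"
    full <- stats::reformulate(lab, response = all.vars(formula)[1],
                               intercept = TRUE)
    environment(full) <- environment()
    glmmTMB::glmmTMB(full, data = data, family = fam_obj, weights = weights)
  }
  ok <- function(f) isTRUE(f$fit$convergence == 0) && isTRUE(f$sdr$pdHess)
  fit <- fit_once(re_terms)
  dropped_re <- character()
  # a variance component sitting on the zero boundary can break the
  # Hessian; simplify by dropping the smallest component and refitting
  while (!ok(fit) && length(re_terms)) {
    vc0 <- glmmTMB::VarCorr(fit)$cond
    v <- vapply(vc0, function(z) as.numeric(z[1, 1]), numeric(1))
    drop_i <- which.min(v)
    dropped_re <- c(dropped_re, re_terms[drop_i])
    re_terms <- re_terms[-drop_i]
    fit <- fit_once(re_terms)
  }
  if (length(dropped_re))
    warning("boundary variance component(s) dropped for a stable fit: ",
            paste(dropped_re, collapse = ", "))
  co <- summary(fit)$coefficients$cond[, 1:4, drop = FALSE]
  colnames(co) <- c("estimate", "se", "z", "p_value")
  vc <- glmmTMB::VarCorr(fit)$cond
  varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  for (nm in dropped_re) varcomp[[gsub("^\\(1 \\| (.*)\\)$", "\\1", nm)]] <- 0
  conv <- ok(fit)
  if (!conv) warning("model did not converge cleanly; fit is flagged")
  structure(list(coefficients = co, varcomp = varcomp, family = family,
                 formula = formula, random = random,
                 logLik = as.numeric(stats::logLik(fit)), converged = conv,
                 penalized = FALSE, n_obs = stats::nobs(fit), data = data,
                 engine = fit), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("GLMM (%s), n = %d%s\n", x$family, x$n_obs,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (length(x$varcomp)) {
    cat("Random-intercept variances:\n")
    print(round(x$varcomp, digits))
  }
  invisible(x)
}

#' @export
summary.glmm_fit <- function(object, ...) {
  r2 <- tryCatch(marginal_r2(object), error = function(e) NA_real_)
  out <- list(coefficients = object$coefficients, varcomp = object$varcomp,
              family = object$family, n_obs = object$n_obs,
              logLik = object$logLik, converged = object$converged,
              marginal_r2 = r2)
  class(out) <- "summary.glmm_fit"
  out
}

#' @export
print.summary.glmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("GLMM (%s), n = %d, logLik = %.2f\n", x$family, x$n_obs, x$logLik))
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (length(x$varcomp)) {
    cat("Random-intercept variances:\n"); print(round(x$varcomp, digits))
  }
  cat(sprintf("Marginal R2 (Nakagawa): %.3f\n", x$marginal_r2))
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...)
  stats::setNames(object$coefficients[, "estimate"],
                  rownames(object$coefficients))

#' @export
vcov.glmm_fit <- function(object, ...) {
  if (is.null(object$engine)) {
    v <- matrix(object$coefficients[, "se"]^2, 1, 1,
                dimnames = list(rownames(object$coefficients),
                                rownames(object$coefficients)))
    return(v)
  }
  stats::vcov(object$engine)$cond
}

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$logLik, df = nrow(object$coefficients) + length(object$varcomp),
            class = "logLik")
}

#' @export
residuals.glmm_fit <- function(object, ...) {
  if (is.null(object$engine)) stop("no residuals for a penalized fallback fit")
  stats::residuals(object$engine, ...)
}

.inv_link <- function(eta, family) {
  switch(family,
         binomial = stats::plogis(eta),
         zt_poisson = {
           lam <- exp(eta)
           lam / (1 - exp(-lam))  # mean of the truncated response
         },
         gamma_log = exp(eta))
}

#' Predict from a fitted GLMM at the population level
#'
#' Linear predictor (and response-scale transform) at random effects = 0,
#' with Wald intervals built on the link scale and mapped through the
#' inverse link. For the zero-truncated Poisson, `type = "response"`
#' returns the truncated mean `lambda / (1 - exp(-lambda))`.
#'
#' @param object A `glmm_fit`.
#' @param newdata Data frame supplying every fixed-effect covariate.
#' @param type `"link"` or `"response"`.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Data frame `fit`, `lwr`, `upr` on the requested scale.
#' @export
predict.glmm_fit <- function(object, newdata, type = c("response", "link"),
                             level = 0.95, ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                  na.action = stats::na.pass,
                                                  xlev = .xlevels(object)))
  beta <- stats::setNames(object$coefficients[, "estimate"],
                          rownames(object$coefficients))
  X <- X[, names(beta), drop = FALSE]
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% vcov(object)) * X))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- eta - zq * se; hi <- eta + zq * se
  if (type == "link") return(data.frame(fit = eta, lwr = lo, upr = hi, se = se))
  data.frame(fit = .inv_link(eta, object$family),
             lwr = .inv_link(lo, object$family),
             upr = .inv_link(hi, object$family), se_link = se)
}

.xlevels <- function(object) {
  mf <- stats::model.frame(stats::delete.response(stats::terms(object$formula)),
                           object$data)
  lv <- lapply(mf, function(col) if (is.factor(col)) levels(col) else NULL)
  lv[!vapply(lv, is.null, TRUE)]
}

#' Nakagawa's marginal R2
#'
#' Variance explained by the fixed effects alone:
#' `var(X beta) / (var(X beta) + sum(random variances) + residual
#' variance)`, with the family-specific latent residual variance:
#' `pi^2 / 3` for the binomial logit, the lognormal approximation
#' `log(1 + 1 / mean(lambda))` for (truncated) Poisson on the log scale,
#' and `trigamma(shape)` for the gamma.
#'
#' @param fit A `glmm_fit`.
#' @return Marginal R2 in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  if (is.null(fit$engine)) return(0)
  tt <- stats::delete.response(stats::terms(fit$formula))
  X <- stats::model.matrix(tt, stats::model.frame(fit$formula, fit$data))
  beta <- stats::setNames(fit$coefficients[, "estimate"],
                          rownames(fit$coefficients))
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  var_f <- stats::var(eta)
  var_r <- sum(fit$varcomp)
  var_e <- switch(fit$family,
                  binomial = pi^2 / 3,
                  zt_poisson = log(1 + 1 / mean(exp(eta))),
                  gamma_log = trigamma(1 / (glmmTMB::sigma(fit$engine)^2)))
  out <- var_f / (var_f + var_r + var_e)
  if (!is.finite(out)) 0 else max(0, min(1, out))
}
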