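# Inference stage: predictor scaling, Spearman collinearity screen, response
# transformations, beta/lognormal mixed models with three random intercepts,
# simulation-based residual diagnostics, buffer-radius selection and
# species-level rank-sum comparisons.

#' Center and scale predictor columns
#'
#' Each column is centered to its mean and scaled to its standard deviation
#' (sample SD), so fixed-effect estimates are comparable across predictors.
#' The constants are recorded in the `"scaling"` attribute for
#' back-transformation.
#'
#' @param table data.frame.
#' @param columns names of numeric columns to scale.
#' @return the table with scaled columns and a `"scaling"` attribute
#'   (list of `c(center, scale)` per column).
#' @export
scale_predictors <- function(table, columns) {
  consts <- list()
  for (cl in columns) {
    v <- table[[cl]]
    stopifnot(is.numeric(v))
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("constant column cannot be scaled: ", cl)
    m <- mean(v)
    table[[cl]] <- (v - m) / s
    consts[[cl]] <- c(center = m, scale = s)
  }
  attr(table, "scaling") <- consts
  table
}

#' Pairwise Spearman collinearity screen
#'
#' All pairwise Spearman rank correlations among candidate predictors; any
#' pair with |rs| at or above the threshold is flagged, and one member of
#' each flagged pair (the one with the larger mean absolute correlation to
#' everything else) is proposed for exclusion.
#'
#' @param table data.frame.
#' @param predictors names of >= 2 numeric columns.
#' @param threshold flag level for |rs| (default 0.5).
#' @return list with `rs` (correlation matrix), `flagged` (data.frame of
#'   offending pairs) and `drop` (suggested exclusions).
#' @export
collinearity_screen <- function(table, predictors, threshold = 0.5) {
  stopifnot(length(predictors) >= 2L)
  m <- as.matrix(table[predictors])
  rs <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  flagged <- data.frame(a = character(), b = character(), rs = numeric())
  drop <- character()
  meanabs <- rowMeans(abs(rs) - diag(nrow(rs)))
  for (i in seq_len(ncol(rs) - 1L)) {
    for (j in seq((i + 1L), ncol(rs))) {
      if (abs(rs[i, j]) >= threshold) {
        flagged <- rbind(flagged, data.frame(
          a = predictors[i], b = predictors[j], rs = rs[i, j]))
        drop <- union(drop, predictors[if (meanabs[i] >= meanabs[j]) i else j])
      }
    }
  }
  list(rs = rs, flagged = flagged, drop = drop)
}

#' Transform a response onto its model family's support
#'
#' Responses on the unit interval are modelled as beta; some raw metrics need
#' division by 10 (e.g., flight speed in m/s, sinuosity) and/or a small
#' additive constant 1e-10 (shares that can be exactly zero) to fall inside
#' the open interval. Values still at or above 1 after transformation are
#' nudged to 1 - 1e-6 with a warning. Lognormal responses must be strictly
#' positive and are passed through.
#'
#' @param values numeric response vector.
#' @param divide_by_10 divide values by 10 first.
#' @param add_epsilon add 1e-10 after any division.
#' @param family `"beta_logit"` or `"lognormal_log"` (controls the support
#'   checks).
#' @return transformed values.
#' @export
transform_response <- function(values, divide_by_10 = FALSE,
                               add_epsilon = FALSE,
                               family = c("beta_logit", "lognormal_log")) {
  family <- match.arg(family)
  stopifnot(all(is.finite(values)))
  v <- values
  if (divide_by_10) v <- v / 10
  if (add_epsilon) v <- v + 1e-10
  if (family == "beta_logit") {
    if (any(v >= 1)) {
      warning(sprintf("%d value(s) at or above 1 nudged to 1 - 1e-6",
                      sum(v >= 1)))
      v[v >= 1] <- 1 - 1e-6
    }
    if (any(v <= 0))
      stop("beta response requires values in (0, 1); use add_epsilon")
  } else {
    if (any(v <= 0))
      stop("lognormal response requires strictly positive values")
  }
  v
}

.fp_families <- c("beta_logit", "lognormal_log")

#' Fit a mixed-effect regression of a movement metric
#'
#' Maximum-likelihood fit (glmmTMB backend) of a beta (logit link) or
#' lognormal (log link) model with random intercepts for habitat area, track
#' duration and site. The continuous grouping variables are treated
#' literally as grouping factors — each distinct value of habitat area or
#' duration is one level — which is what the mixed-model machinery does when
#' handed such terms; `random_as_fixed = TRUE` instead enters them as fixed
#' covariates. Wald z = estimate/SE with two-sided normal p-values.
#'
#' @param table data.frame holding the (already transformed) response, the
#'   (already scaled) fixed-effect columns and the grouping columns.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect column names (a factor such
#'   as `sex` is allowed).
#' @param family `"beta_logit"` or `"lognormal_log"`.
#' @param random names of the grouping columns (default habitat area,
#'   duration, site).
#' @param random_as_fixed enter the continuous grouping variables as fixed
#'   covariates instead of random intercepts.
#' @return object of class `fp_model_fit`: list with `estimates`
#'   (term/estimate/std_error/z/p), `random_variances`, `loglik`, `aic`,
#'   `n`, `resid_df`, `family`, `singular` (any random-effect variance
#'   estimated at ~0), `convergence` (optimizer message; empty when clean),
#'   and the underlying `model`.
#' @export
fit_glmm <- function(table, response, fixed,
                     family = c("beta_logit", "lognormal_log"),
                     random = c("habitat_area_ha", "duration_s", "site_id"),
                     random_as_fixed = FALSE) {
  family <- match.arg(family)
  stopifnot(response %in% names(table), all(fixed %in% names(table)),
            all(random %in% names(table)))
  df <- table
  df$.y <- df[[response]]
  rterms <- character()
  if (random_as_fixed) {
    fixed <- c(fixed, random)
  } else {
    for (r in random) {
      fr <- paste0(".g_", r)
      df[[fr]] <- factor(df[[r]])
      rterms <- c(rterms, sprintf("(1 | %s)", fr))
    }
  }
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(fixed, rterms), collapse = " + ")))
  fam <- switch(family,
                beta_logit = glmmTMB::beta_family(link = "logit"),
                lognormal_log = glmmTMB::lognormal(link = "log"))
  m <- glmmTMB::glmmTMB(fml, data = df, family = fam)
  conv_msg <- m$fit$message %||% ""
  if (!is.null(m$fit$convergence) && m$fit$convergence != 0 &&
      !grepl("singular convergence|false convergence", conv_msg))
    stop("mixed-model fit did not converge: ", conv_msg)
  co <- summary(m)$coefficients$cond
  # nlminb codes 7/8 still return estimates (glmmTMB itself only warns);
  # retained with the message recorded. A non-PD Hessian leaves NaN SEs:
  # point estimates and simulation remain usable, Wald inference does not.
  if (all(!is.finite(co[, 2L])))
    warning("standard errors unavailable (non-positive-definite Hessian); ",
            "Wald columns are NaN")
  est <- data.frame(term = rownames(co), estimate = co[, 1L],
                    std_error = co[, 2L], z = co[, 3L], p = co[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  vc <- glmmTMB::VarCorr(m)$cond
  rv <- vapply(vc, function(v) as.numeric(v[1L, 1L]), numeric(1))
  names(rv) <- sub("^\\.g_", "", names(rv))
  singular <- length(rv) > 0 && any(rv < 1e-8)
  npar <- length(m$obj$par)
  structure(
    list(estimates = est, random_variances = rv,
         loglik = as.numeric(stats::logLik(m)), aic = stats::AIC(m),
         n = nrow(df), resid_df = nrow(df) - npar, family = family,
         singular = singular, convergence = conv_msg,
         response = response, fixed = fixed, model = m),
    class = "fp_model_fit")
}

#' @export
print.fp_model_fit <- function(x, ...) {
  cat(sprintf("<fp_model_fit> %s ~ %s  [%s], n=%d, AIC=%.1f%s\n",
              x$response, paste(x$fixed, collapse = " + "), x$family, x$n,
              x$aic, if (x$singular) " (singular RE)" else ""))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Simulation-based residual diagnostics
#'
#' Randomized-quantile residual checks in the style of simulation-based GLMM
#' diagnostics: `n_sim` response sets are simulated from the fitted model;
#' each observation's randomized rank among its simulations is uniform on
#' (0, 1) under a correctly specified model. Uniformity is measured by the
#' Kolmogorov-Smirnov distance, whose p-value comes from a Monte-Carlo null:
#' every simulated response set is scored exactly like the observed one
#' within the pooled exchangeable set. (Simulations redraw the random
#' effects, so residuals are correlated within grouping levels; against the
#' textbook iid-uniform KS reference that dependence would inflate the
#' rejection rate, while the exchangeable Monte-Carlo null is calibrated by
#' construction.) Dispersion is a two-sided Monte-Carlo test of the observed
#' residual variance among the simulated ones, residuals taken about the
#' simulation-based expectation.
#'
#' @param fit an `fp_model_fit`.
#' @param n_sim number of simulated response sets (>= 250).
#' @param seed RNG seed for the simulations and rank randomization.
#' @param alpha flag level.
#' @param observed optional response vector to diagnose against the fit in
#'   place of the fitting data (e.g., for power analyses of the tests).
#' @return list of class `fp_diagnostics`: `ks_uniformity_p`,
#'   `dispersion_p`, `n_sim`, `flag` (`"ok"` or `"deviation_significant"`).
#' @export
residual_diagnostics <- function(fit, n_sim = 250L, seed = 1L,
                                 alpha = 0.05, observed = NULL) {
  if (n_sim < 250L) stop("n_sim must be at least 250")
  m <- fit$model
  set.seed(seed)
  sims <- as.matrix(stats::simulate(m, nsim = n_sim))
  y <- if (is.null(observed)) stats::model.response(stats::model.frame(m))
       else observed
  n <- length(y)
  # pool the observation with its simulations: every member's randomized
  # rank among the others is computed the same way, so under a correct
  # model the n_sim + 1 KS statistics are exchangeable
  pool <- cbind(y, sims)
  rk <- t(apply(pool, 1L, rank, ties.method = "average"))
  u_all <- (rk - 1 + matrix(stats::runif(n * (n_sim + 1L)), n)) /
    (n_sim + 1L)
  ks_stat <- function(u) {
    su <- sort(u)
    i <- seq_along(su)
    max(pmax(i / n - su, su - (i - 1) / n))
  }
  ks_all <- apply(u_all, 2L, ks_stat)
  ks_p <- (1 + sum(ks_all[-1L] >= ks_all[1L])) / (n_sim + 1)
  # center on the simulation-based expectation: the simulations redraw the
  # random effects, so the conditional fitted values are not a fair center
  mu <- rowMeans(sims)
  obs_var <- stats::var(y - mu)
  sim_var <- apply(sims, 2L, function(s) stats::var(s - mu))
  p_hi <- (1 + sum(sim_var >= obs_var)) / (n_sim + 1)
  p_lo <- (1 + sum(sim_var <= obs_var)) / (n_sim + 1)
  disp_p <- min(1, 2 * min(p_hi, p_lo))
  structure(list(ks_uniformity_p = ks_p, dispersion_p = disp_p,
                 n_sim = n_sim,
                 flag = if (ks_p < alpha || disp_p < alpha)
                   "deviation_significant" else "ok"),
            class = "fp_diagnostics")
}

#' Select the urbanization buffer radius
#'
#' Among model fits of the same response on urbanization covariates measured
#' at different buffer radii, returns the radius whose model has the lowest
#' AIC; exact ties go to the larger radius.
#'
#' @param fits named list of `fp_model_fit`, names are radii in metres.
#' @return list with `radius` (numeric) and `aic_table` (data.frame).
#' @export
select_radius <- function(fits) {
  radii <- as.numeric(names(fits))
  stopifnot(!anyNA(radii))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits compare different row sets")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- max(radii[aic == min(aic)])  # tie -> larger radius
  list(radius = best,
       aic_table = data.frame(radius = radii, aic = aic, row.names = NULL))
}

#' Two-sample Wilcoxon rank sum comparison
#'
#' Two-sided rank-sum test: exact null distribution when both samples have
#' at most 10 untied observations, otherwise the normal approximation with
#' tie-corrected variance (no continuity correction, so identical samples
#' give p = 1).
#'
#' @param values_a,values_b numeric samples.
#' @return list with `statistic` (W) and `p_value`.
#' @export
wilcoxon_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  ex <- length(values_a) <= 10 && length(values_b) <= 10 &&
    !anyDuplicated(c(values_a, values_b))
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, exact = ex, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
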