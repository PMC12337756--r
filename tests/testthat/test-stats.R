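test_that("predictor scaling centers and scales with recorded constants", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- scale_predictors(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0)
  expect_equal(sd(s$b), 1)
  expect_equal(attr(s, "scaling")$a, c(center = 2, scale = 1))
  # idempotent up to constants
  s2 <- scale_predictors(s, c("a", "b"))
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  expect_error(scale_predictors(data.frame(a = rep(1, 5)), "a"), "constant")
  set.seed(1)
  v <- rnorm(40)
  s3 <- scale_predictors(data.frame(v = v), "v")
  expect_equal(s3$v, (v - mean(v)) / sd(v), tolerance = 1e-12)
})

test_that("Spearman screen flags pairs at |rs| >= 0.5", {
  d <- data.frame(x = 1:20, y = 2 * (1:20), z = rnorm(20))
  sc <- collinearity_screen(d, c("x", "y"))
  expect_equal(sc$flagged$rs, 1)
  expect_length(sc$drop, 1)

  set.seed(2)
  d2 <- data.frame(u = runif(500), v = runif(500))
  sc2 <- collinearity_screen(d2, c("u", "v"))
  expect_equal(nrow(sc2$flagged), 0)

  # five-point example against the rank-difference formula
  x <- c(3, 1, 4, 15, 9); y <- c(2, 7, 18, 28, 1)
  dd <- rank(x) - rank(y)
  rs_formula <- 1 - 6 * sum(dd^2) / (5 * (25 - 1))
  sc3 <- collinearity_screen(data.frame(x = x, y = y), c("x", "y"))
  expect_equal(unname(sc3$rs["x", "y"]), rs_formula, tolerance = 1e-12)
})

test_that("response transformations map metrics onto family support", {
  expect_equal(transform_response(0.63, divide_by_10 = TRUE), 0.063)
  expect_equal(transform_response(0, add_epsilon = TRUE), 1e-10)
  expect_warning(v <- transform_response(c(0.5, 1)), "nudged")
  expect_equal(v[2], 1 - 1e-6)
  expect_error(transform_response(c(1, 0), family = "lognormal_log"),
               "positive")
  expect_error(transform_response(0.5, family = "beta_logit",
                                  divide_by_10 = FALSE, add_epsilon = FALSE),
               NA)
})

test_that("mixed-model fits report Wald z = coef/SE and the study's df", {
  cfg <- study_sim_config(n_sites = 19, n_per_site = 4,
                          true_coefs = c(intercept = -1, np_cov = -0.3,
                                         urbanization = 0.3),
                          seed = 5)
  s <- simulate_study(cfg)
  tab <- scale_predictors(s$table, c("np_cov", "urbanization_2000"))
  tab$.resp <- tab$.y_model
  f <- suppressWarnings(fit_glmm(tab, ".resp",
                                 c("np_cov", "urbanization_2000")))
  expect_s3_class(f, "fp_model_fit")
  expect_equal(f$estimates$z, f$estimates$estimate / f$estimates$std_error,
               tolerance = 1e-10)
  expect_true(all(f$estimates$std_error > 0))
  expect_true(all(f$estimates$p > 0 & f$estimates$p <= 1))
  # n = 76 rows; intercept + 2 slopes + 3 RE variances + dispersion = 7
  expect_equal(f$n, 76)
  expect_equal(f$resid_df, 69)
  expect_length(f$random_variances, 3)

  # multiplying a raw predictor by 1000 changes nothing after scaling
  tab2 <- s$table
  tab2$np_cov <- tab2$np_cov * 1000
  tab2 <- scale_predictors(tab2, c("np_cov", "urbanization_2000"))
  tab2$.resp <- tab2$.y_model
  f2 <- suppressWarnings(fit_glmm(tab2, ".resp",
                                  c("np_cov", "urbanization_2000")))
  expect_equal(f2$estimates$estimate, f$estimates$estimate,
               tolerance = 1e-6)

  # single-replicate recovery sanity for both families
  expect_lt(abs(f$estimates$estimate[f$estimates$term == "np_cov"] + 0.3),
            0.15)
  cfgl <- study_sim_config(n_sites = 25, n_per_site = 8,
                           family = "lognormal_log",
                           true_coefs = c(intercept = 0.3, np_cov = 0.2,
                                          urbanization = -0.2),
                           sigma = 0.3, response = "sinuosity", seed = 6)
  sl <- simulate_study(cfgl)
  tabl <- scale_predictors(sl$table, c("np_cov", "urbanization_2000"))
  tabl$.resp <- tabl$.y_model
  fl <- suppressWarnings(fit_glmm(tabl, ".resp",
                                  c("np_cov", "urbanization_2000"),
                                  family = "lognormal_log"))
  expect_lt(abs(fl$estimates$estimate[fl$estimates$term == "np_cov"] - 0.2),
            0.12)

  # continuous grouping terms can instead enter as fixed covariates
  ff <- suppressWarnings(fit_glmm(tab, ".resp",
                                  c("np_cov", "urbanization_2000"),
                                  random_as_fixed = TRUE))
  expect_length(ff$random_variances, 0)
  expect_true("duration_s" %in% ff$estimates$term)
})

test_that("diagnostics validate n_sim and flag deviations", {
  cfg <- study_sim_config(n_sites = 15, n_per_site = 5, seed = 7)
  s <- simulate_study(cfg)
  tab <- scale_predictors(s$table, c("np_cov", "urbanization_2000"))
  tab$.resp <- tab$.y_model
  f <- suppressWarnings(fit_glmm(tab, ".resp",
                                 c("np_cov", "urbanization_2000")))
  expect_error(residual_diagnostics(f, n_sim = 100), "250")
  d <- residual_diagnostics(f, n_sim = 250, seed = 1)
  expect_true(d$flag %in% c("ok", "deviation_significant"))
  expect_gt(d$ks_uniformity_p, 0)
  # determinism under a fixed seed
  d2 <- residual_diagnostics(f, n_sim = 250, seed = 1)
  expect_equal(d$ks_uniformity_p, d2$ks_uniformity_p)
})

test_that("radius selection minimizes AIC with ties to the larger radius", {
  mk <- function(aic, n = 50) structure(list(aic = aic, n = n),
                                        class = "fp_model_fit")
  fits <- list(`500` = mk(100), `1000` = mk(95), `2000` = mk(90))
  expect_equal(select_radius(fits)$radius, 2000)
  ties <- list(`500` = mk(90), `1000` = mk(90), `2000` = mk(90))
  expect_equal(select_radius(ties)$radius, 2000)
  best500 <- list(`500` = mk(80), `1000` = mk(95), `2000` = mk(90))
  expect_equal(select_radius(best500)$radius, 500)
  expect_error(select_radius(list(`500` = mk(1, n = 10),
                                  `1000` = mk(2, n = 12))), "row sets")
})

test_that("rank-sum comparison matches exhaustive enumeration", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # {1,2,3} vs {4,5,6}: enumerate all 20 assignments of ranks
  pooled <- 1:6
  combs <- combn(6, 3)
  w_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 6)
  p_enum <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  got <- wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p_value, p_enum)
  expect_equal(got$p_value, 0.1)

  set.seed(3)
  big <- wilcoxon_compare(rnorm(100), rnorm(100, 5))
  expect_lt(big$p_value, 1e-6)
})
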