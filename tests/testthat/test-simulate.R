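test_that("von Mises sampler hits its closed-form mean cosine", {
  expect_equal(vm_mean_cosine(0), 0)
  expect_equal(kappa_for_c(0), 0)
  for (ct in c(0.3, 0.6, 0.9)) {
    k <- kappa_for_c(ct)
    expect_equal(vm_mean_cosine(k), ct, tolerance = 1e-8)
    set.seed(1)
    draws <- rvonmises(20000, k)
    expect_lt(abs(mean(cos(draws)) - ct), 0.02)
    expect_lt(abs(mean(draws)), 0.05)  # symmetric about 0
  }
  set.seed(2)
  u <- rvonmises(5000, 0)
  expect_true(all(u > -pi & u <= pi))
})

test_that("simulators are pure functions of config and seed", {
  cfg <- track_sim_config(n_steps = 100, seed = 9)
  a <- simulate_track(cfg); b <- simulate_track(cfg)
  expect_identical(a$trajectory$points, b$trajectory$points)
  expect_identical(a$events, b$events)

  t1 <- simulate_transect(40, seed = 4)
  expect_identical(t1, simulate_transect(40, seed = 4))

  l1 <- simulate_landscape(seed = 5)
  expect_identical(l1$sealing$values, simulate_landscape(seed = 5)$sealing$values)

  s1 <- simulate_study(study_sim_config(seed = 6))
  expect_identical(s1$table, simulate_study(study_sim_config(seed = 6))$table)
})

test_that("simulated tracks round-trip through the package readers", {
  sim <- simulate_track(track_sim_config(n_steps = 150, seed = 10))
  td <- withr::local_tempdir()
  write_track(sim$trajectory, file.path(td, "trk.csv"))
  utils::write.csv(sim$events, file.path(td, "ev.csv"), row.names = FALSE)
  expect_no_warning({
    tr <- read_track(file.path(td, "trk.csv"))
    ev <- read_events(file.path(td, "ev.csv"))
  })
  expect_equal(nrow(tr$points), nrow(sim$trajectory$points))
  expect_equal(nrow(ev), nrow(sim$events))
})

test_that("CRW limits behave: straight at c -> 1, no stops at rate 0", {
  near_straight <- simulate_track(track_sim_config(
    n_steps = 300, step_mean = 1, step_cv = 0, c_target = 0.999,
    stop_rate = 0, gap_prob = 0, seed = 11))
  pt <- consolidate(near_straight$trajectory, near_straight$events)
  expect_lt(track_sinuosity(pt), 0.05 * 2)  # well under the c = 0 value

  no_stop <- simulate_track(track_sim_config(n_steps = 100, stop_rate = 0,
                                             seed = 12))
  expect_equal(nrow(no_stop$events), 0)
  expect_equal(no_stop$truth$stopping_share, 0)
  ptn <- consolidate(no_stop$trajectory, no_stop$events)
  expect_equal(unname(time_budget(ptn)["stopping"]), 0)
})

test_that("transect simulator obeys its distribution targets", {
  const <- simulate_transect(5, mean = 9.2, sd = 0, seed = 1)
  expect_equal(const$np_cover_pct, rep(9.2, 5))
  expect_equal(np_coverage(const), 9.2)
  one <- simulate_transect(1, seed = 2)
  expect_equal(np_coverage(one), one$np_cover_pct)
  big <- simulate_transect(10000, mean = 20, sd = 10, seed = 3)
  expect_lt(abs(np_coverage(big) - 20), 1)  # law of large numbers
  expect_true(all(big$np_cover_pct >= 0 & big$np_cover_pct <= 100))
})

test_that("landscape simulator supports imputation and gradient checks", {
  full <- simulate_landscape(coverage_fraction = 1, seed = 21)
  expect_false(anyNA(full$sealing$values))
  out <- impute_sealing(full$sealing, full$biotopes)
  expect_equal(out$values, full$sealing$values)  # identity when covered

  part <- simulate_landscape(coverage_fraction = 0.6, noise_sd = 4,
                             seed = 22)
  got <- class_sealing_means(part$sealing, part$biotopes)
  for (cl in names(part$truth$class_means)) {
    ncl <- sum(part$biotopes$values == cl & !is.na(part$sealing$values))
    if (ncl > 30)
      expect_lt(abs(got[cl] - part$truth$class_means[cl]),
                2 * 4 / sqrt(ncl) + 0.5)
  }

  mono <- simulate_landscape(monocentric = TRUE, coverage_fraction = 1,
                             seed = 23)
  ctr <- c(mono$site_centers$x, mono$site_centers$y)
  expect_gte(zonal_urbanization(mono$sealing_full, ctr, 30),
             zonal_urbanization(mono$sealing_full, ctr, 90))
})

test_that("study simulator matches the pipeline schemas and null case", {
  s <- simulate_study(study_sim_config(n_sites = 10, n_per_site = 4,
                                       include_sex = TRUE,
                                       true_coefs = c(intercept = -1,
                                                      np_cov = 0,
                                                      urbanization = 0,
                                                      sexmale = 0),
                                       species = "PR", seed = 30))
  expect_true(all(c("individual_id", "species", "sex", "site_id",
                    "duration_s", "flight_speed", "stopping", "nectaring",
                    "resting", "sinuosity") %in% names(s$summaries)))
  expect_true(all(c("site_id", "urbanization_500", "urbanization_1000",
                    "urbanization_2000", "habitat_area_ha") %in%
                    names(s$covariates)))
  expect_equal(nrow(s$summaries), 40)
  expect_true(all(s$table$.y_model > 0 & s$table$.y_model < 1))

  # site random-SD monotonicity: doubling the SD inflates the estimated
  # between-site spread of the linear predictor
  spread <- function(sd_site, seed) {
    cfg <- study_sim_config(n_sites = 40, n_per_site = 10,
                            true_coefs = c(intercept = -1, np_cov = 0,
                                           urbanization = 0),
                            random_sd = c(site = sd_site,
                                          habitat_area = 0.01,
                                          duration = 0.01),
                            phi = 200, seed = seed)
    tab <- simulate_study(cfg)$table
    site_means <- tapply(qlogis(tab$.y_model), tab$site_id, mean)
    sd(site_means)
  }
  expect_gt(mean(sapply(41:44, function(s) spread(0.8, s))),
            mean(sapply(41:44, function(s) spread(0.2, s))))
})
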