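# Synthetic-data generators: correlated random walks with annotated stop
# bouts and GPS jitter, transect coverage tables, sealing/biotope landscapes,
# and a study-level simulator with known regression coefficients. Every
# generator is a pure function of (config, seed).

#' Mean turning-angle cosine of a von Mises distribution
#'
#' For von Mises(0, kappa) turning increments the mean cosine has the closed
#' form I1(kappa)/I0(kappa), which makes kappa an analytic dial for path
#' straightness.
#'
#' @param kappa concentration parameter (>= 0).
#' @return mean cosine in \[0, 1).
#' @export
vm_mean_cosine <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises concentration for a target mean cosine
#'
#' Inverse of [vm_mean_cosine()] by root finding.
#'
#' @param c_target mean cosine in \[0, 0.999\].
#' @return kappa.
#' @export
kappa_for_c <- function(c_target) {
  stopifnot(c_target >= 0, c_target <= 0.999)
  if (c_target == 0) return(0)
  stats::uniroot(function(k) vm_mean_cosine(k) - c_target,
                 interval = c(1e-8, 2000), tol = 1e-10)$root
}

#' Draw von Mises(0, kappa) angles
#'
#' Best-Fisher rejection sampler, vectorized in batches; kappa = 0 falls
#' back to uniform angles.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi\].
#' @export
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric())
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  out[seq_len(n)]
}

#' Configuration for the correlated-random-walk track simulator
#'
#' Defaults emulate the field conditions of the tracking study: ~1-s fixes,
#' mean step (= flight speed) of 0.8 m/s, step-length CV 0.5, heading
#' persistence c = 0.6, about 1.5 stop bouts per flight minute lasting 20 s
#' on average, 5 cm stationary GPS/observer jitter, and rare 1-s signal
#' dropouts.
#'
#' @param n_steps number of flight steps (one per second).
#' @param step_mean mean step length p, metres (equals true flight speed in
#'   m/s at 1-s fixes).
#' @param step_cv step-length coefficient of variation b (gamma steps).
#' @param c_target mean turning-angle cosine (sets the von Mises kappa);
#'   alternatively pass `kappa` directly.
#' @param kappa von Mises concentration; overrides `c_target` when given.
#' @param stop_rate stop initiations per flight minute.
#' @param stop_duration_mean mean stop length, s (geometric).
#' @param activity_probs named probabilities over nectaring, resting,
#'   basking, oviposition.
#' @param jitter_sd isotropic jitter SD of stationary fixes, m.
#' @param gap_prob per-second probability that an interior fix is lost.
#' @param seed RNG seed.
#' @return list of class `fp_track_sim_config`.
#' @export
track_sim_config <- function(n_steps = 300L, step_mean = 0.8, step_cv = 0.5,
                             c_target = 0.6, kappa = NULL, stop_rate = 1.5,
                             stop_duration_mean = 20,
                             activity_probs = c(nectaring = 0.45,
                                                resting = 0.35,
                                                basking = 0.15,
                                                oviposition = 0.05),
                             jitter_sd = 0.05, gap_prob = 0.01, seed = 1L) {
  stopifnot(n_steps >= 2, step_mean > 0, step_cv >= 0, stop_rate >= 0,
            stop_duration_mean >= 1, jitter_sd >= 0,
            gap_prob >= 0, gap_prob < 1,
            abs(sum(activity_probs) - 1) < 1e-8)
  if (is.null(kappa)) kappa <- kappa_for_c(c_target)
  structure(list(n_steps = as.integer(n_steps), step_mean = step_mean,
                 step_cv = step_cv, kappa = kappa, stop_rate = stop_rate,
                 stop_duration_mean = stop_duration_mean,
                 activity_probs = activity_probs, jitter_sd = jitter_sd,
                 gap_prob = gap_prob, seed = as.integer(seed)),
            class = "fp_track_sim_config")
}

.rsteps <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Simulate a correlated-random-walk track with stop bouts
#'
#' Headings evolve by von Mises(0, kappa) increments and step lengths are
#' gamma with mean p and CV b, one step per second. Stop bouts freeze the
#' true position and emit jittered fixes; a field-style event log records
#' each bout with its activity. Interior fixes are then dropped with
#' probability `gap_prob` to emulate signal loss. Stops never touch the
#' first or last fix, so the event log's time budget is exactly recoverable.
#'
#' @param cfg an `fp_track_sim_config`.
#' @param individual_id,species,sex,site_id metadata for the trajectory.
#' @return list with `trajectory` (an `fp_trajectory`), `events` (stop
#'   event table) and `truth`: the generating p, c, b, the closed-form
#'   sinuosity 2\[p((1+c)/(1-c)+b^2)\]^(-1/2), realized mean flight speed, and
#'   realized stopping/nectaring/resting shares.
#' @export
simulate_track <- function(cfg, individual_id = "sim1", species = "CP",
                           sex = "unknown", site_id = "site1") {
  stopifnot(inherits(cfg, "fp_track_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_steps
  turns <- c(stats::runif(1, -pi, pi), rvonmises(n - 1L, cfg$kappa))
  headings <- cumsum(turns)
  steps <- .rsteps(n, cfg$step_mean, cfg$step_cv)
  p_stop <- min(cfg$stop_rate / 60, 1)

  t <- 0L; x <- 0; y <- 0
  ts <- c(0L); xs <- c(0); ys <- c(0)
  ev <- list()
  for (i in seq_len(n)) {
    x <- x + steps[i] * cos(headings[i])
    y <- y + steps[i] * sin(headings[i])
    t <- t + 1L
    ts <- c(ts, t); xs <- c(xs, x); ys <- c(ys, y)
    if (i < n && stats::runif(1) < p_stop) {
      d <- stats::rgeom(1, 1 / cfg$stop_duration_mean) + 1L
      act <- sample(names(cfg$activity_probs), 1L,
                    prob = cfg$activity_probs)
      ev[[length(ev) + 1L]] <- data.frame(
        start_s = t, end_s = t + d, activity = act)
      jit <- matrix(stats::rnorm(2L * d, 0, cfg$jitter_sd), ncol = 2L)
      ts <- c(ts, t + seq_len(d))
      xs <- c(xs, x + jit[, 1L]); ys <- c(ys, y + jit[, 2L])
      t <- t + d
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start_s = numeric(), end_s = numeric(),
               activity = character())

  keep <- rep(TRUE, length(ts))
  if (cfg$gap_prob > 0 && length(ts) > 2L) {
    interior <- seq(2L, length(ts) - 1L)
    keep[interior] <- stats::runif(length(interior)) >= cfg$gap_prob
  }
  pts <- data.frame(t = ts[keep], x = xs[keep], y = ys[keep])
  traj <- suppressWarnings(trajectory(
    pts, individual_id = individual_id, species = species, sex = sex,
    site_id = site_id, crs = "simulated-planar"))

  c_theory <- vm_mean_cosine(cfg$kappa)
  span <- t
  stop_secs <- if (nrow(events)) sum(events$end_s - events$start_s) else 0
  act_secs <- function(a) if (nrow(events))
    sum((events$end_s - events$start_s)[events$activity == a]) else 0
  truth <- list(
    p = cfg$step_mean, c = c_theory, b = cfg$step_cv,
    sinuosity = if (c_theory >= 1) 0 else
      2 * (cfg$step_mean * ((1 + c_theory) / (1 - c_theory) +
                              cfg$step_cv^2))^(-0.5),
    speed = sum(steps) / n,
    stopping_share = stop_secs / span,
    nectaring_share = act_secs("nectaring") / span,
    resting_share = act_secs("resting") / span,
    duration_s = span)
  list(trajectory = traj, events = events, truth = truth)
}

#' Simulate a transect nectar-coverage table
#'
#' I.i.d. per-segment percent covers from a beta distribution on \[0, 100\]
#' matched to the requested mean and SD by the method of moments (constant
#' when `sd = 0`). Defaults mirror the observed coverage distribution of the
#' study transects (mean 9.2%, SD 8.3%).
#'
#' @param n_segments number of 1-m segments (>= 1).
#' @param mean,sd target percent mean and SD.
#' @param seed RNG seed.
#' @return data.frame `segment, np_cover_pct`.
#' @export
simulate_transect <- function(n_segments, mean = 9.2, sd = 8.3, seed = 1L) {
  stopifnot(n_segments >= 1, mean >= 0, mean <= 100, sd >= 0)
  set.seed(seed)
  if (sd == 0) {
    v <- rep(mean, n_segments)
  } else {
    m <- mean / 100; s2 <- (sd / 100)^2
    if (s2 >= m * (1 - m))
      stop("sd too large for a beta distribution with this mean")
    nu <- m * (1 - m) / s2 - 1
    v <- 100 * stats::rbeta(n_segments, m * nu, (1 - m) * nu)
  }
  data.frame(segment = seq_len(n_segments), np_cover_pct = v)
}

# repeated 3x3 box smoothing with edge replication
.smooth_matrix <- function(m, passes = 6L) {
  for (k in seq_len(passes)) {
    up <- m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
    dn <- m[c(seq(2L, nrow(m)), nrow(m)), , drop = FALSE]
    lf <- m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
    rt <- m[, c(seq(2L, ncol(m)), ncol(m)), drop = FALSE]
    m <- (m + up + dn + lf + rt) / 5
  }
  m
}

#' Simulate a sealing/biotope landscape
#'
#' A smooth random field is quantile-cut into biotope classes; percent
#' sealing is the class mean plus cell noise, observed only over a smooth
#' random subregion covering `coverage_fraction` of the grid (emulating a
#' sealing map that exists for only part of the study region). The
#' monocentric option instead lets sealing decay with distance from the grid
#' center, giving a rural-urban gradient.
#'
#' @param n_classes number of biotope classes.
#' @param coverage_fraction fraction of cells where sealing is observed.
#' @param grid_dim `c(nrow, ncol)`, at least 50 x 50.
#' @param cellsize cell edge, m (default 2 as in the study's sealing grid).
#' @param noise_sd cell-level sealing noise SD (percent points).
#' @param monocentric logical; sealing decays from the grid center.
#' @param seed RNG seed.
#' @return list of class `fp_landscape`: `sealing` (masked `fp_raster`),
#'   `sealing_full` (unmasked truth), `biotopes` (class `fp_raster`),
#'   `site_centers`, `habitat_polygons`, and `truth` (generating class
#'   means).
#' @export
simulate_landscape <- function(n_classes = 4L, coverage_fraction = 0.6,
                               grid_dim = c(100L, 100L), cellsize = 2,
                               noise_sd = 5, monocentric = FALSE,
                               seed = 1L) {
  stopifnot(all(grid_dim >= 50L), n_classes >= 1L,
            coverage_fraction > 0, coverage_fraction <= 1)
  set.seed(seed)
  nr <- grid_dim[1L]; nc <- grid_dim[2L]
  f1 <- .smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc))
  qs <- stats::quantile(f1, probs = seq(0, 1, length.out = n_classes + 1L))
  cls <- matrix(paste0("C", findInterval(f1, qs[-c(1L, n_classes + 1L)]) + 1L),
                nr, nc)
  class_means <- stats::setNames(
    seq(5, 85, length.out = n_classes) + stats::runif(n_classes, -3, 3),
    paste0("C", seq_len(n_classes)))
  ctr_x <- nc * cellsize / 2; ctr_y <- nr * cellsize / 2
  if (monocentric) {
    cx <- ( matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) * cellsize
    cy <- ((nr - matrix(rep(seq_len(nr), nc), nr, nc) + 0.5)) * cellsize
    dist <- sqrt((cx - ctr_x)^2 + (cy - ctr_y)^2)
    base <- 95 * exp(-dist / (max(dist) / 3))
  } else {
    base <- matrix(class_means[cls], nr, nc)
  }
  sealing_full <- pmin(pmax(base + stats::rnorm(nr * nc, 0, noise_sd), 0), 100)
  f2 <- .smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc))
  observed <- f2 <= stats::quantile(f2, coverage_fraction)
  if (coverage_fraction >= 1) observed[] <- TRUE
  sealing <- sealing_full
  sealing[!observed] <- NA
  half <- 50
  poly <- list(outer = rbind(c(ctr_x - half, ctr_y - half),
                             c(ctr_x + half, ctr_y - half),
                             c(ctr_x + half, ctr_y + half),
                             c(ctr_x - half, ctr_y + half)),
               holes = list())
  structure(list(
    sealing = grid_raster(sealing, cellsize = cellsize),
    sealing_full = grid_raster(sealing_full, cellsize = cellsize),
    biotopes = grid_raster(cls, cellsize = cellsize),
    site_centers = data.frame(site_id = "site1", x = ctr_x, y = ctr_y),
    habitat_polygons = list(site1 = poly),
    truth = list(class_means = class_means, monocentric = monocentric)),
    class = "fp_landscape")
}

#' Configuration for the study-level simulator
#'
#' Defaults emulate the study design: 29 grassland sites along a rural-urban
#' gradient (site-level urbanization mean 31.9%, SD 17.7%), a handful of
#' tracked individuals per site, per-individual nectar coverage mean 9.2%,
#' SD 8.3%, and track durations around 5.6 min. Effects are specified on the
#' linear-predictor (logit or log) scale for predictors scaled to unit SD.
#'
#' @param n_sites number of study sites.
#' @param n_per_site individuals per site.
#' @param species species label written into the tables.
#' @param include_sex add a sex covariate (males vs females).
#' @param true_coefs named effects: `intercept`, `np_cov`, `urbanization`,
#'   and optionally `sexmale`.
#' @param family `"beta_logit"` or `"lognormal_log"`.
#' @param phi beta precision (ignored for lognormal).
#' @param sigma response-scale SD for lognormal (ignored for beta).
#' @param random_sd named SDs of the random intercepts for `site`,
#'   `habitat_area`, `duration`.
#' @param urb_mean,urb_sd site urbanization distribution (percent).
#' @param np_mean,np_sd individual nectar-coverage distribution (percent).
#' @param response name of the focal response column to generate.
#' @param seed RNG seed.
#' @return list of class `fp_study_sim_config`.
#' @export
study_sim_config <- function(n_sites = 29L, n_per_site = 5L, species = "CP",
                             include_sex = FALSE,
                             true_coefs = c(intercept = -1, np_cov = -0.15,
                                            urbanization = 0.15),
                             family = c("beta_logit", "lognormal_log"),
                             phi = 30, sigma = 0.3,
                             random_sd = c(site = 0.2, habitat_area = 0.15,
                                           duration = 0.15),
                             urb_mean = 31.9, urb_sd = 17.7,
                             np_mean = 9.2, np_sd = 8.3,
                             response = "flight_speed", seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_sites >= 2, n_per_site >= 1, phi > 0, sigma > 0,
            all(is.finite(true_coefs)))
  structure(list(n_sites = as.integer(n_sites),
                 n_per_site = as.integer(n_per_site), species = species,
                 include_sex = include_sex, true_coefs = true_coefs,
                 family = family, phi = phi, sigma = sigma,
                 random_sd = random_sd, urb_mean = urb_mean, urb_sd = urb_sd,
                 np_mean = np_mean, np_sd = np_sd, response = response,
                 seed = as.integer(seed)),
            class = "fp_study_sim_config")
}

#' Simulate a full study table with known coefficients
#'
#' Generates site covariates and per-individual responses from the stated
#' beta (logit link) or lognormal (log link) model with random intercepts
#' for site, habitat area and track duration, in the exact schema the
#' pipeline's `summaries.csv`/`covariates.csv` use, so the inference stage
#' can be validated by parameter recovery.
#'
#' @param cfg an `fp_study_sim_config`.
#' @return list with `summaries` (per-individual metric table),
#'   `covariates` (per-site table), `table` (joined analysis-ready table
#'   with the raw focal response), and `truth` (generating coefficients and
#'   scales).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "fp_study_sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_sites; np <- cfg$n_per_site; n <- ns * np
  site_id <- sprintf("S%02d", seq_len(ns))
  urb <- pmin(pmax(stats::rnorm(ns, cfg$urb_mean, cfg$urb_sd), 0.5), 95)
  ha <- round(exp(stats::rnorm(ns, log(3), 0.7)), 2)
  covars <- data.frame(site_id = site_id,
                       urbanization_500 = pmin(pmax(
                         urb + stats::rnorm(ns, 0, 4), 0.5), 95),
                       urbanization_1000 = pmin(pmax(
                         urb + stats::rnorm(ns, 0, 2), 0.5), 95),
                       urbanization_2000 = urb,
                       habitat_area_ha = ha)
  ind <- data.frame(
    individual_id = sprintf("I%03d", seq_len(n)),
    species = cfg$species,
    sex = if (cfg$include_sex)
      sample(c("female", "male"), n, replace = TRUE) else "unknown",
    site_id = rep(site_id, each = np),
    duration_s = pmin(pmax(round(stats::rnorm(n, 336, 158)), 60), 720),
    np_cov = pmin(pmax(stats::rnorm(n, cfg$np_mean, cfg$np_sd), 0.3), 60))
  tab <- merge(ind, covars, by = "site_id", sort = FALSE)
  tab <- tab[order(tab$individual_id), ]
  rownames(tab) <- NULL

  z <- function(v) (v - mean(v)) / stats::sd(v)
  u_site <- stats::rnorm(ns, 0, cfg$random_sd["site"])
  u_ha <- stats::rnorm(ns, 0, cfg$random_sd["habitat_area"])
  dur_lv <- unique(tab$duration_s)
  u_dur <- stats::rnorm(length(dur_lv), 0, cfg$random_sd["duration"])
  eta <- cfg$true_coefs["intercept"] +
    cfg$true_coefs["np_cov"] * z(tab$np_cov) +
    cfg$true_coefs["urbanization"] * z(tab$urbanization_2000) +
    u_site[match(tab$site_id, site_id)] +
    u_ha[match(tab$site_id, site_id)] +
    u_dur[match(tab$duration_s, dur_lv)]
  if (cfg$include_sex)
    eta <- eta + cfg$true_coefs["sexmale"] * (tab$sex == "male")
  eta <- as.numeric(eta)

  if (cfg$family == "beta_logit") {
    mu <- stats::plogis(eta)
    ymodel <- stats::rbeta(n, mu * cfg$phi, (1 - mu) * cfg$phi)
  } else {
    # glmmTMB's lognormal: mean exp(eta), constant SD on the data scale
    mu <- exp(eta)
    sdlog <- sqrt(log(1 + cfg$sigma^2 / mu^2))
    ymodel <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
  }
  # write the focal response back on its raw reporting scale
  raw <- ymodel
  if (cfg$response %in% c("flight_speed", "sinuosity") &&
      cfg$family == "beta_logit")
    raw <- ymodel * 10
  summaries <- data.frame(
    tab[c("individual_id", "species", "sex", "site_id", "duration_s")],
    path_m = NA_real_, flight_speed = NA_real_, stopping = NA_real_,
    nectaring = NA_real_, resting = NA_real_, sinuosity = NA_real_,
    n_stops = NA_integer_, n_segments = 1L)
  summaries[[cfg$response]] <- raw
  tab[[cfg$response]] <- raw
  tab$.y_model <- ymodel
  list(summaries = summaries, covariates = covars, table = tab,
       truth = list(coefs = cfg$true_coefs, family = cfg$family,
                    phi = cfg$phi, sigma = cfg$sigma,
                    random_sd = cfg$random_sd, response = cfg$response))
}
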