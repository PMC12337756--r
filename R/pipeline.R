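# Orchestration: tracks + events + transects + landscape -> summaries ->
# covariates -> models -> report, plus a reproduction mode that fits the
# model roster directly to a pre-derived per-individual table.

#' Default model roster
#'
#' The response-by-species models of the inference stage: for each species,
#' beta (logit) models of flight speed (divided by 10), stopping, nectaring
#' and resting time shares (plus 1e-10), and a tortuosity model — lognormal
#' for C. pamphilus, beta on sinuosity/10 for P. rapae, whose model also
#' carries the sex factor (as do all P. rapae models).
#'
#' @return data.frame with one row per model: species, response, family,
#'   divide_by_10, add_epsilon, with_sex.
#' @export
model_roster <- function() {
  rbind(
    data.frame(species = "CP",
               response = c("flight_speed", "stopping", "nectaring",
                            "resting", "sinuosity"),
               family = c(rep("beta_logit", 4L), "lognormal_log"),
               divide_by_10 = c(TRUE, FALSE, FALSE, FALSE, FALSE),
               add_epsilon = c(FALSE, TRUE, TRUE, TRUE, FALSE),
               with_sex = FALSE),
    data.frame(species = "PR",
               response = c("flight_speed", "stopping", "nectaring",
                            "resting", "sinuosity"),
               family = "beta_logit",
               divide_by_10 = c(TRUE, FALSE, FALSE, FALSE, TRUE),
               add_epsilon = c(FALSE, TRUE, TRUE, TRUE, FALSE),
               with_sex = TRUE))
}

# md5 of an R object via its serialized JSON (for run provenance)
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Fit the model roster to a per-individual analysis table
#'
#' The reproduction harness: given a table with one row per tracked
#' individual carrying the movement metrics, nectar coverage, urbanization
#' at the candidate buffer radii, habitat area and track duration (the shape
#' of the study's deposited dataset), this scales the predictors per
#' species, screens them for collinearity, selects the buffer radius by
#' total AIC across the roster (ties to the larger radius), fits each model
#' and runs residual diagnostics. P. rapae rows of unknown sex are dropped.
#'
#' @param table data.frame with columns `species` (`CP`/`PR`), `sex`,
#'   `site_id`, `duration_s`, `habitat_area_ha`, `np_cov`,
#'   `urbanization_<r>` for each radius, and the metric columns
#'   `flight_speed`, `stopping`, `nectaring`, `resting`, `sinuosity`.
#' @param roster model roster (see [model_roster()]); rows for species
#'   absent from the table are skipped.
#' @param radii candidate buffer radii (m).
#' @param n_sim,seed passed to [residual_diagnostics()].
#' @return list of class `fp_run`: `fits` (named
#'   `<species>.<response>`), `diagnostics`, `radius`, `aic_table`,
#'   `screen` (per species), `models_table` (tidy coefficient table) and
#'   `descriptives`.
#' @export
reproduce_models <- function(table, roster = model_roster(),
                             radii = c(500, 1000, 2000), n_sim = 250L,
                             seed = 1L) {
  stopifnot(all(c("species", "site_id", "np_cov") %in% names(table)))
  urb_cols <- paste0("urbanization_", radii)
  stopifnot(all(urb_cols %in% names(table)))
  roster <- roster[roster$species %in% unique(table$species), , drop = FALSE]

  species_tabs <- list(); screens <- list()
  for (sp in unique(roster$species)) {
    sub <- table[table$species == sp, , drop = FALSE]
    if (sp == "PR") sub <- sub[sub$sex != "unknown", , drop = FALSE]
    sub <- scale_predictors(sub, c("np_cov", urb_cols))
    screens[[sp]] <- collinearity_screen(sub, c("np_cov", urb_cols[1L]))
    species_tabs[[sp]] <- sub
  }

  fit_one <- function(row, sub, radius) {
    y <- transform_response(sub[[row$response]],
                            divide_by_10 = row$divide_by_10,
                            add_epsilon = row$add_epsilon,
                            family = row$family)
    sub$.resp <- y
    fixed <- c("np_cov", paste0("urbanization_", radius))
    if (row$with_sex) fixed <- c(fixed, "sex")
    fit_glmm(sub, ".resp", fixed, family = row$family)
  }

  # radius selection: total AIC of the roster at each candidate radius
  if (nrow(roster) > 0L) {
    aic_tot <- sapply(radii, function(r) {
      sum(vapply(seq_len(nrow(roster)), function(i) {
        row <- roster[i, ]
        fit_one(row, species_tabs[[row$species]], r)$aic
      }, numeric(1)))
    })
  } else {
    aic_tot <- rep(NA_real_, length(radii))
  }
  radius <- if (all(is.na(aic_tot))) max(radii) else
    max(radii[aic_tot == min(aic_tot)])
  aic_table <- data.frame(radius = radii, total_aic = aic_tot)

  fits <- list(); diags <- list(); rows <- list()
  for (i in seq_len(nrow(roster))) {
    row <- roster[i, ]
    key <- paste(row$species, row$response, sep = ".")
    f <- fit_one(row, species_tabs[[row$species]], radius)
    dg <- residual_diagnostics(f, n_sim = n_sim, seed = seed)
    fits[[key]] <- f
    diags[[key]] <- dg
    est <- f$estimates
    rows[[key]] <- data.frame(
      model = key, species = row$species, response = row$response,
      family = row$family, divide_by_10 = row$divide_by_10,
      add_epsilon = row$add_epsilon, radius = radius, est,
      ks_flag = dg$flag, stringsAsFactors = FALSE)
  }
  models_table <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(model = character(), species = character(),
               response = character(), family = character(),
               divide_by_10 = logical(), add_epsilon = logical(),
               radius = numeric(), term = character(), estimate = numeric(),
               std_error = numeric(), z = numeric(), p = numeric(),
               ks_flag = character())

  structure(list(fits = fits, diagnostics = diags, radius = radius,
                 aic_table = aic_table, screen = screens,
                 models_table = models_table,
                 descriptives = descriptive_comparison(table)),
            class = "fp_run")
}

#' Species-level descriptive comparison
#'
#' Mean, SD and a two-sided Wilcoxon rank sum comparison between the two
#' species for each movement metric present.
#'
#' @param table per-individual table with `species` and metric columns.
#' @param metrics metric column names to compare.
#' @return data.frame with per-species mean/SD and the rank-sum p-value.
#' @export
descriptive_comparison <- function(table,
                                   metrics = c("flight_speed", "stopping",
                                               "nectaring", "resting",
                                               "sinuosity")) {
  metrics <- intersect(metrics, names(table))
  sps <- sort(unique(table$species))
  rows <- lapply(metrics, function(m) {
    v <- lapply(sps, function(sp)
      stats::na.omit(table[[m]][table$species == sp]))
    out <- data.frame(metric = m)
    for (k in seq_along(sps)) {
      out[[paste0("mean_", sps[k])]] <- mean(v[[k]])
      out[[paste0("sd_", sps[k])]] <- stats::sd(v[[k]])
    }
    out$wilcoxon_p <- if (length(sps) == 2L &&
                          all(lengths(v) > 0L))
      wilcoxon_compare(v[[1L]], v[[2L]])$p_value else NA_real_
    out
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Reads per-individual tracks, event logs and transects, consolidates
#' stops, derives movement summaries, assembles covariates (from landscape
#' inputs or a ready covariate table), fits the model roster and writes
#' `summaries.csv`, `covariates.csv`, `models.csv`, `models.json`,
#' `diagnostics.csv` and `run.log` into the output directory. If the
#' configuration instead provides `table` (a pre-derived per-individual
#' table in the deposited-data shape), trajectory stages are skipped and
#' models are fitted directly.
#'
#' @param config list with elements:
#'   * `individuals`: data.frame (or CSV path) with columns
#'     `individual_id, species, sex, site_id, track, events, transect`
#'     (file paths);
#'   * `covariates`: per-site covariate data.frame/CSV
#'     (`site_id`, `urbanization_<r>`, `habitat_area_ha`), or `landscape`:
#'     list with `sealing`, `biotopes` (ASCII grids), `sites`,
#'     `habitats` (GeoJSON) to derive them;
#'   * `table`: reproduction-mode input table (replaces all of the above);
#'   * options `gap_threshold_s` (3), `speed_definition` (`"flying"`),
#'     `weighting` (`"length"`), `radii` (500/1000/2000), `n_sim` (250),
#'     `seed` (1), `out_dir` (required).
#' @return the `fp_run` object, with `summaries` and `covariates` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  gap <- config$gap_threshold_s %||% 3
  radii <- config$radii %||% c(500, 1000, 2000)
  seed <- config$seed %||% 1L
  n_sim <- config$n_sim %||% 250L
  log_lines <- c(sprintf("flutterpath %s",
                         as.character(utils::packageVersion("flutterpath"))),
                 sprintf("R %s", getRversion()),
                 sprintf("config_hash %s", .config_hash(
                   config[setdiff(names(config), "table")])),
                 sprintf("seed %d", as.integer(seed)))

  if (!is.null(config$table)) {
    tab <- config$table
    if (is.character(tab)) tab <- utils::read.csv(tab)
    log_lines <- c(log_lines, "mode reproduction (trajectory stages skipped)")
    summaries <- NULL; covars <- NULL
  } else {
    ind <- config$individuals
    if (is.character(ind)) ind <- utils::read.csv(ind)
    srows <- list()
    for (i in seq_len(nrow(ind))) {
      id <- ind$individual_id[i]
      res <- tryCatch({
        traj <- read_track(ind$track[i], individual_id = id,
                           species = ind$species[i], sex = ind$sex[i],
                           site_id = ind$site_id[i])
        ev <- read_events(ind$events[i])
        pt <- consolidate(traj, ev, gap_threshold_s = gap)
        s <- movement_summary(
          pt, weighting = config$weighting %||% "length",
          speed_definition = config$speed_definition %||% "flying")
        s$np_cov <- np_coverage(read_transect(ind$transect[i]))
        s
      }, error = function(e)
        stop(sprintf("stage trajectory/metrics failed for '%s': %s",
                     id, conditionMessage(e)), call. = FALSE))
      srows[[i]] <- res
    }
    summaries <- do.call(rbind, srows)

    if (!is.null(config$covariates)) {
      covars <- config$covariates
      if (is.character(covars)) covars <- utils::read.csv(covars)
    } else if (!is.null(config$landscape)) {
      ls <- config$landscape
      sealing <- read_ascii_grid(ls$sealing)
      biotopes <- read_ascii_grid(ls$biotopes)
      biotopes$values <- matrix(as.character(biotopes$values),
                                nrow(biotopes$values))
      filled <- impute_sealing(sealing, biotopes)
      covars <- site_covariates(read_sites_geojson(ls$sites), filled,
                                read_polygons_geojson(ls$habitats),
                                radii = radii)
    } else stop("config needs either covariates or landscape inputs")
    utils::write.csv(summaries, file.path(out, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(covars, file.path(out, "covariates.csv"),
                     row.names = FALSE)
    tab <- merge(summaries, covars, by = "site_id", sort = FALSE)
  }

  run <- reproduce_models(tab, roster = config$roster %||% model_roster(),
                          radii = radii, n_sim = n_sim, seed = seed)
  run$summaries <- summaries
  run$covariates <- if (is.null(config$table)) covars else NULL

  utils::write.csv(run$models_table, file.path(out, "models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(radius = run$radius, aic_table = run$aic_table,
         models = run$models_table),
    file.path(out, "models.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  diag_df <- do.call(rbind, lapply(names(run$diagnostics), function(k) {
    d <- run$diagnostics[[k]]
    data.frame(model = k, ks_uniformity_p = d$ks_uniformity_p,
               dispersion_p = d$dispersion_p, n_sim = d$n_sim,
               flag = d$flag)
  }))
  utils::write.csv(diag_df, file.path(out, "diagnostics.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines, sprintf("selected_radius %g", run$radius),
                 sprintf("models %d", length(run$fits)))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a run report
#'
#' Markdown summary of an analysis run: per-model coefficient tables
#' (estimate, SE, z, p, with footnote flags for transformations and
#' residual deviations), the radius-selection AIC table and the descriptive
#' species comparison.
#'
#' @param run an `fp_run` from [reproduce_models()] or [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report <- function(run) {
  ln <- c("# Movement analysis run", "",
          sprintf("Selected urbanization buffer radius: %g m", run$radius),
          "", "## Radius selection (total AIC)", "",
          "| radius (m) | total AIC |", "| --- | --- |",
          sprintf("| %g | %.2f |", run$aic_table$radius,
                  run$aic_table[[2L]]),
          "", "## Species descriptives", "")
  d <- run$descriptives
  ln <- c(ln, paste0("| ", paste(names(d), collapse = " | "), " |"),
          paste0("|", paste(rep(" --- ", ncol(d)), collapse = "|"), "|"),
          vapply(seq_len(nrow(d)), function(i)
            paste0("| ", paste(vapply(d[i, ], function(v)
              if (is.numeric(v)) sprintf("%.4g", v) else as.character(v),
              character(1)), collapse = " | "), " |"), character(1)),
          "", "## Models", "")
  mt <- run$models_table
  for (key in unique(mt$model)) {
    sub <- mt[mt$model == key, ]
    foot <- c(if (sub$divide_by_10[1L]) "response divided by 10",
              if (sub$add_epsilon[1L]) "small constant (1e-10) added",
              if (sub$ks_flag[1L] != "ok") "residual deviation significant")
    ln <- c(ln, sprintf("### %s (%s)", key, sub$family[1L]), "",
            "| term | estimate | SE | z | p |", "| --- | --- | --- | --- | --- |",
            sprintf("| %s | %.3f | %.3f | %.3f | %.3g |", sub$term,
                    sub$estimate, sub$std_error, sub$z, sub$p),
            if (length(foot)) c("", paste0("*", foot, "*")) else character(),
            "")
  }
  ln
}
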