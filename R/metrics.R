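# Per-individual response variables: flight speed, time-budget shares and
# Benhamou's corrected sinuosity, weighted across gap-split track segments.

#' Step and turning-angle geometry of a path segment
#'
#' Computes the ingredients of the corrected sinuosity index: step lengths
#' (Euclidean distances between consecutive fixes), signed turning angles at
#' interior fixes, their summaries p (mean step length, m), c (mean cosine of
#' turning angles) and b (coefficient of variation of step length, population
#' SD). Consecutive duplicate fixes (exact zero-length steps) are merged
#' before angle computation, since a zero step has no heading.
#'
#' @param points two-column matrix/data.frame of planar coordinates (m), in
#'   path order.
#' @return object of class `fp_segment_geometry`: list with `step_lengths`,
#'   `turning_angles` (radians, in (-pi, pi]), `p`, `c`, `b` and
#'   `path_length`.
#' @export
segment_geometry <- function(points) {
  xy <- as.matrix(points)
  stopifnot(ncol(xy) == 2L)
  # merge exact duplicates of the preceding fix
  if (nrow(xy) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(xy))) == 0)
    xy <- xy[!dup, , drop = FALSE]
  }
  if (nrow(xy) < 2L)
    stop("degenerate segment: fewer than 2 distinct points")
  d <- diff(xy)
  steps <- sqrt(rowSums(d^2))
  if (nrow(xy) >= 3L) {
    head_ <- atan2(d[, 2L], d[, 1L])
    ang <- diff(head_)
    ang <- ((ang + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
    ang[ang == -pi] <- pi
    cbar <- mean(cos(ang))
  } else {
    ang <- numeric()
    cbar <- NA_real_
  }
  p <- mean(steps)
  b <- sqrt(mean((steps - p)^2)) / p  # population SD by design
  structure(list(step_lengths = steps, turning_angles = ang,
                 p = p, c = cbar, b = b, path_length = sum(steps)),
            class = "fp_segment_geometry")
}

#' Corrected sinuosity of a path segment
#'
#' Benhamou's corrected sinuosity
#' \deqn{Sin = 2 [p ((1+c)/(1-c) + b^2)]^{-1/2}}
#' with p the mean step length (m), c the mean cosine of turning angles and b
#' the step-length coefficient of variation (the estimator behind trajr's
#' `TrajSinuosity2`). Low values indicate nearly straight paths; the
#' perfectly straight limit c = 1 returns 0 by continuity. Units m^(-1/2):
#' uniformly rescaling coordinates by k rescales Sin by k^(-1/2).
#'
#' @param seg an `fp_segment_geometry`, or any list with elements `p`, `c`,
#'   `b`.
#' @return nonnegative sinuosity value.
#' @export
sinuosity <- function(seg) {
  p <- seg$p; cbar <- seg$c; b <- seg$b
  stopifnot(is.finite(p), is.finite(b), p > 0)
  if (is.na(cbar))
    stop("mean turning-angle cosine unavailable: segment too short")
  if (cbar >= 1) return(0)
  bracket <- p * ((1 + cbar) / (1 - cbar) + b^2)
  if (bracket <= 0)
    stop("undefined sinuosity: p((1+c)/(1-c) + b^2) <= 0")
  2 * bracket^(-0.5)
}

#' Length-weighted mean sinuosity over track segments
#'
#' When a track is split by data gaps, sinuosity is computed per segment and
#' averaged with weights proportional to segment path length (the default) or
#' segment duration.
#'
#' @param segments list of `fp_segment_geometry`.
#' @param weights positive weights, one per segment (path lengths or
#'   durations).
#' @return weighted mean sinuosity.
#' @export
weighted_sinuosity <- function(segments, weights) {
  stopifnot(length(segments) == length(weights), all(weights > 0))
  sins <- rep(NA_real_, length(segments))
  for (i in seq_along(segments)) {
    s <- try(sinuosity(segments[[i]]), silent = TRUE)
    if (!inherits(s, "try-error")) sins[i] <- s
  }
  ok <- !is.na(sins)
  if (!any(ok)) stop("no segment admits a sinuosity estimate")
  if (any(!ok))
    warning(sprintf("%d segment(s) too short for sinuosity; dropped",
                    sum(!ok)))
  sum(weights[ok] * sins[ok]) / sum(weights[ok])
}

# split a view data.frame into per-segment coordinate matrices
.view_segments <- function(view) {
  lapply(split(seq_len(nrow(view)), view$segment),
         function(i) view[i, , drop = FALSE])
}

#' Track-level weighted sinuosity
#'
#' Applies [segment_geometry()] and [sinuosity()] to each gap-free segment of
#' the tortuosity view (stop clouds reduced to their first adjusted fix) and
#' returns the weighted mean per [weighted_sinuosity()]. Segments with fewer
#' than `min_points` distinct fixes are dropped with a warning.
#'
#' @param pt an `fp_processed_track`.
#' @param weighting `"length"` (segment path length, default) or
#'   `"duration"` (segment time span).
#' @param min_points minimum distinct fixes per usable segment.
#' @return weighted sinuosity of the track (m^(-1/2)).
#' @export
track_sinuosity <- function(pt, weighting = c("length", "duration"),
                            min_points = 3L) {
  weighting <- match.arg(weighting)
  segs <- .view_segments(pt$tortuosity)
  geoms <- list(); w <- numeric()
  short <- 0L
  for (sg in segs) {
    g <- try(segment_geometry(sg[, c("x", "y")]), silent = TRUE)
    if (inherits(g, "try-error") || length(g$step_lengths) + 1L < min_points ||
        is.na(g$c)) {
      short <- short + 1L
      next
    }
    geoms[[length(geoms) + 1L]] <- g
    w <- c(w, if (weighting == "length") g$path_length
           else diff(range(sg$t)))
  }
  if (short > 0L)
    warning(sprintf("%d segment(s) below %d distinct points; dropped",
                    short, min_points))
  if (!length(geoms)) stop("no segment admits a sinuosity estimate")
  weighted_sinuosity(geoms, w)
}

# seconds of stop time falling inside [a, b], counting a stop interval
# [s, e] as occupying the unit seconds s .. e-1
.stop_overlap <- function(stops, a, b, activities = NULL) {
  if (nrow(stops) == 0L) return(0)
  sel <- if (is.null(activities)) rep(TRUE, nrow(stops))
         else stops$activity %in% activities
  if (!any(sel)) return(0)
  s <- pmax(stops$start_s[sel], a)
  e <- pmin(stops$end_s[sel], b)
  sum(pmax(e - s, 0))
}

#' Mean flight speed of a processed track
#'
#' Path length accumulated over the mobility view (zero within consolidated
#' stops) divided by the time actually spent flying: the retained track span
#' minus stop seconds and minus data-gap seconds, accumulated per gap-free
#' segment so that gaps contribute neither distance nor time. Set
#' `definition = "gross"` for path length over total retained span.
#'
#' @param pt an `fp_processed_track`.
#' @param definition `"flying"` (default) or `"gross"`.
#' @return speed in m/s.
#' @export
flight_speed <- function(pt, definition = c("flying", "gross")) {
  definition <- match.arg(definition)
  mob <- pt$mobility
  segs <- .view_segments(mob)
  dist <- sum(vapply(segs, function(sg) {
    if (nrow(sg) < 2L) return(0)
    sum(sqrt(rowSums(diff(as.matrix(sg[, c("x", "y")]))^2)))
  }, numeric(1)))
  if (definition == "gross") {
    span <- mob$t[nrow(mob)] - mob$t[1L]
    if (span <= 0) stop("zero track span")
    return(dist / span)
  }
  flying <- sum(vapply(segs, function(sg) {
    span <- sg$t[nrow(sg)] - sg$t[1L]
    span - .stop_overlap(pt$stops, sg$t[1L], sg$t[nrow(sg)])
  }, numeric(1)))
  if (flying <= 0) stop("zero flying time")
  dist / flying
}

#' Time-budget shares of a processed track
#'
#' Shares of the analysed (retained) track span spent stopping, nectaring and
#' resting. Stopping aggregates all stop activities, including basking,
#' oviposition and unlabelled stops; nectaring and resting are reported
#' separately. A stop interval \[s, e\] occupies seconds s..e-1.
#'
#' @param pt an `fp_processed_track`.
#' @return named numeric `c(stopping, nectaring, resting)`, each in \[0, 1\].
#' @export
time_budget <- function(pt) {
  mob <- pt$mobility
  a <- mob$t[1L]; b <- mob$t[nrow(mob)]
  dur <- b - a
  if (dur <= 0) stop("zero analysed duration")
  c(stopping = .stop_overlap(pt$stops, a, b) / dur,
    nectaring = .stop_overlap(pt$stops, a, b, "nectaring") / dur,
    resting = .stop_overlap(pt$stops, a, b, "resting") / dur)
}

#' One-row per-individual movement summary
#'
#' Combines [flight_speed()], [time_budget()] and [track_sinuosity()] into
#' the row format of `summaries.csv`.
#'
#' @param pt an `fp_processed_track`.
#' @param weighting,min_points passed to [track_sinuosity()].
#' @param speed_definition passed to [flight_speed()].
#' @return one-row data.frame: individual_id, species, sex, site_id,
#'   duration_s, path_m, flight_speed, stopping, nectaring, resting,
#'   sinuosity, n_stops, n_segments.
#' @export
movement_summary <- function(pt, weighting = "length", min_points = 3L,
                             speed_definition = "flying") {
  tr <- pt$trajectory
  mob <- pt$mobility
  segs <- .view_segments(mob)
  path <- sum(vapply(segs, function(sg) {
    if (nrow(sg) < 2L) return(0)
    sum(sqrt(rowSums(diff(as.matrix(sg[, c("x", "y")]))^2)))
  }, numeric(1)))
  tb <- time_budget(pt)
  sin_w <- tryCatch(
    suppressWarnings(track_sinuosity(pt, weighting = weighting,
                                     min_points = min_points)),
    error = function(e) NA_real_)
  data.frame(
    individual_id = tr$individual_id, species = tr$species, sex = tr$sex,
    site_id = tr$site_id,
    duration_s = mob$t[nrow(mob)] - mob$t[1L],
    path_m = path,
    flight_speed = flight_speed(pt, definition = speed_definition),
    stopping = unname(tb["stopping"]),
    nectaring = unname(tb["nectaring"]),
    resting = unname(tb["resting"]),
    sinuosity = sin_w,
    n_stops = nrow(pt$stops),
    n_segments = max(mob$segment),
    stringsAsFactors = FALSE)
}
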