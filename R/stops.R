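# Stop consolidation: collapse the point cloud recorded while the butterfly
# sat still onto one representative location, and derive the two processed
# views of a track (full view for mobility, reduced view for tortuosity).

#' Geometric median of a planar point set
#'
#' The point minimising the sum of Euclidean distances to the inputs (the
#' "median center" of GIS tooling), computed by Weiszfeld iteration with the
#' standard subgradient check when an iterate lands on an input point.
#'
#' @param points numeric matrix or data.frame with two columns (x, y m).
#' @param tol convergence tolerance on the iterate displacement, in metres.
#' @param max_iter iteration cap.
#' @return length-2 numeric `c(x, y)`.
#' @export
geometric_median <- function(points, tol = 1e-4, max_iter = 1000L) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 1L, tol > 0)
  if (nrow(pts) == 1L) return(as.numeric(pts[1L, ]))
  uni <- unique(pts)
  if (nrow(uni) == 1L) return(as.numeric(uni[1L, ]))
  cur <- colMeans(pts)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(pts, 2L, cur)^2))
    at_vertex <- which(d < .Machine$double.eps^0.5)
    if (length(at_vertex)) {
      # Vardi-Zhang: the vertex is optimal iff the pull of the other points
      # does not exceed the vertex's own multiplicity.
      others <- d >= .Machine$double.eps^0.5
      rvec <- colSums(sweep(pts[others, , drop = FALSE], 2L, cur) /
                        d[others])
      rnorm_ <- sqrt(sum(rvec^2))
      m <- length(at_vertex)
      if (rnorm_ <= m) return(as.numeric(cur))
      step <- (rnorm_ - m) / sum(1 / d[others])
      nxt <- cur + step * rvec / rnorm_
    } else {
      w <- 1 / d
      nxt <- colSums(pts * w) / sum(w)
    }
    if (sqrt(sum((nxt - cur)^2)) < tol)
      return(.snap_to_vertex(nxt, pts, tol))
    cur <- nxt
  }
  stop(structure(
    class = c("fp_median_no_convergence", "error", "condition"),
    list(message = sprintf(
      "geometric median did not converge in %d iterations", max_iter),
      call = sys.call(-1), best = as.numeric(cur))))
}

# If the converged iterate sits next to an input point, check the
# subgradient condition there and return the vertex exactly when optimal
# (Weiszfeld slows to a crawl near optimal vertices).
.snap_to_vertex <- function(cur, pts, tol) {
  d <- sqrt(rowSums(sweep(pts, 2L, cur)^2))
  i <- which.min(d)
  if (d[i] > 10 * tol) return(as.numeric(cur))
  v <- pts[i, ]
  dv <- sqrt(rowSums(sweep(pts, 2L, v)^2))
  others <- dv > .Machine$double.eps^0.5
  if (!any(others)) return(as.numeric(v))
  rvec <- colSums(sweep(pts[others, , drop = FALSE], 2L, v) / dv[others])
  if (sqrt(sum(rvec^2)) <= sum(!others)) as.numeric(v) else as.numeric(cur)
}

#' Match stop events to trajectory points
#'
#' A fix belongs to a stop iff `start_s <= t <= end_s`. Events extending
#' beyond the track span are clipped with a warning; events left with no
#' member fix are flagged.
#'
#' @param traj an `fp_trajectory`.
#' @param events validated event table (see [stop_events()]).
#' @return list with one integer index vector per event row; attribute
#'   `empty` marks events without members.
#' @export
match_stops <- function(traj, events) {
  events <- stop_events(events)
  t <- traj$points$t
  t0 <- t[1L]; t1 <- t[length(t)]
  clipped <- events$start_s < t0 | events$end_s > t1
  if (any(clipped))
    warning(sprintf("%d stop event(s) extend beyond the track span; clipped",
                    sum(clipped)))
  members <- lapply(seq_len(nrow(events)), function(i)
    which(t >= events$start_s[i] & t <= events$end_s[i]))
  empty <- lengths(members) == 0L
  if (any(empty))
    warning(sprintf("%d stop event(s) have no member fixes", sum(empty)))
  structure(members, empty = empty)
}

#' Consolidate stops and build the analysis views of a track
#'
#' Each annotated stop's point cloud is replaced by its geometric median: the
#' consolidated coordinate is attributed to all member fixes (mobility view),
#' and for the tortuosity view all but the first (adjusted) fix of each stop
#' are removed so that stationary jitter cannot corrupt the turning-angle
#' statistics. Stops overlapping the start or end of the logging are excluded
#' from both views entirely. Gap structure is determined on the raw fix
#' times, so stop thinning never creates artificial segment breaks.
#'
#' @param traj an `fp_trajectory`.
#' @param events stop event table (see [stop_events()]).
#' @param gap_threshold_s gap threshold passed to [detect_gaps()].
#' @param tol,max_iter passed to [geometric_median()].
#' @return an object of class `fp_processed_track`: list with elements
#'   `trajectory`, `stops` (per retained stop: start_s, end_s, activity,
#'   center_x, center_y, n_members), `mobility` and `tortuosity` (data.frames
#'   `t,x,y,stop_id,segment`), and `gap_threshold_s`.
#' @export
consolidate <- function(traj, events, gap_threshold_s = 3,
                        tol = 1e-4, max_iter = 1000L) {
  events <- stop_events(events)
  members <- suppressWarnings(match_stops(traj, events))
  pts <- traj$points
  n <- nrow(pts)
  t0 <- pts$t[1L]; t1 <- pts$t[n]

  terminal <- events$start_s <= t0 | events$end_s >= t1
  drop_idx <- unlist(members[terminal], use.names = FALSE)
  keep <- setdiff(seq_len(n), drop_idx)
  if (length(keep) < 2L)
    stop("fewer than 2 fixes remain after terminal-stop exclusion")

  ev_keep <- which(!terminal & lengths(members) > 0L)
  stops <- data.frame(stop_id = seq_along(ev_keep),
                      start_s = events$start_s[ev_keep],
                      end_s = events$end_s[ev_keep],
                      activity = events$activity[ev_keep],
                      center_x = rep(NA_real_, length(ev_keep)),
                      center_y = rep(NA_real_, length(ev_keep)),
                      n_members = rep(0L, length(ev_keep)))
  mob <- pts[keep, , drop = FALSE]
  rownames(mob) <- NULL
  mob$stop_id <- NA_integer_
  for (k in seq_along(ev_keep)) {
    idx <- match(members[[ev_keep[k]]], keep)
    idx <- idx[!is.na(idx)]
    ctr <- geometric_median(mob[idx, c("x", "y")], tol = tol,
                            max_iter = max_iter)
    mob$x[idx] <- ctr[1L]
    mob$y[idx] <- ctr[2L]
    mob$stop_id[idx] <- k
    stops$center_x[k] <- ctr[1L]
    stops$center_y[k] <- ctr[2L]
    stops$n_members[k] <- length(idx)
  }

  # gap structure from the raw inter-fix intervals of the retained points
  seg <- cumsum(c(1L, as.integer(diff(mob$t) >= gap_threshold_s)))
  mob$segment <- seg

  first_of_stop <- !is.na(mob$stop_id) &
    !duplicated(mob$stop_id, incomparables = NA)
  tort_keep <- is.na(mob$stop_id) | first_of_stop
  tort <- mob[tort_keep, , drop = FALSE]
  rownames(tort) <- NULL

  structure(
    list(trajectory = traj, stops = stops, mobility = mob,
         tortuosity = tort, gap_threshold_s = gap_threshold_s),
    class = "fp_processed_track")
}

#' @export
print.fp_processed_track <- function(x, ...) {
  cat(sprintf(
    "<fp_processed_track> %s: %d mobility fixes, %d tortuosity fixes, %d stop(s), %d segment(s)\n",
    x$trajectory$individual_id, nrow(x$mobility), nrow(x$tortuosity),
    nrow(x$stops), max(x$mobility$segment)))
  invisible(x)
}

#' Serialize a processed track to CSV
#'
#' One row per fix per view, tagged `view` (`mobility`/`tortuosity`),
#' `stop_id` and `segment`.
#'
#' @param pt an `fp_processed_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_processed_track <- function(pt, path) {
  mob <- cbind(view = "mobility", pt$mobility)
  tor <- cbind(view = "tortuosity", pt$tortuosity)
  utils::write.csv(rbind(mob, tor), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
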