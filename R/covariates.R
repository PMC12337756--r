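# Environmental predictors: transect nectar-plant coverage, surface-sealing
# imputation by biotope class, multi-radius zonal urbanization, habitat area.

#' Construct a grid raster
#'
#' Minimal regular-grid raster: a value matrix (row 1 = northernmost row,
#' matching the ESRI ASCII grid layout), lower-left corner and square cell
#' size. `NA` marks nodata.
#'
#' @param values numeric (or character, for class maps) matrix.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length (m); the study's sealing grid uses 2 m.
#' @return object of class `fp_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 2) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "fp_raster")
}

#' @export
print.fp_raster <- function(x, ...) {
  cat(sprintf("<fp_raster> %d x %d cells of %gm, origin (%g, %g), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

# cell-center coordinate vectors (x over columns, y over rows, row 1 = top)
.cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

.same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize)))
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, north row
#' first.
#'
#' @param path file path.
#' @return an `fp_raster` (for `read_ascii_grid`).
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "\\s+")[[1L]]
    hdr[[tolower(ln[1L])]] <- as.numeric(ln[2L])
  }
  vals <- scan(con, what = numeric(), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param r an `fp_raster` with numeric values.
#' @export
write_ascii_grid <- function(r, path) {
  m <- r$values
  m[is.na(m)] <- -9999
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value -9999",
                 ncol(m), nrow(m), r$xll, r$yll, r$cellsize)
  writeLines(c(hdr, apply(m, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' Mean nectar-plant coverage of a transect
#'
#' The arithmetic mean of per-segment percent cover: sum of segment
#' coverages over the total number of transect segments.
#'
#' @param transect data.frame with column `np_cover_pct` (see
#'   [read_transect()]), or a bare numeric vector of segment coverages.
#' @return mean coverage, percent.
#' @export
np_coverage <- function(transect) {
  v <- if (is.data.frame(transect)) transect$np_cover_pct else transect
  if (length(v) == 0L) stop("empty transect")
  sum(v) / length(v)
}

#' Mean surface sealing per biotope class
#'
#' Where the sealing raster covers the biotope map, the mean percent sealing
#' is computed for each biotope class; these class means drive the imputation
#' of sealing outside the covered area (see [impute_sealing()]).
#'
#' @param sealing `fp_raster` of percent sealed, `NA` where unobserved.
#' @param biotopes co-registered `fp_raster` of class labels.
#' @return named numeric vector of class means; classes never covered carry
#'   `NA` and a warning.
#' @export
class_sealing_means <- function(sealing, biotopes) {
  if (!.same_grid(sealing, biotopes))
    stop("sealing and biotope rasters must share one grid definition")
  cls <- as.vector(biotopes$values)
  val <- as.vector(sealing$values)
  if (all(is.na(val))) stop("sealing raster has no observed cells")
  means <- tapply(val, cls, function(v) mean(v, na.rm = TRUE))
  means[is.nan(means)] <- NA
  if (anyNA(means))
    warning("biotope class(es) without covered cells: ",
            paste(names(means)[is.na(means)], collapse = ", "))
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Impute missing sealing values from biotope class means
#'
#' Observed cells are kept as-is; each unobserved cell takes the mean sealing
#' of its biotope class. The result covers the full grid.
#'
#' @param sealing `fp_raster`, `NA` where unobserved.
#' @param biotopes co-registered class-label `fp_raster`.
#' @param class_means named vector from [class_sealing_means()] (computed if
#'   omitted).
#' @return fully covered `fp_raster`.
#' @export
impute_sealing <- function(sealing, biotopes,
                           class_means = class_sealing_means(sealing, biotopes)) {
  if (!.same_grid(sealing, biotopes))
    stop("sealing and biotope rasters must share one grid definition")
  out <- sealing$values
  miss <- is.na(out)
  if (any(miss)) {
    cls <- as.character(biotopes$values[miss])
    unknown <- setdiff(unique(cls), names(class_means)[!is.na(class_means)])
    if (length(unknown))
      stop("no sealing mean available for class(es): ",
           paste(unknown, collapse = ", "))
    out[miss] <- class_means[cls]
  }
  grid_raster(out, xll = sealing$xll, yll = sealing$yll,
              cellsize = sealing$cellsize)
}

#' Mean sealing within a circular buffer (zonal urbanization)
#'
#' Mean of raster values whose cell centers fall within `radius` of
#' `center`. At the study's 2-m cells and >= 500-m radii, cell-center
#' membership differs from fractional-area weighting by well under 0.1%.
#'
#' @param r full-coverage `fp_raster` of percent sealed.
#' @param center numeric `c(x, y)` of the site center (m).
#' @param radius buffer radius (m).
#' @return mean percent sealed within the buffer.
#' @export
zonal_urbanization <- function(r, center, radius) {
  cc <- .cell_centers(r)
  dx2 <- outer(rep(1, nrow(r$values)), (cc$x - center[1L])^2)
  dy2 <- outer((cc$y - center[2L])^2, rep(1, ncol(r$values)))
  inside <- (dx2 + dy2) <= radius^2
  if (!any(inside)) stop("buffer does not intersect the raster")
  mean(r$values[inside])
}

# signed shoelace area of a closed ring given as an n x 2 matrix
.ring_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# proper crossing test between segments p1-p2 and p3-p4 (shared endpoints ok)
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.check_simple <- function(m) {
  n <- nrow(m)
  if (n < 3L) stop("polygon ring needs at least 3 vertices")
  j <- c(2:n, 1L)
  for (a in seq_len(n - 2L)) {
    for (b in seq((a + 2L), n)) {
      if (a == 1L && b == n) next  # adjacent through closure
      if (.segments_cross(m[a, ], m[j[a], ], m[b, ], m[j[b], ]))
        stop("self-intersecting polygon")
    }
  }
  invisible(TRUE)
}

#' Habitat patch area in hectares
#'
#' Shoelace area of a simple planar polygon, holes subtracted, divided by
#' 10^4.
#'
#' @param polygon either an n x 2 coordinate matrix (outer ring, unclosed or
#'   closed) or a list `list(outer = matrix, holes = list(matrix, ...))`.
#' @return area in ha.
#' @export
habitat_area <- function(polygon) {
  if (is.matrix(polygon) || is.data.frame(polygon))
    polygon <- list(outer = as.matrix(polygon), holes = list())
  drop_closure <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  outer_ring <- drop_closure(polygon$outer)
  .check_simple(outer_ring)
  area <- abs(.ring_area(outer_ring))
  for (h in polygon$holes) {
    h <- drop_closure(h)
    .check_simple(h)
    area <- area - abs(.ring_area(h))
  }
  if (area <= 0) stop("non-positive habitat area")
  area / 1e4
}

#' Read site center points from GeoJSON
#'
#' FeatureCollection of Point features with an `id` (or `site_id`) property.
#'
#' @param path file path.
#' @return data.frame `site_id, x, y` (coordinates as stored; project first
#'   if geographic).
#' @export
read_sites_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    id <- f$properties$site_id
    if (is.null(id)) id <- f$properties$id
    data.frame(site_id = as.character(id), x = cc[1L], y = cc[2L])
  })
  do.call(rbind, rows)
}

#' Read polygons from GeoJSON
#'
#' FeatureCollection of Polygon features with an `id` (or `site_id`)
#' property; the first ring is the outer boundary, further rings are holes.
#'
#' @param path file path.
#' @return named list of `list(outer, holes)` polygons as accepted by
#'   [habitat_area()].
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("expected Polygon features")
    rings <- lapply(f$geometry$coordinates, function(r)
      do.call(rbind, lapply(r, function(p) unlist(p)[1:2])))
    id <- f$properties$site_id
    if (is.null(id)) id <- f$properties$id
    out[[as.character(id)]] <- list(outer = rings[[1L]],
                                    holes = rings[-1L])
  }
  out
}

#' Assemble per-site covariates
#'
#' Combines zonal urbanization at the requested buffer radii with habitat
#' area into the `covariates.csv` row format; per-individual nectar coverage
#' comes from [np_coverage()] on each individual's transect.
#'
#' @param site_centers data.frame `site_id, x, y`.
#' @param sealing full-coverage sealing `fp_raster` (see
#'   [impute_sealing()]).
#' @param habitat_polygons named list of polygons keyed by site_id.
#' @param radii buffer radii in metres.
#' @return data.frame keyed by `site_id` with `urbanization_<radius>` columns
#'   and `habitat_area_ha`.
#' @export
site_covariates <- function(site_centers, sealing, habitat_polygons,
                            radii = c(500, 1000, 2000)) {
  rows <- lapply(seq_len(nrow(site_centers)), function(i) {
    sid <- site_centers$site_id[i]
    ctr <- c(site_centers$x[i], site_centers$y[i])
    urb <- vapply(radii, function(r) zonal_urbanization(sealing, ctr, r),
                  numeric(1))
    names(urb) <- paste0("urbanization_", radii)
    poly <- habitat_polygons[[sid]]
    if (is.null(poly)) stop("no habitat polygon for site ", sid)
    cbind(data.frame(site_id = sid), as.data.frame(as.list(urb)),
          data.frame(habitat_area_ha = habitat_area(poly)))
  })
  do.call(rbind, rows)
}
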