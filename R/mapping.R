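#' Suitability classification, area accounting and centroid shifts
#'
#' Continuous suitability in \[0,1\] is cut into four equal-interval levels
#' (unsuitable, low, moderate, high at 0.30 / 0.50 / 0.70), class areas are
#' summed with spherical cos-latitude cell weights, scenarios are compared
#' as percent change versus a baseline, and the suitable range is reduced
#' to an (optionally area-weighted) centroid whose displacement between
#' scenarios is reported as a great-circle distance and initial bearing.
#'
#' @name mapping
NULL

SUIT_CLASSES <- c("unsuitable", "low", "moderate", "high")

#' Classify a suitability map into four levels
#'
#' Intervals are left-closed: \[0, 0.30) unsuitable, \[0.30, 0.50) low,
#' \[0.50, 0.70) moderate, \[0.70, 1\] high. NODATA propagates.
#'
#' @param suitability a `grid_layer` with values in \[0, 1\].
#' @param thresholds increasing cut points inside (0, 1), default
#'   `c(0.30, 0.50, 0.70)`.
#' @return a `classified_map`: a `grid_layer` of integer codes 0-3 plus the
#'   thresholds and class labels.
#' @export
classify <- function(suitability, thresholds = c(0.30, 0.50, 0.70)) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0),
            all(thresholds > 0 & thresholds < 1))
  v <- suitability$values
  bad <- which(!is.na(v) & (v < 0 | v > 1))
  if (length(bad))
    stop("suitability outside [0, 1] at cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], thresholds)  # 0..3, left-closed
  layer <- grid_layer(cls, suitability$xll, suitability$yll,
                      suitability$cellsize, name = "class",
                      nodata_value = suitability$nodata_value)
  structure(list(layer = layer, thresholds = thresholds,
                 labels = SUIT_CLASSES),
            class = "classified_map")
}

# spherical cell area in km^2 at each cell of a layer's geometry
cell_area_km2 <- function(layer) {
  cc <- cell_centers(layer)
  a_row <- (KM_PER_DEGREE_LAT * layer$cellsize)^2 * cos(cc$y * pi / 180)
  matrix(rep(a_row, ncol(layer$values)), nrow(layer$values))
}

#' Per-class habitat areas
#'
#' Cell areas use the spherical approximation
#' `(111.32 * cellsize)^2 * cos(lat)` km^2 at each cell center.
#'
#' @param cmap a [classify()] result.
#' @param reference_area_km2 optional land area against which the total
#'   suitable share is reported.
#' @return an `area_summary`: named per-class areas (km^2),
#'   `total_suitable` (low + moderate + high), and optionally `share`.
#' @export
area_summary <- function(cmap, reference_area_km2 = NULL) {
  a <- cell_area_km2(cmap$layer)
  cls <- cmap$layer$values
  areas <- vapply(0:3, function(code) sum(a[!is.na(cls) & cls == code]),
                  numeric(1))
  names(areas) <- SUIT_CLASSES
  out <- list(areas = areas,
              total_suitable = sum(areas[c("low", "moderate", "high")]))
  if (!is.null(reference_area_km2))
    out$share <- 100 * out$total_suitable / reference_area_km2
  structure(out, class = "area_summary")
}

#' Round half-up to a fixed number of decimals
#'
#' `0.5` at the last kept digit rounds away from zero, the convention of
#' most published area tables (unlike R's banker's rounding).
#'
#' @param x numeric.
#' @param digits decimals kept.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change of class areas between scenarios
#'
#' @param current,future `area_summary` objects on the same classes.
#' @param label scenario label carried through to the output.
#' @return data frame (scenario, class, area_km2, pct_change) covering the
#'   three suitable classes and the total; percent change is
#'   `100 (future - current) / current`, rounded half-up to 2 decimals, and
#'   `NA` where the baseline area is zero.
#' @export
compare_scenarios <- function(current, future, label = "future") {
  classes <- c("low", "moderate", "high")
  cur <- c(current$areas[classes], total = current$total_suitable)
  fut <- c(future$areas[classes], total = future$total_suitable)
  pct <- ifelse(cur == 0, NA_real_,
                round_half_up(100 * (fut - cur) / cur, 2))
  data.frame(scenario = label, class = names(cur), area_km2 = unname(fut),
             pct_change = unname(pct), stringsAsFactors = FALSE)
}

#' Centroid of the suitable range
#'
#' Reduces the classified map to a binary suitable mask (by default every
#' class at or above "low", i.e. suitability >= 0.30) and returns the mean
#' of the member cell centers, weighted by spherical cell area unless
#' `area_weighted = FALSE`.
#'
#' @param cmap a [classify()] result.
#' @param include classes forming the mask.
#' @param area_weighted weight cells by their cos-latitude area.
#' @return list `(lon, lat, n_cells)`.
#' @export
centroid <- function(cmap, include = c("low", "moderate", "high"),
                     area_weighted = TRUE) {
  codes <- match(include, SUIT_CLASSES) - 1L
  if (anyNA(codes)) stop("unknown class in include")
  cls <- cmap$layer$values
  sel <- !is.na(cls) & cls %in% codes
  if (!any(sel)) stop("no cells in the included classes")
  cc <- cell_centers(cmap$layer)
  w <- if (area_weighted) cell_area_km2(cmap$layer)[sel] else rep(1, sum(sel))
  list(lon = sum(cc$lon[sel] * w) / sum(w),
       lat = sum(cc$lat[sel] * w) / sum(w),
       n_cells = sum(sel))
}

#' Great-circle displacement between two centroids
#'
#' Haversine distance on a sphere of radius 6371 km and initial bearing
#' (degrees clockwise from north) from `a` to `b`. Coincident points get
#' distance 0 and a flagged bearing of 0.
#'
#' @param a,b lists or vectors with `lon` and `lat` in decimal degrees.
#' @return list `(distance_km, bearing_deg, degenerate)`.
#' @export
centroid_shift <- function(a, b) {
  pa <- c(a$lon, a$lat); pb <- c(b$lon, b$lat)
  if (isTRUE(all.equal(pa, pb)))
    return(list(distance_km = 0, bearing_deg = 0, degenerate = TRUE))
  d <- geosphere::distHaversine(pa, pb, r = 6371) # r in km -> km out
  brg <- geosphere::bearing(pa, pb) %% 360
  list(distance_km = d, bearing_deg = brg, degenerate = FALSE)
}

#' Write a classified map as an ESRI ASCII grid of integer codes
#' @param cmap a [classify()] result.
#' @param path output path.
#' @export
write_classified <- function(cmap, path) {
  write_ascii_grid(cmap$layer, path, digits = 1)
}
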