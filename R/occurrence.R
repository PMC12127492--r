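#' Occurrence records: reading, validation and spatial thinning
#'
#' Presence-only records are handled as plain data frames with columns
#' `species`, `lon`, `lat` (decimal degrees, WGS84) and optionally `source`,
#' carrying the class `occurrence_set`. Spatial thinning retains at most one
#' record per cell of a kilometre-scale grid, the standard remedy for
#' clustered sampling effort in presence-only niche modelling.
#'
#' @name occurrence
NULL

KM_PER_DEGREE_LAT <- 111.32

new_occurrence_set <- function(df) {
  stopifnot(all(c("species", "lon", "lat") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Read occurrence records from a delimited text file
#'
#' Reads a CSV of presence records, validates coordinates, and drops exact
#' duplicates on (lon, lat) keeping the first. Input order is preserved.
#'
#' @param path path to a delimited text file (comma-separated, UTF-8).
#' @param column_map named character vector mapping the canonical names
#'   `species`, `lon`, `lat` (and optionally `source`) to the column names
#'   used in the file.
#' @param sep field separator, default `","`.
#' @return an `occurrence_set` data frame with columns `species`, `lon`,
#'   `lat` and, when mapped, `source`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sp = "a", x = c(101, 101, 103), y = c(25, 25, 26)),
#'           f, row.names = FALSE)
#' occ <- read_occurrences(f, c(species = "sp", lon = "x", lat = "y"))
#' nrow(occ)  # 2: the exact duplicate is dropped
#' @export
read_occurrences <- function(path,
                             column_map = c(species = "species",
                                            lon = "longitude",
                                            lat = "latitude"),
                             sep = ",") {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty occurrence file: ", path)
  need <- c("species", "lon", "lat")
  if (is.null(names(column_map)) || !all(need %in% names(column_map)))
    stop("column_map must name 'species', 'lon' and 'lat'")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))

  lon <- suppressWarnings(as.numeric(raw[[column_map[["lon"]]]]))
  lat <- suppressWarnings(as.numeric(raw[[column_map[["lat"]]]]))
  bad_parse <- which(is.na(lon) | is.na(lat))
  if (length(bad_parse))
    stop("unparsable coordinate(s) at data row(s): ",
         paste(bad_parse, collapse = ", "))
  bad_range <- which(lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad_range))
    stop("coordinate(s) out of range at data row(s): ",
         paste(bad_range, collapse = ", "))

  df <- data.frame(species = raw[[column_map[["species"]]]],
                   lon = lon, lat = lat, stringsAsFactors = FALSE)
  if ("source" %in% names(column_map) &&
      column_map[["source"]] %in% names(raw))
    df$source <- raw[[column_map[["source"]]]]

  dup <- duplicated(df[c("lon", "lat")])
  if (any(dup))
    message(sum(dup), " exact duplicate record(s) dropped")
  new_occurrence_set(df[!dup, , drop = FALSE])
}

#' Define a thinning grid
#'
#' @param cell_km cell size in kilometres (> 0).
#' @param origin numeric `(lon, lat)` anchor of cell (0, 0); if `NULL` it is
#'   derived from the data as `(floor(min lon), floor(min lat))` at thinning
#'   time.
#' @return a `thinning_grid` object.
#' @export
thinning_grid <- function(cell_km = 5, origin = NULL) {
  stopifnot(is.numeric(cell_km), length(cell_km) == 1L, cell_km > 0)
  if (!is.null(origin)) stopifnot(is.numeric(origin), length(origin) == 2L)
  structure(list(cell_km = cell_km, origin = origin,
                 km_per_degree_lat = KM_PER_DEGREE_LAT),
            class = "thinning_grid")
}

grid_origin <- function(grid, occ) {
  if (!is.null(grid$origin)) return(grid$origin)
  c(floor(min(occ$lon)), floor(min(occ$lat)))
}

#' Grid cell index of a point
#'
#' Row index is `floor((lat - lat0) / dlat)` with `dlat = cell_km / 111.32`
#' degrees. The longitude cell width is widened by `1 / cos(lat_band)` where
#' `lat_band` is the latitude of the base of the point's row, so cells stay
#' approximately `cell_km` wide on the ground.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param grid a [thinning_grid()] with a non-`NULL` origin.
#' @return a two-column integer matrix `(col, row)`.
#' @export
cell_index <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "thinning_grid"), !is.null(grid$origin))
  dlat <- grid$cell_km / grid$km_per_degree_lat
  row <- floor((lat - grid$origin[2]) / dlat)
  band_lat <- grid$origin[2] + row * dlat
  if (any(abs(band_lat) >= 90))
    stop("latitude band at or beyond the pole: cosine correction degenerates")
  dlon <- grid$cell_km / (grid$km_per_degree_lat * cos(band_lat * pi / 180))
  col <- floor((lon - grid$origin[1]) / dlon)
  cbind(col = as.integer(col), row = as.integer(row))
}

#' Spatially thin occurrences on a kilometre grid
#'
#' Retains the first record (in input order) within each grid cell. Exact
#' coordinate duplicates should already have been removed by
#' [read_occurrences()]. Thinning is idempotent.
#'
#' @param occ an `occurrence_set`.
#' @param grid a [thinning_grid()]; an origin of `NULL` anchors the grid at
#'   `(floor(min lon), floor(min lat))` of `occ`.
#' @return the thinned `occurrence_set`, with a logical attribute-free
#'   `retained` column when `keep_flag = TRUE`.
#' @param keep_flag if `TRUE`, return *all* input rows with a logical
#'   `retained` column instead of the filtered set.
#' @export
thin_by_grid <- function(occ, grid = thinning_grid(5), keep_flag = FALSE) {
  stopifnot(nrow(occ) >= 1L)
  g <- grid
  g$origin <- grid_origin(grid, occ)
  idx <- cell_index(occ$lon, occ$lat, g)
  key <- paste(idx[, 1], idx[, 2], sep = ":")
  retained <- !duplicated(key)
  if (keep_flag) {
    out <- occ
    out$retained <- retained
    return(new_occurrence_set(out))
  }
  new_occurrence_set(occ[retained, , drop = FALSE])
}

#' Write an occurrence set to CSV
#' @param occ an `occurrence_set`.
#' @param path output file path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
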