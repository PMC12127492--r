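#' Grid-aligned raster layers and ESRI ASCII grid I/O
#'
#' A `grid_layer` is a minimal in-memory raster: a numeric matrix whose first
#' row is the NORTHERNMOST row, a lower-left corner, a square cell size in
#' decimal degrees (WGS84 throughout) and a NODATA sentinel. Missing cells
#' are held as `NA` in the matrix. An `env_stack` is a named list of layers
#' sharing geometry; a cell is valid only where it is valid in every layer.
#'
#' @name raster
NULL

#' Construct a raster layer
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xll,yll lower-left corner of the grid (degrees).
#' @param cellsize cell size in degrees (> 0).
#' @param name layer name.
#' @param nodata_value sentinel written for `NA` cells on output.
#' @return a `grid_layer`.
#' @export
grid_layer <- function(values, xll, yll, cellsize, name = "layer",
                       nodata_value = -9999) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(list(name = name, values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer '%s'> %d x %d cells, %.6g deg, ll = (%.6g, %.6g), %d NA\n",
              x$name, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll, sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a layer
#'
#' @param layer a `grid_layer`.
#' @return list with vectors `x` (by column) and `y` (by row, north first),
#'   and matrices `lon`, `lat` aligned with `layer$values`.
#' @export
cell_centers <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  x <- layer$xll + (seq_len(nc) - 0.5) * layer$cellsize
  y <- layer$yll + (nr - seq_len(nr) + 0.5) * layer$cellsize
  list(x = x, y = y,
       lon = matrix(rep(x, each = nr), nr, nc),
       lat = matrix(rep(y, nc), nr, nc))
}

#' Read an ESRI ASCII grid
#'
#' Accepts the 6-line header dialect (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, case-insensitive); the first data
#' row is the northernmost. Cells equal (exactly, after parsing) to the
#' declared NODATA value become `NA`.
#'
#' @param path file path.
#' @param name layer name; defaults to the file name without extension.
#' @return a `grid_layer`.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ASCII grid header in ", path, ": missing ",
         paste(miss, collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  rows <- lines[i:length(lines)]
  if (length(rows) != nr)
    stop("expected ", nr, " data rows, found ", length(rows), " in ", path)
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    v <- as.numeric(strsplit(trimws(rows[r]), "[[:space:]]+")[[1]])
    if (length(v) != nc)
      stop("ragged data row ", r, " in ", path, ": ", length(v),
           " values, expected ", nc)
    vals[r, ] <- v
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  grid_layer(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
             name = name, nodata_value = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param layer a `grid_layer`.
#' @param path output path.
#' @param digits significant digits written for data values.
#' @export
write_ascii_grid <- function(layer, path, digits = 10) {
  v <- layer$values
  v[is.na(v)] <- layer$nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(layer$xll, digits = 15)),
    paste("yllcorner", format(layer$yll, digits = 15)),
    paste("cellsize", format(layer$cellsize, digits = 15)),
    paste("NODATA_value", format(layer$nodata_value, digits = 15))
  ), con)
  writeLines(apply(v, 1, function(r)
    paste(trimws(formatC(r, digits = digits, format = "g")),
          collapse = " ")), con)
  invisible(path)
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Bundle aligned layers into an environmental stack
#'
#' @param layers a named list of `grid_layer`s (names default to the layers'
#'   own names). All layers must share geometry.
#' @return an `env_stack`.
#' @export
env_stack <- function(layers) {
  if (inherits(layers, "grid_layer")) layers <- list(layers)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- vapply(layers, `[[`, "", "name")
  ref <- layers[[1]]
  for (l in layers)
    if (!same_geometry(ref, l))
      stop("layer '", l$name, "' does not share the stack geometry")
  structure(list(layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s), %d x %d cells, %d jointly valid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values),
              sum(valid_mask(x))))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' A cell is valid only if it is non-missing in every layer: the model needs
#' complete covariate vectors.
#'
#' @param stack an `env_stack`.
#' @return logical matrix.
#' @export
valid_mask <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$values)))
}

#' Extract the covariate matrix of all valid cells
#'
#' @param stack an `env_stack`.
#' @return list with `values` (matrix, one row per valid cell, one column per
#'   layer), `lon`, `lat` (cell centers) and `index` (linear cell index).
#' @export
stack_values <- function(stack) {
  m <- valid_mask(stack)
  idx <- which(m)
  vals <- vapply(stack$layers, function(l) l$values[idx],
                 numeric(length(idx)))
  if (length(idx) == 1L) vals <- matrix(vals, 1L,
                                        dimnames = list(NULL, names(stack$layers)))
  cc <- cell_centers(stack$layers[[1]])
  list(values = vals, lon = cc$lon[idx], lat = cc$lat[idx], index = idx)
}

#' Look up covariates at point locations
#'
#' @param stack an `env_stack`.
#' @param lon,lat coordinates of the points.
#' @return matrix with one row per point; rows falling outside the grid or on
#'   invalid cells are `NA`.
#' @export
extract_values <- function(stack, lon, lat) {
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  col <- floor((lon - ref$xll) / ref$cellsize) + 1L
  row <- nr - floor((lat - ref$yll) / ref$cellsize)
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- matrix(NA_real_, length(lon), length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  if (any(ok)) {
    lin <- (col[ok] - 1L) * nr + row[ok]
    for (j in seq_along(stack$layers))
      out[ok, j] <- stack$layers[[j]]$values[lin]
  }
  out
}

#' Clip a layer to a polygon boundary
#'
#' Cells whose centers fall outside the polygon become NODATA; values inside
#' are untouched.
#'
#' @param layer a `grid_layer`.
#' @param boundary two-column matrix of polygon vertices (lon, lat), in the
#'   same geographic CRS as the layer; rings may be separated by `NA` rows.
#' @return the clipped `grid_layer`.
#' @export
clip_to_mask <- function(layer, boundary) {
  boundary <- as.matrix(boundary)
  stopifnot(ncol(boundary) == 2L)
  cc <- cell_centers(layer)
  pts <- cbind(as.vector(cc$lon), as.vector(cc$lat))
  inside <- mgcv::in.out(boundary, pts)
  v <- layer$values
  v[matrix(!inside, nrow(v), ncol(v))] <- NA_real_
  if (all(is.na(v))) stop("no valid cells: boundary does not intersect layer")
  out <- layer
  out$values <- v
  out
}

#' Parse a WKT POLYGON into a vertex matrix
#'
#' Supports `POLYGON ((x y, x y, ...))` with a single outer ring.
#'
#' @param wkt a WKT character scalar.
#' @return two-column numeric matrix of vertices.
#' @export
parse_wkt_polygon <- function(wkt) {
  body <- regmatches(wkt, regexpr("\\(\\(.*\\)\\)", wkt))
  if (!length(body)) stop("not a WKT POLYGON: ", wkt)
  body <- gsub("[()]", "", body)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "[[:space:]]+")
  do.call(rbind, lapply(pairs, as.numeric))
}
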