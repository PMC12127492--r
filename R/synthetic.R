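#' Virtual species and synthetic climate landscapes
#'
#' Every pipeline stage is testable without real climate downloads: layers
#' are seeded Gaussian random fields (white noise smoothed by a Gaussian
#' kernel of a chosen correlation length, affinely rescaled to a target
#' range, optionally mixed with a deterministic latitude gradient), the
#' species truth is a product of Gaussian (unimodal) niche responses with
#' known optima and breadths, presences are drawn size-biased by truth, and
#' "future climates" are controlled additive shifts of chosen layers.
#'
#' @name synthetic
NULL

#' Configuration of a synthetic landscape
#'
#' @param n_layers number of environmental layers.
#' @param shape `(rows, cols)` grid shape; default `c(200, 200)`.
#' @param xll,yll,cellsize geotransform; defaults put a 10-degree square at
#'   (100E, 20N) with 0.05-degree cells.
#' @param corr_length spatial correlation length in cells (Gaussian kernel
#'   sd); 0 gives i.i.d. noise.
#' @param ranges list (recycled) of `c(min, max)` value ranges per layer.
#' @param lat_gradient numeric vector (recycled) of per-layer weights mixing
#'   in a south-to-north linear gradient: 0 = pure random field, 1 = pure
#'   gradient. The mix happens before rescaling, so ranges are exact.
#' @param seed integer seed.
#' @return a `landscape_config`.
#' @export
landscape_config <- function(n_layers = 4, shape = c(200, 200),
                             xll = 100, yll = 20, cellsize = 0.05,
                             corr_length = 10,
                             ranges = list(c(0, 100)),
                             lat_gradient = 0, seed = 1) {
  stopifnot(all(shape > 0), corr_length >= 0, n_layers >= 1)
  structure(list(n_layers = n_layers, shape = as.integer(shape),
                 xll = xll, yll = yll, cellsize = cellsize,
                 corr_length = corr_length,
                 ranges = rep(ranges, length.out = n_layers),
                 lat_gradient = rep(lat_gradient, length.out = n_layers),
                 seed = seed),
            class = "landscape_config")
}

# smooth a matrix with a separable Gaussian kernel (sd in cells);
# renormalised at the borders so the field stays stationary in mean
gauss_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  smooth_1d <- function(x) {   # x: matrix, smooth down columns
    n <- nrow(x)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      kk <- k[j - i + half + 1L]
      K[i, j] <- kk / sum(kk)
    }
    K %*% x
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Generate a synthetic environmental stack
#'
#' @param cfg a [landscape_config()].
#' @return an `env_stack` with layers `env1 ... envK`, each spanning its
#'   configured range exactly.
#' @export
generate_landscape <- function(cfg) {
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  if (cfg$corr_length >= min(cfg$shape) / 2)
    warning("correlation length >= half the grid: field nearly constant")
  old <- .Random.seed_save()
  set.seed(cfg$seed)
  lat_ramp <- matrix(rep(seq(1, 0, length.out = nr), nc), nr, nc) # north = 1
  layers <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    field <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          cfg$corr_length)
    field <- (field - min(field)) / (max(field) - min(field))
    g <- cfg$lat_gradient[i]
    field <- (1 - g) * field + g * lat_ramp
    rg <- cfg$ranges[[i]]
    field <- rg[1] + (field - min(field)) / (max(field) - min(field)) *
      (rg[2] - rg[1])
    layers[[i]] <- grid_layer(field, cfg$xll, cfg$yll, cfg$cellsize,
                              name = paste0("env", i))
  }
  .Random.seed_restore(old)
  env_stack(layers)
}

#' Configuration of a virtual species
#'
#' @param optima named numeric vector of niche optima, one per used layer.
#' @param breadths named numeric vector of niche breadths (> 0), same
#'   names.
#' @param n_presences presence points to draw (default 200).
#' @param seed sampling seed.
#' @return a `species_config`.
#' @export
species_config <- function(optima, breadths, n_presences = 200, seed = 1) {
  stopifnot(length(optima) == length(breadths),
            identical(names(optima), names(breadths)),
            all(breadths > 0), n_presences >= 1)
  structure(list(optima = optima, breadths = breadths,
                 n_presences = as.integer(n_presences), seed = seed),
            class = "species_config")
}

#' True suitability surface of a virtual species
#'
#' Product over the used layers of Gaussian responses
#' `exp(-(v - mu)^2 / (2 sigma^2))`, rescaled so the landscape maximum is 1.
#'
#' @param stack an `env_stack`.
#' @param sp a [species_config()].
#' @return a `grid_layer` in \[0, 1\].
#' @export
true_suitability <- function(stack, sp) {
  miss <- setdiff(names(sp$optima), names(stack$layers))
  if (length(miss)) stop("species uses missing layer(s): ",
                         paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  s <- matrix(1, nrow(ref$values), ncol(ref$values))
  for (v in names(sp$optima)) {
    val <- stack$layers[[v]]$values
    s <- s * exp(-(val - sp$optima[v])^2 / (2 * sp$breadths[v]^2))
  }
  s[!valid_mask(stack)] <- NA_real_
  s <- s / max(s, na.rm = TRUE)
  grid_layer(s, ref$xll, ref$yll, ref$cellsize, name = "truth")
}

#' Sample presence records from a truth surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; records sit at cell centers.
#'
#' @param truth a `grid_layer` in \[0, 1\].
#' @param n number of presences.
#' @param seed integer seed.
#' @param species label for the records.
#' @return an `occurrence_set`.
#' @export
sample_presences <- function(truth, n, seed = 1, species = "virtual") {
  w <- truth$values
  pos <- which(!is.na(w) & w > 0)
  if (n > length(pos))
    stop("n exceeds the ", length(pos), " cells with positive suitability")
  old <- .Random.seed_save()
  set.seed(seed)
  pick <- pos[sample.int(length(pos), n, prob = w[pos])]
  .Random.seed_restore(old)
  cc <- cell_centers(truth)
  new_occurrence_set(data.frame(species = species,
                                lon = cc$lon[pick], lat = cc$lat[pick],
                                stringsAsFactors = FALSE))
}

#' Canonical virtual-species study preset
#'
#' The reference synthetic study used throughout the package's tests and
#' examples: a 200 x 200 landscape (0.05-degree cells anchored at 100E,
#' 20N) of four layers with correlation length 10 cells — the first mixed
#' 70/30 with a south-to-north gradient so scenario shifts have a
#' geographic direction — and a two-variable Gaussian-niche species
#' (optima 60 and 25, breadths 8 and 6 on ranges 0-100 and 0-50; roughly
#' 10% of the landscape exceeds 0.5 truth, a typical virtual-species
#' prevalence) sampled at 200 presences. The bundled scenario subtracts 15
#' units from the gradient layer, moving its favorable band northward.
#'
#' @param seed master seed; landscape, species and sampling seeds are
#'   derived from it.
#' @return list with `landscape` ([landscape_config()]), `species`
#'   ([species_config()]) and `scenario_deltas` (named list of per-layer
#'   shift vectors).
#' @export
virtual_preset <- function(seed = 1) {
  list(
    landscape = landscape_config(
      n_layers = 4, shape = c(200, 200), xll = 100, yll = 20,
      cellsize = 0.05, corr_length = 10,
      ranges = list(c(0, 100), c(0, 50), c(200, 600), c(0, 2000)),
      lat_gradient = c(0.7, 0, 0, 0), seed = seed),
    species = species_config(
      optima = c(env1 = 60, env2 = 25), breadths = c(env1 = 8, env2 = 6),
      n_presences = 200, seed = seed + 10000),
    scenario_deltas = list(northward = c(env1 = -15)))
}

#' Apply a climate scenario as additive layer shifts
#'
#' @param stack an `env_stack`.
#' @param deltas named numeric vector of per-layer additive shifts.
#' @return the shifted `env_stack` (geometry unchanged).
#' @export
apply_scenario <- function(stack, deltas) {
  miss <- setdiff(names(deltas), names(stack$layers))
  if (length(miss)) stop("deltas reference missing layer(s): ",
                         paste(miss, collapse = ", "))
  out <- stack
  for (v in names(deltas))
    out$layers[[v]]$values <- out$layers[[v]]$values + deltas[v]
  out
}
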