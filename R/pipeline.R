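#' Configuration-driven end-to-end pipeline
#'
#' One call runs the whole analysis: thin occurrences on a kilometre grid,
#' screen layers for collinearity (importance-ranked by a preliminary
#' all-variable fit), tune the regularization multiplier and feature
#' classes by AICc, fit the selected model, evaluate it, predict and
#' classify suitability under the baseline and every scenario, account
#' areas, compare scenarios and track the range centroid. Every stage
#' writes its artifacts into a numbered subdirectory of the run directory
#' and a JSON manifest records inputs, seeds, the selected configuration
#' and output checksums, so a rerun with the same config is bit-identical.
#'
#' @name pipeline
NULL

#' Assemble and validate a pipeline configuration
#'
#' @param occurrences an `occurrence_set` (or path to a CSV readable by
#'   [read_occurrences()] with default column names `species`, `longitude`,
#'   `latitude`).
#' @param stack an `env_stack` (or directory of `.asc` layers).
#' @param out_dir run directory (created).
#' @param cell_km thinning cell size (default 5).
#' @param cor_threshold collinearity cutoff (default 0.8).
#' @param rm_grid regularization multipliers to tune over; default the
#'   conventional 13-value grid 0.1, 0.5, 1, ..., 6.
#' @param fc_grid feature-class combinations; default the conventional six.
#' @param background_size background cells (default 10000).
#' @param thresholds classification cut points.
#' @param scenarios named list of scenarios, each either an `env_stack` or
#'   a named delta vector for [apply_scenario()].
#' @param hinge_knots,threshold_knots feature-basis knot counts.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(occurrences, stack, out_dir,
                            cell_km = 5, cor_threshold = 0.8,
                            rm_grid = c(0.1, seq(0.5, 6, by = 0.5)),
                            fc_grid = c("L", "LQ", "H", "LQH", "LQHP",
                                        "LQHPT"),
                            background_size = 10000,
                            thresholds = c(0.30, 0.50, 0.70),
                            scenarios = list(),
                            hinge_knots = 50, threshold_knots = 20,
                            seed = 1) {
  if (is.character(occurrences)) {
    if (!file.exists(occurrences))
      stop("occurrence file does not exist: ", occurrences)
  } else stopifnot(inherits(occurrences, "occurrence_set"))
  if (is.character(stack)) {
    if (!dir.exists(stack)) stop("layer directory does not exist: ", stack)
  } else stopifnot(inherits(stack, "env_stack"))
  stopifnot(cell_km > 0, cor_threshold > 0, cor_threshold <= 1,
            all(diff(thresholds) > 0))
  structure(list(occurrences = occurrences, stack = stack,
                 out_dir = out_dir, cell_km = cell_km,
                 cor_threshold = cor_threshold, rm_grid = rm_grid,
                 fc_grid = fc_grid, background_size = background_size,
                 thresholds = thresholds, scenarios = scenarios,
                 hinge_knots = hinge_knots,
                 threshold_knots = threshold_knots, seed = seed),
            class = "pipeline_config")
}

stage_dir <- function(root, n, name) {
  d <- file.path(root, sprintf("%02d_%s", n, name))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the full analysis pipeline
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage progress.
#' @return (invisibly) a list with the run directory, the thinned
#'   occurrences, screening result, selection result, fitted model,
#'   evaluation, per-scenario products (suitability, classes, areas,
#'   centroid) and comparisons.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  occ <- if (is.character(cfg$occurrences))
    read_occurrences(cfg$occurrences) else cfg$occurrences
  stack <- if (is.character(cfg$stack)) {
    files <- sort(list.files(cfg$stack, "\\.asc$", full.names = TRUE))
    if (!length(files)) stop("no .asc layers in ", cfg$stack)
    env_stack(lapply(files, read_ascii_grid))
  } else cfg$stack

  # 1. thin
  d <- stage_dir(cfg$out_dir, 1, "thin")
  thinned <- thin_by_grid(occ, thinning_grid(cfg$cell_km))
  write_occurrences(thinned, file.path(d, "occurrences_thinned.csv"))
  say("thin: %d -> %d records", nrow(occ), nrow(thinned))

  # 2. screen: rank variables by permutation importance of a quick
  # all-variable linear fit, then drop the lower-ranked member of every
  # pair with |r| above the threshold
  d <- stage_dir(cfg$out_dir, 2, "screen")
  bg <- sample_background(stack, cfg$background_size, seed = cfg$seed + 1)
  pres_all <- extract_values(stack, thinned$lon, thinned$lat)
  keep_rows <- stats::complete.cases(pres_all)
  if (!all(keep_rows)) {
    say("screen: dropping %d record(s) off the valid grid",
        sum(!keep_rows))
    thinned <- new_occurrence_set(thinned[keep_rows, , drop = FALSE])
    pres_all <- pres_all[keep_rows, , drop = FALSE]
  }
  prelim <- fit_maxent(pres_all, bg, feature_spec("L", rm = 1),
                       trace = FALSE)
  imp <- permutation_importance(prelim, pres_all, seed = cfg$seed + 2)
  rank_order <- names(sort(imp, decreasing = TRUE))
  screen <- select_variables(stack, cfg$cor_threshold, rank_order)
  utils::write.csv(screen$audit, file.path(d, "screening_audit.csv"),
                   row.names = FALSE)
  writeLines(screen$retained, file.path(d, "retained_variables.txt"))
  say("screen: %d -> %d variables in %d round(s)",
      length(stack$layers), length(screen$retained), screen$rounds)

  sub <- env_stack(stack$layers[screen$retained])
  bg_sub <- sample_background(sub, cfg$background_size,
                              seed = cfg$seed + 1)
  pres <- pres_all[, screen$retained, drop = FALSE]
  # collapse duplicate presence cells on the modelling grid
  cell <- extract_cell_id(sub, thinned$lon, thinned$lat)
  first <- !duplicated(cell)
  pres <- pres[first, , drop = FALSE]
  occ_fit <- new_occurrence_set(thinned[first, , drop = FALSE])

  # 3. tune
  d <- stage_dir(cfg$out_dir, 3, "tune")
  sel <- model_selection(pres, sub, cfg$rm_grid, cfg$fc_grid, bg_sub,
                         occ = occ_fit, hinge_knots = cfg$hinge_knots,
                         threshold_knots = cfg$threshold_knots)
  utils::write.csv(sel$results, file.path(d, "selection_grid.csv"),
                   row.names = FALSE)
  say("tune: selected fc=%s rm=%g (delta AICc grid of %d)",
      sel$selected$fc, sel$selected$rm, nrow(sel$results))

  # 4. fit + evaluate
  d <- stage_dir(cfg$out_dir, 4, "fit")
  model <- sel$best_model
  write_maxent_model(model, file.path(d, "model.lambdas"))
  folds <- make_partition(occ_fit, "kfold",
                          k = min(10L, nrow(occ_fit)),
                          seed = cfg$seed + 3)
  cv_auc <- vapply(sort(unique(folds)), function(f) {
    fit_f <- fit_maxent(pres[folds != f, , drop = FALSE], bg_sub,
                        model$spec, trace = FALSE)
    auc(predict_cloglog(fit_f, pres[folds == f, , drop = FALSE]),
        predict_cloglog(fit_f, bg_sub$values))
  }, numeric(1))
  train_auc <- auc(predict_cloglog(model, pres),
                   predict_cloglog(model, bg_sub$values))
  contrib <- percent_contribution(model)
  perm <- permutation_importance(model, pres, seed = cfg$seed + 4)
  utils::write.csv(data.frame(variable = names(contrib),
                              percent_contribution = unname(contrib),
                              permutation_importance = unname(perm)),
                   file.path(d, "importance.csv"), row.names = FALSE)
  curves <- lapply(model$meta$vars, function(v) response_curve(model, v))
  names(curves) <- model$meta$vars
  say("fit: train AUC %.3f, mean CV test AUC %.3f", train_auc,
      mean(cv_auc))

  # 5. predict / classify / areas per scenario
  d <- stage_dir(cfg$out_dir, 5, "scenarios")
  scen_stacks <- c(list(current = sub),
                   lapply(cfg$scenarios, function(s) {
                     if (inherits(s, "env_stack"))
                       env_stack(s$layers[screen$retained])
                     else apply_scenario(sub, s)
                   }))
  products <- lapply(names(scen_stacks), function(nm) {
    suit <- predict_stack(model, scen_stacks[[nm]])
    cm <- classify(suit, cfg$thresholds)
    write_ascii_grid(suit, file.path(d, paste0(nm, "_suitability.asc")))
    write_classified(cm, file.path(d, paste0(nm, "_classes.asc")))
    list(name = nm, suitability = suit, classes = cm,
         areas = area_summary(cm), centroid = centroid(cm))
  })
  names(products) <- names(scen_stacks)

  # 6. compare + centroids
  d <- stage_dir(cfg$out_dir, 6, "summary")
  comparisons <- do.call(rbind, lapply(products[-1], function(p)
    compare_scenarios(products$current$areas, p$areas, p$name)))
  area_tab <- do.call(rbind, lapply(products, function(p)
    data.frame(scenario = p$name, class = SUIT_CLASSES,
               area_km2 = unname(p$areas$areas))))
  cent_tab <- do.call(rbind, lapply(products, function(p)
    data.frame(scenario = p$name, lon = p$centroid$lon,
               lat = p$centroid$lat)))
  shifts <- if (length(products) > 1)
    do.call(rbind, lapply(products[-1], function(p) {
      s <- centroid_shift(products$current$centroid, p$centroid)
      data.frame(scenario = p$name, distance_km = s$distance_km,
                 bearing_deg = s$bearing_deg)
    })) else NULL
  utils::write.csv(area_tab, file.path(d, "areas.csv"), row.names = FALSE)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(d, "comparisons.csv"),
                     row.names = FALSE)
  utils::write.csv(cent_tab, file.path(d, "centroids.csv"),
                   row.names = FALSE)
  if (!is.null(shifts))
    utils::write.csv(shifts, file.path(d, "centroid_shifts.csv"),
                     row.names = FALSE)

  manifest <- list(
    seed = cfg$seed,
    n_occurrences_in = nrow(occ), n_occurrences_thinned = nrow(thinned),
    n_presence_cells = nrow(pres),
    retained_variables = screen$retained,
    screening_rounds = screen$rounds,
    selected = list(fc = sel$selected$fc, rm = sel$selected$rm,
                    k = sel$selected$k, AICc = sel$selected$AICc),
    train_auc = train_auc, cv_test_auc = mean(cv_auc),
    background = list(size = model$background_size,
                      seed = cfg$seed + 1),
    checksums = as.list(tools::md5sum(
      sort(list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE,
                      pattern = "\\.(csv|asc|lambdas|txt)$")))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(out_dir = cfg$out_dir, occurrences = occ_fit,
                 screening = screen, selection = sel, model = model,
                 train_auc = train_auc, cv_test_auc = cv_auc,
                 contribution = contrib, permutation = perm,
                 response_curves = curves, products = products,
                 comparisons = comparisons, centroid_shifts = shifts,
                 manifest = manifest))
}

# linear cell id of points on a stack's grid (NA off-grid)
extract_cell_id <- function(stack, lon, lat) {
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  col <- floor((lon - ref$xll) / ref$cellsize) + 1L
  row <- nr - floor((lat - ref$yll) / ref$cellsize)
  ifelse(col >= 1L & col <= nc & row >= 1L & row <= nr,
         (col - 1L) * nr + row, NA_integer_)
}
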