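#' Model evaluation, tuning and variable importance
#'
#' Discrimination is measured by the rank (Mann-Whitney) AUC of presence
#' versus background scores. Candidate feature-class / regularization
#' settings are compared by the small-sample Akaike criterion
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `k` the number of nonzero
#' coefficients and the likelihood normalised over the full landscape.
#' Variable importance is reported three ways, mirroring standard
#' maximum-entropy tooling: percent contribution (gain credited along the
#' optimisation path), permutation importance (AUC drop when a variable is
#' shuffled), and jackknife training gains.
#'
#' @name evaluation
NULL

#' Partition occurrences for cross-validation
#'
#' `kfold` gives seeded random folds whose sizes differ by at most one.
#' `spatial_block` splits the points at the median longitude and each half
#' at its own median latitude, yielding four spatially coherent quadrant
#' blocks of near-equal size.
#'
#' @param occ an `occurrence_set` (or any data frame with `lon`, `lat`).
#' @param kind `"kfold"` or `"spatial_block"`.
#' @param k folds (10 conventional for kfold; spatial blocking always
#'   yields 4).
#' @param seed RNG seed for kfold assignment.
#' @return integer vector of fold labels, one per record.
#' @export
make_partition <- function(occ, kind = c("kfold", "spatial_block"), k = 10,
                           seed = 1) {
  kind <- match.arg(kind)
  n <- nrow(occ)
  if (kind == "kfold") {
    if (n < k) stop("fewer records (", n, ") than folds (", k, ")")
    old <- .Random.seed_save()
    set.seed(seed)
    lab <- sample(rep_len(seq_len(k), n))
    .Random.seed_restore(old)
    return(lab)
  }
  if (n < 4L) stop("need at least 4 records for spatial blocks")
  # rank-based median splits: deterministic and balanced under ties
  west <- rank(occ$lon, ties.method = "first") <= ceiling(n / 2)
  lab <- integer(n)
  for (half in list(which(west), which(!west))) {
    south <- rank(occ$lat[half], ties.method = "first") <=
      ceiling(length(half) / 2)
    lab[half[south]] <- if (all(west[half])) 1L else 3L
    lab[half[!south]] <- if (all(west[half])) 2L else 4L
  }
  lab
}

#' Rank AUC of presence versus background scores
#'
#' The probability that a random presence outscores a random background
#' point, ties counted half: the Mann-Whitney U statistic scaled to \[0,1\].
#'
#' @param presence_scores,background_scores numeric vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("empty score vector")
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Small-sample AIC of a fitted model
#'
#' The likelihood renormalises the Gibbs density over the full landscape
#' (every jointly valid cell), the convention of standard SDM tuning tools,
#' so models fitted on a background subsample remain comparable.
#'
#' @param model a `maxent_model`.
#' @param presence_values covariate matrix at the n presence cells.
#' @param landscape_values covariate matrix of all valid landscape cells.
#' @return list with `k` (nonzero coefficients), `lnL`, and `AICc` (`NA`
#'   with a flag when `n - k - 1 <= 0`).
#' @export
aicc <- function(model, presence_values, landscape_values) {
  n <- nrow(as.matrix(presence_values))
  k <- sum(model$lambdas != 0)
  rp <- predict_raw(model, presence_values)
  rl <- predict_raw(model, landscape_values)
  lnL <- sum(log(rp / sum(rl)))
  list(k = k, lnL = lnL, AICc = aicc_formula(k, lnL, n),
       valid = n - k - 1 > 0)
}

#' The corrected-AIC formula
#'
#' `2k - 2 lnL + 2k(k+1)/(n-k-1)`; `NA` when `n - k - 1 <= 0`.
#'
#' @param k nonzero parameter count.
#' @param lnL log-likelihood.
#' @param n sample size.
#' @return numeric.
#' @export
aicc_formula <- function(k, lnL, n) {
  ifelse(n - k - 1 > 0, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
         NA_real_)
}

#' Tune feature classes and regularization by AICc
#'
#' Fits every (rm, fc) combination on the full presence set, scores it by
#' [aicc()] over the landscape, and carries spatial-block cross-validation
#' diagnostics (mean test AUC and omission at the 10th-percentile training
#' threshold). Selection: minimum AICc; ties broken by fewer parameters,
#' then larger rm.
#'
#' @param presence_values covariate matrix at presence cells.
#' @param stack the `env_stack` (landscape + background source).
#' @param rm_grid numeric vector of regularization multipliers.
#' @param fc_grid character vector of feature-class strings.
#' @param background a [sample_background()] result (reused across fits).
#' @param occ optional `occurrence_set` aligned with `presence_values`,
#'   enabling the block cross-validation diagnostics.
#' @param hinge_knots,threshold_knots knot counts handed to
#'   [feature_spec()].
#' @param verbose print one line per combination.
#' @return a `model_selection` list: `results` data frame (rm, fc, k, lnL,
#'   AICc, delta_AICc, mean_test_auc, mean_omission), `selected` row, and
#'   the refitted `best_model`.
#' @export
model_selection <- function(presence_values, stack, rm_grid, fc_grid,
                            background, occ = NULL,
                            hinge_knots = 50, threshold_knots = 20,
                            verbose = FALSE) {
  stopifnot(length(rm_grid) >= 1L, length(fc_grid) >= 1L)
  sv <- stack_values(stack)
  blocks <- if (!is.null(occ))
    make_partition(occ, "spatial_block") else NULL
  rows <- list()
  for (fc in fc_grid) for (rm in rm_grid) {
    spec <- feature_spec(fc, rm = rm, hinge_knots = hinge_knots,
                         threshold_knots = threshold_knots)
    fit <- fit_maxent(presence_values, background, spec, trace = FALSE)
    ic <- aicc(fit, presence_values, sv$values)
    cv_auc <- cv_om <- NA_real_
    if (!is.null(blocks)) {
      aucs <- oms <- numeric(0)
      for (b in sort(unique(blocks))) {
        tr <- blocks != b
        if (sum(tr) < 2L || sum(!tr) < 1L) next
        f_b <- tryCatch(
          fit_maxent(presence_values[tr, , drop = FALSE], background, spec,
                     trace = FALSE),
          error = function(e) NULL)
        if (is.null(f_b)) next
        sc_tr <- predict_cloglog(f_b, presence_values[tr, , drop = FALSE])
        sc_te <- predict_cloglog(f_b, presence_values[!tr, , drop = FALSE])
        sc_bg <- predict_cloglog(f_b, background$values)
        aucs <- c(aucs, auc(sc_te, sc_bg))
        thr <- stats::quantile(sc_tr, 0.1, names = FALSE)
        oms <- c(oms, mean(sc_te < thr))
      }
      if (length(aucs)) { cv_auc <- mean(aucs); cv_om <- mean(oms) }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rm = rm, fc = fc, k = ic$k, lnL = ic$lnL, AICc = ic$AICc,
      mean_test_auc = cv_auc, mean_omission = cv_om,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fc=%s rm=%g: k=%d AICc=%s", fc, rm, ic$k,
                      format(ic$AICc)))
  }
  res <- do.call(rbind, rows)
  if (all(is.na(res$AICc)))
    stop("AICc undefined for every combination (too few presences)")
  res$delta_AICc <- res$AICc - min(res$AICc, na.rm = TRUE)
  ord <- order(res$delta_AICc, res$k, -res$rm)
  sel <- res[ord[1], ]
  best <- fit_maxent(presence_values, background,
                     feature_spec(sel$fc, rm = sel$rm,
                                  hinge_knots = hinge_knots,
                                  threshold_knots = threshold_knots))
  structure(list(results = res, selected = sel, best_model = best),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %d combinations; selected fc=%s rm=%g (k=%d, AICc=%.2f)\n",
              nrow(x$results), x$selected$fc, x$selected$rm, x$selected$k,
              x$selected$AICc))
  invisible(x)
}

#' Percent contribution from the optimisation path
#'
#' Each coordinate update's change in penalized gain is credited to the
#' updated feature's source variable (product features split 50/50).
#' Credits may be negative along the path; the final per-variable totals
#' are rescaled to sum to 100. The measure is path-dependent by nature and
#' is deterministic here because the solver is.
#'
#' @param model a `maxent_model` fitted with `trace = TRUE`.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  if (is.null(model$trace))
    stop("model was fitted with trace = FALSE; refit with trace = TRUE")
  credit <- stats::setNames(numeric(length(model$meta$vars)),
                            model$meta$vars)
  tr <- model$trace
  for (i in seq_len(nrow(tr))) {
    if (!is.na(tr$var2[i])) {
      credit[tr$var[i]] <- credit[tr$var[i]] + tr$delta_gain[i] / 2
      credit[tr$var2[i]] <- credit[tr$var2[i]] + tr$delta_gain[i] / 2
    } else {
      credit[tr$var[i]] <- credit[tr$var[i]] + tr$delta_gain[i]
    }
  }
  total <- sum(credit)
  if (total <= 0) return(credit * 0)
  100 * credit / total
}

#' Permutation importance
#'
#' For each variable, its values are shuffled across the combined
#' presence + background rows; the drop in training AUC (floored at zero)
#' is averaged over `n_reps` shuffles and the per-variable means are
#' normalised to sum to 100.
#'
#' @param model a `maxent_model`.
#' @param presence_values,background_values covariate matrices.
#' @param seed RNG seed.
#' @param n_reps shuffles per variable (default 10).
#' @return named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, presence_values,
                                   background_values = NULL,
                                   seed = 1, n_reps = 10) {
  if (is.null(background_values)) background_values <- model$background$values
  presence_values <- as.matrix(presence_values)
  comb <- rbind(presence_values[, model$meta$vars, drop = FALSE],
                background_values[, model$meta$vars, drop = FALSE])
  m <- nrow(presence_values)
  base_auc <- auc(predict_raw(model, comb[seq_len(m), , drop = FALSE]),
                  predict_raw(model, comb[-seq_len(m), , drop = FALSE]))
  old <- .Random.seed_save()
  set.seed(seed)
  drops <- vapply(model$meta$vars, function(v) {
    mean(vapply(seq_len(n_reps), function(r) {
      perm <- comb
      perm[, v] <- sample(perm[, v])
      a <- auc(predict_raw(model, perm[seq_len(m), , drop = FALSE]),
               predict_raw(model, perm[-seq_len(m), , drop = FALSE]))
      max(0, base_auc - a)
    }, numeric(1)))
  }, numeric(1))
  .Random.seed_restore(old)
  if (sum(drops) == 0) {
    warning("no variable produced an AUC drop; uniform attribution")
    return(stats::setNames(rep(100 / length(drops), length(drops)),
                           model$meta$vars))
  }
  100 * drops / sum(drops)
}

# regularized training gain: mean log of N * raw at presences minus the
# L1 penalty; zero for the uniform (all-lambda-zero) model
training_gain <- function(model, presence_values) {
  rp <- predict_raw(model, presence_values)
  mean(log(rp * model$background_size)) -
    sum(model$beta * abs(model$lambdas))
}

#' Jackknife of variable training gains
#'
#' Fits, for every variable, a with-only-this-variable model and a
#' without-this-variable model, plus the full model, and reports their
#' regularized training gains.
#'
#' @param presence_values covariate matrix at presence cells.
#' @param background a [sample_background()] result or covariate matrix.
#' @param spec a [feature_spec()].
#' @return list with `table` (variable, gain_with_only, gain_without) and
#'   `full_gain`.
#' @export
jackknife_gains <- function(presence_values, background,
                            spec = feature_spec()) {
  bg_values <- if (inherits(background, "background_sample"))
    background$values else as.matrix(background)
  presence_values <- as.matrix(presence_values)
  vars <- colnames(bg_values)
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  gain_of <- function(cols) {
    f <- fit_maxent(presence_values[, cols, drop = FALSE],
                    bg_values[, cols, drop = FALSE], spec, trace = FALSE)
    training_gain(f, presence_values[, cols, drop = FALSE])
  }
  tab <- data.frame(
    variable = vars,
    gain_with_only = vapply(vars, function(v) gain_of(v), numeric(1)),
    gain_without = vapply(vars, function(v) gain_of(setdiff(vars, v)),
                          numeric(1)),
    stringsAsFactors = FALSE)
  list(table = tab, full_gain = gain_of(vars))
}

#' Bootstrap confidence intervals for variable importance
#'
#' Resamples the presence set with replacement, refits, and collects the
#' percent-contribution column, giving seeded percentile intervals per
#' variable. Intervals describe sampling variability under this package's
#' path-credit definition of contribution.
#'
#' @param presence_values covariate matrix at presence cells.
#' @param background a [sample_background()] result or covariate matrix.
#' @param spec a [feature_spec()].
#' @param n_boot bootstrap replicates (default 50).
#' @param seed RNG seed.
#' @param level interval coverage (default 0.95).
#' @return data frame: variable, mean, lower, upper (percent).
#' @export
bootstrap_contribution <- function(presence_values, background,
                                   spec = feature_spec(), n_boot = 50,
                                   seed = 1, level = 0.95) {
  presence_values <- as.matrix(presence_values)
  m <- nrow(presence_values)
  old <- .Random.seed_save()
  set.seed(seed)
  draws <- replicate(n_boot, {
    idx <- sample.int(m, m, replace = TRUE)
    fit <- fit_maxent(presence_values[idx, , drop = FALSE], background,
                      spec)
    percent_contribution(fit)
  })
  .Random.seed_restore(old)
  a <- (1 - level) / 2
  data.frame(variable = rownames(draws),
             mean = rowMeans(draws),
             lower = apply(draws, 1, stats::quantile, probs = a),
             upper = apply(draws, 1, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

#' Univariate response curve
#'
#' Sweeps one variable across its background range with every other
#' variable held at its background mean, and records the suitability
#' response, its argmax, and the interval(s) where it exceeds 0.5 (the
#' conventional climatic-envelope cutoff).
#'
#' @param model a `maxent_model`.
#' @param variable variable name.
#' @param n_grid grid points (default 200).
#' @return a `response_curve`: data frame `curve` (value, response),
#'   `optimum`, and `envelope` (matrix of interval bounds, 0 rows if the
#'   response never exceeds 0.5).
#' @export
response_curve <- function(model, variable, n_grid = 200) {
  if (!variable %in% model$meta$vars)
    stop("variable not in model: ", variable)
  bg <- model$background$values
  grid <- seq(model$meta$lo[variable], model$meta$hi[variable],
              length.out = n_grid)
  newdata <- matrix(rep(colMeans(bg), each = n_grid), n_grid,
                    ncol(bg), dimnames = list(NULL, colnames(bg)))
  newdata[, variable] <- grid
  resp <- predict_cloglog(model, newdata)
  above <- resp > 0.5
  env <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(lower = grid[starts[r$values]], upper = grid[ends[r$values]])
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lower", "upper")))
  structure(list(variable = variable,
                 curve = data.frame(value = grid, response = resp),
                 optimum = grid[which.max(resp)], envelope = env),
            class = "response_curve")
}
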