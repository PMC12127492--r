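#' L1-penalized maximum-entropy density estimation
#'
#' The model is the Gibbs distribution over landscape cells,
#' `P(x) = exp(lambda . f(x)) / Z`, whose coefficients maximise the
#' penalized presence log-likelihood
#'
#'   `(1/m) sum_i lambda . f(x_i) - ln Z - sum_j beta_j |lambda_j|`
#'
#' with `Z = sum_background exp(lambda . f(x))`. Features f are built from
#' the raw covariates: linear (min-max scaled to \[0,1\]), quadratic,
#' pairwise products, forward/reverse hinges and step thresholds. The
#' per-feature penalty follows the conventional default rule
#' `beta_j = rm * beta0(class, m) * s_j / sqrt(m)`, where `rm` is the
#' user's regularization multiplier, `beta0` comes from the standard
#' sample-size interpolation tables (linear/quadratic/product values 1.0 at
#' m <= 10 falling to 0.05 at m >= 100; hinge constant 0.5; threshold 2.0
#' falling to 1.0 at m >= 100), and `s_j` is the standard deviation of
#' feature j over the m presence points (floored at 0.01 so nearly
#' constant features stay penalized).
#'
#' Optimisation is cyclic coordinate descent: each coordinate takes a
#' Newton step soft-thresholded by its penalty, backtracked so the penalized
#' objective never decreases. The problem is convex, so this converges to
#' the global optimum.
#'
#' @name maxent
NULL

#' Feature-class specification
#'
#' @param classes character scalar such as `"LQ"` or `"LQHPT"`; letters are
#'   L (linear), Q (quadratic), H (hinge), P (product), T (threshold).
#' @param rm regularization multiplier (> 0).
#' @param hinge_knots hinge knots per variable.
#' @param threshold_knots threshold knots per variable.
#' @return a `feature_spec`.
#' @export
feature_spec <- function(classes = "LQ", rm = 1, hinge_knots = 50,
                         threshold_knots = 20) {
  cls <- strsplit(toupper(classes), "")[[1]]
  if (!length(cls) || !all(cls %in% c("L", "Q", "H", "P", "T")))
    stop("classes must be a non-empty combination of L, Q, H, P, T")
  stopifnot(rm > 0)
  structure(list(classes = unique(cls), rm = rm,
                 hinge_knots = as.integer(hinge_knots),
                 threshold_knots = as.integer(threshold_knots)),
            class = "feature_spec")
}

# beta0 interpolation tables: penalty base per feature class as a function
# of presence sample size m (linear interpolation, clamped at the ends).
beta0_default <- function(class, m) {
  interp <- function(ss, b) stats::approx(ss, b, xout = m, rule = 2)$y
  switch(class,
         L = , Q = , P = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         H = 0.5,
         T = interp(c(0, 100), c(2, 1)),
         stop("unknown feature class: ", class))
}

#' Default per-feature L1 penalties
#'
#' `beta_j = rm * beta0(class, m) * max(s_j, 0.01) / sqrt(m)` with `s_j`
#' the sample standard deviation of feature j over the m presence points.
#'
#' @param presence_features feature matrix at the presence points.
#' @param meta the [feature_meta()] the features were built with.
#' @param rm regularization multiplier.
#' @return numeric vector of penalties, one per feature.
#' @export
default_betas <- function(presence_features, meta, rm) {
  m <- nrow(presence_features)
  b0 <- vapply(meta$features$kind, function(kd)
    beta0_default(substr(kd, 1, 1), m), numeric(1))
  s <- apply(presence_features, 2, stats::sd)
  if (m == 1L) s[] <- 0
  rm * b0 * pmax(s, 0.01) / sqrt(m)
}

#' Build feature metadata from a background sample
#'
#' Records per-variable scaling bounds (background min/max) and knot
#' positions (background quantiles) so that presence and prediction features
#' are built on the identical basis.
#'
#' @param bg_values background covariate matrix (rows = cells).
#' @param spec a [feature_spec()].
#' @return a `feature_meta` with one row per feature: kind, variables,
#'   bounds and knot.
#' @export
feature_meta <- function(bg_values, spec) {
  vars <- colnames(bg_values)
  if (is.null(vars)) stop("background matrix must have column names")
  lo <- apply(bg_values, 2, min)
  hi <- apply(bg_values, 2, max)
  degenerate <- vars[hi <= lo]
  if (length(degenerate))
    stop("degenerate variable(s) with max <= min: ",
         paste(degenerate, collapse = ", "))

  feats <- list()
  add <- function(kind, var, var2 = NA_character_, knot = NA_real_)
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, var = var, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)

  if ("L" %in% spec$classes) for (v in vars) add("L", v)
  if ("Q" %in% spec$classes) for (v in vars) add("Q", v)
  if ("P" %in% spec$classes && length(vars) >= 2L) {
    cmb <- utils::combn(vars, 2)
    for (k in seq_len(ncol(cmb))) add("P", cmb[1, k], cmb[2, k])
  }
  if ("H" %in% spec$classes) {
    probs <- seq(0, 1, length.out = spec$hinge_knots + 2L)
    probs <- probs[-c(1L, length(probs))]
    for (v in vars) {
      ks <- unique(stats::quantile(bg_values[, v], probs, names = FALSE))
      ks <- ks[ks > lo[v] & ks < hi[v]]
      for (k in ks) { add("HF", v, knot = k); add("HR", v, knot = k) }
    }
  }
  if ("T" %in% spec$classes) {
    probs <- seq(0, 1, length.out = spec$threshold_knots + 2L)
    probs <- probs[-c(1L, length(probs))]
    for (v in vars) {
      ks <- unique(stats::quantile(bg_values[, v], probs, names = FALSE))
      ks <- ks[ks > lo[v] & ks < hi[v]]
      for (k in ks) add("T", v, knot = k)
    }
  }
  tab <- do.call(rbind, feats)
  tab$name <- ifelse(tab$kind == "P", paste0(tab$var, "*", tab$var2),
                     ifelse(is.na(tab$knot), paste0(tab$kind, "(", tab$var, ")"),
                            sprintf("%s(%s@%.6g)", tab$kind, tab$var, tab$knot)))
  structure(list(features = tab, lo = lo, hi = hi, vars = vars),
            class = "feature_meta")
}

#' Evaluate the feature basis at covariate values
#'
#' Values outside the background bounds are clamped so every feature lies in
#' \[0, 1\].
#'
#' @param values covariate matrix (rows = points, columns named as in the
#'   meta).
#' @param meta a [feature_meta()].
#' @return numeric matrix, one column per feature.
#' @export
build_features <- function(values, meta) {
  values <- as.matrix(values)
  if (!all(meta$vars %in% colnames(values)))
    stop("values lack variable(s): ",
         paste(setdiff(meta$vars, colnames(values)), collapse = ", "))
  n <- nrow(values)
  scaled <- vapply(meta$vars, function(v) {
    s <- (values[, v] - meta$lo[v]) / (meta$hi[v] - meta$lo[v])
    pmin(pmax(s, 0), 1)
  }, numeric(n))
  if (n == 1L) scaled <- matrix(scaled, 1L, dimnames = list(NULL, meta$vars))
  tab <- meta$features
  out <- matrix(0, n, nrow(tab), dimnames = list(NULL, tab$name))
  for (j in seq_len(nrow(tab))) {
    v <- tab$var[j]; k <- tab$knot[j]
    out[, j] <- switch(tab$kind[j],
      L = scaled[, v],
      Q = scaled[, v]^2,
      P = scaled[, v] * scaled[, tab$var2[j]],
      HF = pmin(pmax((values[, v] - k) / (meta$hi[v] - k), 0), 1),
      HR = pmin(pmax((k - values[, v]) / (k - meta$lo[v]), 0), 1),
      T = as.numeric(values[, v] > k))
  }
  out
}

#' Sample background cells from a stack
#'
#' Uniform, seeded sampling without replacement over the jointly valid
#' cells; if `m` exceeds the number of valid cells, all of them are used
#' with a warning.
#'
#' @param stack an `env_stack`.
#' @param m number of background cells (default 10000).
#' @param seed integer seed.
#' @return a `background_sample`: covariate matrix `values`, coordinates
#'   `lon`/`lat`, cell `index`, `seed`.
#' @export
sample_background <- function(stack, m = 10000, seed = 1) {
  sv <- stack_values(stack)
  n <- nrow(sv$values)
  if (n == 0L) stop("stack has no valid cells")
  if (m >= n) {
    if (m > n) warning("m exceeds valid cell count; using all ", n, " cells")
    pick <- seq_len(n)
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    pick <- sample.int(n, m)
    .Random.seed_restore(old)
  }
  structure(list(values = sv$values[pick, , drop = FALSE],
                 lon = sv$lon[pick], lat = sv$lat[pick],
                 index = sv$index[pick], seed = seed),
            class = "background_sample")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Fit the penalized maximum-entropy model
#'
#' @param presence_values covariate matrix at presence cells (one row per
#'   presence; duplicate raster cells should be collapsed beforehand).
#' @param background a [sample_background()] result, or a covariate matrix.
#' @param spec a [feature_spec()].
#' @param tol relative objective-improvement convergence tolerance per
#'   sweep (default 1e-5).
#' @param max_iter maximum coordinate-descent sweeps (default 500).
#' @param trace keep the per-update gain trace needed by
#'   [percent_contribution()] (default TRUE).
#' @return a `maxent_model`: `lambdas`, `meta`, `spec`, `beta`,
#'   `log_normalizer` (ln Z over the background), `entropy` (H of the raw
#'   distribution), `background`, objective path, and the update trace.
#' @export
fit_maxent <- function(presence_values, background, spec = feature_spec(),
                       tol = 1e-5, max_iter = 500, trace = TRUE) {
  bg_values <- if (inherits(background, "background_sample"))
    background$values else as.matrix(background)
  presence_values <- as.matrix(presence_values)
  if (nrow(presence_values) < 1L) stop("no presence points")
  meta <- feature_meta(bg_values, spec)
  Fp <- build_features(presence_values, meta)
  Fb <- build_features(bg_values, meta)
  m <- nrow(Fp); N <- nrow(Fb); J <- ncol(Fb)
  beta <- default_betas(Fp, meta, spec$rm)

  fbar <- colMeans(Fp)              # empirical presence feature means
  lambda <- numeric(J)
  eta <- numeric(N)                 # F_b %*% lambda
  lnZ <- log(N)
  obj <- sum(lambda * fbar) - lnZ - sum(beta * abs(lambda))
  obj_path <- obj
  upd <- if (trace) vector("list", 0L) else NULL

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    obj_start <- obj
    for (j in seq_len(J)) {
      w <- exp(eta - lnZ)
      fj <- Fb[, j]
      Ef <- sum(w * fj)
      grad <- fbar[j] - Ef
      hess <- sum(w * fj^2) - Ef^2           # Var_w(f_j) >= 0
      if (hess < 1e-12) next
      z <- lambda[j] + grad / hess
      lam_new <- sign(z) * max(0, abs(z) - beta[j] / hess)
      if (lam_new == lambda[j]) next
      # backtracking: the Newton step can overshoot for this non-quadratic
      # objective; halve toward the current value until no decrease
      step_ok <- FALSE
      for (half in 0:30) {
        cand <- lambda[j] + (lam_new - lambda[j]) / 2^half
        eta_c <- eta + (cand - lambda[j]) * fj
        lnZ_c <- log_sum_exp(eta_c)
        obj_c <- as.numeric(
          sum(fbar * lambda) + fbar[j] * (cand - lambda[j]) - lnZ_c -
            sum(beta * abs(lambda)) - beta[j] * (abs(cand) - abs(lambda[j])))
        if (obj_c >= obj - 1e-12) { step_ok <- TRUE; break }
      }
      if (!step_ok) next
      if (trace && abs(obj_c - obj) > 0)
        upd[[length(upd) + 1L]] <- c(j, obj_c - obj)
      lambda[j] <- cand
      eta <- eta_c
      lnZ <- lnZ_c
      obj <- obj_c
    }
    obj_path <- c(obj_path, obj)
    if (abs(obj - obj_start) < tol * (abs(obj_start) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("coordinate descent did not converge in ", max_iter,
         " sweeps; objective path tail: ",
         paste(signif(utils::tail(obj_path, 5), 8), collapse = " "))

  p <- exp(eta - lnZ)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  trace_df <- if (trace && length(upd)) {
    u <- do.call(rbind, upd)
    data.frame(feature = meta$features$name[u[, 1]],
               var = meta$features$var[u[, 1]],
               var2 = meta$features$var2[u[, 1]],
               delta_gain = u[, 2], stringsAsFactors = FALSE)
  } else NULL

  structure(list(lambdas = stats::setNames(lambda, meta$features$name),
                 meta = meta, spec = spec, beta = beta,
                 log_normalizer = lnZ, entropy = H,
                 background = if (inherits(background, "background_sample"))
                   background else list(values = bg_values),
                 background_size = N, n_presence = m,
                 objective = obj, objective_path = obj_path,
                 trace = trace_df),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s, rm = %g: %d/%d nonzero features, %d presences, %d background\n  lnZ = %.4f, H = %.4f, penalized objective = %.4f\n",
    paste(x$spec$classes, collapse = ""), x$spec$rm,
    sum(x$lambdas != 0), length(x$lambdas), x$n_presence,
    x$background_size, x$log_normalizer, x$entropy, x$objective))
  invisible(x)
}

#' Raw (Gibbs) prediction
#'
#' `exp(lambda . f(x) - ln Z)`; over the fitted background these sum to 1.
#'
#' @param model a `maxent_model`.
#' @param values covariate matrix at prediction points.
#' @return nonnegative numeric vector.
#' @export
predict_raw <- function(model, values) {
  Fx <- build_features(values, model$meta)
  as.numeric(exp(Fx %*% model$lambdas - model$log_normalizer))
}

#' Cloglog (and logistic) suitability prediction
#'
#' The cloglog transform `1 - exp(-exp(H) * raw)` maps the raw density to a
#' \[0, 1\] suitability index calibrated so a completely uninformative model
#' scores `1 - exp(-1)` everywhere; H is the entropy of the fitted raw
#' distribution over the background. The logistic variant
#' `r e^H / (1 + r e^H)` is available for comparison with older tools.
#'
#' @param model a `maxent_model`.
#' @param values covariate matrix at prediction points.
#' @param type `"cloglog"` (default) or `"logistic"`.
#' @return numeric vector in \[0, 1\].
#' @export
predict_cloglog <- function(model, values, type = c("cloglog", "logistic")) {
  type <- match.arg(type)
  r <- predict_raw(model, values)
  s <- r * exp(model$entropy)
  if (type == "cloglog") 1 - exp(-s) else s / (1 + s)
}

#' Predict suitability over a whole stack
#'
#' @param model a `maxent_model`.
#' @param stack an `env_stack` aligned with the training layers.
#' @param type passed to [predict_cloglog()]; `"raw"` gives the Gibbs
#'   density.
#' @return a `grid_layer` of predictions (NA outside the valid mask).
#' @export
predict_stack <- function(model, stack, type = "cloglog") {
  sv <- stack_values(stack)
  p <- if (type == "raw") predict_raw(model, sv$values)
       else predict_cloglog(model, sv$values, type)
  ref <- stack$layers[[1]]
  v <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  v[sv$index] <- p
  grid_layer(v, ref$xll, ref$yll, ref$cellsize, name = "suitability",
             nodata_value = ref$nodata_value)
}

#' Serialize a fitted model to a flat text file
#'
#' One `feature TAB lambda TAB lo TAB hi TAB knot` line per feature, with
#' `#`-prefixed header lines for the normalizer, entropy, and background
#' provenance.
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @export
write_maxent_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# classes\t", paste(model$spec$classes, collapse = "")),
    paste0("# rm\t", format(model$spec$rm, digits = 15)),
    paste0("# lnZ\t", format(model$log_normalizer, digits = 17)),
    paste0("# entropy\t", format(model$entropy, digits = 17)),
    paste0("# background_size\t", model$background_size),
    paste0("# n_presence\t", model$n_presence)), con)
  tab <- model$meta$features
  for (j in seq_len(nrow(tab))) {
    v <- tab$var[j]
    writeLines(paste(tab$name[j],
                     format(model$lambdas[j], digits = 17),
                     format(model$meta$lo[v], digits = 17),
                     format(model$meta$hi[v], digits = 17),
                     format(tab$knot[j], digits = 17),
                     sep = "\t"), con)
  }
  invisible(path)
}
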