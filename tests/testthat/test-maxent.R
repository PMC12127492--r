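test_that("feature construction matches its closed forms", {
  bg <- cbind(v = c(0, 2, 4, 6, 8, 10), w = c(1, 1, 2, 3, 5, 8))
  spec <- feature_spec("LQHPT", hinge_knots = 3, threshold_knots = 3)
  meta <- feature_meta(bg, spec)
  F <- build_features(cbind(v = c(0, 5, 10, 99), w = c(1, 4.5, 8, 99)), meta)

  expect_equal(unname(F[, "L(v)"]), c(0, 0.5, 1, 1))   # clamped above
  expect_equal(unname(F[, "Q(v)"]), c(0, 0.25, 1, 1))
  expect_equal(unname(F[, "v*w"]), unname(F[, "L(v)"] * F[, "L(w)"]))
  # forward hinge is 0 exactly at its knot, 1 at the max
  hf <- grep("^HF\\(v", colnames(F), value = TRUE)[1]
  k <- as.numeric(sub(".*@(.*)\\)", "\\1", hf))
  Fk <- build_features(cbind(v = c(k, 10), w = c(1, 1)), meta)
  expect_equal(unname(Fk[, hf]), c(0, 1))
  # threshold is a strict indicator
  th <- grep("^T\\(v", colnames(F), value = TRUE)[1]
  kt <- as.numeric(sub(".*@(.*)\\)", "\\1", th))
  Ft <- build_features(cbind(v = c(kt, kt + 1e-9), w = c(1, 1)), meta)
  expect_equal(unname(Ft[, th]), c(0, 1))
  expect_true(all(F >= 0 & F <= 1))

  expect_error(feature_meta(cbind(v = c(1, 1)), feature_spec("L")),
               "degenerate")
})

test_that("default penalties follow the sd-scaled interpolation tables", {
  # m = 100 presences: beta0 is 0.05 (LQP), 0.5 (hinge), 1.0 (threshold)
  set.seed(4)
  bg <- cbind(v = stats::runif(500, 0, 1), w = stats::runif(500, 0, 1))
  spec <- feature_spec("LQHPT", rm = 2, hinge_knots = 2, threshold_knots = 2)
  meta <- feature_meta(bg, spec)
  Fp <- build_features(bg[1:100, ], meta)
  beta <- default_betas(Fp, meta, rm = 2)
  kinds <- substr(meta$features$kind, 1, 1)
  s <- apply(Fp, 2, stats::sd)
  expect_equal(unname(beta[kinds == "L"]),
               unname(2 * 0.05 * pmax(s[kinds == "L"], 0.01) / 10))
  expect_equal(unname(beta[kinds == "H"]),
               unname(2 * 0.5 * pmax(s[kinds == "H"], 0.01) / 10))
  expect_equal(unname(beta[kinds == "T"]),
               unname(2 * 1.0 * pmax(s[kinds == "T"], 0.01) / 10))
})

test_that("background sampling is seeded, exhaustive at m = n, and unbiased", {
  set.seed(2)
  st <- make_stack(a = matrix(stats::rnorm(10000), 100, 100), cellsize = 0.05)
  b1 <- sample_background(st, 1000, seed = 5)
  b2 <- sample_background(st, 1000, seed = 5)
  expect_identical(b1$index, b2$index)
  expect_equal(nrow(b1$values), 1000)

  ball <- suppressWarnings(sample_background(st, 20000, seed = 5))
  expect_equal(sort(ball$index), which(valid_mask(st)))

  # CLT bound: sample mean within 4 standard errors of the grid mean
  gm <- mean(st$layers$a$values)
  se <- stats::sd(st$layers$a$values) / sqrt(1000)
  expect_lt(abs(mean(b1$values[, "a"]) - gm), 4 * se)
})

test_that("fitting matches a brute-force grid-search oracle in 1-D", {
  bg <- landscape_1d()
  pres <- matrix(c(0.8, 0.9, 1.0), ncol = 1, dimnames = list(NULL, "v"))
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 0.5))
  lam_star <- oracle_lambda_1d(mean(c(0.8, 0.9, 1.0)), bg[, 1],
                               beta = unname(fit$beta))
  expect_equal(unname(fit$lambdas), lam_star, tolerance = 1e-3)

  # raw normalization over the background
  expect_equal(sum(predict_raw(fit, bg)), 1, tolerance = 1e-9)
  # objective path is non-decreasing
  expect_true(all(diff(fit$objective_path) >= -1e-12))
})

test_that("two-feature fits also match an exhaustive 2-D oracle", {
  bg <- cbind(v = seq(0, 1, length.out = 9),
              w = c(0.1, 0.9, 0.3, 0.7, 0.5, 0.2, 0.8, 0.4, 0.6))
  pres <- cbind(v = c(0.875, 1), w = c(0.8, 0.4))
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 0.5))
  # oracle: dense 2-D grid over (lambda_v, lambda_w)
  fbar <- colMeans(pres)
  gr <- seq(-6, 12, 0.01)
  best <- c(NA, NA); bestobj <- -Inf
  for (lv in gr) {
    z <- lv * bg[, "v"]
    o <- fbar["v"] * lv - fit$beta[1] * abs(lv) +
      vapply(gr, function(lw) fbar["w"] * lw -
               log(sum(exp(z + lw * bg[, "w"]))) - fit$beta[2] * abs(lw),
             numeric(1))
    if (max(o) > bestobj) { bestobj <- max(o); best <- c(lv, gr[which.max(o)]) }
  }
  expect_equal(unname(fit$lambdas), best, tolerance = 2e-2)
  expect_equal(fit$objective, bestobj, tolerance = 1e-4)
})

test_that("presence equal to background gives the uniform model", {
  bg <- landscape_1d()
  fit <- fit_maxent(bg, bg, feature_spec("LQ", rm = 1))
  expect_equal(unname(fit$lambdas), c(0, 0))
  expect_equal(predict_raw(fit, bg), rep(1 / 11, 11))
  expect_equal(fit$entropy, log(11))
  # uniform model cloglog is analytically 1 - exp(-1) everywhere
  expect_equal(predict_cloglog(fit, bg), rep(1 - exp(-1), 11))
})

test_that("stronger regularization shrinks the coefficient norm", {
  set.seed(11)
  bg <- cbind(v = stats::runif(200), w = stats::runif(200))
  pres <- bg[bg[, "v"] > 0.6, , drop = FALSE][1:30, ]
  f_small <- fit_maxent(pres, bg, feature_spec("LQ", rm = 0.5))
  f_large <- fit_maxent(pres, bg, feature_spec("LQ", rm = 2))
  expect_lte(sum(abs(f_large$lambdas)), sum(abs(f_small$lambdas)) + 1e-9)
})

test_that("cloglog stays in [0,1] and ranking is monotone in the raw score", {
  set.seed(12)
  for (i in 1:5) {
    bg <- cbind(v = stats::runif(50), w = stats::runif(50))
    pres <- bg[sample(50, 10), , drop = FALSE]
    fit <- fit_maxent(pres, bg, feature_spec("LQ", rm = 0.5))
    p <- predict_cloglog(fit, bg)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(order(p), order(predict_raw(fit, bg)))
    pl <- predict_cloglog(fit, bg, type = "logistic")
    expect_true(all(pl >= 0 & pl <= 1))
  }
})

test_that("an independent L1 Poisson solver reproduces the fit", {
  skip_if_not_installed("glmnet")
  # over a finite background, the penalized maxent optimum coincides with
  # an L1 Poisson log-linear fit of per-cell presence counts with a free
  # intercept, at glmnet penalty lambda * pf_j = (m/N) * beta_j
  set.seed(13)
  N <- 400
  bg <- cbind(v = stats::runif(N), w = stats::runif(N))
  idx <- order(bg[, "v"] + 0.5 * bg[, "w"], decreasing = TRUE)[1:50]
  pres <- bg[idx, , drop = FALSE]
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 1))

  scaled <- apply(bg, 2, function(x) (x - min(x)) / diff(range(x)))
  y <- tabulate(idx, nbins = N)
  m <- length(idx)
  pf <- fit$beta / mean(fit$beta)
  g <- glmnet::glmnet(scaled, y, family = "poisson",
                      lambda = (m / N) * mean(fit$beta),
                      penalty.factor = pf, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$lambdas), as.numeric(g$beta), tolerance = 5e-3)
})

test_that("model serialization writes a parseable lambdas file", {
  bg <- landscape_1d()
  pres <- matrix(c(0.8, 1.0), ncol = 1, dimnames = list(NULL, "v"))
  fit <- fit_maxent(pres, bg, feature_spec("LQ", rm = 0.5))
  f <- tempfile(fileext = ".lambdas")
  write_maxent_model(fit, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "#")), 6)
  body <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  expect_equal(nrow(body), length(fit$lambdas))
  expect_equal(body[[2]], unname(fit$lambdas), tolerance = 1e-12)
})
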