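test_that("kfold partitions are seeded, near-equal and exhaustive", {
  occ <- data.frame(species = "v", lon = stats::runif(20, 100, 110),
                    lat = stats::runif(20, 20, 30))
  f1 <- make_partition(occ, "kfold", k = 10, seed = 3)
  f2 <- make_partition(occ, "kfold", k = 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(as.integer(table(f1)), rep(2L, 10))
  expect_error(make_partition(occ[1:5, ], "kfold", k = 10), "fewer")

  # uneven n: sizes differ by at most 1
  occ37 <- data.frame(lon = stats::runif(37), lat = stats::runif(37))
  sizes <- table(make_partition(occ37, "kfold", k = 10, seed = 1))
  expect_lte(diff(range(sizes)), 1)
})

test_that("spatial blocks are quadrants with near-equal counts", {
  corners <- data.frame(lon = c(100, 100, 110, 110),
                        lat = c(20, 30, 20, 30))
  expect_setequal(make_partition(corners, "spatial_block"), 1:4)

  set.seed(8)
  cloud <- data.frame(lon = stats::runif(98, 100, 110),
                      lat = stats::runif(98, 20, 30))
  b <- make_partition(cloud, "spatial_block")
  expect_true(all(abs(table(b) - 24.5) <= 0.5))
  # oracle: median splits really separate the halves
  west <- b %in% 1:2
  expect_lte(max(cloud$lon[west]), min(cloud$lon[!west]) + 1e-12)
})

test_that("auc equals exhaustive pair enumeration and is rank-invariant", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  # worked pair count: (1 + 1 + 1 + 0 + 1/2 + 1)/6
  expect_equal(auc(c(0.9, 0.4), c(0.6, 0.4, 0.1)), 0.75)
  expect_error(auc(numeric(0), 1), "empty")

  set.seed(21)
  for (i in 1:10) {
    p <- sample(seq(0, 1, 0.05), sample(3:50, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.05), sample(3:50, 1), replace = TRUE)
    a <- auc(p, b)
    expect_equal(a, oracle_auc(p, b))
    # invariance under a strictly increasing transform
    expect_equal(auc(exp(3 * p), exp(3 * b)), a)
  }
})

test_that("aicc follows the small-sample formula and its limits", {
  bg <- landscape_1d()
  pres <- matrix(rep(c(0.8, 0.9, 1.0), 4), ncol = 1,
                 dimnames = list(NULL, "v"))
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 0.5))
  ic <- aicc(fit, pres, bg)
  expect_equal(ic$k, sum(fit$lambdas != 0))
  # independent recomputation of the landscape-normalized likelihood
  raw <- predict_raw(fit, bg)
  lnL <- sum(log(predict_raw(fit, pres) / sum(raw)))
  n <- nrow(pres); k <- ic$k
  expect_equal(ic$lnL, lnL)
  expect_equal(ic$AICc, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))

  # k exceeding n - 1 flags the result invalid
  pres2 <- matrix(c(0.9, 1.0), ncol = 1, dimnames = list(NULL, "v"))
  fit2 <- fit_maxent(pres2, bg, feature_spec("LQ", rm = 0.3), tol = 1e-4)
  ic2 <- aicc(fit2, pres2, bg)
  if (ic2$k >= nrow(pres2) - 1) expect_false(ic2$valid)
})

test_that("model selection spans the grid, zeroes delta at the min, and prefers needed curvature", {
  pre <- virtual_preset(seed = 42)
  pre$landscape$shape <- c(60, 60)
  stack <- generate_landscape(pre$landscape)
  truth <- true_suitability(stack, pre$species)
  occ <- sample_presences(truth, 80, seed = 7)
  pres <- extract_values(stack, occ$lon, occ$lat)
  bg <- sample_background(stack, 1500, seed = 8)

  sel <- model_selection(pres, stack, rm_grid = c(1), fc_grid = c("L", "LQ"),
                         background = bg, occ = occ)
  expect_equal(nrow(sel$results), 2)
  expect_equal(min(sel$results$delta_AICc, na.rm = TRUE), 0)
  # a unimodal Gaussian response needs the quadratic term
  expect_equal(sel$selected$fc, "LQ")

  # singleton grid selects itself with delta 0
  s1 <- model_selection(pres, stack, 1, "L", bg)
  expect_equal(s1$selected$delta_AICc, 0)
  expect_equal(s1$selected$fc, "L")
})

test_that("percent contribution credits the gain path and sums to 100", {
  bg <- landscape_1d()
  pres <- matrix(c(0.8, 0.9, 1.0), ncol = 1, dimnames = list(NULL, "v"))
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 0.5))
  pc <- percent_contribution(fit)
  expect_equal(unname(pc), 100)  # single variable takes everything

  fit_untraced <- fit_maxent(pres, bg, feature_spec("L", rm = 0.5),
                             trace = FALSE)
  expect_error(percent_contribution(fit_untraced), "trace")

  # two exchangeable (independent, equally informative) variables split
  # the credit evenly on average over seeds
  set.seed(31)
  splits <- replicate(10, {
    bg2 <- cbind(a = stats::runif(400), b = stats::runif(400))
    pres2 <- bg2[order(bg2[, "a"] + bg2[, "b"],
                       decreasing = TRUE)[1:50], ]
    f2 <- fit_maxent(pres2, bg2, feature_spec("L", rm = 1))
    percent_contribution(f2)["a"]
  })
  expect_lt(abs(mean(splits) - 50), 5)
})

test_that("permutation importance isolates the separating variable", {
  set.seed(17)
  bg <- cbind(a = stats::runif(500), b = stats::runif(500))
  pres <- bg[order(bg[, "a"], decreasing = TRUE)[1:60], ]
  fit <- fit_maxent(pres, bg, feature_spec("LQ", rm = 1))
  pi <- permutation_importance(fit, pres, seed = 4, n_reps = 10)
  expect_equal(sum(pi), 100, tolerance = 1e-6)
  expect_gt(pi["a"], 90)
  # determinism for a fixed seed
  expect_equal(pi, permutation_importance(fit, pres, seed = 4, n_reps = 10))
})

test_that("bootstrap contribution intervals are seeded and cover the point estimate", {
  set.seed(41)
  bg <- cbind(a = stats::runif(300), b = stats::runif(300))
  pres <- bg[order(bg[, "a"], decreasing = TRUE)[1:40], ]
  ci <- bootstrap_contribution(pres, bg, feature_spec("L", rm = 1),
                               n_boot = 20, seed = 2)
  expect_equal(ci$variable, c("a", "b"))
  expect_true(all(ci$lower <= ci$mean & ci$mean <= ci$upper))
  expect_gt(ci$mean[ci$variable == "a"], 50)
  ci2 <- bootstrap_contribution(pres, bg, feature_spec("L", rm = 1),
                                n_boot = 20, seed = 2)
  expect_identical(ci, ci2)
})

test_that("jackknife gains rank the signal-bearing variable first", {
  set.seed(23)
  bg <- cbind(sig = stats::runif(400), noise1 = stats::runif(400),
              noise2 = stats::runif(400))
  pres <- bg[order(bg[, "sig"], decreasing = TRUE)[1:50], ]
  jk <- jackknife_gains(pres, bg, feature_spec("LQ", rm = 1))
  expect_gte(jk$full_gain, 0)
  tab <- jk$table
  expect_equal(tab$variable[which.max(tab$gain_with_only)], "sig")
  expect_equal(tab$variable[which.min(tab$gain_without)], "sig")

  # uniform presence sample carries no gain
  jk0 <- fit_maxent(bg, bg, feature_spec("L", rm = 1))
  pr <- predict_raw(jk0, bg)
  expect_equal(mean(log(pr * nrow(bg))), 0, tolerance = 1e-9)
})

test_that("response curves recover shape, optimum and >0.5 envelope", {
  set.seed(29)
  bg <- cbind(v = stats::runif(400), w = stats::runif(400))
  # presence concentrated where v is large: monotone response in v
  pres <- bg[order(bg[, "v"], decreasing = TRUE)[1:60], ]
  fit <- fit_maxent(pres, bg, feature_spec("L", rm = 1))
  rc <- response_curve(fit, "v", n_grid = 100)
  expect_true(all(diff(rc$curve$response) >= -1e-12))
  expect_true(all(rc$curve$response >= 0 & rc$curve$response <= 1))
  expect_equal(rc$optimum, max(rc$curve$value))
  if (nrow(rc$envelope)) {
    expect_true(all(rc$curve$response[rc$curve$value >= rc$envelope[1, 1] &
                                      rc$curve$value <= rc$envelope[1, 2]] > 0.5))
  }
  expect_error(response_curve(fit, "nope"), "not in model")
})
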