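# shared fixtures: everything is generated in code at test time

# tiny aligned stack of named layers from matrices (row 1 = north)
make_stack <- function(..., xll = 100, yll = 20, cellsize = 0.5) {
  mats <- list(...)
  env_stack(lapply(names(mats), function(nm)
    grid_layer(mats[[nm]], xll, yll, cellsize, name = nm)))
}

# deterministic 1-D landscape: 11 cells valued 0..1 on one variable
landscape_1d <- function() {
  matrix(seq(0, 1, length.out = 11), ncol = 1,
         dimnames = list(NULL, "v"))
}

# write a small occurrence CSV and return its path
write_occ_csv <- function(df, names = c("species", "longitude", "latitude")) {
  f <- tempfile(fileext = ".csv")
  colnames(df)[seq_along(names)] <- names
  utils::write.csv(df, f, row.names = FALSE)
  f
}

# brute-force penalized-objective grid search for 1-feature problems;
# computes the objective from scratch (independent of the fit internals)
oracle_lambda_1d <- function(fbar, bg_feat, beta, grid = seq(-20, 40, 1e-3)) {
  obj <- vapply(grid, function(l)
    fbar * l - log(sum(exp(l * bg_feat))) - beta * abs(l), numeric(1))
  grid[which.max(obj)]
}

# wrap a single layer as a one-variable stack
make_stack_from <- function(layer) env_stack(list(layer))

# exhaustive AUC by pair enumeration
oracle_auc <- function(pres, bg) {
  tot <- 0
  for (p in pres) for (b in bg)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(pres) * length(bg))
}
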