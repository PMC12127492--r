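#' Collinearity screening of environmental layers
#'
#' Strongly correlated bioclimatic layers destabilise niche models and blur
#' variable-importance attribution. Screening computes the pairwise Pearson
#' matrix over the jointly valid landscape cells (or over a point sample) and
#' iteratively drops, from every offending pair with |r| above the threshold,
#' the variable ranked less important, until the retained set is pairwise
#' clean.
#'
#' @name screening
NULL

#' Pearson correlation matrix of a stack
#'
#' @param stack an `env_stack`.
#' @param points optional two-column matrix / data frame of (lon, lat); when
#'   supplied, correlations are computed over the covariates at these points
#'   instead of all valid landscape cells.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(stack, points = NULL) {
  if (is.null(points)) {
    m <- stack_values(stack)$values
  } else {
    points <- as.matrix(points)
    m <- extract_values(stack, points[, 1], points[, 2])
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need at least 3 complete samples for correlation")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  stats::cor(m)
}

#' Screen variables for pairwise collinearity
#'
#' Iterative rounds: in each round the pairs with `|r| > threshold` are
#' visited in order of decreasing `|r|`; a pair both of whose members are
#' still present loses its lower-ranked member (pairs already resolved by
#' an earlier removal in the round are skipped, since the removal may have
#' settled them). The matrix is then recomputed over the survivors and
#' rounds repeat until no offending pair remains — the multi-round
#' behaviour of conventional manual screening.
#'
#' @param stack an `env_stack`.
#' @param threshold collinearity cutoff in (0, 1]; pairs with `|r|` strictly
#'   above it are offending. Default 0.8.
#' @param importance_rank character vector of variable names ordered from
#'   most to least important (e.g. by permutation importance of a
#'   preliminary all-variable fit); must cover all layers.
#' @param points optional point sample passed to [pearson_matrix()].
#' @return a list with `retained` (names), `rounds` (integer), `audit`
#'   (data frame of removals: round, removed, against, r) and `r_final`
#'   (correlation matrix of the retained set).
#' @export
select_variables <- function(stack, threshold = 0.8, importance_rank,
                             points = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  vars <- names(stack$layers)
  if (!all(vars %in% importance_rank))
    stop("importance_rank must cover all stack variables")
  rank_of <- stats::setNames(match(vars, importance_rank), vars)

  keep <- vars
  audit <- data.frame(round = integer(), removed = character(),
                      against = character(), r = numeric())
  rounds <- 0L
  repeat {
    sub <- env_stack(stack$layers[keep])
    r <- pearson_matrix(sub, points = points)
    off <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
    if (nrow(off) == 0L) break
    rounds <- rounds + 1L
    off <- off[order(-abs(r[off]), off[, 1], off[, 2]), , drop = FALSE]
    drop <- character()
    for (k in seq_len(nrow(off))) {
      a <- keep[off[k, 1]]; b <- keep[off[k, 2]]
      if (a %in% drop || b %in% drop) next  # pair may be settled already
      loser <- if (rank_of[a] <= rank_of[b]) b else a
      winner <- setdiff(c(a, b), loser)
      drop <- c(drop, loser)
      audit <- rbind(audit, data.frame(round = rounds, removed = loser,
                                       against = winner,
                                       r = r[off[k, 1], off[k, 2]]))
    }
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  r_final <- if (length(keep) >= 2L)
    pearson_matrix(env_stack(stack$layers[keep]), points = points)
  else matrix(1, length(keep), length(keep), dimnames = list(keep, keep))
  list(retained = keep, rounds = rounds, audit = audit, r_final = r_final)
}
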