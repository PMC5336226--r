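#' Bias-corrected sample skewness and excess kurtosis
#'
#' Moment conventions used throughout the bimodality machinery: skewness
#' `g1 * sqrt(n (n-1)) / (n - 2)` and excess kurtosis in the SAS
#' convention, where `g1 = m3 / m2^{3/2}` and `g2 = m4 / m2^2 - 3` are the
#' population-style sample moments. These are the corrections the
#' bimodality coefficient's finite-sample term is built for; both require
#' `n >= 4` (kurtosis) and a non-constant sample.
#'
#' @param x numeric sample, all finite.
#' @return scalar moment estimate.
#' @export
sample_skewness <- function(x) {
  n <- check_moment_sample(x, min_n = 3L)
  m2 <- mean((x - mean(x))^2)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @rdname sample_skewness
#' @export
sample_excess_kurtosis <- function(x) {
  n <- check_moment_sample(x, min_n = 4L)
  m2 <- mean((x - mean(x))^2)
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

check_moment_sample <- function(x, min_n) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("sample must be finite numeric", call. = FALSE)
  n <- length(x)
  if (n < min_n)
    stop(sprintf("need at least %d observations", min_n), call. = FALSE)
  if (max(x) == min(x))
    stop("sample is constant: moments undefined", call. = FALSE)
  n
}

#' Sample bimodality coefficient
#'
#' `BC = (m3^2 + 1) / (m4 + 3 (n-1)^2 / ((n-2)(n-3)))`, with `m3` the
#' bias-corrected sample skewness and `m4` the bias-corrected sample excess
#' kurtosis (see [sample_skewness()]). The conventional critical value
#' `BC_crit = 0.55` — the value taken by a uniform distribution, up to its
#' asymptotic 5/9 — separates unimodal (below) from bimodal (above)
#' samples. A balanced two-point mixture approaches BC = 1; a normal sample
#' approaches 1/3.
#'
#' @param x numeric sample of length >= 4, finite, not constant. For host
#'   cohorts, use the composition fractions of *colonized* hosts only
#'   (fraction is undefined at total = 0); see [cohort_fractions()].
#' @return the coefficient (scalar in (0, 1] for non-degenerate samples).
#' @examples
#' bimodality_coefficient(c(rep(0.02, 25), rep(0.97, 25)))  # near 1
#' @export
bimodality_coefficient <- function(x) {
  n <- check_moment_sample(x, min_n = 4L)
  m3 <- sample_skewness(x)
  m4 <- sample_excess_kurtosis(x)
  (m3^2 + 1) / (m4 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Bootstrap confidence interval for the bimodality coefficient
#'
#' Percentile bootstrap: `n_boot` resamples of size n with replacement;
#' resamples that are constant or otherwise degenerate are redrawn (their
#' count is reported in `n_redrawn`). Deterministic given `seed`.
#'
#' @param x numeric sample (as [bimodality_coefficient()]).
#' @param n_boot number of bootstrap replicates (>= 100; default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed (required for pipeline reproducibility).
#' @return An object of class `bc_result`: list with `bc`, `n`, `ci_low`,
#'   `ci_high`, `n_boot`, `level`, `n_redrawn`, `seed`.
#' @export
bootstrap_bc <- function(x, n_boot = 10000L, level = 0.95, seed) {
  bc <- bimodality_coefficient(x)  # errors propagate from the original
  stopifnot(n_boot >= 100, level > 0, level < 1)
  n <- length(x)
  set.seed(as.integer(seed))
  reps <- numeric(n_boot)
  n_redrawn <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      xb <- x[sample.int(n, n, replace = TRUE)]
      v <- tryCatch(bimodality_coefficient(xb), error = function(e) NULL)
      if (!is.null(v)) break
      n_redrawn <- n_redrawn + 1L
    }
    reps[i] <- v
  }
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  structure(list(bc = bc, n = n, ci_low = qs[1], ci_high = qs[2],
                 n_boot = as.integer(n_boot), level = level,
                 n_redrawn = n_redrawn, seed = as.integer(seed)),
            class = "bc_result")
}

#' @export
print.bc_result <- function(x, ...) {
  cat(sprintf("BC = %.3f (n = %d), %g%% bootstrap CI [%.3f, %.3f] (%d reps)\n",
              x$bc, x$n, 100 * x$level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' @export
as.data.frame.bc_result <- function(x, ...) {
  data.frame(bc = x$bc, n = x$n, ci_low = x$ci_low, ci_high = x$ci_high,
             n_boot = x$n_boot, level = x$level, n_redrawn = x$n_redrawn,
             seed = x$seed)
}

#' Locate the bimodal-to-unimodal transition on a BC curve
#'
#' Given bimodality coefficients measured along an increasing grid of
#' colonization rates, finds the colonization rate at which BC first
#' crosses `threshold` downward, by linear interpolation of BC against
#' log10(c). Multiple crossings are counted; the first is returned.
#'
#' @param c_grid strictly increasing positive colonization rates (>= 2).
#' @param bc_values BC at each grid point (NA points are dropped pairwise).
#' @param threshold critical BC (default 0.55).
#' @return list with `c_star` (the crossing rate), `n_crossings`, and the
#'   interpolation bracket `bracket` (indices into the grid).
#' @examples
#' find_transition(c(0.1, 10), c(0.8, 0.3))  # c* = 1
#' @export
find_transition <- function(c_grid, bc_values, threshold = 0.55) {
  keep <- is.finite(c_grid) & is.finite(bc_values)
  c_grid <- c_grid[keep]; bc_values <- bc_values[keep]
  if (length(c_grid) < 2)
    stop("need at least 2 usable grid points", call. = FALSE)
  if (any(c_grid <= 0) || is.unsorted(c_grid, strictly = TRUE))
    stop("c_grid must be strictly increasing and positive", call. = FALSE)
  above <- bc_values > threshold
  if (all(above))
    stop("no crossing: BC exceeds the threshold everywhere (all bimodal)",
         call. = FALSE)
  if (!above[1])
    stop(paste("no downward crossing: BC is below the threshold at the",
               "low-c end (all unimodal)"), call. = FALSE)
  lx <- log10(c_grid)
  down <- which(above[-length(above)] & !above[-1])
  i <- down[1]
  f <- (bc_values[i] - threshold) / (bc_values[i] - bc_values[i + 1])
  list(c_star = 10^(lx[i] + f * (lx[i + 1] - lx[i])),
       n_crossings = length(down), bracket = c(i, i + 1L))
}

#' Mann-Whitney U comparison of two samples
#'
#' Thin wrapper around the two-sided Wilcoxon rank-sum test: exact
#' enumeration when both samples have at most 8 observations and there are
#' no ties, tie-corrected normal approximation otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (statistic for `x`), `p` (two-sided), `n_x`,
#'   `n_y`, `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y), exact = exact)
}

#' Composition fractions of colonized hosts
#'
#' Extracts the `fraction` column of an ensemble/cohort table, dropping
#' uncolonized hosts (total = 0), whose composition is undefined — the
#' convention used for all bimodality statistics on cohorts.
#'
#' @param tab an `ensemble_table` (or any data.frame with a `fraction`
#'   column).
#' @param column name of the fraction column (default `"fraction"`).
#' @return numeric vector of defined fractions.
#' @export
cohort_fractions <- function(tab, column = "fraction") {
  f <- tab[[column]]
  if (is.null(f)) stop(sprintf("no column '%s'", column), call. = FALSE)
  f[is.finite(f)]
}
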