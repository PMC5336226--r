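#' Closed-form logistic growth
#'
#' Deterministic solution of dN/dt = r N (1 - N/K):
#' `N(t) = K N0 e^{rt} / (K + N0 (e^{rt} - 1))`. This is the mean-field
#' description of within-host growth in the absence of new colonization.
#'
#' @param N0 initial abundance (>= 0).
#' @param r net growth rate per hour (may be negative).
#' @param K carrying capacity (> 0).
#' @param t time in hours (vectorized, >= 0).
#' @return abundance at each `t`; exactly 0 when `N0 = 0`, exactly `K` when
#'   `N0 = K`.
#' @examples
#' logistic_solution(N0 = 1, r = 0.06, K = 2e5, t = 192)
#' @export
logistic_solution <- function(N0, r, K, t) {
  for (nm in c("N0", "r", "K", "t")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(sprintf("%s must be finite numeric", nm), call. = FALSE)
  }
  if (N0 < 0) stop("N0 must be >= 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (N0 == 0) return(rep(0, length(t)))
  # algebraically stable form: divide through by e^{rt} for large rt
  ert <- exp(r * t)
  ifelse(is.infinite(ert), K, K * N0 * ert / (K + N0 * (ert - 1)))
}

#' Mean of the linear (non-saturating) birth-death-immigration process
#'
#' Expected abundance at time `t` of a single lineage started empty, with
#' immigration at rate `c`, per-capita birth `b` and death `d`, and no
#' carrying capacity: `c (e^{(b-d)t} - 1) / (b - d)`, continuously extended
#' to `c t` at `b = d`. Serves as the K -> Inf oracle for the stochastic
#' simulator's ensemble mean.
#'
#' @param c immigration rate (>= 0).
#' @param b,d per-capita birth and death rates (>= 0).
#' @param t time in hours (vectorized, >= 0).
#' @return expected abundance at each `t`.
#' @examples
#' linear_bdi_mean(c = 0.1, b = 0.6, d = 0.54, t = 24)
#' @export
linear_bdi_mean <- function(c, b, d, t) {
  check_rate(c, "c"); check_rate(b, "b"); check_rate(d, "d")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  r <- b - d
  if (r == 0) return(c * t)
  # expm1 keeps precision near r*t = 0, matching the c*t limit
  c * expm1(r * t) / r
}

#' Analytic regime summary: timescales and extinction probability
#'
#' For a supercritical strain (`b > d`) the theory gives the founder
#' extinction probability `p_ext = d/b`, the expected time between
#' successful lineage establishments `T_est = 1/(c (1 - p_ext)) = b/(c (b-d))`,
#' and the growth timescale `T_grow = 1/(b - d)`. Their ratio
#' `T_grow / T_est = c/b` controls whether between-host community
#' composition is bimodal (ratio << 1: hosts are won by whichever strain
#' establishes first) or unimodal (ratio >> 1: many lineages establish
#' before any can dominate), with the transition around `c/b = 1`.
#'
#' @param params a [model_params()] object.
#' @param strain index of the strain to summarize (default 1).
#' @param transitional_band ratio interval labelled "transitional"; purely
#'   cosmetic, affects no computed quantity.
#' @return An object of class `regime_summary`: list with `p_ext`, `T_est`,
#'   `T_grow`, `ratio` (= c/b) and a `regime` label.
#' @examples
#' regime_summary(model_params(b = 0.6, d = 0.54, c = 0.1, K = 1e5))
#' @export
regime_summary <- function(params, strain = 1L,
                           transitional_band = c(0.5, 2)) {
  stopifnot(inherits(params, "model_params"))
  s <- params$strains[[strain]]
  if (s$b <= s$d)
    stop("establishment time undefined: b <= d (subcritical growth)",
         call. = FALSE)
  p_ext <- s$d / s$b
  T_grow <- 1 / (s$b - s$d)
  T_est <- if (s$c == 0) Inf else s$b / (s$c * (s$b - s$d))
  ratio <- s$c / s$b
  regime <- if (ratio < transitional_band[1]) "bimodal-leaning"
            else if (ratio > transitional_band[2]) "unimodal-leaning"
            else "transitional"
  structure(list(p_ext = p_ext, T_est = T_est, T_grow = T_grow,
                 ratio = ratio, regime = regime),
            class = "regime_summary")
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf(paste0("regime: %s\n  p_ext = %.4g, T_est = %.4g h, ",
                     "T_grow = %.4g h, T_grow/T_est = c/b = %.4g\n"),
              x$regime, x$p_ext, x$T_est, x$T_grow, x$ratio))
  invisible(x)
}

#' Map feeding density to colonization rate
#'
#' Linear calibration `c = kappa * density`. The default slope
#' `kappa = 1e-7` (CFU/worm/h per CFU/mL) reproduces the observed
#' correspondence between feeding densities of 1e6-1e9 CFU/mL and
#' colonization rates of 0.1-100 CFU/worm/h.
#'
#' @param density external bacterial density, CFU per mL (vectorized, >= 0).
#' @param kappa calibration slope (> 0).
#' @return colonization rate(s) in successful migrants per host per hour.
#' @examples
#' density_to_colonization(1e8)  # 10
#' @export
density_to_colonization <- function(density, kappa = 1e-7) {
  if (!is.numeric(density) || any(!is.finite(density)) || any(density < 0))
    stop("density must be finite and >= 0", call. = FALSE)
  check_rate(kappa, "kappa", positive = TRUE)
  kappa * density
}

#' Deterministic stationary community size
#'
#' Positive root of `(b N + C)(1 - N/K) = d N`, the mean-field fixed point
#' of the saturating process with total immigration `C` (summed over
#' strains). Used as the long-run target for the ensemble mean total.
#'
#' @param params a [model_params()] object (neutral rates assumed for the
#'   shared b and d; immigration summed across strains).
#' @return stationary total abundance (scalar).
#' @export
stationary_total <- function(params) {
  stopifnot(inherits(params, "model_params"))
  m <- rate_matrix(params)
  b <- unname(m[1, "b"]); d <- unname(m[1, "d"])
  C <- sum(m[, "c"]); K <- params$K
  if (C == 0 && b <= d) return(0)
  # quadratic: (b/K) N^2 + (d - b + C/K) N - C = 0
  A <- b / K; B <- d - b + C / K
  if (A == 0) return(if (B < 0) Inf else C / B)
  (-B + sqrt(B^2 + 4 * A * C)) / (2 * A)
}
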