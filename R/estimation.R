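#' Fit a logistic growth curve to per-worm CFU counts
#'
#' Least-squares fit of the logistic closed form to a growth series on the
#' log10(count + 1) scale — counts span orders of magnitude, and the +1
#' keeps any retained zeros finite. Zero-count worms (uncolonized hosts)
#' are excluded by default: they are founder-lineage extinctions, governed
#' by the extinction probability d/b rather than by the growth curve, and
#' feeding them to a least-squares logistic (which has no zero-inflation
#' component) biases the recovered growth rate upward by tens of percent;
#' growth assays report uncolonized worms separately from the average-CFU
#' curve for the same reason. Set `include_zeros = TRUE` to keep them.
#' Parameters are the net growth rate `r` (per
#' hour), the carrying capacity `K`, and the nuisance initial abundance
#' `N0`; optimization is Levenberg-Marquardt over `(log10 N0, log r,
#' log10 K)` from several data-driven starts. Confidence intervals come
#' from a percentile bootstrap that resamples worms within timepoints (the
#' worm is the independent unit) and refits.
#'
#' @param series data.frame with columns `time_h` and `cfu_per_worm`
#'   (optionally `replicate`); needs >= 4 distinct timepoints and at least
#'   one count within a factor of 5 of the plateau.
#' @param n_boot bootstrap replicates (default 1000; 0 skips the CI).
#' @param seed integer RNG seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @param include_zeros keep zero-count worms in the fit (default FALSE,
#'   see Details).
#' @return An object of class `fit_result` with `estimates` (named vector
#'   `r`, `K`, `N0`), `ci` (matrix with rows `ci_low`, `ci_high`),
#'   `n_boot`, `seed`, `residual_sd` (log10 scale), `n_failed` (bootstrap
#'   refits that did not converge) and the fitted model.
#' @examples
#' ser <- data.frame(time_h = rep(c(0, 48, 96, 144, 192), each = 3),
#'                   cfu_per_worm = logistic_solution(10, 0.0625, 2e5,
#'                     rep(c(0, 48, 96, 144, 192), each = 3)))
#' fit_logistic(ser, n_boot = 0)$estimates
#' @export
fit_logistic <- function(series, n_boot = 1000L, seed = 1L, level = 0.95,
                         include_zeros = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "cfu_per_worm") %in% names(series)))
  series <- series[is.finite(series$time_h) &
                   is.finite(series$cfu_per_worm), , drop = FALSE]
  if (all(series$cfu_per_worm == 0))
    stop("all counts are zero: nothing to fit", call. = FALSE)
  if (!include_zeros)
    series <- series[series$cfu_per_worm > 0, , drop = FALSE]
  if (length(unique(series$time_h)) < 4)
    stop("need at least 4 distinct timepoints", call. = FALSE)
  plateau <- max(series$cfu_per_worm)
  if (!any(series$cfu_per_worm >= plateau / 5))
    stop("no counts near the plateau", call. = FALSE)

  fit <- logistic_ls(series)
  if (is.null(fit$par))
    stop(paste0("logistic fit did not converge from any start (tried ",
                fit$n_starts, " starts)"), call. = FALSE)
  est <- fit$par

  ci <- matrix(NA_real_, 2, 3,
               dimnames = list(c("ci_low", "ci_high"), names(est)))
  n_failed <- 0L
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    groups <- split(seq_len(nrow(series)), series$time_h)
    boots <- matrix(NA_real_, n_boot, 3)
    for (i in seq_len(n_boot)) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
      bf <- tryCatch(logistic_ls(series[idx, , drop = FALSE],
                                 start = fit$raw_par),
                     error = function(e) list(par = NULL))
      if (is.null(bf$par)) n_failed <- n_failed + 1L
      else boots[i, ] <- bf$par
    }
    a <- (1 - level) / 2
    ok <- complete.cases(boots)
    if (sum(ok) >= 10)
      ci[] <- apply(boots[ok, , drop = FALSE], 2, quantile,
                    probs = c(a, 1 - a), names = FALSE)
  }
  structure(list(estimates = est, ci = ci, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), level = level,
                 residual_sd = fit$residual_sd, n_failed = n_failed,
                 model = "logistic on log10(cfu + 1)"),
            class = "fit_result")
}

# core least-squares machinery: LM on transformed params; multiple
# data-driven starts, or a single warm start (used by bootstrap refits)
logistic_ls <- function(series, start = NULL) {
  t <- series$time_h
  y <- log10(series$cfu_per_worm + 1)
  plateau <- max(series$cfu_per_worm)
  pos <- series$cfu_per_worm > 0
  n0_guess <- max(min(series$cfu_per_worm[pos]), 1)
  # crude slope of log counts over the early rising phase
  early <- t <= quantile(t, 0.5)
  r_guess <- if (sum(early & pos) >= 2) {
    sl <- coef(lm(log(series$cfu_per_worm[early & pos]) ~ t[early & pos]))[2]
    max(abs(sl), 1e-3)
  } else 0.05
  starts <- if (is.null(start))
    expand.grid(lN0 = log10(n0_guess) + c(-1, 0, 1),
                lr = log(r_guess) + c(-1, 0, 1),
                lK = log10(plateau) + c(0, 0.5))
  else as.data.frame(rbind(start))
  pred <- function(p, t)
    log10(logistic_solution(10^p[1], exp(p[2]), 10^p[3], t) + 1)
  best <- NULL; best_ss <- Inf
  for (s in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[s, ])
    res <- tryCatch(
      minpack.lm::nls.lm(p0, fn = function(p) y - pred(p, t),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:5) {
      ss <- sum(res$fvec^2)
      if (ss < best_ss) { best <- res$par; best_ss <- ss }
    }
  }
  if (is.null(best))
    return(list(par = NULL, n_starts = nrow(starts)))
  list(par = c(r = exp(best[2]), K = 10^best[3], N0 = 10^best[1]),
       raw_par = best,
       residual_sd = sqrt(best_ss / max(length(y) - 3, 1)),
       n_starts = nrow(starts))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit:", x$model, "\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.4g  [%.4g, %.4g]\n", nm, x$estimates[nm],
                x$ci["ci_low", nm], x$ci["ci_high", nm]))
  if (!is.null(x$residual_sd))
    cat(sprintf("  residual sd = %.3g, n_boot = %d\n", x$residual_sd,
                x$n_boot))
  invisible(x)
}

#' Estimate the death rate from a division-arrest decay assay
#'
#' Under division arrest (e.g. a bacteriostatic antibiotic above MIC) the
#' intestinal population decays as `N(t) = N(0) e^{-d t}`, so `d` is minus
#' the slope of log CFU against time: the two-timepoint closed form
#' `d = -log(N(t2)/N(t1)) / (t2 - t1)`, or a log-linear regression when
#' more than two timepoints are available (replicate digests enter the
#' regression as separate observations).
#'
#' @param arrest data.frame with columns `time_h` and `cfu_per_worm`
#'   (positive at the first timepoint; >= 2 distinct times).
#' @param level confidence level for the regression CI.
#' @return A `fit_result` with estimate `d` (per hour). Non-decreasing
#'   counts produce a warning and a reported `d <= 0`.
#' @examples
#' estimate_death_rate(data.frame(time_h = c(0, 24),
#'                                cfu_per_worm = c(100, 50)))
#' @export
estimate_death_rate <- function(arrest, level = 0.95) {
  stopifnot(is.data.frame(arrest),
            all(c("time_h", "cfu_per_worm") %in% names(arrest)))
  arrest <- arrest[is.finite(arrest$cfu_per_worm) &
                   arrest$cfu_per_worm > 0, , drop = FALSE]
  times <- sort(unique(arrest$time_h))
  if (length(times) < 2) stop("need >= 2 timepoints with positive counts",
                              call. = FALSE)
  if (!all(arrest$cfu_per_worm[arrest$time_h == times[1]] > 0))
    stop("counts must be positive at the first timepoint", call. = FALSE)
  fit <- lm(log(cfu_per_worm) ~ time_h, data = arrest)
  d <- -unname(coef(fit)[2])
  ci <- matrix(NA_real_, 2, 1, dimnames = list(c("ci_low", "ci_high"), "d"))
  if (nrow(arrest) > 2) {
    cf <- suppressWarnings(confint(fit, "time_h", level = level))
    ci[, "d"] <- sort(-as.numeric(cf))
  }
  rsd <- if (nrow(arrest) > 2)
    suppressWarnings(summary(fit)$sigma) else NULL
  if (d <= 1e-12)
    warning("counts do not decrease: estimated d <= 0", call. = FALSE)
  structure(list(estimates = c(d = d), ci = ci, n_boot = 0L,
                 seed = NA_integer_, level = level,
                 residual_sd = rsd,
                 n_failed = 0L, model = "log-linear decay under arrest"),
            class = "fit_result")
}

#' Estimate colonization rates and the density calibration slope
#'
#' In a short-time feeding assay (a few hours, so that within-host growth
#' `b N` is still negligible against immigration `c`), mean CFU/worm
#' accumulates linearly: `c` is the slope through the origin of mean
#' CFU/worm against time, per feeding density. The calibration slope
#' `kappa` then comes from regressing those `c` values on density through
#' the origin.
#'
#' @param assay data.frame with columns `density_cfu_ml`, `time_h`,
#'   `mean_cfu_per_worm`; times should be within the linear regime
#'   (<= ~4 h).
#' @return A `fit_result` with one `c_<density>` estimate per density and
#'   `kappa`; `single_timepoint` flags densities where `c = CFU/t` rested
#'   on one timepoint only (a stronger linearity assumption).
#' @examples
#' a <- data.frame(density_cfu_ml = 1e6, time_h = c(1, 4),
#'                 mean_cfu_per_worm = c(0.1, 0.4))
#' estimate_colonization_rate(a)$estimates
#' @export
estimate_colonization_rate <- function(assay) {
  stopifnot(is.data.frame(assay),
            all(c("density_cfu_ml", "time_h", "mean_cfu_per_worm") %in%
                  names(assay)))
  dens <- sort(unique(assay$density_cfu_ml))
  cs <- numeric(length(dens)); single <- logical(length(dens))
  for (i in seq_along(dens)) {
    sub <- assay[assay$density_cfu_ml == dens[i], , drop = FALSE]
    if (length(unique(sub$time_h)) == 1) {
      cs[i] <- mean(sub$mean_cfu_per_worm) / sub$time_h[1]
      single[i] <- TRUE
    } else {
      cs[i] <- unname(coef(lm(mean_cfu_per_worm ~ 0 + time_h, data = sub)))
    }
  }
  kappa <- unname(coef(lm(cs ~ 0 + dens)))
  est <- c(setNames(cs, sprintf("c_%.3g", dens)), kappa = kappa)
  ci <- matrix(NA_real_, 2, length(est),
               dimnames = list(c("ci_low", "ci_high"), names(est)))
  if (any(single))
    message("single-timepoint densities (c = CFU/t assumes strict ",
            "linearity): ", paste(sprintf("%.3g", dens[single]),
                                  collapse = ", "))
  structure(list(estimates = est, ci = ci, n_boot = 0L, seed = NA_integer_,
                 level = NA_real_, residual_sd = NULL, n_failed = 0L,
                 single_timepoint = setNames(single,
                                             sprintf("c_%.3g", dens)),
                 model = "linear short-time accumulation through origin"),
            class = "fit_result")
}

#' Estimate the feeding rate from depletion of external bacteria
#'
#' Bacteria eaten per worm per hour, from the drop in external CFU/mL over
#' a feeding window: `(delta CFU/mL * volume) / (n_worms * hours)`. When a
#' colonization rate `c` is supplied, also reports the establishment
#' fraction `c / feeding_rate` — the probability an ingested bacterium
#' survives passage and adheres (observed scale: well under 1 in 50, often
#' below 1 in 1000).
#'
#' @param cfu_ml_t0,cfu_ml_t1 external density at the start and end of the
#'   window (end must not exceed start: external growth breaks the assay).
#' @param hours window length (> 0).
#' @param n_worms worms in the well (> 0).
#' @param volume_ml culture volume (default 1 mL).
#' @param c optional colonization rate for the establishment fraction.
#' @return list with `feeding_rate` (eaten/worm/h) and, when `c` is given,
#'   `establishment_fraction`.
#' @examples
#' estimate_feeding_rate(1e6, 9.5e5, hours = 10, n_worms = 1000)
#' @export
estimate_feeding_rate <- function(cfu_ml_t0, cfu_ml_t1, hours, n_worms,
                                  volume_ml = 1, c = NULL) {
  stopifnot(hours > 0, n_worms > 0, volume_ml > 0)
  if (cfu_ml_t1 > cfu_ml_t0)
    stop(paste("external CFU/mL increased: growth outside the host",
               "violates the depletion assay"), call. = FALSE)
  rate <- (cfu_ml_t0 - cfu_ml_t1) * volume_ml / (n_worms * hours)
  out <- list(feeding_rate = rate)
  if (!is.null(c))
    out$establishment_fraction <- if (rate > 0) c / rate else NA_real_
  out
}
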