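#' Configuration for a colonization-rate sweep
#'
#' Defines the in-silico version of the central feeding experiment: a grid
#' of colonization rates (or feeding densities converted through
#' [density_to_colonization()] at this boundary, so the core sweep always
#' runs in `c`), the demographic parameters, cohort size and horizon,
#' bootstrap settings, and optionally uncertainty ranges for `(b, d, K)`
#' from which a parameter-uncertainty band is built.
#'
#' @param c_grid increasing grid of colonization rates (per strain, per
#'   hour). Give either this or `densities`.
#' @param densities increasing grid of feeding densities (CFU/mL),
#'   converted with `kappa`.
#' @param kappa density-to-colonization slope (default 1e-7).
#' @param params a [model_params()] (per-strain `c` is overridden along
#'   the grid).
#' @param n_hosts hosts per grid point (default 56).
#' @param t_end horizon in hours (default 192).
#' @param n_boot bootstrap replicates for the per-point BC CI.
#' @param seed integer base seed.
#' @param threshold critical BC for the transition (default 0.55).
#' @param uncertainty optional list with `b_range`, `d_range`, `K_range`
#'   and `n_draws` (default 48): parameter sets are drawn uniformly
#'   (log-uniformly for K) with rejection to enforce `b > d`, and the band
#'   is the mean +/- 1 SD of BC over draws at each grid point.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(c_grid = NULL, densities = NULL, kappa = 1e-7,
                         params = model_params(b = 0.6, d = 0.54, c = 0,
                                               K = 1e5),
                         n_hosts = 56L, t_end = 192, n_boot = 1000L,
                         seed, threshold = 0.55, uncertainty = NULL) {
  if (is.null(c_grid)) {
    if (is.null(densities))
      stop("give c_grid or densities", call. = FALSE)
    c_grid <- density_to_colonization(densities, kappa)
  }
  stopifnot(length(c_grid) >= 1, all(c_grid > 0),
            !is.unsorted(c_grid, strictly = TRUE),
            inherits(params, "model_params"), n_hosts >= 4, t_end > 0)
  if (!is.null(uncertainty)) {
    stopifnot(all(c("b_range", "d_range", "K_range") %in%
                    names(uncertainty)))
    if (is.null(uncertainty$n_draws)) uncertainty$n_draws <- 48L
    if (max(uncertainty$b_range) <= min(uncertainty$d_range))
      stop("uncertainty ranges cannot satisfy b > d", call. = FALSE)
  }
  structure(list(c_grid = c_grid, densities = densities, kappa = kappa,
                 params = params, n_hosts = as.integer(n_hosts),
                 t_end = t_end, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), threshold = threshold,
                 uncertainty = uncertainty),
            class = "sweep_config")
}

#' Sweep colonization rate and measure compositional bimodality
#'
#' For every grid point, simulates a cohort, drops uncolonized hosts,
#' and computes the bimodality coefficient of the composition fractions
#' with a percentile bootstrap CI; grid points with fewer than 4 colonized
#' hosts get `NA` with a warning and the sweep continues. The transition
#' estimate `c_star` is the first downward crossing of the BC threshold
#' (see [find_transition()]); `status` records `"crossing"`,
#' `"all bimodal"`, `"all unimodal"` or `"no transition"` for degenerate
#' grids. With `uncertainty` set, an additional band (mean +/- 1 SD of BC
#' over random `(b, d, K)` draws) is attached per grid point. Fully
#' seed-reproducible.
#'
#' @param config a [sweep_config()].
#' @return An object of class `sweep_result`: list with `table` (one row
#'   per grid point: `c`, `n_colonized`, `bc`, `ci_low`, `ci_high`,
#'   `mean_fraction`, `sd_fraction`, `mean_total`, `sd_total`, and band
#'   columns when requested), `c_star`, `status`, `threshold`, `config`.
#' @examples
#' cfg <- sweep_config(c_grid = c(0.1, 0.6, 10),
#'                     params = model_params(b = 0.6, d = 0.54, c = 0,
#'                                           K = 1e4),
#'                     n_hosts = 24, t_end = 96, n_boot = 200, seed = 42)
#' \donttest{run_sweep(cfg)}
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  g <- config$c_grid
  tab <- data.frame(c = g, n_hosts = config$n_hosts,
                    n_colonized = NA_integer_, bc = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    mean_fraction = NA_real_, sd_fraction = NA_real_,
                    mean_total = NA_real_, sd_total = NA_real_)
  if (!is.null(config$densities)) tab$density <- config$densities
  for (j in seq_along(g)) {
    pt <- sweep_point(config$params, g[j], config, derive_seed(config$seed, j))
    tab[j, names(pt)] <- pt
  }
  if (!is.null(config$uncertainty)) {
    band <- uncertainty_band(config)
    tab$band_mean <- band$mean
    tab$band_sd <- band$sd
  }
  usable <- is.finite(tab$bc)
  trans <- if (sum(usable) >= 2) {
    tryCatch(find_transition(tab$c[usable], tab$bc[usable],
                             config$threshold),
             error = function(e) conditionMessage(e))
  } else "no transition"
  if (is.list(trans)) {
    c_star <- trans$c_star; status <- "crossing"
    n_crossings <- trans$n_crossings
  } else {
    c_star <- NA_real_
    status <- if (grepl("all bimodal", trans)) "all bimodal"
              else if (grepl("all unimodal", trans)) "all unimodal"
              else "no transition"
    n_crossings <- 0L
  }
  structure(list(table = tab, c_star = c_star, status = status,
                 n_crossings = n_crossings, threshold = config$threshold,
                 config = config),
            class = "sweep_result")
}

# one grid point: cohort -> colonized fractions -> BC + bootstrap CI
sweep_point <- function(params, c_j, config, seed_j) {
  m <- rate_matrix(params)
  pj <- model_params(K = params$K,
                     strains = lapply(seq_len(nrow(m)), function(i)
                       strain_params(m[i, "b"], m[i, "d"], c_j)))
  ens <- simulate_ensemble(pj, config$n_hosts, config$t_end,
                           base_seed = seed_j)
  f <- cohort_fractions(ens)
  out <- data.frame(n_colonized = length(f),
                    bc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    mean_fraction = if (length(f)) mean(f) else NA_real_,
                    sd_fraction = if (length(f) > 1) sd(f) else NA_real_,
                    mean_total = mean(ens$total), sd_total = sd(ens$total))
  if (length(f) < 4 || max(f) == min(f)) {
    warning(sprintf(
      "c = %g: fewer than 4 colonized hosts or constant fractions; BC unavailable",
      c_j), call. = FALSE)
    return(out)
  }
  bc <- bootstrap_bc(f, n_boot = config$n_boot,
                     seed = derive_seed(seed_j, 1L))
  out$bc <- bc$bc; out$ci_low <- bc$ci_low; out$ci_high <- bc$ci_high
  out
}

# mean +/- 1 SD of BC over random (b, d, K) draws, per grid point
uncertainty_band <- function(config) {
  u <- config$uncertainty
  set.seed(derive_seed(config$seed, 99991L))
  draws <- matrix(NA_real_, u$n_draws, 3)
  for (i in seq_len(u$n_draws)) {
    repeat {
      b <- runif(1, u$b_range[1], u$b_range[2])
      d <- runif(1, u$d_range[1], u$d_range[2])
      if (b > d) break
    }
    K <- 10^runif(1, log10(u$K_range[1]), log10(u$K_range[2]))
    draws[i, ] <- c(b, d, K)
  }
  bc_mat <- matrix(NA_real_, u$n_draws, length(config$c_grid))
  for (i in seq_len(u$n_draws)) {
    for (j in seq_along(config$c_grid)) {
      ens <- simulate_ensemble(
        model_params(b = draws[i, 1], d = draws[i, 2],
                     c = config$c_grid[j], K = draws[i, 3],
                     n_strains = length(config$params$strains)),
        config$n_hosts, config$t_end,
        base_seed = derive_seed(config$seed, 1000L * i + j))
      f <- cohort_fractions(ens)
      if (length(f) >= 4 && max(f) > min(f))
        bc_mat[i, j] <- bimodality_coefficient(f)
    }
  }
  list(mean = colMeans(bc_mat, na.rm = TRUE),
       sd = apply(bc_mat, 2, sd, na.rm = TRUE), draws = draws)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("colonization-rate sweep: %d grid points, threshold %.2f\n",
              nrow(x$table), x$threshold))
  print(x$table, digits = 3)
  if (x$status == "crossing")
    cat(sprintf("transition: c* = %.3g (c*/b = %.3g)\n", x$c_star,
                x$c_star / x$config$params$strains[[1]]$b))
  else cat("transition:", x$status, "\n")
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$c, tab$bc, log = "x", type = "b", pch = 19,
                 ylim = range(c(0, 1, tab$ci_low, tab$ci_high),
                              na.rm = TRUE),
                 xlab = "colonization rate c (per hour)",
                 ylab = "bimodality coefficient", ...)
  graphics::arrows(tab$c, tab$ci_low, tab$c, tab$ci_high, angle = 90,
                   code = 3, length = 0.03)
  if (!is.null(tab$band_mean)) {
    graphics::polygon(c(tab$c, rev(tab$c)),
                      c(tab$band_mean - tab$band_sd,
                        rev(tab$band_mean + tab$band_sd)),
                      col = grDevices::adjustcolor("grey", 0.4),
                      border = NA)
  }
  graphics::abline(h = x$threshold, lty = 2, col = "red")
  if (is.finite(x$c_star)) graphics::abline(v = x$c_star, lty = 3)
  invisible(x)
}

#' Compare two cohort composition distributions
#'
#' Mann-Whitney U comparison of the colonized-host composition fractions
#' of two cohort tables, the standard check that a high-colonization cohort
#' differs from a low-colonization one.
#'
#' @param table_a,table_b data.frames with a `fraction` column (e.g. from
#'   [simulate_ensemble()] or [generate_cohort()]); each needs >= 3
#'   colonized hosts.
#' @param column fraction column name (default `"fraction"`).
#' @return list with `U`, `p`, per-table colonized counts, and labels.
#' @export
compare_cohorts <- function(table_a, table_b, column = "fraction") {
  fa <- cohort_fractions(table_a, column)
  fb <- cohort_fractions(table_b, column)
  if (length(fa) < 3 || length(fb) < 3)
    stop("each cohort needs at least 3 colonized hosts", call. = FALSE)
  mw <- mann_whitney(fa, fb)
  c(mw, list(label_a = deparse(substitute(table_a)),
             label_b = deparse(substitute(table_b))))
}
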