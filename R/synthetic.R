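#' Dilution-plating observation model
#'
#' Observation layer shared by all synthetic-data generators: a sample at
#' true abundance `N` plated at dilution factor `D` yields a colony count
#' `~ Poisson(N / D)`, and the reported estimate is `colony_count * D`.
#' The detection limit is therefore `D` (one colony). `D = 20` matches a
#' standard workflow (200 uL resuspension per worm, 10 uL spots).
#'
#' @param dilution dilution factor `D` (>= 1).
#' @param poisson set `FALSE` to disable counting noise (observed = truth;
#'   useful for exactness checks).
#' @return An object of class `plating_model`.
#' @export
plating_model <- function(dilution = 20, poisson = TRUE) {
  stopifnot(dilution >= 1)
  structure(list(dilution = dilution, poisson = poisson),
            class = "plating_model")
}

#' Apply a plating model to true abundances
#'
#' @param truth vector of true abundances (>= 0).
#' @param plating a [plating_model()].
#' @return observed abundance estimates (multiples of the dilution factor
#'   under Poisson counting). Unbiased: E[observed] = truth.
#' @export
plate_counts <- function(truth, plating = plating_model()) {
  stopifnot(inherits(plating, "plating_model"), all(truth >= 0))
  if (!plating$poisson) return(truth)
  rpois(length(truth), truth / plating$dilution) * plating$dilution
}

#' Specification of a synthetic feeding cohort
#'
#' The in-silico analogue of feeding worm cohorts on a 50/50 two-strain
#' mixture across a grid of bacterial densities: each density is mapped to
#' a colonization rate via [density_to_colonization()], `n_worms` hosts are
#' simulated for `duration` hours, and endpoint counts pass through the
#' plating model.
#'
#' @param densities feeding densities, CFU/mL (non-empty grid).
#' @param n_worms hosts per density (>= 4; the canonical cohorts use
#'   48-56).
#' @param duration feeding time in hours (default 192 = 8 days).
#' @param params a [model_params()] object; its per-strain `c` is
#'   overridden density-by-density.
#' @param kappa density-to-colonization slope (default 1e-7).
#' @param plating a [plating_model()].
#' @param seed integer base seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(densities, n_worms = 56L, duration = 192,
                        params = model_params(b = 0.6, d = 0.54, c = 0,
                                              K = 1e5),
                        kappa = 1e-7, plating = plating_model(), seed) {
  stopifnot(length(densities) >= 1, all(densities >= 0), n_worms >= 4,
            duration > 0, inherits(params, "model_params"),
            inherits(plating, "plating_model"))
  structure(list(densities = densities, n_worms = as.integer(n_worms),
                 duration = duration, params = params, kappa = kappa,
                 plating = plating, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic multi-density cohort table
#'
#' Simulates the cohort described by a [cohort_spec()] and applies the
#' plating model independently per strain. True endpoint counts are kept in
#' `strain_*`/`total`/`fraction`; plated observations appear as
#' `obs_strain_*`, `obs_total`, `obs_fraction`. `blind = TRUE` drops the
#' truth columns (pipeline results are identical either way, since the
#' analysis only reads observed columns in blind mode).
#'
#' @param spec a [cohort_spec()].
#' @param blind drop truth columns from the output?
#' @return a `data.frame` with one row per worm, including `density` and
#'   the per-density colonization rate `c`.
#' @export
generate_cohort <- function(spec, blind = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", length(spec$densities))
  for (j in seq_along(spec$densities)) {
    dens <- spec$densities[j]
    cj <- density_to_colonization(dens, spec$kappa)
    m <- rate_matrix(spec$params)
    pj <- model_params(K = spec$params$K,
                       strains = lapply(seq_len(nrow(m)), function(i)
                         strain_params(m[i, "b"], m[i, "d"], cj)))
    tab <- simulate_ensemble(pj, spec$n_worms, spec$duration,
                             base_seed = derive_seed(spec$seed, j))
    ns <- nrow(m)
    sc <- paste0("strain_", seq_len(ns))
    set.seed(derive_seed(spec$seed, 1000L + j))
    obs <- vapply(sc, function(cn) plate_counts(tab[[cn]], spec$plating),
                  numeric(nrow(tab)))
    obs_total <- rowSums(obs)
    tab$density <- dens
    for (i in seq_len(ns)) tab[[paste0("obs_", sc[i])]] <- obs[, i]
    tab$obs_total <- obs_total
    tab$obs_fraction <- ifelse(obs_total > 0, obs[, 1] / obs_total, NA)
    out[[j]] <- tab
  }
  out <- do.call(rbind, out)
  if (blind)
    out <- out[, !grepl("^(strain_|total$|fraction$)", names(out)),
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic within-host growth series
#'
#' Emulates destructive cross-sectional sampling of a logistic outgrowth
#' experiment: at each sampling time, each digested worm's true load is the
#' logistic mean times lognormal worm-to-worm scatter (`sigma_log10`
#' decades), zeroed with a time-decaying probability
#' `extinct_prob * 2^(-t / extinct_half_life)` (stochastic extinction of
#' lightly colonized worms, gradually erased by ambient recolonization, as
#' seen in the declining counts of uncolonized worms over the first days of
#' real outgrowth assays), then plated.
#'
#' @param r net growth rate per hour.
#' @param K carrying capacity.
#' @param N0 initial abundance.
#' @param times sampling times in hours.
#' @param n_worms_per_time worms digested per timepoint (default 12).
#' @param sigma_log10 worm-to-worm scatter in decades (default 1.0).
#' @param extinct_prob probability a sampled worm is uncolonized at t = 0
#'   (default 0.2).
#' @param extinct_half_life halving time (hours) of the uncolonized
#'   fraction (default 24).
#' @param plating a [plating_model()].
#' @param seed integer seed.
#' @return data.frame with columns `time_h`, `cfu_per_worm`, `replicate`
#'   (matching the [fit_logistic()] input schema) plus `true_cfu`.
#' @export
generate_growth_series <- function(r, K, N0, times,
                                   n_worms_per_time = 12L,
                                   sigma_log10 = 1.0, extinct_prob = 0.2,
                                   extinct_half_life = 24,
                                   plating = plating_model(), seed) {
  stopifnot(K > 0, N0 >= 0, all(times >= 0), n_worms_per_time >= 1,
            sigma_log10 >= 0, extinct_prob >= 0, extinct_prob <= 1,
            extinct_half_life > 0)
  set.seed(as.integer(seed))
  rows <- expand.grid(replicate = seq_len(n_worms_per_time),
                      time_h = times)[, 2:1]
  mu <- logistic_solution(N0, r, K, rows$time_h)
  scatter <- 10^rnorm(nrow(rows), 0, sigma_log10)
  truth <- mu * scatter
  p_gone <- extinct_prob * 2^(-rows$time_h / extinct_half_life)
  truth[runif(nrow(rows)) < p_gone] <- 0
  data.frame(time_h = rows$time_h,
             cfu_per_worm = plate_counts(truth, plating),
             replicate = rows$replicate, true_cfu = truth)
}

#' Generate a synthetic division-arrest decay assay
#'
#' Exponential-decay truth `N0_mean e^{-d t}` observed through Poisson
#' plating of bulk digests, for death-rate estimation.
#'
#' @param d death rate per hour (>= 0).
#' @param N0_mean mean CFU/worm at the start of arrest.
#' @param times sampling times in hours.
#' @param n_digests bulk digests per timepoint (default 2).
#' @param plating a [plating_model()].
#' @param seed integer seed.
#' @return data.frame with `time_h`, `cfu_per_worm`, `replicate`.
#' @export
generate_arrest_series <- function(d, N0_mean, times, n_digests = 2L,
                                   plating = plating_model(), seed) {
  stopifnot(d >= 0, N0_mean > 0, all(times >= 0), n_digests >= 1)
  set.seed(as.integer(seed))
  rows <- expand.grid(replicate = seq_len(n_digests), time_h = times)[, 2:1]
  truth <- N0_mean * exp(-d * rows$time_h)
  data.frame(time_h = rows$time_h,
             cfu_per_worm = plate_counts(truth, plating),
             replicate = rows$replicate)
}

#' Generate a synthetic short-time colonization assay
#'
#' Linear-regime truth: mean CFU/worm = `kappa * density * t`, observed by
#' Poisson sampling over a disrupted batch of worms (total colonies across
#' the batch ~ Poisson(mean * batch size), reported as a per-worm mean).
#'
#' @param kappa density-to-colonization slope.
#' @param densities feeding densities (CFU/mL).
#' @param times assay times in hours (should stay within ~4 h so that
#'   within-host growth is negligible).
#' @param n_worms_batch worms per disrupted batch (default 50).
#' @param seed integer seed.
#' @return data.frame with `density_cfu_ml`, `time_h`,
#'   `mean_cfu_per_worm` (matching [estimate_colonization_rate()]).
#' @export
generate_short_assay <- function(kappa, densities, times = c(1, 4),
                                 n_worms_batch = 50L, seed) {
  stopifnot(kappa > 0, all(densities >= 0), all(times >= 0),
            all(times <= 4), n_worms_batch >= 1)
  set.seed(as.integer(seed))
  rows <- expand.grid(time_h = times, density_cfu_ml = densities)[, 2:1]
  mean_true <- kappa * rows$density_cfu_ml * rows$time_h
  total <- rpois(nrow(rows), mean_true * n_worms_batch)
  data.frame(density_cfu_ml = rows$density_cfu_ml, time_h = rows$time_h,
             mean_cfu_per_worm = total / n_worms_batch)
}
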