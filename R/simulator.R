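#' Simulate colonization of a single host
#'
#' Realizes the continuous-time Markov process in which strain `i` gains
#' one cell with propensity `(b_i N_i + c_i) * max(0, 1 - sum(N)/K)` and
#' loses one with propensity `d_i N_i`. Both birth and immigration saturate
#' with the same logistic factor, and the factor is clamped at zero so a
#' tau-leap overshoot of `K` never produces negative propensities.
#'
#' `method = "tau"` uses adaptive tau-leaping (leap condition: expected
#' relative propensity change per step below `eps`), falling back to exact
#' SSA steps whenever the total propensity is below `exact_threshold`
#' events/hour or a leap would span fewer than ~10 events; a leap that
#' would drive any count negative is rejected and retried at reduced tau,
#' so final counts are never negative. `method = "exact"` is pure Gillespie.
#' Identical `(params, seed, method)` give identical output.
#'
#' @param params a [model_params()] object.
#' @param t_end simulation horizon in hours (> 0). The canonical feeding
#'   experiment runs 192 h (8 days); 120 h (5 days) is the usual
#'   alternative.
#' @param seed integer RNG seed (required: hosts are meant to be
#'   reproducible records).
#' @param method `"tau"` (default) or `"exact"`.
#' @param record `"endpoint"` (default) or `"path"`. With `"path"` the
#'   state is recorded on `times` (default: 513 evenly spaced points);
#'   tau-leaped intervals report the pre-leap state at interior times.
#' @param times optional explicit recording grid in `[0, t_end]`.
#' @param init optional vector of initial per-strain counts (default all 0).
#' @param eps tau-leap accuracy parameter (expected fractional propensity
#'   change per leap).
#' @param exact_threshold total-propensity floor (events/hour) below which
#'   exact steps are used.
#' @return An object of class `trajectory`: list with `times`, `counts`
#'   (matrix, one column per strain; single endpoint row for
#'   `record = "endpoint"`), `final` (named final counts), `params`,
#'   `seed`, `method`.
#' @examples
#' p <- model_params(b = 0.6, d = 0.54, c = 0.1, K = 1e5)
#' tr <- simulate_host(p, t_end = 192, seed = 1, record = "path")
#' tr$final
#' @export
simulate_host <- function(params, t_end, seed,
                          method = c("tau", "exact"),
                          record = c("endpoint", "path"), times = NULL,
                          init = NULL, eps = 0.03, exact_threshold = 10) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0)
    stop("t_end must be a single finite number > 0", call. = FALSE)
  method <- match.arg(method)
  record <- match.arg(record)
  m <- rate_matrix(params)
  ns <- nrow(m)
  if (is.null(init)) init <- rep(0, ns)
  stopifnot(length(init) == ns, all(init >= 0))
  if (is.null(times)) {
    times <- if (record == "path") seq(0, t_end, length.out = 513L)
             else numeric(0)
  } else {
    stopifnot(all(times >= 0), all(times <= t_end), !is.unsorted(times))
  }

  set.seed(as.integer(seed))
  out <- sim_host_cpp(m[, "b"], m[, "d"], m[, "c"], params$K,
                      as.numeric(init), t_end,
                      if (method == "exact") 0L else 1L,
                      as.numeric(times), eps, exact_threshold)
  counts <- if (length(times)) out$snapshots else
    matrix(out$final, nrow = 1)
  colnames(counts) <- paste0("strain_", seq_len(ns))
  structure(list(times = if (length(times)) times else t_end,
                 counts = counts,
                 final = setNames(out$final, colnames(counts)),
                 params = params, seed = as.integer(seed),
                 method = method),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d strain(s), %d recorded time(s), seed %d\n",
              ncol(x$counts), length(x$times), x$seed))
  cat("final counts:", paste(sprintf("%s = %g", names(x$final), x$final),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Derive a per-host seed from a base seed
#'
#' Deterministic mixing of `(base_seed, index)` through one step of a
#' Lehmer-style congruence, kept in `[1, 2^31 - 2]` so ensembles are
#' reproducible record-by-record and hosts are decorrelated.
#'
#' @param base_seed integer ensemble seed.
#' @param index host index (1-based).
#' @return integer seed for that host.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  x <- (as.numeric(base_seed) %% m) + 1
  for (k in c(48271, 16807)) x <- (x * k + index) %% m
  as.integer(x %% (m - 1) + 1)
}

#' Simulate an ensemble of independently colonized hosts
#'
#' Runs [simulate_host()] for `n_hosts` hosts with per-host seeds derived
#' from `base_seed` via [derive_seed()] and collects endpoint states into
#' an ensemble table: one row per host with per-strain final counts, the
#' total, and `fraction` = strain 1 / total (NA for uncolonized hosts,
#' where composition is undefined).
#'
#' @inheritParams simulate_host
#' @param n_hosts number of hosts (>= 1).
#' @param base_seed integer ensemble seed.
#' @return A `data.frame` of class `ensemble_table` with columns `host_id`,
#'   `strain_1`, ..., `total`, `fraction`, `c`, `b`, `d`, `K`, `t_end`,
#'   `seed` (ready for `write.csv`).
#' @examples
#' p <- model_params(b = 0.6, d = 0.54, c = 0.1, K = 1e4)
#' tab <- simulate_ensemble(p, n_hosts = 8, t_end = 96, base_seed = 7)
#' tab$fraction
#' @export
simulate_ensemble <- function(params, n_hosts, t_end, base_seed,
                              method = c("tau", "exact"), init = NULL,
                              eps = 0.03, exact_threshold = 10) {
  stopifnot(n_hosts >= 1)
  method <- match.arg(method)
  m <- rate_matrix(params)
  ns <- nrow(m)
  finals <- matrix(NA_real_, n_hosts, ns)
  seeds <- integer(n_hosts)
  for (h in seq_len(n_hosts)) {
    seeds[h] <- derive_seed(base_seed, h)
    tr <- simulate_host(params, t_end, seeds[h], method = method,
                        init = init, eps = eps,
                        exact_threshold = exact_threshold)
    finals[h, ] <- tr$final
  }
  total <- rowSums(finals)
  out <- data.frame(host_id = seq_len(n_hosts), finals, total = total,
                    fraction = ifelse(total > 0, finals[, 1] / total, NA),
                    c = unname(m[1, "c"]), b = unname(m[1, "b"]),
                    d = unname(m[1, "d"]),
                    K = params$K, t_end = t_end, seed = seeds)
  names(out)[1 + seq_len(ns)] <- paste0("strain_", seq_len(ns))
  class(out) <- c("ensemble_table", "data.frame")
  attr(out, "params") <- params
  out
}
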