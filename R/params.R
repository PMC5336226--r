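#' Per-strain demographic rates
#'
#' Container for the three per-strain rates of the colonization model: the
#' within-host birth rate `b`, the combined death-plus-excretion rate `d`,
#' and the colonization (successful immigration) rate `c`. All rates are per
#' hour; `c` counts successful migrants per host per hour, i.e. bacteria
#' that survive ingestion and adhere to the intestine.
#'
#' @param b birth rate inside the host (per hour), non-negative (zero
#'   gives a degenerate pure death-immigration process).
#' @param d death + excretion rate (per hour), non-negative.
#' @param c colonization rate (successful migrants per hour), non-negative.
#' @return An object of class `strain_params`.
#' @examples
#' strain_params(b = 0.6, d = 0.54, c = 0.1)
#' @export
strain_params <- function(b, d, c) {
  check_rate(b, "b")
  check_rate(d, "d")
  check_rate(c, "c")
  structure(list(b = unname(b), d = unname(d), c = unname(c)),
            class = "strain_params")
}

#' Model parameters for a multi-strain colonization process
#'
#' Bundles one or more [strain_params()] with the shared carrying capacity
#' `K` (bacteria per host). The common use is the neutral two-strain model,
#' built by giving scalar `b`, `d`, `c` (applied identically to each of
#' `n_strains` strains, `c` per strain); arbitrary non-neutral models are
#' built by passing a list of `strain_params` objects.
#'
#' @param b,d,c scalar rates for a neutral model (ignored when `strains`
#'   is given). `c` is the per-strain colonization rate.
#' @param K carrying capacity (bacteria per host), at least 1.
#' @param n_strains number of identical strains in the neutral shorthand.
#' @param strains optional list of [strain_params()] objects.
#' @return An object of class `model_params` with elements `strains`
#'   (list of `strain_params`) and `K`.
#' @examples
#' # the canonical neutral two-strain parameter set
#' model_params(b = 0.6, d = 0.54, c = 0.1, K = 1e5)
#' @export
model_params <- function(b = NULL, d = NULL, c = NULL, K,
                         n_strains = 2L, strains = NULL) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 1)
    stop("K must be a single finite number >= 1", call. = FALSE)
  if (is.null(strains)) {
    if (is.null(b) || is.null(d) || is.null(c))
      stop("give either scalar b, d, c or a list of strain_params",
           call. = FALSE)
    strains <- replicate(n_strains, strain_params(b, d, c),
                         simplify = FALSE)
  }
  if (!length(strains) ||
      !all(vapply(strains, inherits, logical(1), "strain_params")))
    stop("strains must be a non-empty list of strain_params", call. = FALSE)
  structure(list(strains = strains, K = K), class = "model_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("strain: b = %g, d = %g, c = %g (per hour)\n", x$b, x$d, x$c))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("colonization model: %d strain(s), K = %g\n",
              length(x$strains), x$K))
  for (s in x$strains) print(s)
  if (is_neutral(x)) cat("(neutral: all strains identical)\n")
  invisible(x)
}

#' Are all strains demographically identical?
#'
#' @param params a [model_params()] object.
#' @return `TRUE` when every strain shares the same `b`, `d`, `c`.
#' @export
is_neutral <- function(params) {
  stopifnot(inherits(params, "model_params"))
  m <- rate_matrix(params)
  all(apply(m, 2, function(col) max(col) == min(col)))
}

# strains as an n x 3 matrix (rows = strains, cols = b, d, c)
rate_matrix <- function(params) {
  do.call(rbind, lapply(params$strains, function(s) c(b = s$b, d = s$d,
                                                      c = s$c)))
}

check_rate <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("%s must be > 0", name), call. = FALSE)
  if (!positive && x < 0)
    stop(sprintf("%s must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Read or write model parameters as JSON or YAML
#'
#' Configuration blocks use keys `b`, `d`, `c`, `K` for neutral models, or a
#' `strains` list of `{b, d, c}` records plus `K`. Rates are per hour; no
#' unit suffixes are encoded. Format is chosen by file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param params a [model_params()] object (for writing).
#' @return `read_params` returns a `model_params`; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(x$strains)) {
    sl <- x$strains
    if (is.data.frame(sl))
      sl <- lapply(seq_len(nrow(sl)), function(i) as.list(sl[i, ]))
    strains <- lapply(sl, function(s) strain_params(s$b, s$d, s$c))
    model_params(K = x$K, strains = strains)
  } else {
    model_params(b = x$b, d = x$d, c = x$c, K = x$K,
                 n_strains = if (is.null(x$n_strains)) 2L else x$n_strains)
  }
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  rec <- list(strains = lapply(params$strains, unclass), K = params$K)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(rec, path)
  invisible(path)
}
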