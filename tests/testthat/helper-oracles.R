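# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exact SSA of the LINEAR birth-death-immigration process (no carrying
# capacity), one strain, started empty; returns abundance at t_end
ssa_linear_bdi <- function(c, b, d, t_end) {
  t <- 0; n <- 0
  repeat {
    a <- c + (b + d) * n
    t <- t + rexp(1, a)
    if (t > t_end) return(n)
    n <- n + if (runif(1) < (c + b * n) / a) 1 else -1
  }
}

# pure-death process: N(t) | N(0) is exactly Binomial(N0, e^{-d t})
pure_death_draw <- function(N0, d, t) rbinom(length(t), N0, exp(-d * t))

# bimodality coefficient from an unrelated moment implementation
# (e1071 type-2 = SAS bias-corrected conventions)
bc_oracle <- function(x) {
  n <- length(x)
  m3 <- e1071::skewness(x, type = 2)
  m4 <- e1071::kurtosis(x, type = 2)
  (m3^2 + 1) / (m4 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# canonical neutral two-strain parameter set of the colonization model
canon_params <- function(c = 0.1, K = 1e5, b = 0.6, d = 0.54)
  model_params(b = b, d = d, c = c, K = K)

# validation design for growth-series recovery studies (see vignette):
# enough worms per timepoint that 1-decade scatter resolves K to ~15%
growth_design <- list(r = 0.0625, K = 2e5, N0 = 1000,
                      times = seq(0, 240, by = 24), n_worms = 24L)
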