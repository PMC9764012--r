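# Shared builders for small synthetic populations used across test files.

# A long-format null population: iid Gaussian values on t = 51..t_end.
null_population <- function(n_caps, t_end = 180, mean = 0, sd = 1,
                            t_start = 51) {
  tt <- t_start:t_end
  tibble::tibble(
    capillary_id = rep(seq_len(n_caps), each = length(tt)),
    t = rep(tt, n_caps),
    x = stats::rnorm(n_caps * length(tt), mean, sd))
}

# Deterministic (zero-SD, zero-noise) population spec at given levels.
constant_spec <- function(n = 3, velocity = 300, lineal_density = 50,
                          so2 = 70) {
  population_spec(
    n,
    baseline = list(velocity = c(mean = velocity, sd = 0),
                    lineal_density = c(mean = lineal_density, sd = 0),
                    so2 = c(mean = so2, sd = 0)),
    amplitude = list(velocity = c(mean = 0, sd = 0),
                     lineal_density = c(mean = 0, sd = 0),
                     so2 = c(mean = 0, sd = 0)),
    noise = c(velocity = 0, lineal_density = 0, so2 = 0))
}

# Null kinetics templates (zero amplitude => series constant at baseline).
null_kinetics <- function(X0 = 61) {
  list(velocity = mono_exp_params(300, X0, 0, 1),
       lineal_density = mono_exp_params(50, X0, 0, 1),
       so2 = mono_exp_params(70, X0, 0, 1))
}

# A constant ground-truth series for the STI renderer.
constant_series <- function(seconds, velocity, lineal_density, so2 = 60) {
  tibble::tibble(t = seq_len(seconds), velocity = velocity,
                 lineal_density = lineal_density, so2 = so2)
}
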