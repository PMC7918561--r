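# Shared fixtures built in code.

# Tiny deterministic factor set for consistent-panel constructions.
make_factors <- function(n_factors = 2, m = 8, start_year = 2000) {
  lapply(seq_len(n_factors), function(i)
    annual_series(10 * i * (1 + 0.03 * i)^(seq_len(m) - 1), start_year,
                  name = paste0("F", i)))
}

# Random positive factors under the caller's RNG state.
random_factors <- function(n_factors, m, start_year = 2000) {
  lapply(seq_len(n_factors), function(i)
    annual_series(runif(1, 1, 20) * cumprod(c(1, 1 + runif(m - 1, 0, 0.2))),
                  start_year, name = paste0("F", i)))
}

round2 <- function(x, d) graysys::round_half_up(x, d)

china <- china_health_panel()
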