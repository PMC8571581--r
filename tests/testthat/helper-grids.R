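# Parameter grids shared across tests. Kept deliberately coarse in unit tests;
# the acceptance tests sweep the full grids.
param_grid <- function(l = c(1, 2, 4, 8), m = c(1, 2, 5, 25),
                       epsilon = c(0, 0.5, 1), theta = 0.025) {
  tidyr::expand_grid(l = l, m = m, epsilon = epsilon, theta = theta)
}

# tiny simulation config used for structural tests
tiny_config <- function(l = 2, m = 3, epsilon = 1, theta = 0.025,
                        n_groups = 10, generations = 5, ...) {
  sim_config(dol_params(l, m, epsilon, theta),
             target_pop_size = n_groups * l * m,
             generations = generations, ...)
}

# founder table with explicit genotypes (one group unless stated otherwise)
founders_with <- function(q, s, n_groups = 1) {
  l <- length(q)
  tidyr::expand_grid(group = seq_len(n_groups), founder = seq_len(l)) |>
    dplyr::mutate(q = q[founder], s = s[founder])
}
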