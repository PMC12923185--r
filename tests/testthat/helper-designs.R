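# Shared fixture builders. All designs are built in code; simple-effect
# parameterization: s1 applies at moderator level 1, s2 at level 2.

design_from_simple_effects <- function(s1, s2, sigma = 1, n_per_cell = 25L,
                                       reliability = 1) {
  cell_means_design(m11 = s1 * sigma, m12 = 0, m21 = s2 * sigma, m22 = 0,
                    sigma = sigma, n_per_cell = n_per_cell,
                    reliability = reliability)
}

# randomized nonnull planning designs with reproducible magnitudes
random_nonnull_designs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s1 <- runif(1, 0.15, 0.8) * sample(c(-1, 1), 1)
    s2 <- runif(1, -0.8, 0.8)
    if (abs(s1 - s2) < 0.1) s2 <- s2 - 0.15
    design_from_simple_effects(s1, s2, n_per_cell = sample(20:80, 1))
  })
}

all_answer_combos <- function() {
  expand.grid(mechanistic_plausible = c(FALSE, TRUE),
              theoretical_plausible = c(FALSE, TRUE),
              indirect_population = c(FALSE, TRUE),
              indirect_intervention = c(FALSE, TRUE),
              indirect_outcome = c(FALSE, TRUE))
}
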