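test_that("a field with only true hypotheses has PPV 1", {
  cfg <- field_config(5000, R = 1, alpha = .05, power = .6, seed = 9)
  res <- simulate_field(cfg)
  expect_equal(res$fp, 0L)
  expect_equal(res$tn, 0L)
  expect_equal(res$empirical_ppv, 1)
  expect_equal(res$tp + res$fn, 5000)
})

test_that("identical seed and config reproduce the result bit for bit", {
  cfg <- field_config(20000, R = .25, alpha = .01, power = .5, seed = 123)
  expect_identical(simulate_field(cfg), simulate_field(cfg))
  other <- field_config(20000, R = .25, alpha = .01, power = .5, seed = 124)
  expect_false(identical(simulate_field(cfg), simulate_field(other)))
  # the simulator restores the caller's RNG stream
  set.seed(42); before <- runif(5)
  set.seed(42); invisible(simulate_field(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("counts partition the field and rates sit near their expectations", {
  cfg <- field_config(50000, R = .25, alpha = .01, power = .5, seed = 77)
  res <- simulate_field(cfg)
  expect_equal(res$tp + res$fp + res$tn + res$fn, 50000)
  n_true <- res$tp + res$fn
  se_sig <- sqrt(.5 * .5 / n_true)
  expect_lt(abs(res$true_effect_sig_rate - .5), 3 * se_sig)
  # the realized PPV follows the probability-consistent closed form
  expected <- compute_ppv(.25, .5, .01, "probability_consistent")$ppv
  se_ppv <- sqrt(expected * (1 - expected) / (res$tp + res$fp))
  expect_lt(abs(res$empirical_ppv - expected), 3 * se_ppv)
})

test_that("empirical PPV converges to the closed form as the field grows", {
  expected <- compute_ppv(.25, .5, .05, "probability_consistent")$ppv
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    res <- simulate_field(field_config(as.integer(n), .25, .05,
                                       power = .5, seed = 2024))
    abs(res$empirical_ppv - expected)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("a field that claims no positives reports an undefined PPV", {
  cfg <- field_config(10, R = 1, alpha = .05, power = 0, seed = 5)
  res <- simulate_field(cfg)
  expect_equal(res$tp + res$fp, 0)
  expect_true(is.na(res$empirical_ppv))
  expect_false(identical(res$empirical_ppv, 0))
})

test_that("expected replication rate is the stated convex combination", {
  expect_equal(expected_replication_rate(1, .8, .05), .8)
  expect_equal(expected_replication_rate(0, .8, .05), .05)
  expect_equal(expected_replication_rate(.5, .8, .05), .425)
  # strictly increasing in the PPV whenever power exceeds alpha
  ppvs <- seq(0, 1, by = .1)
  rates <- vapply(ppvs, expected_replication_rate,
                  numeric(1), replication_power = .8, replication_alpha = .05)
  expect_true(all(diff(rates) > 0))
})

test_that("simulated replication rates track the expected ones", {
  cfg <- field_config(100000, R = .25, alpha = .05, power = .8,
                      replication_power = .8, replication_alpha = .05,
                      seed = 31)
  res <- simulate_field(cfg)
  expected <- expected_replication_rate(res$empirical_ppv, .8, .05)
  se <- sqrt(expected * (1 - expected) / (res$tp + res$fp))
  expect_lt(abs(res$replication_rate - expected), 3 * se)
})

test_that("full-data mode reproduces alpha under the null and power otherwise", {
  null_design <- cell_means_design(0.2, 0.2, 0.2, 0.2, n_per_cell = 10)
  cfg0 <- field_config(20000, R = 1, alpha = .05, mode = "full_data",
                       effect_template = null_design, seed = 61)
  res0 <- simulate_field(cfg0)
  se0 <- sqrt(.05 * .95 / 20000)
  expect_lt(abs(res0$true_effect_sig_rate - .05), 3 * se0)

  d_star <- calibrate_reference_effect()
  crossover <- design_from_simple_effects(d_star, -d_star, n_per_cell = 64L)
  cfg1 <- field_config(20000, R = 1, alpha = .05, mode = "full_data",
                       effect_template = crossover, seed = 62)
  res1 <- simulate_field(cfg1)
  analytic <- interaction_power(crossover, .05)$power
  se1 <- sqrt(analytic * (1 - analytic) / 20000)
  expect_lt(abs(res1$true_effect_sig_rate - analytic), 3 * se1)
  # direction-consistent replication of a strong true effect is common,
  # of a null effect rare (at most alpha)
  expect_gt(res1$replication_rate, .7)
  expect_lt(res0$replication_rate, .05)
})

test_that("configs are validated against their mode", {
  expect_error(field_config(100, .5, mode = "bernoulli"),
               class = "ppvplan_validation_error", regexp = "power")
  expect_error(field_config(100, .5, mode = "full_data"),
               class = "ppvplan_validation_error", regexp = "effect_template")
  expect_error(field_config(100, .5, power = .5,
                            effect_template = cell_means_design(1, 0, 0, 0)),
               class = "ppvplan_validation_error")
  expect_error(field_config(0, .5, power = .5),
               class = "ppvplan_validation_error", regexp = "n_studies")
})

test_that("the response surface matches per-cell simulations and theory", {
  surf <- ppv_response_surface(c(.1, .5), c(.1, .8), .05,
                               n_studies = 20000L, seed = 97)
  expect_equal(nrow(surf), 4L)
  for (i in seq_len(nrow(surf))) {
    expected <- compute_ppv(surf$R[i], surf$power[i], surf$alpha[i],
                            "probability_consistent")$ppv
    expect_lt(abs(surf$empirical_ppv[i] - expected), 3 * surf$se[i])
  }
  # the leverage of R is larger at low power, now observed empirically
  gap_low <- surf$empirical_ppv[surf$R == .5 & surf$power == .1] -
    surf$empirical_ppv[surf$R == .1 & surf$power == .1]
  gap_high <- surf$empirical_ppv[surf$R == .5 & surf$power == .8] -
    surf$empirical_ppv[surf$R == .1 & surf$power == .8]
  expect_gt(gap_low, gap_high)
  # a one-cell surface reduces to simulate_field with the derived seed
  one <- ppv_response_surface(.25, .5, .01, n_studies = 5000L, seed = 7)
  direct <- simulate_field(field_config(5000L, .25, .01, power = .5,
                                        seed = 8L))
  expect_equal(one$empirical_ppv, direct$empirical_ppv)
  expect_equal(one$tp, direct$tp)
})
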