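test_that("printed PPV reproduces the heuristic worked example (93%)", {
  res <- compute_ppv(R = .25, power = .5, alpha = .01)
  expect_equal(res$ppv, 0.125 / 0.135, tolerance = 1e-15)
  expect_equal(percent_label(res$ppv), "93%")
  expect_true(res$feasible)
})

test_that("frozen high-precision values for both formula variants", {
  # .125 / (.125 + .0075) = 50/53, frozen from exact rational arithmetic
  pc <- compute_ppv(.25, .5, .01, variant = "probability_consistent")
  expect_equal(pc$ppv, 0.94339622641509435, tolerance = 1e-15)
  # .08 / .13 = 8/13
  pr <- compute_ppv(.1, .8, .05)
  expect_equal(pr$ppv, 0.61538461538461542, tolerance = 1e-15)
})

test_that("zero power gives PPV 0 under either variant", {
  for (v in c("printed", "probability_consistent")) {
    expect_identical(compute_ppv(.3, 0, .05, v)$ppv, 0)
    expect_identical(compute_ppv(1, 0, .001, v)$ppv, 0)
  }
})

test_that("domain violations name the offending field", {
  expect_error(compute_ppv(0, .5, .05), class = "ppvplan_validation_error",
               regexp = "`R`")
  expect_error(compute_ppv(.5, 1.2, .05), class = "ppvplan_validation_error",
               regexp = "`power`")
  expect_error(compute_ppv(.5, .5, 0), class = "ppvplan_validation_error",
               regexp = "`alpha`")
  expect_error(required_power(.5, .05, 1), class = "ppvplan_validation_error",
               regexp = "`target_ppv`")
  expect_error(required_alpha(.5, .8, 0), class = "ppvplan_validation_error",
               regexp = "`target_ppv`")
})

test_that("required_power inverts compute_ppv and reports infeasibility", {
  target <- compute_ppv(.25, .5, .01)$ppv
  expect_equal(required_power(.25, .01, target)$power, .5, tolerance = 1e-10)

  # as alpha shrinks, the power needed for a fixed PPV vanishes
  expect_lt(required_power(.5, 1e-7, .5)$power, 1e-6)

  inf <- required_power(.1, .05, .99)   # closed form demands power 49.5
  expect_false(inf$feasible)
  expect_true(is.na(inf$power))
  expect_equal(inf$ppv, compute_ppv(.1, 1, .05)$ppv)  # max attainable
})

test_that("required_alpha inverts compute_ppv", {
  expect_equal(required_alpha(.5, .8, .8)$alpha, .1, tolerance = 1e-15)
  target <- compute_ppv(.25, .5, .01)$ppv
  expect_equal(required_alpha(.25, .5, target)$alpha, .01, tolerance = 1e-10)
  # monotone approach: alpha -> 0 as the target PPV -> 1
  alphas <- vapply(c(.9, .99, .999, .9999),
                   function(t) required_alpha(.3, .8, t)$alpha, numeric(1))
  expect_true(all(diff(alphas) < 0))
  expect_lt(alphas[4], 1e-3)
})

test_that("round-trip identities hold to 1e-10 over randomized inputs", {
  set.seed(101)
  for (i in 1:200) {
    R <- runif(1, .02, 1); p <- runif(1, .05, 1); a <- runif(1, .001, .2)
    v <- sample(c("printed", "probability_consistent"), 1)
    ppv <- compute_ppv(R, p, a, v)$ppv
    if (ppv > 0 && ppv < 1) {
      expect_equal(required_power(R, a, ppv, v)$power, p, tolerance = 1e-10)
      expect_equal(required_alpha(R, p, ppv, v)$alpha, a, tolerance = 1e-10)
    }
  }
})

test_that("PPV is monotone in R and power, antitone in alpha", {
  set.seed(202)
  for (i in 1:100) {
    R <- runif(1, .05, .9); p <- runif(1, .1, .9); a <- runif(1, .005, .2)
    eps <- .05
    for (v in c("printed", "probability_consistent")) {
      base <- compute_ppv(R, p, a, v)$ppv
      expect_gt(compute_ppv(R + eps, p, a, v)$ppv, base)
      expect_gt(compute_ppv(R, p + eps, a, v)$ppv, base)
      expect_lt(compute_ppv(R, p, a + eps, v)$ppv, base)
    }
  }
})

test_that("probability-consistent PPV strictly dominates the printed form", {
  set.seed(303)
  for (i in 1:100) {
    R <- runif(1, .05, 1); p <- runif(1, .1, 1); a <- runif(1, .005, .2)
    expect_gt(compute_ppv(R, p, a, "probability_consistent")$ppv,
              compute_ppv(R, p, a, "printed")$ppv)
  }
  # at R = 1 no false hypotheses exist: the consistent form returns 1,
  # while the printed form still charges alpha in the denominator
  expect_equal(compute_ppv(1, .7, .05, "probability_consistent")$ppv, 1)
  expect_equal(compute_ppv(1, .7, .05, "printed")$ppv, .7 / .75)
})

test_that("the leverage of R on the PPV is larger at low power", {
  for (a in c(.05, .01)) {
    for (v in c("printed", "probability_consistent")) {
      gap_low <- compute_ppv(.5, .1, a, v)$ppv - compute_ppv(.1, .1, a, v)$ppv
      gap_high <- compute_ppv(.5, .8, a, v)$ppv - compute_ppv(.1, .8, a, v)$ppv
      expect_gt(gap_low, gap_high)
    }
  }
})

test_that("ppv_grid is the ordered full factorial and matches compute_ppv", {
  g <- ppv_grid()
  expect_equal(nrow(g), 18L)
  expect_equal(g[1, c("R", "power", "alpha")],
               data.frame(R = .5, power = .8, alpha = .05))
  # deterministic ordering: R desc, then power desc, then alpha desc
  key <- order(-g$R, -g$power, -g$alpha)
  expect_equal(key, seq_len(18L))
  # contains the 93% cell
  cell <- g[g$R == .25 & g$power == .5 & g$alpha == .01, ]
  expect_equal(percent_label(cell$ppv), "93%")
  # single-cell grid is consistent with compute_ppv
  g1 <- ppv_grid(.5, .8, .05)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$ppv, compute_ppv(.5, .8, .05)$ppv)
  expect_error(ppv_grid(numeric(0)), class = "ppvplan_validation_error")
})

test_that("grid PPVs are monotone along every axis (brute force over rows)", {
  g <- ppv_grid()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(g))) {
      same_pa <- g$power[i] == g$power[j] && g$alpha[i] == g$alpha[j]
      if (same_pa && g$R[i] > g$R[j]) expect_gt(g$ppv[i], g$ppv[j])
      same_Ra <- g$R[i] == g$R[j] && g$alpha[i] == g$alpha[j]
      if (same_Ra && g$power[i] > g$power[j]) expect_gt(g$ppv[i], g$ppv[j])
      same_Rp <- g$R[i] == g$R[j] && g$power[i] == g$power[j]
      if (same_Rp && g$alpha[i] > g$alpha[j]) expect_lt(g$ppv[i], g$ppv[j])
    }
  }
})

test_that("grid export round-trips at full precision", {
  g <- ppv_grid(c(.25, .1), .5, .01)
  csv <- tempfile(fileext = ".csv")
  jsn <- tempfile(fileext = ".json")
  write_ppv_grid(g, csv, "csv")
  write_ppv_grid(g, jsn, "json")
  back_csv <- read.csv(csv)
  expect_equal(back_csv$ppv, g$ppv, tolerance = 1e-15)
  back_json <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_equal(back_json$ppv, g$ppv, tolerance = 1e-15)
  unlink(c(csv, jsn))
})

test_that("percent display rounds half away from zero", {
  expect_equal(percent_label(0.925), "93%")
  expect_equal(percent_label(0.9249), "92%")
  expect_equal(percent_label(0), "0%")
  expect_equal(percent_label(1), "100%")
})
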