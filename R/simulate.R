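# Monte-Carlo simulator of a research field: hypotheses are true with base
# rate R, each gets one original study and (if claimed positive) one
# replication attempt. Two modes:
#   * bernoulli  — significance is drawn directly from the study's power
#                  (true hypotheses) or alpha (false ones);
#   * full_data  — each study of a balanced 2x2 design is simulated from the
#                  normal model and tested with the 1-df interaction F test.
# The full_data mode draws the model's sufficient statistics (four cell
# means ~ Normal(mu, sigma^2/n), pooled SS ~ sigma^2 * chi^2_{N-4}), whose
# joint law is identical to that of raw per-participant draws; this keeps
# large simulations cheap without touching the analytic noncentral-F path.

#' Field simulation configuration
#'
#' @param n_studies Number of hypotheses/studies simulated, >= 1.
#' @param R Base rate of true hypotheses in the field, in (0, 1].
#' @param alpha Significance level of the original studies.
#' @param mode `"bernoulli"` or `"full_data"`.
#' @param power Per-study power for true hypotheses (bernoulli mode only).
#' @param effect_template A [cell_means_design()] giving the true-effect
#'   pattern (full_data mode only); false hypotheses use the corresponding
#'   null design (equal means, same sigma and n).
#' @param replication_power Probability a replication of a true positive is
#'   significant (bernoulli mode). Defaults to `power`.
#' @param replication_alpha Significance level of replications (and, in
#'   bernoulli mode, the success probability for replications of false
#'   positives). Defaults to `alpha`.
#' @param seed Integer seed; every result is bit-for-bit reproducible
#'   from it.
#' @return An object of class `field_config`.
#' @seealso [simulate_field()]
#' @export
field_config <- function(n_studies, R, alpha = 0.05,
                         mode = c("bernoulli", "full_data"),
                         power = NULL, effect_template = NULL,
                         replication_power = NULL, replication_alpha = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  n_studies <- check_count(n_studies, "n_studies", min = 1L)
  check_prob(R, "R", open_lower = TRUE)
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  if (mode == "bernoulli") {
    if (is.null(power) || !is.null(effect_template)) {
      abort_validation("power",
        "bernoulli mode requires `power` and no `effect_template`")
    }
    check_prob(power, "power")
    if (is.null(replication_power)) replication_power <- power
  } else {
    if (is.null(effect_template) || !is.null(power)) {
      abort_validation("effect_template",
        "full_data mode requires `effect_template` and no `power`")
    }
    stopifnot(inherits(effect_template, "cell_means_design"))
    if (is.null(replication_power)) replication_power <- NA_real_
  }
  if (is.null(replication_alpha)) replication_alpha <- alpha
  if (!is.na(replication_power)) {
    check_prob(replication_power, "replication_power")
  }
  check_prob(replication_alpha, "replication_alpha",
             open_lower = TRUE, open_upper = TRUE)
  structure(
    list(n_studies = n_studies, R = R, alpha = alpha, mode = mode,
         power = power, effect_template = effect_template,
         replication_power = replication_power,
         replication_alpha = replication_alpha, seed = seed),
    class = "field_config"
  )
}

# draw the interaction F test for n studies of a design whose standardized
# contrast is delta (already reliability-attenuated); returns significance
# flags and the sign of each estimated contrast
draw_interaction_tests <- function(n, delta, N, alpha) {
  df2 <- N - 4
  # contrast estimate in standardized units: mean delta, variance 16/N
  est <- stats::rnorm(n, mean = delta, sd = sqrt(16 / N))
  mse <- stats::rchisq(n, df = df2) / df2      # pooled variance / sigma^2
  f_stat <- (N / 16) * est^2 / mse
  crit <- stats::qf(1 - alpha, 1, df2)
  list(sig = f_stat > crit, sign = sign(est))
}

#' Simulate a literature of original studies and replications
#'
#' Draws `n_studies` hypotheses, each true with probability `R`, simulates
#' an original study for each, and a replication for each claimed positive.
#' Outcomes are tallied as true/false positives/negatives; the empirical
#' PPV is `tp / (tp + fp)`. In bernoulli mode a replication succeeds with
#' probability `replication_power` (true effects) or `replication_alpha`
#' (false ones); in full_data mode it must be significant *and* have an
#' interaction contrast of the same sign as the original study.
#'
#' Because false positives arise at rate `alpha * (1 - R)`, the empirical
#' PPV converges to the probability-consistent formula variant of
#' [compute_ppv()], not to the printed one (the two coincide as R
#' approaches 1).
#'
#' @param config A [field_config()].
#' @return An object of class `field_result`: counts `tp`, `fp`, `tn`,
#'   `fn`; `empirical_ppv` (`NA` when no positives were claimed, never
#'   coerced to 0); `true_effect_sig_rate`; `replication_rate` among
#'   claimed positives; `n_studies`, `seed`.
#' @examples
#' cfg <- field_config(n_studies = 10000, R = .25, alpha = .01,
#'                     power = .5, seed = 42)
#' simulate_field(cfg)
#' @export
simulate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_studies
  is_true <- stats::runif(n) < config$R

  if (config$mode == "bernoulli") {
    p_sig <- ifelse(is_true, config$power, config$alpha)
    sig <- stats::runif(n) < p_sig
    p_rep <- ifelse(is_true, config$replication_power,
                    config$replication_alpha)
    rep_ok <- stats::runif(n) < p_rep     # consumed for all studies so the
    rep_ok[!sig] <- NA                    # draw order is index-independent
  } else {
    tmpl <- config$effect_template
    delta_att <- summarize_interaction(tmpl)$delta * sqrt(tmpl$reliability)
    deltas <- ifelse(is_true, delta_att, 0)
    orig <- draw_interaction_tests(n, deltas, tmpl$N, config$alpha)
    sig <- orig$sig
    repl <- draw_interaction_tests(n, deltas, tmpl$N,
                                   config$replication_alpha)
    rep_ok <- repl$sig & repl$sign == orig$sign
    rep_ok[!sig] <- NA
  }

  tp <- sum(sig & is_true); fp <- sum(sig & !is_true)
  fn <- sum(!sig & is_true); tn <- sum(!sig & !is_true)
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      empirical_ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      true_effect_sig_rate = if (any(is_true)) mean(sig[is_true]) else NA_real_,
      replication_rate = if (any(sig)) mean(rep_ok[sig]) else NA_real_,
      n_studies = n, seed = config$seed
    ),
    class = "field_result"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf(
    paste0("Simulated field (%d studies, seed %d)\n",
           "  TP %d  FP %d  TN %d  FN %d\n",
           "  empirical PPV = %s, true-effect significance rate = %.4f\n",
           "  replication rate among positives = %s\n"),
    x$n_studies, x$seed, x$tp, x$fp, x$tn, x$fn,
    if (is.na(x$empirical_ppv)) "undefined (no positives)"
      else sprintf("%.4f", x$empirical_ppv),
    x$true_effect_sig_rate,
    if (is.na(x$replication_rate)) "undefined" else
      sprintf("%.4f", x$replication_rate)))
  invisible(x)
}

#' Expected replication rate of a literature with a given PPV
#'
#' True claims replicate with probability `replication_power`, false ones
#' with probability `replication_alpha`, so the expected replication rate
#' among claimed positives is the convex combination
#' `ppv * replication_power + (1 - ppv) * replication_alpha` — strictly
#' increasing in the PPV whenever replications are more powerful than their
#' false-positive rate. This is the formal version of the observation that
#' fields with more true findings replicate better.
#'
#' @param ppv,replication_power,replication_alpha Probabilities.
#' @return The expected replication rate.
#' @examples
#' expected_replication_rate(.5, .8, .05)   # 0.425
#' @export
expected_replication_rate <- function(ppv, replication_power,
                                      replication_alpha) {
  check_prob(ppv, "ppv")
  check_prob(replication_power, "replication_power")
  check_prob(replication_alpha, "replication_alpha")
  ppv * replication_power + (1 - ppv) * replication_alpha
}

#' Empirical PPV response surface over an (R, power, alpha) grid
#'
#' Runs a bernoulli-mode field simulation for every combination of the
#' supplied base rates, powers and alpha levels, reporting the empirical
#' PPV with its binomial Monte-Carlo standard error. Cell seeds are derived
#' deterministically from `seed` and the cell index, so the surface is
#' reproducible and cells are independent of evaluation order.
#'
#' @param R_values,power_values,alpha_values Probability grids.
#' @param n_studies Studies per grid cell.
#' @param seed Base seed.
#' @return Data frame with one row per cell: `R`, `power`, `alpha`,
#'   `n_studies`, `tp`, `fp`, `tn`, `fn`, `empirical_ppv`, `se`,
#'   `replication_rate`.
#' @examples
#' ppv_response_surface(c(.1, .5), c(.1, .8), .05, n_studies = 5000, seed = 7)
#' @export
ppv_response_surface <- function(R_values, power_values, alpha_values,
                                 n_studies = 10000L, seed = 1L) {
  check_prob_vector(R_values, "R_values", open_lower = TRUE)
  check_prob_vector(power_values, "power_values")
  check_prob_vector(alpha_values, "alpha_values",
                    open_lower = TRUE, open_upper = TRUE)
  n_studies <- check_count(n_studies, "n_studies", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  grid <- expand.grid(alpha = alpha_values, power = power_values,
                      R = R_values, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("R", "power", "alpha")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- field_config(n_studies, grid$R[i], grid$alpha[i],
                        mode = "bernoulli", power = grid$power[i],
                        seed = (seed + i) %% .Machine$integer.max)
    res <- simulate_field(cfg)
    npos <- res$tp + res$fp
    se <- if (npos > 0 && !is.na(res$empirical_ppv)) {
      sqrt(res$empirical_ppv * (1 - res$empirical_ppv) / npos)
    } else NA_real_
    data.frame(R = grid$R[i], power = grid$power[i], alpha = grid$alpha[i],
               n_studies = n_studies, tp = res$tp, fp = res$fp, tn = res$tn,
               fn = res$fn, empirical_ppv = res$empirical_ppv, se = se,
               replication_rate = res$replication_rate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo check of analytic interaction power
#'
#' Estimates the rejection rate of the balanced 2x2 interaction F test by
#' simulating `nrep` studies of `design` from the normal model (via its
#' sufficient statistics) and testing each at level `alpha`. Serves as an
#' empirical cross-check of [interaction_power()]; it never evaluates the
#' noncentral-F distribution function.
#'
#' @param design A [cell_means_design()].
#' @param alpha Significance level.
#' @param nrep Number of simulated studies.
#' @param seed Integer seed.
#' @return List with `rejection_rate`, `se` (binomial Monte-Carlo standard
#'   error), `nrep`.
#' @examples
#' d <- cell_means_design(0.35, 0, -0.35, 0, n_per_cell = 64)
#' simulate_interaction_power(d, nrep = 10000, seed = 3)
#' @export
simulate_interaction_power <- function(design, alpha = 0.05, nrep = 10000L,
                                       seed = 1L) {
  stopifnot(inherits(design, "cell_means_design"))
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  nrep <- check_count(nrep, "nrep", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  delta_att <- summarize_interaction(design)$delta * sqrt(design$reliability)
  draws <- draw_interaction_tests(nrep, delta_att, design$N, alpha)
  rate <- mean(draws$sig)
  list(rejection_rate = rate, se = sqrt(rate * (1 - rate) / nrep),
       nrep = nrep)
}
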