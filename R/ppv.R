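#' Positive predictive value of a significant finding
#'
#' The positive predictive value (PPV) is the post-study probability that a
#' statistically significant claim reflects a true effect. It depends on the
#' pre-study probability `R` that the tested effect exists, the power
#' `1 - beta` of the test, and the significance level `alpha`.
#'
#' Two formula variants are provided. The `"printed"` variant is the form
#' most often quoted in the meta-research literature,
#' \deqn{PPV = \frac{(1-\beta)\,R}{(1-\beta)\,R + \alpha},}
#' which treats `R` as a probability in the numerator but omits the
#' `(1 - R)` multiplier on `alpha` in the denominator (it is exact when `R`
#' is read as prior *odds*). The `"probability_consistent"` variant applies
#' Bayes' theorem with `R` as a probability throughout,
#' \deqn{PPV = \frac{(1-\beta)\,R}{(1-\beta)\,R + \alpha\,(1 - R)}.}
#' The printed form is the default because it reproduces the familiar
#' worked examples of that literature (e.g. R = .25, power = .5,
#' alpha = .01 giving 93\%); a field realising false positives at rate
#' `alpha * (1 - R)` — as the Monte-Carlo simulator in this package does —
#' matches the probability-consistent form instead. For `R = 1` the two
#' variants differ only in that the printed one keeps `alpha` in the
#' denominator; see the methods vignette.
#'
#' @param R Pre-study probability that the effect exists, in (0, 1].
#' @param power Statistical power `1 - beta`, in \[0, 1\].
#' @param alpha Significance level, in (0, 1).
#' @param variant `"printed"` (default) or `"probability_consistent"`.
#' @return An object of class `ppv_result`: a list with elements `ppv`,
#'   `R`, `power`, `alpha`, `variant` and `feasible` (always `TRUE` for a
#'   direct computation; inverse solvers may return `FALSE`).
#' @seealso [required_power()], [required_alpha()], [ppv_grid()]
#' @examples
#' compute_ppv(R = .25, power = .5, alpha = .01)           # 0.9259..., "93%"
#' compute_ppv(.25, .5, .01, variant = "probability_consistent")
#' @export
compute_ppv <- function(R, power, alpha,
                        variant = c("printed", "probability_consistent")) {
  variant <- match.arg(variant)
  check_prob(R, "R", open_lower = TRUE)
  check_prob(power, "power")
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  num <- power * R
  denom <- if (variant == "printed") num + alpha else num + alpha * (1 - R)
  ppv <- if (num == 0) 0 else num / denom
  new_ppv_result(ppv, R, power, alpha, variant)
}

new_ppv_result <- function(ppv, R, power, alpha, variant, feasible = TRUE,
                           note = NULL) {
  structure(
    list(ppv = ppv, R = R, power = power, alpha = alpha, variant = variant,
         feasible = feasible, note = note),
    class = "ppv_result"
  )
}

#' @export
print.ppv_result <- function(x, ...) {
  cat(sprintf(
    "PPV = %.6f (%s) given R = %g, power = %s, alpha = %s [%s]\n",
    x$ppv, percent_label(x$ppv), x$R,
    format(x$power), format(x$alpha), x$variant))
  if (!x$feasible) cat("  infeasible:", x$note, "\n")
  invisible(x)
}

# effective false-positive weight in the denominator for each variant
alpha_weight <- function(R, variant) {
  if (variant == "printed") 1 else 1 - R
}

#' Power required to reach a target PPV
#'
#' Solves the PPV identity for power at fixed `R` and `alpha`. The solution
#' is closed-form: `power = alpha * w * ppv / (R * (1 - ppv))` where `w` is
#' 1 for the printed variant and `1 - R` for the probability-consistent one.
#' If the solution exceeds 1 the request is infeasible; the returned object
#' has `feasible = FALSE`, `power = NA`, and `ppv` set to the maximum PPV
#' attainable at power 1 (no clamping is done silently).
#'
#' @inheritParams compute_ppv
#' @param target_ppv Desired PPV, in (0, 1).
#' @return A `ppv_result`; `power` holds the solution when feasible.
#' @examples
#' required_power(R = .25, alpha = .01, target_ppv = .93)
#' required_power(R = .10, alpha = .05, target_ppv = .99)  # infeasible
#' @export
required_power <- function(R, alpha, target_ppv,
                           variant = c("printed", "probability_consistent")) {
  variant <- match.arg(variant)
  check_prob(R, "R", open_lower = TRUE)
  check_prob(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  check_prob(target_ppv, "target_ppv", open_lower = TRUE, open_upper = TRUE)
  w <- alpha_weight(R, variant)
  if (w == 0) {
    # R = 1 under the probability-consistent form: every positive is true
    return(new_ppv_result(1, R, power = NA_real_, alpha, variant,
                          feasible = FALSE,
                          note = "PPV is 1 for any power when R = 1"))
  }
  p <- alpha * w * target_ppv / (R * (1 - target_ppv))
  if (p > 1) {
    max_ppv <- compute_ppv(R, 1, alpha, variant)$ppv
    return(new_ppv_result(max_ppv, R, power = NA_real_, alpha, variant,
                          feasible = FALSE,
                          note = sprintf(
                            "required power %.4g exceeds 1; maximum attainable PPV is %.6f",
                            p, max_ppv)))
  }
  res <- new_ppv_result(target_ppv, R, power = p, alpha, variant)
  res
}

#' Significance level required to reach a target PPV
#'
#' Solves the PPV identity for `alpha` at fixed `R` and power:
#' `alpha = power * R * (1 - ppv) / (ppv * w)` with `w` as in
#' [required_power()]. Infeasible when the solution falls outside (0, 1).
#'
#' @inheritParams compute_ppv
#' @param target_ppv Desired PPV, in (0, 1).
#' @return A `ppv_result`; `alpha` holds the solution when feasible.
#' @examples
#' required_alpha(R = .5, power = .8, target_ppv = .8)   # alpha = .1
#' @export
required_alpha <- function(R, power, target_ppv,
                           variant = c("printed", "probability_consistent")) {
  variant <- match.arg(variant)
  check_prob(R, "R", open_lower = TRUE)
  check_prob(power, "power", open_lower = TRUE)
  check_prob(target_ppv, "target_ppv", open_lower = TRUE, open_upper = TRUE)
  w <- alpha_weight(R, variant)
  if (w == 0) {
    return(new_ppv_result(1, R, power, alpha = NA_real_, variant,
                          feasible = FALSE,
                          note = "PPV is 1 for any alpha when R = 1"))
  }
  a <- power * R * (1 - target_ppv) / (target_ppv * w)
  if (a <= 0 || a >= 1) {
    return(new_ppv_result(target_ppv, R, power, alpha = NA_real_, variant,
                          feasible = FALSE,
                          note = sprintf("required alpha %.4g outside (0, 1)", a)))
  }
  res <- new_ppv_result(target_ppv, R, power, variant = variant, alpha = a)
  res
}

#' Factorial PPV grid
#'
#' Evaluates the PPV over the full factorial crossing of the supplied `R`,
#' power and alpha values. The defaults reproduce the planning grid of three
#' priors (.5, .25, .1), three power levels (.1, .5, .8) and two alpha
#' levels (.05, .01). Rows are ordered R descending, then power descending,
#' then alpha descending.
#'
#' @param R_values,power_values,alpha_values Numeric vectors of probabilities.
#' @param variant Formula variant, see [compute_ppv()].
#' @return A data frame with columns `R`, `power`, `alpha`, `variant`, `ppv`.
#' @examples
#' head(ppv_grid())
#' @export
ppv_grid <- function(R_values = c(.5, .25, .1),
                     power_values = c(.1, .5, .8),
                     alpha_values = c(.05, .01),
                     variant = c("printed", "probability_consistent")) {
  variant <- match.arg(variant)
  check_prob_vector(R_values, "R_values", open_lower = TRUE)
  check_prob_vector(power_values, "power_values")
  check_prob_vector(alpha_values, "alpha_values",
                    open_lower = TRUE, open_upper = TRUE)
  grid <- expand.grid(
    alpha = sort(alpha_values, decreasing = TRUE),
    power = sort(power_values, decreasing = TRUE),
    R = sort(R_values, decreasing = TRUE),
    KEEP.OUT.ATTRS = FALSE
  )[, c("R", "power", "alpha")]
  grid$variant <- variant
  grid$ppv <- mapply(function(R, p, a) compute_ppv(R, p, a, variant)$ppv,
                     grid$R, grid$power, grid$alpha)
  rownames(grid) <- NULL
  grid
}

#' Export a PPV grid
#'
#' Writes a grid produced by [ppv_grid()] as CSV or JSON at full double
#' precision (display rounding is applied only in rendered reports).
#'
#' @param grid Data frame from [ppv_grid()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ppv_grid <- function(grid, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(grid, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Round a probability to an integer percentage, half away from zero
#'
#' Display convention for PPVs in rendered reports: 0.9259 becomes `"93%"`.
#' Uses half-up rounding (unlike [round()], which rounds half to even).
#'
#' @param p Probability in \[0, 1\].
#' @return Character scalar such as `"93%"`.
#' @examples
#' percent_label(25 / 27)   # "93%"
#' @export
percent_label <- function(p) {
  check_prob(p, "p")
  sprintf("%d%%", as.integer(floor(p * 100 + 0.5)))
}
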