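#' Answers to the pre-study probability questionnaire
#'
#' Five yes/no judgements about a hypothesized interaction. Plausibility is
#' split into *mechanistic* (is a supporting mechanism known, e.g.
#' established in an animal model?) and *theoretical* (is the hypothesis
#' aligned with a well-established theoretical framework?). Indirect
#' evidence covers the three indirectness channels of evidence-based
#' medicine: has a similar interaction been reported in a related
#' *population*, for a related *intervention*, or on a related *outcome*?
#' All five answers must be given explicitly; there are no defaults.
#'
#' @param mechanistic_plausible,theoretical_plausible Logical flags.
#' @param indirect_population,indirect_intervention,indirect_outcome
#'   Logical flags.
#' @return An object of class `elicitation_answers`.
#' @seealso [elicit_r()]
#' @export
elicitation_answers <- function(mechanistic_plausible, theoretical_plausible,
                                indirect_population, indirect_intervention,
                                indirect_outcome) {
  fields <- c("mechanistic_plausible", "theoretical_plausible",
              "indirect_population", "indirect_intervention",
              "indirect_outcome")
  for (f in fields) {
    v <- tryCatch(get(f), error = function(e) NULL)
    if (is.null(v)) abort_validation(f, "must be answered")
    check_flag(v, f)
  }
  structure(mget(fields), class = "elicitation_answers")
}

#' Generic pre-study probability from the questionnaire
#'
#' Maps the five answers to one of three generic pre-study probability
#' levels: R = .10 when the hypothesis is implausible and there is no
#' indirect evidence, R = .25 when it is either plausible or indirectly
#' supported (but not both), and R = .50 when both hold. These are
#' heuristic orientation values, not estimates of the "real" prior.
#'
#' The two plausibility flags aggregate with OR by default (the hypothesis
#' counts as plausible if either mechanistic or theoretical plausibility
#' holds); set `combine_plausibility = "and"` to require both. Any one of
#' the three indirectness channels counts as indirect evidence.
#'
#' @param answers An [elicitation_answers()] object.
#' @param combine_plausibility `"or"` (default) or `"and"`.
#' @return An object of class `generic_r`: `value` (one of .10, .25, .50),
#'   `plausible`, `evidence`, `rationale`.
#' @examples
#' a <- elicitation_answers(FALSE, TRUE, FALSE, FALSE, FALSE)
#' elicit_r(a)   # R = .25: plausible but no indirect evidence
#' @export
elicit_r <- function(answers, combine_plausibility = c("or", "and")) {
  stopifnot(inherits(answers, "elicitation_answers"))
  combine_plausibility <- match.arg(combine_plausibility)
  plaus_flags <- c(mechanistic = answers$mechanistic_plausible,
                   theoretical = answers$theoretical_plausible)
  plausible <- if (combine_plausibility == "or") any(plaus_flags)
               else all(plaus_flags)
  ev_flags <- c(population = answers$indirect_population,
                intervention = answers$indirect_intervention,
                outcome = answers$indirect_outcome)
  evidence <- any(ev_flags)
  value <- if (plausible && evidence) 0.50
           else if (plausible || evidence) 0.25
           else 0.10
  fired <- c(
    if (plausible) paste0("plausibility (",
      paste(names(plaus_flags)[plaus_flags], collapse = ", "), ")"),
    if (evidence) paste0("indirect evidence (",
      paste(names(ev_flags)[ev_flags], collapse = ", "), ")")
  )
  rationale <- if (length(fired) == 0) {
    "implausible and no indirect evidence: generic R = .10"
  } else {
    sprintf("%s: generic R = %.2f", paste(fired, collapse = " and "), value)
  }
  structure(
    list(value = value, plausible = plausible, evidence = evidence,
         rationale = rationale),
    class = "generic_r"
  )
}

#' @export
print.generic_r <- function(x, ...) {
  cat(sprintf("Generic R = %.2f — %s\n", x$value, x$rationale))
  invisible(x)
}

#' Shape-by-prior planning sector
#'
#' Places a hypothesized interaction on the two-dimensional planning grid
#' that crosses its shape (disordinal vs. the harder ordinal/attenuated
#' row) with its pre-study probability of being true:
#'
#' * **A** — disordinal, high R: the best of both worlds (small samples
#'   suffice and the claim is likely true);
#' * **B** — ordinal/attenuated, high R: worthwhile but hard to detect;
#'   plan samples from the expected pattern of means;
#' * **C** — ordinal/attenuated, low R: the "danger zone", combining a low
#'   prior with demanding sample sizes;
#' * **D** — disordinal, low R: risky but statistically less demanding
#'   than C.
#'
#' The grid's R axis is continuous; `r_threshold` (default .25, the middle
#' generic level) sets the high/low split, with R strictly above the
#' threshold counting as high.
#'
#' @param shape `"disordinal"`, `"ordinal"` or `"fully_attenuated"` (a
#'   null shape is rejected: there is no interaction to plan for).
#' @param R Pre-study probability in (0, 1].
#' @param r_threshold High/low cut on R.
#' @return An object of class `sector_assignment`: `sector`, `shape`, `R`,
#'   `r_threshold`.
#' @examples
#' classify_sector("disordinal", R = .50)       # sector A
#' classify_sector("fully_attenuated", R = .10) # sector C, the danger zone
#' @export
classify_sector <- function(shape, R, r_threshold = 0.25) {
  if (identical(shape, "null")) {
    abort_validation("shape", "no interaction to plan for (null shape)")
  }
  shape <- match.arg(shape, c("disordinal", "ordinal", "fully_attenuated"))
  check_prob(R, "R", open_lower = TRUE)
  check_prob(r_threshold, "r_threshold", open_lower = TRUE, open_upper = TRUE)
  high_r <- R > r_threshold
  sector <- if (shape == "disordinal") {
    if (high_r) "A" else "D"
  } else {
    if (high_r) "B" else "C"
  }
  structure(
    list(sector = sector, shape = shape, R = R, r_threshold = r_threshold),
    class = "sector_assignment"
  )
}

#' @export
print.sector_assignment <- function(x, ...) {
  cat(sprintf("Sector %s (%s shape, R = %g, threshold %g)\n",
              x$sector, x$shape, x$R, x$r_threshold))
  invisible(x)
}

# standardized simple effects template per shape, anchored at the
# calibrated reference effect d*; ordinal uses the partially attenuated
# pattern whose contrast is 3/14 of the cross-over contrast
shape_template <- function(shape, d_star) {
  switch(shape,
    disordinal = c(d_star, -d_star),
    fully_attenuated = c(d_star, 0),
    ordinal = c(d_star, d_star - (3 / 14) * 2 * d_star),
    abort_validation("shape", paste("no effect template for shape", shape))
  )
}

#' Planning advice for a sector assignment
#'
#' For each candidate alpha, solves the PPV identity for the power required
#' to reach `desired_ppv` at the assignment's R, then converts that power
#' into a total sample size using the shape's calibrated effect template
#' (cross-over `(+d*, -d*)`, fully attenuated `(d*, 0)`, ordinal/partially
#' attenuated contrast 3/14 of the cross-over contrast, with `d*` from
#' [calibrate_reference_effect()]). Combinations whose required power
#' exceeds 1 are flagged infeasible and get no sample size. When the
#' required power does not exceed alpha, the minimal balanced design
#' (N = 8) already suffices and is reported with a note.
#'
#' @param assignment A [classify_sector()] result.
#' @param desired_ppv Target PPV in (0, 1).
#' @param alpha_options Candidate significance levels.
#' @param variant PPV formula variant, see [compute_ppv()].
#' @return An object of class `planning_advice`: a data frame `table` with
#'   columns `alpha`, `required_power`, `feasible`, `N_total`,
#'   `achieved_power`, `note`, plus the inputs.
#' @examples
#' sec <- classify_sector("fully_attenuated", R = .10)
#' advise(sec, desired_ppv = .9, alpha_options = c(.05, .01))
#' @export
advise <- function(assignment, desired_ppv, alpha_options = c(.05, .01),
                   variant = c("printed", "probability_consistent")) {
  stopifnot(inherits(assignment, "sector_assignment"))
  variant <- match.arg(variant)
  check_prob(desired_ppv, "desired_ppv", open_lower = TRUE, open_upper = TRUE)
  check_prob_vector(alpha_options, "alpha_options",
                    open_lower = TRUE, open_upper = TRUE)
  d_star <- calibrate_reference_effect()
  s <- shape_template(assignment$shape, d_star)
  delta <- s[1] - s[2]
  rows <- lapply(alpha_options, function(a) {
    sol <- required_power(assignment$R, a, desired_ppv, variant)
    if (!sol$feasible) {
      return(data.frame(alpha = a, required_power = NA_real_,
                        feasible = FALSE, N_total = NA_integer_,
                        achieved_power = NA_real_, note = sol$note,
                        stringsAsFactors = FALSE))
    }
    if (sol$power <= a) {
      pw <- contrast_power(delta, 8L, a)
      return(data.frame(alpha = a, required_power = sol$power,
                        feasible = TRUE, N_total = 8L,
                        achieved_power = pw$power,
                        note = "required power below alpha; minimal balanced design suffices",
                        stringsAsFactors = FALSE))
    }
    ss <- required_n(delta = delta, alpha = a, target_power = sol$power)
    data.frame(alpha = a, required_power = sol$power, feasible = TRUE,
               N_total = ss$N_total, achieved_power = ss$achieved_power,
               note = "", stringsAsFactors = FALSE)
  })
  structure(
    list(table = do.call(rbind, rows), assignment = assignment,
         desired_ppv = desired_ppv, variant = variant, d_star = d_star,
         template = s),
    class = "planning_advice"
  )
}

#' @export
print.planning_advice <- function(x, ...) {
  cat(sprintf(
    "Planning advice — sector %s, R = %g, desired PPV = %g (%s variant)\n",
    x$assignment$sector, x$assignment$R, x$desired_ppv, x$variant))
  print(x$table, row.names = FALSE)
  invisible(x)
}
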