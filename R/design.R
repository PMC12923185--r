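#' Balanced 2x2 cell-means design
#'
#' Container for a balanced two-by-two between-participants design specified
#' by its pattern of means. Rows index the moderator, columns the focal
#' factor: `m11`/`m12` are the focal-factor means at moderator level 1,
#' `m21`/`m22` at level 2. `sigma` is the common within-cell standard
#' deviation and `n_per_cell` the (balanced) cell size. `reliability` is the
#' reliability of the dependent variable; values below 1 attenuate the
#' standardized effects by `sqrt(reliability)` (classical test theory)
#' before any power computation.
#'
#' @param m11,m12,m21,m22 Cell means on the outcome scale.
#' @param sigma Common within-cell standard deviation, > 0.
#' @param n_per_cell Participants per cell, >= 2; total N is `4 * n_per_cell`.
#' @param reliability Reliability of the dependent variable, in (0, 1].
#' @return An object of class `cell_means_design`.
#' @seealso [summarize_interaction()], [interaction_power()],
#'   [transpose_design()]
#' @examples
#' cross_over <- cell_means_design(0.35, 0, -0.35, 0, sigma = 1, n_per_cell = 64)
#' summarize_interaction(cross_over)
#' @export
cell_means_design <- function(m11, m12, m21, m22, sigma = 1, n_per_cell = 2L,
                              reliability = 1) {
  for (f in c("m11", "m12", "m21", "m22")) check_number(get(f), f)
  check_number(sigma, "sigma")
  if (sigma <= 0) abort_validation("sigma", "must be > 0")
  n_per_cell <- check_count(n_per_cell, "n_per_cell", min = 2L)
  check_prob(reliability, "reliability", open_lower = TRUE)
  structure(
    list(m11 = m11, m12 = m12, m21 = m21, m22 = m22, sigma = sigma,
         n_per_cell = n_per_cell, N = 4L * n_per_cell,
         reliability = reliability),
    class = "cell_means_design"
  )
}

#' @export
print.cell_means_design <- function(x, ...) {
  cat("Balanced 2x2 design (rows = moderator, cols = focal factor)\n")
  print(matrix(c(x$m11, x$m21, x$m12, x$m22), 2, 2,
               dimnames = list(c("mod 1", "mod 2"), c("focal 1", "focal 2"))))
  cat(sprintf("sigma = %g, n per cell = %d (N = %d), reliability = %g\n",
              x$sigma, x$n_per_cell, x$N, x$reliability))
  invisible(x)
}

#' Swap the roles of moderator and focal factor
#'
#' The interaction contrast is invariant under transposition, but the simple
#' effects (and hence the shape label) are not: a design that is ordinal in
#' one orientation can be disordinal in the other.
#'
#' @param design A [cell_means_design()].
#' @return The transposed `cell_means_design`.
#' @export
transpose_design <- function(design) {
  stopifnot(inherits(design, "cell_means_design"))
  cell_means_design(design$m11, design$m21, design$m12, design$m22,
                    sigma = design$sigma, n_per_cell = design$n_per_cell,
                    reliability = design$reliability)
}

#' Standardized simple effects, interaction contrast and shape
#'
#' Computes the standardized simple effects of the focal factor within each
#' moderator level, `s1 = (m11 - m12) / sigma` and `s2 = (m21 - m22) / sigma`,
#' the interaction contrast `delta = s1 - s2`, and classifies the shape:
#'
#' * `disordinal` (cross-over): the simple effects have opposite signs —
#'   the group with the larger mean switches over between moderator levels;
#' * `fully_attenuated`: one simple effect is (numerically) zero — the
#'   moderator eliminates the focal effect at one level without reversing it;
#' * `ordinal`: both simple effects share a sign but differ in magnitude
#'   (covers partially attenuated patterns);
#' * `null`: `delta` is (numerically) zero — no interaction.
#'
#' `eps` is the numerical tolerance for "zero" on the standardized scale;
#' the tight default suits exact planning inputs, widen it for noisy
#' empirical means.
#'
#' @param design A [cell_means_design()].
#' @param eps Zero-tolerance for classification, on standardized effects.
#' @return An object of class `interaction_summary`: list with `s1`, `s2`,
#'   `delta`, `shape`, `largest_simple`.
#' @examples
#' summarize_interaction(cell_means_design(0.35, 0, -0.35, 0))$shape  # disordinal
#' summarize_interaction(cell_means_design(0.35, 0, 0, 0))$shape      # fully_attenuated
#' @export
summarize_interaction <- function(design, eps = 1e-8) {
  stopifnot(inherits(design, "cell_means_design"))
  s1 <- (design$m11 - design$m12) / design$sigma
  s2 <- (design$m21 - design$m22) / design$sigma
  delta <- s1 - s2
  shape <- if (abs(delta) <= eps) {
    "null"
  } else if (s1 * s2 < -eps^2) {
    "disordinal"
  } else if (xor(abs(s1) <= eps, abs(s2) <= eps)) {
    "fully_attenuated"
  } else {
    "ordinal"
  }
  structure(
    list(s1 = s1, s2 = s2, delta = delta, shape = shape,
         largest_simple = max(abs(s1), abs(s2))),
    class = "interaction_summary"
  )
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf(
    "Interaction summary: s1 = %.4g, s2 = %.4g, delta = %.4g\nshape = %s, largest simple effect = %.4g\n",
    x$s1, x$s2, x$delta, x$shape, x$largest_simple))
  invisible(x)
}

#' Read / write cell-means fixture files
#'
#' Fixture CSVs carry one design per row with columns `label, m11, m12,
#' m21, m22, sigma, n_per_cell, reliability`. `read_fixtures()` validates
#' the header and every range before returning.
#'
#' @param path CSV file path.
#' @return `read_fixtures()`: a data frame with the columns above;
#'   `fixture_design()`: the `cell_means_design` for one row.
#' @seealso [generate_fixtures()]
#' @export
read_fixtures <- function(path) {
  if (!file.exists(path)) abort_validation("path", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "m11", "m12", "m21", "m22", "sigma", "n_per_cell",
              "reliability")
  if (!identical(names(df), needed)) {
    abort_validation("fixtures", sprintf(
      "expected columns %s, found %s",
      paste(needed, collapse = ","), paste(names(df), collapse = ",")))
  }
  for (i in seq_len(nrow(df))) {
    fixture_design(df[i, ])  # constructor performs all range checks
  }
  df
}

#' @rdname read_fixtures
#' @param row A single fixture row (data frame with the fixture columns).
#' @export
fixture_design <- function(row) {
  cell_means_design(row$m11, row$m12, row$m21, row$m22, sigma = row$sigma,
                    n_per_cell = row$n_per_cell, reliability = row$reliability)
}
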