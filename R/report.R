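# Planning reports: one document tying together the elicited prior, the
# shape/sector assignment, a PPV grid slice, the required power/alpha/N
# table and an optional simulator cross-check. Every numeric cell in a
# rendered report comes from an operation output recorded in the
# provenance block; display rounding happens only at render time.

plan_config_sections <- c("elicitation", "design", "ppv", "simulate")

#' Read a planning configuration file
#'
#' A planning config is one JSON or YAML document with sections
#' `elicitation` (the five questionnaire booleans), `design` (either a
#' `shape` name or the four cell means with `sigma`, `n_per_cell` and
#' optional `reliability`), `ppv` (`desired_ppv`, `alphas`, optional
#' `variant` and `r_threshold`) and an optional `simulate` section
#' (`n_studies`, optional `seed`). Unknown top-level keys or unknown keys
#' inside a section are rejected outright rather than ignored.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return The validated config as a named list.
#' @export
read_plan_config <- function(path) {
  if (!file.exists(path)) abort_validation("config", paste("no such file:", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) abort_validation("config", "must be a mapping/object")
  unknown <- setdiff(names(cfg), plan_config_sections)
  if (length(unknown) > 0) {
    abort_validation("config", paste("unknown section(s):",
                                     paste(unknown, collapse = ", ")))
  }
  allowed <- list(
    elicitation = c("mechanistic_plausible", "theoretical_plausible",
                    "indirect_population", "indirect_intervention",
                    "indirect_outcome", "combine_plausibility"),
    design = c("shape", "m11", "m12", "m21", "m22", "sigma", "n_per_cell",
               "reliability"),
    ppv = c("desired_ppv", "alphas", "variant", "r_threshold"),
    simulate = c("n_studies", "seed")
  )
  for (sec in intersect(names(cfg), names(allowed))) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad) > 0) {
      abort_validation(sec, paste("unknown key(s):", paste(bad, collapse = ", ")))
    }
  }
  for (sec in c("elicitation", "design", "ppv")) {
    if (is.null(cfg[[sec]])) abort_validation(sec, "section is required")
  }
  cfg
}

config_shape <- function(design_cfg) {
  if (!is.null(design_cfg$shape)) {
    return(match.arg(design_cfg$shape,
                     c("disordinal", "ordinal", "fully_attenuated")))
  }
  d <- cell_means_design(design_cfg$m11, design_cfg$m12, design_cfg$m21,
                         design_cfg$m22,
                         sigma = design_cfg$sigma %||% 1,
                         n_per_cell = design_cfg$n_per_cell %||% 2L,
                         reliability = design_cfg$reliability %||% 1)
  summarize_interaction(d)$shape
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a planning report
#'
#' Composes the full planning workflow: elicits the generic prior from the
#' questionnaire answers, determines the interaction shape (named directly
#' or derived from cell means), assigns the planning sector, slices the
#' PPV grid at the elicited R, builds the required power/N advice table,
#' and (optionally) runs a bernoulli-mode simulator cross-check at the
#' advice table's first feasible power. A provenance block records the
#' package version, seed, config hash and the operations invoked.
#'
#' @param config A config list as returned by [read_plan_config()].
#' @param seed Seed for the optional simulator section.
#' @return An object of class `planning_report`.
#' @seealso [render_report()]
#' @export
build_plan <- function(config, seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  el <- config$elicitation
  answers <- elicitation_answers(
    mechanistic_plausible = isTRUE(el$mechanistic_plausible),
    theoretical_plausible = isTRUE(el$theoretical_plausible),
    indirect_population = isTRUE(el$indirect_population),
    indirect_intervention = isTRUE(el$indirect_intervention),
    indirect_outcome = isTRUE(el$indirect_outcome)
  )
  generic <- elicit_r(answers, el$combine_plausibility %||% "or")
  shape <- config_shape(config$design)
  variant <- config$ppv$variant %||% "printed"
  sector <- classify_sector(shape, generic$value,
                            config$ppv$r_threshold %||% 0.25)
  alphas <- as.numeric(config$ppv$alphas %||% c(.05, .01))
  adv <- advise(sector, config$ppv$desired_ppv, alphas, variant)
  grid <- ppv_grid(R_values = generic$value, alpha_values = alphas,
                   variant = variant)
  ops <- c("elicit_r", "classify_sector", "advise", "ppv_grid")

  sim <- NULL
  feasible_rows <- which(adv$table$feasible & !is.na(adv$table$required_power))
  if (!is.null(config$simulate) && length(feasible_rows) > 0) {
    i <- feasible_rows[1]
    cfg <- field_config(
      n_studies = check_count(config$simulate$n_studies, "n_studies"),
      R = generic$value, alpha = adv$table$alpha[i], mode = "bernoulli",
      power = min(1, max(0, adv$table$required_power[i])),
      seed = config$simulate$seed %||% seed
    )
    sim <- simulate_field(cfg)
    ops <- c(ops, "simulate_field")
  }

  structure(
    list(
      answers = answers, generic_r = generic, shape = shape,
      sector = sector, advice = adv, ppv_slice = grid, simulator = sim,
      provenance = list(
        tool = "ppvplan",
        version = as.character(utils::packageVersion("ppvplan")),
        seed = seed,
        config_hash = hash_config(config),
        operations = ops
      )
    ),
    class = "planning_report"
  )
}

# md5 of the canonicalized (deparsed) config; base tools only
hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

report_as_list <- function(report) {
  list(
    elicitation = list(
      answers = unclass(report$answers),
      R = report$generic_r$value,
      rationale = report$generic_r$rationale
    ),
    shape = report$shape,
    sector = report$sector$sector,
    r_threshold = report$sector$r_threshold,
    desired_ppv = report$advice$desired_ppv,
    variant = report$advice$variant,
    advice = report$advice$table,
    ppv_slice = report$ppv_slice,
    simulator = if (!is.null(report$simulator)) unclass(report$simulator),
    provenance = report$provenance
  )
}

#' Render a planning report
#'
#' `"json"` is lossless: numbers are serialized at full double precision
#' and the output parses and re-renders byte-identically. `"markdown"`
#' applies the display conventions (PPVs as integer percentages, powers to
#' three decimals); an absent simulator section is simply omitted.
#'
#' @param report A [build_plan()] result.
#' @param format `"markdown"` or `"json"`.
#' @return A character scalar holding the document.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  stopifnot(inherits(report, "planning_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(report_as_list(report), dataframe = "rows",
                            auto_unbox = TRUE, digits = NA, null = "null",
                            pretty = TRUE))
  }
  adv <- report$advice$table
  lines <- c(
    "# Interaction planning report",
    "",
    sprintf("- Generic R: **%.2f** (%s)", report$generic_r$value,
            report$generic_r$rationale),
    sprintf("- Interaction shape: **%s**; planning sector: **%s**",
            report$shape, report$sector$sector),
    sprintf("- Desired PPV: **%s** (%s variant)",
            percent_label(report$advice$desired_ppv), report$advice$variant),
    "",
    "## Required power and sample size",
    "",
    "| alpha | required power | feasible | N total | note |",
    "|-------|----------------|----------|---------|------|"
  )
  for (i in seq_len(nrow(adv))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s |",
      format(adv$alpha[i]),
      if (is.na(adv$required_power[i])) "—"
        else sprintf("%.3f", adv$required_power[i]),
      if (adv$feasible[i]) "yes" else "no",
      if (is.na(adv$N_total[i])) "—" else adv$N_total[i],
      adv$note[i]))
  }
  lines <- c(lines, "", "## PPV at the elicited R", "",
             "| R | power | alpha | PPV |", "|---|-------|-------|-----|")
  g <- report$ppv_slice
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("| %g | %g | %g | %s |", g$R[i], g$power[i],
                              g$alpha[i], percent_label(g$ppv[i])))
  }
  if (!is.null(report$simulator)) {
    s <- report$simulator
    lines <- c(lines, "", "## Simulator cross-check", "", sprintf(
      "%d simulated studies (seed %d): empirical PPV %s, replication rate %s.",
      s$n_studies, s$seed,
      if (is.na(s$empirical_ppv)) "undefined" else percent_label(s$empirical_ppv),
      if (is.na(s$replication_rate)) "undefined"
        else percent_label(s$replication_rate)))
  }
  lines <- c(lines, "", "## Provenance", "", sprintf(
    "%s %s — seed %d, config %s, operations: %s.",
    report$provenance$tool, report$provenance$version,
    report$provenance$seed, report$provenance$config_hash,
    paste(report$provenance$operations, collapse = ", ")))
  paste(lines, collapse = "\n")
}

#' Generate cell-means fixtures covering all interaction shapes
#'
#' Emits `count` planning designs with randomized effect magnitudes, at
#' least one per shape class (disordinal, ordinal, fully attenuated,
#' null); shapes cycle so every class appears once per block of four.
#' Null fixtures have an interaction contrast of exactly 0 by
#' construction. Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param count Number of fixtures, >= 4.
#' @param path Optional CSV destination; when given, the fixture table is
#'   also written there.
#' @return The fixture data frame (see [read_fixtures()] for the schema).
#' @export
generate_fixtures <- function(seed = 1L, count = 8L, path = NULL) {
  seed <- check_count(seed, "seed", min = 0L)
  count <- check_count(count, "count", min = 1L)
  if (count < 4L) abort_validation("count", "must be >= 4 to cover all shapes")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  shapes <- rep(c("disordinal", "ordinal", "fully_attenuated", "null"),
                length.out = count)
  rows <- lapply(seq_len(count), function(i) {
    d <- stats::runif(1, 0.2, 0.8)          # largest simple effect
    base <- stats::runif(1, -0.5, 0.5)      # shared baseline mean
    s <- switch(shapes[i],
      disordinal = c(d, -stats::runif(1, 0.1, 1) * d),
      ordinal = c(d, stats::runif(1, 0.15, 0.85) * d),
      fully_attenuated = c(d, 0),
      null = c(d, d))
    data.frame(
      label = sprintf("%s_%02d", shapes[i], i),
      m11 = base + s[1], m12 = base, m21 = base + s[2], m22 = base,
      sigma = 1, n_per_cell = sample(c(25L, 50L, 100L), 1),
      reliability = 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}
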