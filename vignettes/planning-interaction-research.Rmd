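---
title: "Planning interaction research with the positive predictive value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning interaction research with the positive predictive value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppvplan)
```

## The problem

Interaction effects replicate worse than main effects, and two of the main
suspects are statistical: interaction tests are often badly underpowered
for the pattern of means actually being hypothesized, and many tested
interactions have a low pre-study probability of being true in the first
place. `ppvplan` treats both together through the positive predictive
value (PPV): the probability that a *significant* claim reflects a *true*
effect.

## The PPV model

For pre-study probability $R$ that the effect exists, power $1-\beta$ and
significance level $\alpha$, the package computes

$$\mathrm{PPV} = \frac{(1-\beta)\,R}{(1-\beta)\,R + \alpha}$$

as its default ("printed") variant — the form in which the quantity is
usually quoted, and the one that reproduces the familiar worked example
`compute_ppv(.25, .5, .01)` $= .125/.135 = 0.9259\ldots \to$ "93%". Read
strictly as probabilities, Bayes' theorem puts a factor $(1-R)$ on
$\alpha$; that "probability-consistent" variant is available behind an
explicit `variant` flag. The two forms answer subtly different readings of
$R$ (prior odds vs. prior probability). We default to the printed form to
match the planning literature, and we document — rather than hide — that a
simulated field in which false hypotheses are tested at rate $1-R$
realizes the probability-consistent value (see below). The probability-
consistent PPV strictly exceeds the printed one on $R \in (0,1]$, reaching
1 at $R=1$ where no false hypotheses exist.

Inverse solvers (`required_power()`, `required_alpha()`) use the closed
forms; round-trip identities hold to $10^{-10}$, and a solution outside
the parameter's domain is reported as infeasible together with the maximum
attainable PPV — never silently clamped.

## Pattern-of-means power for the 2×2 interaction

A balanced 2×2 between-participants design is specified by its four cell
means, common within-cell SD $\sigma$, and per-cell $n$ (`cell_means_design()`;
rows are the moderator, columns the focal factor — `transpose_design()`
swaps the roles). With standardized simple effects
$s_1 = (m_{11}-m_{12})/\sigma$ and $s_2 = (m_{21}-m_{22})/\sigma$, the
tested 1-df quantity is the interaction contrast $\Delta = s_1 - s_2$.
Shapes follow the standard taxonomy: *disordinal* (cross-over, $s_1 s_2 <
0$), *fully attenuated* (one simple effect zero), *ordinal* (same sign,
unequal magnitude — including partially attenuated patterns), *null*
($\Delta = 0$). Classification of exact planning inputs uses a zero
tolerance of $10^{-8}$ on the standardized scale; the `eps` argument
widens it for noisy empirical means.

For the balanced contrast $(+1,-1,-1,+1)$ the noncentrality is

$$\lambda = \frac{N\,\Delta^2\,\rho}{16},$$

where $\rho$ is the reliability of the dependent variable (classical test
theory: unreliability multiplies standardized effects by $\sqrt{\rho}$,
applied before the power computation; `reliability_sensitivity()` shows
the — substantial — effect of improving it). Power is the upper tail of a
noncentral $F(1, N-4, \lambda)$ beyond the central critical value, which
is exactly the 2×2 ANOVA interaction test. `required_n()` brackets the
minimal balanced $N$ with the normal approximation and then scans in steps
of 4, guaranteeing minimality.

### The calibrated reference effect

Published sample-size benchmarks for "typical" interactions inherit an
unprinted effect size. We calibrate it at run time:
`calibrate_reference_effect()` returns the $d^*$ for which a two-sided
two-sample $t$-test at $\alpha=.05$ reaches power .80 with exactly 256
participants ($d^* \approx 0.3515$, via `stats::power.t.test`; never
hard-coded). The shape templates anchored at $d^*$ are:

| shape | simple effects | contrast | required N (power .80, α=.05) |
|---|---|---|---|
| disordinal (cross-over) | $(+d^*, -d^*)$ | $2d^*$ | 256 |
| fully attenuated | $(d^*, 0)$ | $d^*$ | 1020 |
| partially attenuated | — | $\tfrac{3}{14}\cdot 2d^*$ | 5536 |

The cross-over line is forced by an exact identity: the interaction
noncentrality for $(+d,-d)$ at total $N$, $N(2d)^2/16 = Nd^2/4$, equals
the two-group noncentrality for $d$ at the same $N$ — so the cross-over
interaction is exactly as detectable as the main effect it crosses, and a
fully attenuated interaction (half the contrast) needs four times the
sample (`attenuated_vs_main_ratio()`, exactly 4 in the infinite-df limit,
3.85–4.0 at realistic sizes). The partially attenuated fraction 3/14 is a
reverse-engineered calibration: the literature says only "between one
fourth and one fifth" of the cross-over contrast, and 3/14 is the round
fraction in that interval consistent with the published benchmark near
5575; our exact noncentral-F search returns 1020 and 5536 where the
published figures are 1024 and 5575 — sub-percent differences attributable
to the approximation conventions of the original calculations, which are
not printed. At a *fixed largest simple effect* the disordinal contrast is
twice the ordinal one, so its noncentrality is four times larger and its
power in mid-power regimes roughly three times higher
(`compare_shapes_at_fixed_largest_simple()`).

## Eliciting R and the planning sectors

When no direct evidence exists, `elicit_r()` maps five booleans —
mechanistic plausibility, theoretical plausibility, and indirectness of
population / intervention / outcome — to a generic prior: .10 (implausible,
no indirect evidence), .25 (either plausibility or indirect evidence), .50
(both). Open choices we fixed: the two plausibility flags combine with OR
(the heuristic asks whether the hypothesis is plausible *on some* ground;
`combine_plausibility = "and"` tightens it), any one indirectness channel
counts as indirect evidence, and the rule table is applied literally —
evidence accompanied by active implausibility still yields .25.

`classify_sector()` crosses shape with prior: **A** disordinal/high-R
(best of both worlds), **B** ordinal-attenuated/high-R (worth doing,
needs real sample-size planning), **C** ordinal-attenuated/low-R (the
danger zone), **D** disordinal/low-R (risky but statistically cheap). The
R axis is continuous; the high/low cut defaults to .25, the middle
generic level, and is configurable. Both ordinal and fully attenuated
shapes occupy the hard row. `advise()` then solves the PPV identity for
the power each candidate $\alpha$ requires at the elicited R and converts
it to an N via the shape's $d^*$-anchored template; an infeasible
combination (required power > 1) is flagged and gets no N, and a required
power at or below $\alpha$ reports the minimal balanced design ($N=8$)
with a note.

## The field simulator

`simulate_field()` draws a literature: each of `n_studies` hypotheses is
true with probability R; originals and replications are tested at their
alpha levels, outcomes tallied as TP/FP/TN/FN. Bernoulli mode draws
significance directly from power/alpha — this is the model the PPV
algebra describes, and the empirical PPV converges to the
probability-consistent closed form (false positives arise at rate
$\alpha(1-R)$). Full-data mode instead simulates each study of a
`cell_means_design` from the normal model and runs the interaction F
test; replication success there additionally requires a contrast of the
same sign as the original (direction consistency is undefined in
bernoulli mode, where replication success is significance alone).

Numerical choices: full-data studies are drawn through the model's
sufficient statistics — four cell means $\sim N(\mu_{ij}, \sigma^2/n)$ and
a pooled SS $\sim \sigma^2\chi^2_{N-4}$ — whose joint law is identical to
raw per-participant draws but orders of magnitude cheaper; the same
machinery backs `simulate_interaction_power()`, the Monte-Carlo
cross-check of the analytic power (it never evaluates the noncentral-F
distribution function, so the two routes are independent). Randomness is
one seeded stream per simulation with a fixed vectorized draw order
(truth, then significance, then replication), making results bit-for-bit
reproducible and independent of any study iteration order; the caller's
RNG state is restored. A field that claims no positives reports an
undefined (NA) PPV, never 0. `expected_replication_rate()` is the convex
combination $\mathrm{PPV}\cdot p_{rep} + (1-\mathrm{PPV})\cdot
\alpha_{rep}$ — the precise sense in which fields with more true findings
replicate better.

What the simulator does *not* emulate: p-hacking, publication bias,
effect-size heterogeneity, unbalanced or within-participant designs.
Passing tests therefore show that the analytic formulas are internally
correct under the idealized model, not that real literatures behave this
way.

## Test problem sizes

The test suite checks Monte-Carlo agreement at sizes chosen to make a
3-standard-error criterion informative while keeping the default run
fast: field simulations of 2×10^4–2×10^5 studies, power cross-checks on
20 randomized nonnull designs at 10^5 replicates each, and convergence
checks over fields of 10^3, 10^4 and 10^5 studies on a fixed seed
schedule. All seeds are fixed in code.

## A worked planning session

```{r worked}
answers <- elicitation_answers(
  mechanistic_plausible = FALSE, theoretical_plausible = TRUE,
  indirect_population = FALSE, indirect_intervention = FALSE,
  indirect_outcome = FALSE)
generic <- elicit_r(answers)
generic

sector <- classify_sector("fully_attenuated", generic$value)
sector

advise(sector, desired_ppv = .9, alpha_options = c(.05, .01))
```

## Known limitations

Only balanced 2×2 between-participants designs with one continuous
outcome are supported; continuous moderators, unbalanced cells, and
within or mixed designs are out of scope, as is any estimation of R from
published literature (p-curve methods and the like). The generic R levels
are orientation values by construction, not estimates of a field's real
base rate.
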