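---
title: "Quadrant-arena chemotaxis analysis: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-arena chemotaxis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormarena)
```

## The assay and its statistics

A population of more than 100 young-adult *C. elegans* is released at the
centre of a rectangular arena roughly 80 mm long, with a volatile odorant
dissolved in vehicle (e.g. ethanol) spotted at one end and vehicle alone at
the other. After about an hour the worms are counted in the four equal
quadrants along the long axis, `q1` (vehicle end) to `q4` (odorant end).
Because a worm is ~1 mm long and must travel ~20 mm from the origin to reach
an extreme quadrant, transient exploration does not masquerade as a
response. No paralytic or trap is used: the counts are a snapshot of freely
moving animals.

Three per-arena statistics carry all downstream inference, with
$p_i = q_i / n$ the quadrant proportions:

* **dispersal** $= -\sum_{i=1}^{4} p_i \log_2 p_i$ — base-2 Shannon entropy
  of occupancy. 2 bits means uniform spread, ~1 bit means the population
  stayed in the two central quadrants (locomotion defect or attraction to
  the origin), ~0 means accumulation in a single quadrant (an unknown
  gradient inside the arena);
* **response ratio** $= (q_1 + q_4)/n$ — the fraction of worms committed to
  either extreme, regardless of direction;
* **chemotaxis index** $= (q_4 - q_1)/(q_4 + q_1)$ — +1 is pure attraction,
  −1 pure aversion; undefined when both extremes are empty.

The three are deliberately redundant-looking but are not: an index of 0.8
can come from 10 committed worms out of 100 or from 50, and only the
response ratio tells these apart; only dispersal (measured on paired
no-odorant plates) certifies that the worms could move at all.

Replicate summaries use the median as the headline statistic, a
t-distribution confidence interval on the mean (replicate counts are small,
typically 3 populations per condition), Student's pooled-variance unpaired
t-test (a Welch switch is provided; the classical reading of "unpaired
t-test" is the pooled one), and Cohen's
$d = (\bar{x}_T - \bar{x}_C)/\sqrt{(s_T^2 + s_C^2)/2}$ with sample
standard deviations. Note the equal-weight average of the two variances:
this is intentionally *not* the pooled-by-degrees-of-freedom estimator, and
the two differ whenever group sizes differ.

## Orientation canonicalization and the external-gradient control

Arenas are run in two sets rotated 180° in the laboratory frame, so a true
odorant response moves worms in opposite physical directions in the two
sets. Files store counts physically, left-to-right; `canonicalize()` maps
orientation A identically and reverses orientation B, after which indices
from both sets estimate the same quantity. A laboratory-frame gradient
(temperature, light, a stray odour) instead pushes worms the *same*
physical way in both sets, which canonicalization converts into a
systematic difference between the two orientations' indices.
`orientation_consistency()` tests exactly that difference; a significant
result flags an external gradient and explains inflated between-arena
variance and shrunken effect sizes. In the degenerate case where both
orientations are internally constant but disagree (easy to hit with
simulated saturated responses), the check reports a definitive flag
(`t = Inf`, `p = 0`) instead of failing.

## Preconditions and the decision rubric

A verdict is only issued when (i) every plate carried more than 100 worms
(strict threshold `min_worms = 101`, configurable) and (ii) the paired
no-odorant controls dispersed freely (dispersal at or above
`dispersal_high_min`). Failing controls are classified by nearest anchor
with boundaries at 0.5 and 1.5 bits — conventions, since the ~2/~1/~0
regimes have no published tolerance.

The rubric itself is a total lookup over the $2^3$ combinations of
high/low dispersal, response ratio, and |index|, with the index's sign
resolving "attraction" versus "aversion". Two choices deserve record:

* **Which dispersal feeds the rubric.** The dispersal level is classified
  from the median over the *no-odorant control* arenas, not the chemotaxis
  arenas. A strongly responding population piles into one quadrant and has
  near-zero entropy on the chemotaxis plate — that is signal, not a
  locomotion problem; free dispersal is only observable without an odorant,
  and the rubric's own row wording ("on dispersal plates") refers to the
  control measurement. Response-ratio and index levels use medians over the
  chemotaxis arenas.
* **Cut-off defaults.** 1.8 bits, 0.4, and |CI| 0.5 are conventions chosen
  so the canonical regimes classify correctly (controls near 2 bits are
  high; worked response ratios 0.1/0.5 split low/high; clear indices of
  magnitude 0.8–0.99 are high). The rubric's published form explicitly
  delegates cut-offs to the researcher; all are overridable via
  `chemo_thresholds()` or a plain-text config file.

Within the decision chart, low-dispersal rubric rows are unreachable —
failing controls already halt at the precondition. They remain available
through `infer_verdict()` because the rubric is meaningful for post-hoc
reading of archived or third-party data.

## What the simulator emulates — and what it does not

`simulate_arena()` is an agent-based biased random walk: worms start at the
arena centre with ~1 mm seeded jitter, and each 1 s step turns the heading
by Gaussian noise (`turn_sd`, default 0.5 rad) plus a deterministic
reorientation towards the locally preferred direction, then advances
`speed * dt` (0.15 mm/s default) with reflective walls. The reorientation
is klinotaxis-style — bias acts on heading, not as an added velocity — so
crawl speed and chemotactic strength are independently controllable. The
preferred direction sums up to three influences: the odorant gradient
(weight `bias` in [−1, 1]), an optional laboratory-frame drift used to
exercise the orientation control, and, in `origin_attraction` mode, a pull
towards the centre. Modes map onto the regimes the analysis must
distinguish: `normal` (no field), `locomotion_defect` (speed forced to 0,
so worms provably never leave the central quadrants and dispersal is ≤ 1),
`origin_attraction` (~1), `unknown_gradient` (a point source in one seeded
random quadrant, ~0), and `chemotaxis` (a linear gradient along the long
axis).

Geometry is the one externally constrained part: 80 mm × 10 mm, four 20 mm
quadrants, 3600 s. Locomotion parameters are plausible-scale choices
verified once by Monte Carlo: at the defaults, `normal` mode yields
dispersal 1.91–2.0 across seeds, comfortably in the ~2 regime, so no
recalibration away from the stated defaults was needed. Worm–worm
interaction, food, odorant depletion and diffusion dynamics, and real
sensory transduction are all omitted. Consequently a green simulator test
establishes that the *pipeline* recovers planted structure (sign and
ordering of bias, failing controls, injected external gradients) — it does
not establish anything about real worm physiology, and the package makes no
attempt to reproduce published per-odorant medians from living animals.
One visible artefact of the model's simplicity: any appreciable bias
saturates the index near ±1 over a full hour, because an 80 mm arena is
short relative to biased displacement. Monotonicity checks therefore allow
ties at the extremes.

Reproducibility: one seed per experiment; per-arena substreams are drawn
deterministically from it, so arenas are independent but the whole
experiment is bit-reproducible.

## Numerical conventions

* $0 \log_2 0 = 0$ in the entropy; a single-quadrant arena gives exactly 0
  bits (clamped against `-0`).
* An undefined chemotaxis index (`q1 + q4 = 0`) is `NA_real_`, an in-band
  value treated as non-interpretable downstream — not an error, because
  dispersal-only arenas legitimately have empty extremes.
* Zero-variance groups: identical groups give $d = 0$ and $t = 0, p = 1$;
  zero variance with differing means is an explicit error at the metric
  level (and a definitive flag inside the orientation check, see above).
* Level thresholds are inclusive (`>=`), and boundary worms are assumed
  assigned to exactly one quadrant upstream — counts are taken as given.

## Worked example

```{r example}
arenas <- read_counts_table(system.file("extdata", "methods_examples.csv",
                                        package = "wormarena"))
arena_metrics(arenas)[, c("plate_id", "n_total", "dispersal",
                          "response_ratio", "chemotaxis_index")]
```

Both configurations share index 0.8, yet their response ratios (0.1 versus
0.5) tell opposite stories about how many worms actually responded — the
reason all three metrics are required for inference.

```{r pipeline}
set.seed(1)
exp <- generate_experiment(
  simulation_config(mode = "chemotaxis", bias = 0.7, seed = 7),
  n_arenas_per_orientation = 2)
run_decision_chart(exp)
```

## Known limitations

* The simulator's behavioural realism is limited to the emergent regimes;
  absolute index magnitudes saturate and should not be compared to bench
  values.
* The rubric consumes per-arena indices then takes medians (replicate-level
  reading); pooling counts across arenas before computing one index is
  possible by summing `canonical_counts()` rows but is not the default.
* Age matching ("young adults") is metadata the package trusts; it is not
  computable from counts.
* No multiple-testing correction across odorants, matching the assay's
  reporting of raw unpaired t-tests.
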