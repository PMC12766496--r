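---
title: "Risk modelling in nmrisk: scales, barriers, fault trees and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk modelling in nmrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrisk)
```

## The model

`nmrisk` treats a clinical process as a map of steps, each with declared
functions; negating a function yields a process failure. One *failure
chain* is a cause, a mode and an effect, rated on three ten-step scales:

* **Severity (S)** — qualitative 1..10 grading of the worst credible
  consequence; it has no probabilistic meaning and is never changed by
  barriers.
* **Occurrence (O)** — mapped to a per-procedure probability
  $P_{occ}(O)$ by a monotone ten-bin table.
* **Detectability (D)** — mapped to the probability that an occurred
  failure escapes detection, $P_{miss}(D) = 1 - P_{det}(D)$, also monotone
  in D. Note the convention: *high* D means *poor* detectability.

The criticality surrogate is $RPN = S \cdot O \cdot D \in [1, 1000]$.

Safeguards enter as *barriers* with a miss probability $p_{miss} \in
(0,1]$, assumed mutually independent. Proactive barriers prevent
occurrence; reactive barriers catch an occurred failure before harm:

$$P_{occ} = P_{occ,i} \prod_{\text{proactive}} p_{miss}, \qquad
  (1-P_{det}) = P_{miss,i} \prod_{\text{reactive}} p_{miss}.$$

Residual scores are recovered by the inverse table lookup and give the
residual $RPN = S \cdot O \cdot D$ with the updated scores. The quantity
that ultimately matters for patient safety is the rate at which a failure
occurs *and* goes undetected,

$$N_{e\!f\!f} = P_{occ} \cdot (1 - P_{det}),$$

which multiplied by the annual patient throughput becomes events per year.

Converting the register to fault trees goes through the failure modes and
effects summary (FMES): all failure modes sharing one effect are grouped,
and the group becomes one tree whose top event is the effect. Within a
branch the cause is the basic event, the mode the fault event, and each
barrier an AND-ed "barrier failed" leaf carrying its $p_{miss}$ — so the
branch rate is structurally the product above. Branches join under an OR
gate; for the rare events of interest the top-event rate is the sum
$\sum_j N_{e\!f\!f,j}$ (see *Numerical choices* for the error this
incurs). A failure mode referenced by several top events is shared by
reference across their trees, not duplicated as independent data.

## Rating tables: defaults and overrides

Only two points of the score↔probability tables are treated as normative
anchors: occurrence score 1 at 0.01 % and detectability score 2 at 0.2 %.
The shipped defaults interpolate the remaining bins on a roughly
logarithmic grid and put score 10 at 100 % (certain occurrence / certain
non-detection):

```{r}
rs <- default_rating_system()
rs
```

Departments calibrate these tables to their own incident statistics;
every table is overridable via `rating_scale()`, and a frequency-mode
scale can be filled from failures-per-year counts with
`frequency_to_probability()`. The inverse mapping `score_from_prob()`
returns the *smallest* score whose bin probability is at least the given
probability. This ceiling convention is deliberately conservative: the
displayed residual score never understates the residual probability, a
probability below bin 1 maps to score 1 (the scale has no zero), and ties
resolve to the smaller score so that exactly 0.2 % gives D = 2.

Initial probabilities normally come from the scores; when an explicit
probability is supplied (as in well-characterized chains such as the
vial-exchange scenario), it is authoritative and the displayed initial
score is derived from it by the same inverse mapping.

## Worked chain

```{r}
prj <- load_template("nm_therapeutic")
vial <- prj$failure_modes[[3]]
assess(vial, prj$rating_system, prj$effect_vocab)
```

A 0.01 % initial occurrence with a 1 % proactive miss gives a residual
occurrence of 10^-6^ (still score 1); an initially undetectable exchange
($P_{miss,i}=1$) checked by a barrier that fails 0.2 % of the time gives a
residual non-detection of 0.002 (score 2); their product is the branch
rate 2×10^-9^ per procedure.

## Multi-rater consensus and portfolio weighting

Different professionals score the same event differently; the consensus
per dimension is the weighted arithmetic mean of the raters' scores,
rounded half-up and clamped to 1..10. Half-up rounding (rather than R's
round-half-to-even) is chosen because it is reproducible by hand and never
rounds a borderline score down on one scale and up on another. Role
weights default to 1 and are configurable.

For the overarching ranking across workflows the weighting scheme is a
genuinely open design choice — no single formula is canonical. The default
weights each workflow by its annual patient throughput (criticality scales
with exposure opportunity), normalized to sum 1; uniform weights,
small/medium/large size-class multipliers and fully user-specified tables
are provided as alternatives, and the scheme used is recorded in the
output metadata. The choice matters: a therapy RPN of 324 in a
400-patients/year service outranks a diagnostic RPN of 20 in a
14000-patients/year service under uniform weights but not under raw
throughput weights. Users comparing departments should state the scheme
alongside the ranking.

The questionnaire ingester maps the stated "chance of prevention" to a
proactive barrier with $p_{miss} = 1 - \text{chance}$ — the only slot of
the model that reduces occurrence — and resolves cause-class ties to
`procedural`, the most common class for process failures.

## Templates and the synthetic questionnaire generator

The packaged templates are *synthetic fixtures*: their process maps follow
the standard diagnostic workflow (admittance, activity preparation,
history, administration, acquisition, processing, discharge/reporting —
seven steps, with discharge and reporting merged so the diagnostic map has
the conventional seven entries) and the eight-step therapeutic analogue.
Their registers are authored to realistic envelopes — diagnostic:
occurrence 1–2, detectability 1–4, RPN spanning 1..20; therapeutic: RPN
spanning 36..324 with the two fully-scored administration chains (RPN 140
and 60, both feeding the temporary-adverse-effect top event) and the
radioembolization vial-exchange chain. They exercise every code path
(overrides, both barrier kinds, shared effects) but are not survey data,
and passing tests against them demonstrates the arithmetic and the
conversions, not the risk profile of any real department.

The questionnaire generator draws scores uniformly within per-scenario
ranges (diagnostic: S 1..10, O 1..2, D 1..4; therapeutic: S 1..10, O 1..7,
D 1..10 — the therapeutic occurrence range spans both the extreme and the
mid-range values seen in scored chains), a chance
of prevention uniform in [0, 0.99), and cause classes uniformly over the
five-class taxonomy, cycling raters over the six professional roles. Real
responses are not uniform — they cluster by profession and event — so the
generator validates plumbing and determinism (byte-identical output for
equal seeds), not rater behaviour.

## Numerical choices

* **OR-gate aggregation.** The top-event rate is the plain sum of branch
  rates, as the rare-event approximation prescribes; the exact
  $1-\prod_j(1-N_{e\!f\!f,j})$ is available via `exact = TRUE`. For all
  branch rates below 10^-3^ the relative discrepancy is below 10^-3^
  (property-tested); if the sum ever exceeds 1 it is clamped with a
  warning.
* **Severity filtering** of tree branches uses strict `>` ("exceeding" a
  threshold), with `inclusive = TRUE` available.
* **Persistence.** Project files carry every probability twice: a percent
  display value and an exact `%.17g` decimal string; the exact string wins
  on load, so save→load round-trips doubles bit for bit. Percent is purely
  an interface convention; the core stores fractions in (0, 1].
* **Monte-Carlo oracle.** `simulate_branch()` draws through the mechanism
  stage by stage — occurrence, each proactive barrier, initial detection,
  each reactive barrier — restricting the uniform draws to trials still
  alive at each stage (statistically identical to a per-trial loop and
  never forming the analytic product). Trees are combined per trial as an
  exact OR over branch index sets. Intervals are ±3 standard errors,
  replaced by an exact Clopper–Pearson interval at the same nominal level
  when fewer than 5 harms are observed (ultra-rare branches). One seeded
  generator per call; the caller's RNG state is restored.
* **Calibration study sizes.** `mc_coverage_study()` draws trees of up to
  6 branches with up to 3 barriers of each kind, branch occurrence in
  10^-3^..10^-1.7^ and initial miss in 10^-2.5^..10^-1.2^ — inside the
  rare-event regime the summation assumes, while keeping expected counts
  at 10^6^ trials informative. The shipped checks run 200 configurations
  at 10^6^ trials each; nominal interval coverage is ≈ 99.7 %, and the
  acceptance threshold of 95 % leaves headroom for the summation error.

## Known limitations

* Barriers are assumed independent; common-cause failures (one event
  defeating several barriers) are not modelled.
* No minimal cut sets or importance measures — the trees here are
  register-shaped (one AND level under one OR gate), not general Boolean
  structures.
* RPN itself is an ordinal surrogate with well-known caveats (equal
  products from very different S/O/D triples); the severity-first
  tie-break mitigates but does not remove this.
* The portfolio weighting scheme is a modelling choice, not an estimated
  quantity; conclusions that depend on it should be checked under at least
  the uniform alternative.
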