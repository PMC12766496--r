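# nmrisk

Combined FMEA and fault-tree risk analysis for nuclear-medicine workflows.

Accidental or unintended exposures in nuclear medicine — administering a
radiopharmaceutical to the wrong patient, with the wrong activity, in the
wrong order, or to a pregnant patient — are rare but can be severe,
especially in therapy. `nmrisk` is a toolkit for the medical physicists,
physicians, radiopharmacists, technologists and quality managers who run
proactive risk assessments of these workflows. It implements, in one
consistent data model:

* **FMEA** — failure chains (cause → mode → effect) rated on ten-step
  severity (S), occurrence (O) and detectability (D) scales, ranked by the
  risk priority number RPN = S·O·D;
* **barrier modelling** — a proactive barrier reduces the occurrence
  probability and a reactive barrier the non-detection probability, each
  multiplying in its miss probability *p*<sub>miss</sub> (barriers are
  assumed independent):

  P<sub>occ</sub> = P<sub>occ,i</sub> · ∏<sub>proactive</sub> p<sub>miss</sub>  and  (1 − P<sub>det</sub>) = P<sub>miss,i</sub> · ∏<sub>reactive</sub> p<sub>miss</sub>,

  with residual scores recovered through the monotone score↔probability
  tables and an updated RPN = S·O·D;
* **FMES → FTA conversion** — failure modes sharing an effect are grouped
  (failure modes and effects summary) and become the branches of one fault
  tree: the cause is the basic event, the mode the fault event, the effect
  the top event; barriers are AND-ed "barrier failed" leaves, branches join
  under an OR gate. Each branch contributes the undetected adverse-event
  rate N<sub>eff,j</sub> = P<sub>occ,j</sub> · (1 − P<sub>det,j</sub>); the
  top-event rate is the rare-event sum Σ N<sub>eff,j</sub>, convertible to
  events/year by the patient throughput;
* **multi-rater consensus** — weighted means of professional ratings,
  rounded half-up; **portfolio ranking** — a throughput-weighted (or
  uniform, or custom) overarching ranking of failure modes across
  departments of different sizes;
* **templates and synthesis** — packaged diagnostic and therapeutic
  nuclear-medicine process templates (synthetic registers constrained to
  realistic score envelopes) and a seeded generator of multi-professional
  questionnaire responses;
* **a Monte-Carlo oracle** — a trial-by-trial simulator of the barrier
  mechanism used to validate the analytic rates independently.

## Worked example

The highest-risk therapeutic scenario shipped with the package is ⁹⁰Y
microsphere radioembolization with two vials to be injected in a prescribed
order. Vial labelling keeps the initial occurrence probability at 0.01 %;
without any check, an exchange goes undetected (P<sub>miss,i</sub> = 1).

```r
library(nmrisk)

prj <- load_template("nm_therapeutic")
reg <- assess_all(prj$failure_modes, prj$rating_system, prj$effect_vocab)

reg[reg$id %in% c("t01", "t02"), c("id", "S", "O_in", "D_in", "RPN_in")]
#>    id S O_in D_in RPN_in
#> 1 t01 5    4    7    140
#> 2 t02 6    2    5     60

vial <- prj$failure_modes[[3]]          # the vial-exchange chain, id "t03"
assess(vial, prj$rating_system, prj$effect_vocab)
#> <assessment t03> S=10 O=1->1 D=10->2 RPN 100 -> 20, N_eff = 2e-09
```

Adding the proactive "box labelling" prevention (p_miss = 1 %) lowers the
occurrence probability from 0.01 % to 0.0001 % (occurrence stays at score
1), and the reactive "checking box labelling" barrier lowers the miss
probability to 0.2 % (detectability improves from 10 to 2), so the chain's
undetected adverse-event rate is 10⁻⁶ × 0.002 = 2×10⁻⁹ per procedure — about
2×10⁻⁷ events/year in a small 100-patients/year therapy service
(`events_per_year(2e-9, 100)`).

The same register viewed as a fault tree:

```r
tree <- build_fault_tree(prj$failure_modes, prj$effect_vocab,
                         "temporary_adverse_effect")
top_event_rate(tree, reg)
#> [1] 3.3e-05
cat(tree_to_dot(tree))   # Graphviz DOT, one branch per failure mode
```

A command-line interface wraps the same functions; after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","nmrisk",package="nmrisk"))')" \
  demo --template nm_therapeutic -o project.json
# then: validate / assess / fta / rank / simulate / synth-questionnaire / ingest
```

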