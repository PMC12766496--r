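# Shared fixtures, built in code.

default_rs <- default_rating_system()

tiny_vocab <- function() {
  effect_vocabulary(data.frame(
    effect_id = c("harm", "rework"),
    label = c("Patient harm", "Procedure repeated"),
    severity_default = c(9L, 3L)))
}

# The 90Y vial-exchange chain: explicit initial probabilities, one
# labelling prevention (proactive) and one label-check barrier (reactive).
vial_exchange_fm <- function() {
  failure_mode(
    id = "vx", step_ref = "s1", cause = "two vials prepared",
    cause_class = "procedural", mode = "vials administered in wrong order",
    effect_id = "harm", severity = 10, occurrence_initial = 1,
    detectability_initial = 10, p_occ_initial = 1e-4, p_miss_initial = 1,
    barriers = list(barrier("Box labelling", "proactive", 0.01),
                    barrier("Checking box labelling", "reactive", 0.002)))
}

simple_fm <- function(id = "fm1", S = 5, O = 4, D = 7, effect = "harm",
                      barriers = list()) {
  failure_mode(id, "s1", paste0("cause of ", id), "organizational",
               paste0("mode of ", id), effect, S, O, D, barriers = barriers)
}

# Random failure mode for property tests; assumes the RNG is seeded by the
# caller.
random_fm <- function(id, effect = "harm", max_barriers = 3) {
  n_pro <- sample(0:max_barriers, 1)
  n_rea <- sample(0:max_barriers, 1)
  bars <- c(
    lapply(seq_len(n_pro), function(k)
      barrier(sprintf("p%d", k), "proactive", runif(1, 0.05, 1))),
    lapply(seq_len(n_rea), function(k)
      barrier(sprintf("r%d", k), "reactive", runif(1, 0.05, 1))))
  failure_mode(id, "s1", "random cause", sample(c(
    "organizational", "procedural", "technical", "training",
    "informatic_technology"), 1), "random mode", effect,
    severity = sample(1:10, 1), occurrence_initial = sample(1:10, 1),
    detectability_initial = sample(1:10, 1), barriers = bars)
}

template_fm <- function(prj, id) {
  prj$failure_modes[[which(vapply(prj$failure_modes, `[[`, character(1),
                                  "id") == id)]]
}
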