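QUESTIONNAIRE_ROLES <- c("physician", "nurse", "administrative",
                         "technician", "radiopharmacist", "medical physicist")

QUESTIONNAIRE_COLUMNS <- c("center", "patients_per_year", "professional",
                           "scenario", "hypothesized_event",
                           "expected_cases_per_year", "severity",
                           "occurrence", "chance_of_prevention",
                           "detectability", "cause_class")

#' Default questionnaire score ranges per scenario
#'
#' Diagnostic responses span severity 1..10, occurrence 1..2 and
#' detectability 1..4; therapeutic responses span severity 1..10,
#' occurrence 1..7 and detectability 1..10. Override any entry by passing a
#' modified copy to [generate_questionnaire()].
#'
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @return Named list with integer vectors `S`, `O`, `D` of admissible
#'   scores.
#' @export
default_score_ranges <- function(scenario = c("diagnostic", "therapeutic")) {
  scenario <- match.arg(scenario)
  if (scenario == "diagnostic") {
    list(S = 1:10, O = 1:2, D = 1:4)
  } else {
    list(S = 1:10, O = 1:7, D = 1:10)
  }
}

#' Generate a synthetic multi-rater risk questionnaire
#'
#' Emulates the records of a multi-professional risk survey: every rater
#' (cycling over the six professional roles: physician, nurse,
#' administrative, technician, radiopharmacist, medical physicist) scores
#' every hypothesized event, drawing severity, occurrence and detectability
#' uniformly within the configured ranges, a chance of prevention uniform in
#' [0, 0.99], a cause class uniformly over the five-class taxonomy, and an
#' expected yearly case count consistent with the occurrence score and the
#' center throughput. Output is reproducible for a fixed seed.
#'
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @param n_raters,n_events positive integers.
#' @param score_ranges list with integer vectors `S`, `O`, `D`; defaults to
#'   [default_score_ranges()].
#' @param seed integer RNG seed.
#' @param center center label.
#' @param patients_per_year center throughput recorded on every row.
#' @return Data frame with one row per (rater, event) pair and the columns
#'   of the questionnaire schema.
#' @export
#' @examples
#' q <- generate_questionnaire("diagnostic", n_raters = 6, n_events = 13,
#'                             seed = 7)
#' nrow(q)  # 78
generate_questionnaire <- function(scenario = c("diagnostic", "therapeutic"),
                                   n_raters, n_events, score_ranges = NULL,
                                   seed = 1L, center = "synthetic center",
                                   patients_per_year = NULL) {
  scenario <- match.arg(scenario)
  if (!is_scalar_number(n_raters) || n_raters < 1 ||
      !is_scalar_number(n_events) || n_events < 1) {
    stop("n_raters and n_events must be positive integers", call. = FALSE)
  }
  ranges <- score_ranges %||% default_score_ranges(scenario)
  for (d in c("S", "O", "D")) {
    r <- ranges[[d]]
    if (is.null(r) || length(r) == 0L || any(r < 1 | r > 10)) {
      stop(sprintf("score range for '%s' must be a non-empty subset of 1..10", d),
           call. = FALSE)
    }
  }
  patients_per_year <- patients_per_year %||%
    if (scenario == "diagnostic") 1300L else 400L

  with_local_seed(seed, {
    n <- n_raters * n_events
    event <- rep(sprintf("event_%02d", seq_len(n_events)), each = n_raters)
    role <- rep(QUESTIONNAIRE_ROLES[
      (seq_len(n_raters) - 1L) %% length(QUESTIONNAIRE_ROLES) + 1L],
      times = n_events)
    draw <- function(r) r[sample.int(length(r), n, replace = TRUE)]
    O <- draw(ranges$O)
    occ_prob <- prob_from_score(default_rating_system()$occurrence, 1L)
    data.frame(
      center = center,
      patients_per_year = as.integer(patients_per_year),
      professional = role,
      scenario = scenario,
      hypothesized_event = event,
      expected_cases_per_year = round(
        patients_per_year *
          vapply(O, function(o)
            prob_from_score(default_rating_system()$occurrence, o),
            numeric(1)), 3),
      severity = draw(ranges$S),
      occurrence = O,
      chance_of_prevention = round(stats::runif(n, 0, 0.99), 3),
      detectability = draw(ranges$D),
      cause_class = CAUSE_CLASSES[sample.int(length(CAUSE_CLASSES), n,
                                             replace = TRUE)]
    )
  })
}

#' Ingest questionnaire records into scored failure modes
#'
#' Groups records by hypothesized event and, per event: takes the weighted
#' consensus of the raters' S/O/D scores (role weights default to 1), turns
#' the mean stated chance of prevention into a proactive barrier with
#' `p_miss = 1 - chance` (the only slot of the model that reduces
#' occurrence), and assigns the majority cause class (ties resolved to
#' `"procedural"`). All records must share one scenario.
#'
#' @param records a questionnaire data frame (schema of
#'   [generate_questionnaire()]).
#' @param role_weights optional named numeric vector of per-role weights.
#' @return A [risk_project()] whose effect vocabulary and failure modes are
#'   derived from the hypothesized events (one single-step process map).
#' @export
ingest_questionnaire <- function(records, role_weights = NULL) {
  missing <- setdiff(QUESTIONNAIRE_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("questionnaire is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scen <- unique(records$scenario)
  if (length(scen) != 1L) {
    stop("questionnaire records mix scenarios; ingest one scenario at a time",
         call. = FALSE)
  }
  if (any(records$chance_of_prevention < 0 | records$chance_of_prevention >= 1)) {
    stop("chance_of_prevention must lie in [0, 1)", call. = FALSE)
  }
  events <- unique(records$hypothesized_event)

  vocab <- effect_vocabulary(data.frame(
    effect_id = slugify(events), label = events,
    severity_default = vapply(events, function(e) {
      as.integer(round_half_up(mean(
        records$severity[records$hypothesized_event == e])))
    }, integer(1))
  ))

  step <- process_step("q1", "Questionnaire-derived process", 1L,
                       "Deliver the assessed procedure safely", scen)

  fms <- lapply(seq_along(events), function(i) {
    sub <- records[records$hypothesized_event == events[i], , drop = FALSE]
    w <- if (is.null(role_weights)) rep(1, nrow(sub))
         else unname(role_weights[sub$professional]) %||% rep(1, nrow(sub))
    w[is.na(w)] <- 1
    cons <- consensus_scores(data.frame(S = sub$severity, O = sub$occurrence,
                                        D = sub$detectability, weight = w))
    chance <- stats::weighted.mean(sub$chance_of_prevention, w)
    bars <- if (chance > 0) {
      list(barrier("Stated prevention", "proactive", p_miss = 1 - chance,
                   description = "Aggregated chance of prevention from raters"))
    } else list()
    tab <- sort(table(sub$cause_class), decreasing = TRUE)
    top <- tab[tab == max(tab)]
    cclass <- if (length(top) > 1L) "procedural" else names(top)[1]
    failure_mode(
      id = sprintf("q%02d", i), step_ref = "q1",
      cause = sprintf("Hypothesized: %s", events[i]), cause_class = cclass,
      mode = events[i], effect_id = slugify(events[i]),
      severity = cons$S, occurrence_initial = cons$O,
      detectability_initial = cons$D, barriers = bars
    )
  })

  workflows <- list(workflow_context(
    "survey", sprintf("%s service (questionnaire)", scen), scen,
    max(records$patients_per_year)))

  risk_project(name = sprintf("questionnaire_%s", scen), scenario = scen,
               rating_system = default_rating_system(), process_map = list(step),
               effect_vocab = vocab, failure_modes = fms,
               workflows = workflows, metadata = list(source = "questionnaire"))
}

#' Write / read questionnaire CSV
#'
#' Fixed-header CSV matching the questionnaire schema.
#'
#' @param records questionnaire data frame.
#' @param path file path.
#' @return `read_questionnaire` returns the data frame;
#'   `write_questionnaire` returns `path` invisibly.
#' @export
write_questionnaire <- function(records, path) {
  utils::write.csv(records[, QUESTIONNAIRE_COLUMNS, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_questionnaire
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(QUESTIONNAIRE_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("questionnaire CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}
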