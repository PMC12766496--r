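#' Process step of a workflow map
#'
#' Each step carries the functions it is meant to fulfil; process failures
#' are deduced by negating these functions, which is why `functions` must be
#' non-empty.
#'
#' @param step_id identifier.
#' @param name step name.
#' @param order integer position in the map (unique within a map).
#' @param functions non-empty character vector of step functions.
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @return An object of class `process_step`.
#' @export
process_step <- function(step_id, name, order, functions,
                         scenario = c("diagnostic", "therapeutic")) {
  scenario <- match.arg(scenario)
  functions <- as.character(functions)
  if (length(functions) == 0L || any(!nzchar(trimws(functions)))) {
    stop(sprintf("step '%s' must declare at least one non-empty function",
                 step_id), call. = FALSE)
  }
  structure(
    list(step_id = as.character(step_id), name = as.character(name),
         order = as.integer(order), functions = functions,
         scenario = scenario),
    class = "process_step"
  )
}

#' Load a packaged nuclear-medicine risk-assessment template
#'
#' Two synthetic templates ship with the package: `"nm_diagnostic"` (7
#' process steps, 13 failure modes, occurrence 1-2, detectability 1-4, RPN
#' 1..20) and `"nm_therapeutic"` (8 steps, 20 failure modes, RPN 36..324,
#' including the two fully-scored administration chains with initial RPNs
#' 140 and 60 and the 90Y radioembolization vial-exchange chain with its
#' labelling prevention and box-labelling check barrier). The register
#' contents are fixtures authored for this package — constrained to
#' realistic count and score envelopes, not survey data.
#'
#' @param name `"nm_diagnostic"` or `"nm_therapeutic"`.
#' @return A [risk_project()].
#' @export
#' @examples
#' prj <- load_template("nm_therapeutic")
#' length(prj$failure_modes)  # 20
load_template <- function(name = c("nm_diagnostic", "nm_therapeutic")) {
  name <- match.arg(name)
  path <- system.file("extdata", "templates", paste0(name, ".yaml"),
                      package = "nmrisk", mustWork = TRUE)
  parse_project_document(yaml::read_yaml(path))
}

# Turn a parsed project document (from a template or a saved project file)
# into a risk_project. Probabilities in files are percent when the document
# carries *_percent fields, or exact decimal strings in saved projects.
parse_project_document <- function(doc) {
  required <- c("name", "scenario", "steps", "effects", "failure_modes")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0L) {
    stop(sprintf("project document is missing required field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scenario <- match.arg(doc$scenario, c("diagnostic", "therapeutic"))

  rs <- parse_rating_system(doc$rating_system)

  steps <- lapply(doc$steps, function(s) {
    process_step(s$step_id, s$name, s$order, unlist(s$functions), scenario)
  })

  vocab <- effect_vocabulary(do.call(rbind, lapply(doc$effects, function(e) {
    data.frame(effect_id = e$effect_id, label = e$label,
               severity_default = e$severity_default)
  })))

  # Exact fraction fields (decimal strings written by save_project) win over
  # the human-facing percent fields; templates carry percent only.
  read_prob <- function(exact, percent) {
    if (!is.null(exact)) {
      return(if (is.character(exact)) string_to_num(exact) else as.numeric(exact))
    }
    if (is.null(percent)) return(NULL)
    v <- if (is.character(percent)) string_to_num(percent) else as.numeric(percent)
    v / 100
  }

  fms <- lapply(doc$failure_modes, function(f) {
    bars <- lapply(f$barriers %||% list(), function(b) {
      # [[ with exact names: $ would partial-match p_miss to p_miss_percent
      barrier(b$name, b$kind,
              read_prob(b[["p_miss"]], b[["p_miss_percent"]]),
              b$description %||% "")
    })
    p_occ <- read_prob(f[["p_occ_initial"]], f[["p_occ_initial_percent"]])
    p_miss <- read_prob(f[["p_miss_initial"]], f[["p_miss_initial_percent"]])
    failure_mode(
      id = f$id, step_ref = f$step_ref, cause = f$cause,
      cause_class = f$cause_class, mode = f$mode, effect_id = f$effect_id,
      severity = f$severity, occurrence_initial = f$occurrence_initial,
      detectability_initial = f$detectability_initial,
      p_occ_initial = p_occ, p_miss_initial = p_miss, barriers = bars,
      preventions = f$preventions %||% "",
      initial_barriers = f$initial_barriers %||% ""
    )
  })

  workflows <- lapply(doc$workflows %||% list(), function(w) {
    workflow_context(w$workflow_id, w$name, w$scenario, w$patients_per_year,
                     w$size_class)
  })

  risk_project(name = doc$name, scenario = scenario, rating_system = rs,
               process_map = steps, effect_vocab = vocab,
               failure_modes = fms, workflows = workflows,
               metadata = doc$metadata %||% list())
}

parse_rating_system <- function(conf) {
  if (is.null(conf) || identical(conf, "default")) {
    return(default_rating_system())
  }
  if (inherits(conf, "rating_system")) return(conf)
  # serialized form: bins as [score, percent] pairs per dimension, with an
  # optional exact `probs` fraction-string list (written by save_project)
  scale_from <- function(dim) {
    if (!is.null(conf[[dim]]$probs)) {
      probs <- vapply(conf[[dim]]$probs, function(p) {
        if (is.character(p)) string_to_num(p) else as.numeric(p)
      }, numeric(1))
    } else {
      bins <- conf[[dim]]$bins
      probs <- numeric(length(bins))
      for (b in bins) {
        p <- b[[2]]
        probs[as.integer(b[[1]])] <- if (is.character(p)) string_to_num(p) / 100
                                     else as.numeric(p) / 100
      }
    }
    rating_scale(dim, probs, mode = conf[[dim]]$mode %||% "probability",
                 name = conf[[dim]]$name %||% NULL)
  }
  sev <- if (!is.null(conf$severity)) {
    severity_scale(unlist(conf$severity$descriptors))
  } else severity_scale()
  rating_system(scale_from("occurrence"), scale_from("detectability"),
                sev, name = conf$name %||% "custom")
}
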