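PROJECT_SCHEMA_VERSION <- "1.0"

#' Risk-assessment project container
#'
#' Bundles everything one risk analysis needs: the rating system, the
#' process map, the controlled effect vocabulary, the failure-mode register
#' and the workflow contexts, plus metadata (schema version, creation time,
#' seed registry).
#'
#' @param name project name.
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @param rating_system a [rating_system()].
#' @param process_map list of [process_step()] objects.
#' @param effect_vocab an [effect_vocabulary()].
#' @param failure_modes list of [failure_mode()] objects.
#' @param workflows list of [workflow_context()] objects.
#' @param metadata named list.
#' @return An object of class `risk_project`.
#' @export
risk_project <- function(name, scenario, rating_system, process_map,
                         effect_vocab, failure_modes, workflows = list(),
                         metadata = list()) {
  metadata$schema_version <- metadata$schema_version %||% PROJECT_SCHEMA_VERSION
  prj <- structure(
    list(name = as.character(name),
         scenario = match.arg(scenario, c("diagnostic", "therapeutic")),
         rating_system = rating_system, process_map = process_map,
         effect_vocab = effect_vocab, failure_modes = failure_modes,
         workflows = workflows, metadata = metadata),
    class = "risk_project"
  )
  violations <- validate_project(prj)
  if (length(violations) > 0L) {
    stop(paste(c("invalid project:", violations), collapse = "\n  "),
         call. = FALSE)
  }
  prj
}

#' Validate a project's cross-references and invariants
#'
#' @param prj a `risk_project` (or a raw list shaped like one).
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_project <- function(prj) {
  out <- character(0)
  rs_issues <- validate_rating_system(prj$rating_system)
  if (nrow(rs_issues) > 0L) out <- c(out, rs_issues$message)
  orders <- vapply(prj$process_map, `[[`, integer(1), "order")
  if (anyDuplicated(orders)) {
    out <- c(out, "process steps have duplicate order values")
  }
  step_ids <- vapply(prj$process_map, `[[`, character(1), "step_id")
  eff_ids <- prj$effect_vocab$entries$effect_id
  fm_ids <- vapply(prj$failure_modes, `[[`, character(1), "id")
  if (anyDuplicated(fm_ids)) {
    out <- c(out, "failure-mode ids are not unique")
  }
  for (fm in prj$failure_modes) {
    if (!fm$step_ref %in% step_ids) {
      out <- c(out, sprintf("failure mode '%s' references unknown step '%s'",
                            fm$id, fm$step_ref))
    }
    if (!fm$effect_id %in% eff_ids) {
      out <- c(out, sprintf("failure mode '%s' references unknown effect '%s'",
                            fm$id, fm$effect_id))
    }
  }
  out
}

# ---- serialization ---------------------------------------------------------
# Saved files carry every probability twice: a human-facing percent display
# value and an exact fraction decimal string (%.17g round-trips IEEE doubles
# bit for bit); the exact string wins when reading back.

pct_display <- function(p) sprintf("%.6g", p * 100)

project_to_document <- function(prj) {
  rs <- prj$rating_system
  ser_scale <- function(sc) {
    list(bins = lapply(seq_len(nrow(sc$bins)), function(i) {
           list(sc$bins$score[i], pct_display(sc$bins$prob[i]))
         }),
         probs = lapply(sc$bins$prob[order(sc$bins$score)], num_to_string),
         mode = sc$mode, name = sc$name)
  }
  list(
    name = prj$name,
    scenario = prj$scenario,
    metadata = prj$metadata,
    rating_system = list(
      name = rs$name,
      occurrence = ser_scale(rs$occurrence),
      detectability = ser_scale(rs$detectability),
      severity = list(descriptors = as.list(rs$severity$levels$descriptor))
    ),
    steps = lapply(prj$process_map, function(s) {
      list(step_id = s$step_id, name = s$name, order = s$order,
           functions = as.list(s$functions))
    }),
    effects = lapply(seq_len(nrow(prj$effect_vocab$entries)), function(i) {
      e <- prj$effect_vocab$entries[i, ]
      list(effect_id = e$effect_id, label = e$label,
           severity_default = e$severity_default)
    }),
    failure_modes = lapply(prj$failure_modes, function(f) {
      doc <- list(id = f$id, step_ref = f$step_ref, cause = f$cause,
                  cause_class = f$cause_class, mode = f$mode,
                  effect_id = f$effect_id, severity = f$severity,
                  occurrence_initial = f$occurrence_initial,
                  detectability_initial = f$detectability_initial)
      if (!is.null(f$p_occ_initial)) {
        doc$p_occ_initial <- num_to_string(f$p_occ_initial)
        doc$p_occ_initial_percent <- pct_display(f$p_occ_initial)
      }
      if (!is.null(f$p_miss_initial)) {
        doc$p_miss_initial <- num_to_string(f$p_miss_initial)
        doc$p_miss_initial_percent <- pct_display(f$p_miss_initial)
      }
      if (length(f$barriers) > 0L) {
        doc$barriers <- lapply(f$barriers, function(b) {
          list(name = b$name, kind = b$kind,
               p_miss = num_to_string(b$p_miss),
               p_miss_percent = pct_display(b$p_miss),
               description = b$description)
        })
      }
      if (nzchar(f$preventions)) doc$preventions <- f$preventions
      if (nzchar(f$initial_barriers)) doc$initial_barriers <- f$initial_barriers
      doc
    }),
    workflows = lapply(prj$workflows, function(w) {
      list(workflow_id = w$workflow_id, name = w$name, scenario = w$scenario,
           patients_per_year = w$patients_per_year, size_class = w$size_class)
    })
  )
}

#' Save / load a risk project
#'
#' Projects persist as JSON (default) or YAML, chosen by file extension.
#' Probabilities are written in percent as exact decimal strings, so
#' `load_project(save_project(p))` reproduces `p` exactly. Loading validates
#' the document and raises on schema violations or dangling references.
#'
#' @param prj a [risk_project()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `save_project` returns `path` invisibly; `load_project` returns
#'   the `risk_project`.
#' @export
save_project <- function(prj, path) {
  stopifnot(inherits(prj, "risk_project"))
  doc <- project_to_document(prj)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else {
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), path)
  }
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$rating_system)) {
    stop("project file is missing the 'rating_system' field", call. = FALSE)
  }
  parse_project_document(doc)
}

#' Export an assessment register as a report
#'
#' Deterministic, criticality-ranked report of a project's assessment:
#' initial and residual scores and RPNs, the undetected adverse-event rate
#' per failure mode, and — per declared workflow — expected events per
#' year. Probabilities are rendered in percent with 4 significant digits.
#'
#' @param prj a [risk_project()].
#' @param register an [assess_all()] data frame; computed from the project
#'   when omitted.
#' @param format `"csv"` or `"markdown"`.
#' @param use rank on `"initial"` or `"residual"` RPN.
#' @return The report as a single string.
#' @export
export_report <- function(prj, register = NULL,
                          format = c("csv", "markdown"),
                          use = c("initial", "residual")) {
  format <- match.arg(format)
  use <- match.arg(use)
  stopifnot(inherits(prj, "risk_project"))
  register <- register %||%
    assess_all(prj$failure_modes, prj$rating_system, prj$effect_vocab)
  ranked <- rank_failure_modes(register, use = use)
  disp <- ranked
  disp$p_occ_res <- sprintf("%.4g%%", ranked$p_occ_res * 100)
  disp$p_nondet_res <- sprintf("%.4g%%", ranked$p_nondet_res * 100)
  disp$N_eff <- sprintf("%.4g", ranked$N_eff)
  for (w in prj$workflows) {
    disp[[paste0("events_per_year_", w$workflow_id)]] <-
      sprintf("%.4g", events_per_year(ranked$N_eff, w$patients_per_year))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(disp, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  # markdown
  header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
  rows <- apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(sprintf("# Risk register: %s", prj$name), "",
          sprintf("Ranked by %s RPN.", use), "", header, sep, rows),
        collapse = "\n")
}

#' @export
print.risk_project <- function(x, ...) {
  cat(sprintf("<risk_project '%s'> %s: %d step(s), %d failure mode(s), %d effect(s), %d workflow(s)\n",
              x$name, x$scenario, length(x$process_map),
              length(x$failure_modes), nrow(x$effect_vocab$entries),
              length(x$workflows)))
  invisible(x)
}
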