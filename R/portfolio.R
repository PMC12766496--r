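#' Department workflow context
#'
#' Describes one assessed workflow: a diagnostic or therapeutic service with
#' an annual patient throughput. Throughput is used both for annualizing
#' event rates and as the default weighting in the cross-workflow ranking.
#'
#' @param workflow_id unique identifier.
#' @param name display name.
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @param patients_per_year positive integer throughput.
#' @param size_class `"small"`, `"medium"` or `"large"`; derived from the
#'   throughput via [classify_service_size()] when omitted.
#' @return An object of class `workflow_context`.
#' @export
workflow_context <- function(workflow_id, name,
                             scenario = c("diagnostic", "therapeutic"),
                             patients_per_year, size_class = NULL) {
  scenario <- match.arg(scenario)
  if (!is_scalar_number(patients_per_year) || patients_per_year < 1) {
    stop("patients_per_year must be a positive integer (>= 1)", call. = FALSE)
  }
  size_class <- size_class %||% classify_service_size(patients_per_year, scenario)
  size_class <- match.arg(size_class, c("small", "medium", "large"))
  structure(
    list(workflow_id = as.character(workflow_id), name = as.character(name),
         scenario = scenario,
         patients_per_year = as.integer(patients_per_year),
         size_class = size_class),
    class = "workflow_context"
  )
}

#' Classify a service by annual throughput
#'
#' Default thresholds bracket typical conventional-NM/PET diagnostic
#' services (small ~1300, medium ~8000, large ~14000 patients/year) and NM
#' therapy services (small ~100, medium ~400 patients/year).
#'
#' @param patients_per_year throughput.
#' @param scenario `"diagnostic"` or `"therapeutic"`.
#' @param thresholds numeric length 2: upper bounds (exclusive) of the small
#'   and medium classes.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
classify_service_size <- function(patients_per_year,
                                  scenario = c("diagnostic", "therapeutic"),
                                  thresholds = NULL) {
  scenario <- match.arg(scenario)
  thresholds <- thresholds %||%
    if (scenario == "diagnostic") c(5000, 10000) else c(250, 1000)
  if (patients_per_year < thresholds[1]) "small"
  else if (patients_per_year < thresholds[2]) "medium"
  else "large"
}

#' Cross-workflow weights
#'
#' Weights used to combine failure modes from several workflows into one
#' overarching ranking. The default scheme is throughput-proportional
#' (criticality scales with exposure opportunity); `"uniform"` gives every
#' workflow the same weight; `"size_class"` uses small/medium/large
#' multipliers; `"table"` takes user-supplied relative weights. All schemes
#' normalize to sum 1.
#'
#' @param workflows list of [workflow_context()] objects.
#' @param scheme `"throughput"`, `"uniform"`, `"size_class"` or `"table"`.
#' @param table named numeric vector of relative weights (scheme
#'   `"table"`), names = workflow ids.
#' @param size_multipliers named numeric vector for scheme `"size_class"`.
#' @return Named numeric vector of weights summing to 1.
#' @export
#' @examples
#' wfs <- list(workflow_context("A", "small NM", "diagnostic", 1300),
#'             workflow_context("B", "medium PET", "diagnostic", 8000),
#'             workflow_context("C", "large PET", "diagnostic", 14000))
#' workflow_weights(wfs)  # 1300/23300, 8000/23300, 14000/23300
workflow_weights <- function(workflows,
                             scheme = c("throughput", "uniform",
                                        "size_class", "table"),
                             table = NULL,
                             size_multipliers = c(small = 1, medium = 2,
                                                  large = 3)) {
  scheme <- match.arg(scheme)
  if (!is.list(workflows) || length(workflows) == 0L) {
    stop("workflows must be a non-empty list of workflow contexts", call. = FALSE)
  }
  stopifnot(all(vapply(workflows, inherits, logical(1), "workflow_context")))
  ids <- vapply(workflows, `[[`, character(1), "workflow_id")
  raw <- switch(
    scheme,
    throughput = vapply(workflows, `[[`, integer(1), "patients_per_year"),
    uniform = rep(1, length(workflows)),
    size_class = unname(size_multipliers[
      vapply(workflows, `[[`, character(1), "size_class")]),
    table = {
      if (is.null(table) || !all(ids %in% names(table))) {
        stop("scheme 'table' needs a named weight for every workflow id",
             call. = FALSE)
      }
      unname(table[ids])
    }
  )
  stats::setNames(raw / sum(raw), ids)
}

#' Overarching cross-workflow criticality ranking
#'
#' Compiles the failure modes of several workflow assessments into one
#' combined list, scoring each entry by `RPN * weight(workflow)` and
#' sorting descending. Ties are broken by raw RPN, then severity, then
#' stable input order. With uniform weights the combined order reduces to
#' the plain RPN order of the concatenated registers.
#'
#' @param portfolios list of `list(workflow = workflow_context, register =
#'   assess_all() data frame)` entries.
#' @param scheme,table,size_multipliers passed to [workflow_weights()].
#' @param use rank on `"initial"` or `"residual"` RPN.
#' @return Data frame of portfolio entries: `rank`, `workflow_id`,
#'   `failure_mode_id`, `rpn`, `severity`, `weight`,
#'   `weighted_criticality`; the weight scheme is recorded in
#'   `attr(, "weight_scheme")`.
#' @export
overarching_rank <- function(portfolios, scheme = "throughput", table = NULL,
                             size_multipliers = c(small = 1, medium = 2,
                                                  large = 3),
                             use = c("initial", "residual")) {
  use <- match.arg(use)
  if (!is.list(portfolios) || length(portfolios) == 0L) {
    stop("portfolios must be a non-empty list", call. = FALSE)
  }
  wfs <- lapply(portfolios, `[[`, "workflow")
  w <- workflow_weights(wfs, scheme = scheme, table = table,
                        size_multipliers = size_multipliers)
  rows <- lapply(portfolios, function(p) {
    reg <- p$register
    if (nrow(reg) == 0L) return(NULL)
    rpn <- if (use == "initial") reg$RPN_in else reg$RPN_out
    data.frame(workflow_id = p$workflow$workflow_id,
               failure_mode_id = reg$id, rpn = rpn, severity = reg$S,
               weight = unname(w[p$workflow$workflow_id]),
               weighted_criticality = rpn * unname(w[p$workflow$workflow_id]))
  })
  combined <- do.call(rbind, c(Filter(Negate(is.null), rows),
                               list(make.row.names = FALSE)))
  if (is.null(combined)) {
    combined <- data.frame(workflow_id = character(),
                           failure_mode_id = character(), rpn = integer(),
                           severity = integer(), weight = numeric(),
                           weighted_criticality = numeric())
  }
  ord <- order(-combined$weighted_criticality, -combined$rpn,
               -combined$severity, seq_len(nrow(combined)))
  out <- combined[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  attr(out, "weight_scheme") <- scheme
  out
}
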