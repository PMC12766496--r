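#' Ten-step rating scale mapping scores to probabilities
#'
#' A rating scale associates each integer score 1..10 of one FMEA rating
#' dimension (occurrence or detectability) with a probability. For the
#' occurrence dimension the probability is the chance that the failure mode
#' occurs per procedure, `P_occ(O)`; for detectability it is the chance that
#' the failure, once it has occurred, escapes detection, `P_miss(D) = 1 -
#' P_det(D)`. Both are monotonically increasing in the score, which is what
#' makes the inverse mapping from a residual probability back to a residual
#' score well defined.
#'
#' @param dimension `"occurrence"` or `"detectability"`.
#' @param probs numeric vector of 10 strictly increasing probabilities in
#'   (0, 1], one per score 1..10 (fractions, not percent).
#' @param mode `"probability"` (per-procedure chance) or `"frequency"`
#'   (scale calibrated from failures per unit time via
#'   [frequency_to_probability()]).
#' @param name optional scale name.
#' @return An object of class `rating_scale`.
#' @seealso [prob_from_score()], [score_from_prob()], [default_rating_system()]
#' @export
rating_scale <- function(dimension = c("occurrence", "detectability"),
                         probs,
                         mode = c("probability", "frequency"),
                         name = NULL) {
  dimension <- match.arg(dimension)
  mode <- match.arg(mode)
  structure(
    list(
      dimension = dimension,
      bins = data.frame(score = seq_along(probs), prob = as.numeric(probs)),
      mode = mode,
      name = name %||% paste0("default_", dimension)
    ),
    class = "rating_scale"
  )
}

#' Ten-step severity scale
#'
#' Severity has no probabilistic interpretation; it is a qualitative 1..10
#' grading of the worst credible consequence of a failure effect, associated
#' with top events (10 typically standing for severe patient harm such as a
#' grossly wrong absorbed dose or dose location).
#'
#' @param descriptors character vector of 10 non-empty labels, one per score.
#' @return An object of class `severity_scale`.
#' @export
severity_scale <- function(descriptors = default_severity_descriptors()) {
  structure(
    list(levels = data.frame(score = seq_along(descriptors),
                             descriptor = as.character(descriptors))),
    class = "severity_scale"
  )
}

default_severity_descriptors <- function() {
  c("No noticeable effect",
    "Inconvenience, no clinical consequence",
    "Rebooking or repetition of the procedure",
    "Minor deviation from intended exposure",
    "Temporary adverse effect",
    "Suboptimal treatment or diagnostic outcome",
    "Significant unintended exposure",
    "Serious adverse effect, recoverable",
    "Permanent harm or major overexposure",
    "Very wrong dose, dose distribution or location; potentially lethal")
}

#' Rating system: occurrence, detectability and severity scales
#'
#' @param occurrence,detectability [rating_scale()] objects of the matching
#'   dimension.
#' @param severity a [severity_scale()].
#' @param name system name (recorded in project files).
#' @return An object of class `rating_system`.
#' @export
rating_system <- function(occurrence, detectability,
                          severity = severity_scale(),
                          name = "default") {
  structure(
    list(occurrence = occurrence, detectability = detectability,
         severity = severity, name = name),
    class = "rating_system"
  )
}

#' Default ten-bin rating system
#'
#' The shipped tables are anchored to two normative points — occurrence score
#' 1 at 0.01 % and detectability score 2 at 0.2 % — and filled in between on
#' a roughly logarithmic grid, with the top bin of each scale at 100 %
#' (certain occurrence / certain non-detection). Every table is fully
#' overridable: build your own with [rating_scale()] if your department
#' calibrates differently.
#'
#' Occurrence (%): 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 100.
#' Detectability (%): 0.01, 0.2, 0.5, 1, 1.5, 2, 3, 5, 10, 100.
#'
#' @return A [rating_system()].
#' @export
#' @examples
#' rs <- default_rating_system()
#' prob_from_score(rs$occurrence, 1)      # 1e-04
#' score_from_prob(rs$detectability, 0.002)  # 2
default_rating_system <- function() {
  occ <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 100) / 100
  det <- c(0.01, 0.2, 0.5, 1, 1.5, 2, 3, 5, 10, 100) / 100
  rating_system(
    occurrence = rating_scale("occurrence", occ),
    detectability = rating_scale("detectability", det),
    severity = severity_scale(),
    name = "default"
  )
}

#' Probability associated with a rating score
#'
#' @param scale a [rating_scale()].
#' @param score integer in 1..10.
#' @return The bin probability (fraction in (0, 1]).
#' @export
prob_from_score <- function(scale, score) {
  stopifnot(inherits(scale, "rating_scale"))
  if (!is_scalar_number(score) || score != as.integer(score) ||
      score < 1L || score > 10L) {
    stop(sprintf("score for the %s scale must be an integer in 1..10 (got %s)",
                 scale$dimension, format(score)), call. = FALSE)
  }
  scale$bins$prob[match(as.integer(score), scale$bins$score)]
}

#' Score associated with a probability (conservative inverse)
#'
#' Returns the smallest score whose bin probability is at least `p`. This
#' ceiling convention never understates risk: the score assigned to a
#' residual probability always corresponds to a bin probability >= the true
#' residual. Probabilities below bin 1 map to score 1 (the scale has no
#' zero); `p` can never exceed bin 10 (which is 1 on the default scales).
#'
#' @param scale a [rating_scale()].
#' @param p probability in (0, 1].
#' @return Integer score in 1..10.
#' @export
score_from_prob <- function(scale, p) {
  stopifnot(inherits(scale, "rating_scale"))
  if (!is_scalar_number(p) || p <= 0 || p > 1) {
    stop(sprintf("probability for the %s scale must lie in (0,1] (got %s)",
                 scale$dimension, format(p)), call. = FALSE)
  }
  idx <- which(scale$bins$prob >= p)
  if (length(idx) == 0L) return(max(scale$bins$score))
  scale$bins$score[min(idx)]
}

#' Convert an event frequency to a per-procedure probability
#'
#' Departments often find it easier to estimate failures per unit time than
#' per-procedure probabilities; dividing by the annual procedure throughput
#' converts between the two (clamped at certainty).
#'
#' @param failures_per_year non-negative number of failures per year.
#' @param procedures_per_year positive integer throughput.
#' @return `min(failures_per_year / procedures_per_year, 1)`.
#' @export
frequency_to_probability <- function(failures_per_year, procedures_per_year) {
  if (!is_scalar_number(failures_per_year) || failures_per_year < 0) {
    stop("failures_per_year must be a non-negative number", call. = FALSE)
  }
  if (!is_scalar_number(procedures_per_year) || procedures_per_year < 1) {
    stop("procedures_per_year must be a positive integer (>= 1)", call. = FALSE)
  }
  min(failures_per_year / procedures_per_year, 1)
}

#' Validate a rating system against its structural invariants
#'
#' Checks, per scale: exactly 10 bins with each score 1..10 once, all
#' probabilities in (0, 1], probabilities strictly increasing with score;
#' for the severity scale: 10 unique scores with non-empty descriptors.
#' Reports violations rather than raising, so a hand-edited system can be
#' inspected.
#'
#' @param rs a [rating_system()].
#' @return A data frame with columns `scale`, `bin`, `rule`, `message`;
#'   zero rows iff the system is valid.
#' @export
validate_rating_system <- function(rs) {
  out <- data.frame(scale = character(), bin = integer(),
                    rule = character(), message = character())
  add <- function(scale, bin, rule, message) {
    rbind(out, data.frame(scale = scale, bin = as.integer(bin),
                          rule = rule, message = message))
  }
  for (nm in c("occurrence", "detectability")) {
    sc <- rs[[nm]]
    bins <- sc$bins
    if (nrow(bins) != 10L || !setequal(bins$score, 1:10)) {
      out <- add(nm, NA, "cardinality",
                 sprintf("scale '%s' must have exactly 10 bins scored 1..10 (has %d)",
                         nm, nrow(bins)))
      next
    }
    bins <- bins[order(bins$score), ]
    bad_range <- which(bins$prob <= 0 | bins$prob > 1)
    for (b in bad_range) {
      out <- add(nm, bins$score[b], "range",
                 sprintf("bin %d of '%s' has probability %s outside (0,1]",
                         bins$score[b], nm, format(bins$prob[b])))
    }
    non_inc <- which(diff(bins$prob) <= 0)
    for (b in non_inc) {
      out <- add(nm, bins$score[b], "monotonicity",
                 sprintf("'%s' probability does not strictly increase from score %d to %d",
                         nm, bins$score[b], bins$score[b + 1L]))
    }
    if (!identical(sc$dimension, nm)) {
      out <- add(nm, NA, "dimension",
                 sprintf("scale in slot '%s' is declared as dimension '%s'",
                         nm, sc$dimension))
    }
  }
  lv <- rs$severity$levels
  if (nrow(lv) != 10L || !setequal(lv$score, 1:10)) {
    out <- add("severity", NA, "cardinality",
               sprintf("severity scale must have 10 unique scores 1..10 (has %d)",
                       nrow(lv)))
  } else if (any(!nzchar(trimws(lv$descriptor)))) {
    for (b in which(!nzchar(trimws(lv$descriptor)))) {
      out <- add("severity", lv$score[b], "descriptor",
                 sprintf("severity score %d has an empty descriptor", lv$score[b]))
    }
  }
  out
}

#' @export
print.rating_system <- function(x, ...) {
  cat(sprintf("<rating_system '%s'>\n", x$name))
  cat("  occurrence  (%):", paste(format(x$occurrence$bins$prob * 100,
                                         trim = TRUE), collapse = ", "), "\n")
  cat("  detectability(%):", paste(format(x$detectability$bins$prob * 100,
                                          trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}
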