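CAUSE_CLASSES <- c("organizational", "procedural", "technical",
                   "training", "informatic_technology")

#' Safety barrier with a miss probability
#'
#' A barrier either prevents a failure from occurring (proactive, reduces
#' occurrence) or detects it after it occurs but before harm is done
#' (reactive, reduces detectability). Its effectiveness is expressed as
#' `p_miss`, the probability that the barrier fails to act; barriers are
#' assumed independent, so their miss probabilities multiply into the
#' occurrence or non-detection probability.
#'
#' @param name barrier name.
#' @param kind `"proactive"` or `"reactive"`.
#' @param p_miss fraction in (0, 1]: probability the barrier fails to act.
#' @param description optional free text.
#' @return An object of class `barrier`.
#' @export
barrier <- function(name, kind = c("proactive", "reactive"), p_miss,
                    description = "") {
  kind <- match.arg(kind)
  structure(
    list(name = as.character(name), kind = kind,
         p_miss = assert_fraction(p_miss, sprintf("barrier '%s' p_miss", name)),
         description = as.character(description)),
    class = "barrier"
  )
}

#' Failure chain: cause, mode, effect, with ratings and barriers
#'
#' One row of an FMEA register. Initial ratings are integer scores against a
#' [rating_system()]; optionally, explicit initial probabilities can be given
#' instead (`p_occ_initial`, `p_miss_initial`), in which case the displayed
#' initial scores are derived from them by the conservative inverse mapping.
#'
#' @param id unique identifier.
#' @param step_ref identifier of the process step the failure belongs to.
#' @param cause free-text failure cause (becomes the basic event in the
#'   fault-tree view).
#' @param cause_class one of `"organizational"`, `"procedural"`,
#'   `"technical"`, `"training"`, `"informatic_technology"`.
#' @param mode free-text failure mode (the fault event).
#' @param effect_id identifier into the project's effect vocabulary (the top
#'   event).
#' @param severity,occurrence_initial,detectability_initial integer scores
#'   1..10.
#' @param p_occ_initial,p_miss_initial optional explicit initial occurrence /
#'   non-detection probabilities in (0, 1]; when given they take precedence
#'   over the corresponding score.
#' @param barriers list of [barrier()] objects.
#' @param preventions,initial_barriers free-text descriptions of measures
#'   already reflected in the initial ratings (narrative only; they carry no
#'   `p_miss` and do not change any number).
#' @return An object of class `failure_mode`.
#' @export
failure_mode <- function(id, step_ref, cause, cause_class, mode, effect_id,
                         severity, occurrence_initial, detectability_initial,
                         p_occ_initial = NULL, p_miss_initial = NULL,
                         barriers = list(), preventions = "",
                         initial_barriers = "") {
  cause_class <- match.arg(cause_class, CAUSE_CLASSES)
  if (!is.null(p_occ_initial))
    p_occ_initial <- assert_fraction(p_occ_initial, "p_occ_initial")
  if (!is.null(p_miss_initial))
    p_miss_initial <- assert_fraction(p_miss_initial, "p_miss_initial")
  stopifnot(all(vapply(barriers, inherits, logical(1), "barrier")))
  structure(
    list(id = as.character(id), step_ref = as.character(step_ref),
         cause = as.character(cause), cause_class = cause_class,
         mode = as.character(mode), effect_id = as.character(effect_id),
         severity = assert_score(severity, "severity"),
         occurrence_initial = assert_score(occurrence_initial, "occurrence_initial"),
         detectability_initial = assert_score(detectability_initial,
                                              "detectability_initial"),
         p_occ_initial = p_occ_initial, p_miss_initial = p_miss_initial,
         barriers = barriers,
         preventions = as.character(preventions),
         initial_barriers = as.character(initial_barriers)),
    class = "failure_mode"
  )
}

#' Risk priority number
#'
#' The criticality surrogate `RPN = S * O * D` over the three ten-step
#' scores; lies in 1..1000.
#'
#' @param S,O,D integer scores in 1..10.
#' @return Integer RPN.
#' @export
#' @examples
#' compute_rpn(5, 4, 7)  # 140
compute_rpn <- function(S, O, D) {
  S <- assert_score(S, "S"); O <- assert_score(O, "O"); D <- assert_score(D, "D")
  S * O * D
}

#' Apply proactive barriers to an initial occurrence probability
#'
#' Residual occurrence is the initial occurrence probability multiplied by
#' the miss probabilities of all proactive barriers (independence assumed);
#' reactive barriers in the list are ignored.
#'
#' @param p_occ_initial fraction in (0, 1].
#' @param barriers list of [barrier()] objects (any kind; only proactive
#'   ones act here).
#' @return Residual occurrence probability in (0, 1].
#' @export
apply_proactive_barriers <- function(p_occ_initial, barriers = list()) {
  p <- assert_fraction(p_occ_initial, "p_occ_initial")
  for (b in barriers) if (b$kind == "proactive") p <- p * b$p_miss
  p
}

#' Apply reactive barriers to an initial non-detection probability
#'
#' Residual non-detection `(1 - P_det)` is the initial miss probability
#' multiplied by the miss probabilities of all reactive barriers; proactive
#' barriers in the list are ignored.
#'
#' @param p_miss_initial fraction in (0, 1].
#' @param barriers list of [barrier()] objects.
#' @return Residual non-detection probability in (0, 1].
#' @export
apply_reactive_barriers <- function(p_miss_initial, barriers = list()) {
  p <- assert_fraction(p_miss_initial, "p_miss_initial")
  for (b in barriers) if (b$kind == "reactive") p <- p * b$p_miss
  p
}

#' Assess one failure mode against a rating system
#'
#' Composes the whole barrier model for one failure chain: initial
#' probabilities come from the scores through the rating tables (or from
#' explicit overrides), proactive barriers multiply into the occurrence
#' probability and reactive barriers into the non-detection probability,
#' residual probabilities are mapped back to residual scores by the
#' conservative inverse, and the initial and residual RPNs plus the
#' undetected adverse-event rate `N_eff = P_occ * (1 - P_det)` are computed.
#'
#' @param fm a [failure_mode()].
#' @param rs a [rating_system()].
#' @param vocab optional [effect_vocabulary()]; when given, `fm$effect_id`
#'   must resolve in it.
#' @return An object of class `assessment`: a list with fields
#'   `failure_mode_id`, `severity`, `occurrence_initial`,
#'   `detectability_initial`, `rpn_initial`, `p_occ_initial`,
#'   `p_miss_initial`, `p_occ_residual`, `p_nondet_residual`,
#'   `occurrence_residual`, `detectability_residual`, `rpn_residual`,
#'   `n_eff`.
#' @export
#' @examples
#' rs <- default_rating_system()
#' fm <- failure_mode("vx", "adm", "vials exchanged", "procedural",
#'                    "incorrect vial administered", "wrong_order",
#'                    severity = 10, occurrence_initial = 1,
#'                    detectability_initial = 10,
#'                    p_occ_initial = 1e-4, p_miss_initial = 1,
#'                    barriers = list(
#'                      barrier("Box labelling", "proactive", 0.01),
#'                      barrier("Checking box labelling", "reactive", 0.002)))
#' a <- assess(fm, rs)
#' a$n_eff  # 2e-09
assess <- function(fm, rs, vocab = NULL) {
  stopifnot(inherits(fm, "failure_mode"), inherits(rs, "rating_system"))
  if (!is.null(vocab) && !fm$effect_id %in% vocab$entries$effect_id) {
    stop(sprintf("failure mode '%s' references unknown effect_id '%s'",
                 fm$id, fm$effect_id), call. = FALSE)
  }
  p_occ_i <- fm$p_occ_initial %||% prob_from_score(rs$occurrence,
                                                   fm$occurrence_initial)
  p_miss_i <- fm$p_miss_initial %||% prob_from_score(rs$detectability,
                                                     fm$detectability_initial)
  # Displayed initial scores: explicit probabilities are authoritative when
  # given, so the score shown is derived from them.
  O_in <- if (is.null(fm$p_occ_initial)) fm$occurrence_initial
          else score_from_prob(rs$occurrence, p_occ_i)
  D_in <- if (is.null(fm$p_miss_initial)) fm$detectability_initial
          else score_from_prob(rs$detectability, p_miss_i)

  p_occ_res <- apply_proactive_barriers(p_occ_i, fm$barriers)
  p_nondet_res <- apply_reactive_barriers(p_miss_i, fm$barriers)
  O_res <- score_from_prob(rs$occurrence, p_occ_res)
  D_res <- score_from_prob(rs$detectability, p_nondet_res)

  structure(
    list(failure_mode_id = fm$id,
         severity = fm$severity,
         occurrence_initial = O_in,
         detectability_initial = D_in,
         rpn_initial = compute_rpn(fm$severity, O_in, D_in),
         p_occ_initial = p_occ_i,
         p_miss_initial = p_miss_i,
         p_occ_residual = p_occ_res,
         p_nondet_residual = p_nondet_res,
         occurrence_residual = O_res,
         detectability_residual = D_res,
         rpn_residual = compute_rpn(fm$severity, O_res, D_res),
         n_eff = p_occ_res * p_nondet_res),
    class = "assessment"
  )
}

#' Assess a list of failure modes into a register
#'
#' @param fms list of [failure_mode()] objects.
#' @param rs a [rating_system()].
#' @param vocab optional [effect_vocabulary()].
#' @return A data frame with one row per failure mode (columns: id, step,
#'   cause, cause_class, mode, effect, S, O_in, D_in, RPN_in, O_res, D_res,
#'   RPN_out, p_occ_res, p_nondet_res, N_eff).
#' @export
assess_all <- function(fms, rs, vocab = NULL) {
  rows <- lapply(fms, function(fm) {
    a <- assess(fm, rs, vocab)
    data.frame(id = fm$id, step = fm$step_ref, cause = fm$cause,
               cause_class = fm$cause_class, mode = fm$mode,
               effect = fm$effect_id, S = a$severity,
               O_in = a$occurrence_initial, D_in = a$detectability_initial,
               RPN_in = a$rpn_initial, O_res = a$occurrence_residual,
               D_res = a$detectability_residual, RPN_out = a$rpn_residual,
               p_occ_res = a$p_occ_residual,
               p_nondet_res = a$p_nondet_residual, N_eff = a$n_eff)
  })
  if (length(rows) == 0L) return(as_register(list()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Weighted multi-rater consensus scores
#'
#' Different professionals (physician, technician, nurse, radiopharmacist,
#' medical physicist, administrative staff) often rate the same event
#' differently; the consensus per dimension is the weighted arithmetic mean
#' of the raters' scores, rounded half-up to an integer and clamped to
#' 1..10. Role weights default to 1.
#'
#' @param ratings data frame with columns `S`, `O`, `D` (integer scores) and
#'   optionally `weight` (positive) and `rater_role`.
#' @return Named list `list(S =, O =, D =)` of integer consensus scores.
#' @export
#' @examples
#' consensus_scores(data.frame(S = c(2, 10), O = c(1, 1), D = c(3, 3),
#'                             weight = c(3, 1)))$S  # 4
consensus_scores <- function(ratings) {
  if (!is.data.frame(ratings) || nrow(ratings) == 0L) {
    stop("ratings must be a non-empty data frame of rater scores", call. = FALSE)
  }
  w <- ratings$weight %||% rep(1, nrow(ratings))
  if (any(w <= 0)) stop("rater weights must be positive", call. = FALSE)
  for (col in c("S", "O", "D")) {
    v <- ratings[[col]]
    if (is.null(v) || any(v < 1 | v > 10 | v != as.integer(v))) {
      stop(sprintf("column '%s' must hold integer scores in 1..10", col),
           call. = FALSE)
    }
  }
  one <- function(v) as.integer(clamp(round_half_up(sum(v * w) / sum(w)), 1L, 10L))
  list(S = one(ratings$S), O = one(ratings$O), D = one(ratings$D))
}

#' Rank assessments by criticality
#'
#' Sorts descending by RPN (initial or residual); ties broken by higher
#' severity, then higher occurrence, then higher detectability, then stable
#' input order.
#'
#' @param assessments a register data frame from [assess_all()], or a list
#'   of `assessment` objects (coerced).
#' @param use `"initial"` or `"residual"`: which RPN to rank on.
#' @return The register sorted by descending criticality, with a `rank`
#'   column prepended.
#' @export
rank_failure_modes <- function(assessments, use = c("initial", "residual")) {
  use <- match.arg(use)
  reg <- as_register(assessments)
  if (nrow(reg) == 0L) {
    return(cbind(rank = integer(0), reg))
  }
  rpn <- if (use == "initial") reg$RPN_in else reg$RPN_out
  O <- if (use == "initial") reg$O_in else reg$O_res
  D <- if (use == "initial") reg$D_in else reg$D_res
  ord <- order(-rpn, -reg$S, -O, -D, seq_len(nrow(reg)))
  out <- reg[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

# Coerce a list of assessment objects into the register layout used by
# assess_all(); a data frame passes through.
as_register <- function(x) {
  if (is.data.frame(x)) return(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "assessment")))
  rows <- lapply(x, function(a) {
    data.frame(id = a$failure_mode_id, step = NA_character_,
               cause = NA_character_, cause_class = NA_character_,
               mode = NA_character_, effect = NA_character_,
               S = a$severity, O_in = a$occurrence_initial,
               D_in = a$detectability_initial, RPN_in = a$rpn_initial,
               O_res = a$occurrence_residual, D_res = a$detectability_residual,
               RPN_out = a$rpn_residual, p_occ_res = a$p_occ_residual,
               p_nondet_res = a$p_nondet_residual, N_eff = a$n_eff)
  })
  if (length(rows) == 0L) {
    return(data.frame(id = character(), step = character(),
                      cause = character(), cause_class = character(),
                      mode = character(), effect = character(),
                      S = integer(), O_in = integer(), D_in = integer(),
                      RPN_in = integer(), O_res = integer(), D_res = integer(),
                      RPN_out = integer(), p_occ_res = numeric(),
                      p_nondet_res = numeric(), N_eff = numeric()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("<assessment %s> S=%d O=%d->%d D=%d->%d RPN %d -> %d, N_eff = %.4g\n",
              x$failure_mode_id, x$severity,
              x$occurrence_initial, x$occurrence_residual,
              x$detectability_initial, x$detectability_residual,
              x$rpn_initial, x$rpn_residual, x$n_eff))
  invisible(x)
}

#' @export
print.failure_mode <- function(x, ...) {
  cat(sprintf("<failure_mode %s> %s -> %s -> %s [S=%d O=%d D=%d, %d barrier(s)]\n",
              x$id, x$cause, x$mode, x$effect_id, x$severity,
              x$occurrence_initial, x$detectability_initial,
              length(x$barriers)))
  invisible(x)
}
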