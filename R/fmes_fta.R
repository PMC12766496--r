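#' Controlled vocabulary of failure effects (top events)
#'
#' Grouping failure modes by effect — the FMES step that bridges FMEA tables
#' and fault trees — only works if effects are worded consistently. The
#' vocabulary enforces that: failure modes reference effects by id, not by
#' free text.
#'
#' @param entries data frame with columns `effect_id`, `label`,
#'   `severity_default` (integer 1..10).
#' @return An object of class `effect_vocabulary`.
#' @export
effect_vocabulary <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("effect_id", "label", "severity_default") %in% names(entries)))
  if (anyDuplicated(entries$effect_id)) {
    stop("effect ids must be unique", call. = FALSE)
  }
  norm <- slugify(entries$label)
  if (anyDuplicated(norm)) {
    stop("effect labels must be unique after normalization", call. = FALSE)
  }
  entries$effect_id <- as.character(entries$effect_id)
  entries$label <- as.character(entries$label)
  entries$severity_default <- as.integer(entries$severity_default)
  structure(list(entries = entries), class = "effect_vocabulary")
}

#' Failure modes and effects summary (FMES)
#'
#' Groups all failure modes sharing the same effect into one summary row;
#' the grouped failure modes become the causes of the summarized one. This
#' is the data reduction that turns a flat FMEA register into one fault tree
#' per top event.
#'
#' @param fms list of [failure_mode()] objects.
#' @param vocab an [effect_vocabulary()]; every referenced effect must
#'   resolve.
#' @return A data frame with one row per distinct effect referenced:
#'   `effect_id`, `label`, `n_causes`, `causes` (failure-mode ids, `;`
#'   separated).
#' @export
fmes_summarize <- function(fms, vocab) {
  stopifnot(inherits(vocab, "effect_vocabulary"))
  ids <- vapply(fms, `[[`, character(1), "effect_id")
  unknown <- setdiff(unique(ids), vocab$entries$effect_id)
  if (length(unknown) > 0L) {
    stop(sprintf("failure modes reference unknown effect id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(fms) == 0L) {
    return(data.frame(effect_id = character(), label = character(),
                      n_causes = integer(), causes = character()))
  }
  fm_ids <- vapply(fms, `[[`, character(1), "id")
  eff <- unique(ids)
  rows <- lapply(eff, function(e) {
    members <- fm_ids[ids == e]
    data.frame(effect_id = e,
               label = vocab$entries$label[match(e, vocab$entries$effect_id)],
               n_causes = length(members),
               causes = paste(members, collapse = ";"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build the fault tree for one top event
#'
#' Converts the FMEA rows referencing `effect_id` into a fault tree: the
#' failure effect becomes the top event (OR gate over branches), each
#' failure mode becomes a fault event, its cause becomes the basic event
#' beneath it, and each barrier appears as an AND-ed "barrier failed" leaf
#' carrying its miss probability — which makes the branch rate structurally
#' the product `P_occ * (1 - P_det)`.
#'
#' @param fms list of [failure_mode()] objects.
#' @param vocab an [effect_vocabulary()].
#' @param effect_id the top event to build the tree for; at least one
#'   failure mode must reference it.
#' @return An object of class `fault_tree`: `top_event`, `label`, `nodes`
#'   (data frame: node_id, level, label, gate, parent, prob), `branches`
#'   (data frame: failure_mode_id, fault_node), and `failure_modes` (the
#'   contributing [failure_mode()] objects, by reference, keyed by id).
#' @export
build_fault_tree <- function(fms, vocab, effect_id) {
  stopifnot(inherits(vocab, "effect_vocabulary"))
  if (!effect_id %in% vocab$entries$effect_id) {
    stop(sprintf("unknown effect id '%s'", effect_id), call. = FALSE)
  }
  members <- Filter(function(fm) fm$effect_id == effect_id, fms)
  if (length(members) == 0L) {
    stop(sprintf("no failure mode references effect '%s'; cannot build a tree",
                 effect_id), call. = FALSE)
  }
  # deterministic branch ordering by failure-mode id
  members <- members[order(vapply(members, `[[`, character(1), "id"))]
  label <- vocab$entries$label[match(effect_id, vocab$entries$effect_id)]

  nodes <- list(data.frame(node_id = "top", level = "top", label = label,
                           gate = "OR", parent = NA_character_,
                           prob = NA_real_))
  branches <- list()
  for (fm in members) {
    fault_id <- paste0("fe_", fm$id)
    nodes[[length(nodes) + 1L]] <-
      data.frame(node_id = fault_id, level = "fault_event", label = fm$mode,
                 gate = "AND", parent = "top", prob = NA_real_)
    nodes[[length(nodes) + 1L]] <-
      data.frame(node_id = paste0("be_", fm$id), level = "basic_event",
                 label = fm$cause, gate = NA_character_, parent = fault_id,
                 prob = NA_real_)
    for (k in seq_along(fm$barriers)) {
      b <- fm$barriers[[k]]
      nodes[[length(nodes) + 1L]] <-
        data.frame(node_id = sprintf("bar_%s_%d", fm$id, k),
                   level = "barrier_event",
                   label = sprintf("%s fails [%s]", b$name, b$kind),
                   gate = NA_character_, parent = fault_id, prob = b$p_miss)
    }
    branches[[length(branches) + 1L]] <-
      data.frame(failure_mode_id = fm$id, fault_node = fault_id)
  }
  fm_by_id <- stats::setNames(members, vapply(members, `[[`, character(1), "id"))
  structure(
    list(top_event = effect_id, label = label,
         nodes = do.call(rbind, c(nodes, list(make.row.names = FALSE))),
         branches = do.call(rbind, c(branches, list(make.row.names = FALSE))),
         failure_modes = fm_by_id),
    class = "fault_tree"
  )
}

#' Undetected adverse-event rate of one branch
#'
#' The rate at which a branch's failure occurs and remains undetected:
#' `N_eff = P_occ * (1 - P_det)`, taken from the residual probabilities of
#' the branch's assessment.
#'
#' @param assessment an [assess()] result.
#' @return Fraction in (0, 1].
#' @export
branch_n_eff <- function(assessment) {
  stopifnot(inherits(assessment, "assessment"))
  assessment$p_occ_residual * assessment$p_nondet_residual
}

#' Top-event rate of a fault tree
#'
#' Branches are joined by an OR gate; under the rare-event approximation the
#' top-event rate is the sum of the per-branch rates `N_eff_j`. The exact OR
#' combination `1 - prod(1 - N_eff_j)` is available via `exact = TRUE`; for
#' rates typical of clinical failure modes the two agree to well under a
#' permille. The approximate sum is clamped at 1 with a warning if branch
#' rates are large enough to push it past certainty.
#'
#' @param tree a [build_fault_tree()] result.
#' @param assessments named list of [assess()] results (names = failure-mode
#'   ids) or an [assess_all()] register covering every branch.
#' @param exact use the exact OR combination instead of the sum.
#' @return Top-event rate in \\[0, 1\\].
#' @export
top_event_rate <- function(tree, assessments, exact = FALSE) {
  stopifnot(inherits(tree, "fault_tree"))
  rates <- branch_rates(tree, assessments)
  if (exact) return(1 - prod(1 - rates))
  total <- sum(rates)
  if (total > 1) {
    warning("rare-event sum of branch rates exceeds 1; clamping at certainty",
            call. = FALSE)
    total <- 1
  }
  total
}

# Per-branch N_eff vector, in branch order, from either a named assessment
# list or a register data frame.
branch_rates <- function(tree, assessments) {
  ids <- tree$branches$failure_mode_id
  if (is.data.frame(assessments)) {
    idx <- match(ids, assessments$id)
    if (anyNA(idx)) {
      stop(sprintf("no assessment for branch failure mode(s): %s",
                   paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    return(assessments$N_eff[idx])
  }
  missing <- setdiff(ids, names(assessments))
  if (length(missing) > 0L) {
    stop(sprintf("no assessment for branch failure mode(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vapply(assessments[ids], branch_n_eff, numeric(1))
}

#' Convert an event rate to events per year
#'
#' @param rate per-procedure event rate (fraction).
#' @param throughput positive integer: procedures (patients) per year.
#' @return Expected events per year, `rate * throughput`.
#' @export
events_per_year <- function(rate, throughput) {
  if (!is_scalar_number(throughput) || throughput < 1) {
    stop("throughput must be a positive integer (>= 1)", call. = FALSE)
  }
  rate * throughput
}

#' Restrict a fault tree to high-severity branches
#'
#' Keeps only branches whose failure-mode severity exceeds the threshold
#' (strict `>` by default; `inclusive = TRUE` keeps `>=`). A threshold of 0
#' leaves the tree unchanged; a threshold of 10 empties it while preserving
#' the top-event label.
#'
#' @param tree a [build_fault_tree()] result.
#' @param threshold integer in 0..10.
#' @param inclusive keep branches with severity equal to the threshold too.
#' @return A `fault_tree` restricted to the surviving branches.
#' @export
filter_branches_by_severity <- function(tree, threshold, inclusive = FALSE) {
  stopifnot(inherits(tree, "fault_tree"))
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 10) {
    stop("threshold must lie in 0..10", call. = FALSE)
  }
  keep <- vapply(tree$failure_modes, function(fm) {
    if (inclusive) fm$severity >= threshold else fm$severity > threshold
  }, logical(1))
  kept_ids <- names(tree$failure_modes)[keep]
  kept_faults <- tree$branches$fault_node[
    tree$branches$failure_mode_id %in% kept_ids]
  nodes <- tree$nodes
  nodes <- nodes[nodes$level == "top" |
                 nodes$node_id %in% kept_faults |
                 nodes$parent %in% kept_faults, , drop = FALSE]
  rownames(nodes) <- NULL
  branches <- tree$branches[tree$branches$failure_mode_id %in% kept_ids, ,
                            drop = FALSE]
  rownames(branches) <- NULL
  structure(
    list(top_event = tree$top_event, label = tree$label, nodes = nodes,
         branches = branches, failure_modes = tree$failure_modes[keep]),
    class = "fault_tree"
  )
}

#' Recover the FMEA rows from a fault tree
#'
#' The inverse of [build_fault_tree()]: reads each branch back into a
#' [failure_mode()] (cause from the basic event, mode from the fault event,
#' effect from the top event, barriers from the barrier leaves, ratings from
#' the stored failure-mode record). `build_fault_tree()` then
#' `tree_to_table()` round-trips.
#'
#' @param tree a `fault_tree`.
#' @return A list of [failure_mode()] objects, in branch order.
#' @export
tree_to_table <- function(tree) {
  stopifnot(inherits(tree, "fault_tree"))
  lvl_ok <- tree$nodes$level %in% c("top", "fault_event", "basic_event",
                                    "barrier_event")
  if (!all(lvl_ok)) {
    stop("malformed fault tree: unknown node level(s)", call. = FALSE)
  }
  lapply(seq_len(nrow(tree$branches)), function(i) {
    fmid <- tree$branches$failure_mode_id[i]
    fault_id <- tree$branches$fault_node[i]
    fm <- tree$failure_modes[[fmid]]
    kids <- tree$nodes[!is.na(tree$nodes$parent) &
                       tree$nodes$parent == fault_id, , drop = FALSE]
    basic <- kids[kids$level == "basic_event", , drop = FALSE]
    if (nrow(basic) != 1L) {
      stop(sprintf("malformed fault tree: branch '%s' lacks a single basic event",
                   fmid), call. = FALSE)
    }
    bars <- kids[kids$level == "barrier_event", , drop = FALSE]
    barriers <- lapply(seq_len(nrow(bars)), function(k) {
      lbl <- bars$label[k]
      kind <- if (grepl("\\[reactive\\]$", lbl)) "reactive" else "proactive"
      name <- sub(" fails \\[(proactive|reactive)\\]$", "", lbl)
      # descriptions are not drawn in the tree; recover them from the
      # stored record when the leaf still matches it
      desc <- if (k <= length(fm$barriers) &&
                  identical(fm$barriers[[k]]$name, name) &&
                  identical(fm$barriers[[k]]$kind, kind)) {
        fm$barriers[[k]]$description
      } else ""
      barrier(name, kind, bars$prob[k], desc)
    })
    failure_mode(
      id = fmid, step_ref = fm$step_ref, cause = basic$label,
      cause_class = fm$cause_class,
      mode = tree$nodes$label[tree$nodes$node_id == fault_id],
      effect_id = tree$top_event, severity = fm$severity,
      occurrence_initial = fm$occurrence_initial,
      detectability_initial = fm$detectability_initial,
      p_occ_initial = fm$p_occ_initial, p_miss_initial = fm$p_miss_initial,
      barriers = barriers, preventions = fm$preventions,
      initial_barriers = fm$initial_barriers
    )
  })
}

#' Export a fault tree as a Graphviz DOT digraph
#'
#' Node shape encodes the level (top = doubleoctagon, fault events = box
#' with the AND gate label, basic events = circle, barrier leaves =
#' diamond); output is deterministic for a fixed tree.
#'
#' @param tree a `fault_tree`.
#' @param file optional path; when given the DOT text is written there.
#' @return The DOT source as a single string (invisibly when `file` is
#'   given).
#' @export
tree_to_dot <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "fault_tree"))
  shape <- c(top = "doubleoctagon", fault_event = "box",
             basic_event = "circle", barrier_event = "diamond")
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph fault_tree {", "  rankdir=BT;")
  for (i in seq_len(nrow(tree$nodes))) {
    nd <- tree$nodes[i, ]
    lbl <- esc(nd$label)
    if (!is.na(nd$gate)) lbl <- paste0(lbl, "\\n[", nd$gate, "]")
    if (!is.na(nd$prob)) lbl <- paste0(lbl, "\\np_miss=", format(nd$prob))
    lines <- c(lines, sprintf('  "%s" [label="%s", shape=%s];',
                              nd$node_id, lbl, shape[[nd$level]]))
  }
  kids <- tree$nodes[!is.na(tree$nodes$parent), , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    lines <- c(lines, sprintf('  "%s" -> "%s";',
                              kids$node_id[i], kids$parent[i]))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Export a fault tree as a nested JSON document
#'
#' @param tree a `fault_tree`.
#' @param file optional path.
#' @return JSON string (invisibly when `file` is given).
#' @export
tree_to_json <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "fault_tree"))
  build <- function(node_id) {
    nd <- tree$nodes[tree$nodes$node_id == node_id, ]
    kids <- tree$nodes$node_id[!is.na(tree$nodes$parent) &
                               tree$nodes$parent == node_id]
    out <- list(node_id = nd$node_id, level = nd$level, label = nd$label)
    if (!is.na(nd$gate)) out$gate <- nd$gate
    if (!is.na(nd$prob)) out$p_miss <- nd$prob
    if (length(kids) > 0L) out$children <- lapply(sort(kids), build)
    out
  }
  doc <- list(top_event = tree$top_event, tree = build("top"))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @export
print.fault_tree <- function(x, ...) {
  cat(sprintf("<fault_tree> top event '%s' (%s), %d branch(es), %d node(s)\n",
              x$label, x$top_event, nrow(x$branches), nrow(x$nodes)))
  invisible(x)
}
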