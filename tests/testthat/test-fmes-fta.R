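test_that("FMES groups failure modes by shared effect", {
  fms <- list(simple_fm("a", 5, 4, 7, "harm"), simple_fm("b", 6, 2, 5, "harm"))
  tab <- fmes_summarize(fms, tiny_vocab())
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$n_causes, 2L)
  expect_identical(tab$causes, "a;b")

  distinct <- list(simple_fm("a", 5, 4, 7, "harm"),
                   simple_fm("b", 6, 2, 5, "rework"))
  expect_identical(nrow(fmes_summarize(distinct, tiny_vocab())), 2L)
  expect_identical(nrow(fmes_summarize(list(), tiny_vocab())), 0L)
  expect_error(fmes_summarize(list(simple_fm("x", 1, 1, 1, "ghost")),
                              tiny_vocab()), "unknown effect")
})

test_that("FMES conserves the failure-mode count (property)", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    fms <- lapply(seq_len(n), function(i)
      simple_fm(sprintf("fm%02d", i), effect = sample(c("harm", "rework"), 1)))
    tab <- fmes_summarize(fms, tiny_vocab())
    expect_identical(sum(tab$n_causes), n)
    expect_identical(nrow(tab),
                     length(unique(vapply(fms, `[[`, character(1), "effect_id"))))
  }
})

test_that("fault-tree structure: cause under mode under effect, barriers AND-ed", {
  # minimal chain: exactly top + fault event + basic event
  one <- list(simple_fm("solo"))
  tree <- build_fault_tree(one, tiny_vocab(), "harm")
  expect_identical(nrow(tree$nodes), 3L)
  expect_identical(sort(tree$nodes$level),
                   c("basic_event", "fault_event", "top"))
  expect_identical(tree$nodes$gate[tree$nodes$level == "top"], "OR")
  expect_identical(tree$nodes$gate[tree$nodes$level == "fault_event"], "AND")

  # two contributors: two fault events under the OR top
  two <- list(simple_fm("a"), simple_fm("b"))
  tree2 <- build_fault_tree(two, tiny_vocab(), "harm")
  expect_identical(sum(tree2$nodes$parent %in% "top", na.rm = TRUE), 2L)
  expect_identical(nrow(tree2$branches), 2L)

  # barriers become AND-ed leaves carrying their miss probability
  treev <- build_fault_tree(list(vial_exchange_fm()), tiny_vocab(), "harm")
  bars <- treev$nodes[treev$nodes$level == "barrier_event", ]
  expect_identical(nrow(bars), 2L)
  expect_setequal(bars$prob, c(0.01, 0.002))

  expect_error(build_fault_tree(one, tiny_vocab(), "rework"),
               "no failure mode references")
  expect_error(build_fault_tree(one, tiny_vocab(), "ghost"), "unknown effect")
})

test_that("branch and top-event rates follow the rare-event OR sum", {
  a <- assess(vial_exchange_fm(), default_rs)
  expect_equal(branch_n_eff(a), 2e-9)
  expect_equal(branch_n_eff(a), a$p_occ_residual * a$p_nondet_residual)

  fms <- list(simple_fm("a", 5, 4, 7), simple_fm("b", 6, 2, 5))
  tree <- build_fault_tree(fms, tiny_vocab(), "harm")
  reg <- assess_all(fms, default_rs)
  expect_equal(top_event_rate(tree, reg), sum(reg$N_eff))

  # single branch: the sum is that branch's rate
  t1 <- build_fault_tree(fms[1], tiny_vocab(), "harm")
  expect_equal(top_event_rate(t1, reg), reg$N_eff[reg$id == "a"])

  # exact OR differs from the sum in fourth decimal at rates 0.01 and 0.02
  certain <- list(
    simple_fm("c1", 5, 1, 1, barriers = list()), simple_fm("c2", 5, 1, 1))
  certain[[1]]$p_occ_initial <- 0.01; certain[[1]]$p_miss_initial <- 1
  certain[[2]]$p_occ_initial <- 0.02; certain[[2]]$p_miss_initial <- 1
  tc <- build_fault_tree(certain, tiny_vocab(), "harm")
  regc <- assess_all(certain, default_rs)
  expect_equal(top_event_rate(tc, regc), 0.03)
  expect_equal(top_event_rate(tc, regc, exact = TRUE), 1 - 0.99 * 0.98)

  # pathological inputs clamp at certainty with a warning
  big <- lapply(1:3, function(i) {
    fm <- simple_fm(paste0("big", i))
    fm$p_occ_initial <- 0.9; fm$p_miss_initial <- 0.9
    fm
  })
  tb <- build_fault_tree(big, tiny_vocab(), "harm")
  expect_warning(r <- top_event_rate(tb, assess_all(big, default_rs)),
                 "clamping")
  expect_identical(r, 1)

  expect_error(top_event_rate(tree, reg[reg$id == "a", ]), "no assessment")
})

test_that("rare-event summation tracks the exact OR to within a permille", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    fms <- lapply(seq_len(n), function(i) {
      fm <- simple_fm(sprintf("r%02d", i))
      fm$p_occ_initial <- 10^runif(1, -5, -3)
      fm$p_miss_initial <- 10^runif(1, -3, 0)
      fm
    })
    tree <- build_fault_tree(fms, tiny_vocab(), "harm")
    reg <- assess_all(fms, default_rs)
    s <- top_event_rate(tree, reg)
    e <- top_event_rate(tree, reg, exact = TRUE)
    expect_lt(abs(s - e) / e, 1e-3)
  }
})

test_that("events per year scale with patient throughput", {
  expect_equal(events_per_year(2e-9, 100), 2e-7)
  expect_equal(events_per_year(0.123, 1), 0.123)
  expect_equal(events_per_year(1e-4, 14000), 1.4)
  expect_error(events_per_year(0.1, 0), "positive")
})

test_that("severity filtering keeps branches strictly above the threshold", {
  fms <- list(simple_fm("s5", 5, 4, 7), simple_fm("s6", 6, 2, 5))
  tree <- build_fault_tree(fms, tiny_vocab(), "harm")
  reg <- assess_all(fms, default_rs)

  kept <- filter_branches_by_severity(tree, 5)
  expect_identical(kept$branches$failure_mode_id, "s6")
  expect_equal(top_event_rate(kept, reg), reg$N_eff[reg$id == "s6"])

  incl <- filter_branches_by_severity(tree, 5, inclusive = TRUE)
  expect_identical(nrow(incl$branches), 2L)

  expect_identical(filter_branches_by_severity(tree, 0)$branches,
                   tree$branches)
  none <- filter_branches_by_severity(tree, 10)
  expect_identical(nrow(none$branches), 0L)
  expect_identical(none$label, tree$label)  # top label preserved

  # OR additivity: rates over a severity partition sum to the full rate
  lo <- filter_branches_by_severity(tree, 5, inclusive = FALSE)
  hi_only <- setdiff(tree$branches$failure_mode_id,
                     lo$branches$failure_mode_id)
  expect_equal(top_event_rate(lo, reg) +
                 sum(reg$N_eff[reg$id %in% hi_only]),
               top_event_rate(tree, reg))
})

test_that("fault trees convert back to failure chains losslessly", {
  fms <- list(vial_exchange_fm(), simple_fm("a", 5, 4, 7))
  tree <- build_fault_tree(fms, tiny_vocab(), "harm")
  back <- tree_to_table(tree)
  expect_identical(vapply(back, `[[`, character(1), "id"), c("a", "vx"))
  orig <- fms[order(vapply(fms, `[[`, character(1), "id"))]
  expect_equal(back, orig)

  # build -> table -> build is idempotent
  tree2 <- build_fault_tree(back, tiny_vocab(), "harm")
  expect_equal(tree2, tree)

  # minimal 3-node tree recovers one barrier-free row
  mini <- tree_to_table(build_fault_tree(list(simple_fm("m")), tiny_vocab(),
                                         "harm"))
  expect_identical(length(mini), 1L)
  expect_identical(length(mini[[1]]$barriers), 0L)
})

test_that("DOT and JSON exports are deterministic and well formed", {
  tree <- build_fault_tree(list(vial_exchange_fm(), simple_fm("a")),
                           tiny_vocab(), "harm")
  dot1 <- tree_to_dot(tree)
  expect_identical(dot1, tree_to_dot(tree))
  expect_match(dot1, "digraph fault_tree")
  expect_match(dot1, "doubleoctagon")
  expect_match(dot1, "\\[AND\\]")
  expect_match(dot1, "\\[OR\\]")

  js <- tree_to_json(tree)
  expect_identical(js, tree_to_json(tree))
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(parsed$top_event, "harm")
  expect_identical(parsed$tree$level, "top")
  expect_length(parsed$tree$children, 2L)
})
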