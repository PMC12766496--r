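test_that("packaged templates carry the expected process and register sizes", {
  d <- load_template("nm_diagnostic")
  expect_identical(length(d$process_map), 7L)
  expect_identical(length(d$failure_modes), 13L)
  expect_identical(d$scenario, "diagnostic")

  t <- load_template("nm_therapeutic")
  expect_identical(length(t$process_map), 8L)
  expect_identical(length(t$failure_modes), 20L)
  expect_identical(t$scenario, "therapeutic")

  expect_error(load_template("nm_unknown"))

  # every step declares functions; orders are unique
  for (prj in list(d, t)) {
    expect_identical(length(validate_project(prj)), 0L)
    expect_true(all(vapply(prj$process_map,
                           function(s) length(s$functions) > 0, logical(1))))
  }
})

test_that("the therapeutic register reproduces the worked RPNs through the engine", {
  t <- load_template("nm_therapeutic")
  reg <- assess_all(t$failure_modes, t$rating_system, t$effect_vocab)
  expect_identical(reg$RPN_in[reg$id == "t01"], 140L)
  expect_identical(reg$S[reg$id == "t01"], 5L)
  expect_identical(reg$O_in[reg$id == "t01"], 4L)
  expect_identical(reg$D_in[reg$id == "t01"], 7L)
  expect_identical(reg$RPN_in[reg$id == "t02"], 60L)
  # both administration chains share the temporary-adverse-effect top event
  fmes <- fmes_summarize(t$failure_modes, t$effect_vocab)
  expect_identical(fmes$n_causes[fmes$effect_id == "temporary_adverse_effect"],
                   2L)
})

test_that("the vial-exchange chain in the template reproduces the barrier arithmetic", {
  t <- load_template("nm_therapeutic")
  a <- assess(template_fm(t, "t03"), t$rating_system, t$effect_vocab)
  expect_equal(a$p_occ_initial, 1e-4)
  expect_equal(a$p_occ_residual, 1e-6)
  expect_equal(a$p_nondet_residual, 0.002)
  expect_identical(a$detectability_residual, 2L)
  expect_equal(a$n_eff, 2e-9)
})

test_that("register score ranges stay inside the template design envelopes", {
  d <- load_template("nm_diagnostic")
  regd <- assess_all(d$failure_modes, d$rating_system, d$effect_vocab)
  expect_true(all(regd$O_in %in% 1:2))
  expect_true(all(regd$D_in %in% 1:4))
  expect_identical(range(regd$RPN_in), c(1L, 20L))

  t <- load_template("nm_therapeutic")
  regt <- assess_all(t$failure_modes, t$rating_system, t$effect_vocab)
  expect_true(all(regt$D_in %in% 1:10))
  expect_identical(range(regt$RPN_in), c(36L, 324L))
})

test_that("questionnaire generation respects ranges, roles and the seed", {
  q <- generate_questionnaire("diagnostic", n_raters = 6, n_events = 13,
                              seed = 7)
  expect_identical(nrow(q), 78L)
  expect_true(all(q$occurrence %in% 1:2))
  expect_true(all(q$detectability <= 4))
  expect_identical(sort(unique(q$professional)),
                   sort(c("physician", "nurse", "administrative", "technician",
                          "radiopharmacist", "medical physicist")))
  expect_identical(q, generate_questionnaire("diagnostic", 6, 13, seed = 7))
  expect_false(identical(q, generate_questionnaire("diagnostic", 6, 13,
                                                   seed = 8)))

  # therapeutic defaults stay on the 1..10 scales, so all RPNs are in range
  qt <- generate_questionnaire("therapeutic", 1, 20, seed = 3)
  rpn <- qt$severity * qt$occurrence * qt$detectability
  expect_true(all(rpn >= 1 & rpn <= 1000))

  # large draw: every score falls inside the configured ranges
  big <- generate_questionnaire("diagnostic", 10, 1000, seed = 99)
  expect_identical(nrow(big), 10000L)
  expect_true(all(big$severity %in% 1:10))
  expect_true(all(big$occurrence %in% 1:2))
  expect_true(all(big$detectability %in% 1:4))
  expect_true(all(big$chance_of_prevention >= 0 & big$chance_of_prevention < 1))

  expect_error(generate_questionnaire("diagnostic", 0, 5), "positive")
  expect_error(generate_questionnaire("diagnostic", 2, 5,
                                      score_ranges = list(S = 1:10, O = 0:2,
                                                          D = 1:4)),
               "subset of 1..10")
})

test_that("questionnaire serialization is byte-identical for equal seeds", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_questionnaire(generate_questionnaire("therapeutic", 4, 8, seed = 21), f1)
  write_questionnaire(generate_questionnaire("therapeutic", 4, 8, seed = 21), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_questionnaire(f1),
                   generate_questionnaire("therapeutic", 4, 8, seed = 21))
})

test_that("questionnaire ingestion aggregates raters into scored failure modes", {
  q <- generate_questionnaire("diagnostic", 2, 3, seed = 5)
  # two raters with identical scores: consensus equals those scores
  q$severity <- rep(c(4L, 6L, 8L), each = 2)
  q$occurrence <- 1L
  q$detectability <- 2L
  q$chance_of_prevention <- 0.99
  prj <- ingest_questionnaire(q)
  expect_identical(length(prj$failure_modes), 3L)
  fm1 <- prj$failure_modes[[1]]
  expect_identical(fm1$severity, 4L)
  expect_identical(fm1$occurrence_initial, 1L)
  expect_identical(fm1$detectability_initial, 2L)
  # stated 99 % chance of prevention becomes a 1 % miss proactive barrier
  expect_identical(length(fm1$barriers), 1L)
  expect_identical(fm1$barriers[[1]]$kind, "proactive")
  expect_equal(fm1$barriers[[1]]$p_miss, 0.01)

  # unequal scores with equal weights: S = mean(4, 6) = 5
  q2 <- q[q$hypothesized_event == "event_01", ]
  q2$severity <- c(4L, 6L)
  prj2 <- ingest_questionnaire(q2)
  expect_identical(prj2$failure_modes[[1]]$severity, 5L)

  mixed <- q
  mixed$scenario[1] <- "therapeutic"
  expect_error(ingest_questionnaire(mixed), "mix scenarios")
})
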