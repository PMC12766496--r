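test_that("projects survive save/load exactly, in JSON and YAML", {
  prj <- load_template("nm_therapeutic")
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    on.exit(unlink(path), add = TRUE)
    save_project(prj, path)
    expect_identical(load_project(path), prj)
  }

  # worked-example RPNs are preserved through persistence
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  save_project(prj, path)
  reloaded <- load_project(path)
  reg <- assess_all(reloaded$failure_modes, reloaded$rating_system,
                    reloaded$effect_vocab)
  expect_identical(reg$RPN_in[reg$id %in% c("t01", "t02")], c(140L, 60L))
  a <- assess(template_fm(reloaded, "t03"), reloaded$rating_system)
  expect_equal(a$n_eff, 2e-9)
})

test_that("loading rejects schema violations and dangling references", {
  bad <- tempfile(fileext = ".json")
  on.exit(unlink(bad), add = TRUE)
  writeLines(jsonlite::toJSON(list(name = "x", scenario = "diagnostic"),
                              auto_unbox = TRUE), bad)
  expect_error(load_project(bad), "rating_system")

  expect_error(
    risk_project("x", "diagnostic", default_rs,
                 list(process_step("s1", "step", 1, "do", "diagnostic")),
                 tiny_vocab(),
                 list(simple_fm("fm1", effect = "ghost"))),
    "unknown effect 'ghost'")
  expect_error(
    risk_project("x", "diagnostic", default_rs,
                 list(process_step("s1", "step", 1, "do", "diagnostic"),
                      process_step("s2", "step2", 1, "do", "diagnostic")),
                 tiny_vocab(), list()),
    "duplicate order")
})

test_that("reports are deterministic, ranked, and annualized per workflow", {
  prj <- load_template("nm_therapeutic")
  csv1 <- export_report(prj, format = "csv")
  expect_identical(csv1, export_report(prj, format = "csv"))
  tab <- read.csv(text = csv1)
  expect_identical(tab$RPN_in[1], 324L)      # ranked descending
  expect_true("events_per_year_ther_medium" %in% names(tab))
  expect_identical(tab$id[tab$RPN_in == 140], "t01")

  md <- export_report(prj, format = "markdown", use = "residual")
  expect_match(md, "Ranked by residual RPN")
  expect_match(md, "\\| rank \\|")

  empty <- risk_project("empty", "diagnostic", default_rs,
                        list(process_step("s1", "s", 1, "f", "diagnostic")),
                        tiny_vocab(), list())
  lines <- strsplit(export_report(empty, format = "csv"), "\n")[[1]]
  expect_identical(length(lines), 1L)        # header only
})

test_that("the CLI drives the whole pipeline deterministically", {
  tmp <- tempfile(fileext = ".json")
  dot <- tempfile(fileext = ".dot")
  qcsv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, dot, qcsv)))

  # demo writes a loadable template project
  expect_identical(suppressMessages(
    nmrisk_cli(c("demo", "--template", "nm_therapeutic", "-o", tmp))), 0L)
  expect_identical(load_project(tmp), load_template("nm_therapeutic"))

  expect_identical(nmrisk_cli(c("validate", tmp)), 0L)
  expect_identical(nmrisk_cli(c("validate", tempfile())), 1L)

  # assess prints the ranked register with the worked-example RPN on top
  out <- capture.output(status <- nmrisk_cli(c("assess", tmp)))
  expect_identical(status, 0L)
  reg <- read.csv(text = paste(out, collapse = "\n"))
  expect_identical(reg$RPN_in[1], 324L)

  # fta exports a deterministic DOT file
  expect_identical(
    nmrisk_cli(c("fta", tmp, "--effect", "temporary_adverse_effect",
                 "--dot", dot)), 0L)
  expect_match(paste(readLines(dot), collapse = "\n"), "digraph fault_tree")

  # rank over two project files
  tmp2 <- tempfile(fileext = ".json")
  on.exit(unlink(tmp2), add = TRUE)
  nmrisk_cli(c("demo", "--template", "nm_diagnostic", "-o", tmp2))
  out <- capture.output(status <- nmrisk_cli(c("rank", tmp, tmp2,
                                               "--weights", "uniform")))
  expect_identical(status, 0L)
  expect_match(out[1], "weight_scheme: uniform")

  # synthetic questionnaire: byte-identical for equal seeds
  out1 <- capture.output(nmrisk_cli(c("synth-questionnaire", "--scenario",
                                      "diagnostic", "--raters", "3",
                                      "--events", "4", "--seed", "7")))
  out2 <- capture.output(nmrisk_cli(c("synth-questionnaire", "--scenario",
                                      "diagnostic", "--raters", "3",
                                      "--events", "4", "--seed", "7")))
  expect_identical(out1, out2)

  # ingest the questionnaire into a valid project
  nmrisk_cli(c("synth-questionnaire", "--scenario", "diagnostic", "--raters",
               "3", "--events", "4", "--seed", "7", "-o", qcsv))
  prj_out <- tempfile(fileext = ".json")
  on.exit(unlink(prj_out), add = TRUE)
  expect_identical(nmrisk_cli(c("ingest", qcsv, "-o", prj_out)), 0L)
  ingested <- load_project(prj_out)
  expect_identical(length(ingested$failure_modes), 4L)

  # simulate returns a JSON payload with the requested seed
  out <- capture.output(status <- nmrisk_cli(
    c("simulate", tmp, "--effect", "temporary_adverse_effect", "--trials",
      "10000", "--seed", "3")))
  expect_identical(status, 0L)
  expect_identical(jsonlite::fromJSON(paste(out, collapse = "\n"))$seed, 3L)
})
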