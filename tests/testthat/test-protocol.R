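test_that("file-based and in-process orchestration produce identical fits", {
  co <- small_cohort(seed = 47, n = c(80L, 100L, 60L))
  for (fam in c("linear", "logistic", "cox")) {
    sp <- co$specs[[fam]]
    fm <- dra_fit(co$sites, sp, engine = "memory")
    ff <- dra_fit(co$sites, sp, engine = "files")
    expect_identical(ff$coefficients, fm$coefficients)
    expect_identical(ff$se, fm$se)
    expect_identical(ff$vcov, fm$vcov)
    expect_identical(ff$fit_statistics, fm$fit_statistics)
    expect_identical(ff$iterations, fm$iterations)
  }
})

test_that("a single-partner run equals the pooled in-process computation", {
  co <- small_cohort(seed = 49, n = c(700L))
  sp <- co$specs$logistic
  ff <- dra_fit(co$sites, sp, engine = "files")
  fp <- dra_pooled_fit(co$sites, sp)
  expect_identical(unname(ff$coefficients), unname(fp$coefficients))
  expect_identical(ff$fit_statistics, fp$fit_statistics)
})

test_that("the linear protocol writes exactly two payloads per partner", {
  co <- small_cohort(seed = 51, n = c(110L, 130L))
  wd <- withr::local_tempdir()
  f <- dra_fit(co$sites, co$specs$linear, engine = "files", workdir = wd,
               keep_workdir = TRUE)
  for (s in names(co$sites)) {
    pl <- list.files(file.path(wd, paste0("from_", s)),
                     pattern = "^payload_.*\\.dra$")
    expect_length(pl, 2L)
  }
  expect_identical(f$iterations, 2L)
})

test_that("a stop directive as first message exits cleanly with only an ack", {
  wd <- withr::local_tempdir()
  sp <- dra_spec("linear", "y", "x")
  dranet:::protocol_dirs(wd, "s1")
  dranet:::write_directive(
    c(dranet:::new_directive("stop", 0L, sp), list(seq = 1L)),
    dranet:::directive_path(wd, "s1", 1L))
  d <- data.frame(x = rnorm(5), y = rnorm(5))
  handled <- dra_run_partner(wd, "s1", d, sp, timeout = 5)
  expect_identical(handled, 1L)
  out <- list.files(file.path(wd, "from_s1"))
  expect_true(any(grepl("^ack_", out)))
  expect_false(any(grepl("^payload_", out)))
})

test_that("corrupted payloads surface a parse error naming node and round", {
  wd <- withr::local_tempdir()
  writeLines("garbage", file.path(wd, "bad.dra"))
  err <- expect_error(
    dranet:::center_read_payload(file.path(wd, "bad.dra"), "site2", 3L),
    class = "dranet_protocol_error")
  expect_match(conditionMessage(err), "site2")
  expect_match(conditionMessage(err), "3")
})

test_that("malformed directives make the partner report an error file", {
  wd <- withr::local_tempdir()
  sp <- dra_spec("linear", "y", "x")
  dranet:::protocol_dirs(wd, "s1")
  path <- dranet:::directive_path(wd, "s1", 1L)
  dranet:::write_with_trigger(function(p) writeLines("{not json", p), path)
  st <- dranet:::partner_state(
    wd, "s1", dranet:::site_env(data.frame(x = 1:4, y = rnorm(4)), sp,
                                "s1"), sp)
  expect_true(dranet:::partner_step(st))
  expect_true(file.exists(file.path(wd, "from_s1", "error_0001_s1.json")))
})

test_that("stale directive triggers are ignored with a log entry", {
  wd <- withr::local_tempdir()
  sp <- dra_spec("linear", "y", "x")
  dranet:::protocol_dirs(wd, "s1")
  env <- dranet:::site_env(data.frame(x = rnorm(6), y = rnorm(6)), sp, "s1")
  st <- dranet:::partner_state(wd, "s1", env, sp)
  d1 <- c(dranet:::new_directive("compute_intermediates", 0L, sp),
          list(seq = 1L))
  dranet:::write_directive(d1, dranet:::directive_path(wd, "s1", 1L))
  expect_true(dranet:::partner_step(st))          # processes round 1
  d2 <- c(dranet:::new_directive("compute_diagnostics", 1L, sp,
                                 beta = c(0, 0)), list(seq = 2L))
  dranet:::write_directive(d2, dranet:::directive_path(wd, "s1", 2L))
  expect_true(dranet:::partner_step(st))          # processes round 2
  # re-deliver the round-1 trigger: it is stale and must be ignored
  file.create(paste0(dranet:::directive_path(wd, "s1", 1L), ".trigger"))
  expect_false(dranet:::partner_step(st))
  log <- dranet:::read_log_file(file.path(wd, "from_s1", "log_s1.jsonl"))
  expect_true(all(c("download", "compute", "upload") %in% log$step))
  expect_true("stale_ignored" %in% log$step)
})

test_that("center collection times out with the missing nodes named", {
  wd <- withr::local_tempdir()
  dranet:::protocol_dirs(wd, c("s1", "s2"))
  sp <- dra_spec("linear", "y", "x")
  collect <- dranet:::center_collect_factory(wd, c("s1", "s2"), sp,
                                             timeout = 0.3)
  err <- expect_error(
    collect(dranet:::new_directive("compute_intermediates", 0L, sp)),
    class = "dranet_timeout_error")
  expect_match(conditionMessage(err), "s1, s2")
})

test_that("transfer directories contain only protocol-schema files", {
  co <- small_cohort(seed = 53, n = c(60L, 80L))
  wd <- withr::local_tempdir()
  dra_fit(co$sites, co$specs$logistic, engine = "files", workdir = wd,
          keep_workdir = TRUE)
  audit <- dra_audit_workdir(wd)
  expect_true(attr(audit, "clean"))
  expect_gt(nrow(audit), 10)
  expect_true(all(audit$type %in% c("directive", "payload", "trigger",
                                    "ack/error", "log")))
  # planting a row-level file is caught
  utils::write.csv(co$sites[[1]],
                   file.path(wd, "from_site1", "leak.csv"))
  audit2 <- dra_audit_workdir(wd)
  expect_false(attr(audit2, "clean"))
  expect_identical(audit2$type[!audit2$ok], "unknown")
})

test_that("timing summaries reduce the transfer log correctly", {
  one <- data.frame(node = "s1", node_class = "partner", iteration = 0L,
                    step = "compute", start = 10, end = 12.5)
  s <- summarize_timings(one)
  expect_equal(s$mean, 2.5)
  expect_equal(s$se, 0)

  log <- rbind(
    data.frame(node = "c", node_class = "center", iteration = 0:1,
               step = "upload", start = c(0, 10), end = c(1, 13)),
    data.frame(node = "s1", node_class = "partner", iteration = 0:1,
               step = "compute", start = c(2, 11), end = c(4, 17)))
  s2 <- summarize_timings(log)
  up <- s2[s2$node_class == "center" & s2$step == "upload", ]
  expect_equal(up$mean, 2)                      # (1 + 3) / 2
  expect_equal(up$se, stats::sd(c(1, 3)) / sqrt(2))
  cm <- s2[s2$node_class == "partner" & s2$step == "compute", ]
  expect_equal(cm$mean, 4)                      # (2 + 6) / 2
  # absent categories are absent, not zero
  expect_false("download" %in% s2$step)
  expect_identical(nrow(s2), 2L)
})

test_that("a full timing report carries all four step categories", {
  co <- small_cohort(seed = 57, n = c(40L, 40L))
  f <- dra_fit(co$sites, co$specs$linear, engine = "files")
  s <- summarize_timings(f$transfer_log)
  expect_true(all(c("download", "compute", "upload") %in%
                    s$step[s$node_class == "partner"]))
  expect_true(all(c("download", "compute", "upload") %in%
                    s$step[s$node_class == "center"]))
  expect_true("transfer" %in% s$step)
  expect_gt(attr(s, "total_time"), 0)
})

test_that("separate partner processes reproduce the cooperative fit", {
  co <- small_cohort(seed = 59, n = c(90L, 110L, 80L))
  sim <- dra_simulate("linear", seed = 59, mode = "processes",
                      n_per_site = c(90L, 110L, 80L), timeout = 90)
  ref <- dra_fit(co$sites, co$specs$linear, engine = "files")
  # partner processes read their data back from CSV, which perturbs
  # doubles in the last digit or two; agreement is still far below the
  # equivalence bound
  expect_equal(unname(sim$fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-9)
  expect_identical(sim$fit$iterations, ref$iterations)
  expect_true(sim$comparison$pass)
  expect_lt(sim$comparison$max_abs_diff, 1e-6)
})
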