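test_that("identical seed and config give a byte-identical bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_faers(sim_config(seed = 42, n_reports = 500), dir = d1)
  simulate_faers(sim_config(seed = 42, n_reports = 500), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_faers(sim_config(seed = 43, n_reports = 500), dir = d3)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d3, "DEMO.txt"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_faers(sim_config(seed = 5, n_reports = 50)))
  expect_identical(stats::runif(1), before)
})

test_that("expected_ror is closed-form consistent and invariant as planned", {
  cfg <- sim_config(seed = 1, n_reports = 10000)
  e <- expected_ror(cfg, "Nausea")
  cells <- e$expected
  expect_equal((cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]]),
               e$or, tolerance = 1e-12)
  # OR = 1 gives cross-product ratio exactly 1
  ev <- cfg$events; ev$or[1] <- 1
  cfg1 <- sim_config(seed = 1, n_reports = 10000, events = ev)
  e1 <- expected_ror(cfg1, ev$pt[1])
  cells1 <- e1$expected
  expect_equal((cells1[["a"]] * cells1[["d"]]) /
                 (cells1[["b"]] * cells1[["c"]]), 1, tolerance = 1e-12)
  # doubling the background probability leaves the planned OR unchanged
  ev2 <- cfg$events; ev2$p0 <- ev2$p0 * 2
  cfg2 <- sim_config(seed = 1, n_reports = 10000, events = ev2)
  expect_equal(expected_ror(cfg2, "Nausea")$or, e$or)
  expect_error(expected_ror(cfg, "No such PT"), "unknown PT")
})

test_that("Monte-Carlo cell means match the closed-form expectation", {
  cfg <- sim_config(seed = 0, n_reports = 10000, duplicate_rate = 0,
                    deleted_rate = 0)
  e <- expected_ror(cfg, "Nausea")
  acc <- matrix(0, 200, 2)
  for (i in 1:200) {
    sim <- simulate_faers(sim_config(seed = i, n_reports = 10000,
                                     duplicate_rate = 0, deleted_rate = 0))
    r <- sim$truth$realized
    acc[i, ] <- unlist(r[r$pt == "Nausea", c("a", "c")])
  }
  expect_equal(mean(acc[, 1]), e$expected[["a"]], tolerance = 0.02)
  expect_equal(mean(acc[, 2]), e$expected[["c"]], tolerance = 0.02)
})

test_that("planted duplicates and deletions reconcile after deduplication", {
  cfg <- sim_config(seed = 99, n_reports = 2000, duplicate_rate = 0.1,
                    deleted_rate = 0.02)
  sim <- simulate_faers(cfg)
  uni <- deduplicate_cases(sim$bundle)
  expect_equal(nrow(uni$cases), sim$truth$n_unique_cases)
  expect_equal(uni$n_removed_duplicates,
               length(sim$truth$duplicate_caseids))
  expect_equal(nrow(uni$cases), 2000 - length(sim$truth$deleted_caseids))
  # the surviving version of a duplicated case is the higher primaryid
  dup <- setdiff(sim$truth$duplicate_caseids, sim$truth$deleted_caseids)
  kept <- uni$cases$primaryid[match(dup, uni$cases$caseid)]
  expect_true(all(kept %% 10 == 2))
})

test_that("generated dates are consistent except for the planted corruption", {
  cfg <- sim_config(seed = 7, n_reports = 4000, miss_event_date = 0,
                    miss_start_date = 0, partial_start_date = 0,
                    corrupt_date = 0)
  sim <- simulate_faers(cfg)
  uni <- deduplicate_cases(sim$bundle)
  scfg <- sema_config()
  ids <- match_target_cases(uni, scfg)
  sel <- select_target_events(uni$reac, gi_map(), scfg$target_soc)
  s <- compute_tto(uni, ids, sel$events[sel$events$primaryid %in% ids, ],
                   scfg)
  excl <- attr(s, "exclusions")
  expect_equal(sum(excl), 0)
  expect_true(all(s$tto_days >= 0))
})

test_that("the full pipeline recovers strongly injected signals", {
  # planned OR >= 5 with 20,000 reports: positive signal in >= 95% of runs
  cfg0 <- sim_config(seed = 1)
  strong <- cfg0$events$pt[cfg0$events$or >= 5 &
                             cfg0$events$p0 * 20000 * 0.05 >= 15]
  hits <- 0; trials <- 0
  scfg <- sema_config()
  for (s in 1:20) {
    sim <- simulate_faers(sim_config(seed = 100 + s))
    uni <- deduplicate_cases(sim$bundle)
    ids <- match_target_cases(uni, scfg)
    sel <- select_target_events(uni$reac, gi_map(), scfg$target_soc)
    sc <- screen_signals(uni, ids, sel$events, scfg)
    for (pt in strong) {
      trials <- trials + 1
      if (isTRUE(sc$is_signal[match(pt, sc$term)])) hits <- hits + 1
    }
  }
  expect_gte(hits / trials, 0.95)
})

test_that("invalid configurations fail before anything is generated", {
  expect_error(sim_config(target_share = 1.2), "probabilities")
  ev <- sim_config()$events
  ev$or[1] <- -1
  expect_error(sim_config(events = ev), "odds ratios")
  expect_error(sim_config(n_reports = 0), "n_reports")
})
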