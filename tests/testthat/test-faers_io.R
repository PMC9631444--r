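test_that("a generated bundle on disk parses back with the generator's counts", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 1, n_reports = 100, duplicate_rate = 0,
                    deleted_rate = 0)
  sim <- simulate_faers(cfg, dir = dir)
  bundle <- read_faers_bundle(dir)
  expect_equal(nrow(bundle$demo), 100)
  expect_equal(bundle$parse_report$demo$n_rows, 100)
  expect_equal(bundle$parse_report$demo$n_skipped, 0)
  for (tb in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    expect_equal(bundle[[tb]], sim$bundle[[tb]], ignore_attr = TRUE)
  }
  expect_equal(bundle$deleted_caseids, sim$bundle$deleted_caseids)
})

test_that("an empty table parses to zero records without error", {
  dir <- withr::local_tempdir()
  writeLines("primaryid$caseid$pt", file.path(dir, "REAC.txt"))
  reac <- read_faers_table(file.path(dir, "REAC.txt"), "reac")
  expect_equal(nrow(reac), 0)
  expect_equal(attr(reac, "n_skipped"), 0)
})

test_that("malformed lines and non-numeric ids are skipped and counted", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$pt",
               "1230001$123$Nausea",
               "only$two",
               "abc$124$Vomiting",
               "1240001$124$Vomiting"),
             file.path(dir, "REAC.txt"))
  reac <- read_faers_table(file.path(dir, "REAC.txt"), "reac")
  expect_equal(nrow(reac), 2)
  expect_equal(attr(reac, "n_skipped"), 1)
  expect_equal(attr(reac, "n_bad_id"), 1)
})

test_that("unknown headers, missing columns and missing tables are fatal", {
  dir <- withr::local_tempdir()
  writeLines("primaryid$caseid$pt$bogus_col", file.path(dir, "REAC.txt"))
  expect_error(read_faers_table(file.path(dir, "REAC.txt"), "reac"),
               "unknown column")
  writeLines("primaryid$caseid", file.path(dir, "REAC2.txt"))
  expect_error(read_faers_table(file.path(dir, "REAC2.txt"), "reac"),
               "missing mandatory column")
  expect_error(read_faers_bundle(dir), "mandatory FAERS table missing")
})

test_that("deduplication keeps the highest primaryid and honours deletions", {
  uni <- deduplicate_cases(tiny_bundle())
  expect_equal(nrow(uni$cases), 4)
  kept_555 <- uni$cases[uni$cases$caseid == 555, ]
  expect_equal(kept_555$primaryid, 5550002)
  expect_equal(uni$n_removed_duplicates, 1)
  # child tables follow the surviving version
  expect_setequal(uni$reac$pt[uni$reac$primaryid == 5550002],
                  c("Nausea", "Vomiting"))
  expect_false(5550001 %in% uni$reac$primaryid)

  uni_del <- deduplicate_cases(tiny_bundle(deleted = c(556, 999)))
  expect_false(556 %in% uni_del$cases$caseid)
  expect_equal(uni_del$n_removed_deleted, 1)
})

test_that("deduplication is idempotent and independent of row order", {
  base <- deduplicate_cases(tiny_bundle())
  tabs <- tiny_tables()
  set.seed(11)
  for (i in 1:10) {
    shuf <- tabs
    shuf$demo <- shuf$demo[sample.int(nrow(shuf$demo)), , drop = FALSE]
    uni <- deduplicate_cases(as_faers_bundle(shuf))
    expect_setequal(uni$cases$primaryid, base$cases$primaryid)
  }
  # cases <= distinct caseids, equality iff deletion list disjoint
  expect_lte(nrow(base$cases), length(unique(tabs$demo$caseid)))
  expect_equal(nrow(base$cases), length(unique(tabs$demo$caseid)))
})

test_that("same-primaryid duplicate rows resolve to the last-read row", {
  tabs <- tiny_tables()
  extra <- tabs$demo[tabs$demo$primaryid == 5570001, ]
  extra$age <- "46"
  tabs$demo <- rbind(tabs$demo, extra)
  uni <- deduplicate_cases(as_faers_bundle(tabs))
  expect_equal(uni$cases$age_years[uni$cases$caseid == 557], 46)
})

test_that("age and weight convert to analysis units, degrading to missing", {
  expect_equal(convert_age_years(744, "MON"), 62)
  expect_equal(convert_age_years(6.2, "DEC"), 62)
  expect_equal(round(convert_weight_kg(212, "LBS"), 2), 96.16)
  expect_equal(convert_weight_kg(70500, "GMS"), 70.5)
  expect_true(is.na(convert_age_years("abc", "YR")))
  expect_true(is.na(convert_age_years(50, "FORTNIGHT")))
  expect_true(is.na(convert_weight_kg(-3, "KG")))
})

test_that("only complete 8-digit dates parse; the year survives partials", {
  p <- parse_faers_date(c("20180324", "2018", "201803", "20181340", "", "x"))
  expect_equal(p$date[1], as.Date("2018-03-24"))
  expect_true(all(is.na(p$date[-1])))
  expect_equal(p$year, c(2018L, 2018L, 2018L, 2018L, NA, NA))
})

test_that("writing and re-loading a bundle reproduces every field", {
  dir <- withr::local_tempdir()
  sim <- simulate_faers(sim_config(seed = 3, n_reports = 200))
  write_faers_bundle(sim$bundle, dir)
  back <- read_faers_bundle(dir)
  for (tb in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    expect_equal(back[[tb]], sim$bundle[[tb]], ignore_attr = TRUE)
  }
  expect_equal(back$deleted_caseids, sim$bundle$deleted_caseids)
})
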