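test_that("seriousness classification follows the outcome-code mapping", {
  tabs <- tiny_tables()
  uni <- deduplicate_cases(as_faers_bundle(tabs))
  lab <- classify_seriousness(uni)
  row556 <- lab[lab$primaryid == 5560001, ]
  expect_true(row556$serious)
  expect_equal(row556$categories, "hospitalization,other")
  row558 <- lab[lab$primaryid == 5580001, ]
  expect_equal(row558$categories, "death")
  # a case with no OUTC record is non-serious
  row555 <- lab[lab$primaryid == 5550002, ]
  expect_false(row555$serious)
  expect_equal(row555$categories, "")
  # unknown codes count as "other", with a warning
  tabs$outc <- rbind(tabs$outc,
                     data.frame(primaryid = 5550002, caseid = 555,
                                outc_cod = "ZZ"))
  uni2 <- deduplicate_cases(as_faers_bundle(tabs))
  expect_warning(lab2 <- classify_seriousness(uni2), "unknown outcome code")
  expect_equal(lab2$categories[lab2$primaryid == 5550002], "other")
})

test_that("the chi-squared statistic equals the closed 2x2 formula", {
  closed <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  set.seed(8)
  for (i in 1:20) {
    cells <- sample(5:400, 4)
    got <- pearson_chi2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$statistic, closed(cells[1], cells[2], cells[3],
                                       cells[4]), tolerance = 1e-10)
    # invariance under swapping rows and under swapping columns
    expect_equal(pearson_chi2(cells[3], cells[4], cells[1],
                              cells[2])$statistic, got$statistic)
    expect_equal(pearson_chi2(cells[2], cells[1], cells[4],
                              cells[3])$statistic, got$statistic)
  }
  expect_equal(pearson_chi2(50, 50, 100, 100)$statistic, 0)
  expect_error(pearson_chi2(0, 0, 10, 20), "zero margin")
})

test_that("Fisher p matches hypergeometric enumeration on small tables", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = rep(0.25, 4)))
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_equal(got, fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact(0, 10, 0, 20)$p_value, 1)
})

test_that("Mann-Whitney Z has the documented sign and tie-safe p-values", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u, 0)
  expect_lt(sep$statistic, 0)
  same <- mann_whitney(rep(3, 5), rep(3, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(15)
  x <- stats::rnorm(500)
  y <- stats::rnorm(500, mean = 0.3)
  mw <- mann_whitney(x, y)
  expect_lt(mw$p_value, 0.01)
  expect_lt(mw$statistic, 0)
  # agrees with the standard normal-approximation implementation
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)

  # close to the exact permutation distribution on a small sample
  set.seed(16)
  xs <- stats::rnorm(7); ys <- stats::rnorm(7, 1)
  perm_stats <- apply(utils::combn(14, 7), 2, function(idx) {
    sum(rank(c(xs, ys))[idx])
  })
  obs <- sum(rank(c(xs, ys))[1:7])
  p_perm <- mean(abs(perm_stats - mean(perm_stats)) >=
                   abs(obs - mean(perm_stats)))
  expect_equal(mann_whitney(xs, ys)$p_value, p_perm, tolerance = 0.03)
})

test_that("test auto-selection uses the expected-count rule per PT", {
  sev <- gi_severity()
  n_s <- 1778; n_ns <- 3664
  chosen <- mapply(function(a, cc) {
    select_test(a, n_s - a, cc, n_ns - cc)
  }, sev$serious_n, sev$nonserious_n)
  expect_equal(unname(chosen), sev$test)
})

test_that("the severity comparison table is internally consistent", {
  sim <- simulate_faers(sim_config(seed = 31, n_reports = 8000))
  uni <- deduplicate_cases(sim$bundle)
  cfg <- sema_config()
  ids <- match_target_cases(uni, cfg)
  sel <- select_target_events(uni$reac, gi_map(), cfg$target_soc)
  ev <- sel$events[sel$events$primaryid %in% ids, ]
  lab <- classify_seriousness(uni, ids)
  cmp <- compare_event_severity(ev, lab, ids)
  expect_true(all(cmp$test %in% c("pearson-chi2", "fisher-exact")))
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  # per-PT totals recompute from the event table
  for (i in seq_len(nrow(cmp))) {
    ids_pt <- unique(ev$primaryid[toupper(ev$pt) == toupper(cmp$pt[i])])
    expect_equal(cmp$serious_n[i] + cmp$nonserious_n[i], length(ids_pt))
  }
  # serious percentages use the serious-arm denominator
  n_serious <- sum(lab$serious)
  expect_equal(cmp$serious_pct,
               round(100 * cmp$serious_n / n_serious, 2))
})
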