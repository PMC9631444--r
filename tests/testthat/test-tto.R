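test_that("TTO is whole days from first therapy start, with exclusions counted", {
  uni <- deduplicate_cases(tiny_bundle())
  cfg <- sema_config()
  ids <- match_target_cases(uni, cfg)
  sel <- select_target_events(uni$reac, gi_map(), cfg$target_soc)
  ev <- sel$events[sel$events$primaryid %in% ids, ]
  s <- compute_tto(uni, ids, ev, cfg)
  # case 555: start 2018-03-01, event 2018-03-24 -> 23 days, two PTs
  expect_equal(sort(unique(s$pt[s$primaryid == 5550002])),
               c("Nausea", "Vomiting"))
  expect_true(all(s$tto_days[s$primaryid == 5550002] == 23))
  # case 556: partial event date ("2018") -> excluded as missing
  expect_false(5560001 %in% s$primaryid)
  excl <- attr(s, "exclusions")
  expect_equal(unname(excl["missing_event_date"]), 1)
  # emitted + excluded = candidate pairs; never negative
  expect_equal(nrow(s) + sum(excl), nrow(ev))
  expect_true(all(s$tto_days >= 0))
})

test_that("partial therapy start dates are excluded as inaccurate entries", {
  tabs <- tiny_tables()
  tabs$demo$event_dt[tabs$demo$primaryid == 5560001] <- "20180610"
  uni <- deduplicate_cases(as_faers_bundle(tabs))
  cfg <- sema_config()
  ids <- match_target_cases(uni, cfg)
  sel <- select_target_events(uni$reac, gi_map(), cfg$target_soc)
  s <- compute_tto(uni, ids, sel$events[sel$events$primaryid %in% ids, ], cfg)
  # case 556's THER start is "201803": year-month only, no usable day
  expect_false(5560001 %in% s$primaryid)
  expect_equal(unname(attr(s, "exclusions")["missing_start_date"]), 1)
})

test_that("events dated before therapy start are excluded as input errors", {
  tabs <- tiny_tables()
  tabs$demo$event_dt[tabs$demo$primaryid == 5550002] <- "20180215"
  uni <- deduplicate_cases(as_faers_bundle(tabs))
  cfg <- sema_config()
  ids <- match_target_cases(uni, cfg)
  sel <- select_target_events(uni$reac, gi_map(), cfg$target_soc)
  s <- compute_tto(uni, ids, sel$events[sel$events$primaryid %in% ids, ], cfg)
  expect_false(5550002 %in% s$primaryid)
  expect_equal(unname(attr(s, "exclusions")["event_before_start"]), 2)
})

test_that("TTO summaries use linear-interpolation quantiles", {
  s <- summarize_tto(c(0, 2, 23, 92, 833))
  expect_equal(s$median, 23)
  expect_equal(s$min, 0)
  expect_equal(s$max, 833)
  s7 <- summarize_tto(rep(7, 12))
  expect_equal(s7$median, 7)
  expect_equal(c(s7$q1, s7$q3), c(7, 7))
  expect_error(summarize_tto(numeric(0)), "no TTO samples")
})

test_that("the Weibull MLE recovers known parameters", {
  set.seed(9)
  fit <- fit_weibull_tto(stats::rweibull(2000, shape = 0.34, scale = 8))
  expect_gt(fit$shape, 0.32); expect_lt(fit$shape, 0.36)
  expect_gt(fit$scale, 7.2); expect_lt(fit$scale, 8.8)
  expect_equal(fit$failure_type, "early")

  # exponential limit: the shape CI contains 1
  set.seed(10)
  fit1 <- fit_weibull_tto(stats::rweibull(2000, shape = 1, scale = 5))
  expect_lte(fit1$shape_ci[1], 1)
  expect_gte(fit1$shape_ci[2], 1)

  expect_error(suppressWarnings(fit_weibull_tto(rep(5, 5))), "degenerate")
})

test_that("the fit is scale-equivariant", {
  set.seed(12)
  t <- stats::rweibull(400, 0.5, 10)
  f1 <- fit_weibull_tto(t)
  f2 <- fit_weibull_tto(t * 3)
  expect_equal(f2$scale, 3 * f1$scale, tolerance = 1e-6)
  expect_equal(f2$shape, f1$shape, tolerance = 1e-6)
})

test_that("the analytic information matrix matches numerical curvature", {
  skip_if_not_installed("pracma")
  set.seed(13)
  t <- stats::rweibull(300, 0.6, 12)
  fit <- fit_weibull_tto(t)
  x <- log(t)
  num <- pracma::hessian(function(p)
    faersignal:::.weibull_loglik(p[1], p[2], x),
    c(log(fit$scale), log(fit$shape)))
  ana <- faersignal:::.weibull_hessian(log(fit$scale), log(fit$shape), x)
  expect_equal(ana, num, tolerance = 1e-5)
})

test_that("estimates agree with an independent Weibull fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(14)
  t <- stats::rweibull(1000, 0.45, 9)
  fit <- fit_weibull_tto(t)
  ref <- fitdistrplus::fitdist(t, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 2e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 2e-3)
  # the profile-likelihood optimum is at least as good as the reference's
  expect_gte(fit$loglik, ref$loglik - 1e-6)
})

test_that("failure types follow the shape CI against 1", {
  mk <- function(lo, hi) structure(list(shape_ci = c(lo, hi)),
                                   class = "weibull_tto")
  expect_equal(classify_failure_type(mk(0.34, 0.46)), "early")
  expect_equal(classify_failure_type(mk(0.90, 1.10)), "random")
  expect_equal(classify_failure_type(mk(1.20, 1.80)), "wear-out")
})

test_that("band-pooled TTO rows carry summaries and fits", {
  set.seed(15)
  samples <- data.frame(
    pt = rep(c("Pancreatitis", "Nausea", "Dry mouth"), each = 60),
    tto_days = c(round(stats::rweibull(60, 0.4, 30)),
                 round(stats::rweibull(60, 0.4, 9)),
                 round(stats::rweibull(60, 0.4, 9))))
  scores <- data.frame(pt = c("Pancreatitis", "Nausea", "Dry mouth"),
                       band = c("strong", "moderate", "weak"))
  tab <- tto_by_band(samples, scores)
  expect_equal(tab$band, c("strong", "moderate", "weak"))
  expect_equal(tab$n, rep(60L, 3))
  expect_true(all(tab$q1 <= tab$median & tab$median <= tab$q3))
  expect_true(all(tab$min <= tab$q1 & tab$q3 <= tab$max))
  expect_true(all(is.finite(tab$beta)))
})
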