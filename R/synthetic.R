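# Synthetic FAERS bundle generator with known ground truth.
#
# Reports are generated one primary-suspect drug per report.  Each study PT
# is drawn per report as an independent Bernoulli whose probability is
# odds-scaled for target-drug reports, so every injected reporting odds
# ratio has a closed-form expected 2x2.  A filler reaction drawn from a
# non-target vocabulary guarantees every report carries at least one PT
# without disturbing the study PTs' tables.

.default_events <- function() {
  data.frame(
    pt = c("Nausea", "Vomiting", "Diarrhoea", "Constipation",
           "Abdominal pain", "Pancreatitis", "Eructation"),
    soc = "Gastrointestinal disorders",
    p0 = c(0.030, 0.020, 0.020, 0.010, 0.010, 0.002, 0.001),
    or = c(8, 7, 4, 6, 3.5, 20, 40),
    p_serious = c(0.30, 0.35, 0.30, 0.25, 0.40, 0.85, 0.20),
    p_death = c(0.001, 0.002, 0.001, 0.001, 0.002, 0.01, 0),
    tto_shape = c(0.40, 0.40, 0.35, 0.40, 0.40, 0.45, 0.35),
    tto_scale = c(8, 8, 6, 10, 10, 30, 8),
    stringsAsFactors = FALSE
  )
}

.default_fillers <- function() {
  data.frame(
    pt = c("Headache", "Fatigue", "Dizziness", "Rash", "Arthralgia",
           "Insomnia"),
    soc = c("Nervous system disorders", "General disorders",
            "Nervous system disorders", "Skin disorders",
            "Musculoskeletal disorders", "Psychiatric disorders"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic FAERS bundles
#'
#' The defaults emulate, at simulation scale, the statistical structure of a
#' GLP-1 receptor agonist gastrointestinal safety study: a female-majority,
#' middle-aged cohort with sparse weight reporting, roughly one third
#' serious cases, sub-exponential (shape < 1) onset-time distributions, and
#' realistic duplicate/deletion housekeeping.
#'
#' @param seed integer RNG seed; identical seed + config gives a
#'   byte-identical bundle.
#' @param n_reports number of reports to generate (before duplicate
#'   versions are appended).
#' @param target_share probability a report's primary-suspect drug is the
#'   target drug.
#' @param target_generic,target_brands target drug names; brands appear in
#'   `drugname`, the generic in `prod_ai` and `drugname`.
#' @param other_drugs comparator drug-name vocabulary.
#' @param events data frame with one row per study PT: `pt`, `soc`, `p0`
#'   (background report probability), `or` (injected reporting odds ratio
#'   for the target drug), `p_serious`, `p_death` (given any outcome),
#'   `tto_shape`, `tto_scale` (Weibull onset-time parameters, days).
#' @param fillers data frame `pt`, `soc` of non-study reactions, one drawn
#'   per report.
#' @param sex_female,sex_missing sex distribution.
#' @param age_mean,age_sd,age_min,age_max,age_missing truncated-normal age
#'   (years).
#' @param weight_median_kg,weight_sdlog,weight_missing log-normal weight.
#' @param country_us,reporter_hp,reporter_missing country and reporter
#'   margins.
#' @param filler_p_serious,filler_p_death seriousness of filler-only
#'   reports.
#' @param p_hosp,p_lt,p_disab,p_other conditional probabilities of the
#'   non-death outcome codes on serious reports.
#' @param miss_event_date,miss_start_date,partial_start_date,corrupt_date
#'   date-quality rates: missing onset date, missing start date, partial
#'   (`YYYYMM`) start date, onset corrupted to precede the start.
#' @param duplicate_rate fraction of cases emitted twice (same caseid,
#'   higher primaryid, perturbed demographics).
#' @param deleted_rate fraction of caseids put on the deleted-case list.
#' @param indication_probs named probabilities of indication terms on
#'   target reports (remainder: no INDI row).
#' @param co_drug_probs named probabilities of concomitant drugs on target
#'   reports.
#' @param name_noise_rate fraction of target drug names emitted with
#'   case/whitespace noise.
#' @return a `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reports = 20000L, target_share = 0.05,
                       target_generic = "SEMAGLUTIDE",
                       target_brands = c("OZEMPIC", "RYBELSUS", "WEGOVY"),
                       other_drugs = sprintf("COMPARATOR_%02d", 1:30),
                       events = .default_events(),
                       fillers = .default_fillers(),
                       sex_female = 0.58, sex_missing = 0.02,
                       age_mean = 62, age_sd = 12, age_min = 18,
                       age_max = 90, age_missing = 0.36,
                       weight_median_kg = 96, weight_sdlog = 0.2,
                       weight_missing = 0.82,
                       country_us = 0.89, reporter_hp = 0.40,
                       reporter_missing = 0.005,
                       filler_p_serious = 0.25, filler_p_death = 0.02,
                       p_hosp = 0.45, p_lt = 0.04, p_disab = 0.04,
                       p_other = 0.65,
                       miss_event_date = 0.45, miss_start_date = 0.30,
                       partial_start_date = 0.05, corrupt_date = 0.02,
                       duplicate_rate = 0.05, deleted_rate = 0.01,
                       indication_probs = c("Type 2 diabetes mellitus" = 0.30,
                                            "Diabetes mellitus" = 0.13,
                                            "Obesity" = 0.03,
                                            "Weight decreased" = 0.04),
                       co_drug_probs = c("METFORMIN HYDROCHLORIDE" = 0.10,
                                         "INSULIN GLARGINE" = 0.03),
                       name_noise_rate = 0.10) {
  probs <- c(target_share, sex_female, sex_missing, age_missing,
             weight_missing, country_us, reporter_hp, reporter_missing,
             filler_p_serious, filler_p_death, p_hosp, p_lt, p_disab,
             p_other, miss_event_date, miss_start_date, partial_start_date,
             corrupt_date, duplicate_rate, deleted_rate, name_noise_rate,
             events$p0, events$p_serious, events$p_death, indication_probs,
             co_drug_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(events$or <= 0)) stop("injected odds ratios must be positive",
                                call. = FALSE)
  if (n_reports < 1) stop("n_reports must be >= 1", call. = FALSE)
  stopifnot(all(events$tto_shape > 0), all(events$tto_scale > 0),
            nrow(fillers) >= 1)
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "sim_config")
}

# odds-scaled event probability for exposed reports:
# p1 / (1 - p1) = OR * p0 / (1 - p0)
.p_exposed <- function(p0, or) or * p0 / (1 - p0 + or * p0)

#' Closed-form expected 2x2 and planned ROR for a study PT
#'
#' Expectations refer to the deduplicated universe: generated reports minus
#' the configured deleted fraction (duplicate versions collapse at dedup
#' and do not enter).
#'
#' @param config a `sim_config`.
#' @param pt a PT present in `config$events`.
#' @return list `pt`, `or` (the planned reporting odds ratio), `p0`, `p1`,
#'   and `expected` (named a/b/c/d).
#' @export
expected_ror <- function(config, pt) {
  stopifnot(inherits(config, "sim_config"))
  i <- match(.norm_name(pt), .norm_name(config$events$pt))
  if (is.na(i)) stop("unknown PT: ", pt, call. = FALSE)
  p0 <- config$events$p0[i]
  p1 <- .p_exposed(p0, config$events$or[i])
  n <- config$n_reports * (1 - config$deleted_rate)
  pt_share <- config$target_share
  a <- n * pt_share * p1
  b <- n * pt_share * (1 - p1)
  cc <- n * (1 - pt_share) * p0
  d <- n * (1 - pt_share) * (1 - p0)
  list(pt = config$events$pt[i], or = config$events$or[i], p0 = p0, p1 = p1,
       expected = c(a = a, b = b, c = cc, d = d))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.fmt_date <- function(d) format(d, "%Y%m%d")

.noisy_name <- function(x, noisy) {
  x[noisy] <- paste0(tolower(x[noisy]), " ")
  x
}

#' Generate a synthetic FAERS bundle with ground truth
#'
#' Emits the six FAERS tables (plus a deleted-case list) either in memory or
#' written to disk in the `$`-delimited ASCII dialect readable by
#' [read_faers_bundle()].  The returned ground truth carries, per study PT,
#' the planned odds ratio with its expected 2x2 cells and the realized cell
#' counts over the deduplicated universe, plus per-case seriousness, the
#' true onset-time parameters, and the planted duplicate and deleted
#' caseids.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory; when given, the bundle and the
#'   ground truth (`ground_truth.json`) are written there.
#' @return list `bundle` (a `faers_bundle`) and `truth`.
#' @export
simulate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  n <- config$n_reports
  ev <- config$events
  k <- nrow(ev)

  caseid <- 90000000 + seq_len(n)
  primaryid <- caseid * 10 + 1
  is_target <- stats::runif(n) < config$target_share

  # drug names, with occasional case/whitespace noise on the target names
  tnames <- c(config$target_generic, config$target_brands)
  drugname <- character(n)
  prod_ai <- character(n)
  drugname[is_target] <- sample(tnames, sum(is_target), replace = TRUE)
  prod_ai[is_target] <- config$target_generic
  drugname[!is_target] <- sample(config$other_drugs, sum(!is_target),
                                 replace = TRUE)
  prod_ai[!is_target] <- drugname[!is_target]
  noisy <- stats::runif(n) < config$name_noise_rate
  drugname <- .noisy_name(drugname, noisy & is_target)

  # study PT incidence matrix: odds-scaled for exposed reports
  p0 <- matrix(ev$p0, n, k, byrow = TRUE)
  p1 <- matrix(.p_exposed(ev$p0, ev$or), n, k, byrow = TRUE)
  p <- ifelse(matrix(is_target, n, k), p1, p0)
  has <- matrix(stats::runif(n * k), n, k) < p
  colnames(has) <- ev$pt
  filler_idx <- sample.int(nrow(config$fillers), n, replace = TRUE)

  # seriousness: any present PT (or the filler) can trigger a serious case
  log_ns <- has %*% log(1 - ev$p_serious)
  p_serious <- 1 - (1 - config$filler_p_serious) * exp(drop(log_ns))
  serious <- stats::runif(n) < p_serious
  hit_idx <- which(has, arr.ind = TRUE)
  p_death <- rep(config$filler_p_death, n)
  if (nrow(hit_idx) > 0) {
    mx <- tapply(ev$p_death[hit_idx[, 2]], hit_idx[, 1], max)
    rows <- as.integer(names(mx))
    p_death[rows] <- pmax(p_death[rows], as.numeric(mx))
  }
  died <- serious & stats::runif(n) < p_death

  # therapy start, Weibull onset lag governed by the first present study PT
  start <- as.Date("2018-01-01") + sample.int(1250, n, replace = TRUE) - 1
  first_pt <- rep(NA_integer_, n)
  if (nrow(hit_idx) > 0) {
    fp <- tapply(hit_idx[, 2], hit_idx[, 1], min)
    first_pt[as.integer(names(fp))] <- as.integer(fp)
  }
  shape <- ifelse(is.na(first_pt), 0.40, ev$tto_shape[first_pt])
  scale <- ifelse(is.na(first_pt), 8, ev$tto_scale[first_pt])
  tto <- stats::rweibull(n, shape = shape, scale = scale)
  event <- start + round(tto)
  fda <- event + stats::rpois(n, 30)

  # date quality degradation
  u <- stats::runif(n)
  ev_str <- .fmt_date(event)
  corrupt <- u < config$corrupt_date
  ev_str[corrupt] <- .fmt_date(start[corrupt] -
                                 sample(30:200, sum(corrupt), replace = TRUE))
  miss_ev <- u >= config$corrupt_date &
    u < config$corrupt_date + config$miss_event_date
  ev_str[miss_ev] <- ""
  v <- stats::runif(n)
  st_str <- .fmt_date(start)
  st_str[v < config$miss_start_date] <- ""
  partial <- v >= config$miss_start_date &
    v < config$miss_start_date + config$partial_start_date
  st_str[partial] <- substr(st_str[partial], 1, 6)

  # demographics
  sex <- ifelse(stats::runif(n) < config$sex_female, "F", "M")
  sex[stats::runif(n) < config$sex_missing] <- ""
  age <- round(.rtruncnorm(n, config$age_mean, config$age_sd,
                           config$age_min, config$age_max), 1)
  age_cod <- rep("YR", n)
  in_months <- stats::runif(n) < 0.02
  age[in_months] <- round(age[in_months] * 12)
  age_cod[in_months] <- "MON"
  age_str <- as.character(age)
  age_str[stats::runif(n) < config$age_missing] <- ""
  wt <- round(stats::rlnorm(n, log(config$weight_median_kg),
                            config$weight_sdlog), 1)
  wt_cod <- rep("KG", n)
  in_lbs <- stats::runif(n) < 0.3
  wt[in_lbs] <- round(wt[in_lbs] / 0.453592, 1)
  wt_cod[in_lbs] <- "LBS"
  wt_str <- as.character(wt)
  wt_str[stats::runif(n) < config$weight_missing] <- ""
  country <- ifelse(stats::runif(n) < config$country_us, "US",
                    sample(c("CA", "GB", "DE", "JP", "FR"), n,
                           replace = TRUE))
  occp <- ifelse(stats::runif(n) < config$reporter_hp,
                 sample(c("MD", "PH", "OT"), n, replace = TRUE), "CN")
  occp[stats::runif(n) < config$reporter_missing] <- ""

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     event_dt = ev_str, fda_dt = .fmt_date(fda),
                     age = age_str, age_cod = age_cod, sex = sex,
                     wt = wt_str, wt_cod = wt_cod,
                     reporter_country = country, occp_cod = occp,
                     stringsAsFactors = FALSE)

  drug <- data.frame(primaryid = primaryid, caseid = caseid, drug_seq = "1",
                     role_cod = "PS", drugname = drugname,
                     prod_ai = prod_ai, stringsAsFactors = FALSE)
  # concomitant drugs on target reports
  co_rows <- list()
  seqno <- 2L
  for (cd in names(config$co_drug_probs)) {
    with_cd <- is_target & stats::runif(n) < config$co_drug_probs[[cd]]
    if (any(with_cd)) {
      co_rows[[cd]] <- data.frame(primaryid = primaryid[with_cd],
                                  caseid = caseid[with_cd],
                                  drug_seq = as.character(seqno),
                                  role_cod = sample(c("C", "SS"),
                                                    sum(with_cd),
                                                    replace = TRUE),
                                  drugname = cd, prod_ai = cd,
                                  stringsAsFactors = FALSE)
    }
    seqno <- seqno + 1L
  }
  drug <- do.call(rbind, c(list(drug), unname(co_rows)))

  reac_study <- data.frame(
    primaryid = rep(primaryid, k)[as.vector(has)],
    caseid = rep(caseid, k)[as.vector(has)],
    pt = rep(ev$pt, each = n)[as.vector(has)], stringsAsFactors = FALSE)
  reac <- rbind(reac_study,
                data.frame(primaryid = primaryid, caseid = caseid,
                           pt = config$fillers$pt[filler_idx],
                           stringsAsFactors = FALSE))

  # outcome codes for serious cases (at least one code each)
  out_rows <- list()
  add_code <- function(sel, code) {
    if (any(sel)) {
      out_rows[[length(out_rows) + 1L]] <<-
        data.frame(primaryid = primaryid[sel], caseid = caseid[sel],
                   outc_cod = code, stringsAsFactors = FALSE)
    }
  }
  add_code(died, "DE")
  hosp <- serious & stats::runif(n) < config$p_hosp
  lt <- serious & stats::runif(n) < config$p_lt
  disab <- serious & stats::runif(n) < config$p_disab
  other <- serious & stats::runif(n) < config$p_other
  other <- other | (serious & !died & !hosp & !lt & !disab)
  add_code(hosp, "HO"); add_code(lt, "LT"); add_code(disab, "DS")
  add_code(other, "OT")
  outc <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(primaryid = numeric(0), caseid = numeric(0),
               outc_cod = character(0))

  ther <- data.frame(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = "1", start_dt = st_str,
                     stringsAsFactors = FALSE)

  indi_term <- rep(NA_character_, n)
  uu <- stats::runif(n)
  edges <- cumsum(config$indication_probs)
  for (j in rev(seq_along(edges))) {
    indi_term[is_target & uu < edges[j]] <- names(edges)[j]
  }
  with_indi <- !is.na(indi_term)
  indi <- data.frame(primaryid = primaryid[with_indi],
                     caseid = caseid[with_indi],
                     indi_drug_seq = rep("1", sum(with_indi)),
                     indi_pt = indi_term[with_indi], stringsAsFactors = FALSE)

  # duplicate report versions: same caseid, higher primaryid, later rows
  n_dup <- floor(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  if (n_dup > 0) {
    dup_demo <- demo[dup_idx, , drop = FALSE]
    dup_demo$primaryid <- dup_demo$primaryid + 1
    perturb <- nzchar(dup_demo$age)
    dup_demo$age[perturb] <- as.character(
      suppressWarnings(as.numeric(dup_demo$age[perturb])) + 1)
    demo <- rbind(demo, dup_demo)
    for (nm in c("drug", "reac", "outc", "ther", "indi")) {
      tab <- get(nm)
      extra <- tab[tab$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      extra$primaryid <- extra$primaryid + 1
      assign(nm, rbind(tab, extra))
    }
  }

  n_del <- floor(config$deleted_rate * n)
  deleted <- if (n_del > 0) sort(sample(caseid, n_del)) else numeric(0)

  bundle <- as_faers_bundle(list(demo = demo, drug = drug, reac = reac,
                                 outc = outc, ther = ther, indi = indi),
                            deleted_caseids = deleted, quarter = "SYN")

  kept <- !(caseid %in% deleted)
  realized <- data.frame(
    pt = ev$pt, planned_or = ev$or,
    a = colSums(has[kept & is_target, , drop = FALSE]),
    c = colSums(has[kept & !is_target, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
  realized$b <- sum(kept & is_target) - realized$a
  realized$d <- sum(kept & !is_target) - realized$c
  expected <- do.call(rbind, lapply(ev$pt, function(pp) {
    e <- expected_ror(config, pp)
    data.frame(pt = e$pt, or = e$or, a = e$expected[["a"]],
               b = e$expected[["b"]], c = e$expected[["c"]],
               d = e$expected[["d"]], stringsAsFactors = FALSE)
  }))
  truth <- list(n_reports = n, n_unique_cases = sum(kept),
                n_target_cases = sum(kept & is_target),
                n_serious_cases = sum(kept & serious),
                realized = realized, expected = expected,
                serious = data.frame(caseid = caseid, serious = serious),
                tto_parameters = ev[, c("pt", "tto_shape", "tto_scale")],
                duplicate_caseids = caseid[dup_idx],
                deleted_caseids = deleted)

  if (!is.null(dir)) {
    write_faers_bundle(bundle, dir)
    jsonlite::write_json(truth[c("n_reports", "n_unique_cases",
                                 "n_target_cases", "n_serious_cases",
                                 "realized", "expected",
                                 "duplicate_caseids", "deleted_caseids")],
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(bundle = bundle, truth = truth)
}

#' Mini semaglutide-like simulation preset
#'
#' A `sim_config` whose study-PT vocabulary is the bundled 45-term
#' semaglutide gastrointestinal signal table: per-PT background
#' probabilities are scaled from the published report counts and the
#' injected odds ratios track the published ROR lower bounds, with the
#' bundled toy PT-to-SOC map and DME/IME lists.
#'
#' @param seed RNG seed.
#' @param n_reports bundle size.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config` with attributes `pt_soc_map`, `dme_terms`,
#'   `ime_terms` pointing at the bundled fixtures.
#' @export
preset_mini_semaglutide <- function(seed = 1L, n_reports = 20000L, ...) {
  feats <- utils::read.csv(system.file("extdata",
                                       "semaglutide_gi_signal_features.csv",
                                       package = "faersignal"),
                           stringsAsFactors = FALSE)
  # cohort-frequency-scaled exposure probability; odds ratio anchored a
  # little above the published lower bound
  p1 <- pmin(0.5, feats$n_reports / 5442)
  or <- pmax(1.5, feats$ror025 * 1.25)
  p0 <- p1 / (or * (1 - p1) + p1)
  events <- data.frame(pt = feats$pt, soc = "Gastrointestinal disorders",
                       p0 = p0, or = or,
                       p_serious = pmin(0.95, 0.25 + feats$deaths /
                                          pmax(feats$n_reports, 1)),
                       p_death = pmin(0.5, feats$deaths /
                                        pmax(feats$n_reports, 1)),
                       tto_shape = 0.40,
                       tto_scale = ifelse(feats$band == "strong", 30, 9),
                       stringsAsFactors = FALSE)
  cfg <- sim_config(seed = seed, n_reports = n_reports, events = events, ...)
  attr(cfg, "pt_soc_map") <- system.file("extdata", "gi_pt_soc_map.csv",
                                         package = "faersignal")
  attr(cfg, "dme_terms") <- system.file("extdata", "dme_terms.txt",
                                        package = "faersignal")
  attr(cfg, "ime_terms") <- system.file("extdata", "ime_terms.txt",
                                        package = "faersignal")
  cfg
}
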