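# Reporting odds ratio disproportionality: 2x2 construction, ROR with Wald
# CI, signal screening and stratified analysis.
#
# The counting unit everywhere is the deduplicated report.  The comparator is
# "all other drugs in the deduplicated universe".  Zero-cell tables are
# reported as undefined, never continuity-corrected.

#' Build the 2x2 contingency table for a drug-event pair
#'
#' Partitions the deduplicated universe into the four cells of the classic
#' disproportionality table: `a` target drug & target event, `b` target drug
#' & other events, `c` other drugs & target event, `d` neither.
#'
#' @param universe_ids primaryids of the whole deduplicated universe.
#' @param target_ids primaryids of reports where the target drug is primary
#'   suspect.
#' @param event_ids primaryids of reports carrying the event (a PT or any PT
#'   of a SOC).
#' @return a `contingency_table` (named list `a`, `b`, `c`, `d`).
#' @export
contingency_table <- function(universe_ids, target_ids, event_ids) {
  n <- length(unique(universe_ids))
  if (n == 0L) stop("empty universe", call. = FALSE)
  target_ids <- intersect(target_ids, universe_ids)
  event_ids <- intersect(event_ids, universe_ids)
  a <- length(intersect(target_ids, event_ids))
  b <- length(target_ids) - a
  cc <- length(event_ids) - a
  d <- n - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); CI = exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' Any zero cell leaves the ROR undefined (`defined = FALSE`); no continuity
#' correction is applied.
#'
#' @param tab a `contingency_table`, or `a` when the four counts are given
#'   separately.
#' @param b,c,d optional individual cell counts.
#' @param conf confidence level (default 0.95).
#' @return list `ror`, `ci_low`, `ci_high`, `defined`, plus the cells.
#' @export
ror <- function(tab, b = NULL, c = NULL, d = NULL, conf = 0.95) {
  if (inherits(tab, "contingency_table")) {
    a <- tab$a; bb <- tab$b; cc <- tab$c; dd <- tab$d
  } else {
    a <- tab; bb <- b; cc <- c; dd <- d
  }
  stopifnot(a >= 0, bb >= 0, cc >= 0, dd >= 0)
  if (min(a, bb, cc, dd) == 0) {
    return(list(a = a, b = bb, c = cc, d = dd, ror = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, defined = FALSE))
  }
  est <- (a * dd) / (bb * cc)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / bb + 1 / cc + 1 / dd)
  list(a = a, b = bb, c = cc, d = dd, ror = est,
       ci_low = exp(log(est) - z * se), ci_high = exp(log(est) + z * se),
       defined = TRUE)
}

.event_ids_by_pt <- function(events) {
  split(events$primaryid, .norm_name(events$pt))
}

#' Screen PT-level disproportionality signals
#'
#' Evaluates every PT with at least `min_reports` target-drug reports and
#' applies the signal rule: a PT is a positive signal when the lower 95% CI
#' bound of its ROR (ROR025) exceeds one.  PTs below the report threshold
#' are listed in the `excluded` attribute, not evaluated.
#'
#' @param universe a `faers_universe`.
#' @param target_ids cohort primaryids.
#' @param events event table (`primaryid`, `pt`) restricted to the target
#'   SOC, from [select_target_events()].
#' @param config a `study_config` (`min_reports`).
#' @return a `signal_screen` data frame: `term`, `level`, `a`, `b`, `c`,
#'   `d`, `ror`, `ci_low`, `ci_high`, `defined`, `is_signal`, sorted by `a`
#'   descending.  Attribute `excluded` holds the below-threshold PT counts.
#' @export
screen_signals <- function(universe, target_ids, events, config) {
  universe_ids <- universe$cases$primaryid
  by_pt <- .event_ids_by_pt(events)
  label <- vapply(split(trimws(events$pt), .norm_name(events$pt)),
                  function(v) v[[1L]], character(1))
  a_counts <- vapply(by_pt, function(ids)
    length(intersect(unique(ids), target_ids)), integer(1))
  eval_pts <- names(by_pt)[a_counts >= config$min_reports]
  excl <- data.frame(term = unname(label[setdiff(names(by_pt), eval_pts)]),
                     a = unname(a_counts[setdiff(names(by_pt), eval_pts)]))
  rows <- lapply(eval_pts, function(pt) {
    tab <- contingency_table(universe_ids, target_ids, unique(by_pt[[pt]]))
    r <- ror(tab)
    data.frame(term = label[[pt]], level = "PT", a = r$a, b = r$b, c = r$c,
               d = r$d, ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
               defined = r$defined,
               is_signal = isTRUE(r$defined) && r$ci_low > 1,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), level = character(0), a = integer(0),
               b = integer(0), c = integer(0), d = integer(0),
               ror = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               defined = logical(0), is_signal = logical(0))
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  class(out) <- c("signal_screen", "data.frame")
  out
}

#' @export
print.signal_screen <- function(x, digits = 2, ...) {
  cat("Disproportionality screen:", nrow(x), "terms evaluated,",
      sum(x$is_signal), "positive signals (ROR025 > 1)\n")
  y <- as.data.frame(x)
  y$ror <- round(y$ror, digits)
  y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits)
  print(utils::head(y, 20), row.names = FALSE)
  if (nrow(y) > 20) cat("  ... and", nrow(y) - 20, "more rows\n")
  invisible(x)
}

#' SOC-level disproportionality
#'
#' One 2x2 for "any event in the SOC" against the whole universe.
#'
#' @inheritParams screen_signals
#' @param soc_label label carried into the result row.
#' @return one-row `signal_screen`-style data frame at level `"SOC"`.
#' @export
soc_signal <- function(universe, target_ids, events,
                       soc_label = "target SOC") {
  tab <- contingency_table(universe$cases$primaryid, target_ids,
                           unique(events$primaryid))
  r <- ror(tab)
  data.frame(term = soc_label, level = "SOC", a = r$a, b = r$b, c = r$c,
             d = r$d, ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
             defined = r$defined,
             is_signal = isTRUE(r$defined) && r$ci_low > 1,
             stringsAsFactors = FALSE)
}

#' Default stratification plan
#'
#' Sex (female/male), age bands, weight bands and reporter type, with band
#' edges from the study configuration.
#'
#' @param config a `study_config`.
#' @return named list of stratum specifications.
#' @export
default_strata <- function(config) {
  list(sex = list(variable = "sex", categories = c("female", "male")),
       age = list(variable = "age_years", breaks = config$age_breaks),
       weight = list(variable = "weight_kg", breaks = config$weight_breaks),
       reporter = list(variable = "reporter",
                       categories = c("health-professional", "consumer")))
}

#' Stratified SOC-level ROR
#'
#' For each stratum the universe is restricted *before* table construction;
#' cases missing the stratification variable are excluded from that whole
#' stratification (both margins).  Strata with a zero cell yield a flagged
#' undefined row, never a silent drop.
#'
#' @param universe a `faers_universe`.
#' @param target_ids cohort primaryids.
#' @param events SOC-restricted event table.
#' @param strata list of stratum specs as produced by [default_strata()]:
#'   each has `variable` and either `categories` (discrete) or `breaks`
#'   (numeric band edges).
#' @return data frame with one row per (variable, stratum).
#' @export
stratified_ror <- function(universe, target_ids, events, strata) {
  cases <- universe$cases
  event_ids <- unique(events$primaryid)
  rows <- list()
  for (sname in names(strata)) {
    spec <- strata[[sname]]
    v <- cases[[spec$variable]]
    if (is.null(v)) stop("unknown stratification variable: ", spec$variable,
                         call. = FALSE)
    if (!is.null(spec$breaks)) {
      miss <- is.na(v)
      grp <- as.character(.band_cut(v, spec$breaks))
    } else {
      miss <- is.na(v) | !(v %in% spec$categories)
      grp <- as.character(v)
    }
    lvls <- if (!is.null(spec$breaks)) .band_labels(spec$breaks) else
      spec$categories
    for (lv in lvls) {
      ids <- cases$primaryid[!miss & grp == lv]
      if (length(ids) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = sname, stratum = lv, n = 0L, a = 0L, b = 0L, c = 0L,
          d = 0L, ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          defined = FALSE, is_signal = FALSE, stringsAsFactors = FALSE)
        next
      }
      tab <- contingency_table(ids, intersect(target_ids, ids),
                               intersect(event_ids, ids))
      r <- ror(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = sname, stratum = lv, n = length(ids), a = r$a, b = r$b,
        c = r$c, d = r$d, ror = r$ror, ci_low = r$ci_low,
        ci_high = r$ci_high, defined = r$defined,
        is_signal = isTRUE(r$defined) && r$ci_low > 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
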