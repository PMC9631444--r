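# Seriousness classification and serious vs non-serious comparisons:
# uncorrected Pearson chi-squared, Fisher exact (two-sided probability
# ordering), Mann-Whitney with tie-corrected normal approximation, and
# expected-count-based test auto-selection.

.outcome_map <- c(DE = "death", LT = "life-threatening",
                  HO = "hospitalization", DS = "disability",
                  CA = "other", RI = "other", OT = "other")

#' Classify case seriousness from outcome codes
#'
#' A case is serious iff it carries at least one outcome code.  Codes map to
#' categories: DE death, LT life-threatening, HO hospitalization, DS
#' disability; CA, RI and OT all fall under "other".  Unknown codes are
#' counted under "other" with a warning.
#'
#' @param universe a `faers_universe` (or a bare OUTC-style data frame with
#'   `primaryid`, `outc_cod` plus a vector of all case primaryids).
#' @param case_ids optional primaryids to classify; defaults to every case
#'   in the universe.
#' @return data frame `primaryid`, `serious`, `categories`
#'   (comma-separated; empty for non-serious cases).
#' @export
classify_seriousness <- function(universe, case_ids = NULL) {
  outc <- universe$outc
  if (is.null(case_ids)) case_ids <- universe$cases$primaryid
  code <- toupper(trimws(outc$outc_cod))
  known <- code %in% names(.outcome_map)
  if (any(!known & nzchar(code))) {
    warning(sum(!known & nzchar(code)),
            " unknown outcome code(s) counted as 'other'", call. = FALSE)
  }
  cat_vec <- ifelse(known, .outcome_map[code],
                    ifelse(nzchar(code), "other", NA_character_))
  keep <- !is.na(cat_vec) & outc$primaryid %in% case_ids
  cats <- lapply(split(cat_vec[keep], outc$primaryid[keep]),
                 function(v) sort(unique(v)))
  idx <- match(as.character(case_ids), names(cats))
  categories <- vapply(idx, function(i)
    if (is.na(i)) "" else paste(cats[[i]], collapse = ","), character(1))
  data.frame(primaryid = case_ids, serious = nzchar(categories),
             categories = categories, stringsAsFactors = FALSE)
}

.as_cells <- function(tab, b, c, d) {
  if (inherits(tab, "contingency_table")) {
    c(tab$a, tab$b, tab$c, tab$d)
  } else if (is.matrix(tab)) {
    c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else c(tab, b, c, d)
}

#' Uncorrected Pearson chi-squared test on a 2x2 table
#'
#' Equivalent to the closed form N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); no
#' Yates continuity correction, 1 degree of freedom.
#'
#' @param tab a `contingency_table`, a 2x2 matrix, or cell `a`.
#' @param b,c,d remaining cells when given individually.
#' @return list `test_name`, `statistic`, `p_value`, `cells`.
#' @export
pearson_chi2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  cells <- .as_cells(tab, b, c, d)
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: the chi-squared test is undefined; use fisher_exact()",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(test_name = "pearson-chi2", statistic = unname(ht$statistic),
       p_value = unname(ht$p.value), cells = cells)
}

#' Fisher exact test on a 2x2 table (two-sided)
#'
#' Two-sided p by the probability-ordering rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed one.  Degenerate tables (an empty margin)
#' return p = 1.
#'
#' @inheritParams pearson_chi2
#' @return list `test_name`, `statistic` (`NA`; the test has no statistic),
#'   `p_value`, `cells`.
#' @export
fisher_exact <- function(tab, b = NULL, c = NULL, d = NULL) {
  cells <- .as_cells(tab, b, c, d)
  m <- matrix(cells, 2, 2, byrow = TRUE)
  p <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) 1 else
    stats::fisher.test(m)$p.value
  list(test_name = "fisher-exact", statistic = NA_real_,
       p_value = min(p, 1), cells = cells)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Reports the U statistic of group 1 and the standardized Z with the sign
#' convention Z < 0 when group 1 ranks lower than group 2.  The variance is
#' tie-corrected; no continuity correction is applied (the intended use is
#' samples in the hundreds or thousands).
#'
#' @param x,y numeric samples for the two groups.
#' @return list `test_name`, `statistic` (Z), `u`, `p_value`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty",
                                 call. = FALSE)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) {
    return(list(test_name = "mann-whitney", statistic = 0, u = u1,
                p_value = 1, n1 = n1, n2 = n2))
  }
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  list(test_name = "mann-whitney", statistic = z, u = u1,
       p_value = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
}

#' Choose between chi-squared and Fisher for a 2x2 table
#'
#' The standard expected-count rule: Pearson chi-squared when every expected
#' cell count under independence is at least `threshold` (default 5),
#' otherwise Fisher exact.
#'
#' @inheritParams pearson_chi2
#' @param threshold minimum expected cell count for the chi-squared test.
#' @return `"pearson-chi2"` or `"fisher-exact"`.
#' @export
select_test <- function(tab, b = NULL, c = NULL, d = NULL, threshold = 5) {
  cells <- .as_cells(tab, b, c, d)
  m <- matrix(cells, 2, 2, byrow = TRUE)
  n <- sum(m)
  if (n == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return("fisher-exact")
  }
  expected <- outer(rowSums(m), colSums(m)) / n
  if (min(expected) >= threshold) "pearson-chi2" else "fisher-exact"
}

#' Serious vs non-serious comparison per PT
#'
#' For each PT, tests whether the event is reported disproportionately among
#' serious cases: the 2x2 is (has PT vs not) x (serious vs not) over the
#' cohort, tested with Pearson chi-squared when all expected counts are >= 5
#' and Fisher exact otherwise.  Percentages are within-arm shares of the
#' serious and non-serious case totals.
#'
#' @param events cohort event table (`primaryid`, `pt`).
#' @param labels seriousness labels from [classify_seriousness()] covering
#'   every cohort case.
#' @param target_ids cohort primaryids.
#' @return data frame `pt`, `serious_n`, `serious_pct`, `nonserious_n`,
#'   `nonserious_pct`, `test`, `statistic`, `p_value`, sorted by total count
#'   descending.
#' @export
compare_event_severity <- function(events, labels, target_ids) {
  labels <- labels[labels$primaryid %in% target_ids, , drop = FALSE]
  serious_ids <- labels$primaryid[labels$serious]
  ns_ids <- labels$primaryid[!labels$serious]
  n_s <- length(serious_ids); n_ns <- length(ns_ids)
  by_pt <- .event_ids_by_pt(events[events$primaryid %in% target_ids, ,
                                   drop = FALSE])
  label <- vapply(split(trimws(events$pt), .norm_name(events$pt)),
                  function(v) v[[1L]], character(1))
  rows <- lapply(names(by_pt), function(pt) {
    ids <- unique(by_pt[[pt]])
    a <- length(intersect(ids, serious_ids))
    cc <- length(intersect(ids, ns_ids))
    cells <- c(a, n_s - a, cc, n_ns - cc)
    test <- select_test(cells[1], cells[2], cells[3], cells[4])
    res <- if (test == "pearson-chi2") {
      pearson_chi2(cells[1], cells[2], cells[3], cells[4])
    } else {
      fisher_exact(cells[1], cells[2], cells[3], cells[4])
    }
    data.frame(pt = label[[pt]], serious_n = a,
               serious_pct = round(100 * a / n_s, 2), nonserious_n = cc,
               nonserious_pct = round(100 * cc / n_ns, 2), test = test,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-(out$serious_n + out$nonserious_n), out$pt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
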