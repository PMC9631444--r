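# Five-feature semiquantitative clinical-priority scoring of
# disproportionality signals: report count, ROR025, death proportion,
# DME/IME status, and an analyst-supplied evidence grade.  Composite scores
# band as weak (0-4), moderate (5-7), strong (8-10).

#' Clinical-priority scoring rubric
#'
#' Per-feature breakpoint tables mapping a feature value to points.  The
#' defaults assign: ROR025 in \[1,2) 1 pt, \[2,5) 2 pts, >= 5 3 pts; report
#' count >= 50 1 pt; death proportion >= 20% 1 pt and >= 50% 2 pts; DME 2
#' pts, IME 1 pt; evidence "++" 2 pts, "+" 1 pt, "-" 0.  Every breakpoint is
#' configurable; the maximum total is 10.
#'
#' @param ror025_breaks,ror025_points ascending lower bounds and the points
#'   awarded at or above each (below the first bound is out of domain).
#' @param n_breaks,n_points same for the report count (0 pts below the
#'   first bound).
#' @param death_breaks,death_points same for the death proportion (fraction
#'   of the PT's reports; 0 pts below the first bound).
#' @param dme_points,ime_points points for designated / important medical
#'   events.
#' @param evidence_points named vector mapping evidence grades to points.
#' @return a `priority_rubric`.
#' @export
priority_rubric <- function(ror025_breaks = c(1, 2, 5),
                            ror025_points = c(1, 2, 3),
                            n_breaks = 50, n_points = 1,
                            death_breaks = c(0.2, 0.5),
                            death_points = c(1, 2),
                            dme_points = 2, ime_points = 1,
                            evidence_points = c("++" = 2, "+" = 1, "-" = 0)) {
  stopifnot(length(ror025_breaks) == length(ror025_points),
            length(n_breaks) == length(n_points),
            length(death_breaks) == length(death_points),
            !is.unsorted(ror025_breaks, strictly = TRUE),
            all(c(ror025_points, n_points, death_points, dme_points,
                  ime_points, evidence_points) >= 0))
  structure(list(ror025_breaks = ror025_breaks,
                 ror025_points = ror025_points,
                 n_breaks = n_breaks, n_points = n_points,
                 death_breaks = death_breaks, death_points = death_points,
                 dme_points = dme_points, ime_points = ime_points,
                 evidence_points = evidence_points),
            class = "priority_rubric")
}

# step function: points of the highest break <= x, else `below`
.step_points <- function(x, breaks, points, below = 0) {
  idx <- findInterval(x, breaks)
  ifelse(idx == 0, below, points[pmax(idx, 1L)])
}

#' Band a composite priority score
#'
#' @param score integer score(s) in 0-10.
#' @return `"weak"` (0-4), `"moderate"` (5-7) or `"strong"` (8-10).
#' @export
priority_band <- function(score) {
  stopifnot(all(score >= 0 & score <= 10))
  cut(score, breaks = c(-0.5, 4.5, 7.5, 10.5),
      labels = c("weak", "moderate", "strong")) |> as.character()
}

#' Flag a PT as DME, IME or neither
#'
#' DME takes precedence when a term is on both lists; matching is
#' case-insensitive after trimming.
#'
#' @param pt character vector of preferred terms.
#' @param dme_terms,ime_terms term lists (see [read_term_list()]).
#' @return character vector `"DME"`, `"IME"` or `"none"`.
#' @export
flag_dme_ime <- function(pt, dme_terms, ime_terms) {
  key <- .norm_name(pt)
  out <- rep("none", length(key))
  out[key %in% .norm_name(ime_terms)] <- "IME"
  out[key %in% .norm_name(dme_terms)] <- "DME"
  out
}

#' Score signals on the five-feature priority rubric
#'
#' @param signals data frame with columns `pt`, `n_reports`, `ror025`,
#'   `deaths`, `dme_ime` (`"DME"`, `"IME"` or `"none"`) and `evidence`
#'   (a grade present in the rubric's `evidence_points`; an analyst
#'   annotation, never computed).
#' @param rubric a [priority_rubric()].
#' @return a `priority_scores` data frame: the inputs plus the five
#'   per-feature point columns (`pts_n`, `pts_ror`, `pts_death`, `pts_dme`,
#'   `pts_evidence`), the composite `score` and the `band`.
#' @export
score_signals <- function(signals, rubric = priority_rubric()) {
  need <- c("pt", "n_reports", "ror025", "deaths", "dme_ime", "evidence")
  if (!all(need %in% names(signals))) {
    stop("signals must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(rubric, "priority_rubric"))
  if (any(signals$ror025 < rubric$ror025_breaks[1L])) {
    stop("feature 'ror025' below the rubric domain (", rubric$ror025_breaks[1L],
         "): signals here require ROR025 above the signal threshold",
         call. = FALSE)
  }
  if (any(signals$deaths < 0 | signals$deaths > signals$n_reports)) {
    stop("feature 'deaths' must lie in [0, n_reports]", call. = FALSE)
  }
  if (!all(signals$dme_ime %in% c("DME", "IME", "none"))) {
    stop("feature 'dme_ime' must be one of DME, IME, none", call. = FALSE)
  }
  ev <- trimws(signals$evidence)
  # tolerate typographic dashes in hand-entered evidence grades
  ev[ev %in% c("–", "—", "−")] <- "-"
  if (!all(ev %in% names(rubric$evidence_points))) {
    stop("feature 'evidence' has grade(s) outside the rubric: ",
         paste(unique(ev[!ev %in% names(rubric$evidence_points)]),
               collapse = ", "), call. = FALSE)
  }
  pts_ror <- .step_points(signals$ror025, rubric$ror025_breaks,
                          rubric$ror025_points)
  pts_n <- .step_points(signals$n_reports, rubric$n_breaks, rubric$n_points)
  pts_death <- .step_points(signals$deaths / signals$n_reports,
                            rubric$death_breaks, rubric$death_points)
  pts_dme <- ifelse(signals$dme_ime == "DME", rubric$dme_points,
                    ifelse(signals$dme_ime == "IME", rubric$ime_points, 0))
  pts_ev <- unname(rubric$evidence_points[ev])
  score <- pts_n + pts_ror + pts_death + pts_dme + pts_ev
  out <- data.frame(pt = signals$pt, n_reports = signals$n_reports,
                    ror025 = signals$ror025, deaths = signals$deaths,
                    dme_ime = signals$dme_ime, evidence = ev,
                    pts_n = pts_n, pts_ror = pts_ror, pts_death = pts_death,
                    pts_dme = pts_dme, pts_evidence = pts_ev,
                    score = as.integer(score),
                    band = priority_band(score), stringsAsFactors = FALSE)
  class(out) <- c("priority_scores", "data.frame")
  out
}

#' Score a single signal
#'
#' Convenience wrapper around [score_signals()] for one PT.
#'
#' @param pt preferred term.
#' @param n_reports,ror025,deaths,dme_ime,evidence feature values.
#' @param rubric a [priority_rubric()].
#' @return one-row `priority_scores` data frame.
#' @export
score_signal <- function(pt, n_reports, ror025, deaths, dme_ime = "none",
                         evidence = "-", rubric = priority_rubric()) {
  score_signals(data.frame(pt = pt, n_reports = n_reports, ror025 = ror025,
                           deaths = deaths, dme_ime = dme_ime,
                           evidence = evidence, stringsAsFactors = FALSE),
                rubric)
}

#' Band counts of scored signals
#'
#' @param results a `priority_scores` data frame.
#' @return list `counts` (named strong/moderate/weak) and the audit `table`.
#' @export
summarize_priorities <- function(results) {
  stopifnot(nrow(results) >= 1)
  counts <- vapply(c("strong", "moderate", "weak"),
                   function(bd) sum(results$band == bd), integer(1))
  list(counts = counts, table = results)
}

#' @export
print.priority_scores <- function(x, ...) {
  counts <- table(factor(x$band, c("strong", "moderate", "weak")))
  cat("Clinical priority scores:", nrow(x), "signals —",
      paste(sprintf("%d %s", as.integer(counts), names(counts)),
            collapse = ", "), "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
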