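# Target-drug cohort construction, PT -> SOC mapping, and the descriptive
# summary of the cohort.

#' Study configuration
#'
#' Bundles the drug-name lists, target SOC, screening threshold and the
#' stratification bin edges used throughout the pipeline.
#'
#' @param generic_names character vector of generic (active-ingredient)
#'   names, matched against both `drugname` and `prod_ai`.
#' @param brand_names character vector of trade names, matched against
#'   `drugname`.
#' @param target_soc System Organ Class under study.
#' @param min_reports minimum report count for a PT to enter signal
#'   evaluation (default 10).
#' @param age_breaks inner age band edges in years; default `c(18, 65)`
#'   yields bands `<18`, `18-65`, `>65`.
#' @param weight_breaks inner weight band edges in kg; default `c(80, 100)`.
#' @param indication_groups optional named list mapping group label ->
#'   character vector of indication PTs; ungrouped terms fall into
#'   `"Others"`.
#' @return a `study_config`.
#' @export
study_config <- function(generic_names, brand_names = character(0),
                         target_soc = "Gastrointestinal disorders",
                         min_reports = 10, age_breaks = c(18, 65),
                         weight_breaks = c(80, 100),
                         indication_groups = NULL) {
  generic_names <- toupper(trimws(generic_names))
  brand_names <- toupper(trimws(brand_names))
  generic_names <- generic_names[nzchar(generic_names)]
  brand_names <- brand_names[nzchar(brand_names)]
  if (length(generic_names) + length(brand_names) == 0L) {
    stop("study_config requires at least one generic or brand name",
         call. = FALSE)
  }
  stopifnot(min_reports >= 1,
            !is.unsorted(age_breaks, strictly = TRUE),
            !is.unsorted(weight_breaks, strictly = TRUE))
  structure(list(generic_names = generic_names, brand_names = brand_names,
                 target_soc = target_soc, min_reports = as.integer(min_reports),
                 age_breaks = age_breaks, weight_breaks = weight_breaks,
                 indication_groups = indication_groups),
            class = "study_config")
}

#' Read a PT -> SOC mapping table
#'
#' Two-column CSV `pt, soc` with an optional logical `primary_soc` column;
#' MedDRA is multi-axial, so a PT may appear on several rows.
#'
#' @param path CSV path.
#' @return data frame with columns `pt`, `soc`, `primary_soc`.
#' @export
read_pt_soc_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("PT->SOC map must have columns 'pt' and 'soc'", call. = FALSE)
  }
  if (is.null(map$primary_soc)) map$primary_soc <- TRUE
  map$pt <- trimws(map$pt)
  map$soc <- trimws(map$soc)
  map
}

#' Read a one-term-per-line list (DME/IME lists)
#'
#' @param path plain-text file, one term per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of terms.
#' @export
read_term_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

.norm_name <- function(x) toupper(trimws(as.character(x)))

#' Identify target-drug cases
#'
#' A case belongs to the cohort iff at least one of its drug records has
#' role `PS` (primary suspect) and a `drugname` matching any configured
#' generic or brand name, or a `prod_ai` matching a generic name — exact
#' token match after upper-casing and trimming.
#'
#' @param universe a `faers_universe`.
#' @param config a `study_config`.
#' @return numeric vector of cohort primaryids.
#' @export
match_target_cases <- function(universe, config) {
  stopifnot(inherits(universe, "faers_universe"),
            inherits(config, "study_config"))
  drug <- universe$drug
  role <- .norm_name(drug$role_cod)
  dn <- .norm_name(drug$drugname)
  ai <- .norm_name(drug$prod_ai)
  names_all <- c(config$generic_names, config$brand_names)
  hit <- role == "PS" & (dn %in% names_all | ai %in% config$generic_names)
  sort(unique(drug$primaryid[hit]))
}

# internal: logical index of target-drug rows in universe$drug
.target_drug_rows <- function(universe, config) {
  drug <- universe$drug
  names_all <- c(config$generic_names, config$brand_names)
  .norm_name(drug$drugname) %in% names_all |
    .norm_name(drug$prod_ai) %in% config$generic_names
}

#' Restrict reactions to a target SOC
#'
#' A PT counts toward the target SOC if *any* of its SOC links matches
#' (multi-axiality).  Reactions whose PT is absent from the map are routed to
#' an `unmapped` table rather than dropped silently; mapped PTs outside the
#' SOC go to `out_of_soc`.
#'
#' @param reac reaction table (`primaryid`, `pt`).
#' @param pt_soc_map data frame from [read_pt_soc_map()].
#' @param target_soc SOC name (case-insensitive match).
#' @return list with data frames `events` (primaryid, pt, in SOC),
#'   `out_of_soc`, `unmapped`.
#' @export
select_target_events <- function(reac, pt_soc_map, target_soc) {
  pt_norm <- .norm_name(reac$pt)
  map_pt <- .norm_name(pt_soc_map$pt)
  map_soc <- .norm_name(pt_soc_map$soc)
  in_soc_pts <- unique(map_pt[map_soc == .norm_name(target_soc)])
  mapped <- pt_norm %in% map_pt
  hit <- pt_norm %in% in_soc_pts
  events <- reac[hit, c("primaryid", "pt"), drop = FALSE]
  events$pt <- trimws(events$pt)
  rownames(events) <- NULL
  list(events = events,
       out_of_soc = reac[mapped & !hit, c("primaryid", "pt"), drop = FALSE],
       unmapped = reac[!mapped, c("primaryid", "pt"), drop = FALSE])
}

.band_labels <- function(breaks, unit = "") {
  k <- length(breaks)
  inner <- if (k > 1L) {
    paste0(breaks[-k], "-", breaks[-1L])
  } else character(0)
  c(paste0("<", breaks[1L]), inner, paste0(">", breaks[k]))
}

.band_cut <- function(x, breaks) {
  # bands: < first edge, [e1, e2], ..., > last edge (edges inclusive inward)
  cut(x, breaks = c(-Inf, breaks[1L] - 1e-9, breaks[-1L] + 1e-9, Inf),
      labels = .band_labels(breaks), right = TRUE)
}

.count_pct <- function(tab, denom) {
  data.frame(category = names(tab), n = as.integer(tab),
             pct = if (denom > 0) round(100 * as.integer(tab) / denom, 2)
             else rep(NA_real_, length(tab)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Descriptive summary of the cohort
#'
#' Reproduces the standard spontaneous-report descriptive table: counts and
#' available-denominator percentages by sex, age band, weight band, country
#' (US vs non-US), indication group, outcome category, reporter type and
#' reporting year, plus medians of age and weight.  Seriousness is defined by
#' presence of any outcome code; category shares among serious cases use the
#' serious-case count as denominator (and may sum past 100% since a case can
#' carry several outcome codes).
#'
#' @param universe a `faers_universe`.
#' @param target_ids cohort primaryids from [match_target_cases()].
#' @param config a `study_config` (band edges, indication grouping).
#' @return a `cohort_summary` (list of per-variable data frames).
#' @export
describe_cohort <- function(universe, target_ids, config) {
  cases <- universe$cases[universe$cases$primaryid %in% target_ids, ,
                          drop = FALSE]
  n <- nrow(cases)
  if (n == 0L) stop("cohort is empty", call. = FALSE)
  out <- list(n_cases = n)

  sex <- cases$sex[cases$sex != "unknown"]
  out$sex <- list(available = length(sex),
                  table = .count_pct(table(factor(sex, c("female", "male"))),
                                     length(sex)))

  age <- cases$age_years[!is.na(cases$age_years)]
  out$age <- list(available = length(age),
                  median = if (length(age)) stats::median(age) else NA_real_,
                  table = .count_pct(table(.band_cut(age, config$age_breaks)),
                                     length(age)))

  wt <- cases$weight_kg[!is.na(cases$weight_kg)]
  out$weight <- list(available = length(wt),
                     median = if (length(wt)) stats::median(wt) else NA_real_,
                     table = .count_pct(table(.band_cut(wt, config$weight_breaks)),
                                        length(wt)))

  ctry <- cases$country[!is.na(cases$country)]
  us <- ctry %in% c("US", "USA", "UNITED STATES")
  out$country <- list(available = length(ctry),
                      table = .count_pct(table(factor(ifelse(us, "US", "Non-US"),
                                                      c("US", "Non-US"))),
                                         length(ctry)))

  # indications: one contribution per case, grouped if a map is configured
  indi <- universe$indi[universe$indi$primaryid %in% cases$primaryid, ,
                        drop = FALSE]
  indi <- indi[nzchar(trimws(indi$indi_pt)), , drop = FALSE]
  indi <- indi[!duplicated(indi$primaryid), , drop = FALSE]
  grp <- trimws(indi$indi_pt)
  if (!is.null(config$indication_groups)) {
    g <- rep("Others", length(grp))
    for (lab in names(config$indication_groups)) {
      g[.norm_name(grp) %in% .norm_name(config$indication_groups[[lab]])] <- lab
    }
    grp <- g
  }
  tab <- sort(table(grp), decreasing = TRUE)
  out$indications <- list(available = length(grp),
                          table = .count_pct(tab, length(grp)))

  labels <- classify_seriousness(universe)
  lab <- labels[match(cases$primaryid, labels$primaryid), , drop = FALSE]
  serious <- lab$serious
  n_serious <- sum(serious)
  cat_counts <- vapply(c("death", "life-threatening", "hospitalization",
                         "disability", "other"),
                       function(cc) sum(serious & grepl(cc, lab$categories,
                                                        fixed = TRUE)),
                       integer(1))
  out$outcomes <- list(
    available = n,
    n_serious = n_serious, n_nonserious = n - n_serious,
    pct_serious = round(100 * n_serious / n, 2),
    pct_nonserious = round(100 * (n - n_serious) / n, 2),
    categories = .count_pct(as.table(cat_counts), n_serious))

  rep_known <- cases$reporter[cases$reporter != "unknown"]
  out$reporters <- list(available = length(rep_known),
                        table = .count_pct(table(factor(rep_known,
                                                        c("health-professional",
                                                          "consumer"))),
                                           length(rep_known)))

  yr <- cases$receipt_year[!is.na(cases$receipt_year)]
  out$years <- list(available = length(yr),
                    table = .count_pct(table(yr), length(yr)))

  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_cases, "cases\n")
  cat(sprintf("  serious: %d (%.2f%%) | non-serious: %d (%.2f%%)\n",
              x$outcomes$n_serious, x$outcomes$pct_serious,
              x$outcomes$n_nonserious, x$outcomes$pct_nonserious))
  for (sec in c("sex", "age", "weight", "country", "reporters")) {
    s <- x[[sec]]
    cat(sprintf("  %s (available n = %d):\n", sec, s$available))
    tb <- s$table
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("    %-22s %6d  %s\n", tb$category[i], tb$n[i],
                  ifelse(is.na(tb$pct[i]), "", sprintf("(%.2f%%)", tb$pct[i]))))
    }
  }
  invisible(x)
}

#' Concomitant medication tabulation
#'
#' Counts, for each non-target drug name appearing with role SS, C or I on a
#' cohort report, the number of distinct cohort cases co-reporting it, with
#' the cohort size as percentage denominator.
#'
#' @param universe a `faers_universe`.
#' @param target_ids cohort primaryids.
#' @param config a `study_config` (to exclude the target drug's own names).
#' @return data frame `drugname`, `n`, `pct`, sorted by `n` descending.
#' @export
concomitant_drugs <- function(universe, target_ids, config) {
  drug <- universe$drug[universe$drug$primaryid %in% target_ids, ,
                        drop = FALSE]
  role <- .norm_name(drug$role_cod)
  dn <- .norm_name(drug$drugname)
  target_names <- c(config$generic_names, config$brand_names)
  is_target <- dn %in% target_names |
    .norm_name(drug$prod_ai) %in% config$generic_names
  co <- drug[role %in% c("SS", "C", "I") & !is_target, , drop = FALSE]
  if (nrow(co) == 0L) {
    return(data.frame(drugname = character(0), n = integer(0),
                      pct = numeric(0)))
  }
  key <- paste(co$primaryid, .norm_name(co$drugname), sep = "\r")
  co <- co[!duplicated(key), , drop = FALSE]
  tab <- sort(table(.norm_name(co$drugname)), decreasing = TRUE)
  data.frame(drugname = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(target_ids), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
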