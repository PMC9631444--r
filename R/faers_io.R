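# Reading, validating and deduplicating FAERS quarterly ASCII bundles.
#
# The public FAERS Quarterly Data Extract distributes one header line and one
# `$`-separated record per line.  Only the columns this pipeline consumes are
# required; tables are matched by filename prefix (DEMO*.txt, DRUG*.txt, ...).

.faers_tables <- c("demo", "drug", "reac", "outc", "ther", "indi")

.faers_columns <- list(
  demo = c("primaryid", "caseid", "event_dt", "fda_dt", "age", "age_cod",
           "sex", "wt", "wt_cod", "reporter_country", "occp_cod"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

# FAERS drug role codes: primary suspect, secondary suspect, concomitant,
# interacting.
.faers_roles <- c("PS", "SS", "C", "I")

#' Read one `$`-delimited FAERS table
#'
#' Lines whose field count does not match the header are skipped and counted;
#' rows whose `primaryid` (or `caseid`, where present) is not numeric are
#' likewise skipped.  An unknown column name is a fatal error, as is a missing
#' mandatory column.
#'
#' @param path path to a single ASCII table file.
#' @param table one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`,
#'   `"indi"`.
#' @return a `data.frame` of character columns with attributes `n_skipped`
#'   (malformed lines) and `n_bad_id` (non-numeric ids).
#' @export
read_faers_table <- function(path, table) {
  table <- match.arg(tolower(table), .faers_tables)
  if (!file.exists(path)) {
    stop("FAERS table file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("FAERS table file is empty (no header line): ", path, call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  wanted <- .faers_columns[[table]]
  unknown <- setdiff(header, wanted)
  if (length(unknown) > 0L) {
    stop("unknown column header(s) in ", toupper(table), " table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(wanted, header)
  if (length(missing) > 0L) {
    stop("missing mandatory column(s) in ", toupper(table), " table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n_skipped <- 0L
  n_bad_id <- 0L
  if (length(body) > 0L) {
    fields <- strsplit(body, "$", fixed = TRUE)
    # strsplit drops a trailing empty field; pad rows short by exactly one
    nf <- lengths(fields)
    pad <- nf == length(header) - 1L & endsWith(body, "$")
    fields[pad] <- lapply(fields[pad], function(f) c(f, ""))
    nf[pad] <- length(header)
    ok <- nf == length(header)
    n_skipped <- sum(!ok)
    fields <- fields[ok]
  } else {
    fields <- list()
  }
  if (length(fields) == 0L) {
    out <- as.data.frame(matrix(character(), ncol = length(wanted),
                                dimnames = list(NULL, wanted)))
  } else {
    mat <- do.call(rbind, fields)
    colnames(mat) <- header
    out <- as.data.frame(mat[, wanted, drop = FALSE])
  }
  out$primaryid <- suppressWarnings(as.numeric(trimws(out$primaryid)))
  out$caseid <- suppressWarnings(as.numeric(trimws(out$caseid)))
  bad <- is.na(out$primaryid) | is.na(out$caseid)
  n_bad_id <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_bad_id") <- n_bad_id
  out
}

.find_table_file <- function(dir, prefix) {
  files <- list.files(dir, full.names = TRUE)
  hit <- files[grepl(paste0("^", prefix), basename(files),
                     ignore.case = TRUE)]
  if (length(hit) == 0L) return(NULL)
  sort(hit)[[1L]]
}

#' Load a FAERS quarterly bundle from a directory
#'
#' Expects files named `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`, `OUTC*.txt`,
#' `THER*.txt`, `INDI*.txt` (case-insensitive) and, optionally, a deleted-case
#' list `DELETED*.txt` with one caseid per line.  Records in the non-DEMO
#' tables whose `primaryid` is absent from DEMO are counted as orphans and
#' dropped; duplicated `(primaryid, pt)` reaction rows collapse to one.
#'
#' @param dir directory containing the bundle.
#' @param quarter optional quarter label, e.g. `"2018Q1"`.
#' @return a `faers_bundle`: a list with one data frame per table, the
#'   `deleted_caseids` vector, the `quarter` label and a `parse_report`
#'   (per-table row/skip/orphan counts).
#' @export
read_faers_bundle <- function(dir, quarter = NULL) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir, call. = FALSE)
  tables <- list()
  report <- list()
  for (tb in .faers_tables) {
    path <- .find_table_file(dir, tb)
    if (is.null(path)) {
      stop("mandatory FAERS table missing from bundle: ", toupper(tb),
           call. = FALSE)
    }
    parsed <- read_faers_table(path, tb)
    report[[tb]] <- list(file = basename(path), n_rows = nrow(parsed),
                         n_skipped = attr(parsed, "n_skipped"),
                         n_bad_id = attr(parsed, "n_bad_id"))
    attr(parsed, "n_skipped") <- NULL
    attr(parsed, "n_bad_id") <- NULL
    tables[[tb]] <- parsed
  }
  deleted <- numeric(0)
  del_path <- .find_table_file(dir, "delet")
  if (!is.null(del_path)) {
    raw <- trimws(readLines(del_path, warn = FALSE))
    raw <- raw[nzchar(raw) & tolower(raw) != "caseid"]
    deleted <- suppressWarnings(as.numeric(raw))
    deleted <- deleted[!is.na(deleted)]
  }
  as_faers_bundle(tables, deleted_caseids = deleted, quarter = quarter,
                  parse_report = report)
}

#' Assemble a FAERS bundle from in-memory tables
#'
#' Applies the same referential checks as [read_faers_bundle()]: orphan
#' records (primaryids absent from DEMO) are counted and dropped, and
#' duplicate `(primaryid, pt)` reaction rows collapse to one.
#'
#' @param tables named list with data frames `demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi` carrying the columns of the FAERS dialect.
#' @param deleted_caseids numeric vector of caseids slated for removal.
#' @param quarter optional quarter label.
#' @param parse_report optional per-table parse bookkeeping to carry along.
#' @return a `faers_bundle`.
#' @export
as_faers_bundle <- function(tables, deleted_caseids = numeric(0),
                            quarter = NULL, parse_report = NULL) {
  stopifnot(all(.faers_tables %in% names(tables)))
  tables <- tables[.faers_tables]
  for (tb in .faers_tables) {
    need <- .faers_columns[[tb]]
    if (!all(need %in% names(tables[[tb]]))) {
      stop("table ", toupper(tb), " lacks required columns", call. = FALSE)
    }
    tables[[tb]]$primaryid <- as.numeric(tables[[tb]]$primaryid)
    tables[[tb]]$caseid <- as.numeric(tables[[tb]]$caseid)
  }
  known <- unique(tables$demo$primaryid)
  orphans <- integer(length(.faers_tables))
  names(orphans) <- .faers_tables
  for (tb in setdiff(.faers_tables, "demo")) {
    keep <- tables[[tb]]$primaryid %in% known
    orphans[[tb]] <- sum(!keep)
    tables[[tb]] <- tables[[tb]][keep, , drop = FALSE]
  }
  # multi-axial duplicates of the same reported reaction collapse to one
  rk <- paste(tables$reac$primaryid, toupper(trimws(tables$reac$pt)),
              sep = "\r")
  tables$reac <- tables$reac[!duplicated(rk), , drop = FALSE]
  for (tb in .faers_tables) rownames(tables[[tb]]) <- NULL
  structure(list(demo = tables$demo, drug = tables$drug, reac = tables$reac,
                 outc = tables$outc, ther = tables$ther, indi = tables$indi,
                 deleted_caseids = as.numeric(deleted_caseids),
                 quarter = quarter,
                 parse_report = c(parse_report,
                                  list(orphans_dropped = as.list(orphans)))),
            class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS bundle", if (!is.null(x$quarter)) paste0("(", x$quarter, ")"),
      "\n")
  for (tb in .faers_tables) {
    cat(sprintf("  %-5s %7d records\n", toupper(tb), nrow(x[[tb]])))
  }
  cat(sprintf("  deleted-case list: %d caseids\n", length(x$deleted_caseids)))
  invisible(x)
}

#' Write a bundle back to the FAERS ASCII dialect
#'
#' One header line, `$`-separated fields, one record per line.  Round-trips
#' through [read_faers_bundle()] field-for-field.
#'
#' @param bundle a `faers_bundle` (or a bare named list of the six tables).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in .faers_tables) {
    df <- bundle[[tb]][, .faers_columns[[tb]], drop = FALSE]
    for (j in seq_along(df)) {
      v <- df[[j]]
      out <- if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE)
      else as.character(v)
      df[[j]] <- ifelse(is.na(v), "", out)
    }
    lines <- c(paste(names(df), collapse = "$"),
               do.call(paste, c(unname(df), sep = "$")))
    writeLines(lines, file.path(dir, paste0(toupper(tb), ".txt")))
  }
  del <- bundle$deleted_caseids
  if (!is.null(del)) {
    writeLines(c("caseid", format(del, trim = TRUE, scientific = FALSE)),
               file.path(dir, "DELETED.txt"))
  }
  invisible(dir)
}

# ---- demographic normalization -------------------------------------------

# FAERS age unit codes to years; weight unit codes to kg.
.age_factor <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25,
                 DEC = 10, HR = 1 / 8765.8)
.wt_factor <- c(KG = 1, KGS = 1, LBS = 0.453592, GMS = 1 / 1000)

#' Convert a FAERS age field to years
#'
#' @param value raw age value (character or numeric).
#' @param unit FAERS age unit code (`YR`, `MON`, `WK`, `DY`, `DEC`, `HR`).
#' @return age in years; `NA` when the value or unit is absent, non-numeric,
#'   unknown, or non-positive.
#' @export
convert_age_years <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  f <- .age_factor[toupper(trimws(as.character(unit)))]
  out <- unname(v * f)
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}

#' Convert a FAERS weight field to kilograms
#'
#' @param value raw weight value.
#' @param unit FAERS weight unit code (`KG`, `LBS`, `GMS`).
#' @return weight in kg, `NA` when unconvertible or non-positive.
#' @export
convert_weight_kg <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  f <- .wt_factor[toupper(trimws(as.character(unit)))]
  out <- unname(v * f)
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}

#' Parse a FAERS date field
#'
#' Only complete 8-digit `YYYYMMDD` entries yield a date; partial entries
#' (`YYYY`, `YYYYMM`) and malformed strings are missing.  The year component
#' of any entry with at least four digits is retained separately for
#' reporting-year tabulation.
#'
#' @param x character vector of raw date fields.
#' @return a list with `date` (`Date`, `NA` unless complete and valid) and
#'   `year` (integer, `NA` unless a 4-digit year prefix is present).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  digits <- grepl("^[0-9]+$", x)
  year <- rep(NA_integer_, length(x))
  full <- digits & nchar(x) >= 4L
  year[full] <- as.integer(substr(x[full], 1L, 4L))
  year[!is.na(year) & (year < 1900L | year > 2100L)] <- NA_integer_
  date <- rep(as.Date(NA), length(x))
  cand <- digits & nchar(x) == 8L
  if (any(cand)) {
    d <- as.Date(x[cand], format = "%Y%m%d")
    date[cand] <- d
  }
  list(date = date, year = year)
}

.reporter_map <- function(occp) {
  occp <- toupper(trimws(as.character(occp)))
  out <- rep("unknown", length(occp))
  out[occp %in% c("MD", "PH", "OT", "HP", "RN")] <- "health-professional"
  out[occp == "CN"] <- "consumer"
  out
}

.sex_map <- function(sex) {
  sex <- toupper(trimws(as.character(sex)))
  out <- rep("unknown", length(sex))
  out[sex == "F"] <- "female"
  out[sex == "M"] <- "male"
  out
}

.normalize_demo <- function(demo) {
  ev <- parse_faers_date(demo$event_dt)
  fda <- parse_faers_date(demo$fda_dt)
  country <- toupper(trimws(demo$reporter_country))
  country[!nzchar(country)] <- NA_character_
  data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    sex = .sex_map(demo$sex),
    age_years = convert_age_years(demo$age, demo$age_cod),
    weight_kg = convert_weight_kg(demo$wt, demo$wt_cod),
    country = country,
    reporter = .reporter_map(demo$occp_cod),
    event_date = ev$date,
    event_year = ev$year,
    receipt_year = fda$year,
    stringsAsFactors = FALSE
  )
}

# ---- deduplication --------------------------------------------------------

#' Deduplicate a bundle into the case universe
#'
#' FAERS reports are versioned: several `primaryid`s may share one `caseid`.
#' One case survives per caseid — the row with the numerically largest
#' primaryid (ties broken by keeping the last-read row) — and caseids on the
#' deletion list are removed entirely.  The child tables (DRUG, REAC, OUTC,
#' THER, INDI) are restricted to the surviving primaryids.  The operation is
#' idempotent and independent of input row order.
#'
#' @param bundle a `faers_bundle`.
#' @return a `faers_universe`: list with the normalized `cases` data frame
#'   (one row per surviving case: demographics in analysis units, parsed
#'   dates, reporting year) plus the filtered child tables and dedup counts.
#' @export
deduplicate_cases <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  demo <- bundle$demo
  n_in <- nrow(demo)
  if (n_in > 0L) {
    ord <- order(demo$caseid, demo$primaryid, seq_len(n_in))
    demo <- demo[ord, , drop = FALSE]
    demo <- demo[!duplicated(demo$caseid, fromLast = TRUE), , drop = FALSE]
  }
  n_dup <- n_in - nrow(demo)
  deleted <- demo$caseid %in% bundle$deleted_caseids
  n_del <- sum(deleted)
  demo <- demo[!deleted, , drop = FALSE]
  keep <- demo$primaryid
  out <- list(cases = .normalize_demo(demo))
  for (tb in setdiff(.faers_tables, "demo")) {
    tab <- bundle[[tb]]
    out[[tb]] <- tab[tab$primaryid %in% keep, , drop = FALSE]
    rownames(out[[tb]]) <- NULL
  }
  rownames(out$cases) <- NULL
  out$n_input_rows <- n_in
  out$n_removed_duplicates <- n_dup
  out$n_removed_deleted <- n_del
  out$quarter <- bundle$quarter
  class(out) <- "faers_universe"
  out
}

#' @export
print.faers_universe <- function(x, ...) {
  cat("FAERS deduplicated case universe\n")
  cat(sprintf("  cases: %d (from %d DEMO rows; %d duplicate versions, %d deleted)\n",
              nrow(x$cases), x$n_input_rows, x$n_removed_duplicates,
              x$n_removed_deleted))
  cat(sprintf("  drug rows: %d | reaction rows: %d | outcome rows: %d\n",
              nrow(x$drug), nrow(x$reac), nrow(x$outc)))
  invisible(x)
}
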