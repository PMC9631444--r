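# Time-to-onset (TTO) analysis: exclusion rules, nonparametric summaries,
# Weibull maximum-likelihood fit (the WSP test) and failure-type
# classification from the shape parameter's confidence interval.

#' Compute time-to-onset samples
#'
#' TTO is the whole-day interval from the earliest complete therapy start
#' date of the target drug to the case's event onset date.  Candidate
#' (case, PT) pairs are the cohort's SOC events; pairs are excluded — and
#' counted per reason — when the event date is missing, the start date is
#' missing or partial, or the event precedes the start (an input error).
#'
#' @param universe a `faers_universe`.
#' @param target_ids cohort primaryids.
#' @param events SOC-restricted event table (`primaryid`, `pt`).
#' @param config a `study_config` (identifies the target drug's THER rows).
#' @return data frame `primaryid`, `pt`, `tto_days` with attribute
#'   `exclusions`: named counts (`missing_event_date`, `missing_start_date`,
#'   `event_before_start`) such that exclusions + rows = candidate pairs.
#' @export
compute_tto <- function(universe, target_ids, events, config) {
  cases <- universe$cases
  drug <- universe$drug
  target_rows <- .target_drug_rows(universe, config) &
    .norm_name(drug$role_cod) == "PS"
  td <- drug[target_rows & drug$primaryid %in% target_ids, , drop = FALSE]
  ther <- universe$ther
  key_d <- paste(td$primaryid, trimws(td$drug_seq), sep = "\r")
  key_t <- paste(ther$primaryid, trimws(ther$dsg_drug_seq), sep = "\r")
  ther <- ther[key_t %in% key_d, , drop = FALSE]
  start <- parse_faers_date(ther$start_dt)$date
  ok <- !is.na(start)
  starts <- vapply(split(as.numeric(start[ok]), ther$primaryid[ok]), min,
                   numeric(1))
  cand <- events[events$primaryid %in% target_ids, , drop = FALSE]
  ev_date <- cases$event_date[match(cand$primaryid, cases$primaryid)]
  st_date <- starts[as.character(cand$primaryid)]
  miss_ev <- is.na(ev_date)
  miss_st <- !miss_ev & is.na(st_date)
  tto <- as.numeric(ev_date) - st_date
  neg <- !miss_ev & !miss_st & tto < 0
  keep <- !miss_ev & !miss_st & !neg
  out <- data.frame(primaryid = cand$primaryid[keep],
                    pt = trimws(cand$pt[keep]),
                    tto_days = as.integer(tto[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(missing_event_date = sum(miss_ev),
                               missing_start_date = sum(miss_st),
                               event_before_start = sum(neg))
  out
}

#' Summarize TTO samples
#'
#' Median and quartiles by the linear-interpolation convention
#' (`stats::quantile` type 7), with integer min and max.
#'
#' @param tto_days numeric vector of TTO samples (days).
#' @return list `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_tto <- function(tto_days) {
  tto_days <- tto_days[!is.na(tto_days)]
  if (length(tto_days) == 0L) stop("no TTO samples to summarize",
                                   call. = FALSE)
  q <- stats::quantile(tto_days, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(tto_days), median = q[2], q1 = q[1], q3 = q[3],
       min = min(tto_days), max = max(tto_days))
}

# profile log-likelihood machinery: for fixed shape b, the MLE of the scale
# is a(b) = (mean(t^b))^(1/b); the profile score in b has a single root.
.weibull_profile_score <- function(b, x) {
  w <- exp(b * x)
  1 / b + mean(x) - sum(w * x) / sum(w)
}

.weibull_loglik <- function(u, v, x) {
  # u = log alpha, v = log beta
  b <- exp(v)
  z <- b * (x - u)
  length(x) * v - sum(exp(z)) + sum(z) - sum(x)
}

# analytic Hessian of the log-likelihood in (u, v) = (log alpha, log beta)
.weibull_hessian <- function(u, v, x) {
  b <- exp(v)
  n <- length(x)
  w <- x - u
  ez <- exp(b * w)
  s0 <- sum(ez); s1 <- sum(ez * w); s2 <- sum(ez * w^2)
  l_uu <- -b^2 * s0
  l_uv <- -n * b + b * s0 + b^2 * s1
  l_vv <- b * sum(w) - b * s1 - b^2 * s2
  matrix(c(l_uu, l_uv, l_uv, l_vv), 2, 2)
}

#' Fit a Weibull distribution to TTO samples
#'
#' Maximum likelihood via the one-dimensional profile score in the shape
#' parameter (root-bracketed, relative tolerance 1e-8), with the scale in
#' closed form given the shape.  Confidence intervals are Wald intervals on
#' the log-parameter scale (positivity-respecting), using the analytic
#' observed information at the optimum.  Zero-day samples (same-day onset)
#' enter the likelihood shifted to `zero_shift` days; summaries keep the
#' zeros.
#'
#' @param tto_days numeric vector of TTO samples in days (>= 0).
#' @param zero_shift value substituted for exact zeros in the likelihood
#'   (default 0.5, the midpoint of a same-day event).
#' @param conf confidence level (default 0.95).
#' @return a `weibull_tto` fit: `n`, `scale` (alpha, days), `shape` (beta),
#'   `scale_ci`, `shape_ci`, `vcov_log` (on the log scale), `loglik`,
#'   `failure_type`, and the [summarize_tto()] summary.
#' @export
fit_weibull_tto <- function(tto_days, zero_shift = 0.5, conf = 0.95) {
  t0 <- tto_days[!is.na(tto_days)]
  n <- length(t0)
  if (n < 2L) stop("need at least two TTO samples", call. = FALSE)
  if (n < 10L) warning("fewer than 10 TTO samples: estimates are unstable",
                       call. = FALSE)
  stopifnot(all(t0 >= 0), zero_shift > 0)
  t <- ifelse(t0 == 0, zero_shift, t0)
  if (stats::sd(t) == 0) {
    stop("degenerate fit: all TTO samples are identical", call. = FALSE)
  }
  x <- log(t)
  # bracket the profile score root; the score is decreasing in the shape
  lo <- 0.01; hi <- 1
  while (.weibull_profile_score(hi, x) > 0 && hi < 1e3) hi <- hi * 2
  while (.weibull_profile_score(lo, x) < 0 && lo > 1e-8) lo <- lo / 2
  root <- stats::uniroot(.weibull_profile_score, c(lo, hi), x = x,
                         tol = 1e-8 * max(1, hi))
  beta <- root$root
  alpha <- mean(exp(beta * x))^(1 / beta)
  u <- log(alpha); v <- log(beta)
  H <- .weibull_hessian(u, v, x)
  vc <- solve(-H)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(diag(vc))
  scale_ci <- exp(u + c(-1, 1) * z * se[1])
  shape_ci <- exp(v + c(-1, 1) * z * se[2])
  fit <- structure(list(n = n, scale = alpha, shape = beta,
                        scale_ci = scale_ci, shape_ci = shape_ci,
                        vcov_log = vc, conf = conf,
                        loglik = .weibull_loglik(u, v, x),
                        zero_shift = zero_shift,
                        summary = summarize_tto(t0)),
                   class = "weibull_tto")
  fit$failure_type <- classify_failure_type(fit)
  fit
}

#' Classify the hazard behaviour from the Weibull shape CI
#'
#' Early failure (decreasing hazard) when the shape CI lies entirely below
#' 1; wear-out (increasing hazard) when entirely above 1; random
#' (near-constant hazard) otherwise.
#'
#' @param fit a `weibull_tto` fit.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure_type <- function(fit) {
  stopifnot(inherits(fit, "weibull_tto"))
  if (fit$shape_ci[2] < 1) "early"
  else if (fit$shape_ci[1] > 1) "wear-out"
  else "random"
}

#' @export
coef.weibull_tto <- function(object, ...) {
  c(scale = object$scale, shape = object$shape)
}

#' @export
vcov.weibull_tto <- function(object, ...) {
  vc <- object$vcov_log
  dimnames(vc) <- list(c("log(scale)", "log(shape)"),
                       c("log(scale)", "log(shape)"))
  vc
}

#' @export
logLik.weibull_tto <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
confint.weibull_tto <- function(object, parm = c("scale", "shape"),
                                level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  m <- rbind(scale = object$scale_ci, shape = object$shape_ci)
  colnames(m) <- sprintf("%g %%", 100 * c((1 - object$conf) / 2,
                                          1 - (1 - object$conf) / 2))
  m[parm, , drop = FALSE]
}

#' @export
print.weibull_tto <- function(x, digits = 3, ...) {
  s <- x$summary
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", x$n))
  cat(sprintf("  TTO days: median %s (IQR %s-%s), range %s-%s\n",
              format(s$median), format(s$q1), format(s$q3), format(s$min),
              format(s$max)))
  cat(sprintf("  scale alpha = %.*g  [%.*g, %.*g]\n", digits, x$scale,
              digits, x$scale_ci[1], digits, x$scale_ci[2]))
  cat(sprintf("  shape beta  = %.*g  [%.*g, %.*g]\n", digits, x$shape,
              digits, x$shape_ci[1], digits, x$shape_ci[2]))
  cat("  failure type:", x$failure_type, "\n")
  invisible(x)
}

#' @export
summary.weibull_tto <- function(object, ...) {
  c(list(n = object$n, scale = object$scale, shape = object$shape,
         scale_ci = object$scale_ci, shape_ci = object$shape_ci,
         failure_type = object$failure_type), object$summary)
}

#' Pooled TTO analysis by clinical-priority band
#'
#' Pools TTO samples over the PTs of each priority band and fits one
#' Weibull per band, mirroring the strong/moderate/weak presentation.
#'
#' @param samples TTO samples from [compute_tto()].
#' @param scores a `priority_scores` data frame mapping PT to band.
#' @param min_n bands with fewer samples are reported without a fit.
#' @return data frame, one row per band: `band`, `n`, `median`, `q1`, `q3`,
#'   `min`, `max`, `alpha`, `alpha_lo`, `alpha_hi`, `beta`, `beta_lo`,
#'   `beta_hi`, `failure_type`.
#' @export
tto_by_band <- function(samples, scores, min_n = 10) {
  band <- scores$band[match(.norm_name(samples$pt), .norm_name(scores$pt))]
  rows <- lapply(c("strong", "moderate", "weak"), function(bd) {
    tt <- samples$tto_days[!is.na(band) & band == bd]
    if (length(tt) == 0L) return(NULL)
    s <- summarize_tto(tt)
    base <- data.frame(band = bd, n = s$n, median = s$median, q1 = s$q1,
                       q3 = s$q3, min = s$min, max = s$max,
                       stringsAsFactors = FALSE)
    if (length(tt) >= min_n && stats::sd(pmax(tt, 0.5)) > 0) {
      f <- fit_weibull_tto(tt)
      cbind(base, data.frame(alpha = f$scale, alpha_lo = f$scale_ci[1],
                             alpha_hi = f$scale_ci[2], beta = f$shape,
                             beta_lo = f$shape_ci[1],
                             beta_hi = f$shape_ci[2],
                             failure_type = f$failure_type,
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, data.frame(alpha = NA_real_, alpha_lo = NA_real_,
                             alpha_hi = NA_real_, beta = NA_real_,
                             beta_lo = NA_real_, beta_hi = NA_real_,
                             failure_type = NA_character_,
                             stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
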