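#' @name landscape
#' @title Cohort landscape summaries
#' @description
#' Cohort-level reporting: eligibility filtering (one specimen per
#' patient, minimum median exon coverage), per-disease TMB distributions
#' with the fraction of high-TMB cases (> 20 mutations/Mb) and Wilson
#' binomial confidence intervals, the log-linear age trend, the MSI-by-TMB
#' cross-tabulation, and the fraction of high-TMB cases explained by
#' listed driver lesions.
NULL

# round half away from zero at a given number of decimals (display rule
# for printed percentages; base round() is round-half-even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage from a count pair under the display rounding rule
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits decimals to keep (half-away-from-zero; default 1).
#' @return percentage `100 k / n` rounded for display.
#' @export
tally_percent <- function(k, n, digits = 1L) {
  if (any(n <= 0) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n, n > 0", call. = FALSE)
  round_half_up(100 * k / n, digits)
}

#' Filter a cohort to eligible specimens
#'
#' Duplicate assays for the same patient are dropped (first occurrence in
#' the stable input order is kept), then specimens with median exon
#' coverage below `min_coverage` are dropped. Idempotent.
#'
#' @param specimens data.frame with `patient_id` and `median_coverage`.
#' @param min_coverage minimum retained coverage (default 300; a specimen
#'   at 299x is excluded, 300x retained).
#' @return list: `specimens` (eligible rows), `excluded` (named counts by
#'   reason: duplicate, low_coverage).
#' @export
filter_cohort <- function(specimens, min_coverage = 300) {
  if (!nrow(specimens))
    return(list(specimens = specimens,
                excluded = c(duplicate = 0L, low_coverage = 0L)))
  dup <- duplicated(specimens$patient_id)
  kept <- specimens[!dup, , drop = FALSE]
  low <- kept$median_coverage < min_coverage
  list(specimens = {
    out <- kept[!low, , drop = FALSE]; rownames(out) <- NULL; out
  }, excluded = c(duplicate = sum(dup), low_coverage = sum(low)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` in percent.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n)
    stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  if (level >= 1) return(c(low = 0, high = 100))
  z <- qnorm(1 - (1 - level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  100 * c(low = max(0, center - half), high = min(1, center + half))
}

#' Per-disease TMB summary (Table-1 style)
#'
#' Diseases with at least `min_n` specimens are summarized: median and
#' quartiles of TMB (type-7 quantiles) and the percentage of cases with
#' TMB strictly above `high_threshold`, with a Wilson interval.
#'
#' @param specimens data.frame with `disease` and `tmb`.
#' @param high_threshold high-TMB cutoff in mutations/Mb (default 20,
#'   strict `>`).
#' @param min_n minimum specimens per summarized disease (default 50).
#' @param level CI level (default 0.95).
#' @return data.frame sorted by `pct_high` descending: `disease`, `n`,
#'   `median_tmb`, `q25`, `q75`, `n_high`, `pct_high`, `ci_low`,
#'   `ci_high`.
#' @export
disease_summary <- function(specimens, high_threshold = 20, min_n = 50L,
                            level = 0.95) {
  stopifnot(all(c("disease", "tmb") %in% names(specimens)))
  if (any(is.na(specimens$tmb))) stop("tmb must be present", call. = FALSE)
  sp <- split(specimens$tmb, specimens$disease)
  sp <- sp[vapply(sp, length, 0L) >= min_n]
  rows <- lapply(names(sp), function(d) {
    x <- sp[[d]]
    k <- sum(x > high_threshold)
    ci <- binomial_ci(k, length(x), level)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(disease = d, n = length(x), median_tmb = q[2], q25 = q[1],
               q75 = q[3], n_high = k, pct_high = 100 * k / length(x),
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(disease = character(0), n = integer(0),
                      median_tmb = numeric(0), q25 = numeric(0),
                      q75 = numeric(0), n_high = integer(0),
                      pct_high = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  out <- out[order(-out$pct_high, out$disease), ]
  rownames(out) <- NULL
  out
}

#' Age trend of TMB
#'
#' Least squares of `log10(tmb + pseudo_count)` on age in years. The
#' fold-change between two ages is `10^(slope * (a2 - a1))`; the
#' conventional report is the fold between ages 10 and 90.
#'
#' @param specimens data.frame with `age` and `tmb`.
#' @param pseudo_count added to TMB before log10 (default 0; specimens
#'   with `tmb + pseudo_count <= 0` are dropped with a warning).
#' @return list: `slope` (log10 TMB per year), `se`, `p_value`,
#'   `fold_10_90`, `n`.
#' @export
age_trend <- function(specimens, pseudo_count = 0) {
  stopifnot(all(c("age", "tmb") %in% names(specimens)))
  y0 <- specimens$tmb + pseudo_count
  keep <- y0 > 0 & is.finite(specimens$age)
  if (sum(keep) < nrow(specimens))
    warning(sum(!keep), " specimen(s) dropped (tmb + pseudo_count <= 0)")
  age <- specimens$age[keep]
  if (length(unique(age)) < 2)
    stop("age_trend needs at least 2 distinct ages", call. = FALSE)
  fit <- lm(log10(y0[keep]) ~ age)
  sm <- summary(fit)$coefficients
  slope <- sm["age", "Estimate"]
  list(slope = unname(slope), se = unname(sm["age", "Std. Error"]),
       p_value = unname(sm["age", "Pr(>|t|)"]),
       fold_10_90 = unname(10^(slope * 80)), n = sum(keep))
}

#' MSI-by-TMB cross-tabulation
#'
#' Reports the conditional proportions that relate the two biomarkers:
#' P(TMB > high | MSI-H), P(TMB >= msi_tmb_threshold | MSI-H) and
#' P(MSI-H | TMB > high), plus a per-disease decomposition. Conditionals
#' with an empty conditioning set are reported as undefined (`NA` with
#' `defined = FALSE`), never as 0.
#'
#' @param specimens data.frame with `tmb` and `msi_call` (values
#'   `"MSI-H"`, `"ambiguous"`, `"MSS"`) and optionally `disease`.
#' @param high_threshold high-TMB cutoff (default 20, strict `>`).
#' @param msi_tmb_threshold secondary TMB cutoff (default 10, `>=`).
#' @return list: `p_high_given_msih`, `p_ge_thr_given_msih`,
#'   `p_msih_given_high`, `defined` (named logicals), `counts`,
#'   `by_disease` (data.frame or NULL).
#' @export
msi_tmb_crosstab <- function(specimens, high_threshold = 20,
                             msi_tmb_threshold = 10) {
  stopifnot(all(c("tmb", "msi_call") %in% names(specimens)))
  msih <- specimens$msi_call == "MSI-H"
  high <- specimens$tmb > high_threshold
  ge <- specimens$tmb >= msi_tmb_threshold
  prop <- function(num, den) if (sum(den) == 0) NA_real_
          else sum(num & den) / sum(den)
  by_disease <- NULL
  if (!is.null(specimens$disease)) {
    sp <- split(seq_len(nrow(specimens)), specimens$disease)
    by_disease <- do.call(rbind, lapply(names(sp), function(d) {
      i <- sp[[d]]
      data.frame(disease = d, n = length(i), n_msih = sum(msih[i]),
                 n_high = sum(high[i]),
                 p_msih_given_high = prop(msih[i], high[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(p_high_given_msih = prop(high, msih),
       p_ge_thr_given_msih = prop(ge, msih),
       p_msih_given_high = prop(msih, high),
       defined = c(msih = sum(msih) > 0, high = sum(high) > 0),
       counts = c(n = nrow(specimens), n_msih = sum(msih),
                  n_high = sum(high)),
       by_disease = by_disease)
}

#' Fraction of high-TMB specimens explained by listed drivers
#'
#' @param specimens data.frame with `tmb`.
#' @param driver logical vector (or matrix of flags, any TRUE per row)
#'   marking specimens that carry any listed driver lesion.
#' @param high_threshold high-TMB cutoff (default 20, strict `>`).
#' @param level CI level for the Wilson interval.
#' @return list: `k`, `n`, `percent`, `ci` (percent), `defined`.
#' @export
explained_fraction <- function(specimens, driver, high_threshold = 20,
                               level = 0.95) {
  if (is.matrix(driver) || is.data.frame(driver))
    driver <- apply(driver, 1, any)
  driver <- as.logical(driver)
  stopifnot(length(driver) == nrow(specimens))
  high <- specimens$tmb > high_threshold
  n <- sum(high)
  if (n == 0)
    return(list(k = 0L, n = 0L, percent = NA_real_, ci = c(NA, NA),
                defined = FALSE))
  k <- sum(driver & high)
  list(k = k, n = n, percent = 100 * k / n, ci = binomial_ci(k, n, level),
       defined = TRUE)
}
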