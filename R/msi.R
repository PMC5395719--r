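#' @name msi
#' @title Microsatellite instability scoring
#' @description
#' MSI status is inferred from length variability of intronic homopolymer
#' repeats captured by the panel. For each locus, the repeat length in
#' every read spanning it is recorded; per-locus means and variances over
#' reads form the feature vector (2 features per locus, 228 for the
#' default 114-locus panel). Principal components analysis of the
#' centered feature matrix projects specimens onto the first principal
#' component — the "MSI score" — which is then partitioned into
#' MSI-High / MSI-ambiguous / MSS ranges.
NULL

#' Default 114-locus homopolymer panel
#'
#' A deterministic stand-in for the assay's 114 selected intronic
#' homopolymer loci (synthetic coordinates; reference repeat lengths cycle
#' over the 10-20 bp range the assay requires so slippage is frequent yet
#' loci remain within a 49 bp read).
#'
#' @param n number of loci (default 114).
#' @return data.frame: `locus_id`, `chrom`, `start`, `end`,
#'   `reference_repeat_len`, `intronic`.
#' @export
default_msi_loci <- function(n = 114L) {
  ref_len <- 10L + (seq_len(n) * 7L) %% 11L   # cycles through 10..20
  start <- 2000000L + seq_len(n) * 50000L
  data.frame(
    locus_id = sprintf("MSI%03d", seq_len(n)),
    chrom = paste0("chr", (seq_len(n) %% 22L) + 1L),
    start = start, end = start + ref_len - 1L,
    reference_repeat_len = ref_len, intronic = TRUE,
    stringsAsFactors = FALSE)
}

#' Select the most variable loci for the MSI panel
#'
#' Given candidate loci annotated with between-sample variability of mean
#' repeat length, retain the `k` most variable. Ties break
#' lexicographically on `locus_id` so selection is deterministic.
#'
#' @param candidates data.frame with `locus_id` and `variability` columns
#'   (candidates are assumed pre-filtered to intronic loci with reference
#'   repeat length 10-20 bp).
#' @param k panel size (default 114).
#' @return the selected rows, ordered by locus_id.
#' @export
select_loci <- function(candidates, k = 114L) {
  stopifnot(all(c("locus_id", "variability") %in% names(candidates)))
  if (k > nrow(candidates))
    stop("k exceeds the number of candidate loci", call. = FALSE)
  ord <- order(-candidates$variability, candidates$locus_id)
  sel <- candidates[ord[seq_len(k)], , drop = FALSE]
  sel <- sel[order(sel$locus_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Featurize an MSI profile
#'
#' Concatenates per-locus (mean, variance) of read repeat lengths in fixed
#' panel order; the default 114-locus panel yields 228 features. Variances
#' use the n-1 denominator, so every locus needs at least 2 reads.
#'
#' @param profile long-format profile for one specimen (`specimen_id`,
#'   `locus_id`, `repeat_length`).
#' @param loci locus panel (default [default_msi_loci()]).
#' @return named numeric vector of length `2 * nrow(loci)`
#'   (`<locus>_mean`, `<locus>_var`).
#' @export
featurize <- function(profile, loci = default_msi_loci()) {
  sp <- split(profile$repeat_length, profile$locus_id)
  missing <- setdiff(loci$locus_id, names(sp))
  if (length(missing))
    stop("profile missing data for locus: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  few <- loci$locus_id[vapply(sp[loci$locus_id], length, 0L) < 2L]
  if (length(few))
    stop("locus with fewer than 2 reads (variance undefined): ",
         paste(head(few, 5), collapse = ", "), call. = FALSE)
  m <- vapply(sp[loci$locus_id], mean, 0)
  v <- vapply(sp[loci$locus_id], var, 0)
  out <- as.vector(rbind(m, v))
  names(out) <- as.vector(rbind(paste0(loci$locus_id, "_mean"),
                                paste0(loci$locus_id, "_var")))
  out
}

#' Featurize all specimens in a long-format profile table
#'
#' @param profiles long-format table over multiple specimens.
#' @param loci locus panel.
#' @return numeric matrix, one row per specimen.
#' @export
featurize_cohort <- function(profiles, loci = default_msi_loci()) {
  sp <- split(profiles, profiles$specimen_id)
  X <- t(vapply(sp, featurize, numeric(2L * nrow(loci)), loci = loci))
  rownames(X) <- names(sp)
  X
}

#' Compute the MSI score (first principal component projection)
#'
#' Columns are centered (not scaled by default — locus variances carry the
#' instability signal and standardizing would dilute it); specimens are
#' projected on the first principal component. Because a principal
#' component's sign is arbitrary, scores are oriented so that higher score
#' correlates positively with mean per-locus variance, i.e. higher =
#' more unstable.
#'
#' @param features numeric matrix from [featurize_cohort()] (>= 3 rows).
#' @param scale. standardize columns before PCA (default FALSE).
#' @return list: `scores` (named vector), `variance_explained` (fraction
#'   per component), `rotation` (loadings of PC1).
#' @export
msi_score <- function(features, scale. = FALSE) {
  if (nrow(features) < 3)
    stop("msi_score needs at least 3 specimens", call. = FALSE)
  if (any(!is.finite(features)))
    stop("features must be finite", call. = FALSE)
  sds <- apply(features, 2, sd)
  if (all(sds == 0))
    stop("degenerate PCA: all features are constant across specimens",
         call. = FALSE)
  if (scale.) features <- features[, sds > 0, drop = FALSE]
  pc <- prcomp(features, center = TRUE, scale. = scale.)
  scores <- pc$x[, 1]
  ## orient: higher score = more unstable (greater mean variance-feature)
  var_cols <- grepl("_var$", colnames(features))
  inst <- if (any(var_cols)) rowMeans(features[, var_cols, drop = FALSE])
          else rowMeans(features)
  if (sd(inst) > 0 && stats::cor(scores, inst) < 0) {
    scores <- -scores
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve,
       rotation = pc$rotation[, 1])
}

# Two-component 1-D Gaussian mixture by EM; returns component parameters
# ordered so component 2 has the larger mean.
.gmm2 <- function(x, max_iter = 200L, tol = 1e-8) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(q[1], q[2])
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 2
  sg <- rep(max(sd(x) / 2, 1e-6), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot
    pi1 <- mean(1 - g)
    mu <- c(sum((1 - g) * x) / sum(1 - g), sum(g * x) / sum(g))
    sg <- sqrt(c(sum((1 - g) * (x - mu[1])^2) / sum(1 - g),
                 sum(g * (x - mu[2])^2) / sum(g)))
    sg <- pmax(sg, 1e-6)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {   # order: component 2 = high (unstable)
    mu <- rev(mu); sg <- rev(sg); pi1 <- 1 - pi1
  }
  list(mu = mu, sigma = sg, pi = c(pi1, 1 - pi1))
}

.posterior_high <- function(x, fit) {
  d1 <- fit$pi[1] * dnorm(x, fit$mu[1], fit$sigma[1])
  d2 <- fit$pi[2] * dnorm(x, fit$mu[2], fit$sigma[2])
  d2 / pmax(d1 + d2, .Machine$double.xmin)
}

#' Classify MSI scores into MSI-H / ambiguous / MSS
#'
#' Replaces manual unsupervised clustering with a reproducible rule: a
#' two-component 1-D Gaussian mixture is fitted to the scores (or to each
#' labelled class when training labels are given) and two thresholds are
#' placed where the posterior probability of the high (unstable) component
#' crosses `posterior_band`. Scores above the upper threshold are MSI-H,
#' below the lower MSS, between them MSI-ambiguous.
#'
#' @param scores numeric MSI scores (>= 10 specimens for unsupervised
#'   thresholding).
#' @param labels optional training labels (`"MSI-H"`/`"MSS"` or
#'   `"unstable"`/`"stable"`).
#' @param posterior_band posterior range treated as ambiguous (default
#'   `c(0.1, 0.9)`).
#' @return list: `calls` (character vector), `thresholds` (lower, upper),
#'   `fit` (mixture parameters).
#' @export
classify_msi <- function(scores, labels = NULL,
                         posterior_band = c(0.1, 0.9)) {
  if (sd(scores) == 0)
    stop("all scores identical; MSI classes undefined", call. = FALSE)
  if (is.null(labels)) {
    if (length(scores) < 10)
      stop("unsupervised thresholding needs >= 10 specimens",
           call. = FALSE)
    fit <- .gmm2(scores)
  } else {
    hi <- labels %in% c("MSI-H", "unstable")
    if (!any(hi) || all(hi))
      stop("training labels must contain both classes", call. = FALSE)
    fit <- list(mu = c(mean(scores[!hi]), mean(scores[hi])),
                sigma = pmax(c(sd(scores[!hi]), sd(scores[hi])), 1e-6),
                pi = c(mean(!hi), mean(hi)))
  }
  ## the posterior rises from ~0 to ~1 between the component means (it
  ## can revert to 1 in the far tail of the narrow component, where its
  ## density underflows, so only the inter-mean segment is searched)
  grid <- seq(fit$mu[1], fit$mu[2], length.out = 20000L)
  post <- .posterior_high(grid, fit)
  lower <- grid[which(post >= posterior_band[1])[1]]
  upper <- grid[which(post >= posterior_band[2])[1]]
  if (is.na(lower)) lower <- fit$mu[2]
  if (is.na(upper)) upper <- fit$mu[2]
  calls <- ifelse(scores >= upper, "MSI-H",
                  ifelse(scores < lower, "MSS", "ambiguous"))
  list(calls = calls, thresholds = c(lower = lower, upper = upper),
       fit = fit)
}

#' Score and classify a cohort of MSI profiles
#'
#' @param profiles long-format read-length table for the cohort.
#' @param loci locus panel.
#' @param labels optional training labels aligned to sorted specimen ids.
#' @return data.frame: `specimen_id`, `msi_score`, `msi_call`; thresholds
#'   and variance-explained attached as attributes.
#' @export
msi_pipeline <- function(profiles, loci = default_msi_loci(),
                         labels = NULL) {
  X <- featurize_cohort(profiles, loci)
  sc <- msi_score(X)
  cl <- classify_msi(sc$scores, labels = labels)
  out <- data.frame(specimen_id = rownames(X), msi_score = sc$scores,
                    msi_call = cl$calls, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "thresholds") <- cl$thresholds
  attr(out, "variance_explained") <- sc$variance_explained
  out
}
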