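#' @name downsampling
#' @title Binomial downsampling of TMB measurement
#' @description
#' Models the precision of a TMB measurement as a function of megabases
#' sequenced: with a true burden of `t` mutations/Mb, each of the
#' `round(mb * 1e6)` sequenced bases is mutated independently with
#' probability `t * 1e-6`, so the observed count is Binomial and the
#' observed TMB is `k / mb`. The percent deviation `100 |obs - t| / t`
#' summarizes measurement error; its spread shrinks like `1 / sqrt(mb)`,
#' and below roughly 0.5 Mb the measurement becomes markedly unreliable.
NULL

#' Simulate observed TMB at a given sequenced footprint
#'
#' @param true_tmb true burden in mutations/Mb (> 0).
#' @param mb megabases sequenced (> 0).
#' @param n_reps number of simulation replicates (default 1000).
#' @param seed optional RNG seed.
#' @return list of class `downsample_result`: `true_tmb`, `mb_sequenced`,
#'   `n_reps`, `observed` (simulated TMB per rep), `deviations` (percent),
#'   `median`, `q10`, `q90` (type-7 empirical quantiles, percent).
#' @export
simulate_observed_tmb <- function(true_tmb, mb, n_reps = 1000L,
                                  seed = NULL) {
  if (true_tmb <= 0) stop("true_tmb must be > 0", call. = FALSE)
  if (mb <= 0) stop("mb must be > 0", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(mb * 1e6)
  p <- true_tmb * 1e-6
  if (p > 1) stop("true_tmb implies per-base probability > 1", call. = FALSE)
  k <- rbinom(n_reps, n, p)
  observed <- k / mb
  dev <- 100 * abs(observed - true_tmb) / true_tmb
  qs <- quantile(dev, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  structure(list(true_tmb = true_tmb, mb_sequenced = mb, n_reps = n_reps,
                 observed = observed, deviations = dev,
                 q10 = qs[1], median = qs[2], q90 = qs[3]),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf(
    "downsample: true TMB %.3g/Mb at %.3g Mb, %d reps; %% deviation median %.2f (q10 %.2f, q90 %.2f)\n",
    x$true_tmb, x$mb_sequenced, x$n_reps, x$median, x$q10, x$q90))
  invisible(x)
}

#' Deviation grid over TMB levels and sequenced megabases
#'
#' One simulation per (TMB level, Mb) pair; the classic presentation uses
#' levels 100, 20 and 10 mutations/Mb over 0.2-10 Mb (0 Mb is undefined,
#' so the grid starts at the first positive step).
#'
#' @param tmb_levels true TMB levels (mutations/Mb).
#' @param mb_grid megabases sequenced (> 0).
#' @param n_reps replicates per cell (default 1000).
#' @param seed RNG seed for the whole grid.
#' @return data.frame with one row per (level, mb):
#'   `true_tmb`, `mb_sequenced`, `n_reps`, `median`, `q10`, `q90`.
#' @export
deviation_grid <- function(tmb_levels = c(100, 20, 10),
                           mb_grid = seq(0.2, 10, by = 0.2),
                           n_reps = 1000L, seed = NULL) {
  if (!length(tmb_levels) || !length(mb_grid))
    stop("tmb_levels and mb_grid must be non-empty", call. = FALSE)
  if (any(mb_grid <= 0)) stop("mb values must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(tmb_levels, function(t)
    lapply(mb_grid, function(m) {
      r <- simulate_observed_tmb(t, m, n_reps)
      data.frame(true_tmb = t, mb_sequenced = m, n_reps = n_reps,
                 median = r$median, q10 = r$q10, q90 = r$q90)
    }))
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
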