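#' @name association
#' @title Association of gene and mutation status with TMB
#' @description
#' Genes (and individual mutations) are tested for association with TMB
#' with the model `log10(TMB + pseudo-count) ~ carrier status + disease
#' type`. The carrier coefficient — the factor loading — is the change in
#' log10(TMB) attributable to carrying a functional mutation while
#' holding disease type constant; `10^loading` is the corresponding
#' fold-change. P-values are corrected by Benjamini-Hochberg FDR within
#' each analysis family. Co-occurrence of a binary specimen status (e.g.
#' PMS2-promoter mutation in melanoma) with gene mutations is tested by
#' logistic regression with TMB as covariate, so associations driven only
#' by overall burden are absorbed.
NULL

#' Model thresholds for the association analyses
#'
#' @param pseudo_count mutations/Mb added to TMB before log10 (default 1;
#'   keeps specimens with zero counted mutations in the model).
#' @param min_carriers_gene minimum carriers for a gene to be tested
#'   (default 6).
#' @param mutation_frequency_floor minimum carrier frequency for an
#'   individual mutation (default 1/2000).
#' @param homopolymer_exclusion_len mutations in homopolymers at least
#'   this long are excluded (default 6 bp).
#' @param fdr_level_gene FDR level for the gene analysis (default 1e-4).
#' @param fdr_level_mutation FDR level for the mutation analysis (0.05).
#' @param loading_cutoff_gene effect-size cutoff for reported genes (0.5
#'   log10 units, ~3.1-fold).
#' @param loading_cutoff_mutation effect-size cutoff for reported
#'   mutations (0.15).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(pseudo_count = 1, min_carriers_gene = 6L,
                       mutation_frequency_floor = 1 / 2000,
                       homopolymer_exclusion_len = 6L,
                       fdr_level_gene = 1e-4, fdr_level_mutation = 0.05,
                       loading_cutoff_gene = 0.5,
                       loading_cutoff_mutation = 0.15) {
  spec <- list(pseudo_count = pseudo_count,
               min_carriers_gene = min_carriers_gene,
               mutation_frequency_floor = mutation_frequency_floor,
               homopolymer_exclusion_len = homopolymer_exclusion_len,
               fdr_level_gene = fdr_level_gene,
               fdr_level_mutation = fdr_level_mutation,
               loading_cutoff_gene = loading_cutoff_gene,
               loading_cutoff_mutation = loading_cutoff_mutation)
  if (any(unlist(spec) <= 0 & names(unlist(spec)) != "pseudo_count"))
    stop("model_spec thresholds must be positive", call. = FALSE)
  if (pseudo_count < 0)
    stop("pseudo_count must be >= 0", call. = FALSE)
  class(spec) <- "model_spec"
  spec
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' clipped to 1 (p-values in ascending order).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  ord <- order(p_values)
  q <- p_values[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

# Fit log10(TMB + pc) ~ carrier + disease for one term. Returns loading,
# p, and an estimable flag (FALSE when the carrier coefficient is
# confounded with the design, e.g. all carriers in one single-level
# disease stratum).
.fit_term <- function(y, carrier, disease) {
  dis <- factor(disease)
  if (nlevels(dis) > 1) {
    ref <- names(sort(table(dis), decreasing = TRUE))[1]
    dis <- stats::relevel(dis, ref = ref)
    fit <- lm(y ~ carrier + dis)
  } else {
    fit <- lm(y ~ carrier)
  }
  sm <- summary(fit)$coefficients
  if (!"carrierTRUE" %in% rownames(sm) || is.na(coef(fit)["carrierTRUE"]))
    return(list(loading = NA_real_, p = NA_real_, estimable = FALSE))
  list(loading = unname(sm["carrierTRUE", "Estimate"]),
       p = unname(sm["carrierTRUE", "Pr(>|t|)"]), estimable = TRUE)
}

.assoc_table <- function(specimens, carrier_sets, spec, min_carriers) {
  y <- log10(specimens$tmb + spec$pseudo_count)
  res <- lapply(names(carrier_sets), function(term) {
    carrier <- specimens$specimen_id %in% carrier_sets[[term]]
    nc <- sum(carrier)
    if (nc < min_carriers || nc == nrow(specimens)) return(NULL)
    f <- .fit_term(y, carrier, specimens$disease)
    data.frame(term = term, n_carriers = nc, factor_loading = f$loading,
               p_value = f$p, estimable = f$estimable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term = character(0), n_carriers = integer(0),
                      factor_loading = numeric(0), p_value = numeric(0),
                      estimable = logical(0), q_value = numeric(0),
                      fold_change = numeric(0)))
  out$q_value <- NA_real_
  est <- out$estimable
  if (any(est)) out$q_value[est] <- bh_fdr(out$p_value[est])
  out$fold_change <- 10^out$factor_loading
  out <- out[order(-out$factor_loading, out$term), ]
  rownames(out) <- NULL
  out
}

# Normalize carriers input: long data.frame (specimen_id, term) or a
# named list of specimen-id vectors.
.carrier_sets <- function(carriers) {
  if (is.data.frame(carriers)) {
    stopifnot(all(c("specimen_id", "term") %in% names(carriers)))
    split(carriers$specimen_id, carriers$term)
  } else if (is.list(carriers)) carriers
  else stop("carriers must be a data.frame or named list", call. = FALSE)
}

#' Gene-level association with TMB
#'
#' @param specimens data.frame with `specimen_id`, `tmb`, `disease`.
#' @param carriers long data.frame (`specimen_id`, `term`) of specimens
#'   carrying a functional mutation per gene, or a named list of specimen
#'   ids.
#' @param spec a [model_spec()].
#' @return data.frame sorted by factor loading: `term`, `n_carriers`,
#'   `factor_loading`, `p_value`, `estimable`, `q_value`, `fold_change`,
#'   plus a logical `significant` column at the gene FDR level and
#'   loading cutoff.
#' @export
gene_association <- function(specimens, carriers, spec = model_spec()) {
  stopifnot(all(c("specimen_id", "tmb", "disease") %in% names(specimens)))
  if (any(specimens$tmb < 0)) stop("tmb must be >= 0", call. = FALSE)
  out <- .assoc_table(specimens, .carrier_sets(carriers), spec,
                      spec$min_carriers_gene)
  out$significant <- !is.na(out$q_value) &
    out$q_value < spec$fdr_level_gene &
    out$factor_loading > spec$loading_cutoff_gene
  out
}

#' Mutation-level association with TMB
#'
#' Individual mutations are eligible when their carrier frequency exceeds
#' `mutation_frequency_floor`, they do not sit in a homopolymer of length
#' `homopolymer_exclusion_len` or more, and they are absent from dbSNP.
#'
#' @param specimens data.frame with `specimen_id`, `tmb`, `disease`.
#' @param carriers long data.frame (`specimen_id`, `term`) per mutation.
#' @param mutation_info data.frame with `term`, `homopolymer_len`,
#'   `dbsnp` used for eligibility filtering (mutations absent from it are
#'   assumed eligible).
#' @param spec a [model_spec()].
#' @return as [gene_association()]; `significant` uses the mutation FDR
#'   level and loading cutoff.
#' @export
mutation_association <- function(specimens, carriers,
                                 mutation_info = NULL,
                                 spec = model_spec()) {
  sets <- .carrier_sets(carriers)
  n <- nrow(specimens)
  freq_ok <- vapply(sets, function(s)
    length(unique(s)) / n > spec$mutation_frequency_floor, TRUE)
  sets <- sets[freq_ok]
  if (!is.null(mutation_info)) {
    bad <- mutation_info$term[
      mutation_info$homopolymer_len >= spec$homopolymer_exclusion_len |
        mutation_info$dbsnp]
    sets <- sets[!names(sets) %in% bad]
  }
  out <- .assoc_table(specimens, sets, spec, min_carriers = 1L)
  out$significant <- !is.na(out$q_value) &
    out$q_value < spec$fdr_level_mutation &
    out$factor_loading > spec$loading_cutoff_mutation
  out
}

#' Co-occurrence of a binary specimen status with gene mutations
#'
#' Per gene: `status ~ carrier + TMB` by logistic regression; the carrier
#' odds ratio measures co-occurrence beyond what TMB explains. Complete
#' separation is detected (diverging coefficient or degenerate fitted
#' probabilities) and reported as non-estimable rather than failing.
#'
#' @param status logical (or 0/1) outcome per specimen, e.g. carrying a
#'   PMS2-promoter mutation.
#' @param carriers long data.frame (`specimen_id`, `term`) or named list.
#' @param specimens data.frame with `specimen_id` and `tmb` aligned to
#'   `status`.
#' @param min_carriers minimum carriers for a gene to be tested
#'   (default 3).
#' @return data.frame: `term`, `n_carriers`, `odds_ratio`, `p_value`,
#'   `q_value`, `estimable`.
#' @export
cooccurrence_test <- function(status, carriers, specimens,
                              min_carriers = 3L) {
  status <- as.logical(status)
  if (all(status) || !any(status))
    stop("outcome is degenerate (all 0 or all 1)", call. = FALSE)
  if (any(!is.finite(specimens$tmb)))
    stop("tmb must be finite", call. = FALSE)
  sets <- .carrier_sets(carriers)
  res <- lapply(names(sets), function(term) {
    carrier <- specimens$specimen_id %in% sets[[term]]
    nc <- sum(carrier)
    if (nc < min_carriers || nc == length(carrier)) return(NULL)
    est <- TRUE; beta <- NA_real_; p <- NA_real_
    fit <- suppressWarnings(glm(status ~ carrier + specimens$tmb,
                                family = binomial()))
    sm <- summary(fit)$coefficients
    if ("carrierTRUE" %in% rownames(sm)) {
      beta <- sm["carrierTRUE", "Estimate"]
      p <- sm["carrierTRUE", "Pr(>|z|)"]
      mu <- fit$fitted.values
      if (abs(beta) > 15 || !fit$converged ||
          all(mu[carrier] > 1 - 1e-8) || all(mu[carrier] < 1e-8))
        est <- FALSE
    } else est <- FALSE
    data.frame(term = term, n_carriers = nc,
               odds_ratio = if (est) exp(beta) else NA_real_,
               p_value = if (est) p else NA_real_, estimable = est,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term = character(0), n_carriers = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      estimable = logical(0), q_value = numeric(0)))
  out$q_value <- NA_real_
  est <- out$estimable
  if (any(est)) out$q_value[est] <- bh_fdr(out$p_value[est])
  rownames(out) <- NULL
  out
}

#' Derive functional-mutation carriers per gene from a variant table
#'
#' A specimen carries a functional mutation in a gene when it has a
#' coding, non-synonymous variant there that is not in a long homopolymer
#' and not flagged as a germline polymorphism (dbSNP / predicted
#' germline).
#'
#' @param variants variant-call table.
#' @param spec a [model_spec()] (homopolymer exclusion length).
#' @return long data.frame (`specimen_id`, `term`).
#' @export
functional_carriers <- function(variants, spec = model_spec()) {
  variants <- validate_variants(variants)
  functional <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "splice")
  keep <- variants$coding & variants$effect %in% functional &
    variants$homopolymer_len < spec$homopolymer_exclusion_len &
    !variants$dbsnp & variants$zygosity_call != "germline"
  out <- unique(data.frame(specimen_id = variants$specimen_id[keep],
                           term = variants$gene[keep],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
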