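#' @name tmb_engine
#' @title Somatic filter cascade and TMB computation
#' @description
#' TMB is defined as the number of somatic, coding, base substitution and
#' indel mutations per megabase of coding territory examined. Without a
#' matched normal, called variants are filtered to remove (a) non-coding
#' alterations, (b) known somatic hotspots and truncations in tumor
#' suppressors (the panel is biased toward functionally mutated genes, so
#' these would inflate TMB), and (c) likely germline polymorphisms flagged
#' by zygosity prediction, cohort recurrence, dbSNP membership, or
#' population allele counts (two or more ExAC-style counts). Synonymous
#' alterations ARE counted: they carry no immunogenicity but track the
#' same mutational processes with less sampling noise.
NULL

.filter_reasons <- c("noncoding", "known_somatic", "ts_truncation",
                     "zygosity_germline", "recurrent_germline", "dbsnp",
                     "population_count", "counted")

.variant_flag_cols <- c("known_somatic_hotspot", "ts_truncation", "dbsnp",
                        "recurrent_germline")

#' Validate (and normalize) a variant-call table
#'
#' Required columns: `specimen_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `effect`, `coding`. Missing flag columns default to `FALSE`,
#' `population_count` to 0, `zygosity_call` to `"uncalled"`,
#' `homopolymer_len` to 0 and `allele_fraction` to `NA`.
#'
#' @param variants data.frame of variant calls.
#' @return the normalized data.frame.
#' @export
validate_variants <- function(variants) {
  req <- c("specimen_id", "chrom", "pos", "ref", "alt", "gene", "effect",
           "coding")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(variants)
  for (fc in .variant_flag_cols)
    if (is.null(variants[[fc]])) variants[[fc]] <- rep(FALSE, n)
  if (is.null(variants$population_count))
    variants$population_count <- rep(0L, n)
  if (is.null(variants$zygosity_call))
    variants$zygosity_call <- rep("uncalled", n)
  if (is.null(variants$homopolymer_len))
    variants$homopolymer_len <- rep(0L, n)
  if (is.null(variants$allele_fraction))
    variants$allele_fraction <- rep(NA_real_, n)
  if (nrow(variants)) {
    if (any(variants$pos < 1))
      stop("pos must be >= 1 (1-based coordinates)", call. = FALSE)
    af <- variants$allele_fraction
    if (any(!is.na(af) & (af < 0 | af > 1)))
      stop("allele_fraction must lie in [0, 1]", call. = FALSE)
    if (any(variants$population_count < 0))
      stop("population_count must be >= 0", call. = FALSE)
    bad <- variants$effect == "noncoding" & variants$coding
    if (any(bad))
      stop("effect = 'noncoding' requires coding = FALSE", call. = FALSE)
  }
  variants
}

#' Classify variants through the somatic filter cascade
#'
#' Applies the fixed cascade to each variant and records the first
#' matching exclusion reason:
#' noncoding -> known_somatic -> ts_truncation -> zygosity_germline ->
#' recurrent_germline -> dbsnp -> population_count (>= 2) -> counted.
#' The cascade order only affects which reason is reported; the counted
#' set is order-independent because every rule is a pure predicate of the
#' variant.
#'
#' @param variants a variant-call table (see [validate_variants()]).
#' @param population_count_min minimum population allele count that
#'   triggers exclusion (default 2, "two or more counts").
#' @return the table with logical `counted` and factor-like character
#'   `reason` columns appended.
#' @export
classify_variants <- function(variants, population_count_min = 2L) {
  variants <- validate_variants(variants)
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  pick <- function(cond, r) {
    sel <- is.na(reason) & cond
    reason[sel] <<- r
  }
  pick(!variants$coding, "noncoding")
  pick(variants$known_somatic_hotspot, "known_somatic")
  pick(variants$ts_truncation, "ts_truncation")
  pick(variants$zygosity_call == "germline", "zygosity_germline")
  pick(variants$recurrent_germline, "recurrent_germline")
  pick(variants$dbsnp, "dbsnp")
  pick(variants$population_count >= population_count_min, "population_count")
  reason[is.na(reason)] <- "counted"
  variants$counted <- reason == "counted"
  variants$reason <- reason
  variants
}

#' Compute TMB for one specimen
#'
#' Counts cascade-passing variants within the panel's genes and divides by
#' the panel coding territory. Dinucleotide and other multi-nucleotide
#' substitutions are assumed to be represented as single rows (one event).
#'
#' @param variants variant calls for a single specimen (may be empty).
#' @param panel a [panel_definition()]; `genes = NULL` means no gene
#'   restriction (whole-exome).
#' @return a one-row data.frame: `specimen_id`, `counted_mutations`,
#'   `territory_mb`, `tmb` (mutations/Mb).
#' @export
compute_tmb <- function(variants, panel) {
  if (!inherits(panel, "panel_definition"))
    stop("panel must be a panel_definition", call. = FALSE)
  if (panel$coding_mb <= 0)
    stop("panel territory_mb must be > 0", call. = FALSE)
  sid <- unique(variants$specimen_id)
  if (length(sid) > 1)
    stop("compute_tmb expects variants from a single specimen; got ",
         length(sid), call. = FALSE)
  if (length(sid) == 0) sid <- NA_character_
  if (is.null(variants$counted)) variants <- classify_variants(variants)
  keep <- variants$counted
  if (!is.null(panel$genes)) keep <- keep & variants$gene %in% panel$genes
  k <- sum(keep)
  data.frame(specimen_id = sid, counted_mutations = k,
             territory_mb = panel$coding_mb, tmb = k / panel$coding_mb,
             stringsAsFactors = FALSE)
}

#' Compute TMB for every specimen in a cohort
#'
#' @param variants variant calls for one or more specimens.
#' @param panel a [panel_definition()].
#' @param specimen_ids optional vector of specimen ids to report (specimens
#'   without variants get `tmb = 0`).
#' @return a data.frame with one row per specimen.
#' @export
cohort_tmb <- function(variants, panel, specimen_ids = NULL) {
  if (is.null(variants$counted)) variants <- classify_variants(variants)
  keep <- variants$counted
  if (!is.null(panel$genes)) keep <- keep & variants$gene %in% panel$genes
  if (is.null(specimen_ids))
    specimen_ids <- sort(unique(variants$specimen_id))
  counts <- table(factor(variants$specimen_id[keep], levels = specimen_ids))
  data.frame(specimen_id = specimen_ids,
             counted_mutations = as.integer(counts),
             territory_mb = panel$coding_mb,
             tmb = as.numeric(counts) / panel$coding_mb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simplified somatic/germline zygosity proxy
#'
#' Stand-in for the full somatic-germline-zygosity model: given tumor
#' purity and local copy number, the expected allele fraction of a
#' germline heterozygote is `(p * m + (1 - p)) / (p * cn + 2 (1 - p))`
#' with one mutant copy (`m = 1`), and 1 for a homozygote. Observed
#' fractions within `delta` of a germline expectation are called germline;
#' fractions within `delta` of a clonal somatic expectation
#' (`p * m / (p * cn + 2 (1 - p))`, `m = 1..cn`) or below the lowest
#' clonal band (subclonal) are called somatic; anything else — e.g.
#' between two clonal bands at low purity — is ambiguous.
#'
#' @param allele_fraction observed variant allele fraction(s) in [0, 1].
#' @param local_copy_number tumor local copy number (>= 0; default diploid).
#' @param purity tumor purity in (0, 1].
#' @param delta allele-fraction tolerance (default 0.10).
#' @return character vector: `"somatic"`, `"germline"` or `"ambiguous"`.
#' @export
call_zygosity_proxy <- function(allele_fraction, local_copy_number = 2,
                                purity = 1, delta = 0.10) {
  if (any(purity <= 0 | purity > 1))
    stop("purity must lie in (0, 1]", call. = FALSE)
  if (any(local_copy_number < 0))
    stop("local_copy_number must be >= 0", call. = FALSE)
  if (any(allele_fraction < 0 | allele_fraction > 1, na.rm = TRUE))
    stop("allele_fraction must lie in [0, 1]", call. = FALSE)
  n <- max(length(allele_fraction), length(local_copy_number), length(purity))
  af <- rep_len(allele_fraction, n)
  cn <- rep_len(local_copy_number, n)
  p <- rep_len(purity, n)
  out <- character(n)
  for (i in seq_len(n)) {
    denom <- p[i] * cn[i] + 2 * (1 - p[i])
    if (is.na(af[i]) || denom <= 0) { out[i] <- "ambiguous"; next }
    het <- (p[i] * 1 + (1 - p[i])) / denom
    germ_exp <- c(het, 1)
    som_exp <- if (cn[i] >= 1) p[i] * seq_len(cn[i]) / denom else numeric(0)
    if (min(abs(af[i] - germ_exp)) <= delta) {
      out[i] <- "germline"
    } else if (length(som_exp) &&
               (min(abs(af[i] - som_exp)) <= delta ||
                af[i] < min(som_exp))) {
      out[i] <- "somatic"
    } else {
      out[i] <- "ambiguous"
    }
  }
  out
}

#' Flag variants recurrently predicted germline across the cohort
#'
#' A variant site (chrom:pos:ref:alt) predicted germline by the zygosity
#' call in at least `max(min_specimens, min_fraction * n_cohort)` distinct
#' specimens is flagged `recurrent_germline` in every specimen carrying
#' it.
#'
#' @param variants cohort variant table with `zygosity_call`.
#' @param min_specimens absolute recurrence threshold (default 3).
#' @param min_fraction cohort-fraction threshold (default 0.001).
#' @param n_cohort cohort size; defaults to the number of distinct
#'   specimens in `variants`.
#' @return `variants` with `recurrent_germline` updated.
#' @export
annotate_recurrent_germline <- function(variants, min_specimens = 3L,
                                        min_fraction = 0.001,
                                        n_cohort = NULL) {
  variants <- validate_variants(variants)
  if (!nrow(variants)) return(variants)
  if (is.null(n_cohort)) n_cohort <- length(unique(variants$specimen_id))
  thr <- max(min_specimens, ceiling(min_fraction * n_cohort))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  germ <- variants$zygosity_call == "germline"
  if (any(germ)) {
    tab <- tapply(variants$specimen_id[germ], key[germ],
                  function(s) length(unique(s)))
    hot <- names(tab)[tab >= thr]
    variants$recurrent_germline <- variants$recurrent_germline |
      key %in% hot
  }
  variants
}

#' Compare panel-restricted TMB against exome-wide TMB
#'
#' For each specimen, TMB is computed twice from the same exome-wide
#' variant table: restricted to panel genes over the panel territory, and
#' unrestricted over the exome territory. Returns both together with the
#' squared Pearson correlation.
#'
#' @param variants exome-wide variant calls (>= 3 specimens).
#' @param panel a [panel_definition()] with a gene set.
#' @param exome_mb exome coding size in Mb (default 38).
#' @return list with `table` (specimen_id, panel_tmb, exome_tmb) and
#'   `r_squared`.
#' @export
panel_vs_exome <- function(variants, panel, exome_mb = 38) {
  variants <- classify_variants(variants)
  ids <- sort(unique(variants$specimen_id))
  if (length(ids) < 3)
    stop("panel_vs_exome needs at least 3 specimens", call. = FALSE)
  ex <- cohort_tmb(variants, exome_panel(exome_mb), ids)
  pa <- cohort_tmb(variants, panel, ids)
  tab <- data.frame(specimen_id = ids, panel_tmb = pa$tmb,
                    exome_tmb = ex$tmb, stringsAsFactors = FALSE)
  r2 <- if (sd(tab$panel_tmb) == 0 || sd(tab$exome_tmb) == 0) NA_real_
        else stats::cor(tab$panel_tmb, tab$exome_tmb)^2
  list(table = tab, r_squared = r2)
}
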