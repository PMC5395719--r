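#' @name synthetic_cohort
#' @title Synthetic cohort generator
#' @description
#' Generates specimens, variant calls and MSI read profiles with the
#' statistical structure the downstream analyses assume: per-disease
#' lognormal true TMB, a log-linear age effect, multiplicative driver
#' effects (mismatch repair, POLE, PMS2-promoter), Poisson somatic counts
#' over the panel territory, germline polymorphisms with population allele
#' counts and allele fractions consistent with zygosity, and homopolymer
#' locus read-length distributions for stable versus unstable specimens.
#' Ground truth (true TMB, driver flags, MSI state, per-variant origin) is
#' recorded so parameter recovery can be tested.
NULL

# Default disease mix with baseline median TMB (mutations/Mb) typical of
# a large pan-cancer clinical cohort: melanoma and lung highly mutated,
# most carcinomas near the 3-4/Mb pan-cancer median.
.default_diseases <- data.frame(
  disease = c("Skin melanoma",
              "Lung adenocarcinoma",
              "Lung squamous cell carcinoma (SCC)",
              "Bladder urothelial (transitional cell) carcinoma",
              "Head and neck squamous cell carcinoma (HNSCC)",
              "Uterus endometrial adenocarcinoma endometrioid",
              "Unknown primary adenocarcinoma",
              "Soft tissue angiosarcoma",
              "Brain oligodendroglioma"),
  prob = c(0.10, 0.20, 0.10, 0.05, 0.10, 0.10, 0.20, 0.05, 0.10),
  median_tmb = c(14.4, 6.3, 9.0, 7.2, 5.0, 4.5, 3.6, 3.3, 2.7),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults state the world the generator emulates: a 1.1 Mb coding panel
#' inside a 38 Mb exome, per-disease baseline TMB, a 2.4-fold TMB increase
#' across an 80-year age span, mismatch-repair / POLE / PMS2-promoter
#' drivers that multiply TMB, and MSI-unstable specimens with strongly
#' elevated TMB.
#'
#' @param n_specimens number of specimens to generate.
#' @param disease_mix named numeric vector of disease probabilities
#'   (must sum to 1).
#' @param age_range min/max patient age in years (uniform draw).
#' @param baseline_log10_tmb data.frame with columns `disease`, `mean`
#'   (mean log10 true TMB at the reference age of 60), `sd`.
#' @param driver_prevalence named probabilities for `MMR`, `POLE`,
#'   `PMS2_promoter` carrier status.
#' @param driver_fold_effect named multiplicative TMB effects per driver
#'   class (PMS2-promoter default 5.3-fold).
#' @param age_fold_per_80y fold-change in TMB across an 80-year span
#'   (default 2.4); the log10-linear age slope is
#'   `log10(age_fold_per_80y) / 80` per year.
#' @param germline_snp_rate expected germline variants per specimen within
#'   the panel.
#' @param synonymous_fraction fraction of somatic coding variants that are
#'   synonymous.
#' @param msi_high_rate probability a specimen is microsatellite-unstable.
#' @param msi_fold_effect multiplicative TMB effect of MSI instability.
#' @param noncoding_fraction non-coding somatic calls as a fraction of the
#'   coding somatic rate (excluded from TMB by the cascade).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_specimens = 1000L,
                          disease_mix = NULL,
                          age_range = c(10, 90),
                          baseline_log10_tmb = NULL,
                          driver_prevalence = c(MMR = 0.009, POLE = 0.001,
                                                PMS2_promoter = 0.01),
                          driver_fold_effect = c(MMR = 5.3, POLE = 10,
                                                 PMS2_promoter = 5.3),
                          age_fold_per_80y = 2.4,
                          germline_snp_rate = 20,
                          synonymous_fraction = 0.3,
                          msi_high_rate = 0.05,
                          msi_fold_effect = 10,
                          noncoding_fraction = 0.05,
                          seed = 1L) {
  if (is.null(disease_mix))
    disease_mix <- setNames(.default_diseases$prob, .default_diseases$disease)
  if (is.null(baseline_log10_tmb))
    baseline_log10_tmb <- data.frame(
      disease = .default_diseases$disease,
      mean = log10(.default_diseases$median_tmb),
      sd = 0.3, stringsAsFactors = FALSE)
  cfg <- structure(list(
    n_specimens = as.integer(n_specimens), disease_mix = disease_mix,
    age_range = age_range, baseline_log10_tmb = baseline_log10_tmb,
    driver_prevalence = driver_prevalence,
    driver_fold_effect = driver_fold_effect,
    age_fold_per_80y = age_fold_per_80y,
    germline_snp_rate = germline_snp_rate,
    synonymous_fraction = synonymous_fraction,
    msi_high_rate = msi_high_rate, msi_fold_effect = msi_fold_effect,
    noncoding_fraction = noncoding_fraction, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  chk <- function(ok, field, what)
    if (!ok) stop(sprintf("invalid cohort_config field '%s': %s",
                          field, what), call. = FALSE)
  chk(config$n_specimens >= 1, "n_specimens", "must be a positive count")
  chk(abs(sum(config$disease_mix) - 1) < 1e-9, "disease_mix",
      "probabilities must sum to 1")
  chk(all(config$disease_mix >= 0 & config$disease_mix <= 1),
      "disease_mix", "probabilities must lie in [0,1]")
  probs <- c(config$driver_prevalence, config$msi_high_rate,
             config$synonymous_fraction, config$noncoding_fraction)
  chk(all(probs >= 0 & probs <= 1), "driver_prevalence",
      "rates/probabilities must lie in [0,1]")
  chk(all(config$driver_fold_effect > 0), "driver_fold_effect",
      "fold effects must be > 0")
  chk(config$age_fold_per_80y > 0, "age_fold_per_80y", "must be > 0")
  chk(config$msi_fold_effect > 0, "msi_fold_effect", "must be > 0")
  chk(config$germline_snp_rate >= 0, "germline_snp_rate", "must be >= 0")
  chk(all(names(config$disease_mix) %in% config$baseline_log10_tmb$disease),
      "baseline_log10_tmb", "every disease in disease_mix needs a baseline")
  invisible(config)
}

# Germline polymorphism site catalog shared across the cohort; popularity
# weights follow a power law so recurrence across specimens arises
# naturally. Population (ExAC-style) counts are >= 2 with probability
# 0.95 so the population filter is exercised both ways.
.germline_catalog <- function(panel, n_sites = 400L) {
  gene_mb <- attr(panel, "gene_mb")
  gene <- sample(names(gene_mb), n_sites, replace = TRUE, prob = gene_mb)
  gi <- match(gene, panel$genes)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  common <- runif(n_sites) < 0.95
  popcount <- ifelse(common, 2L + stats::rnbinom(n_sites, size = 0.5,
                                                 mu = 200),
                     rbinom(n_sites, 1L, 0.5))
  data.frame(
    site_id = seq_len(n_sites),
    chrom = paste0("chr", (gi %% 22L) + 1L),
    pos = gi * 100000L + sample.int(90000L, n_sites, replace = TRUE),
    ref = ref, alt = unname(alt), gene = gene,
    weight = 1 / seq_len(n_sites),
    dbsnp = runif(n_sites) < 0.9,
    population_count = as.integer(popcount),
    stringsAsFactors = FALSE)
}

.somatic_effects <- function(n, synonymous_fraction) {
  nonsyn <- c(missense = 0.75, nonsense = 0.10, frameshift = 0.08,
              inframe_indel = 0.04, splice = 0.03)
  eff <- character(n)
  syn <- runif(n) < synonymous_fraction
  eff[syn] <- "synonymous"
  eff[!syn] <- sample(names(nonsyn), sum(!syn), replace = TRUE,
                      prob = nonsyn)
  eff
}

.hp_len <- function(n) {
  # 10% of variants sit in long homopolymer context (>= 6 bp) so the
  # association-stage exclusion is exercised
  long <- runif(n) < 0.10
  len <- integer(n)
  len[long] <- sample(6:12, sum(long), replace = TRUE)
  len[!long] <- sample(0:5, sum(!long), replace = TRUE)
  len
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param panel a [panel_definition()] with per-gene territories
#'   (default [default_panel()]).
#' @param loci MSI locus panel (default [default_msi_loci()]).
#' @param include_variants generate the variant table (default TRUE).
#' @param include_msi generate MSI read profiles (default TRUE); can be
#'   expensive for large cohorts.
#' @param msi_reads reads per MSI locus (default 50).
#' @return list with `specimens`, `variants`, `msi_profiles`, and
#'   `ground_truth` (list: `specimens` with true TMB / driver / MSI truth,
#'   `variant_origin` mapping variant_id to somatic/germline, `config`).
#' @export
generate_cohort <- function(config, panel = default_panel(),
                            loci = default_msi_loci(),
                            include_variants = TRUE, include_msi = TRUE,
                            msi_reads = 50L) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_specimens
  specimen_id <- sprintf("S%05d", seq_len(n))
  disease <- sample(names(config$disease_mix), n, replace = TRUE,
                    prob = config$disease_mix)
  age <- round(runif(n, config$age_range[1], config$age_range[2]), 1)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  median_coverage <- pmax(0, round(rnorm(n, 500, 60)))

  base <- config$baseline_log10_tmb
  mu <- base$mean[match(disease, base$disease)]
  sdv <- base$sd[match(disease, base$disease)]
  slope <- log10(config$age_fold_per_80y) / 80   # per year, reference 60

  prev <- config$driver_prevalence
  fold <- config$driver_fold_effect
  mmr <- runif(n) < prev[["MMR"]]
  pole <- runif(n) < prev[["POLE"]]
  pms2p <- runif(n) < prev[["PMS2_promoter"]]
  msi_truth <- runif(n) < config$msi_high_rate

  log10_tmb <- mu + slope * (age - 60) +
    mmr * log10(fold[["MMR"]]) + pole * log10(fold[["POLE"]]) +
    pms2p * log10(fold[["PMS2_promoter"]]) +
    msi_truth * log10(config$msi_fold_effect) +
    rnorm(n, 0, sdv)
  true_tmb <- 10^log10_tmb

  specimens <- data.frame(
    specimen_id = specimen_id, patient_id = sprintf("P%05d", seq_len(n)),
    disease = disease, age = age, sex = sex,
    median_coverage = median_coverage, stringsAsFactors = FALSE)
  truth <- data.frame(
    specimen_id = specimen_id, true_tmb = true_tmb, mmr = mmr, pole = pole,
    pms2_promoter = pms2p, msi_truth = ifelse(msi_truth, "unstable",
                                              "stable"),
    stringsAsFactors = FALSE)

  variants <- NULL
  origin <- NULL
  if (include_variants) {
    gen <- .generate_variants(config, panel, specimens, truth)
    variants <- gen$variants
    origin <- gen$origin
  }

  msi_profiles <- NULL
  if (include_msi) {
    msi_profiles <- do.call(rbind, lapply(seq_len(n), function(i)
      generate_msi_profile(specimen_id[i], loci,
                           msi_truth = truth$msi_truth[i],
                           n_reads = msi_reads)))
  }

  list(specimens = specimens, variants = variants,
       msi_profiles = msi_profiles,
       ground_truth = list(specimens = truth, variant_origin = origin,
                           config = config))
}

.generate_variants <- function(config, panel, specimens, truth) {
  n <- nrow(specimens)
  gene_mb <- attr(panel, "gene_mb")
  if (is.null(gene_mb))
    stop("panel lacks per-gene territories (use default_panel())",
         call. = FALSE)
  ts_genes <- attr(panel, "ts_genes")
  catalog <- .germline_catalog(panel)
  gi_all <- setNames(seq_along(panel$genes), panel$genes)
  bases <- c("A", "C", "G", "T")

  ## somatic coding calls: Poisson(true_tmb * panel Mb)
  k_som <- rpois(n, truth$true_tmb * panel$coding_mb)
  som_sid <- rep(specimens$specimen_id, k_som)
  m <- length(som_sid)
  som_gene <- sample(names(gene_mb), m, replace = TRUE, prob = gene_mb)
  som_eff <- .somatic_effects(m, config$synonymous_fraction)
  som_ref <- sample(bases, m, replace = TRUE)
  som_alt <- vapply(som_ref, function(r) sample(setdiff(bases, r), 1L), "")
  gi <- gi_all[som_gene]
  trunc_eff <- som_eff %in% c("nonsense", "frameshift")
  somatic <- if (m == 0) NULL else data.frame(
    specimen_id = som_sid,
    chrom = paste0("chr", (gi %% 22L) + 1L),
    pos = gi * 100000L + sample.int(90000L, m, replace = TRUE),
    ref = som_ref, alt = unname(som_alt), gene = som_gene, effect = som_eff,
    coding = TRUE,
    known_somatic_hotspot = som_eff == "missense" & runif(m) < 0.02,
    ts_truncation = trunc_eff & som_gene %in% ts_genes,
    dbsnp = FALSE, population_count = 0L, recurrent_germline = FALSE,
    zygosity_call = sample(c("somatic", "uncalled"), m, replace = TRUE,
                           prob = c(0.9, 0.1)),
    allele_fraction = runif(m, 0.05, 0.85),
    homopolymer_len = .hp_len(m),
    stringsAsFactors = FALSE, row.names = NULL)

  ## non-coding somatic calls (never counted toward TMB); PMS2 is
  ## reserved for the driver promoter lesions below
  k_nc <- rpois(n, config$noncoding_fraction * truth$true_tmb *
                  panel$coding_mb)
  nc_sid <- rep(specimens$specimen_id, k_nc)
  mnc <- length(nc_sid)
  nc_mb <- gene_mb[names(gene_mb) != "PMS2"]
  nc_gene <- sample(names(nc_mb), mnc, replace = TRUE, prob = nc_mb)
  ginc <- gi_all[nc_gene]
  nc_ref <- sample(bases, mnc, replace = TRUE)
  noncoding <- if (mnc == 0) NULL else data.frame(
    specimen_id = nc_sid,
    chrom = paste0("chr", (ginc %% 22L) + 1L),
    pos = ginc * 100000L + 95000L +
      sample.int(4000L, mnc, replace = TRUE),
    ref = nc_ref,
    alt = vapply(nc_ref, function(r) sample(setdiff(bases, r), 1L), "",
                 USE.NAMES = FALSE),
    gene = nc_gene,
    effect = sample(c("noncoding", "promoter"), mnc, replace = TRUE,
                    prob = c(0.8, 0.2)),
    coding = FALSE, known_somatic_hotspot = FALSE, ts_truncation = FALSE,
    dbsnp = FALSE, population_count = 0L, recurrent_germline = FALSE,
    zygosity_call = sample(c("somatic", "uncalled"), mnc, replace = TRUE,
                           prob = c(0.9, 0.1)),
    allele_fraction = runif(mnc, 0.05, 0.85),
    homopolymer_len = .hp_len(mnc),
    stringsAsFactors = FALSE, row.names = NULL)

  ## PMS2-promoter driver lesions: clustered ~50-100 bp upstream of the
  ## TSS on chr7; frequently dinucleotide substitutions (one event/row)
  pp_sid <- specimens$specimen_id[truth$pms2_promoter]
  pms2_prom <- if (length(pp_sid)) {
    dinuc <- runif(length(pp_sid)) < 0.4
    data.frame(
      specimen_id = pp_sid, chrom = "chr7",
      pos = sample(c(6048723L, 6048760L, 6048788L, 6048824L),
                   length(pp_sid), replace = TRUE),
      ref = ifelse(dinuc, "CC", "C"), alt = ifelse(dinuc, "TT", "T"),
      gene = "PMS2", effect = "promoter", coding = FALSE,
      known_somatic_hotspot = FALSE, ts_truncation = FALSE, dbsnp = FALSE,
      population_count = 0L, recurrent_germline = FALSE,
      zygosity_call = "somatic",
      allele_fraction = runif(length(pp_sid), 0.05, 0.85),
      homopolymer_len = 0L, stringsAsFactors = FALSE, row.names = NULL)
  } else NULL

  ## MMR / POLE driver coding lesions
  drv_rows <- function(sel, genes, effect) {
    sid <- specimens$specimen_id[sel]
    if (!length(sid)) return(NULL)
    g <- sample(genes, length(sid), replace = TRUE)
    gi <- gi_all[g]
    data.frame(
      specimen_id = sid, chrom = paste0("chr", (gi %% 22L) + 1L),
      pos = gi * 100000L + sample.int(90000L, length(sid), replace = TRUE),
      ref = "C", alt = ifelse(effect == "frameshift", "CA", "T"),
      gene = g, effect = effect, coding = TRUE,
      known_somatic_hotspot = FALSE,
      ts_truncation = effect == "frameshift" & g %in% ts_genes,
      dbsnp = FALSE, population_count = 0L, recurrent_germline = FALSE,
      zygosity_call = "somatic",
      allele_fraction = runif(length(sid), 0.05, 0.85),
      homopolymer_len = 0L, stringsAsFactors = FALSE, row.names = NULL)
  }
  mmr_rows <- drv_rows(truth$mmr, c("MLH1", "MSH2", "MSH6", "PMS2"),
                       "frameshift")
  pole_rows <- drv_rows(truth$pole, "POLE", "missense")

  ## germline polymorphisms drawn from the shared site catalog
  k_g <- rpois(n, config$germline_snp_rate)
  g_sid <- rep(specimens$specimen_id, k_g)
  mg <- length(g_sid)
  site <- sample(catalog$site_id, mg, replace = TRUE, prob = catalog$weight)
  hom <- runif(mg) < 0.1
  af <- pmin(1, pmax(0, rnorm(mg, ifelse(hom, 1.0, 0.5), 0.05)))
  germline <- if (mg == 0) NULL else data.frame(
    specimen_id = g_sid, chrom = catalog$chrom[site],
    pos = catalog$pos[site], ref = catalog$ref[site],
    alt = catalog$alt[site], gene = catalog$gene[site],
    effect = sample(c("synonymous", "missense"), mg, replace = TRUE),
    coding = TRUE, known_somatic_hotspot = FALSE, ts_truncation = FALSE,
    dbsnp = catalog$dbsnp[site],
    population_count = catalog$population_count[site],
    recurrent_germline = FALSE,
    zygosity_call = sample(c("germline", "ambiguous"), mg, replace = TRUE,
                           prob = c(0.95, 0.05)),
    allele_fraction = af, homopolymer_len = .hp_len(mg),
    stringsAsFactors = FALSE, row.names = NULL)

  parts <- list(somatic = somatic, noncoding = noncoding,
                pms2_prom = pms2_prom, mmr = mmr_rows, pole = pole_rows,
                germline = germline)
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) {
    empty <- validate_variants(data.frame(
      specimen_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), gene = character(0),
      effect = character(0), coding = logical(0),
      stringsAsFactors = FALSE))
    empty$variant_id <- character(0)
    return(list(variants = empty,
                origin = data.frame(variant_id = character(0),
                                    origin = character(0),
                                    stringsAsFactors = FALSE)))
  }
  variants <- do.call(rbind, parts)
  rownames(variants) <- NULL
  orig <- rep(ifelse(names(parts) == "germline", "germline", "somatic"),
              vapply(parts, nrow, 0L))
  variants$variant_id <- sprintf("V%07d", seq_len(nrow(variants)))
  ## stable shuffle so specimen blocks are interleaved as in real input
  ord <- order(variants$specimen_id, variants$chrom, variants$pos)
  origin <- data.frame(variant_id = variants$variant_id, origin = orig,
                       stringsAsFactors = FALSE)[ord, ]
  variants <- variants[ord, ]
  rownames(variants) <- rownames(origin) <- NULL
  list(variants = variants, origin = origin)
}

#' Generate an MSI read-length profile for one specimen
#'
#' Each read spanning a homopolymer locus yields one observed repeat
#' length. Stable specimens concentrate tightly around the reference
#' length (polymerase slippage noise `stable_sd`); unstable specimens show
#' inflated variance (`unstable_sd`) and a shifted mean (`unstable_shift`,
#' typically deletions) at a random `unstable_fraction` of loci.
#'
#' @param specimen_id specimen identifier.
#' @param loci locus panel data.frame (see [default_msi_loci()]); reference
#'   repeat lengths must lie in [10, 20] bp.
#' @param msi_truth `"stable"` or `"unstable"`.
#' @param seed optional seed (otherwise inherits the RNG stream).
#' @param n_reads reads per locus (>= 20).
#' @param stable_sd read-length sd at stable loci (bp; 0 = noiseless).
#' @param unstable_sd read-length sd at unstable loci (bp).
#' @param unstable_fraction fraction of loci destabilized in an unstable
#'   specimen.
#' @param unstable_shift mean repeat-length shift at unstable loci (bp).
#' @return long-format data.frame: `specimen_id`, `locus_id`,
#'   `read_index`, `repeat_length`.
#' @export
generate_msi_profile <- function(specimen_id, loci = default_msi_loci(),
                                 msi_truth = c("stable", "unstable"),
                                 seed = NULL, n_reads = 50L,
                                 stable_sd = 0.5, unstable_sd = 2,
                                 unstable_fraction = 0.6,
                                 unstable_shift = -2) {
  msi_truth <- match.arg(msi_truth)
  if (!is.null(seed)) set.seed(seed)
  if (any(loci$reference_repeat_len < 10 | loci$reference_repeat_len > 20))
    stop("locus reference repeat length must lie in [10, 20] bp",
         call. = FALSE)
  if (n_reads < 20)
    stop("read support per locus must be >= 20", call. = FALSE)
  L <- nrow(loci)
  unstable <- msi_truth == "unstable" & runif(L) < unstable_fraction
  mu <- loci$reference_repeat_len + ifelse(unstable, unstable_shift, 0)
  sdv <- ifelse(unstable, unstable_sd, stable_sd)
  len <- round(rnorm(L * n_reads, rep(mu, each = n_reads),
                     rep(sdv, each = n_reads)))
  data.frame(
    specimen_id = specimen_id,
    locus_id = rep(loci$locus_id, each = n_reads),
    read_index = rep(seq_len(n_reads), times = L),
    repeat_length = pmax(0L, as.integer(len)),
    stringsAsFactors = FALSE)
}
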