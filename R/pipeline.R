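#' Run configuration for the end-to-end pipeline
#'
#' Either point `variants`/`specimens` (and optionally `msi_profiles`) at
#' input files, or set `simulate_n` to generate a synthetic cohort.
#'
#' @param out_dir output directory.
#' @param variants path to a MAF-like variant TSV (or NULL to simulate).
#' @param specimens path to a specimen TSV (or NULL to simulate).
#' @param msi_profiles optional path to an MSI profile TSV.
#' @param simulate_n simulate a cohort of this size when inputs are NULL.
#' @param panel a [panel_definition()] (default [default_panel()]).
#' @param high_threshold high-TMB cutoff (default 20 mutations/Mb).
#' @param min_coverage specimen eligibility coverage floor (default 300).
#' @param min_n minimum specimens per summarized disease (default 50).
#' @param spec a [model_spec()].
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, variants = NULL, specimens = NULL,
                       msi_profiles = NULL, simulate_n = 500L,
                       panel = default_panel(), high_threshold = 20,
                       min_coverage = 300, min_n = 50L,
                       spec = model_spec(), seed = 1L) {
  cfg <- list(out_dir = out_dir, variants = variants,
              specimens = specimens, msi_profiles = msi_profiles,
              simulate_n = simulate_n, panel = panel,
              high_threshold = high_threshold,
              min_coverage = min_coverage, min_n = min_n, spec = spec,
              seed = as.integer(seed))
  for (p in c("variants", "specimens", "msi_profiles"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("run_config: input path does not exist: ", cfg[[p]],
           call. = FALSE)
  if (is.null(cfg$variants) != is.null(cfg$specimens))
    stop("run_config: variants and specimens must be given together",
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Stage order: cohort filtering, TMB computation through the filter
#' cascade, MSI scoring and classification (when profiles are present),
#' landscape summaries, and gene association. All tables are written
#' under `out_dir` together with a JSON manifest recording the package
#' version, seed and MD5 checksums of every output; reruns with the same
#' config are byte-identical.
#'
#' @param config a [run_config()].
#' @return invisible list of results (`specimens`, `tmb`, `audit`, `msi`,
#'   `summary`, `age_trend`, `crosstab`, `association`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (is.null(config$variants)) {
    cc <- cohort_config(n_specimens = config$simulate_n,
                        seed = config$seed)
    cohort <- generate_cohort(cc, panel = config$panel)
    specimens <- cohort$specimens
    variants <- cohort$variants
    profiles <- cohort$msi_profiles
  } else {
    specimens <- read_specimens(config$specimens)
    variants <- read_variants(config$variants, "maf_tsv")
    profiles <- if (!is.null(config$msi_profiles))
      read_msi_profiles(config$msi_profiles) else NULL
  }

  ## stage 1: cohort eligibility
  flt <- filter_cohort(specimens, config$min_coverage)
  specimens <- flt$specimens

  ## stage 2: filter cascade + TMB
  variants <- annotate_recurrent_germline(variants,
                                          n_cohort = nrow(specimens))
  audit <- classify_variants(variants)
  audit <- audit[audit$specimen_id %in% specimens$specimen_id, ]
  tmb <- cohort_tmb(audit, config$panel, specimens$specimen_id)
  specimens$tmb <- tmb$tmb[match(specimens$specimen_id, tmb$specimen_id)]

  ## stage 3: MSI
  msi <- NULL
  if (!is.null(profiles)) {
    profiles <- profiles[profiles$specimen_id %in% specimens$specimen_id, ]
    msi <- msi_pipeline(profiles)
    specimens$msi_call <- msi$msi_call[match(specimens$specimen_id,
                                             msi$specimen_id)]
  }

  ## stage 4: landscape
  summary_tab <- disease_summary(specimens, config$high_threshold,
                                 config$min_n)
  trend <- if (length(unique(specimens$age)) >= 2)
    age_trend(specimens, pseudo_count = config$spec$pseudo_count)
  else NULL
  crosstab <- if (!is.null(specimens$msi_call))
    msi_tmb_crosstab(specimens, config$high_threshold) else NULL

  ## stage 5: association
  carriers <- functional_carriers(audit, config$spec)
  assoc <- gene_association(specimens, carriers, config$spec)

  ## outputs + manifest
  out <- function(f) file.path(config$out_dir, f)
  write_specimens(specimens, out("specimens.tsv"))
  .fwrite_tsv(tmb, out("tmb.tsv"))
  .fwrite_tsv(audit[, c("specimen_id", "variant_id", "counted",
                        "reason")[c("specimen_id", "variant_id",
                                    "counted", "reason") %in%
                                  names(audit)]],
              out("filter_audit.tsv"))
  if (!is.null(msi)) .fwrite_tsv(msi, out("msi_calls.tsv"))
  .fwrite_tsv(summary_tab, out("disease_summary.tsv"))
  .fwrite_tsv(assoc, out("gene_association.tsv"))
  files <- c("specimens.tsv", "tmb.tsv", "filter_audit.tsv",
             if (!is.null(msi)) "msi_calls.tsv", "disease_summary.tsv",
             "gene_association.tsv")
  manifest <- list(
    package = "tmbscape",
    version = as.character(packageVersion("tmbscape")),
    seed = config$seed,
    n_specimens = nrow(specimens),
    excluded = as.list(flt$excluded),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(specimens = specimens, tmb = tmb, audit = audit,
                 msi = msi, summary = summary_tab, age_trend = trend,
                 crosstab = crosstab, association = assoc,
                 manifest = manifest))
}
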