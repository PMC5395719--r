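# in-code fixtures shared across test files

# a single variant row with every annotation defaulted to "counted"
make_variant <- function(specimen_id = "S1", chrom = "chr1", pos = 100L,
                         ref = "A", alt = "T", gene = "TP53",
                         effect = "missense", coding = TRUE,
                         known_somatic_hotspot = FALSE,
                         ts_truncation = FALSE, dbsnp = FALSE,
                         population_count = 0L,
                         recurrent_germline = FALSE,
                         zygosity_call = "uncalled",
                         allele_fraction = 0.3, homopolymer_len = 0L) {
  data.frame(specimen_id = specimen_id, chrom = chrom, pos = pos,
             ref = ref, alt = alt, gene = gene, effect = effect,
             coding = coding,
             known_somatic_hotspot = known_somatic_hotspot,
             ts_truncation = ts_truncation, dbsnp = dbsnp,
             population_count = population_count,
             recurrent_germline = recurrent_germline,
             zygosity_call = zygosity_call,
             allele_fraction = allele_fraction,
             homopolymer_len = homopolymer_len, stringsAsFactors = FALSE)
}

make_variants <- function(n, ...) {
  out <- make_variant(...)[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# specimen-level simulator for the association models: log10(TMB) =
# disease baseline + loading * carrier + N(0, sd). Cheap enough for
# replicate studies, unlike the full variant-level generator.
sim_assoc_cohort <- function(n, loading = 0.5, prevalence = 0.02,
                             sd = 0.3, n_diseases = 4L) {
  disease <- sample(paste0("D", seq_len(n_diseases)), n, replace = TRUE)
  mu <- setNames(seq(0.3, 1.1, length.out = n_diseases),
                 paste0("D", seq_len(n_diseases)))
  carrier <- runif(n) < prevalence
  tmb <- 10^(mu[disease] + loading * carrier + rnorm(n, 0, sd))
  list(specimens = data.frame(specimen_id = sprintf("S%05d", seq_len(n)),
                              tmb = as.numeric(tmb), disease = disease,
                              stringsAsFactors = FALSE),
       carrier = carrier)
}

carriers_from_flag <- function(specimens, flag, term = "GENE1") {
  data.frame(specimen_id = specimens$specimen_id[flag], term = term,
             stringsAsFactors = FALSE)
}

# small cohort with MSI, cached per session (generation is the slow part)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(
        cohort_config(n_specimens = 150, msi_high_rate = 0.2, seed = 11))
    cache
  }
})
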