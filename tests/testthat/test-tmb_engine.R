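# filter cascade, TMB arithmetic, zygosity proxy, panel-vs-exome

test_that("cascade counts clean coding variants, synonymous included", {
  v <- classify_variants(rbind(make_variant(effect = "synonymous"),
                               make_variant(effect = "missense",
                                            population_count = 1L)))
  expect_true(all(v$counted))
  expect_true(all(v$reason == "counted"))
})

test_that("each exclusion rule fires with its reason", {
  cases <- rbind(
    make_variant(effect = "noncoding", coding = FALSE),
    make_variant(known_somatic_hotspot = TRUE),
    make_variant(ts_truncation = TRUE, effect = "nonsense"),
    make_variant(zygosity_call = "germline"),
    make_variant(recurrent_germline = TRUE),
    make_variant(dbsnp = TRUE),
    make_variant(population_count = 2L))
  out <- classify_variants(cases)
  expect_false(any(out$counted))
  expect_equal(out$reason,
               c("noncoding", "known_somatic", "ts_truncation",
                 "zygosity_germline", "recurrent_germline", "dbsnp",
                 "population_count"))
})

test_that("first matching rule wins when several flags are set", {
  v <- make_variant(effect = "noncoding", coding = FALSE, dbsnp = TRUE,
                    population_count = 5L)
  expect_equal(classify_variants(v)$reason, "noncoding")
  v2 <- make_variant(dbsnp = TRUE, population_count = 5L)
  expect_equal(classify_variants(v2)$reason, "dbsnp")
})

test_that("counted set is invariant to input ordering", {
  coh <- small_cohort()
  v <- coh$variants
  a <- classify_variants(v)
  set.seed(1)
  perm <- sample(nrow(v))
  b <- classify_variants(v[perm, ])
  expect_setequal(a$variant_id[a$counted], b$variant_id[b$counted])
})

test_that("removing any filter flag never decreases the counted set", {
  coh <- small_cohort()
  v <- coh$variants
  base <- sum(classify_variants(v)$counted)
  clears <- list(
    function(v) { v$known_somatic_hotspot <- FALSE; v },
    function(v) { v$ts_truncation <- FALSE; v },
    function(v) { v$zygosity_call[v$zygosity_call == "germline"] <-
                    "uncalled"; v },
    function(v) { v$dbsnp <- FALSE; v },
    function(v) { v$population_count <- 0L; v })
  for (cl in clears)
    expect_gte(sum(classify_variants(cl(v))$counted), base)
})

test_that("compute_tmb normalizes counted mutations by territory", {
  panel <- default_panel()
  empty <- make_variant()[0, ]
  expect_equal(compute_tmb(empty, panel)$tmb, 0)
  v11 <- make_variants(11)
  expect_equal(compute_tmb(v11, panel)$tmb, 10.0)
  v38 <- make_variants(38)
  expect_equal(compute_tmb(v38, exome_panel())$tmb, 1.0)
  expect_error(compute_tmb(rbind(make_variant(specimen_id = "A"),
                                 make_variant(specimen_id = "B")), panel),
               "single specimen")
  expect_error(panel_definition("bad", "TP53", 0), "positive")
})

test_that("compute_tmb is linear in the counted variants", {
  v <- make_variants(7)
  panel <- default_panel()
  one <- compute_tmb(v, panel)$tmb
  two <- compute_tmb(rbind(v, v), panel)$tmb
  expect_identical(two, 2 * one)
})

test_that("zygosity proxy matches allele-fraction expectations", {
  expect_equal(call_zygosity_proxy(0.50, 2, 1.0), "germline")
  expect_equal(call_zygosity_proxy(1.00, 2, 1.0), "germline")
  expect_equal(call_zygosity_proxy(0.05, 2, 1.0), "somatic")
  # between het - delta and the somatic clonal band at purity 0.5:
  # het expectation 0.5, somatic clonal 0.25 -> 0.37 is ambiguous
  expect_equal(call_zygosity_proxy(0.37, 2, 0.5, delta = 0.05),
               "ambiguous")
  expect_error(call_zygosity_proxy(0.5, 2, 0), "purity")
  expect_error(call_zygosity_proxy(1.2, 2, 1), "allele_fraction")
})

test_that("recurrent-germline annotation uses the cohort threshold", {
  site <- function(sid) make_variant(specimen_id = sid, pos = 777L,
                                     zygosity_call = "germline")
  v3 <- rbind(site("A"), site("B"), site("C"), make_variant(pos = 888L))
  out <- annotate_recurrent_germline(v3, n_cohort = 100)
  expect_equal(sum(out$recurrent_germline), 3L)
  v2 <- rbind(site("A"), site("B"))
  expect_false(any(annotate_recurrent_germline(v2,
                                               n_cohort = 100)$recurrent_germline))
})

test_that("panel restricted to the whole exome reproduces exome TMB", {
  set.seed(4)
  v <- do.call(rbind, lapply(1:5, function(i)
    make_variants(10 + i, specimen_id = paste0("S", i))))
  res <- panel_vs_exome(v, exome_panel(), exome_mb = 38)
  expect_equal(res$r_squared, 1.0)
  expect_equal(res$table$panel_tmb, res$table$exome_tmb)
})

test_that("panel TMB tracks exome TMB on a thinned synthetic exome", {
  # 2000 equal-territory genes, 58 in a panel (1.1/38 of the exome);
  # mutation placement uniform over territory, true TMB log-uniform 1-100
  set.seed(42)
  n_genes <- 2000L
  genes <- sprintf("G%04d", seq_len(n_genes))
  panel_genes <- genes[seq_len(round(n_genes * 1.1 / 38))]
  rows <- lapply(seq_len(200), function(i) {
    tmb <- 10^runif(1, 0, 2)
    k <- rpois(1, tmb * 38)
    if (k == 0) return(NULL)
    v <- make_variants(k, specimen_id = sprintf("S%03d", i))
    v$gene <- sample(genes, k, replace = TRUE)
    v
  })
  v <- do.call(rbind, Filter(Negate(is.null), rows))
  panel <- panel_definition("sub", panel_genes,
                            38 * length(panel_genes) / n_genes)
  res <- panel_vs_exome(v, panel, exome_mb = 38)
  expect_gte(res$r_squared, 0.9)
  expect_error(panel_vs_exome(v[v$specimen_id %in% c("S001", "S002"), ],
                              panel), "3 specimens")
})

test_that("variant validation enforces invariants", {
  expect_error(validate_variants(make_variant(pos = 0L)), "pos")
  expect_error(validate_variants(make_variant(allele_fraction = 1.5)),
               "allele_fraction")
  expect_error(validate_variants(make_variant(effect = "noncoding",
                                              coding = TRUE)),
               "noncoding")
  v <- make_variant()[, 1:8]   # only required columns
  out <- validate_variants(v)
  expect_false(out$dbsnp)
  expect_equal(out$zygosity_call, "uncalled")
})
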