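# association models and FDR

test_that("bh_fdr matches hand-computed and brute-force step-up values", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force oracle: q_i = min over j with p_j >= p_i of p_j * m / rank_j
  brute <- function(p) {
    m <- length(p)
    ord <- order(p)
    r <- numeric(m)
    r[ord] <- seq_len(m)
    vapply(seq_len(m), function(i)
      min(1, min(vapply(which(p >= p[i]), function(j)
        p[j] * m / r[j], 0))), 0)
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))))
  }
  base <- c(0.001, 0.02, 0.21, 0.5, 0.95)
  for (p in perms(base)) {
    expect_equal(bh_fdr(p), brute(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  }
})

test_that("noiseless constructed effect is recovered exactly", {
  # carriers at exactly 10^0.5 x the non-carrier TMB in each disease
  sp <- data.frame(specimen_id = sprintf("S%02d", 1:40),
                   disease = rep(c("A", "B"), each = 20),
                   tmb = rep(c(2, 5), each = 20), stringsAsFactors = FALSE)
  carrier <- rep(c(rep(TRUE, 8), rep(FALSE, 12)), 2)
  sp$tmb[carrier] <- sp$tmb[carrier] * 10^0.5
  res <- suppressWarnings(   # summary.lm "essentially perfect fit"
    gene_association(sp, carriers_from_flag(sp, carrier),
                     spec = model_spec(pseudo_count = 0)))
  expect_equal(res$factor_loading, 0.5, tolerance = 1e-12)
  expect_equal(res$fold_change, 10^0.5, tolerance = 1e-12)
  expect_equal(res$n_carriers, 16L)
})

test_that("genes below the carrier minimum are not tested", {
  set.seed(1)
  sim <- sim_assoc_cohort(200, loading = 0, prevalence = 0.5)
  sp <- sim$specimens
  few <- carriers_from_flag(sp, seq_len(nrow(sp)) <= 5, "RARE")
  res <- gene_association(sp, few)
  expect_false("RARE" %in% res$term)
  six <- carriers_from_flag(sp, seq_len(nrow(sp)) <= 6, "SIX")
  expect_true("SIX" %in% gene_association(sp, six)$term)
})

test_that("fold_change equals 10^loading to machine precision", {
  set.seed(2)
  sim <- sim_assoc_cohort(500, loading = 0.4, prevalence = 0.1)
  res <- gene_association(sim$specimens,
                          carriers_from_flag(sim$specimens, sim$carrier))
  expect_identical(res$fold_change, 10^res$factor_loading)
})

test_that("disease-wise TMB rescaling leaves gene loadings unchanged", {
  # noiseless world so the check is exact
  sp <- data.frame(specimen_id = sprintf("S%02d", 1:60),
                   disease = rep(c("A", "B", "C"), each = 20),
                   tmb = rep(c(2, 4, 8), each = 20),
                   stringsAsFactors = FALSE)
  carrier <- rep(c(rep(TRUE, 7), rep(FALSE, 13)), 3)
  sp$tmb[carrier] <- sp$tmb[carrier] * 10^0.3
  spec0 <- model_spec(pseudo_count = 0)
  ca <- carriers_from_flag(sp, carrier)
  r1 <- suppressWarnings(gene_association(sp, ca, spec0))
  sp2 <- sp
  scale_by <- c(A = 3, B = 0.5, C = 10)
  sp2$tmb <- sp2$tmb * scale_by[sp2$disease]
  r2 <- suppressWarnings(gene_association(sp2, ca, spec0))
  expect_equal(r2$factor_loading, r1$factor_loading, tolerance = 1e-10)
})

test_that("injected effect is recovered with small bias", {
  set.seed(3)
  est <- replicate(50, {
    sim <- sim_assoc_cohort(2000, loading = 0.5, prevalence = 0.02)
    res <- gene_association(sim$specimens,
                            carriers_from_flag(sim$specimens, sim$carrier),
                            spec = model_spec(pseudo_count = 0))
    res$factor_loading
  })
  expect_lt(abs(mean(est) - 0.5), 0.02)
})

test_that("mutation eligibility filters fire before testing", {
  set.seed(4)
  sim <- sim_assoc_cohort(3000, loading = 0, prevalence = 0.01)
  sp <- sim$specimens
  ca <- rbind(carriers_from_flag(sp, sim$carrier, "M_ok"),
              carriers_from_flag(sp, sim$carrier, "M_hp"),
              carriers_from_flag(sp, sim$carrier, "M_dbsnp"),
              carriers_from_flag(sp, seq_len(nrow(sp)) <= 1, "M_rare"))
  info <- data.frame(term = c("M_ok", "M_hp", "M_dbsnp", "M_rare"),
                     homopolymer_len = c(2L, 6L, 0L, 0L),
                     dbsnp = c(FALSE, FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  res <- mutation_association(sp, ca, info)
  expect_equal(res$term, "M_ok")      # 1/3000 < 1/2000 floor drops M_rare
})

test_that("mutation-level effect is recovered at 1% prevalence", {
  set.seed(5)
  sim <- sim_assoc_cohort(5000, loading = 0.7, prevalence = 0.01)
  res <- mutation_association(
    sim$specimens, carriers_from_flag(sim$specimens, sim$carrier, "MUT"),
    spec = model_spec(pseudo_count = 0))
  expect_lt(abs(res$factor_loading - 0.7), 0.1)
  expect_lt(res$q_value, 0.05)
  expect_true(res$significant)
})

test_that("singular designs are reported, not fatal", {
  sp <- data.frame(specimen_id = sprintf("S%02d", 1:20), disease = "A",
                   tmb = rep(c(1, 2), 10), stringsAsFactors = FALSE)
  # carrier identical to an all-TRUE column after single-disease collapse
  all_car <- carriers_from_flag(sp, rep(TRUE, 20), "ALL")
  res <- gene_association(sp, all_car)
  expect_equal(nrow(res), 0L)   # all-carrier genes cannot be contrasted
})

test_that("co-occurrence detects nothing for a TMB-independent gene", {
  set.seed(6)
  nulls <- replicate(60, {
    n <- 1000
    tmb <- 10^rnorm(n, 0.7, 0.4)
    status <- runif(n) < plogis(-3 + 1.5 * log10(tmb))
    if (all(status) || !any(status)) return(NA_real_)
    carrier <- runif(n) < 0.1
    sp <- data.frame(specimen_id = sprintf("S%04d", 1:n), tmb = tmb,
                     stringsAsFactors = FALSE)
    res <- cooccurrence_test(status, carriers_from_flag(sp, carrier),
                             sp)
    res$q_value
  })
  expect_gte(mean(nulls >= 0.05, na.rm = TRUE), 0.90)
})

test_that("complete separation is flagged non-estimable, not an error", {
  n <- 200
  sp <- data.frame(specimen_id = sprintf("S%03d", 1:n),
                   tmb = rep(5, n), stringsAsFactors = FALSE)
  status <- seq_len(n) <= 40
  perfect <- carriers_from_flag(sp, status, "PERF")
  res <- cooccurrence_test(status, perfect, sp)
  expect_false(res$estimable)
  expect_true(is.na(res$odds_ratio))
  expect_error(cooccurrence_test(rep(TRUE, n), perfect, sp), "degenerate")
})

test_that("functional carriers derive from coding non-synonymous calls", {
  v <- rbind(make_variant(effect = "missense", gene = "G1"),
             make_variant(effect = "synonymous", gene = "G2"),
             make_variant(effect = "frameshift", gene = "G3",
                          homopolymer_len = 7L),
             make_variant(effect = "missense", gene = "G4", dbsnp = TRUE),
             make_variant(effect = "missense", gene = "G5",
                          zygosity_call = "germline"))
  ca <- functional_carriers(v)
  expect_equal(ca$term, "G1")
})
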