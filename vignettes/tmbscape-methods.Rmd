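---
title: "Methods: panel-based TMB, MSI scoring, and cohort analysis in tmbscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based TMB, MSI scoring, and cohort analysis in tmbscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbscape)
```

# The problem

Tumor mutational burden (TMB) — somatic, coding base substitutions and
indels per megabase of sequenced coding territory — predicts response to
immune checkpoint blockade. Measuring it from a targeted panel (a few
hundred cancer genes, ~1.1 Mb of coding territory) rather than a matched
tumor/normal whole exome (~38 Mb) raises three methodological problems
that this package implements and tests:

1. **Somatic versus germline.** Without a matched normal, germline
   polymorphisms must be removed by filtering, not subtraction.
2. **Sampling noise.** 1.1 Mb is a thinned sample of the exome; how much
   measurement error does the footprint introduce?
3. **Downstream inference.** Microsatellite instability (MSI) calling,
   gene/mutation associations with TMB, and cohort landscape summaries
   all consume the panel TMB and inherit its error structure.

Because the motivating clinical cohorts are proprietary, every analysis
here runs against a synthetic cohort generator whose ground truth (true
TMB, driver status, MSI state, per-variant origin) is recorded, so the
pipeline is tested by parameter recovery rather than by re-printing
cohort numbers.

# The TMB filter cascade

All coding base substitutions and indels are counted initially,
*including synonymous* variants: they are not immunogenic themselves,
but they track the same underlying mutational processes and reduce
sampling noise at panel scale. Variants are then excluded in a fixed
order, each with an audited reason:

| order | reason | rationale |
|---|---|---|
| 1 | `noncoding` | TMB counts coding territory only |
| 2 | `known_somatic` | known hotspots are enriched by panel design and would bias TMB upward |
| 3 | `ts_truncation` | truncations in tumor suppressors, same enrichment bias |
| 4 | `zygosity_germline` | predicted germline by allele-fraction/copy-number model |
| 5 | `recurrent_germline` | predicted germline recurrently across the cohort |
| 6 | `dbsnp` | known germline polymorphism |
| 7 | `population_count` | ≥ 2 ExAC-style population counts |

Each rule is a pure predicate of the variant, so the **counted set is
independent of both the rule order and the input row order**; the order
fixes only which reason is reported. Removing any filter can only grow
the counted set (monotonicity). Both properties are tested. TMB is
`counted / territory_mb`; multi-nucleotide substitutions (e.g. CC>TT)
are represented as one row and counted as one event (the convention for
dinucleotide events at adjacent positions; the alternative, counting
per base, is not supported).

The cohort-recurrence rule needs a threshold the method description does
not give: a site predicted germline in at least `max(3, 0.1%)` distinct
specimens is flagged, both knobs configurable
(`annotate_recurrent_germline()`).

## The zygosity proxy

The production somatic–germline–zygosity model is a published algorithm
in its own right; `call_zygosity_proxy()` implements a declared
simplification. For purity $p$ and local copy number $c$, a germline
heterozygote is expected at allele fraction
$(p + (1-p)) / (pc + 2(1-p))$ and a homozygote at 1; clonal somatic
bands sit at $pm/(pc + 2(1-p))$ for $m = 1..c$. An observed fraction
within $\delta = 0.10$ of a germline expectation is germline; within
$\delta$ of a somatic band, or below the lowest band (subclonal), is
somatic; anything else (e.g. between bands at low purity) is ambiguous.
The synthetic generator does **not** use this proxy to label its
variants: the proxy would misclassify roughly a quarter of somatic
variants whose fractions happen to fall near 0.5, which is far below the
accuracy of the production model the labels emulate. Instead the
generator emits `zygosity_call` as a noisy function of true origin
(95% of germline variants labelled germline, 90% of somatic labelled
somatic, the rest ambiguous/uncalled), and the proxy remains a separate,
fully tested operation for uncalled inputs.

# Downsampling: measurement error versus footprint

With true burden $t$ mutations/Mb over $m$ megabases, the observed count
is $k \sim \mathrm{Binomial}(n = m \cdot 10^6,\ p = t \cdot 10^{-6})$
and the observed TMB is $k/m$. `simulate_observed_tmb()` reports the
percent deviation $100\,|k/m - t|/t$ with type-7 empirical quantiles
(median, 10th, 90th). The relative standard deviation is
$\sqrt{(1-p)/(np)}$ — about 3.16% at $t = 100$, $m = 10$ — and grows
like $1/\sqrt{m}$ as the footprint shrinks, exploding below ~0.5 Mb.

One numerical subtlety matters for testing: because $k$ is an integer,
deviations are quantized in steps of $1/(tm)$, and the *population*
median deviation is not strictly monotone in $m$ — it oscillates by up
to $\approx 100/(2np)$ percentage points, which above ~2.5 Mb exceeds
the smooth decrement between 0.2 Mb grid steps. This is why published
versions of this figure smooth the curves with a cubic spline
(presentation only; excluded here from all computation paths), why the
monotonicity invariant is tested on a dyadic grid (0.25–8 Mb) where
decrements dominate quantization, and why a strict non-increasing check
on the fine grid is expected to fail by ~11 tiny inversions no matter
how many replicates are drawn.

# The MSI score

114 intronic homopolymer loci with reference repeat length 10–20 bp
(long enough to slip, short enough to sit inside a read) are profiled:
for each locus, the repeat length observed in every spanning read. Per
locus the mean and the variance (denominator $n-1$; the method source is
silent, and at ≥ 20 reads the difference is negligible) over reads give
2 features — 228 per specimen for the default panel. The feature matrix
is centered per column but **not** scaled (the locus variances carry the
instability signal; standardizing would dilute it — a `scale.` toggle is
exposed), and specimens are projected on the first principal component.
A principal component's sign is arbitrary, so scores are oriented to
correlate positively with the mean variance feature: higher score =
more unstable. On generated mixtures PC1 dominates the spectrum
(~50–60% of variance against ≤ ~5% for every other component), which is
asserted as dominance, not as the cohort-specific percentages.

"Manual unsupervised clustering" of the score into MSI-H / ambiguous /
MSS is replaced by a reproducible rule: a two-component 1-D Gaussian
mixture (EM), with the ambiguous band defined by posterior probability
of the unstable component between 0.1 and 0.9. The posterior is searched
between the two component means because in the far tail of the narrow
(stable) component its density underflows and the posterior spuriously
returns to 1. With training labels, class-conditional Gaussians replace
the EM fit. Thresholds are returned so calls transfer to held-out
specimens.

# Association models

Gene–TMB association uses
$\log_{10}(\mathrm{TMB} + \mathrm{pseudo}) \sim \mathrm{carrier} +
\mathrm{disease}$, ordinary least squares, with the most frequent
disease as reference level (loadings are invariant to this choice;
intercepts are not). The carrier coefficient — the *factor loading* —
is the change in log10 TMB holding disease constant; $10^{\beta}$ is the
fold-change (a loading of 0.5 ≈ 3.16-fold). Genes need ≥ 6 carriers;
individual mutations need carrier frequency > 1/2000 and are excluded
when they sit in homopolymers ≥ 6 bp (error-prone indels) or appear in
dbSNP. Benjamini–Hochberg FDR is applied within each analysis family
(genes at $10^{-4}$, mutations at 0.05), matching the per-family levels
reported with those analyses. Reported significance combines the FDR
level with the loading cutoffs (0.5 for genes, 0.15 for mutations).
Degenerate designs (all carriers, single-stratum confounding) are
reported per term as non-estimable rather than aborting.

The pseudo-count is not given a value in the method source; the default
is 1 mutation/Mb, which keeps zero-count specimens in the model and
preserves ordering. `age_trend()` defaults to pseudo-count 0 instead:
it fits $\log_{10}$ TMB directly, because with typical burdens of
2–5/Mb a pseudo-count of 1 visibly attenuates the age slope (a true
2.4-fold span would fit as ~2.0) and the generator's true TMB is never
zero; specimens with non-positive values are dropped with a warning if
they occur.

Co-occurrence of a binary specimen status (e.g. PMS2-promoter mutation
in melanoma) with gene mutations is tested by logistic regression with
TMB as covariate, so co-occurrence driven purely by shared high burden
is absorbed by the covariate. Complete separation is detected
(diverging coefficient or degenerate fitted probabilities) and flagged
non-estimable.

# Landscape summaries

Eligibility mirrors clinical practice: one specimen per patient (first
in stable order), then median exon coverage ≥ 300× (a specimen at 299×
is excluded). Diseases with ≥ 50 specimens are summarized with type-7
quantiles and the percentage of cases with TMB **strictly above**
20 mutations/Mb ("high TMB"); the MSI comparison uses TMB ≥ 10. Binomial
confidence intervals are Wilson score intervals (for 4/50 the upper
bound is 18.8%, matching printed values; the lower bound is 3.2% where
some published tables print 3.1%, so the CI flavor is configurable and
recorded as ambiguous). Display percentages round half-away-from-zero
at one decimal (`tally_percent()`).

# The synthetic generator: the stated world

The generator's defaults are fixed once and not tuned against tests:

* **Cohort structure.** Disease mix over nine pan-cancer disease labels
  with baseline median TMB from 2.7 (oligodendroglioma) to 14.4
  (melanoma) mutations/Mb; log10 TMB noise sd 0.3 per disease (the
  source gives no per-disease variance; 0.3 gives the realistic pattern
  of overlapping lognormal burden distributions with rare > 100/Mb
  outliers). Ages uniform on 10–90 years, coverage ~ N(500, 60).
* **Age effect.** log-linear slope $\log_{10}(2.4)/80$ per year — a
  2.4-fold TMB span across 80 years, centered at age 60.
* **Drivers.** Mismatch-repair (0.9% prevalence, 5.3-fold TMB),
  POLE (0.1%, 10-fold — polymerase-proofreading tumors are
  ultramutated), PMS2-promoter (1% overall, 5.3-fold, the reported
  median fold in melanoma); multiplicative on true TMB. MSI-unstable
  specimens (5% default) get 10-fold TMB, producing the observed
  asymmetry that nearly all MSI-H specimens have TMB ≥ 10 while most
  high-TMB specimens are microsatellite stable.
* **Counts.** Somatic coding calls per specimen are Poisson with mean
  true TMB × 1.1 Mb (no generative model is stated; Poisson is the
  small-$p$ limit of the binomial thinning used in the downsampling
  model). Non-coding calls at 5% of the coding rate exercise the
  noncoding filter. Somatic allele fractions Uniform(0.05, 0.85),
  matching the reported somatic range.
* **Germline.** ~20 germline variants per specimen drawn from a shared
  400-site catalog with power-law popularity (so cohort recurrence
  arises naturally); het/hom fractions N(0.5, 0.05)/N(1.0, 0.05);
  population counts ≥ 2 with probability 0.95; dbSNP membership 90%.
* **Annotations.** 10% of variants get homopolymer context ≥ 6 bp; 2% of
  somatic missense calls are flagged as known hotspots; truncations in
  the tumor-suppressor subset get the `ts_truncation` flag.
* **MSI reads.** 50 reads per locus; stable loci jitter around the
  reference length with sd 0.5 bp (polymerase slippage noise); in
  unstable specimens 60% of loci shift −2 bp with sd 2. Read lengths
  are integers, so generated per-locus variances include a rounding
  term (≈ +1/12); the relevant test freezes its expectation against the
  rounded-normal value, not the nominal $\sigma^2$.

What the generator deliberately does **not** emulate: trinucleotide
signature structure, read-level errors, coverage nonuniformity, gene-
level mutation hotspots beyond the configured drivers, and correlation
between MSI status and MMR coding mutations. A green test therefore
establishes that the pipeline recovers the parameters of this stated
world — not that it reproduces any proprietary cohort's printed values,
which are explicitly out of scope.

# Numerical choices and degenerate inputs

* Quantiles everywhere are type 7 (linear interpolation).
* PCA is `prcomp` on the centered matrix; an all-constant feature matrix
  is a named error, as are < 3 specimens.
* The Gaussian-mixture EM floors component sd at $10^{-6}$ and stops on
  log-likelihood change < $10^{-8}$.
* `compute_tmb` of an empty variant table is 0; `panel_vs_exome` with
  < 3 specimens, constant-age `age_trend`, degenerate co-occurrence
  outcomes, and identical MSI scores are all rejected with named errors.
* Conditional proportions with empty conditioning sets (e.g. no MSI-H
  specimens) are reported as undefined, never as 0.
* All randomness flows from the seed of the relevant config; identical
  config + seed reproduces tables byte-identically, and the pipeline
  manifest records MD5 checksums of every output.

# Known limitations

* The zygosity proxy is intentionally crude; at purity below ~0.4 its
  germline band overlaps clonal somatic bands and most calls become
  ambiguous.
* Locus selection (`select_loci`) ranks candidates by a supplied
  between-sample variability statistic; computing that statistic from a
  training corpus of profiles is left to the caller.
* The gene association refits one OLS model per gene; at panel scale
  (hundreds of genes) this is fast, but it is not optimized for
  exome-wide mutation sets.
* The VCF dialect read/written here covers this package's own INFO
  annotations; arbitrary third-party VCF annotation schemes are not
  interpreted (flags default to FALSE with a count of unknowns).
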