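---
title: "Methods: two-sample MR for microbiome exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for microbiome exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmr)
```

## The design

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here, the relative abundance of a gut-microbiota taxon) on an
outcome (kidney phenotypes such as eGFR or CKD) from two independent GWAS:
one for the exposure, one for the outcome. Each SNP that robustly predicts
the exposure acts as an instrumental variable; because alleles are assorted
at conception, the per-SNP outcome effect divided by the exposure effect (the
Wald ratio) is protected from classical confounding and reverse causation,
provided the instrument affects the outcome only through the exposure.

`mbmr` implements the whole workflow against plain summary-statistic tables
(`snp, chr, pos, ea, oa, eaf, beta, se, p, n`, tab-separated), so it runs on
any GWAS export that can be mapped onto those columns.

## Instrument selection

The funnel in `select_instruments()` applies, in order:

1. **Locus-wide significance** `p <= 1e-5` on the exposure. Microbiome GWAS
   are modest in size (tens of thousands of samples), and genome-wide
   significant hits per taxon are rare, so the conventional locus-wide
   threshold is used to retain enough instruments.
2. **Greedy LD clumping** (`r2 > 0.001` within 10,000 kb removed, most
   significant SNP kept per clump). Ties in p are broken by chromosome,
   position, then SNP id, making the output invariant to input row order.
3. **MAF filter**: `min(eaf, 1 - eaf) >= 0.01`.
4. **Instrument strength**: per-SNP variance explained is approximated by
   `2 maf (1 - maf) beta^2` (standardized trait), and
   `F = (R2/(1 - R2)) ((N - K - 1)/K)`. The default applies the filter per
   SNP (`K = 1`), dropping variants with `F < 10`, which matches the reading
   that individual weak variants are excluded; `f_mode = "set"` instead
   rejects the whole set on the aggregate F. A sign-flipped variant of the
   formula, `R2/(R2 - 1)`, circulates in print; it is negative for
   `R2 < 1` and is exposed only behind `f_formula = "as_printed"` for
   comparison.
5. **Confounder blocklist**: a static file of SNP ids stands in for a manual
   confounder screen (PhenoScanner-style lookups of hypertension, diabetes,
   heart-disease associations). A live query is neither reproducible nor
   runnable offline, so the screen is frozen into a list.
6. **Outcome-association exclusion**: SNPs missing from the outcome table
   are dropped (reason `missing in outcome`), as are SNPs with outcome
   `p < 0.05`.

### A caveat on stage 6

Excluding instruments associated with the outcome at `p < 0.05` is meant to
enforce the exclusion restriction, but under a *true* causal effect every
strong instrument is associated with the outcome — that is the signal MR
measures. The filter therefore removes precisely the informative instruments
and truncates the surviving outcome effects toward zero. The analysis
scripts demonstrate this: with a true slope of 0.3 and 12 selected
instruments, the faithful funnel ends at zero instruments, while disabling
the stage (`p_outcome_exclude = 0`) recovers the effect as a strong tier.
Users analysing real data should prefer a genome-wide exclusion threshold
(e.g. `5e-8`) or disable the stage; the default remains 0.05 for fidelity to
the published workflow this package operationalizes.

## Harmonization

`harmonize()` aligns each exposure SNP's outcome record to the exposure
effect allele: identical allele pairs are kept, swapped pairs have the
outcome beta negated (and eaf complemented), anything else is removed as a
mismatch. Palindromic SNPs (A/T, C/G) are removed unconditionally — no
frequency-based strand inference — trading power for fidelity and safety.
Strand-complement recovery for non-palindromic SNPs (A/G recorded as T/C) is
off by default and available via `resolve_complements = TRUE`.

## Estimators

With harmonized vectors `(bx_j, sx_j, by_j, sy_j)`:

- **Wald ratio** (single SNP): `by/bx`, first-order delta-method SE
  `|sy/bx|`.
- **IVW**: zero-intercept weighted regression of `by` on `bx` with weights
  `1/sy^2`; equivalently the inverse-variance-weighted mean of Wald ratios
  with weights `bx^2/sy^2`. The *primary* model is multiplicative random
  effects — the fixed-effect SE scaled by `max(1, sqrt(Q/(K - 1)))` — since
  a fixed-effects model is the designated sensitivity check. Both are always
  computed; classification uses the random-effects p exclusively.
- **MR-Egger**: weighted regression with a free intercept after orienting
  all SNPs to `bx >= 0`. The slope is consistent under InSIDE (instrument
  strength independent of direct effects); the intercept estimates average
  directional pleiotropy. SEs carry the `max(1, sqrt(RSS/(K - 2)))`
  overdispersion scale, p-values use a t reference on `K - 2` df.
- **Weighted median**: the weighted 50% point of sorted ratios (linear
  interpolation across cumulative weights `s_j = sum w_i - w_j/2`),
  consistent while valid instruments carry more than half the weight.
- **Weighted mode**: argmax of a weighted Gaussian kernel density over the
  ratios with bandwidth `h = phi * 0.9 * min(sd, IQR/1.349) * K^{-1/5}`
  (`phi = 1` by default), consistent when the largest cluster of similar
  ratios is valid. The point estimate refines a 512-point grid argmax by
  golden-section search; bootstrap replicates use the grid argmax only, a
  deliberate speed/precision trade that is far below the bootstrap noise.

Median and mode SEs come from a parametric bootstrap (default 1000
replicates, seeded): betas are redrawn from normals centred on the observed
values with the reported SEs and the replicate-estimate SD is used with a
normal CI. CIs elsewhere use 1.96 SEs (t-quantiles for Egger). For binary
outcomes (CKD, dialysis, rapid progression/decline endpoints) estimates are
also reported as odds ratios by exponentiation.

## Diagnostics

- **Cochran's Q** about the fixed-effect IVW centre, chi-square on `K - 1`
  df; calibrated exactly under the null generative model.
- **Egger intercept test**: "no significant horizontal pleiotropy" iff the
  intercept p exceeds 0.05.
- **MR-PRESSO**: observed residual sum of squares with each SNP's residual
  measured against the leave-one-out IVW prediction; the null distribution
  is rebuilt by parametric simulation (default 1000 draws), giving an
  empirical global p with floor `1/(n_sim + 1)`. Per-SNP outliers are
  flagged by Bonferroni-corrected empirical p. Note `n_sim` must exceed
  `n_snp / alpha` for the outlier test to be able to flag anything; the
  distortion is reported descriptively (IVW before/after removal) rather
  than with its own test, since only the global test drives conclusions
  here.
- **Leave-one-out**: the primary IVW recomputed without each SNP; a
  `dominant_snp` flag marks variants whose removal destroys an otherwise
  significant result.

## Multiplicity and tiers

Bonferroni correction is applied within taxonomic rank: 0.05 divided by the
number of taxa at that rank (131 genera, 35 families, 20 orders, 16 classes,
9 phyla), giving thresholds of about 3.8e-4 to 5.6e-3. A primary-IVW p below
the rank threshold is a *strong* signal; between the threshold and 0.05,
*nominal*; otherwise *none*. `run_grid()` applies this over the full
taxon-by-outcome grid with deterministic ordering and per-pair derived
seeds, so reruns are byte-identical.

**Reverse direction**: `reverse_mr()` swaps the roles and instruments the
outcome at genome-wide significance (5e-8) by default — the criteria for
instrumenting disease GWAS are a design choice here, documented rather than
inherited — configurable down to the forward threshold, in which case
swapping twice reproduces the forward analysis exactly.

## The synthetic generator

`simulate_two_sample()` draws summary statistics directly — no
individual-level genotypes — under a transparent generative model: true
SNP-exposure effects `gamma_j ~ N(0, sigma_gamma^2)`, standard errors from
the allele-frequency/sample-size identity `se = (2 maf (1-maf) n)^{-1/2}`,
observed betas normal around the truth, outcome means
`theta * gamma_j + sign(gamma_j) * alpha_j`. Direct (pleiotropic) effects
`alpha_j ~ N(mu_alpha, sigma_alpha^2)` on the invalid fraction are defined
relative to the *exposure-increasing allele*: with symmetric `gamma` an
allele-frame constant would cancel under the `bx >= 0` orientation and no
estimator could see it, whereas the oriented definition makes `mu_alpha`
exactly the directional pleiotropy the Egger intercept estimates and the
quantity that biases IVW. An `inside_violation` parameter correlates
`alpha` with `|gamma|` to break InSIDE on demand.

Default conditions: 50 instruments among 500 SNPs, exposure GWAS of 18,340
(the scale of the microbiome consortium data this emulates), outcome GWAS of
20,000, MAF uniform on (0.05, 0.5), 20% palindromic SNPs, no LD
(`ld_block_size = 1`). `sigma_gamma = 0.3` puts locus-wide-significant
instruments firmly in the strong-instrument regime (per-SNP F in the
hundreds, comparable to the strongest known microbiome QTLs such as the
LCT–*Bifidobacterium* locus). This is deliberate: two-sample IVW with noisy
exposure betas carries weak-instrument attenuation of order
`theta * se_x^2 / sigma_gamma^2`, and validating estimator *correctness*
requires conditions where that known finite-sample bias is below Monte-Carlo
resolution. Robustness scenarios use 30% invalid instruments with
`mu_alpha = 0.1`, `sigma_alpha = 0.05`.

LD is emulated only as the pairwise r-squared lookup that clumping consumes
(equal r-squared within blocks, zero across); effect-size correlation across
linked SNPs is *not* simulated, so the generator tests clumping correctness,
not fine-mapping realism. Likewise not modelled: sample overlap between the
two GWAS, case-control ascertainment, allele-frequency drift between
cohorts, and outcome-specific genetic architecture (the outcome trait has no
instruments of its own, so "reverse" signals in simulated data can only be
leaks of the forward effect — the reverse-direction machinery is therefore
validated by role-swapping, and a null reverse analysis is the expected
simulated result). Passing tests demonstrate algorithmic and statistical
correctness under this model, not performance on real consortium data.

## Numerical choices and degenerate inputs

- p-values are floored at 1e-300 to stay within (0, 1] under underflow.
- Summary-statistic files are written with 17 significant digits so
  write-then-read round-trips are bit-exact.
- Duplicate LD entries must agree within 1e-9; conflicting duplicates are an
  error, not a silent overwrite.
- All-identical ratios: Q = 0 with p = 1, Egger fits perfectly (intercept
  0), the mode returns the common ratio (zero-bandwidth guard).
- Empty selection stages produce a flagged empty instrument set, never an
  exception; insufficiency for an estimator (fewer than 3 SNPs) is recorded
  in the report.
- One seed governs a run; per-pair and per-component sub-seeds are derived
  by fixed offsets, keeping grids deterministic yet streams independent.

## Problem sizes

The validation suite simulates at the sizes its claims need: 200 replicates
for slope recovery (Monte-Carlo SE about 4e-4), 1000 for type-I rates
(binomial SE about 0.7 percentage points at the 5% level), 100 for
robustness orderings and detection rates, with 20–100 SNPs per replicate.
These sizes keep the whole suite and the acceptance script in the
seconds-to-minutes range on a single CPU.
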