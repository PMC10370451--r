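---
title: "Methods: genotype-likelihood eQTL architecture in lceqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood eQTL architecture in lceqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lceqtl` links low-coverage whole-genome genotypes to single-mRNA and
module-level expression and to physiological traits. This vignette is the
package's own account of the models it fits, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the methodology was genuinely open.

## 1. Working on genotype likelihoods

At ~4x coverage a hard genotype call is wrong often enough to distort
downstream inference, so every quantity in the package is an expectation
over the genotype posterior. The container (`gl_set`) stores, per site and
individual, the three linear-scale likelihoods of carrying 0/1/2 copies of
the alternate allele, normalized to sum to one; an individual with no reads
carries a flat triplet and is treated as missing.

**Allele frequencies** (`estimate_allele_freq_em`) maximize
$\sum_i \log \sum_g L_i(g)\,\mathrm{HWE}(g;p)$ by EM. The E-step forms
genotype posteriors under the current Hardy–Weinberg prior; the M-step sets
$p$ to half the mean expected dosage. The update is a textbook EM, so the
marginal likelihood is non-decreasing — asserted per-iteration in the test
suite via the `trace` argument. EM starts at $p = 0.25$; the 1-D likelihood
is well behaved and the start point is immaterial, so no multi-start is
used. Convergence is $|\Delta p| < 10^{-6}$ (default) within 200
iterations. Missing individuals contribute a constant factor to the
likelihood: they are retained (keeping indexing simple and matching GL-tool
conventions) and the fixed point equals the estimate over informative
individuals only; `n_eff` reports the informative count. With fully certain
likelihoods the estimate equals the allele-count frequency exactly.

**Genotype posteriors and dosages** (`genotype_posteriors`) combine the
likelihoods with the HWE prior at the estimated frequency; the expected
dosage $d_i = P(g{=}1) + 2P(g{=}2) \in [0,2]$ is the genotype summary used
in association. A degenerate prior ($p = 0$ or $1$) returns the prior
itself when the likelihood has no overlapping support.

**Expected heterozygosity** is $H_e = 2p(1-p)$, computed from the EM
frequency by default. A hard-call alternative is available simply by
passing count-based frequencies; the two agree in the certainty limit.

## 2. Association: a dosage score test

For phenotype $y$ and covariates $X$ (always including an intercept), the
null model $y = X\gamma + \varepsilon$ is fit by least squares; with
residuals $r$, $\hat\sigma^2 = \mathrm{RSS}/n$, and the dosage vector
residualized against the covariate space ($\tilde d$):

$$U = \tilde d^\top r/\hat\sigma^2,\qquad
  V = \tilde d^\top \tilde d/\hat\sigma^2,\qquad
  T = U^2/V \sim \chi^2_1 .$$

With certain genotypes this is exactly the classical score statistic for
adding the genotype to the null regression (verified against an independent
projection-matrix oracle to $10^{-8}$ relative error). With uncertain
genotypes the expected dosage replaces the latent genotype; the
latent-genotype variance correction used by ANGSD's score machinery is
approximated by this dosage form. The two coincide at high depth, and
rather than assuming the approximation is harmless at 4x we verify
calibration empirically: under the generator's null at depth 4x, $n = 50$,
MAF 0.2 with an active temperature covariate, the empirical type-I error at
$\alpha = 0.05$ must fall in [0.035, 0.065] and the p-values must pass a KS
uniformity check (these are acceptance-grade tests in the suite). One
consequence of estimating $\hat\sigma^2$ under the null is that $T \le n$:
with ~25–35 phenotyped individuals the smallest reachable p-value is about
`pchisq(35, 1, lower = FALSE)` ≈ 3e-9, a deliberate, conservative contrast
to likelihood-ratio statistics that can run away at tiny $n$.

The p-value uses the central $\chi^2_1$ upper tail — the standard
`pchisq(T, 1, lower.tail = FALSE)` reading of a "one-sided" chi-squared
test (noncentrality zero under the null).

**Covariates.** Acclimation temperature enters every model; acclimation
order additionally enters the trait models. Temperature matters twice: the
generator lets it shift both expression factors and traits, so covariate
adjustment is testably necessary. Note that with randomized acclimation the
score test stays calibrated even when temperature is omitted (the phenotype
variance inflates but so does $\hat\sigma^2$); omission only inflates
type-I error when genotype and temperature are dependent, and the test
suite constructs exactly that confounded case.

**Testability filters** (`apply_site_filters`) reproduce the default
filters of the association tool family: expected minor-allele count
$\min(\sum d_i,\, 2n - \sum d_i) \ge 10$ (`minCount`), and at least 10
individuals with max genotype posterior $\ge 0.9$ in each of the two most
populous high-credibility genotype classes (`minHigh`). The exact `minHigh`
semantics differ across tool versions; this reading is recorded as the
package's rule and both thresholds are plain config keys
(`assoc_config()`). When both filters fail, `minCount_fail` is reported.

**Multiplicity and pruning.** BH adjustment is applied within one
phenotype's tested sites (not pooled across phenotypes), significance is
adjusted p < 0.05, and significant hits are pruned greedily by ascending
raw p so that no two retained SNPs per phenotype are within 500 bp — the
distance at which LD decays in the target system; ties on p break by
(chromosome, position) so the result is order-invariant. The greedy rule
provably keeps the most significant SNP of every 500-bp cluster; the test
suite checks it against an independent iterative oracle over all
configurations of up to 8 hits on a position grid. An optional
"sensitivity floor" restricts the significant set to raw p > 1.1102e-16,
guarding summaries against likelihood-ratio p-value underflow when
re-analyzing external results.

## 3. Module summaries

Module detection is an input, not something the package does: assignments
come from an upstream co-expression analysis. What the package computes is
what the downstream analyses actually consume:

- **Module eigengene (ME)**: columns standardized (zero-variance mRNAs
  dropped with a warning; missing values mean-imputed per mRNA with a
  logged count), first right singular vector's individual scores scaled to
  unit variance. Sign is fixed so mean correlation with member mRNAs is
  non-negative, making the ME deterministic and order-invariant.
- **Module membership (kME)**: Pearson correlation of each mRNA with its
  module's ME.
- **Top-k selection**: the k = 10 highest-kME mRNAs per module (signed
  ranking by default, absolute ranking available), ties broken by mRNA id;
  modules smaller than k return all members, flagged.

## 4. Linkage disequilibrium

`pairwise_r2_em` estimates the four two-locus haplotype frequencies by EM
over both sites' genotype likelihoods assuming random union of haplotypes,
then $D = f_{AB} - p_A p_B$ and $r^2 = D^2/(p_A q_A p_B q_B)$. EM starts at
linkage equilibrium (products of the marginal EM frequencies), tolerance
$10^{-6}$ on the frequencies, at most 500 iterations; a monomorphic site
makes $r^2$ undefined and is an error. At full genotype certainty the
estimator reduces to the classic genotype-based haplotype EM, and on phased
fixtures without double heterozygotes (where genotypes determine haplotype
counts uniquely) it reproduces direct-count $r^2$ to $10^{-6}$. `ld_decay`
bins same-sequence pairs by distance; cross-sequence pairs have no distance
and are excluded, and empty bins are reported empty rather than as zero.

## 5. Architecture analyses

- **cis/trans** is chromosome-level, exactly: same sequence ⇒ cis, however
  distal (distance to the nearest gene boundary is reported; 0 inside the
  gene), different sequence ⇒ trans. A distance-based cis definition is
  exposed via the reported distances, but the chromosome rule is the
  default because it is the one the downstream summaries assume.
  Eigengene associations are never classified — a module has no single
  location.
- **Hotspots**: a SNP associated with ≥ 2 distinct mRNAs within one
  tissue; per-SNP and per-mRNA count distributions are summarized per
  tissue because catalogs are tissue-specific.
- **Chromosome-aware trans null**: under random eQTL placement an eQTL
  with target on sequence $s$ is trans with probability
  $1 - n_s/n_{\mathrm{tot}}$ computed from the tested-site distribution;
  summed probabilities give expected cis/trans counts and a 1-df
  goodness-of-fit chi-square. Expected counts below 5 are flagged
  `low_count`; an expected count of 0 makes the test undefined rather than
  silently significant.
- **Proximity**: genic means inside any gene interval (introns and exons
  are not distinguished without subfeature annotation; all overlapping
  genes are reported, nested genes unresolved). "Within 5 kb" is inclusive
  (≤ 5000 bp to the nearest gene boundary, strand-symmetric — no TSS rule
  is imposed because none is defined for this analysis).
- **Sharing test**: the unit is the unordered pair of tested mRNAs, with a
  binary indicator of any shared eQTL SNP; Welch t-test of within- versus
  among-module pairs. The unit and the "identical SNP" notion of sharing
  are deliberate choices (a per-module-mean unit and a same-gene notion are
  available switches); degenerate indicator sets are reported as "no
  difference" rather than forced through a t-test.
- **He comparison**: Welch t-test by default with a permutation test
  (10,000 draws of |focal|-sized sets from the background) reported
  alongside, since eQTL catalogs are small and He is bounded.

## 6. What the generator emulates — and what it does not

`simulate_study()` produces, under one integer seed and R's default RNG,
a complete study: genotypes, likelihoods, expression, traits.

| parameter | default | rationale |
|---|---|---|
| `n_ind` | 172 | genotyped cohort size of the target design |
| `mean_depth` | 4.1x (Poisson) | lcWGS operating point |
| `base_error` | 0.01 | typical post-filter per-read error |
| `n_expr` | 35 | phenotyped pool; per-test n ≈ 22–35 |
| `n_pheno` | 25 | non-missing individuals per trait |
| genome | 24 chromosomes of 30 Mb + 50 scaffolds | scaffolds hold 21.6% of total length |
| `maf_range` | U(0.05, 0.5) | post-filter frequency spectrum |
| `n_sites` | 5,000 | desk-scale stand-in for ~1.4 M sites |
| modules | 10 x 30 genes | desk-scale stand-in for ~40 modules of 90–554 mRNAs |
| `loading_range` | U(0.5, 0.9) | moderate-to-strong module coherence |
| `expr_noise_sd` | 0.6 | keeps median kME ≈ 0.7–0.85, typical of reported modules |
| planted eQTL | 20 trans + 2 cis, β = 1 | mostly-trans architecture |
| `eqtl_maf_min` | 0.1 | planted sites stay identifiable under the MAF > 0.05 filter, mirroring the elevated He of detectable eQTL |
| trait model | one module factor per trait, w = 1; temperature 0.5, order 0.25, σ = 0.5 | module-dominated traits with real covariate structure |

Trans effects are planted on latent module factors, not as independent
per-gene effects: a module-factor SNP perturbs every member mRNA at once,
which is precisely the mechanism that creates hotspot eQTL and makes the
hotspot detector's target well-defined. Cis effects are per-gene dosage
terms whose target gene is placed on the SNP's sequence. Planted cis
targets additionally receive the top loading of the range and halved
residual noise: they emulate detectable cis eQTL — mRNAs that are both
strongly module-affiliated and cis-regulated — and without this their
extra cis-dosage variance pushes them just below the top-k membership
cutoff, so the generator's cis arm would never be exercised end to end.
The phenotyped pool is drawn once and shared across traits with per-trait
masks, and temperature shifts both expression factors and traits so that
covariate handling is genuinely load-bearing.

Deliberately **not** emulated: linkage between sites (sites are
independent, so LD decay carries no signal — the LD module is validated on
constructed block fixtures instead); genic enrichment of SNPs (sites land
uniformly on the layout, so almost all simulated SNPs are intergenic,
unlike the 61–80% genic fraction in real catalogs); population structure
and admixture (the target population showed none); read-level artifacts
(likelihoods come from the binomial read model, not from BAMs); and
residual correlation between heart and brain expression of shared genes —
the two tissues are independent replicate expression sets sharing only the
genotypes, covariates and pool. Passing tests therefore certify the
statistical machinery under the stated generative model, not robustness to
structure, batch effects or annotation error in real data.

## 7. Numerical choices and edge cases

- Coordinates are 1-based inclusive throughout (VCF/GFF convention); BED
  export converts to 0-based half-open at the boundary.
- Strand is parsed and carried but ignored in distance math, which is
  strand-symmetric.
- Beagle triplets are renormalized on read; write–read round trips are
  exact up to the 6-decimal float format.
- Individuals exceeding 5% missingness are flagged with a warning, never
  auto-dropped: per-test cohorts are tiny and dropping is the caller's
  decision.
- Dosages collinear with the covariates (e.g. monomorphic posteriors) make
  a site `untestable`; no p-value is fabricated. Phenotypes with fewer
  complete cases than `min_n` (default 10) or the covariate rank plus two
  are skipped with a logged reason.
- `he_comparison` with a singleton focal set reports the permutation p
  only; `sharing_test` with variance-free indicators reports means and a
  "degenerate" note.
- The two-locus EM guards zero-mass posteriors with a 1e-300 floor;
  haplotype frequencies below 1e-8 of a margin count as monomorphic.

## 8. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at sizes chosen to make each
property measurable with comfortable margins on a single CPU: 2,000 null
replicates for calibration (n = 50, 4x); 100 datasets for the
score-statistic oracle; 500 replicates of m = 1,000 p-values for FDR
control; one full pipeline run with 5,000 sites, 300 individuals at 30x,
10 modules x 30 genes and 22 planted eQTL for parameter recovery; 500
replicates for the trans-null calibration; 20 phased fixtures for the LD
oracle; 255 enumerated configurations for the pruning oracle; and 100
replicates for eigengene recovery. The analysis scripts run the
study-scaled configuration (172 individuals at 4.1x, 5,000 sites, pools of
35) with β = 4 planted effects — the very large effect sizes that a 25–35
individual cohort can detect at all, as the score cap $T \le n$ makes
explicit.

## 9. Known limitations

- The dosage score test is an approximation to full latent-genotype
  scoring; equivalence is exact only in the certainty limit, and
  calibration at 4x is established empirically, not analytically.
- The chromosome-level cis definition counts same-chromosome-but-distal
  SNPs as cis; with 24 large chromosomes this inflates cis counts only
  marginally, but analyses of fragmented assemblies should reconsider.
- The sharing test treats mRNA pairs as exchangeable; correlated pairs
  within a module mildly overstate the effective sample size, which is why
  the group means are always reported next to the p-value.
- `expected_trans_test` conditions on the observed target distribution;
  it does not model uncertainty in which mRNAs could have been targets.
- At n ≈ 25–35 the score statistic is bounded by n, so extremely small
  published p-values cannot be reproduced by this statistic; comparisons
  across studies should be made on effect direction and catalog structure,
  not raw p.
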