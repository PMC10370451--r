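# lceqtl — eQTL architecture from low-coverage whole-genome genotype likelihoods

`lceqtl` is an R package and analysis workflow for asking how much of the
variation in physiological traits is under genetic control *indirectly*,
through mRNA expression — and whether that control is cis- or trans-acting —
when the genotypes come from low-coverage whole-genome sequencing (lcWGS,
~4x) of a wild population. At such depths individual genotypes are
uncertain, so every step works on genotype likelihoods rather than hard
calls: per site and individual, the likelihood of carrying 0, 1 or 2 copies
of the alternate allele.

It is aimed at evolutionary physiologists and population geneticists who
have: a beagle genotype-likelihood file over filtered biallelic SNPs; heart-
or brain-specific expression for a (typically much smaller) subset of the
genotyped individuals, already summarized into co-expression modules; and a
handful of whole-animal or organ-level traits measured under two acclimation
temperatures.

## The statistics at the core

**Association.** For a phenotype *y* (a trait, a single mRNA's expression,
or a module eigengene) with covariate matrix *X* (intercept, acclimation
temperature, and for traits acclimation order), the null model *y = Xγ + ε*
is fit by least squares. With residuals *r*, *σ̂² = RSS/n*, and the expected
dosage *d* (posterior mean genotype under a Hardy–Weinberg prior at the
EM-estimated allele frequency) residualized against *X* to give *d̃*, the
score statistic is

    U = d̃ᵀr / σ̂²,   V = d̃ᵀd̃ / σ̂²,   T = U² / V  ~  χ²(1 df)

with the p-value from the upper tail. Sites are only tested when they pass
ANGSD-style testability filters (expected minor-allele count ≥ 10; at least
10 high-credibility individuals in each of the two most populous genotype
classes at posterior ≥ 0.9). P-values are Benjamini–Hochberg adjusted within
each phenotype, and significant hits (adjusted p < 0.05) are pruned so that
no two retained SNPs per phenotype lie within 500 bp, keeping the most
significant SNP of each cluster.

**Architecture.** Significant single-mRNA eQTL are classified cis or trans
by the chromosome-level rule (trans ⇔ SNP on a different chromosome or
scaffold than the target gene); hotspots are SNPs associated with more than
one mRNA; the observed trans proportion is tested against a chromosome-aware
null (an eQTL with target on sequence *s* is trans with probability
1 − n_sites(s)/n_total under random placement); SNPs are annotated
genic/intergenic and flagged within 5 kb of a transcription factor; module
eigengene associations (eQTL_ME) are checked for proximity to their own
module's genes; eQTL sharing is compared within versus among modules (Welch
t-test over mRNA pairs); and expected heterozygosity He = 2p(1−p) of eQTL
SNPs is compared against all tested sites (Welch t-test plus permutation).

**Supporting numerics.** Allele frequencies come from a per-site EM over the
genotype likelihoods; pairwise LD (r²) from a two-locus haplotype-frequency
EM; module eigengenes are the unit-variance first principal component of
each module's standardized expression with module membership (kME) as the
mRNA–eigengene correlation.

A fully seeded synthetic-data generator (`sim_config()`, `simulate_study()`)
emulates the whole study — HWE genotypes over 24 chromosomes plus scaffolds,
Poisson-coverage genotype likelihoods, module-structured expression with
planted cis (per-gene) and trans (latent module-factor) eQTL, and
covariate-driven traits — so the entire pipeline runs and is testable with
no data download.

## Worked example

```r
library(lceqtl)

cfg <- sim_config(
  n_ind = 120, n_expr = 120, n_pheno = 60, n_sites = 400,
  n_modules = 4, genes_per_module = 15, mean_depth = 8,
  n_trans_eqtl = 4, n_cis_eqtl = 1, eqtl_beta = 1.5,
  n_traits = 2, seed = 42
)
study <- simulate_study(cfg)
study$gl
#> gl_set: 400 sites x 120 individuals (0.0% missing triplets)

filtered <- filter_sites(study$gl)
suite <- run_association_suite(filtered$gl, study$pheno, study$es)
suite
#> assoc_suite: 46 phenotype(s), 398 sites, 50 significant, 50 pruned-independent

eqtl <- subset(suite$pruned, class == "single_mRNA")
eqtl$target <- eqtl$phenotype
classified <- classify_cis_trans(eqtl, study$es$genes)
table(classified$classification)
#>   cis trans
#>     1    43

hot <- find_hotspots(data.frame(id = eqtl$id, target = eqtl$target))
hot$summary[, c("n_assoc", "n_snp", "n_hotspot", "mrna_per_snp_max")]
#>   n_assoc n_snp n_hotspot mrna_per_snp_max
#> 1      44     7         5               10

he <- he_comparison(
  suite$freq$he[suite$freq$id %in% eqtl$id], suite$freq$he,
  n_perm = 1000, seed = 1
)
round(c(he_eqtl = he$mean_focal, he_all = he$mean_background, perm_p = he$perm_p), 3)
#> he_eqtl  he_all  perm_p
#>   0.397   0.367   0.513
```

Reading the output: of the 46 phenotypes (2 traits, 40 top-membership
mRNAs, 4 module eigengenes), 50 site–phenotype associations survive BH
correction and 500-bp pruning. The 44 single-mRNA associations involve only
7 distinct SNPs, 5 of which are hotspots — one SNP reaches all 10 tested
mRNAs of its module, the signature of a trans-acting module-factor eQTL —
and 43 of 44 are trans by the chromosome rule, recovering the planted
architecture (4 module-factor eQTL + 1 cis eQTL). The heterozygosity of
eQTL SNPs (0.397) sits above the background mean (0.367), though with only
7 SNPs the permutation test is, as expected, far from significant.

## The analysis workflow

The `analysis/` scripts run a desk-scale version of the full study end to
end, writing tables under `results/` and regenerable data under `scratch/`:

1. `analysis/01_simulate.R` — synthetic study: 172 individuals at 4.1x,
   5,000 SNPs, heart + brain expression (10 modules x 30 genes each) for a
   shared pool of 35 individuals, six traits observed for 25 each.
2. `analysis/02_genotype_qc.R` — EM allele frequencies, site filters,
   heterozygosity summary, background LD.
3. `analysis/03_association.R` — eigengenes, top-10 mRNA selection, the
   score-test association suite, BH correction and pruning, per tissue.
4. `analysis/04_architecture.R` — cis/trans classification, hotspots,
   chromosome-aware trans test, proximity annotation, eQTL_ME module
   overlap, sharing test, He comparison, and cross-catalog overlap sets.

Run them in order with `Rscript analysis/01_simulate.R` etc.

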