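# bovfat

Genomic analysis of visceral fat accumulation and metabolic health in dairy
cattle.

Visceral (omental) fat is metabolically active tissue linked to insulin
sensitivity, lipid mobilization and disease susceptibility in dairy cows,
yet its genetic basis is hard to study: the phenotype is measured as an
extreme-group binary score (low/high fat deposition), sample sizes are
small, and part of the gene action is non-additive. `bovfat` provides the
full analysis chain used in this setting, together with a synthetic-data
generator that reproduces the statistical structure of such studies so
every method can be exercised and validated without access to commercial
genotype or herd data.

## What the package computes

**Two-step mixed-model genome scan.** A polygenic null model

  y = Xb + u + e,  u ~ N(0, G σ²ᵤ),  e ~ N(0, I σ²ₑ)

is fitted once by REML (eigen-decomposition of the VanRaden method-1
genomic relationship matrix G, one-dimensional profile over σ²ᵤ/σ²ₑ). Each
SNP is then tested at the fixed null covariance V₀ = G σ²ᵤ + I σ²ₑ with the
score/Wald statistic

  z = x′V₀⁻¹(y − Xb̂) / √(x′Px),  P = V₀⁻¹ − V₀⁻¹X(X′V₀⁻¹X)⁻¹X′V₀⁻¹,

where the coded column x targets a chosen gene action: additive (0, 1, 2),
dominance (0, 1, 1), recessive (0, 0, 1) or overdominance (0, 1, 0).
Genomic-inflation diagnostics (λ, Q-Q tables, Manhattan plots) are built
in.

**Gene-set overrepresentation.** SNPs map to genes within a 10 kb flank;
genes with at least one additive-scan p ≤ 0.01 are flagged; each gene set
is tested with the one-sided cumulative hypergeometric (Fisher's exact)
probability P(X ≥ k) against the universe of genes with at least one
scanned SNP. GFF3/BED annotations and GMT gene sets are supported.

**Single-step genomic threshold model.** Repeated binary health records
(e.g. displaced abomasum at 1.8 % incidence, ketosis at 10.4 %) are
analyzed on the liability scale

  l = Xβ + Z₁·hys + Z₂·u + W·pe + e,  e ~ N(0, I),  outcome = 1(l > 0),

with lactation classes (1–5+) as fixed effects, herd-year-season and
permanent-environment effects, and u ~ N(0, H σ²ᵤ) where H⁻¹ merges the
pedigree A-inverse with a blended, tuned genomic block (single-step GBLUP).
Fitting is Bayesian Gibbs sampling with latent-liability augmentation and
an interweaving step that keeps the variance components mixing. SNP
effects are back-solved from genomic breeding values via
ŝ = DM′[MDM′]⁻¹âg and summarized as the percentage of additive genetic
variance explained by disjoint 2.0 Mb windows.

**Synthetic data.** `simulate_genotypes()`, `simulate_pedigree()`,
`simulate_binary_trait()` and `simulate_health_records()` generate
genotypes in Hardy–Weinberg equilibrium with a marker map, multi-generation
pedigrees, extreme-group phenotypes driven by liability QTL of any of the
four gene actions, and repeated low-incidence binary records with
herd-year-season, additive (pedigree-correlated) and permanent-environment
variance components.

## Worked example

Simulate an extreme-group study with one purely recessive liability QTL,
fit the null model, and scan with both additive and recessive codings:

```r
library(bovfat)

cfg <- sim_config(400, 5000, n_chromosomes = 5, maf_range = c(0.1, 0.5),
                  qtl = data.frame(snp = 2500, mode = "recessive",
                                   effect = 1.5),
                  h2_liability = 0.4, prevalence_or_split = 0.5, seed = 11)
geno  <- simulate_genotypes(cfg)
trait <- simulate_binary_trait(geno, cfg)

null <- fit_null_model(trait$phenotype$score, compute_G(geno))
print(null)
#> Polygenic null model (REML)
#>   n = 400, sigma_u^2 = 0.0949, sigma_e^2 = 0.1526, h2 = 0.383

scan <- scan_snps(null, geno, modes = c("additive", "recessive"))
print(scan, n = 4)
#> scan_result: 5000 SNPs x 2 coding(s)
#>   genomic inflation lambda: additive = 0.992, recessive = 1.016
#>   top associations:
#>    snp_id chrom      pos    coding   beta     z        p skipped
#>  snp02500  chr3 47408109 recessive  0.398  5.09 3.55e-07   FALSE
#>  snp02500  chr3 47408109  additive  0.152  4.05 5.02e-05   FALSE
#>  snp03781  chr4 76120570  additive -0.148 -3.70 2.17e-04   FALSE
#>  snp00079  chr1  7740022  additive -0.150 -3.51 4.44e-04   FALSE
```

The planted QTL (`snp02500`) tops the scan, and the recessive coding —
which matches the simulated gene action — outperforms the additive one by
two orders of magnitude in p-value, with λ near 1 for both codings. The
null model attributes ~38 % of the score variance to the genomic
relationship structure, close to the simulated 40 % liability
heritability.

A threshold-model run on simulated health records (2,000 cows, up to 3
lactations, 10 % incidence, true variances hys 0.1 / u 0.2 / pe 0.1):

```r
ped <- simulate_pedigree(1400, n_generations = 2, offspring_per_mating = 3,
                         seed = 3)
cfg <- health_sim_config(n_cows = 2000, max_lactation = 3,
                         n_herd_year_seasons = 50, var_hys = 0.1,
                         var_additive = 0.2, var_pe = 0.1,
                         incidence_target = 0.1, seed = 3)
sim <- simulate_health_records(ped, cfg)
fit <- fit_threshold_model(sim$records, compute_A_inverse(ped),
                           n_iter = 6000, burn_in = 1500, thin = 3, seed = 1)
print(fit)
#> Single-step threshold model (Gibbs), 4008 records, 6701 animals, 1500 posterior samples
#>
#> Variance components (residual liability variance fixed at 1):
#>   component   mean    sd lower_95 upper_95   ess
#>  sigma2_hys 0.0778 0.024   0.0415    0.138 271.1
#>    sigma2_u 0.1022 0.051   0.0336    0.227  58.5
#>   sigma2_pe 0.1381 0.071   0.0429    0.295  38.4
#>
#> Liability-scale h2: posterior mean 0.077 [0.026, 0.161]
```

All three 95 % posterior intervals cover the simulated truth; at 10 %
incidence and ~2 records per cow the posteriors are wide, which is the
honest information content of binary records on this scale.

See `vignettes/methods.Rmd` for the models, priors, numerical choices and
their rationale.

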