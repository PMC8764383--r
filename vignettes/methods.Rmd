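---
title: "Models and methods in bovfat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bovfat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovfat)
```

`bovfat` implements the computational machinery of a genomic dissection of a
binary trait in dairy cattle along two complementary tracks: a two-step
mixed-model genome scan for additive and non-additive SNP effects on an
extreme-group phenotype (low/high visceral-fat score), and a single-step
genomic threshold model for repeated binary health records (e.g. displaced
abomasum, ketosis) with SNP-effect back-solution and windowed variance
decomposition. A synthetic-data generator reproduces the statistical
structure both models assume, so every stage is testable without access to
commercial chip or herd data. This vignette explains the models, the
numerical choices and their rationale, and what the simulation-based tests
do and do not establish.

## The two-step mixed-model scan

**Step 1 (null model).** The 0/1 phenotype is analyzed on the observed scale
with the linear mixed model

$$y = Xb + u + e, \qquad u \sim N(0,\, G\sigma_u^2), \quad e \sim N(0,\, I\sigma_e^2),$$

where $G$ is the VanRaden method-1 genomic relationship matrix computed from
observed allele frequencies, $G = Z_cZ_c'/k$ with $k = 2\sum_j p_j(1-p_j)$.
Because there is a single random effect, the restricted likelihood can be
profiled on the eigenbasis of $G$ down to a one-dimensional search over the
variance ratio $\delta = \sigma_u^2/\sigma_e^2$. `fit_null_model()` bounds
$\delta \in [10^{-6}, 10^6]$ and maximizes by golden-section search on
$\log\delta$ (tolerance $10^{-8}$); the GLS fixed effects, the null
covariance $V_0 = G\sigma_u^2 + I\sigma_e^2$, its inverse and the residuals
are stored. Fixed effects default to an intercept only — extreme-group designs match
animals on body condition precisely so that no further covariates are
needed — but any design matrix is accepted.

**Step 2 (per-SNP tests).** Each SNP's dosage vector is recoded for one of
four gene-action models — additive $(0,1,2)$, dominance $(0,1,1)$, recessive
$(0,0,1)$, overdominance $(0,1,0)$ — and tested with the score statistic at
fixed $V_0$:

$$z = \frac{x'V_0^{-1}(y - X\hat b)}{\sqrt{x'Px}}, \qquad
P = V_0^{-1} - V_0^{-1}X(X'V_0^{-1}X)^{-1}X'V_0^{-1}.$$

Two numerical points deserve comment. First, the statistic is reported as a
ratio over the *square root* of the information, which is the form that is
asymptotically standard normal; the plain ratio $s/i$ is the effect estimate
$\hat\beta_{SNP}$, not a test statistic. Second, the information uses the
projected form $x'Px$ rather than $x'V_0^{-1}x$: coded genotype columns have
non-zero means, and ignoring the fixed-effect projection deflates $z$
substantially (a test against an intercept-only model would otherwise be
conservative by a factor related to the allele frequency). With $x'Px$ in
the denominator the two-step $z$ coincides exactly with the Wald $z$ of the
SNP coefficient in a GLS fit of $y \sim X + x$ at fixed $V_0$, which the
test suite verifies to $10^{-8}$ against an independently coded dense
solver. The residual covariance of the second-step model is $V_0$ itself
(the variant form $V_0\sigma_e^2$ sometimes written for this model would
count $\sigma_e^2$ twice, since $V_0$ already contains it).

Coded columns that are constant across individuals (e.g. a recessive coding
with no homozygous carriers) carry no information; they are flagged and
skipped rather than raised as errors. Two-sided p-values come from the
standard normal; no multiple-testing correction is applied inside the scan.
`genomic_inflation()` reports $\lambda = \mathrm{median}(z^2)/0.4549$ and a
Q-Q table with expected quantiles $r/(n+1)$.

Calibration at realistic sizes is good but not metrologically exact: at
$n = 300$ the scan shows the familiar GRAMMAR-type behaviour in which the
polygenic fit slightly absorbs individual SNP effects ($\lambda$ a few
percent below 1), while score statistics on discrete genotypes carry a small
$O(1/n)$ excess variance in artificial corners such as $G = I$ with a
balanced binary phenotype. The calibration tests therefore check the
replicate-averaged rejection rate against the binomial interval of a single
2,000-SNP scan and $\bar\lambda \in [0.9, 1.1]$, which is the precision the
method itself supports at these sample sizes.

## Gene-set overrepresentation

SNPs are assigned to annotated genes when they fall within the gene body or
at most 10 kb up- or downstream (1-based inclusive coordinates; interval
overlap is delegated to `IRanges`). A gene is *significant* when at least
one assigned SNP has an additive-scan p-value at or below 0.01. For each
gene set, `fisher_enrichment()` computes the one-sided cumulative
hypergeometric probability $P(X \ge k)$ of observing $k$ significant genes
among the set's $K$ analyzed genes, given $n$ significant genes in an
analyzed universe of $N$.

Two genuinely open conventions are resolved as follows and exposed as
configuration: the universe is restricted to genes with at least
one assigned SNP (genes without markers are untestable and would dilute
$N$), and no cross-set multiple-testing correction is applied by default
(a Benjamini–Hochberg option exists). Annotations are read from GFF3 (gene
features, via `rtracklayer`) or 4-column BED-like tables; gene sets from
GMT.

## Relationship matrices

`compute_A()` builds the numerator relationship matrix by the tabular
method; `compute_A_inverse()` assembles the sparse inverse directly from
Henderson's rules with Meuwissen–Luo inbreeding coefficients, so it is
exact for inbred pedigrees. `compute_H_inverse()` forms the single-step
inverse

$$H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1} \end{pmatrix},
\qquad G^* = (1-w)\,G_{tuned} + w\,A_{22},$$

with default blend weight $w = 0.05$ and tuning that linearly rescales $G$
so its mean diagonal and mean off-diagonal match $A_{22}$. These constants
are the single-step literature's defaults and are exposed as explicit
arguments. Dense linear algebra is used
throughout `compute_H_inverse()` — the intended scale (up to ~10k animals)
does not require sparse approximations — while the pedigree-only path stays
sparse end to end.

## The single-step threshold model

Repeated binary records are modeled through a latent liability

$$l = X\beta + Z_1\,hys + Z_2\,u + W\,pe + e, \qquad e \sim N(0, I),$$

with outcome 1 when $l > 0$; fixed effects are the lactation classes
(1, 2, 3, 4, 5+; cell-means coding, so no separate intercept is needed and
the design stays full rank), $hys$ is the herd-year-season contemporary
group, $u$ the additive genetic effect with covariance $H\sigma_u^2$, and
$pe$ the cow's permanent environment. The residual liability variance is
fixed at 1 for identifiability (probit scale).

Estimation is by Gibbs sampling with latent-liability augmentation:
truncated-normal draws for $l$ (inverse-CDF forms written to stay accurate
far in the tail, as needed at 1–2 % incidence), normal full conditionals
for all location effects, and scaled-inverse-chi-square full conditionals
($\nu = 4$, scales from user-supplied values) for the three variances. The
animal effects are updated single-site so that only $H^{-1}$ is ever
required — the single-step inverse is sparse except for the genotyped
block, and no $H$ is ever formed.

Single-site samplers for binary data are notoriously slow-mixing in the
joint direction of an effect vector and its variance. The sampler therefore
adds an ancillarity–sufficiency interweaving step for $(u, \sigma_u^2)$ and
$(pe, \sigma_{pe}^2)$: in the whitened parameterization $u = \sigma_u \tilde
u$, the conditional of $\sigma_u$ given $\tilde u$ and the liabilities is a
Gaussian likelihood times the variance prior, and an independence proposal
from the Gaussian part is accepted with just the prior ratio. This joint
rescaling move raises the effective sample size of the variance components
by roughly an order of magnitude and makes chains from dispersed starting
values agree; the default chain (20,000 iterations, 5,000 burn-in, thinning
10) is conservative, and the simulation tests use 14,000 iterations with a
quarter burn-in, which gives the variance components effective sample sizes
near 100 at 5,000 cows. Before fitting, pedigrees are pruned to the
phenotyped animals and their ancestors (`prune_pedigree()`), which leaves
every relationship among them unchanged while shrinking the equations. Truncated-normal draws use simple rejection in the body of the
distribution and Robert's shifted-exponential rejection in the tail — exact
and fast even at 1–2 % incidence. Chains are bitwise reproducible under a
fixed seed because all draws use R's RNG.

## Back-solution and window variance

Marker effects are recovered from the genomic breeding values of the
genotyped animals as $\hat s = DM'[MDM']^{-1}\hat a_g$ with $M$ the dosage
matrix centered by twice the observed allele frequency (the same centering
as $G$) and $D = I$ by default. Because column-centering makes $1'M = 0$,
$MDM'$ is always rank-deficient by one: only deviations of $\hat a_g$ from
their mean are identifiable. The implementation mean-centers $\hat a_g$ and
solves with a symmetric pseudo-inverse (relative eigenvalue tolerance
$10^{-10}$), which reproduces the centered $\hat a_g$ exactly through
$M\hat s$; a ridge fallback is available.

`window_variance()` tiles each chromosome with disjoint half-open 2.0 Mb
windows anchored at position 1 (a sliding mode exists but is off by
default, since "windows of adjacent SNPs" does not by itself imply
overlap), computes the window-restricted genomic value $u_i = \sum_{j \in i}
M_js_j$ across animals, and reports its empirical variance as a percentage
of two denominators: the empirical variance of $M\hat s$ (so that a single
window containing every SNP gives exactly 100 %) and, when supplied, the
additive genetic variance $\sigma_u^2$ (the conventional reporting scale). Window sums
partition $M\hat s$ exactly; the sum of window *variances* is not asserted
to match the total, because cross-window covariance is nonzero under
linkage.

## The synthetic-data generator

The generator's defaults encode the study conditions the models assume:

* **Genotypes** — biallelic dosages in Hardy–Weinberg and linkage
  equilibrium, allele frequencies uniform on a configurable interval
  (default 0.05–0.5). Linkage equilibrium is the default because nothing in
  either analysis depends on a specific LD model; a copy-with-mutation
  block mode exists for window experiments.
* **Extreme-group phenotype** — liability = QTL effects (each injected
  through its gene-action coding, on the liability scale, so the generator
  is consistent with both the scan and the probit health model) + polygenic
  term + normal residual, with the genetic share scaled to `h2_liability`
  and the threshold at the standard-normal quantile of the case proportion.
* **Pedigree** — discrete generations, random sire assignment, topological
  order by construction. Breeding values are gene-dropped with
  Mendelian-sampling variances adjusted for parental inbreeding, which
  reproduces the $A$-covariance exactly.
* **Health records** — one record per cow-lactation (1 up to
  `max_lactation`), herd-year-season groups assigned per record, intercept
  set to $\Phi^{-1}(\text{incidence})\sqrt{1 + \sigma^2_{hys} + \sigma^2_u +
  \sigma^2_{pe}}$ so the expected incidence matches the target. Lactation
  fixed effects default to zero so that the all-variances-zero
  configuration is exactly i.i.d. Bernoulli.

Simulation scales used by the tests (50 null scans of 2,000 SNPs at
$n=300$; 200 recessive-power replicates at $n=400$; 20 threshold fits at
5,000 cows and 10 % incidence) were chosen to give stable Monte-Carlo
estimates of each property at desk scale; the acceptance script runs
reduced replicate counts of the same experiments.

What passing these tests shows — and does not show. The generator matches
the models' assumptions by construction, so the tests establish internal
correctness (estimators recover the parameters that generated the data,
oracles agree, calibration holds). They cannot establish robustness to the
features of real cattle data the generator omits: linkage disequilibrium
and chip ascertainment, selection and non-random mating, herd-recording
artifacts, or genotype-environment correlation.

## Known limitations

* The scan analyzes the 0/1 score with a linear model, as in the original
  design; it is a test of association, not a liability-scale effect
  estimator, and no logistic/GLMM alternative is provided.
* `compute_H_inverse()` is dense; very large genotyped sets (≫10k) would
  need APY-type approximations that are out of scope.
* The threshold model's variance posteriors at low incidence are diffuse
  and prior-sensitive; this is a property of binary data, not of the
  sampler, and is visible in the width of the reported 95 % intervals.
* SNP weights $D$ other than identity are accepted but no iterative
  reweighting scheme is provided.
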