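---
title: "Bayesian animal models for boldness and survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian animal models for boldness and survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`boldqg` analyses repeated boldness assays (emergence tests: latency in
seconds to leave a dark refuge, right-censored at 300 s, low values = bold)
collected on a pedigreed captive population across four age classes, together
with a binary record of survival to the final test. The questions it is
built to answer are quantitative-genetic: how much of the variation in
boldness is additive genetic ($V_A$), maternal ($V_M$), stable
among-individual ($V_{ID}$), or residual ($V_R$); whether those
contributions change with age or differ between sexes (G×A, G×S); whether
the trait is repeatable over short and long time scales; whether boldness
and survival covary at the phenotypic and genetic level; and whether the
population-level decline of boldness with age is driven by within-individual
change (plasticity) or by selective disappearance of bolder individuals.

# The model family

All analyses are multi-response linear mixed models fitted by Gibbs
sampling. The core is the *animal model*: an individual-level random effect
$a$ whose covariance across individuals is $\sigma^2_A A$, where $A$ is the
additive genetic relationship matrix implied by the pedigree
($A_{ii} = 1 + F_i$; parent-offspring 0.5, paternal half-sibs 0.25 in the
absence of inbreeding). The sampler never forms $A$; it uses the sparse
$A^{-1}$ assembled directly from parent links with inbreeding corrections
(Henderson's rules, with $F$ from the Meuwissen-Luo ancestor recursion).

Age-varying genetics are handled with the character-state approach: the
trait at each age class is treated as a separate trait, and each random
term (among-individual identity, animal, maternal identity) carries an
unstructured 4×4 covariance matrix across age classes. Residuals are
heterogeneous by age with cross-age covariances fixed at zero, because no
two trials are simultaneous. Cross-age genetic correlations
$r_A(j,j') = \mathrm{cov}_A(j,j')/\sqrt{V_{A,j} V_{A,j'}}$ near 1 mean the
genotype ranking is stable across life; values clearly below 1, or unequal
$V_A$ across ages, indicate G×A.

Three response families are supported:

* **gaussian** - standardized emergence scores;
* **censored gaussian** - records flagged at the 300-s bound are treated as
  right-censored: the latent value is re-imputed each iteration from the
  normal full conditional truncated to $[\text{bound}, \infty)$ on the
  standardized scale, with the bound mapped as $(300 - \bar{y})/s_y$ using
  the scaling constants recorded at load time;
* **binary probit** - survival is a latent Gaussian liability crossing zero;
  the liability is imputed from a truncated normal each iteration and the
  binary residual variance is fixed at 1 for identification.

The bivariate boldness-survival model pairs one Gaussian record (the mean
of the two first-age trials, standardized) with one binary record per
individual. Its residual is an unstructured 2×2 matrix whose binary diagonal
element is fixed at 1; the Gaussian variance and the residual covariance are
sampled through a conditional-regression parameterisation (regress the
Gaussian residual on the liability residual: the slope is the covariance,
slope² plus the conditional variance is the Gaussian variance), which
respects the fixed element exactly. The phenotypic correlation and the
regression of boldness on survival are then assembled per draw from the
summed additive and residual (co)variances.

# The Gibbs sampler

One iteration updates, in order: (1) censored values and liabilities from
truncated-normal full conditionals; (2) all location effects (fixed effects
and every random-effect level) as a single joint block from their
multivariate-normal full conditional - the mixed-model equations
$C = W'R^{-1}W + \bigoplus_k G_k^{-1} \otimes K_k^{-1}$ are assembled on a
fixed sparsity pattern and factored by a left-looking sparse Cholesky, and
the draw is $\theta = C^{-1}W'R^{-1}y^\ast + L^{-\top}z$; (3) optionally a
redundant working-scale multiplier per trait of each flagged random term
(parameter expansion, below); (4) each covariance block from its
inverse-Wishart full conditional $\mathrm{IW}(\nu_0 + q,\; \nu_0 V_0 + U'K^{-1}U)$;
(5) residual variances from scaled inverse-chi-squared conditionals (or the
constrained 2×2 update above). The symbolic analysis - fill-reducing
permutation and factor pattern - is done once per model with
`Matrix::Cholesky()`; the numeric factorization runs in compiled code every
iteration. All randomness flows through R's RNG, so a seed makes a run
exactly reproducible and lengthening `nitt` prefix-extends the chain.

## Priors

Each covariance block has an inverse-Wishart prior with scale $\nu V$ and
degrees of freedom $\nu$; the defaults are $V = I$, $\nu = 0.002$ for every
block and for residual variances. The package deliberately defaults to the
weak end of the usual $\nu$ range because the prior scale matrix is
diagonal: with $\nu$ of order $d$, the $\nu V$ term visibly shrinks
covariance-block correlations toward zero (on a toy dataset with a true
correlation of 1 and 300 individuals, the posterior median drops from 0.98
under $\nu = 0.002$ to 0.83 under $\nu = 1.002$). Robustness to the prior
should be checked by refitting with a modified `prior` argument.

## Parameter expansion

Variance components that are small relative to their uncertainty (here:
maternal variances, and the additive-vs-identity split) mix poorly under
the plain Gibbs scheme - the chain sticks near zero. The engine therefore
implements parameter expansion: for a flagged term, a redundant multiplier
$\alpha_a$ per trait is drawn each iteration from its Gaussian full
conditional (a generalized-least-squares regression of the current
residuals on the term's effects, prior $\alpha \sim N(0, 1000)$) and the
block's effects and covariance are rescaled by it. The induced prior on
each standard deviation is half-t-like. The engine default is off; every
model-suite constructor switches it on, which is the package's resolution
of the open choice for weakly identified maternal components - without it,
desk-scale chains (tens of thousands of iterations) leave effective sample
sizes in the tens for the animal and identity blocks and visibly
misattribute family variance.

## Chain settings

Defaults are `nitt = 50000`, `burnin = 5000`, `thin = 10` (4,500 stored
draws). These are desk-scale settings chosen so a full age-specific animal
model on ~400 individuals per sex fits in about three minutes; production
analyses of the kind the models are designed for are usually run one to two
orders of magnitude longer, which the engine supports unchanged. The
convergence report (`check_convergence()`) compares the effective sample
size of every stored parameter (initial-positive-sequence truncated
autocorrelation sum) with a user floor; desk-scale chains typically leave
the weakest covariance elements with ESS in the tens-to-hundreds, so
summaries of single elements should be read with that in mind.

# Derived statistics

Every ratio is computed per draw and then summarized (never a ratio of
summaries), so posterior uncertainty propagates exactly:

* $h^2_j = V_{A,j} / (V_{A,j} + V_{M,j} + V_{ID,j} + V_{R,j})$ and $m^2_j$
  analogously, per age class $j$;
* repeatabilities: age-specific $R_j = V_{ID,j}/(V_{ID,j}+V_{R,j})$ (model
  2a); cross-age $R_j = (V_{ID}+V_{ID,j})/(V_{ID}+V_{ID,j}+V_{R,j})$ and
  long-term $R = V_{ID}/(V_{ID}+\overline{V_{ID,j}}+\overline{V_{R,j}})$
  (model 2b). The exact functional forms over the two individual-effect
  blocks are a package decision (a variance-partitioning reading of the
  short- vs long-term distinction);
* survival heritability on the liability scale:
  $h^2 = V_{A,s}/(V_{A,s}+1)$ - the denominator is additive plus the fixed
  probit residual, with no extra link-variance term, because the fixed unit
  residual is the only residual in the threshold model (the alternative
  convention adds another 1; switching is a one-line change in
  `survival_assoc`);
* genotype-by-sex and genotype-by-age tests as paired-draw differences of
  $V_A$ (between sexes at each age, or between ages within sex), with the
  HPD interval of the difference as the criterion;
* pairwise age contrasts of the fixed age-class means with Holm-Bonferroni
  step-down adjustment (via `stats::p.adjust`) over the six pairs;
* selective disappearance from the within-subject centred model 3c: the
  between-individual age slope ($\beta_{AgeM}$), the within-individual
  slope ($\beta_{AgeWH}$, plasticity), and their contrast
  $\beta_{AgeM}-\beta_{AgeWH}$, whose pMCMC is the disappearance test. Both
  the contrast and $\beta_{AgeM}$ alone are reported, the two standard
  readings of within-subject centering.

Summaries are the posterior median, the kernel-density mode (Silverman
bandwidth, 512-point grid), the 95% highest posterior density interval
(shortest contiguous window of the sorted draws, ties broken at the lowest
start), and for signed quantities pMCMC
$= \min(1,\, 2\max(1/N,\, \min(N_{>0}, N_{<0})/N))$ - floored at $2/N$ so it
is never exactly zero.

# The synthetic-data generator

The simulator reproduces the study design: 50 parental sires × 2 dams each
(one brood per dam), F1 crossed as 16 males × 32 females in trios whose
three members come from three different F1 families, brood sizes truncated
Poisson (mean 4, minimum 1). Additive values are gene-dropped through the
pedigree (founders from $N(0, G)$; offspring = midparent + Mendelian
deviation with variance $\tfrac12(1 - (F_s+F_d)/2)G$), jointly for the four
age-class boldness values and the survival liability; the liability's
additive part is tied to the age-1 boldness value by a regression
construction so any PSD $G_A$ stays valid. Maternal effects are one draw
per dam per age class shared by her brood, which deliberately conflates
maternal identity with early common environment, as in the study housing.
The trial schedule is 2 standard trials at age 1, three trials in
randomized contexts (standard / with female / with object) at ages 2 and 3,
and 2 standard trials at age 4. Latent values map to seconds by
`raw_seconds = 150 + 60 * latent`, floored at 1 s and right-censored at
300 s. Survival is `intercept + additive liability + N(0,1) > 0` with the
intercept 0.54 chosen so about 67% survive; non-survivors get a death
interval with probabilities proportional to the observed attrition
(23:56:54), and their later records are removed.

Default generating values (the conditions under which all recovery tests
run): $G_A = 0.3\,\mathbf{1}\mathbf{1}'$ (additive variance 0.3 at every
age, rank one, so all cross-age genetic correlations are exactly 1);
$G_M$ zero except 0.1 at age 2, expressed in daughters only; $G_{ID} =
0.2 I$; residuals 0.5 (0.4 for females at age 2) so the latent phenotypic
variance is 1 at every age in both sexes, giving $h^2 = 0.3$ and a female
age-2 $m^2$ of 0.1. Males are 0.4 SD bolder; emergence time rises by 0.5 SD
after age 1; a positive additive covariance between emergence time and the
survival liability (genetic correlation 0.4) reproduces the
bolder-genotypes-die-younger pattern on the recorded scale. Sample-size
conventions used in the package's own experiments: the shipped default
design (~540 phenotyped individuals) for fast checks, and the same design
with brood mean 6 (~800 phenotyped) for the headline recovery experiments,
which is the scale at which per-age heritability medians become reliable
to about ±0.1.

The `fixture_study()` dataset reduces a simulated study to the real study's
marginal counts - 399 individuals scored at age 1 (210 females, 189 males),
376, 320 and 266 at ages 2-4 - by subsampling scored individuals and
reassigning death intervals to the lowest-liability individuals first,
preserving the survival-boldness link. It is synthetic: only those margins,
not any fitted estimate, are matched to the real data.

What the simulator does **not** emulate: growth and feeding dynamics, mate
choice, predation, continuous-time mortality (deaths only occur between
test sessions), observer effects, and any non-Gaussian trait architecture.
Passing recovery tests therefore demonstrates that the estimators work when
the generating process matches the model family; they cannot certify
behaviour under real-data misspecification.

# Numerical choices and degenerate inputs

* Fixed effects get an improper flat prior; a ridge of 1e-8 on their
  diagonal guards the factorization (with full-rank designs its effect is
  far below Monte-Carlo noise). Aliased fixed-effect columns are dropped
  with a warning.
* A non-positive pivot in the sparse factor is floored at 1e-10 and a
  non-PSD inverse-Wishart scale is jittered on its diagonal; both events
  are counted and reported on the fit object (`njitter`).
* Truncated normals are drawn by the log-space inverse-CDF method, stable
  arbitrarily deep into the tail.
* Residual classes consisting entirely of censored records are flagged with
  a warning (weakly identified, not fatal); a residual class made of binary
  records has its variance fixed at 1; age classes with no data for a sex
  contribute prior-only draws.
* The stored draw count is exactly `floor((nitt - burnin)/thin)`; draws of
  every covariance block are symmetric PSD by construction.
* `hpd()` ties are broken at the lowest window start; `pmode()` of a
  constant vector returns that constant; `effective_size()` of a constant
  vector is 0 with a degeneracy attribute.

# Interfaces and reproducibility

Data enter as two UTF-8 CSVs (pedigree: `id,sire,dam,sex,generation`, empty
string = unknown parent; phenotypes: one row per trial with censoring flag,
body size and the survival indicator). `load_study()` validates both,
standardizes the scores over all records before any subsetting (so
male and female models share one scale, a prerequisite for comparing $V_A$
across sexes), and derives the model columns. `run_pipeline()` drives
simulate/load - fit - summarize from a named list or a plain-text
`key = value` config (unknown keys are errors) and writes draws, summaries,
a log and a digest manifest; identical configs reproduce identical digests.
The package's interface is its functions - the pipeline entry point is
`run_pipeline()` rather than a shell executable.

# Known limitations

Single-chain inference (between-chain diagnostics are out of scope; the
seed argument makes independent replicate chains trivial to run). The
censored-Gaussian family treats the 1-s floor as exact observation - left
censoring is not modelled. The bivariate residual update supports exactly
one Gaussian plus one binary trait. Posterior medians of weakly identified
variance ratios (notably maternal effects with ~100 dams) remain
prior-sensitive at this design size, and per-age heritability medians at
the ~800-individual scale carry sampling noise of roughly ±0.1; both are
properties of the design, not of the sampler.
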