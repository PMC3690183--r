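---
title: "Estimating genetic correlations from SNPs and from twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic correlations from SNPs and from twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pleiokit estimates the genetic correlation between two quantitative traits in
two independent ways — from genome-wide SNP similarity among conventionally
unrelated individuals (bivariate GREML) and from the classical MZ/DZ twin
contrast (bivariate Cholesky ACE) — and provides the simulation and
preprocessing machinery to exercise both end to end against known ground
truth. This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design choices the package makes.

## The DNA-based model

For trait $y$ on $n$ unrelated individuals, GREML fits
$y = X\beta + g + e$, with $\mathrm{Cov}(g) = A\,\sigma^2_G$ where $A$ is the
genomic relationship matrix and $\mathrm{Cov}(e) = I\,\sigma^2_e$. The GRM
entry for individuals $j,k$ is

$$A_{jk} = \frac{1}{M_{jk}} \sum_i
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1 - p_i)},$$

summing over SNPs non-missing in both individuals ($M_{jk}$ of them), with
$p_i$ the sample alternate-allele frequency. Allele frequencies come from the
analysis sample itself, which keeps the pipeline self-contained; the same
formula is applied on the diagonal. Missing genotypes are handled by
pairwise-complete counting by default, with mean-imputation available as an
option.

The bivariate extension stacks two traits: genetic structure
$\begin{pmatrix} \sigma^2_{G1} & \sigma_{G12} \\ \sigma_{G12} & \sigma^2_{G2}
\end{pmatrix} \otimes A$ and residual structure with $I$, where residual
covariance links the two traits only within the same individual. Individuals
observed for one trait still contribute (full-information stacking). The
REML objective $-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ is maximized by
one EM-flavoured update followed by average-information (AI) updates;
convergence is declared when the objective changes by less than $10^{-8}$
(iteration cap 100, both overridable through `greml_control()`). Sampling
(co)variances of the six components come from the inverse AI matrix at the
optimum, and

$$r_G = \frac{C(G)_{12}}{\sqrt{V(G)_1 V(G)_2}}, \qquad
  r_E = \frac{C(e)_{12}}{\sqrt{V(e)_1 V(e)_2}},$$

with delta-method standard errors from the corresponding $3\times3$ blocks.
The delta gradient $(-r/2v_1,\; -r/2v_2,\; 1/\sqrt{v_1v_2})$ is used directly,
so the variance stays finite as the covariance component approaches zero.
Written out term by term this variance is
$r^2\{\mathrm{Var}(v_1)/4v_1^2 + \mathrm{Var}(v_2)/4v_2^2 +
\mathrm{Var}(c)/c^2 + \mathrm{Cov}(v_1,v_2)/2v_1v_2 -
\mathrm{Cov}(v_1,c)/v_1c - \mathrm{Cov}(v_2,c)/v_2c\}$ — the standard
correlation-of-components result that reporting conventions for the residual
correlation transcribe (published transcriptions of this formula are
sometimes garbled; the package implements the delta form and verifies the
term-by-term algebra in its test suite).

Key choices:

* **Unconstrained components.** Variance components are not constrained to be
  nonnegative during optimization (the usual GCTA-style convention);
  constraining biases standard errors near the boundary. Fits with a negative
  variance component are flagged (`glance()`), and a correlation whose
  denominator variance is non-positive is reported as undefined — never
  silently clamped.
* **Step control.** Any proposed update that would decrease the objective is
  halved until it does not; a singular AI matrix is bent by adding
  $\varepsilon I$, $\varepsilon = 10^{-6}\,\mathrm{tr}(AI)$. Starting values
  assign half the phenotypic (co)variance to each component, and a starting
  genetic correlation outside $(-1, 1)$ is shrunk to $\pm 0.5$.
* **Two computational paths, one objective.** When both traits are observed
  on the same individuals, the model is solved in the eigenbasis of the GRM,
  where $V$ factorizes into per-eigenvalue $2\times2$ blocks
  $\Sigma_G d_i + \Sigma_E$; a cohort-scale bivariate fit then costs one
  eigendecomposition plus cheap iterations. Non-identical trait samples use a
  dense stacked representation. The test suite checks both against
  derivative-free maximization of an independently coded REML objective.
* **Reported n** is the pairwise-complete count (the most conservative
  sample size), while estimation uses all individuals with either trait.

## The twin model

Each twin pair contributes a 4-vector (two traits × two twins) assumed
multivariate normal with within-person covariance
$\Sigma_A + \Sigma_C + \Sigma_E$ and cross-twin covariance
$\Sigma_A + \Sigma_C$ (MZ) or $\tfrac12\Sigma_A + \Sigma_C$ (DZ) — the
standard biometric expectations, with the DZ additive coefficient fixed at
$\tfrac12$ (no assortative-mating adjustment) and same- and opposite-sex DZ
pairs pooled. Components are parameterized through lower-triangular path
matrices ($\Sigma_A = aa'$, ...), which keeps them positive semi-definite by
construction. The likelihood is invariant to column sign flips of the path
matrices, so the reported solution is canonicalized to nonnegative diagonals.
One free mean per trait is shared across twin order and zygosity, matching
pre-normalized inputs; pairs with missing cells contribute their observed
sub-vectors.

The fit groups pairs by zygosity and missingness pattern and carries only the
group counts, means and scatter matrices, so each likelihood evaluation is
$O(\text{number of patterns})$ and a 4,000-pair fit takes well under a
second. `fit_twin_moments()` exposes the same machinery on user-supplied
moment matrices; fed exact population moments it reproduces the generating
components to optimizer precision, which is the package's noise-free check.
Optimization uses a quasi-Newton method with 5 seeded random restarts
(analytic moment-based start first); the reported solution is the lowest
$-2\ln L$. Standard errors come from the numerical Hessian at the optimum
(flagged unavailable when singular), and standardized quantities —
per-trait variance shares, the cross-trait covariance split scaled by
$\sqrt{V_{p1}V_{p2}}$ so the three standardized covariance components sum to
the fitted phenotypic correlation, and $r_G$, $r_C$, $r_E$ — carry
delta-method standard errors via a numerical Jacobian. Restricted AE/CE/E
models use the same machinery with whole path matrices fixed at zero. For
two traits the Cholesky and correlated-factor parameterizations are
likelihood-equivalent; the package reports both the path matrices and the
correlation-style summaries rather than privileging one narrative.

## Preprocessing

The phenotype pipeline mirrors standard practice for web-collected cognitive
batteries, in this order per test score:

1. single-pass exclusion of values more than $k$ SD from the mean
   (default $k = 3$; zero-variance input retains everything with a warning);
2. OLS regression on sex and age, keeping standardized residuals
   (rank-deficient designs error, naming the collinear columns; rows with
   missing covariates drop from the regression and downstream analysis);
3. van der Waerden quantile normalization
   $\Phi^{-1}(r/(n+1))$ with average ranks for ties — the standard
   convention; the transform is rank-based, hence idempotent and invariant
   to monotone transforms;
4. unit-weighted composites requiring a minimum number of complete tests
   (e.g. 3 of 4, or 2 of 3).

Whether outliers are screened on raw scores or residuals is a genuine
ambiguity in descriptions of such pipelines; the package follows the order
above (raw scores first) without claiming it is the only defensible choice.
Anthropometric traits can skip step 3 (`quantile_norm = FALSE`), keeping only
covariate adjustment. `select_one_per_family()` reduces a twin cohort to
conventionally unrelated individuals, selecting uniformly per family under a
seed.

## GRM hygiene, PCA and Tracy–Widom selection

`prune_related()` greedily removes individuals until no retained pair exceeds
the relatedness cutoff (default 0.025, roughly fourth-cousin level),
dropping at each step the individual in the most over-threshold pairs, ties
to the higher index — deterministic and close to the minimal removal on the
structures that matter in practice. `ld_prune()` scans windows of 50 SNPs
advancing by 5 (defaults; only the $r^2 \le 0.2$ cutoff is substantive) and
keeps the earlier-positioned SNP of any conflicting pair. `pca_axes()`
decomposes the covariance of column-standardized dosages on the pruned set,
fixes axis signs (largest-magnitude loading positive), and assesses axis
significance by the sequential Tracy–Widom procedure: for each leading
eigenvalue the remaining spectrum supplies an effective sample size
$n_{\mathrm{eff}} = (p+1)S_1^2 / ((p-1)S_2 - S_1^2)$, the normalized largest
eigenvalue is centred and scaled with the white-Wishart constants, and
referred to the TW1 distribution. TW1 tail probabilities come from a static
table embedded in the package (computed once from the Painlevé II
representation of the TW1 distribution function; generator script in
`tools/`), with log-linear interpolation; the table reproduces the published
significance points (0.9793 at $p = 0.05$, 2.0234 at $p = 0.01$) to three
decimals, ample for axis selection. Selection keeps the leading run of axes
with $p < \alpha$ (default 0.05), and the workflow carries the selected axes
into GREML as fixed-effect covariates. By default sex and age do **not**
re-enter GREML (traits are already residualized on them); `add_sex_age`
restores them.

## What the simulator emulates — and what it does not

`sim_genotypes()` draws unlinked biallelic SNPs with ancestral frequencies
uniform on `maf_range` and, when `fst > 0`, Balding–Nichols subpopulation
frequencies, exercising the stratification-correction path.
`sim_phenotypes()` implements exactly the additive architecture GREML
assumes: `n_causal` SNPs drawn uniformly among polymorphic sites, bivariate
effects $\sim N(0, \Sigma_G/n_{\text{causal}})$ on the standardized-dosage
scale, residuals $\sim N(0, \Sigma_E)$ — the simplest architecture under
which GREML is unbiased, making parameter-recovery tests interpretable.
`sim_twins()` inverts the biometric model. The defaults describe the
emulated study: ~2,000 unrelated genotyped individuals, 5,000 SNPs, 500
causal, $\Sigma_G$ and $\Sigma_E$ set to the reference general-ability /
language components (true $r_G = 0.81$, $h^2 \approx 0.36$), and 2,000 MZ +
2,000 DZ pairs from the reference ACE components.

Deliberately **not** modelled: linkage disequilibrium and haplotype
structure (LD pruning is still testable via planted duplicate columns),
imperfect tagging of causal variants (the attenuation that makes real
SNP-heritability estimates undershoot twin estimates), X-linked, dominance
and epistatic effects, assortative mating, and genotype imputation. Passing
recovery tests therefore demonstrates correctness of the estimators under
their own assumptions — not robustness to the violations real cohorts carry.
In particular, the million-SNP, restricted-access cohort behind the reference
tables is far beyond desk scale; full-sample standard errors are instead
validated by calibration (across 200 simulated replicates at $n = 500$ the
empirical SD of $\hat r_G$ must sit within 25% of the mean delta-method SE).

One desk-scale consequence deserves its own note: with $m$ SNPs the
relatedness estimate of a truly unrelated pair has sampling SD
$\approx 1/\sqrt m$. At $m$ in the thousands, a 0.025 cutoff sits inside the
noise and greedy pruning would discard most of the sample; at the millions of
markers the cutoff was designed for, it only catches real relatives.
`run_pipeline()` therefore floors the effective cutoff at
$z/\sqrt m$ (default $z = 4$, configurable, with a warning when the floor
binds), while `prune_related()` itself applies whatever cutoff it is given.

## Workflow and reporting

`run_pipeline()` chains the stages under a single `run_config()` (YAML-
serializable; every threshold — $k$ SD, $r^2$, relatedness cutoff, $\alpha$ —
flows from the config). The genotype cohort carries family ids (families of
two by default) so the one-member-per-family selection mirrors the
one-per-twin-pair design; the twin branch draws from the ACE matrices of the
same configuration, so both estimators target a common generating truth.
Reports are `table1.tsv` (DNA-based vs twin $r_G$ side by side), `table2.tsv`
(the full GREML component set with SEs and the conservative $n$),
`table3.tsv` (standardized twin components), plus `run.json` metadata
recording the seed and every defaulted parameter, and a stage log.
`check_table_consistency()` re-verifies the ratio identities among reported
columns at a rounding tolerance. Identical configs (including seed) give
identical tables.

The test suite's problem sizes are the package's choices for tight,
informative checks: cohort-scale recovery at 2,000 × 5,000 (20 replicates),
null controls at 1,000 × 2,000, SE calibration at 500 × 1,000 (200
replicates), twin recovery at 2,000 + 2,000 pairs, and toy oracle
comparisons at $n \le 30$ where the REML surface can be maximized
independently by multi-start Nelder–Mead.

## Known limitations

* Two traits only; no multi-trait or GxE extensions, no liability-threshold
  models for binary traits, no genomic partitioning.
* The GREML dense (non-identical-sample) path scales as $O((n_1+n_2)^3)$ per
  iteration and is intended for moderate samples; the eigen path covers the
  complete-data cohort scale.
* Tracy–Widom probabilities are table-interpolated on $s \in [-5, 8]$;
  p-values are clamped at the table edges (below ~$10^{-9}$ and near 1),
  which cannot affect axis selection at conventional $\alpha$.
* The twin model assumes multivariate normality and equal means across twin
  order and zygosity; gross violations (e.g. unnormalized skewed traits)
  should be handled in preprocessing.
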