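---
title: "Population-level PCA: model, estimation, and stratification correction"
author: "stratpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level PCA: model, estimation, and stratification correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratpca)
```

## The model

`stratpca` implements the *population* (theoretical) formulation of the PCA
that Eigenstrat-style methods apply to genotype data. Individuals
$i = 1, \dots, n$ are sampled from $K$ populations with sizes $n_s$. For a
randomly chosen biallelic marker, the allele frequency vector
$(f_1, \dots, f_K)$ is random with means $\mu_s$ and covariance matrix
$\psi$, and the allele count of an individual from population $s$ is
$X \mid f \sim \mathrm{Binomial}(2, f_s)$, with individuals conditionally
independent given $f$. The law of total covariance then gives the
variance-covariance parameters of the genotype vector:

$$\sigma_s^2 = 2\mu_s(1-\mu_s) + 2\psi_{ss}, \qquad
  c_s = 4\psi_{ss}, \qquad d_{st} = 4\psi_{st},$$

so the $n \times n$ genotype covariance is a block matrix: diagonal blocks
$(\sigma_s^2 - c_s) I + c_s J$ and off-diagonal blocks $d_{st} J$. Its
spectrum splits into *small* within-population eigenvalues
$\sigma_s^2 - c_s$ (multiplicity $n_s - 1$) and $K$ *large* eigenvalues
whose eigenvectors are constant within populations.

Two assumptions matter in practice: markers are exchangeable draws from one
frequency law (no outlier markers, no linkage disequilibrium between the
markers used), and individuals are unadmixed members of exactly one
population. Admixed individuals are outside the model.

### Mean adjustment

The overall co-variation of all individuals produces one large eigenvalue
unrelated to structure. Per-marker centering across individuals (the mean
adjustment) removes it: with
$r_s = \frac{1}{n}\bigl[\sigma_s^2 + (n_s-1)c_s + \sum_{t \neq s} n_t d_{st}\bigr]$
and $g = \mathrm{Var}(\bar X)$, the adjusted parameters are
$\tilde\sigma_s^2 = \sigma_s^2 - 2r_s + g$, and likewise for $\tilde c_s$
and $\tilde d_{st}$. Two exact algebraic facts anchor the implementation and
its tests: the within-population spread is untouched
($\tilde\sigma_s^2 - \tilde c_s = \sigma_s^2 - c_s$), and the adjusted
parameters satisfy a zero-sum identity,
$(\tilde\sigma_t^2 - \tilde c_t) + n_t \tilde c_t +
\sum_{s\neq t} n_s \tilde d_{st} = 0$, which forces zero row sums of the
reduced matrix and hence the existence of the trivial eigensolution.

### The reduced eigen-equation

Because the large-eigenvalue eigenvectors take one value $a_s$ per
population, the $n \times n$ eigenproblem collapses to the $K \times K$
equation $R a = \lambda a$ with $R_{ss} = n_s \tilde c_s +
(\tilde\sigma_s^2 - \tilde c_s)$ and $R_{st} = n_t \tilde d_{st}$. One
solution is trivial ($\lambda = 0$, constant $a$); the other $K - 1$ *axes
of variation* satisfy $\sum_s n_s a_s = 0$ and are normalised to
$\sum_s n_s a_s^2 = 1$. Each population is represented by a single point
per axis; the geometry of those points is the theoretical skeleton of a PC
scatter plot.

```{r reduced-example}
lay <- pop_layout(c(5, 10, 100))
params <- cov_params(sigma2 = rep(1, 3), c = rep(0.8, 3),
                     d = matrix(0.1, 3, 3))
adj <- mean_adjust(params, lay)$params
solve_reduced(build_reduced(adj, lay))
```

With identical covariance parameters the pattern above purely reflects
sample sizes: the constraint $\sum_s n_s a_s = 0$ pushes small populations
away from the origin.

Numerical notes. `R` is not symmetric; the solver works on the similar
symmetric matrix $B = S R S^{-1}$, $S = \mathrm{diag}(\sqrt{n_s})$, so a
stable symmetric eigensolver can be used and the back-transformed
coefficients automatically carry the $\sum n_s a_s^2 = 1$ normalisation.
The trivial axis is detected at $|\lambda| < 10^{-9}\max(|\lambda|, 1)$
(the unit floor makes the one-population case, whose only eigenvalue is the
trivial zero, well defined). Signs are fixed per axis by making the
coefficient of largest magnitude positive, with magnitude ties broken by
the lowest population index — mirrored scatter plots are otherwise
arbitrary, and the tie-break keeps exchangeable populations (for which the
dominant-magnitude coefficient is not unique) reproducible. Ties between
eigenvalues are ordered by the ascending population index of the dominant
coefficient.

### Two populations, and the large-$n$ limit

For $K = 2$ the constraints alone force
$a = (\sqrt{n_2/(n_1 n)}, -\sqrt{n_1/(n_2 n)})$: the only informative axis
depends on the sample-size ratio and on nothing else, and its eigenvalue is
$-n \tilde d_{12}$. For general $K$, letting all $n_s \to \infty$ at fixed
proportions $w_s$ turns the reduced equation into $A a = \Lambda a$ with
$A_{st} = w_t \tilde d_{st}$: large eigenvalues grow linearly in $n$ while
the coefficient pattern converges to an asymptotic shape that does not
involve the variances $\sigma_s^2$ at all — the per-population term
neglected in the limit is $(\sigma_s^2 - c_s)/n$. In the exchangeable case
(equal $\sigma^2$, $c$, $d$) the neglected term is comparable to the
smallest non-trivial eigenvalue at the critical size
$n^* = K(\sigma^2 - c)/(c - d)$, implemented in `critical_size()` up to a
dimensionless prefactor; only its monotonicity ($n^* \to \infty$ as
$d \to c$) is treated as meaningful.

## Estimation

With known memberships, each parameter is estimated by averaging the
corresponding cells of the $n \times n$ sample covariance of individuals
across markers (`sample_cov()`, per-individual centering,
pairwise-complete over missing genotypes): diagonal cells give
$\hat\sigma_s^2$, within-block off-diagonals give $\hat c_s$, cross-blocks
give $\hat d_{st}$. Raw parameters are estimated *without* marker-wise
centering and the tilde parameters are then obtained analytically by
`mean_adjust()`; re-estimating them from a marker-centred matrix would
break the zero-sum identity by sampling noise, while the analytic route
keeps it exact. The attached standard errors treat averaged cells as
independent; cells share markers, so these SEs are approximate (typically
understated) and are meant for reading tables, not formal inference.
Markers monomorphic across the sample carry no covariance information and
are dropped with a message. No $p(1-p)$ standardisation is applied: the
theory is stated on raw allele counts. Correlations
$\rho_{st} = \hat d_{st}/\sqrt{\hat\sigma_s^2\hat\sigma_t^2}$ provide a
sample-size-free summary of population proximity.

`popca()` wraps this pipeline into a single fit: block-average estimates,
adjusted parameters, axes of variation, and (optionally) the sample
eigenvectors of the marker-centred covariance for overlay plots, with the
usual `print`/`summary`/`coef`/`plot`/`residuals`/`predict` methods.

## Correcting association tests

The Eigenstrat correction removes the projection of each marker row on the
top $L$ sample PCs. Using the *representative* PCs instead — the axes of
variation expanded to piecewise-constant vectors — is algebraically
identical to subtracting each population's per-marker mean allele count
(`popu_residual()`); the package tests this identity to $10^{-10}$ against
an explicit projection. The corrected statistic is the generalised Armitage
trend $\chi^2 = (N - \mathit{df}_{loss})\, r^2$ on the residualised
genotype, with $r$ the genotype-phenotype correlation and
$\mathit{df}_{loss} = 0$ by default (the degrees-of-freedom convention of
the original EIGENSTRAT program is not documented; the charge is exposed
rather than guessed).

A design choice deserves emphasis: **only the genotype is residualised by
default**, for both the sample-PC and the representative-PC corrections.
The correction is defined as an operation on the genotype expansion, and
with the phenotype left raw the corrected statistic's denominator keeps the
full phenotype variance, making both corrections mildly conservative under
stratified sampling (null rejection around $0.6\alpha$ in the simulation
study below) — the behaviour the simulation table reproduces. Double
residualisation (`residualize_phenotype = TRUE`) restores nominal
calibration but nearly collapses the popu correction onto covariate
adjustment, hiding the distinction the comparison is meant to show. The
covariate arm itself is a 1-df likelihood-ratio test of the genotype term
in a logistic model with $K - 1$ population indicators; whether the
original comparison used a logistic or a stratified-trend formulation is
not recorded, and the logistic reading is implemented.

For causal markers the package reports *direction-aware* power: a
rejection counts only if the sign of the genotype-phenotype correlation
matches the simulated risk allele. Under confounding the uncorrected test
can reject essentially always with the *wrong* sign — power 0 with tiny
p-values — and this bookkeeping is what makes that phenomenon visible.

## The simulation study

`simulate_assoc_study()` emulates a stratified case-control study with three
populations: expected case counts (30, 60, 150) and controls (80, 80, 80)
(disease prevalences 1:2:5 with equal sampling priors; expected, not
multinomially drawn, counts). Four SNP categories of 10,000 markers each
are generated: Null/Causal-StruInfo with Balding-Nichols frequencies
($p \sim U(0.1, 0.9)$, $f_s \mid p \sim
\mathrm{Beta}(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F})$), and
Null/Causal-Specific with fixed frequency sets $(0.75, 0.30, 0.15)$ and
$(0.15, 0.30, 0.75)$. Causal cases are drawn at the tilted frequency
$f' = rf/(1 - f + rf)$, the closed form of a multiplicative relative risk
$r$ per allele copy under Hardy-Weinberg — verified in the tests against
direct three-cell normalisation. Two constants are calibrated rather than
copied: the significance threshold $\alpha = 0.01$ (the only round value
consistent with the characteristic pattern of inflated uncorrected and
just-sub-nominal corrected null rates) and the relative risk $r = 1.5$ (a
modest per-allele effect placing corrected power near 0.4 — large enough
to compare the correction arms, far from saturation at either end). Both
are arguments, not constants.

What the generator deliberately does not emulate: linkage disequilibrium
(markers are independent), admixture, genotyping error, missingness (the
estimation layer handles missing data, but the simulator never produces
it), and ascertainment of markers by polymorphism — monomorphic draws are
retained and flagged downstream rather than resampled. Passing the
simulation tests therefore says nothing about LD-induced PC artefacts or
admixed samples on real data.

The subtle-substructure scenario (`subtle_structure_scenario()`) builds
four populations of which two are near-twins: P3's frequency vector is
P2's plus an i.i.d. $U(-\delta, \delta)$ perturbation. The default
$\delta = 0.05$ was calibrated once, against the scenario's own success
criterion: the twin contrast must be resolvable on sample eigenvector 3
while the twins stay several-fold closer to each other than any pair of
outer populations. At $\delta = 0.01$ the twin axis eigenvalue sits below
the sample-PCA detection threshold even at 500 individuals per population
and $10^5$ markers (the standardised axis-3 separation stays at noise
level), so no feasible marker count reveals the contrast; at
$\delta = 0.05$ all of the scenario's qualitative signatures — twin
distance invariant to marker count, cluster spread shrinking with markers
and with individuals, axis-3 separation — appear from $10^4$ markers and
100 individuals per population. $\delta$ remains an argument.

## Problem sizes and tolerances used by the test suite

The suite checks the reduced-versus-dense eigen equivalence on 200 random
parameter systems ($K \le 6$, $n \le 300$) at relative tolerance $10^{-8}$;
the group-mean/projection identity at $10^{-10}$; Monte-Carlo moment
recoveries at $10^5$ markers within 3 MC standard errors computed from
per-marker statistics; and the full simulation study at its native size of
10,000 SNPs per category. Stochastic assertions fix their seeds;
qualitative figure geometry is asserted as inequalities on seeded runs, not
as pixel comparisons. `scripts/acceptance.R` re-runs the simulation study
from scratch at the same sizes and writes the headline rejection rates as
JSON.

## Known limitations

* Membership labels are required for estimation and for the popu
  correction; the package does not infer them (clustering a PC plot or a
  mixture model is the usual route).
* The block-average SEs understate uncertainty because cells share
  markers; a resampling scheme over markers would be needed for honest
  intervals.
* The critical-size constant and the generalised-trend df charge are
  reconstructions up to documented ambiguity; only their monotone
  behaviour is asserted.
* Quantitative phenotypes, genomic control, and eigenvalue significance
  tests are out of scope.
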