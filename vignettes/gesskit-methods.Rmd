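---
title: "Methods: the correlated service-sire/dam model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the correlated service-sire/dam model and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Female reproductive phenotypes — conception rate (CR), 56-day non-return
rate (NRR56), calving ease (CE), stillbirth (SB) and gestation length
(GL) — are measured on the cow, but the bull whose semen was used (the
*service sire*) contributes genetically to the outcome. `gesskit` fits
one linear mixed model per trait with *two correlated genetic effects*:

$$y = X\beta + Z_1 u_{ss} + Z_2 u_d + W_1 pe_{ss} + W_2 pe_d + Z_h\,hym + e$$

where $u_{ss}$ is the genetic effect of the service sire (GESS), $u_d$
the genetic effect of the cow/dam (GED), $pe_{ss}$ and $pe_d$ the
permanent-environment effects of bull and cow, and $hym$ the
herd-year-month contemporary group. The stacked genetic effect
$[u_{ss}; u_d]$ (animal-major within effect) has prior covariance
$G_0 \otimes A$, with $A$ the pedigree numerator relationship matrix and

$$G_0 = \begin{pmatrix}\sigma^2_{ss} & \sigma_{ss,d}\\
\sigma_{ss,d} & \sigma^2_d\end{pmatrix}.$$

Both genetic effects are defined for *every* pedigree animal, so a bull's
GESS and a cow's GED are linked through ordinary pedigree relationships
and through $\sigma_{ss,d}$. All other random terms are i.i.d. Fixed
effects are AI technician, parity, semen type and insemination number for
the success traits, and calf sex, parity and calf-size group
(30-40/40-50/50-60 kg birth weight) for the calving traits.

Binary and ordinal traits are *analyzed on the observed scale* with this
linear model. Threshold (probit) analyses of the same traits give very
similar heritability rankings at these incidences, and the linear model
keeps the variance-component machinery exact; the choice is deliberate
and fixed.

## Derived parameters and the denominator convention

Heritabilities and repeatabilities are ratios of components to the
phenotypic variance,

$$h^2_{ss} = \sigma^2_{ss} / V_P,\qquad
re_{ss} = (\sigma^2_{ss}+\sigma^2_{pe_{ss}})/V_P,$$

and analogously for the dam effect. Two conventions exist for $V_P$:
with or without the $2\sigma_{ss,d}$ term. The bundled reference
estimates are only internally consistent under the *covariance-omitted*
denominator, so `include_cov = FALSE` is the default in
`heritability()`/`repeatability()`; the flag exposes the alternative.
The sire-dam genetic correlation is
$r = \sigma_{ss,d}/\sqrt{\sigma^2_{ss}\sigma^2_d}$, clamped to
$[-1, 1]$. Standard errors of all derived parameters come from the delta
method with analytic gradients and the AI-based sampling covariance;
Wald tests are two-sided normal tests against zero.

## AI-REML implementation

Variance components are estimated by restricted maximum likelihood on
the sparse mixed-model equations (MME), assembled in residual-precision
units with prior precision $G_0^{-1}\otimes A^{-1}$ for the genetic
block. The restricted log-likelihood is evaluated exactly through one
sparse Cholesky factorization per parameter point:
$-2\ell_R = n\log\sigma^2_e + \log|G| + \log|C| + y'Py$ (the constant
$\tfrac{n-p}{2}\log 2\pi$ is omitted consistently). The symbolic
factorization is reused across evaluations and re-analyzed only when the
sparsity pattern changes (the sire-dam cross blocks appear or vanish
with $\sigma_{ss,d}$).

Numerical choices, all of which were fixed before the validation runs:

* **Curvature**: the exact average-information (AI) matrix, computed with
  the Johnson-Thompson working vectors — one multi-right-hand-side MME
  solve per iteration; $A$-products use the sparse Cholesky of
  $A^{-1}$. Its inverse at convergence is the reported sampling
  covariance (eigenvalue-floored to stay PSD at boundaries).
* **Gradient**: finite differences of the exact restricted likelihood
  (step $10^{-3}|\theta_i| + 10^{-4}\,\mathrm{var}(y)$); forward
  differences while far from the optimum, central near it. The trace
  terms of the analytic gradient would require a selected inverse of the
  sparse coefficient matrix, which would have to be written from
  scratch; the finite-difference gradient with an exact likelihood and
  exact AI curvature gives the same stationary point to well below one
  standard error.
* **Safeguards**: Levenberg-Marquardt damping of the AI step plus
  step-halving, accepting only non-decreasing likelihood values, so the
  restricted log-likelihood is monotone over accepted iterates.
  Parameters are kept feasible by projection: variances floored at
  $10^{-8}\,\mathrm{var}(y)$, $|\sigma_{ss,d}| \le
  0.999\sqrt{\sigma^2_{ss}\sigma^2_d}$. Variances stuck at the floor
  with an outward gradient are frozen for that iteration (projected
  Newton). This projection-plus-line-search plays the role usually given
  to an EM fallback step and provides the same guarantee (monotonicity
  inside the parameter space) at lower cost.
* **Mode switching**: the sire (dam) genetic variance and its
  permanent-environment twin are exchangeable local optima when family
  information is weak, and the degenerate basin (genetic variance on the
  floor, covariance forced to zero) can trap a single-start ascent. If a
  genetic variance converges onto its floor, the fitter restarts once
  from the swapped variance split with the sire-dam covariance re-seeded
  at half its feasible bound, and keeps the higher restricted
  likelihood.
* **Convergence**: relative parameter change below `tol_par` or
  likelihood change below `tol_ll` on an essentially undamped step;
  defaults $10^{-8}$/$10^{-9}$. On problems up to 2,000 records a short
  derivative-free (Nelder-Mead) polish in a log/Fisher-z
  parameterization follows, which guards against stalls of the
  finite-difference gradient on flat small-sample surfaces.
* **Degenerate inputs**: a singular $G_0$ is ridge-stabilized with a
  warning; factor levels without records drop out of the design; a
  rank-deficient fixed block is reduced to a basis (reference-level
  constraint).

## Breeding values, reliabilities, deregression

BLUPs come from the converged MME; animals without records receive
parent-average values through $A$. Reliability is
$1 - \mathrm{PEV}_i/((1+F_i)\sigma^2_u)$ with the prediction-error
variance taken from the exact inverse coefficient-matrix diagonal
(sparse solves for the requested animals — exact, not approximated).
De-regressed proofs follow the classical parent-average-removal
construction: with $r^2_{PA} = (rel_s + rel_d)/4$ and own-information
reliability $r^2_{der} = (rel - r^2_{PA})/(1 - r^2_{PA})$,
$\mathrm{DRP} = PA + (\mathrm{EBV} - PA)/r^2_{der}$, with weight
$w = (1-h^2)/\big((c + (1-r^2_{der})/r^2_{der})h^2\big)$ and $c = 0.5$
by default (fraction of genetic variance not captured by markers). The
weight uses the reliability of the *deregressed* information — the only
reading under which re-regressing the DRP reproduces the original EBV,
which the test suite checks as a round trip. A `simple = TRUE` mode
(plain EBV/rel scaling) is provided. Animals with accuracy
$\sqrt{rel} \le 0.10$ are flagged and excluded downstream.

The approximate genetic correlation between two EBV sets (Calo's method)
scales the Pearson correlation by
$\sqrt{\sum rel_1 \sum rel_2}/\sum\sqrt{rel_1 rel_2} \ge 1$. Its SE
treats that factor as fixed, $SE = f\,(1-r^2_{raw})/\sqrt{n-2}$; the
suite validates this closed form against a nonparametric bootstrap.

## The association scan

De-regressed proofs of included animals are the response of a
FarmCPU-style multi-locus scan: a fixed-effect step tests every SNP by
weighted least squares (DRP weights) with the current pseudo-QTNs as
covariates — excluding any pseudo-QTN within 10 Mb of the tested SNP —
alternating with a selection step that bins markers by position
(bin-size grid $10^4$, $10^5$, $10^6$ bp; set sizes 5, 10, ... up to
`max_qtn` = 10) and keeps the candidate set maximizing the likelihood of
a random-effect model whose kinship is built from the candidate markers
(evaluated in low rank). Iteration stops when the FDR-significant set is
stable, after 10 iterations, or immediately when nothing passes the
seeding threshold $0.01/m$ in the first pass — which is what keeps the
scan calibrated under the null. `max_qtn = 0` reduces the scan exactly
to single-marker weighted regression, the verifiable baseline. Missing
genotypes are mean-imputed per SNP after QC (order-independent);
X-pseudo-autosomal markers are treated as diploid autosomal.

QC removes markers with MAF < 0.05, Hardy-Weinberg $p < 10^{-6}$
(1-df chi-squared, exact-test option for small counts), unknown map
position, or imputation concordance $\le 0.90$. Multiple testing uses
Benjamini-Hochberg at the 5% genome-wise level; calibration is
monitored with the inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs})/0.4549$ and Q-Q data.
Significant SNPs are mapped to gene/QTL intervals whose bodies intersect
a ±200 kb window (boundary inclusive, gene-body distance; BED and GFF3
dialects converted on input).

## What the synthetic herd does and does not emulate

The generator reproduces the statistical structure the model assumes:
topologically valid multi-generation pedigrees; correlated sire/dam
breeding values gene-dropped with Mendelian-sampling variance reduced by
parental inbreeding ($\tfrac12 G_0(1 - (F_s+F_d)/2)$); repeated
parities; Zipf-weighted service-sire assignment reproducing the heavily
skewed usage of real insemination logs (a handful of bulls serve
thousands of cows); i.i.d. herd-year-month effects; and binary/ordinal
traits generated by thresholding the latent Gaussian at cut points
calibrated to the observed incidences (CR 0.43, CE scores >1 5.21%
split 4.42%/0.79%, SB 6.67%, NRR56 0.50). Genotypes are unlinked
biallelic SNPs gene-dropped through the same pedigree.

It deliberately does **not** emulate: linkage disequilibrium (so
association hits localize to the causal marker itself, not a region),
selection or non-random mating, seasonality and heat stress on GL,
semen-quality biology, estrus-cycle timing, or recording error beyond
the structural cases the editing layer handles. Passing tests therefore
demonstrate correctness of the estimation machinery *under the model*,
not robustness to the ways real herd data violate it.

## Validation problem sizes

The parameter-recovery study uses the gestation-length reference
components as truth and 40,000 records: 5,000 cows with 8 parities each,
three cohorts bred from 200 founders, 80 contemporary service sires and
10 herds x 4 years x 12 months. Eight parities is more than a typical
cow records; the depth was chosen so permanent-environment and genetic
variances separate cleanly at this herd size. Recovery fits use forward
gradients and stopping at `tol_ll` $10^{-4}$ — at $|\ell_R|\approx
9\times10^4$ this is far below one standard error of any component.
Null calibration of the scan uses 2,000 unrelated animals x 5,000 SNPs;
localization uses 20 replicates with one marker explaining 5% of the
response variance. Dense-matrix oracles (likelihood, GLS/BLUP,
relationship algebra) run at 40-200 animals where exact dense
computation is cheap.

## Known limitations

* Single-trait models only; between-trait genetic correlations are
  approximated from EBV sets (Calo), not estimated jointly.
* No genomic relationship matrix; the evaluation is pedigree-based, and
  genotypes enter only through the association scan.
* No unknown-parent groups; unknown parents are unrelated founders.
* Non-additive genetic effects (dominance, epistasis) are not modeled.
* The observed-scale linear treatment of binary/ordinal traits makes
  heritabilities incidence-dependent; they are comparable within, not
  across, incidences.
* Reported sampling covariances at a variance floor are
  information-matrix approximations; profile-likelihood intervals would
  be preferable exactly at the boundary.
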