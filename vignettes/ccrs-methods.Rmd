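---
title: "Region-based rare-variant testing with convex-concave selection"
author: "CCRS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based rare-variant testing with convex-concave selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-variant association tests are essentially powerless for variants
with minor allele frequency (MAF) below 0.05: each site carries a handful
of minor alleles, and a sequenced genome contains millions of such sites.
Region-based tests therefore aggregate consecutive rare variants — here,
count-based sliding windows of 50 variants stepping by 25 — and test each
window jointly against a quantitative trait. Two features of rare-variant
dosage blocks drive the design of this package:

* **Linkage disequilibrium (LD)** makes the window's dosage matrix
  ill-conditioned or singular, so naive penalized regression on the raw
  variants selects unstable, arbitrary representatives of correlated sets.
* **Sparsity of effects**: most variants in a window are neutral, so a
  test that spreads its degrees of freedom over everything pays for noise.

## The model

For a window $X_k \in \{0,1,2\}^{n \times p}$ ($p < n$), phenotype $y$ and
covariates $T$, the working model is the Gaussian linear model

$$ y = \alpha + X_k \beta_k + T\theta + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2 I). $$

The CCRS pipeline reparameterizes this model in two penalized steps.

**Convex step — constrained factorization.** The (column-centered) window
is approximated by $X \approx U D V^\top$ with, for each component $j$,

$$ \|v_j\|_2 \le 1,\quad \|v_j\|_1 \le c, \qquad
   \|u_j\|_2 = 1,\quad u_1 \perp \dots \perp u_r, $$

computed by alternating exact updates of the rank-1 problem
$\max_{u,v} u^\top X v$ on the deflated residual $(I - UU^\top)X$. The
$v$-update soft-thresholds $X^\top u$ with the smallest threshold (found
by bisection) that satisfies the $L_1$ bound after normalization; the
$u$-update is $Xv/\|Xv\|_2$. The $L_1$ bound is feasible for
$c \in (1, \sqrt{p}\,]$; at $c = \sqrt{p}$ the constraint is inactive and
the factorization equals the truncated SVD (this is the package's main
internal oracle check). The bound can be fixed, left at the default
$\max(1 + 10^{-6},\, 0.5\sqrt{p})$ (moderately sparse loadings), or
selected per window by entry-holdout cross-validation: a random scattered
fraction of matrix entries is masked and replaced by column means, and
the bound minimizing squared reconstruction error on the masked entries
wins, ties going to the sparser value.

**Concave step — bridge selection.** With components $Z = U D$, the
coefficients solve

$$ \min_{\gamma,\theta}\ \tfrac12 \|y - Z\gamma - T\theta\|_2^2
   + \nu \sum_j |\gamma_j|^{\kappa}, \qquad \kappa \in (0,1), $$

a bridge ($L_q$, $q<1$) penalty: concave, sparser than the lasso, and with
shrinkage that vanishes as $|\gamma_j|$ grows, so large effects are
essentially unbiased. Covariates and the intercept are unpenalized and
handled by projection (Frisch–Waugh); the component coefficients are then
found by cyclic coordinate descent with an exact scalar minimizer per
coordinate, run from two deterministic starts (zero and least squares),
keeping the lower final objective. The penalty weight is chosen by

$$ \mathrm{BIC}(\nu) = \log\{\|y - Z\hat\gamma - T\hat\theta\|_2^2 / n\}
   + \log(n)\, d(\nu)/n, $$

with $d(\nu)$ the number of selected components plus covariates plus
intercept; ties go to the larger (sparser) $\nu$.

**Region test.** The selected model is compared to the covariate-only
null $H_0: \gamma = 0$ with the Gaussian profile-likelihood ratio
$n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$. Two references are offered:

* `chisq` — $\chi^2$ with df = number of selected components. Fast, but
  anti-conservative in principle because $\nu$ is selected on the same
  data; used for interactive scans and rank screening.
* `perm` — covariate-preserving permutation: residuals of $y$ on $(1,T)$
  are permuted, re-projected, and the entire selection-plus-test step is
  re-run ($\nu$ reselected each time; the genotype factorization is
  reused, since it depends only on $X$). This is the calibrated option
  and what the calibration checks use. P-values use the add-one
  estimator $(1 + \#\{S_b \ge S_{\mathrm{obs}}\})/(B+1)$.

Genome-wide thresholds mirror the sliding-window practice: the same
permutations are applied to a sample of windows, each permuted statistic
becomes a within-window rank p-value, and the family-wise threshold is
the $\alpha$-quantile of the per-permutation minimum p (a min-p
construction); Bonferroni is reported alongside.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `windowSize`, `step`, `minSize` | 50, 25, 10 | count-based windows; 50 variants capture local LD, 50% overlap avoids boundary loss; trailing windows below 10 variants are dropped |
| `maf` | 0.05 | inclusive rare/low-frequency cutoff on dosage-derived MAF |
| `c` | $\max(1{+}10^{-6}, 0.5\sqrt p)$ | loading sparsity bound; `"cv"` enables entry-holdout CV; $\sqrt p$ recovers plain PCA |
| `kappa` | 0.5 | bridge concavity exponent |
| `nuGrid` | 0.001–0.05 (5 values) | BIC grid for the penalty weight; wider windows warrant larger values |
| `pvalue`, `B` | `"chisq"`, 200 | reference distribution; permutation is the calibrated choice |
| `rankTol` | 1e-8 | relative cutoff $d_j/d_1$ for retaining components |
| `rhoGrid` (SKAT-O) | 0, 0.25, …, 1 | kernel interpolation between dispersion and burden |

A practical note on the default `nuGrid`: at these small values the
bridge threshold only zeroes components whose signal is near machine
scale, so on noisy windows the selected model is close to full rank and
the concave step mostly re-weights rather than prunes. The grid is kept
because it is the configuration the method is defined with; the
permutation reference makes the resulting test exactly calibrated
regardless, and `selectNu()` accepts any grid when stronger pruning is
wanted (the test suite demonstrates exact support recovery with larger
$\nu$).

## Comparators

* **Collapsing (col)** — regression of $y$ on the indicator that a sample
  carries any minor allele in the window.
* **CAST (cast)** — regression of $y$ on the per-sample burden
  $\sum_j x_{ij}$.
* **Simplified SKAT-O (skato)** — score statistic
  $(y-\hat\mu)^\top X R_\rho X^\top (y-\hat\mu)$ with
  $R_\rho = (1-\rho)I + \rho\mathbf{1}\mathbf{1}^\top$, evaluated on a
  $\rho$ grid; each quadratic form's null is moment-matched to a scaled
  noncentral chi-square, and the grid is combined by Bonferroni (or by
  permutation of the minimum p). This is deliberately **not** the exact
  optimal-$\rho$ integration of the original method; it is self-contained
  and conservative by construction, which the calibration test verifies.
  The kernel is unweighted, with a per-variant weight hook.
* **SPC (spc)** — the same constrained factorization, but regressing on
  the first $k$ components (default: smallest $k$ explaining 80% of the
  factorized variance) with a standard F-test. This is the
  dimension-reduction strategy CCRS is designed to improve on: when the
  association sits in a non-leading component, first-$k$ regression
  misses it while the concave selection does not (a fixed-seed test
  exercises exactly this contrast).

## The synthetic-data generator

Real rare-variant genotypes are controlled-access, so all testing runs on
a latent-Gaussian threshold simulator. Per region of 50 variants: target
MAFs are uniform on [0.005, 0.05]; each haplotype gets a latent Gaussian
vector with compound-symmetric correlation 0.7 inside each of five
disjoint 5-variant blocks (the other half of the region independent); an
allele is carried when the latent value exceeds the $(1-\mathrm{maf})$
quantile, and dosage is the sum of two independent haplotypes. Columns
that come out monomorphic or above MAF 0.05 are redrawn (whole blocks are
redrawn when a shared factor makes the bound unreachable, so LD is
preserved). Six architectures assign effects within influential regions
(default: half the regions): 10% causal with effects $+1$ placed inside
blocks (model 1) or outside (model 3), the same with balanced $\pm 1$
signs (models 2 and 4), and 20% causal with magnitudes $U(0.5,1)$, half
in blocks, half outside, all-positive (model 5) or sign-balanced
(model 6). The residual standard deviation defaults to 1; "$\pm 1$" is
implemented as an exactly balanced random sign assignment (odd counts
leave a one-variant imbalance at random).

What the generator does **not** emulate: realistic LD decay (blocks are
exchangeable, not distance-decaying), population structure, relatedness,
allele-frequency spectra from demography, genotype calling error, or
multi-allelic sites. Passing tests therefore demonstrate correctness of
the algorithms and calibration under exchangeable block LD — not
performance on any particular cohort.

A deliberate consequence of the phenotype contract (one phenotype summing
*all* causal variants genome-wide) is that with 100 influential regions
each region explains only about 1% of the phenotypic variance, so
absolute per-region power at benchmark scale is modest for every method;
the benchmark's meaningful output is the comparison between methods under
identical conditions, which is what the acceptance checks assert.

## Numerical choices

* Columns are centered before factorization; no variance scaling (the
  dosage scale carries the frequency information).
* Rank-1 initialization is the leading right singular vector (computed
  from the smaller Gram matrix), i.e. the unconstrained optimum;
  deterministic by construction. Signs are fixed so the
  largest-magnitude loading is positive.
* The soft-threshold level is found by bisection to 1e-8; the feasible
  endpoint is kept, so the $L_1$ bound holds exactly (the reported
  objective may wiggle at the 1e-9 level as a result). Alternation stops
  when the largest elementwise change falls below 1e-7 (200 iteration
  cap).
* Components are extracted by deflation but reported sorted by
  decreasing $d_j$: with a binding $L_1$ constraint the alternation can
  stop at a local optimum, so the raw extraction order need not be
  monotone; ordering is a labeling convention and the reconstruction is
  order-invariant.
* The scalar bridge minimizer compares $\gamma = 0$ against the smooth
  branch's local minimum, bracketed between the stationary point of $g'$
  and $|b|$ and bisected to 1e-10; exact ties go to 0. Coordinate
  descent runs in Gram form ($O(r^2)$ per sweep), converging on max
  coefficient change below 1e-8, 200 sweep cap; hitting the cap flags
  the fit rather than erroring.
* Degenerate inputs: all-constant windows return a skip row with
  p-value 1; $p = 1$ windows bypass the factorization (the centered
  column is its own component); zero matrices and infeasible sparsity
  bounds are errors; a zero residual sum of squares maps BIC to a large
  negative sentinel with a warning.
* Missing genotypes impute to homozygous reference by default (rare
  dosages are overwhelmingly 0), with a column-mean-rounded alternative;
  multi-allelic sites split into one biallelic column per alternate
  allele; the MAF boundary is inclusive.

## Scoring

`scoreReplicate()` counts, per replicate and level $\alpha$: significant
regions $R$, true discoveries $T$, false positives $F = R - T$, and forms
$\mathrm{FDR} = F/R$ (0 when $R = 0$, matching
$E[F/R \mid R>0]\,P[R>0]$). Two true-positive rates are reported:
`tpr_conventional` $= T/\#\{\text{influential}\}$, the quantity plotted
and asserted by default, and `tpr_printed` $= T/(M-R)$, retained verbatim
for fidelity to the display-equation form even though its denominator
(the non-significant count) is not a natural TPR normalizer; it is
flagged `NA` when $M = R$.

## Problem sizes used by the checks

The package's own acceptance checks run at desk scale, chosen to finish
in minutes on one core while keeping Monte-Carlo error meaningful: 100
random matrices (up to 40×20) for the SVD oracle; 100 random draws for
the bridge grid oracle; 500 null windows ($n = 200$, 50 variants,
$B = 200$ permutations) for type-I calibration with an acceptance band
of [0.03, 0.07] at $\alpha = 0.05$; and a 200-region, $n = 400$,
model-4 benchmark for the method ordering. `scripts/acceptance.R`
recomputes all of these from scratch.

## Known limitations

* Quantitative traits only; no logistic/case-control extension.
* The chi-square reference ignores post-selection effects; use the
  permutation reference for calibrated inference.
* The simplified SKAT-O is conservative relative to the exact
  optimal-$\rho$ method, mildly understating that comparator's power.
* Entry-holdout CV for the sparsity bound has high variance on small
  windows; the fixed default is used in the benchmarks.
* Windows are count-based and may span chromosome boundaries if a
  multi-chromosome matrix is scanned; scan per chromosome when that
  matters.
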