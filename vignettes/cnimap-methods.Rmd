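---
title: "Mapping cyto-nuclear interaction QTL subject to genomic imprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cyto-nuclear interaction QTL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnimap)
```

## The genetic model

`cnimap` dissects three entangled parent-of-origin contributions to a
quantitative trait in crosses of two inbred lines (P1 carrying allele A,
P2 carrying allele B): the cytoplasmic maternal effect, genomic
imprinting at a nuclear QTL, and their interaction. Ordered genotypes
write the maternal allele first, so the reciprocal heterozygotes AmBf and
BmAf are distinct states; a cross direction carries a cytoplasm indicator
$m$, equal to $-1$ when the maternal cytoplasm descends from P1 (the
reference line) and $+1$ when it descends from P2.

The genotypic mean of ordered genotype $j$ in a cross with indicator $m$
is

$$\mu_j \;=\; \mu + c\,m + a\,x_a + d\,x_d + i\,x_i
          + I_{ca}\,m x_a + I_{cd}\,m x_d + I_{ci}\,m x_i,$$

with indicator coding $(x_a, x_d, x_i)$ of $(1,0,0)$, $(0,1,1)$,
$(0,1,-1)$, $(-1,0,0)$ for AmAf, AmBf, BmAf, BmBf. All effects are in
trait units. Stacking the eight classes of a design family — two
reciprocal F2 directions times four genotypes, or four backcrosses times
their two segregating genotypes — gives an invertible $8\times 8$ design
matrix, so class means and effects are in one-to-one correspondence
(`design_matrix()`, `effects_from_means()`). The condition numbers are
modest (about `r round(kappa(design_matrix("F2")), 1)` for the F2 and
`r round(kappa(design_matrix("BC")), 1)` for the backcross matrix), so the
inversion is numerically benign.

A single unified coding covers both families: the backcross rows are the
F2 rows of the genotypes that segregate in each backcross. In every row
the interaction columns are exactly $m$ times the main-effect columns.

## Genotype posteriors from flanking markers

The QTL genotype is unobserved; its posterior given the two flanking
markers supplies the mixture proportions. Both F2 gametes come from F1
parents that are heterozygous at every locus in coupling phase, so a
gamete is a haplotype governed by a Markov crossover process. We use the
Haldane map function $r = (1 - e^{-2d/100})/2$ (no interference), which is
what makes the three-point factorisation exact: the marker–marker
fraction satisfies $r_{12} = r_1 + r_2 - 2 r_1 r_2$.

Sex matters. A sex-averaged distance $d$ splits into female and male
distances $d_f = 2\lambda d/(1+\lambda)$, $d_m = 2d/(1+\lambda)$ with the
map-expansion ratio $\lambda$ (default 1.25, the genome-wide mouse
average; per-call override available). The maternal gamete is scored with
female fractions and the paternal gamete with male fractions. This is
what gives the two reciprocal heterozygotes different posterior weights:
with $\lambda = 1$ and symmetric marker data they are exactly
equiprobable, and the method collapses to classical sex-averaged interval
mapping. Two analytic facts are worth recording because they constrain
tests: at the exact midpoint of an interval, and for double-heterozygote
flanks at any position, the two heterozygote posteriors are equal for
*any* $\lambda$ (allele-complement symmetry); the asymmetry appears for
informative flank patterns such as (AB, AA).

`qtl_genotype_posterior()` enumerates the ordered (maternal, paternal)
configurations of the flanking alleles consistent with the observed
unordered codes, weighs each by its gamete-pair probability, applies the
per-gamete three-point rule, and normalises. Missing marker codes are
marginalised exactly over all compatible states rather than imputed. In a
backcross only the maternal (F1) gamete segregates and marker codes
identify the maternal allele outright, so the posterior reduces to the
female-map three-point rule. The implementation is checked in the test
suite against an independent brute-force oracle that enumerates all
ordered three-locus haplotypes of both gametes and conditions exactly;
agreement is required to $10^{-10}$.

Scan positions run from the first to the last marker of each linkage
group in `step` cM increments (default 2). A grid position that coincides
with a marker (to $10^{-8}$ cM) conditions on that marker alone — the
flanking interval degenerates to the marker itself — which discards
neighbour phase information at those isolated positions; off-marker
positions always use both flanks.

## Likelihood and EM

The phenotype model is a four-component Gaussian mixture with
design-constrained means and a common residual variance $\sigma^2$
(shared across components and cross directions):

$$\log L = \sum_i \log \sum_j \pi_{j|i}\,
  \phi\!\left(y_i;\, x_{ij}^\top\beta,\, \sigma^2\right).$$

EM maximises it: the E-step computes responsibilities proportional to
$\pi_{j|i}\phi(y_i; x_{ij}^\top\beta, \sigma^2)$; the M-step solves the
responsibility-weighted least-squares problem for the free effects and
updates $\sigma^2$ as the weighted mean squared residual (an MLE, divisor
$n$). Because the design rows take at most eight distinct values per
family, the weighted normal equations are assembled from per-(class,
component) aggregates, making each iteration O(n). Initialisation is
deterministic — one weighted least-squares pass with the prior mixture
proportions as weights — so fits are reproducible without a seed.
Convergence is declared when the log-likelihood increment falls below
$10^{-8}$ (absolute), with a 500-iteration cap; non-convergence is
flagged, not an error. The log-likelihood trace is retained and the test
suite asserts monotone ascent. The iteration loop is compiled
(Rcpp/RcppArmadillo); a reference R implementation of the identical
update is kept in the package and asserted equal in tests, alongside two
independent oracles: a brute-force enumeration of the mixture likelihood
on tiny data, and the closed-form regression fit that EM must reproduce
in one step when the genotype posteriors are degenerate.

Rank-deficient designs (for example a single cross direction, which
confounds the cytoplasmic effect with the intercept) raise an error
naming the confounded effects.

### Identifiability in the F2, and what the scan fits

An F2 cannot infer the imprinting *direction*: relabelling the two
reciprocal heterozygotes flips the signs of $i$ and $I_{ci}$ while
changing the likelihood only through the small $\lambda$-induced
asymmetry of the posteriors. The magnitude of the pair is therefore
weakly identified and the sign essentially not. This drives two design
choices:

* **The genome scan fits the estimable parameterisation.** Along the
  profile, a pure-F2 scan holds $i = I_{ci} = 0$ (`effects =
  "estimable"`, the default; `effects = "all"` frees them). Freeing the
  weakly identified pair at every grid position lets it chase noise,
  which empirically depresses the residual-variance estimate at the peak
  (mean $\hat\sigma^2 \approx 1.20$ versus 1.25 under the estimable
  parameterisation when the truth is 1.26 in the recovery study below)
  without improving position or effect estimates. Reported F2 output
  treats $i$ and $I_{ci}$ as not estimable, which is also how this design
  is conventionally reported. Backcross scans fit all eight effects —
  the backcrosses identify imprinting directly.
* **The test battery fits the full model.** Tests about $i$ need $i$
  free under the alternative, so `test_battery()` fits all eight effects
  at the tested position and `tidy()` flags `i` and `ici` as
  sign-unidentified in F2 output.

### Scan null and hypothesis tests

The no-QTL null retains the cytoplasm term, $y = \mu + c\,m +
\varepsilon$, fitted once in closed form: the cytoplasmic effect is
estimable without any QTL, and keeping it in the null prevents a pure
cytoplasmic effect from masquerading as a QTL peak. The scan statistic is
$LR = 2(\ell_{\text{full}} - \ell_0)$, clipped at zero; $LOD = LR/(2\ln
10)$. Profile ties are broken by the leftmost position.

At a detected QTL, four nested likelihood-ratio tests are run against the
full model: cytoplasmic ($c = 0$, 1 df), imprinting ($i = 0$, 1 df by
default; a joint variant zeroing $\{i, I_{ci}\}$ with 2 df is available
since either convention is defensible), all cyto-nuclear interactions
($I_{ca} = I_{cd} = I_{ci} = 0$, 3 df), and additive/dominance ($a = d =
0$, 2 df). Degrees of freedom always equal the number of zeroed effects.
P-values use the chi-square reference by default; given the weak
identification of $i$ in the F2 the chi-square reference for the
imprinting test is an approximation, and its empirical size is checked by
simulation (about 0.04–0.06 at the study's settings). Position-fixed
permutation p-values are available as an alternative; battery
permutations exchange phenotypes freely by default, which enforces each
sub-test's complete null, while genome-wide threshold permutations
stratify within cross direction by default to preserve the cytoplasmic
structure under the scan null (both behaviours can be toggled).

## The simulator

`simulate_population()` draws gametes locus by locus (markers plus the
QTL jointly, so marker and QTL states are always consistent): the first
allele is uniform, successive loci switch with the sex-specific Haldane
fraction of the interval, maternal gametes on the female map and paternal
gametes on the male map. Phenotypes are the genotypic class mean plus
Gaussian noise. The same seed reproduces a population bitwise.

The preset scenarios fix the study conditions: one 100 cM linkage group
with 6 equidistant markers, QTL at 48 cM, $\lambda = 1.25$, half the
offspring per reciprocal direction. The recovery preset
(`table_scenarios("table2")`) uses truth $(\mu, c, a, d, I_{ca}, I_{cd})
= (10, 1, 1, 0.8, 0.6, 0.5)$ with $i = I_{ci} = 0$ and residual variance
3.81, 2.04 or 1.26 at nominal heritability 0.1, 0.25 or 0.4 — the printed
variances are used directly because no equal-class-probability variance
bookkeeping reproduces them from the stated heritabilities (the
enumerated genetic variance of that truth is 2.465, implying
$\sigma^2 = 3.70$ at $H^2 = 0.4$, far from 1.26), and printed inputs
trump ambiguous formulas. The calibration preset
(`table_scenarios("table3")`) fixes all effects at 0.8 except the varied
one — cytoplasmic $c \in \{0, 0.461, 0.679\}$ or imprinting $i \in \{0,
0.680, 1.020\}$ as its variance share is 0, 5 or 10% — and calibrates
$\sigma^2$ from the heritability as $\sigma^2_g (1 - H^2)/H^2$, where
$\sigma^2_g$ is the variance of the eight class means under equal class
probabilities (Mendelian segregation, balanced directions); this is
verified in tests against the empirical phenotypic variance.

What the simulator emulates: sex-specific recombination, unordered marker
codes, reciprocal-direction structure, Mendelian segregation, Gaussian
residuals with a common variance. What it does not: genotyping error,
missing-data patterns of real panels, crossover interference, polygenic
background, multiple or sex-linked QTL, non-Gaussian traits (real
phenotypes may need the `boxcox_transform()` utility first). Passing
tests therefore certify the estimator under its own model assumptions,
not robustness to their violation.

## Replicated study and problem sizes

`run_simulation_study()` repeats simulate–scan–summarise, reading
estimates at each replicate's peak. The package's own study (also rerun
by `scripts/acceptance.R`) uses 200 replicates of the $n = 800$,
$\sigma^2 = 1.26$ recovery experiment and 500 replicates per calibration
experiment at the 2 cM scan step — sizes chosen so each study completes
in minutes on one CPU while keeping the Monte-Carlo standard error of a
5% rejection rate near 0.01. At these settings the mean peak position is
within a small fraction of a cM of the simulated 48 cM, mean estimates of
$\mu$, $I_{ca}$ and $\sigma^2$ track their truths to within Monte-Carlo
error (with the expected mild downward $p/n$ bias of the $\sigma^2$ MLE
plus a small peak-selection effect), the RMSE of $\hat\mu$ is about 0.07,
the cytoplasmic and imprinting tests hold close to their nominal 5% size
under their nulls, and the additive/dominance test has essentially unit
power at effects of 0.8.

## Numerical choices and degenerate inputs

* Distances and positions are in cM throughout; positions are absolute
  on each linkage group's map (simulated maps start at 0).
* $\sigma^2$ is floored at $10^{-12}$ inside EM; an exactly noiseless
  dataset is simulable (`sigma2 = 0`) but should be fitted with care.
* Tiny negative LR values from finite EM tolerance are clipped at zero;
  tiny log-likelihood decreases (under $10^{-6}$) at the convergence
  check are treated as numerical noise.
* Permutation thresholds use the empirical type-1 quantile, so
  `alpha = 1` returns the minimum of the null maxima.
* Scan grids always include the last marker even when the step does not
  divide the map length.
* Unknown genotype tokens on input become missing values (logged);
  missing codes are marginalised, not imputed.
* Zero-probability marker configurations (e.g. discordant homozygous
  flanks at zero recombination) raise an explicit error rather than
  returning NaN.

## Limitations

Single-QTL interval mapping shares its usual caveats: closely linked QTL
can blur into clustered peaks, and no marker-cofactor adjustment is
implemented. Standard errors are not reported (inference is by
likelihood-ratio tests, with permutation options); bootstrap position
intervals are out of scope. Two alleles per locus, autosomal loci, and a
shared residual variance are assumed throughout.
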