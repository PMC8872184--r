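---
title: "FST reduction at constrained sites: model, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FST reduction at constrained sites: model, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstpurge)
```

## The model

Consider two populations and a panel of biallelic SNPs split into a neutral
class (synonymous SNPs) and a constrained class (nonsynonymous SNPs). Write
$H_w$ and $H_b$ for the within- and between-population heterozygosity of the
neutral class. At constrained sites only a fraction of mutations — the
neutral plus the not-yet-purged slightly deleterious ones — segregate, and
that fraction differs between the within-population comparison ($f_w$) and
the between-population comparison ($f_b$): deleterious variants segregating
within a population are younger, so fewer of them have been removed by
selection. Writing $f_w = f_b(1+\eta)$, the constrained-class heterozygosities
are $H_w f_w$ and $H_b f_b$, and the Hudson fixation indices of the two
classes are

$$F_{ST}(S) = \frac{H_b - H_w}{H_b}, \qquad
  F_{ST}(N) = \frac{H_b f_b - H_w f_w}{H_b f_b}.$$

With $\eta > 0$ the constrained class is strictly less differentiated,
$F_{ST}(N) < F_{ST}(S)$. The proportional reduction

$$\rho = 1 - \frac{F_{ST}(N)}{F_{ST}(S)}
       = 1 - \frac{H_b - H_w(1+\eta)}{H_b - H_w}
       = \eta\,\frac{H_w}{H_b - H_w}$$

is linear in $\eta$ with slope $H_w/(H_b - H_w) = (1 - F_{ST})/F_{ST}$
(neutral-class Hudson $F_{ST}$). Two consequences the package asserts as
invariants:

* $\rho$ is strictly increasing in $\eta$ for any valid basis
  ($H_b > H_w > 0$);
* closely related pairs (small $F_{ST}$) have far steeper $\rho$–$\eta$
  curves than distant pairs, so the same observed $\rho$ implies a much
  smaller $\eta$ for a close pair.

The same algebra holds for the Nei/GST form with $H_T$ (total) in place of
$H_b$ and $H_S$ in place of $H_w$. Note $\eta$ inferred on the Nei basis is
a different (smaller) number than on the Hudson basis, because
$H_T - H_S = (p_1-p_2)^2/2$ per site is half the Hudson numerator; only the
sign and the qualitative size of the effect are comparable across
estimators.

`eta_from_rho()` inverts the relationship exactly,
$\eta = \rho\,(H_b - H_w)/H_w$, rather than reading predictions off a
plotted curve: the inverse is closed-form, so interpolation would add error
for no benefit. $\eta$ is carried at full precision and rounded only for
display (we quote four significant digits).

## Estimators and their combination

Per site with derived-allele frequencies $p_1, p_2$:

$$H_S = p_1(1-p_1) + p_2(1-p_2),\quad
  H_B = p_1(1-p_2) + p_2(1-p_1),\quad
  H_T = 2\bar p(1-\bar p).$$

The identity $H_B - H_S = (p_1-p_2)^2$ holds to machine precision and is
tested at tolerance $10^{-12}$. Multi-SNP estimates average the numerator
and denominator terms separately and divide the averages (ratio of
averages). The two combinations genuinely differ — for sites
$\{(1,0), (0.5,0.5)\}$ the ratio of averages is $2/3$ while the average of
per-site ratios is $1/2$ — and only the former is used.

Numerical choices, made once:

* **No sample-size correction.** Frequencies are treated as the population
  frequencies; the finite-panel correction terms $-p(1-p)/(n-1)$ are not
  applied. Panel sizes belong in metadata. With panels of dozens to
  hundreds of diploids the correction is far smaller than the bootstrap
  noise of any class examined here.
* **Zero-denominator sites** (derived allele absent or fixed in both
  populations) are excluded from both averages and counted in
  `n_excluded`. A $0/0$ term is undefined and such sites carry no
  information. Sites monomorphic in only one population are ordinary
  informative sites.
* **Negative per-site numerators** (possible under Nei when $H_S > H_T$)
  are retained; the combination is defined on sums and only the final ratio
  is the estimate. Empirical $\rho < 0$ (a constrained class more
  differentiated than the neutral class, by noise) is likewise reported
  as-is, with a warning when it propagates to a negative $\eta$; masking it
  would hide the noise level from the user.

## Uncertainty

Standard errors come from bootstrap resampling of SNPs within the class
being estimated: each of $R = 1000$ pseudoreplicates redraws $n$ sites with
replacement and recomputes the ratio of averages; the standard error is the
standard deviation (denominator $R-1$) of the replicates. The reported point
estimate is always the full-data ratio of averages, never the bootstrap
mean. Replicates whose denominator happens to sum to zero are redrawn and
counted; more than $R$ redraws aborts. The neutral-versus-constrained
comparison uses a Z statistic,
$z = (\hat F_a - \hat F_b)/\sqrt{se_a^2 + se_b^2}$, one-sided by default
since the scientific hypothesis is directional (neutral differentiation is
higher); the two-sided version is a flag away.

For $\rho$ and $\eta$ the neutral and constrained classes are resampled
independently (they share no sites, so a paired resample is impossible) and
the replicate chain re-derives the curve basis from each neutral resample,
mirroring the full pipeline. Randomness is controlled by a single master
seed from which each (estimator, class) combination receives a child seed
via a fixed counter scheme (`child_seed()`, counter
$100\cdot\text{method} + \text{class}$), so adding or removing a class never
perturbs the replicates of another.

## Stratification

Nonsynonymous SNPs are stratified by a deleteriousness C-score into seven
right-closed bins with edges at 5-point intervals: `<=5`, `(5,10]`, …,
`(25,30]`, `>30`. Only the two anchor categories ("relaxed", $\le 5$, and
"highly constrained", $> 30$) are scientifically load-bearing; the interior
edges are a conventional equal-width choice and are configurable
(`cadd_bin_scheme()`). A score exactly on an edge falls in the lower bin.
Nonsynonymous sites without a score go to an `unscored` bucket that
bin-level analyses exclude but class-level analyses keep.

The rare-variant control (`rare_filter()`) keeps sites whose derived-allele
frequency, averaged over the two populations, is strictly positive and
strictly below the threshold (default 0.5%). The pooled-mean criterion was
chosen because the control's diagnostic — that the retained neutral and
constrained classes have comparable mean frequencies — is itself stated on
per-class means; a per-population AND criterion is available via the
package's building blocks. Orientation of alleles to the derived state uses
the ancestral allele where known; both estimators are invariant under
orientation flips (a tested property), so unresolved ancestral states can
only affect rare-filter membership, never FST itself.

## What the simulator emulates — and what it does not

`simulate_panel()` is a forward Wright–Fisher model of standing variation:
each site draws an ancestral frequency, the population splits into two
independent daughters of $n_{pop}$ haploid genomes, and each daughter
evolves for $t_{div}$ generations. Neutral sites experience binomial drift
only. Deleterious sites apply the deterministic genic-selection update
$p' = p(1-s)/(1-ps)$ before each drift step. Initial frequencies follow the
classic $1/x$ spectrum on $\{1/n, \dots, (n-1)/n\}$; deleterious sites
reweight it by $e^{-2 n_{pop} s x}$, the mutation–selection skew toward rare
alleles. Defaults — $n_{pop} = 2000$, $t_{div} = 200$, $s = 0.005$ (so
$2 n_{pop} s = 20$, firmly deterministic purging), 50,000 sites per class —
were fixed a priori as a small but mechanistically faithful scenario; the
documentation seed is 20220194.

The truth label of a panel is defined the way the theory defines it:
$f_w$ and $f_b$ are the realized deleterious-to-neutral ratios of the
within- and between-population heterozygosity sums, and
$\eta_{true} = f_w/f_b - 1$ — not a function of $s$ directly. A pleasant
consequence of using the same sums in the estimator: on a complete panel
the Hudson pipeline's $\hat\eta$ equals $\eta_{true}$ algebraically, so
simulation tests of the estimation chain are exact up to the class-sum
bookkeeping rather than statistical only.

Deliberate omissions: no new mutations after the split, no demography
(growth, bottlenecks, migration), no linkage, no dominance, and C-scores
for simulated sites are a monotone map of $s$ plus Gaussian noise rather
than a functional annotation. Passing tests on these panels therefore show
that the estimation chain recovers a built-in purging signal of realistic
size; they do not show robustness to demography or linked selection, and on
real data the neutral/constrained contrast additionally depends on how
well synonymous sites approximate neutrality.

The archetype constructor (`build_archetype_panel()`) is the other half of
the validation design: panels made only of shared-polymorphism sites
$(p, p)$ and fixed differences $(1, 0)$, for which the Hudson FST of a
class with $a$ shared and $b$ fixed sites is exactly
$b/(2ap(1-p) + b)$. Scaling the fixed-difference count of the constrained
class mimics purging with a closed-form target, and the pipeline must
reproduce FST, $\rho$ and $\eta$ to $10^{-12}$.

## Validation problem sizes

The simulation study run by the test suite uses the default configuration
at divergence times $\{50, 200, 800\}$ generations with 10 seeds each
(positive-$\eta$ recovery at $t_{div}=200$; strict increase of mean
$\hat\rho$ with $t_{div}$; Hudson/Nei sign concordance), and 20 null seeds
($s = 0$, $R = 1000$ bootstrap) for calibration — the median $|\hat\eta|$
must sit below twice the median bootstrap standard error and at most 2 of
20 seeds may reach one-sided $p < 0.01$. These sizes give the rank-order
and calibration assertions comfortable margins while keeping the full
suite to a few minutes on one core.

## Known limitations

* $\eta$ is identified only as a composite; the underlying fractions
  $f, f_1, f_2, f_b, f_w$ are latent and not separately estimable from a
  two-class panel.
* The Nei-basis $\eta$ is not numerically comparable to the Hudson-basis
  $\eta$ (factor-of-two denominator difference); compare within one
  estimator only.
* Bootstrap resampling treats SNPs as independent; in dense real data,
  linkage makes the standard errors anti-conservative.
* The VCF reader computes frequencies from called genotypes
  (`alt count / (2 × called)`), dropping missing genotypes from the
  denominator; no genotype-quality filtering is attempted.
* The neutral class is taken to be all synonymous sites, unfiltered by
  C-score.
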