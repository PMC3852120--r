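---
title: "Combined genotype and haplotype region-based association tests"
author: "combSKAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined genotype and haplotype region-based association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combSKAT)
```

# The problem

Region-based association tests ask whether any of the variation inside a
genomic region — a gene plus flanking sequence — is associated with a
phenotype. Two natural summaries of that variation exist: the multi-site
*genotype* (per-variant minor-allele dosages) and the pair of
*haplotypes* each individual carries. Depending on the unknown disease
architecture, either summary can carry more signal: haplotypes tag causal
variants better when local linkage disequilibrium is informative or when
cis-interactions matter; genotypes win when a causal common variant is
poorly tagged by its haplotype background. Since the architecture is not
known in advance, combSKAT tests both and combines the two p-values into
a single region-level decision.

# The two underlying tests

Both underlying tests are variance-component score tests (SKAT) with a
linear kernel and **uniform variant weights** — no frequency-based
down-weighting, because that would handicap associations driven by common
variants. Writing $\hat\varepsilon$ for the residuals of the reduced
model $Y = a + Cc + \varepsilon$ (covariates only), the statistic for a
design matrix $X$ is

$$ Q = \frac{\hat\varepsilon^{\top} X X^{\top} \hat\varepsilon}{2\hat\sigma^2} $$

for a quantitative phenotype ($\hat\sigma^2$ the reduced-model residual
variance); for a dichotomous phenotype the denominator is 2 and the
fitted variances $\hat p_i(1-\hat p_i)$ enter the null distribution
instead. Under the null, $Q \sim \sum_k \lambda_k \chi^2_{1,k}$, where
the $\lambda_k$ are half the eigenvalues of the covariate-projected
kernel $X^{\top}(I-H)X$ (variance-weighted for the binomial family).

**Genotype design matrix.** Rare variants (sample MAF below 1% by
default, cases and controls pooled) are collapsed into a single burden
super-variant: the per-individual sum of rare minor alleles, capped at 2.
Common variants keep their own dosage columns. Missing dosages are
mean-imputed per variant first, which preserves the sample allele
frequency; the imputed contribution to the super-variant is rounded back
onto $\{0,1,2\}$. Columns whose counted allele is the major allele in the
sample (possible for derived-allele dosages from simulations) are
re-oriented before entering the rare-variant sum; for common columns the
orientation is irrelevant to $Q$ because residuals are orthogonal to the
intercept.

**Haplotype design matrix.** Haplotypes at or above 1% pooled frequency
each form their own group; all rarer haplotypes are pooled into one
group. Entry $(i,j)$ of the matrix counts how many of individual $i$'s
two haplotypes fall in group $H_j$; the most common group is the omitted
reference, so each row sums to 2 minus the individual's reference count.
When no haplotype reaches 1%, a three-bin fallback partitions haplotypes
at 0.05% and 0.1% (closed middle interval, empty bins dropped). These
cut points sit below one chromosome out of $2n$ for typical sample
sizes, so the fallback is computed on sample frequencies and logged; it
matters mainly when frequencies come from a large external pool.
Frequency ties for the reference group are broken toward the group
containing the lexicographically smallest haplotype label, making the
design deterministic.

## The mixture tail probability

The analytic p-value needs $P(\sum_k \lambda_k \chi^2_{1,k} > q)$. A
single eigenvalue is a scaled chi-square and is evaluated in closed
form. For several eigenvalues the exact tail is computed by a series
expansion into central chi-square CDFs: scaling by
$\beta = \min_k \lambda_k$ makes $Q/\beta$ a proper mixture over
$\chi^2_{m}, \chi^2_{m+2}, \dots$ whose coefficients follow a simple
recursion, so the truncation error is bounded by the unassigned mixture
mass and is driven below $10^{-9}$. When the eigenvalue spread is so
wide that the series would need more than a few thousand terms, the
moment-matched noncentral chi-square approximation of Liu-type is used
instead, and the result is tagged `moment-matched` rather than `davies`
so the choice is auditable. The same moment-matched tail, which
vectorises cheaply, also converts bulk permutation-replicate statistics
to p-values; only observed statistics use the series.

# The combined tests

Let $p_1, p_2$ be the genotype- and haplotype-test p-values and
$y_k = \Phi^{-1}(1-p_k)$ their inverse-normal transforms (large $y$ means
significant; p-values are clamped to $[10^{-12}, 1-10^{-12}]$ so the
transform stays finite). The pair $(y_1, y_2)$ is modelled as bivariate
normal with correlation $\rho$, since the two tests are computed on the
same data.

* **SumP-val** rejects for large $y_1 + y_2$, which under the null is
  $N(0,\, 2 + 2\rho)$.
* **MinP-val** rejects for small $x = \min(p_1, p_2)$; with
  $q = \Phi^{-1}(1-x)$ its p-value is
  $1 - \mathrm{BVN}(q, q; \rho)$, evaluated with a high-accuracy
  bivariate-normal CDF. At $\rho = 0$ this is $1-(1-x)^2$; as
  $\rho \to 1$ it tends to $x$.

$\rho$ is estimated by the Pearson correlation of the transformed
permutation p-values of the two tests (500 permutations by default). The
estimate is clamped to $[-0.999, 0.999]$: negative values can arise by
sampling noise and are allowed (both formulas remain valid), while the
clamp prevents a degenerate zero variance at $\rho = -1$. A directly
supplied correlation may be exactly 1, where both tests have clean
limits.

**Normality gate.** The theoretical p-values assume bivariate normality
of the transformed pair. Before trusting them, a Shapiro–Wilk test is
applied to each transformed margin with a Bonferroni factor of 2 — a
transparent, conservative proxy for a multivariate normality test. If
the minimum adjusted p-value is significant at the genome-wide level
(default $0.05/36146 \approx 1.38\times 10^{-6}$, i.e. the same
Bonferroni threshold used for association significance), the pipeline
falls back to permutation p-values: empirical add-one p-values
$(\#\{\text{replicates} \ge \text{observed}\}+1)/(B+1)$ for the
underlying tests (1000 permutations by default) and for the combined
statistics against their permuted counterparts. The add-one convention
keeps p-values strictly positive so they survive the inverse-normal
transform; ties count toward rejection, which is conservative.

# Permutation of residuals under the reduced model

Permuting the raw phenotype would destroy phenotype–covariate structure
and distort the type-I error of partial tests. Instead, the reduced
model $Y = a + Cc + \varepsilon$ is fitted once and null replicates are
formed as $Y^* = \hat\mu + \pi(\hat\varepsilon)$ for random permutations
$\pi$. Covariate effects are *not* re-estimated per replicate: the score
statistics only need $Y^* - \hat\mu = \pi(\hat\varepsilon)$, so the
permuted statistics are a single matrix product per region. For a
dichotomous phenotype without covariates the fitted value is constant
and the scheme coincides with plain case-control label permutation,
which is exact; with covariates it is the same response-scale
approximation as in the quantitative case and is documented as such.

Each replicate draws its permutation from a counter-derived sub-seed, so
the whole stream is reproducible from one seed and any single replicate
can be regenerated in isolation.

# The theoretical power model

To study the combined tests abstractly, the two underlying statistics
are modelled as $S_g = y_1^2$, $S_h = y_2^2$ with $(y_1, y_2)$ bivariate
normal, unit variances, correlation $\rho$, and means
$(\sqrt{a}, \sqrt{b})$ — so that marginally $S_g \sim \chi^2_1(a)$ and
$S_h \sim \chi^2_1(b)$. The mean parameterisation matters: means on the
NCP scale would square to noncentrality $a^2$ and break the anchor that
NCP 10.5 gives 90% power at $\alpha = 0.05$, which this package
reproduces in closed form. The weaker test's NCP defaults to $b = a/2$;
a "fraction" rule ($a$ fixed at 10.5, $b$ a fraction of it) is also
available. Powers are estimated from 500,000 simulated pairs per
scenario by default; rejection for the combined tests is decided through
the exact critical value on the $\min(p_1,p_2)$ and $y_1+y_2$ scales,
which gives decisions identical to evaluating each pair's p-value while
avoiding half a million bivariate-normal CDF calls per cell.

One caveat worth knowing: at $\rho > 0$ the construction squares the
underlying normals, and the transforms $\Phi^{-1}(1-p_k)$ recover
$|y_k|$ rather than $y_k$. Under the null ($a = b = 0$), the correlation
of the transforms is therefore below the generating $\rho$, and feeding
$\rho$ into the combined formulas makes them mildly conservative (for
SumP-val at $\rho = 0.6$, measured size ≈ 0.044 at nominal 0.05). At
$\rho = 0$, and under alternatives with non-trivial means, the effect
vanishes. The tests assert exact size at $\rho = 0$ and the conservative
direction at positive correlation.

Under this model with $b = a/2$ on an NCP grid $a \in \{1..20\}$:
MinP-val loses at most about 5 percentage points of power against the
better underlying test at $\rho = 0.9$ and gains up to about 2.8 points
at $\rho = 0$ (the exact closed-form maximum at $\rho=0$ is 2.82 pp at
$a = 8$), while SumP-val can lose well over 5 points at high
correlation — the minimum-based combination is the more robust of the
two when one test underperforms.

# The case-control simulator

The population-genetics study needs pools of region haplotypes with a
realistic site-frequency spectrum and linkage disequilibrium. The
generator builds a Kingman coalescent genealogy over the pool
chromosomes (default 40,000, i.e. 20,000 diploid "individuals"):
exponential epoch durations with rate $k(k-1)/2$ while $k$ lineages
remain, one mutation per site placed on a branch with probability
proportional to branch length, carriers being the subtree below it. This
yields an approximately neutral $1/x$ frequency spectrum — a majority of
sites below 1% minor frequency at the default pool size — and strong LD
through the shared tree (without recombination, haplotypes form a
perfect phylogeny, so a region with $L$ sites carries at most $L+1$
distinct haplotypes). The default of 33 segregating sites matches the
regime of published exon-scale simulations. What the generator does
*not* emulate: explicit demography (bottlenecks, expansion), selection,
recombination within the region, genotyping error, or phasing
uncertainty — so passing simulation tests demonstrate the statistical
machinery, not robustness to those features of real data.

Disease status is assigned by a logistic model with baseline prevalence
0.01. For a genotype-based scenario, each causal variant adds
$g_l \log(\mathrm{OR}_l)$ to the log-odds; for a haplotype-based
scenario, each of the individual's two haplotypes adds
$\log d_r$ if it is a causal rare haplotype and $\log d_c$ if it is the
causal common one. Scenarios follow the published design: "Rare" (rare
OR 4, no common causal), "Both" (3 and 1.2), "Common" (1.5 and 2), with
50%, 20% or 10% of the rare items (pool frequency < 1%) causal —
$\lceil \text{proportion} \times \#\text{rare} \rceil$ of them, sampled
uniformly — plus one uniformly chosen common item where the scenario
requires it. Causal eligibility uses *pool* frequencies; the analysis
side is blind to causality and collapses on *sample* frequencies — the
two thresholds are deliberately distinct settings. Individuals are drawn
by sampling two haplotypes with replacement proportional to pool counts
(the genotype is their element-wise sum) and kept until the 500-case /
500-control quotas are filled.

# Scales, defaults and numerical choices

* MAF and haplotype-frequency thresholds: 0.01 on the analyzed sample.
* Permutations: 500 for $\rho$ estimation, 1000 for empirical p-values;
  study harness defaults scale these down (200 permutations, 100
  replicates) so a full scenario runs on a laptop; the full
  1000 × 1000 design is a parameter change.
* The scaled null calibration run used by the test suite: 1000
  replicates of 500 cases / 500 controls, 200 permutations each, pools
  of 40,000 chromosomes shared by 5 replicates (fresh haplotype
  sampling per replicate keeps null replicates effectively independent;
  sharing pools only affects how between-pool variability averages,
  which is immaterial under the null). The empirical type-I error of
  all four tests is checked against the one-sided 99% binomial bound
  $0.067 = q_{0.99}(\mathrm{Bin}(1000, 0.05))/1000$.
* Theory surfaces default to $a \in \{1..20\}$,
  $\rho \in \{0, 0.3, 0.6, 0.9\}$ and 500,000 pairs/cell (about 1.5 s
  per cell); a fast mode (50,000) exists for exploratory runs.
* Degenerate inputs: an all-constant design matrix returns p-value 1
  with a warning rather than an error; a region with a single distinct
  haplotype is an error (the haplotype test is undefined); all-missing
  variant columns are rejected at construction; zero-variance
  permutation margins are an error in correlation estimation.
* Region mapping: variants are assigned to flank-extended (10 kb) gene
  regions; multi-gene hits resolve by the functional-category priority
  coding > intronic > 5'UTR > 3'UTR when a category column is supplied,
  otherwise by nearest gene body with a warning (the hierarchy is not
  computable without annotations). Unassigned variants form inter-gene
  blocks named by their flanking genes. Coordinates are 1-based
  inclusive on the external surface.

# Known limitations

* The three-bin haplotype fallback is rarely exercisable at typical
  sample sizes (its cut points are sub-chromosome); it exists for
  frequency maps supplied from large pools.
* Binomial-family residual permutation with covariates is a
  response-scale approximation; without covariates it is exact.
* The combined tests assume the transformed pair is bivariate normal;
  the Shapiro–Wilk gate catches gross violations but is a per-margin
  proxy, not a full multivariate test.
* Combining more than two underlying tests is a natural extension of
  the same machinery but is not implemented.

# Session info

```{r}
sessionInfo()
```
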