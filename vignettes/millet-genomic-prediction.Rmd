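---
title: "Models and methods: genomic prediction and domestication scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genomic prediction and domestication scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milletgp)
```

## Scope

`milletgp` bundles the quantitative-genetics machinery of a pearl-millet
style breeding and diversity programme: genomic prediction of line and
hybrid performance, discovery of heterotic groups among inbred parents, a
windowed wild-versus-cultivated selection scan, linkage-disequilibrium
decay, ordination and distance trees, mixed-model variance components and
heritability, single-marker association, and k-mer genome-size estimation.
Every analysis is driven either by user VCF/CSV inputs or by the built-in
synthetic-data generator, so the full pipeline runs and is tested without
any external data.

## The synthetic-data generator

The generator is first-class, tested code: it defines the statistical
conditions every downstream method is validated under.

**Genotypes.** Loci are biallelic SNPs placed uniformly on a single
chromosome, with ancestral alt-allele frequencies drawn once per
configuration (Uniform(0.05, 0.95) by default; any vector can be supplied,
e.g. a 1/p-shaped spectrum for neutral-equilibrium behaviour). Populations
diverge by the Balding–Nichols model: a population at divergence $F$ from
its ancestor draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, which
has mean $p$ and variance $F\,p(1-p)$.

A design point worth spelling out: `fst_target` is defined as the expected
*Hudson* $F_{ST}$ between the cultivated pool and the pooled wild sample.
Because two populations each at divergence $F$ from a common ancestor show
a pairwise Hudson $F_{ST}$ of about $F$, and because extra wild subgroup
scatter would inflate the pooled wild variance, the wild side's divergence
budget is split between a shared wild shift and three-subgroup scatter
(parameter `wild_subpop_fst`, capped at `3 * fst_target`) such that the
pooled wild variance still equals $F\,p(1-p)$ with $F$ = `fst_target`. The
result: strong three-group structure inside the wild sample, weak (well,
none beyond inbreeding) structure in the cultivated panel, and a realized
genome-wide $F_{ST}$ that matches the requested target by construction. At
`fst_target = 0` the model collapses to panmixia.

Cultivated lines and parent panels are fully inbred (dosages 0/2 — the
conventional reading of "inbred line", and what makes F1 genotypes
deterministic); wild accessions are Hardy–Weinberg diploids.

**Sweeps.** Domestication sweeps are emulated as frequency pushes: inside
each designated window the cultivated frequency moves toward its nearest
fixation point, $p' = (1-\delta)p + \delta\,\mathrm{round}(p)$ with push
strength $\delta = 0.95$ by default. This deliberately sidesteps coalescent
sweep machinery — what the scan consumes is the joint signature of lost
cultivated diversity and elevated differentiation, and the push produces
exactly that (including, as it turns out, strongly negative Tajima's D in
the swept windows). It does not produce sweep-shaped haplotype structure,
so haplotype-based statistics are out of scope.

**Phenotypes.** Genetic values follow the additive + dominance
architecture $g_j = \sum_i (x_{ij}-1)a_i + \sum_i 1[x_{ij}=1]\,d_i$ with,
by default, 500 causal loci, exponential additive effects of random sign
and half-scale dominance (the trait architecture is a convention, exposed
in `sim_truth()`, not an empirical claim). Trial records are generated per
genotype × year × stress × replication with environment main effects,
G×Y/G×S/G×Y×S (and optional extra G×E) interactions whose variances are
specified as multiples of the realized genetic variance; interactions
involving a single-level factor are dropped, since they would otherwise
masquerade as genetic main effects. The residual variance is then *solved*
from the line-mean heritability identity
$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_{GS}/s +
(\sigma^2_{GYS}+\sigma^2_{GE})/(ys) + \sigma^2_e/(ysr)}$$
so the realized line-mean heritability matches the target; an unattainable
target (interaction terms alone exceeding the non-genetic budget) is an
error rather than a silent clamp. Blocks are balanced and nested in
replications — a simplification of field alpha-lattice layouts; spatial
trends and unbalancedness of real trials are not emulated, which is the
main caveat when reading test results across to field data.

All generators are pure functions of (parameters, seed), using a local RNG
stream that does not disturb the caller's RNG state.

## The selection scan

Per 100-kb window (non-overlapping by default; the window and step are
parameters) and per population the scan computes:

* $S$, the segregating-site count;
* $\theta_\pi$: the sum of per-site unbiased heterozygosities
  $2\hat p(1-\hat p)\,n/(n-1)$, divided by the effective window length;
* $\theta_W = S/(a_{n-1}L)$, applied per site with each site's own allele
  count so missingness is handled exactly;
* Tajima's D from the standard 1989 constants, with the window's allele
  count taken as the median per-site count (windows with $S=0$ are
  reported missing, never zero);
* Hudson's $F_{ST}$, aggregated as a ratio of averages (summed per-site
  numerators over summed denominators) — the recommended aggregation for
  window scans of two populations; a Weir–Cockerham-style alternative was
  considered and not needed at this scope;
* the diversity-loss statistic $-\log_{10}(\pi_{cult}/\pi_{wild})$, in
  base 10 so that 1 means a tenfold loss and 0 means parity. Windows where
  either diversity is zero are flagged undefined and excluded from
  quantiles — never clamped to infinities.

Inbred samples contribute two identical alleles by default (an option
counts them as haploid). Outlier calling takes the empirical (type 7)
quantile of each statistic over the windows where both are defined and
flags windows at or above *both* thresholds — the joint rule, at the
classical unilateral 95% level or the stringent 99.5% level — then merges
adjacent flagged windows into regions. Under independent null statistics
the joint flag rate is about $(1-q)^2$; on correlated real statistics it
is larger, which is the point of requiring both.

The number of outlier regions reported on any particular dataset depends
on that dataset's window count and correlation structure; only the
procedure, not any specific region count, is reproducible here.

LD decay uses squared Pearson correlation of dosages — exact haplotype
$r^2$ for inbred lines, an approximation for heterozygous samples — in
distance bins, with the decay distance read off the binned curve by linear
interpolation at the $r^2 = 0.2$ convention. PCA imputes missing dosages
to the column mean, centres, and takes the SVD. Distance trees use the
allele-sharing distance (mean absolute dosage difference over shared
sites, halved; a dosage stand-in for sequence p-distance, which a VCF
cannot provide) and Saitou–Nei neighbour joining via `ape`, with negative
branch lengths clamped to zero and their length transferred to adjacent
branches.

## Genomic prediction

The kinship is the VanRaden-type genomic relationship matrix
$G = WW^\top / (2\sum_j p_j(1-p_j))$, $W = X - 2p$, with allele
frequencies taken from the analyzed sample itself and monomorphic markers
dropped. With missing genotypes every pairwise entry uses only the
markers observed in both samples, with a pair-specific denominator — and
reduces exactly to the dense formula on complete data. Note the expected
diagonal: about 1 for Hardy–Weinberg diploids but about 2 for fully
inbred lines, which is correct behaviour, not miscalibration.

G-BLUP fits $y = 1\mu + g + e$, $g \sim N(0, \sigma^2_g G)$. All solves
run in the eigenbasis of $G$: REML is a one-dimensional profile likelihood
in $\delta = \sigma^2_e/\sigma^2_g$ (optimized on the log scale), and the
fixed-variance path stays numerically exact down to $\sigma^2_e \to 0$,
where G-BLUP interpolates the data. Deficient directions of $V$ are
floored at $10^{-12}$ of the leading eigenvalue — a minimal directional
jitter that preserves the defining formula rather than truncating the
spectrum. Sample-frequency centring puts the all-ones vector in the null
space of $G$; the fixed mean absorbs that direction.

Cross-validation repeats a random k-fold partition (5 folds, 100 runs by
default, no stratification), re-estimates variance components on each
training set, and scores each run as the *mean over folds* of the Pearson
correlation between predicted and observed values within the held-out
fold. Computing r within each test set avoids the spurious negative
correlation that pooled cross-validation predictions pick up from
between-fold mean differences. Accuracies are reported raw and
standardized by $\sqrt{h^2}$, with $h^2$ an input (it can come from the
package's own REML) rather than a constant.

## Hybrid prediction and heterotic groups

For a cross of inbred parents with dosages $d_1, d_2$, the design codes
are $Z_A = (d_1+d_2)/2 - 1 \in \{-1,0,1\}$ and $Z_D = 1$ iff the parents
carry different homozygous genotypes. The additive + dominance
ridge-regression BLUP $y = 1\mu + Z_A a + Z_D d + e$ is solved in kernel
form with $V = \sigma^2_a Z_AZ_A^\top + \sigma^2_d Z_DZ_D^\top +
\sigma^2_e I$; unknown variance components are maximized by bounded
quasi-Newton REML on the log scale over the two marker kernels. A purely
additive truth drives $\hat\sigma^2_d$ to the zero boundary — though, as
for any boundary variance component, the REML estimate has roughly half
its mass exactly at zero and half at small positive values, which the
tests' fixed seeds account for.

Scoring all crosses of a large panel never forms the full design: with
0/2-coded homozygotes, $Z_D^{(12)} = (d_1+d_2)/2 - d_1 d_2/2$ per marker,
so all pair predictions reduce to parent-level scores plus one
parents × parents cross-product matrix. The 580-line panel's 167,910
crosses evaluate in well under a second.

Selection keeps the top $\lceil 0.001\,N \rceil$ predicted crosses with
ties at the cutoff included; for $N = 167{,}910$ that is 168. A fraction
reported as "0.1%" of this panel elsewhere corresponds to 170, a rounding
convention that cannot be recovered from the fraction alone; the ceiling
rule is adopted and both counts are documented here. Previously tested
combinations are flagged by order-insensitive pair matching.

Heterotic groups come from average-linkage hierarchical clustering (the
linkage is a parameter) of the rows of the symmetric predicted-performance
matrix, Euclidean distance, selfs excluded and absent pairs imputed by row
means; the dendrogram is cut into two groups by default and the
"heterotic gain" is reported as
$100 \times (\overline{y}_{inter}/\overline{y}_{all} - 1)$ over predicted
cross values.

## Mixed models, heritability and association

`fit_lmm()` implements EM-REML on Henderson's mixed-model equations for
models with independent random terms, with three numerical choices worth
noting: (i) Aitken acceleration of the linearly convergent EM map, with
each extrapolated step accepted only if the restricted likelihood —
computed cheaply from the MME Cholesky via the determinant identity — does
not decrease; (ii) convergence at a maximum relative component change of
$10^{-6}$ (cap 500 iterations, non-convergence is an error reporting the
last iterate), with a flat-likelihood secondary criterion so components
pinned against the zero boundary, whose relative changes never settle, do
not stall the fit; (iii) negative iterates floored at zero (boundary
REML). On balanced designs the estimates match closed-form ANOVA
method-of-moments values to $10^{-6}$, and they agree with `lme4` on
crossed designs. Fixed terms are checked for estimability incrementally,
so a confounded term is rejected by name; when the first fixed term is a
factor it is coded as cell means, which makes a genotype-fixed fit return
genotype BLUEs directly.

Heritabilities are ratios of variance components with design-count
divisors: line-mean
$h^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_{GS}/s +
\sigma^2_{GYS}/(ys) + \sigma^2_e/(ysr))$, broad-sense
$H^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_{GE}/l + \sigma^2_e/(lr))$, and
within-environment repeatability
$w^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_e/N_R)$ with environments below
$w^2 = 0.5$ droppable by `filter_environments()`.

The association scan is deliberately simple: per SNP, a fixed-effects
analysis of variance `phenotype ~ block + dosage` with a 1-df F test on
the additive dosage term (dosage coding is the biallelic-GWAS convention;
the paper trail for factor coding exists but costs a df), casewise
exclusion of missing dosages, MAF/missingness pre-filters, and
Benjamini–Hochberg q-values alongside a hard $p < 10^{-10}$ flag.
Kinship- or structure-corrected mixed-model GWAS is intentionally out of
scope; the QQ calibration (`qq_calibration()`, genomic inflation as the
median 1-df $\chi^2$ ratio) is the supplied diagnostic for judging
whether that simplicity was adequate.

## k-mer genome size

`kmer_histogram()` counts canonical k-mers (lexicographic minimum of a
window and its reverse complement — strand-collapsed, matching the
Poisson depth model) with 1-bp slide, skipping windows containing N.
`estimate_genome_size()` applies *genome size = total k-mers / peak
depth*, where the peak is the histogram mode at or above an error-depth
cutoff (default 3) that keeps low-depth error k-mers from dominating the
mode. The simulator offers both literal error-free read sampling and the
standard per-k-mer Poisson(depth) approximation; at depth 30 on a 100-kb
random genome the estimate lands within a few percent (the Poisson mode
at an integer mean of 30 is attained at 29 and 30 with equal mass, so a
±1 peak is expected, not an error).

## Problem sizes and limitations

The test and validation workloads were sized for a laptop-class single
core: panels of 100–600 samples, 1,000–30,000 loci, 400 scan windows,
50-instance duality sweeps, and six-replicate heritability recoveries —
the whole suite runs in well under a minute. These sizes are the
package's own validation choices; all methods accept larger inputs.

Known limitations: no coalescent haplotype structure in the generator
(LD-based statistics are validated on a separate copying-model
construction); no read-error or quality model in the k-mer simulator; no
multiallelic-site splitting (such records are skipped with a warning); no
spatial field models or alpha-lattice recovery beyond balanced blocks; no
structure-corrected GWAS; dosage-based r² and p-distances are
approximations for heterozygous material and exact only for inbreds.
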