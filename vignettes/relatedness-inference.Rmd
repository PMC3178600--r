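---
title: "Inferring pairwise relatedness from SNP genotypes with ibdwindow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pairwise relatedness from SNP genotypes with ibdwindow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdwindow)
```

## The problem

Large SNP cohorts routinely contain mislabeled duplicates and unannotated
relatives, and both distort downstream association, linkage and population
analyses. `ibdwindow` infers the relationship of every sample pair directly
from biallelic genotype calls (AA/AB/BB/no-call), without haplotypes,
pedigree annotation or known allele frequencies. It combines two
complementary views of a pair:

* a **genome-wide informative-IBS statistic** (the IBS2\* ratio), which
  screens thousands of pairs cheaply and is allele-frequency-free under the
  null of unrelatedness; and
* a **windowed Bayesian IBD estimator**, which scans the genome in
  overlapping windows of informative SNPs and integrates window posteriors
  into estimates (K0, K1, K2) of the Cotterman coefficients (k0, k1, k2):
  the genome-wide probabilities that a random autosomal locus shares 0, 1 or
  2 alleles identical by descent.

Only autosomes are used; X, Y and mitochondrial markers are removed by
`filter_autosomes()` before any statistic is computed.

## The IBS2\* screen

At one locus, two samples are IBS0 (discordant homozygotes, AA/BB), IBS1
(one shared allele) or IBS2. The IBS2 state is split into concordant
homozygotes and **IBS2\*** — both samples heterozygous (AB/AB). IBS0 and
IBS2\* are the *informative* states: for two unrelated members of one
Hardy-Weinberg population, at a marker with allele frequencies $p, q$,

$$P(\mathrm{IBS2}^*) = 4p^2q^2, \qquad P(\mathrm{IBS0}) = 2p^2q^2,$$

so the conditional fraction

$$\frac{\mathrm{IBS2}^*}{\mathrm{IBS0} + \mathrm{IBS2}^*} = \frac{2}{3}$$

at every marker, whatever the allele frequency. Summing counts over the
genome, `ibs2star_stat()` computes this **IBS2\*_ratio** together with the
fraction of informative SNPs, a one-sample binomial-proportion Z-test of
the ratio against 2/3 on the $m$ informative markers (variance
$\tfrac{2}{9}/m$), and a two-sided p-value. `exact_binom_p()` provides the
exact-test alternative; at genome-wide $m$ the two agree essentially always.
Relatedness pushes the ratio above 2/3 (extra IBS2\*, missing IBS0); allele
frequency differences between the two samples — population mismatch or
depressed heterozygosity such as runs of homozygosity — push it below.
A ratio above 0.70 is the conventional empirical screen for a potentially
related pair; it is exposed as `flag_threshold`.

Multiple testing over a cohort is Bonferroni-corrected at family-wise
`alpha` over the emitted pair count (the default divisor in `all_pairs()`).

## The windowed IBD model

For one pair, `build_tracks()` removes concordant-homozygote and missing
loci and forms two event tracks:

* **d0 track** — loci that are IBS0 or IBS2\*; the event is IBS0. Within an
  IBD0 region the event fraction is exactly 1/3 (the same cancellation as
  above); within a region sharing at least one allele IBD the only IBS0
  calls come from genotyping error.
* **d12 track** — loci that are IBS1 or IBS2\*; the event is IBS1. Within
  IBD1 the event fraction is modeled by the allele-frequency integral `c`
  (below); within IBD2 only errors produce IBS1.

`iter_windows()` cuts each chromosome of each track into overlapping
windows of `window_size` track SNPs (default 300) advanced by `step`
(default `window_size/3`). Windows never cross chromosome boundaries; a
tail of uncovered SNPs at a chromosome end is emitted as a partial window
when it has at least half a window of SNPs and is otherwise merged into the
last window, so telomeric signal is never discarded. Chromosomes with fewer
than half a window of track SNPs are skipped with a warning.

Per d0-track window with $k$ events among $n$ SNPs, Bayes' rule with
binomial likelihoods and prior $P(D_0) = 1/3$ gives

$$P(D_0 \mid S) = \frac{\binom{n}{k}(1/3)^k(2/3)^{n-k}\,\pi_0}
  {\binom{n}{k}(1/3)^k(2/3)^{n-k}\,\pi_0 +
   \binom{n}{k}e^k(1-e)^{n-k}\,(1-\pi_0)},$$

with genotyping error $e$ (default 0.01). Per d12-track window the
remaining mass $P(\lnot D_0 \mid S)$ is split between IBD1 and IBD2 with
likelihood success probabilities `c` and $e$ and equal sub-priors.
Likelihoods are computed in log space and posteriors clamped to $[0, 1]$.

**Reconciling the two tracks.** The tracks have different SNP densities, so
their windows span different genomic lengths. `estimate_k()` projects both
window sets onto base-pair intervals, averages overlapping windows of the
same track per position (so overlap never double-counts genome length),
multiplies the d0 posterior profile with the d12 conditional split per
position, and integrates:

$$K_j = \frac{\sum_w P_w(D_j \mid S)\, l_w}{\sum_w l_w},$$

with $l_w$ the inclusive first-to-last marker span. Positions covered by no
d0 window contribute no length; positions with d0 but no d12 coverage use
the prior 1/2 split of the non-IBD0 mass. K0 + K1 + K2 = 1 by construction.

### The parameter `c`

Within an IBD1 region the fraction of IBS1 among IBS1 + IBS2\* depends on
allele frequency. From the model's conditional-probability table
(`ibs_given_ibd()`), $f(p) = 2pq / (2pq + (1/2 - pq))$. `compute_c()`
integrates $f$ against a prior on $p$: a flat prior gives 0.479; the
default **empirical Bayes** weight applies two Bayes updates of the flat
prior with $P(O \mid p) = 1/2 + pq$ (the complement of the
concordant-homozygote chance in the working table), i.e. a weight
$\propto (1/2 + pq)^2$, giving $c = 0.5185 \approx 0.518$. Admissible
values satisfy $e < c \le 2/3$, the ceiling being $f(1/2)$.

A note on the algebra: for an IBD1 pair sharing allele $s$ with independent
non-shared alleles, the exact HWE conditional is
$P(\mathrm{IBS2}^* \mid D_1) = pq$, under which the IBS1 fraction is 2/3 at
every $p$ — the ceiling itself. The working table's $1/2 - pq$ entry (which
matches it only at $p = 1/2$) is retained because the estimator does not
depend on the distinction: the IBD1-vs-IBD2 split only requires the IBD1
event rate to exceed `c`, which in turn must exceed the error rate. We
verify empirically that K1/K2 change by less than 0.02 for any
$c \in [0.25, 0.6]$, so the published default 0.518 is used as-is.

### Window size, step and resolution

300-SNP windows were adopted because, at array-like density (roughly 300
markers per Mb before filtering), a d0 window spans ~6-7 cM — small against
IBD segment lengths but large enough that the binomial likelihood separates
a 1/3 event rate from an error-level rate decisively. Halving or doubling
the window changes sibling K2 by less than 0.05 in simulation. Because the
per-window likelihood ratio saturates, a window flips to IBD0 once roughly
30% of it overlaps an IBD0 segment; each IBD0 boundary therefore migrates
about 0.2 window-spans outward. At sparse marker density this is the
estimator's dominant error: on the desk-scale test genome (~50k markers,
windows ~13 cM) it depresses sibling K2 by about 0.03 and inflates K0
correspondingly, while leaving duplicate, parent-child and unrelated pairs
essentially exact. The step default `window_size/3` is a compromise between
smoothness and cost; results are insensitive down to `step = 1`.

## The gene-dropping simulator

`simulate_cohort()` and `simulate_scenario()` generate genotype pairs with
exact truth for validation. Founders are drawn in HWE from a configurable
B-allele-frequency spectrum (default uniform on [0.05, 0.95], a neutral
stand-in for an array's spectrum); each meiosis places crossovers by a
Poisson process at 1 cM/Mb (Haldane model, no interference) and transmits
recombined haplotypes carrying founder-ancestry labels, so the per-marker
IBD state of any pair is known exactly (`pair_ibd_truth()`,
`realized_k()`). Noise is applied after gene dropping: each call is moved
to an adjacent genotype (AA/BB to AB; AB to either homozygote) with
probability `error_rate` (default 0.01), set to no-call with `nc_rate`
(default 0.005), and optional intervals are forced homozygous to emulate
runs of homozygosity.

The default genome is desk-scale — the 22 human autosomes at 10% physical
length carrying ~50,000 markers — chosen so that validation suites with
tens of replicates complete in minutes while retaining genuine
recombination structure; `genome_model(n_markers = 870000, scale = 1)`
mirrors a genome-wide array. Built-in scenarios cover duplicate,
parent-child, full/half sibling, avuncular, first-cousin, second-cousin-
once-removed (coefficient of relatedness 1/64, the method's detection
floor with expected k1 = 0.03125) and unrelated pairs, with
`expected_k()` giving pedigree expectations.

What the simulator deliberately does not model: linkage disequilibrium
between markers, admixture or population structure, crossover interference,
genotyping-error dependence on genotype or cluster quality, and realistic
marker spacing (positions are uniform). Passing tests therefore demonstrate
correctness of the method under its own assumptions — clean HWE founders
and independent markers — not robustness to array artifacts or admixed
cohorts, where the low-ratio tail of the IBS2\* plot needs care.

## Classification

`classify_pair()` maps (ratio, K0, K1, K2, heterozygosity) to a category.
Identical pairs (K2 high) and parent-child pairs (K1 high, K2 low) require
a ratio near 1: error-free they lack informative IBS0 entirely, and at
per-call error rate $e$ a parent-child ratio concentrates near $1 - e$
(errors convert IBS1 loci to IBS0 against an IBS2\* density of $pq$), so
the default gate is $0.98 = 1 - 2e$ at the default error rate. Pairs with
substantial K1 or K2 are assigned the nearest of (k1, k2) = (0.5, 0.25)
(full sibling), (0.5, 0) (second degree) or (0.25, 0) (third degree) by
Euclidean distance. The classical sibling ratio band 0.92-0.95 observed on
array data is recorded in the rationale but does not veto a sibling call:
the band's location shifts with the cohort's allele-frequency spectrum
(under the simulator's uniform spectrum sibling ratios center near 0.91),
whereas the (k1, k2) evidence does not. K1 between 0.03125 — the 1/64
detection floor — and 0.15 is reported as `distant`; an elevated ratio
without K1 support as `high_het_artifact` (atypical heterozygosity, not
relatedness); a ratio significantly below 2/3 with below-reference pair
heterozygosity as `low_het_outlier`. All boundaries live in
`classify_thresholds()` and are reported alongside every call.

## Degenerate inputs and numerical choices

Pairs with zero informative markers are reported with null statistics, not
dropped. Monomorphic markers are retained by the readers (they contribute
only concordant-homozygote or missing states and drop out of both tracks).
Heterozygote order is normalized at parse time (BA to AB); the A/B
labelling at a marker is arbitrary (A is the lexicographically smaller
observed allele in PED input) and every statistic is invariant to swapping
it. Posterior normalization and K normalization hold to 1e-9; window
posteriors match a direct Bayes evaluation to 1e-12 on small windows where
both are computable without underflow.

## Known limitations

* The detection floor is a K1 of about 0.03 (second cousins once removed);
  more distant relationships are indistinguishable from background.
* Window-boundary migration biases K0 upward (and K2 downward) by a few
  hundredths at sparse marker density; at array density the effect is ~0.02
  or less.
* Atypically high heterozygosity can raise the IBS2\* ratio to ~0.70-0.75
  without relatedness; the classifier separates these cases by their lack
  of K1 support, but they remain a caveat for the bare IBS screen.
* Population mismatch and admixture lower the ratio below 2/3 and are
  reported only descriptively (`low_het_outlier` covers the
  homozygosity-driven case with a cohort reference).
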