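---
title: "Monitoring the genetics of a two-population fish release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring the genetics of a two-population fish release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`troutmon` implements the analysis chain used to monitor what happens,
genetically, after two distinct source populations of a fish species are
released into a previously empty water system: hybridization between the
released populations as they colonize a chain of lakes, leakage of their
genes over a one-way waterfall into native downstream creek populations,
and the management-facing "traffic-light" indicators that summarize whether
genetic change is acceptable, a warning, or an alarm. This vignette
explains the models, the estimators, the tunable parameters, and the design
choices; every number it mentions is computed by the package's tests or by
`scripts/acceptance.R`, never asserted from memory.

## The data model

All statistics operate on a `genotype_matrix`: individuals by biallelic SNP
loci, coded as the dosage (0/1/2) of a per-locus reference allele, with `NA`
for missing genotypes. Missing data are never coded as 0 and every statistic
is complete-case per locus, the convention of the classical population
genetics tools for this data type. GENEPOP (2- and 3-digit), STRUCTURE
two-row (read-only) and a plain dosage CSV are supported; in GENEPOP the
reference allele is the lexicographically smaller allele code, which is
deterministic and dialect-independent. One format caveat: GENEPOP stores no
record of alleles that were never observed, so a locus monomorphic for the
alternate allele re-reads with flipped polarity; frequency-based statistics
are unaffected.

## The synthetic study system

The simulator (`sim_config()`, `simulate_founder_freqs()`,
`simulate_release_and_spread()`) is a first-class module: it generates data
with known per-individual pedigree ancestry so that every downstream
estimator can be tested against truth.

**Founders.** Per-locus ancestral frequencies are uniform on (0.05, 0.95).
Each population pair — the two released founders, and the two native creek
demes — is drawn from a Balding–Nichols beta model,
$p_k \sim \mathrm{Beta}\!\big(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\big)$,
whose single divergence knob $F$ is calibrated by bisection (with common
random numbers, so the objective is deterministic) until the parametric
multi-locus Weir–Cockerham $\theta$ between the pair hits its target:
0.40 for the founders, 0.21 for the creeks. The first locus is made
diagnostic — fixed for opposite alleles in the two founders, fixed in the
upper creek and naturally polymorphic (frequency 0.9/0.1) in the lower one —
mirroring how a single contrasting marker can be used to identify pure
source fish in the first generations. A configurable share (default 0.3)
of strongly founder-diagnostic loci also segregates at low frequency in the
lower creek, emulating pre-existing natural polymorphism at otherwise
"diagnostic" alleles, which degrades introgression detection there exactly
as it does in real systems.

**Release and spread.** Generations are discrete and non-overlapping, five
years each. The released cohort is produced through the founder bottlenecks
(100 and 17 spawners; 1000 fry per population) and starts in the uppermost
lake of a seven-lake chain; the creek demes run in parallel from their own
frequencies. Each generation, adults migrate first and then mate at random
(two distinct parents, offspring count fixed at the deme capacity,
Mendelian transmission, pedigree ancestry = parental mean). Migration is
strictly downstream: a fish in lake $i$ moves to lake $i+1$ with probability
$\min(1, m_0 + \beta\,Q_A)$, where $Q_A$ is its true ancestry fraction from
the migratory founder, and a fish that moves may attempt a further hop from
its new position within the same generation. This cascade is deliberate: a
one-hop-per-generation rule cannot carry any gene past lake $k$ before
generation $k$, which would contradict the monitoring design this simulator
emulates (alien genes below the waterfall within four generations). From
the lowest lake, fish pass the waterfall into the upper creek with
probability `waterfall_rate` — one-way, nothing moves upstream — and creek
fish drop to the lower creek with `creek_downstream_rate`. The final cohort
also migrates before sampling, so creek samples can contain immigrant
adults.

**Defaults.** `m0 = 0.1`, `beta = 0.3`, `waterfall_rate = 0.005`,
`creek_downstream_rate = 0.02`, lake capacity 300, creek capacity 200.
These were chosen once, as a realistic configuration for a subarctic lake
chain: they produce a clear downstream ancestry cline, local
linkage-disequilibrium effective sizes of a few tens to ~100, and creek
introgression of a few percent after six generations — the regime the
analysis chain is meant for. They are study conditions, not tuning dials.

**What the generator does not emulate:** overlapping generations and age
structure, selection, density dependence beyond a fixed capacity, linked
loci (96 SNPs spread over 40 chromosomes justify free recombination), and
ecological interactions with resident species. Tests that pass on this
generator therefore certify the statistics, not those aspects of real data.

**Sampling.** `sample_population()` samples a cohort either by adult
(post-migration) location — the right choice for immigrant detection in the
creeks — or by natal deme (`by = "natal"`), the locally produced cohort.
The distinction matters: post-dispersal lake samples mix birth demes and
show a Wahlund heterozygote deficit, while the locally produced cohorts
show the small heterozygote excess expected during ongoing admixture.

## Diversity, Hardy–Weinberg, divergence

Per group and locus the package reports $H_E = 1 - \sum p^2$, the unbiased
$uH_E = \frac{2n}{2n-1}H_E$, observed heterozygosity, allele counts, and
allelic richness by hypergeometric rarefaction
$A_R = \sum_i [1 - \binom{2N-N_i}{g}/\binom{2N}{g}]$, with $g$ defaulting
to the smallest typed copy count among the compared samples. Hardy–Weinberg
deviation uses the conditional exact test (two-sided, probabilities summed
over heterozygote counts of matching parity) with Fisher's combination
across loci. $F_{IS}$, $F_{ST}$ and $F_{IT}$ are the Weir–Cockerham (1984)
variance-component estimators; multi-locus values are always ratios of
summed components, never means of per-locus ratios, and negative per-locus
components are retained in the sums. Pairwise $\theta$ significance uses
permutation of individuals between the pair (the function default is 9999
permutations; the pipeline configuration uses 199 so a default end-to-end
run stays interactive — raise `n_perm` for production reports). $F_{IS}$
significance permutes gene copies within the sample at each locus, which
enforces Hardy–Weinberg proportions while preserving allele frequencies.

A finite-sample caveat the test suite pins down: at exact Hardy–Weinberg
genotype counts (1 AA, 2 AB, 1 aa) the Weir–Cockerham $f$ is $1/7$, not 0 —
the estimator is unbiased over sampling, not zero on every HWP-proportioned
sample; it approaches 0 as the sample grows.

Between-sample relationships use Nei's
$D_a = 1 - \frac{1}{L}\sum_l \sum_u \sqrt{x_{lu} y_{lu}}$ and a
neighbor-joining tree (via `ape::nj`) with negative branch lengths clamped
to zero and the deficit moved to the sister branch. Bootstrap support
resamples loci with replacement (default 1000 replicates) and counts
bipartitions of the point tree.

## Supervised ancestry and introgression

Ancestry against fixed baselines replaces a full Bayesian clustering run:
the analyses it supports condition on baseline samples anyway, and with 96
informative loci the likelihood in $Q$ is sharply peaked, so the maximum
likelihood point estimate is sufficient and orders of magnitude faster.
For individual genotype $g_l$ and baseline frequencies $p_{kl}$,
$\ell(Q) = \sum_l [\,g_l \ln \sum_k Q_k p_{kl} + (2-g_l)\ln \sum_k Q_k(1-p_{kl})]$
is maximized over the simplex by EM from a uniform start (tolerance
$10^{-8}$ on the log-likelihood, cap 2000 iterations; the trace is stored
and is non-decreasing by construction). Baseline frequencies are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2n+2)$ — the weak
uniform-prior guard against $-\infty$ likelihoods from alleles unobserved
in a finite baseline. An unsupervised block-EM variant (joint $(Q, P)$,
multiple restarts) is provided for checking that the data support the
expected cluster structure; the number of clusters is a user input, model
selection is out of scope.

Classification rules follow the monitoring conventions: lake fish are
called A when $Q_A \ge 0.75$, B when $Q_A \le 0.25$, hybrids otherwise
(boundaries belong to the pure groups); purity cutoffs are
$\max Q \ge 0.99$ (strict) or $> 0.75$ (relaxed). In the creeks, a fish
assigned less than 0.25 to the locality where it was caught is an
immigrant, and a lower-creek fish assigned at least 0.75 to the upper creek
is a downstream immigrant (this call takes precedence). Introgression is
the mean alien ancestry $Q_A + Q_B$ among non-immigrants; the total alien
contribution, including the immigrants themselves, is reported alongside.
Only mass on the released-population baselines counts as introgression;
mass on the other creek's baseline does not.

One honest limitation, measured by the tests: introgression estimates have
a one-sided noise floor. When the waterfall is sealed in the simulator the
true alien fraction in the creeks is exactly zero, but the estimate sits
around 1–2.5%, because the creek samples drift away from their pre-release
baselines over 4–6 generations and $Q$ cannot go negative. Estimates of a
few percent should therefore be read against this floor, and the floor
shrinks as baselines grow and the monitoring interval shortens.

## Effective population size

Two estimators, chosen to mirror standard monitoring practice.

**Linkage disequilibrium.** For each pair of loci passing the
minor-allele-frequency screen (default `maf = 0.02`), the Burrows composite
disequilibrium from unphased genotypes,
$\hat\Delta = \frac{n}{n-1}\big[\frac{\sum_i X_i Y_i}{2n} - 2\hat p \hat q\big]$,
gives $\hat r^2 = \hat\Delta^2 / [\hat p(1-\hat p)\hat q(1-\hat q)]$. The
mean over pairs (weighted by pairwise sample size) is corrected by the
random-mating sampling expectation ($1/S + 3.19/S^2$ for $S \ge 30$, the
small-sample constants otherwise) and inverted to
$\hat N_e = (1/3 + \sqrt{1/9 - 2.76\,\hat r^2{}'})/(2\hat r^2{}')$, with the
matching small-sample constants for $S < 30$; a non-positive corrected
$r^2$ or negative discriminant reports $\infty$ — no drift signal. The
parametric CI treats the number of pairs as chi-square degrees of freedom.
Only the random-mating model is implemented.

**Temporal.** The standardized variance pooled over loci,
$F_s = \sum_l (x_l - y_l)^2 / \sum_l z_l(1-z_l)$ with $z = (x+y)/2$, is
corrected for finite samples under sampling plan II (individuals sampled
before reproduction and not returned),
$F_s' = [F_s(1 - \frac{1}{4\tilde n}) - \frac{1}{\tilde n}]/(1 + F_s/4)$
with $\tilde n$ the harmonic mean sample size, and
$\hat N_e = t/(2F_s')$ for $t$ elapsed generations (computed from years and
the five-year generation length). The CI is a jackknife over loci. The
plan-II assumption is consequential: the recovery tests sample juvenile
cohorts binomially from the gamete pool; sampling a large fraction of a
small census without replacement would overstate the correction and push
estimates to $\infty$.

Both estimators are validated by Wright–Fisher recovery (true $N_e = 50$,
$S = 50$ for LD; true $N_e = 100$, $t = 2$, $S = 60$ for temporal; 200
replicates each in the acceptance suite) rather than by transcribing any
published worked example. `harmonic_mean_ne()` combines per-time-point LD
estimates, with infinite values contributing zero to the reciprocal sum.

## The traffic-light indicators

Three indicators, each deterministic given its inputs:

* **ΔH** (per measure: $H_E$, $H_O$, $A_n$, $A_R$). The observed change
  over $t$ years is converted to a 100-year retention assuming a constant
  proportional rate, $(\text{after}/\text{before})^{100/t}$ — compounded in
  years, not generations, because the indicator system is policy-facing;
  a generations clock can be emulated by passing generation-years.
  Non-significant change is green; a significant decrease is green at
  retention ≥ 95%, yellow in [75%, 95%), red below 75%; a significant
  increase is yellow when attributable to anthropogenic activity (an
  external flag supplied by the analyst — the package cannot know it) and
  green with a note otherwise. Significance is the locus-paired Wilcoxon
  matched-pairs test (zero differences dropped; exact for ≤ 25 informative
  pairs, else normal approximation with continuity correction), with the
  paired t reported alongside; the nonparametric test is primary because
  per-locus heterozygosities are bounded and skewed. α = 0.05 two-sided,
  no multiple-testing correction on the gate. Per-measure statuses are
  reported separately (they genuinely diverge; a worst-status roll-up is a
  reporting convention, not a statistic).

* **Ne** (50/500 rule). Because both estimators tend to underestimate the
  inbreeding effective size in subdivided systems, the indicator takes the
  largest of the temporal estimate and the harmonic-mean LD estimate.
  Above 500 is green, (50, 500] yellow, ≤ 50 red — exactly 500 is yellow
  and exactly 50 is red, following the strict inequalities of the printed
  thresholds.

* **ΔFST.** The divergence between the monitored populations at each time
  point is mapped to an effective number of migrants with the island model,
  $N_m = (1/F_{ST} - 1)/4$, and the percentage change in $N_m$ is
  classified: a significant 50–100% increase or 25–50% reduction in gene
  flow is yellow, a > 100% increase or > 50% reduction is red, anything
  else green. The island-model mapping is an inference — the indicator
  definition does not print its formula — adopted because it exactly
  reproduces the published worked example in which lowering the warning
  threshold from a 50% to a 40% increase would flip the 0.21 → 0.16 creek
  comparison to a warning (the mapping gives +39.6%, i.e. 40% to the
  nearest percent). Significance gating uses the locus-paired Wilcoxon test
  on per-locus $\theta$ — a convention chosen here, since the indicator
  definition does not fix the test.

## Pipeline and reproducibility

`run_monitoring()` chains the stages — simulate, build baselines (released
populations by diagnostic-locus homozygosity in the first post-release
cohort; creeks from their pre-release samples), assign ancestry, compute
diversity and F-statistics, estimate $N_e$ per time point and period,
classify indicators — and writes nine artifacts (diversity, F-statistics,
Q matrix, group calls, introgression, Ne records, indicator report, Newick
tree, manifest). A single global seed fans out to per-stage seeds by
hashing the stage name (`stage_seed()`), so stages are individually
reproducible; the manifest records MD5 digests of every artifact and two
runs with the same seed produce identical digests. The
`troutmon` CLI (`inst/cli/troutmon`, or `troutmon_cli()` in R) exposes six
subcommands — `simulate`, `stats`, `assign`, `ne`, `indicators`, `report` —
as thin wrappers over these functions.

Problem sizes in the shipped tests are the package's own choices for a
thorough-but-interactive suite: 200 Wright–Fisher replicates per $N_e$
recovery claim, 100 replicates for introgression recovery, 50 seeded
replicates of the full default simulation for the qualitative pattern
checks (downstream ancestry cline, admixture-elevated heterozygosity,
heterozygote excess in the locally produced lake cohorts), and reduced
permutation counts in end-to-end pipeline tests.

## Known limitations

* Posterior uncertainty on $Q$ is not quantified (ML point estimates only).
* The LD estimator implements only the random-mating model; monogamy and
  age-structure corrections are out of scope, and in subdivided systems
  both estimators read low relative to the inbreeding effective size — the
  indicator's max rule is a partial, not a full, remedy.
* The introgression noise floor described above.
* $D_a$ is not a metric; only symmetry and range are guaranteed.
* The unsupervised EM finds a local optimum per restart; the number of
  restarts, not any convergence theory, is the safeguard.
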