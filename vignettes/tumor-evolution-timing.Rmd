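---
title: "Inferring tumor subclonality and the molecular timing of somatic events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor subclonality and the molecular timing of somatic events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonechron)
```

## The problem

A single deeply sequenced tumor biopsy carries a surprising amount of
chronological information. Somatic point mutations accumulate throughout a
tumor's life; when a chromosome (or the whole genome) is later duplicated,
the mutations already present on the duplicated copies are duplicated with
them. At biopsy, a mutation present on two of the segment's copies
(multiplicity 2) must predate the duplication, while a single-copy mutation
on a duplicated segment must postdate it. Read counts therefore let us order
chromosome-scale copy-number events — copy-neutral LOH with duplication
(uniparental disomy), trisomy gains, whole-genome duplication (WGD) — along a
"molecular clock" whose unit is the fraction of the tumor's biopsy-time
mutation load, and to place individual driver mutations into time intervals
relative to those events.

clonechron implements that inference for a single tumor/normal pair:
contamination estimation and correction, allelic copy-number analysis,
VAF clustering, multiplicity-based event timing, WGD detection, and clone
tree assembly, plus a generative simulator used to validate every stage.

## The mixing model

The sequenced sample is a mixture of tumor cells (purity $1-\alpha$) and
diploid normal cells (contamination $\alpha$). All observables follow from
one linear mixing model. A mutation on $m$ of $n_t$ tumor copies, carried by
a fraction $f$ of tumor cells, is observed at

$$v = \frac{(1-\alpha)\,f\,m}{(1-\alpha)\,n_t + 2\alpha},$$

and a segment with minor-allele copy number $n_{minor}$ shows a lesser
allele fraction (LAF) of

$$\ell = \frac{(1-\alpha)\,n_{minor} + \alpha}{(1-\alpha)\,n_t + 2\alpha}.$$

With $\alpha = 0$ these reduce to the familiar lattices: heterozygous clonal
mutations on diploid chromosomes at VAF 0.5, single-copy mutations on
tetraploid chromosomes at 0.25, trisomy mutations at 2/3 (pre-gain) and
1/3 (post-gain), and LAF 1/3 for the state AAB. `correct_vaf()` and
`correct_allelic_cn()` invert these forms exactly; the inversions are
identities on the forward model to numerical precision, which the test suite
checks property-style.

These closed forms are the unique linear mixture of a tumor compartment with
a diploid normal compartment; nothing beyond that assumption enters.

## Estimating contamination

`estimate_purity()` performs a grid search over $\alpha \in [0, 0.5]$
(step 0.005 by default; the objective is non-convex and a grid is cheap and
exactly reproducible). The objective sums two terms, weighted 1:1:

1. **Allelic copy number.** After correction at the candidate $\alpha$,
   every clonally imbalanced segment should land on an integer
   (major, minor) pair; the mean squared distance to the nearest pair is
   penalized. Un-clipped corrected values are used, so over-correction
   (negative minor copies) is penalized symmetrically.
2. **VAF mode.** The dominant mode of somatic VAFs on balanced diploid
   chromosomes, found by kernel density estimation with Silverman's
   bandwidth (robust to subclonal tails), should correct to a lattice value
   $m/2$. Because the correction is linear in VAF at fixed copy number, the
   mode is computed once on the observed scale and transformed analytically
   per candidate — the optimum is identical to re-running the KDE on
   corrected values.

Ties are broken toward smaller $\alpha$, and sex chromosomes are excluded
(single-copy states are ambiguous there). Recovery on simulated tumors is
within $\pm 0.03$ across the contamination range 0–0.33 at 105x coverage.

## Subclonal copy number and mutations

A clonal segment has integer allelic copy number after correction; a mixture
of two tumor lineages does not. `detect_subclonal_cna()` accepts a segment
as clonal when the nearest integer state is within $\varepsilon = 0.05$ in
both the copy-number and LAF coordinates (about two binomial standard
deviations at ~100x; exposed as an argument). Otherwise it solves the
two-state mixing equations

$$\mathrm{cn} = (1-\varphi)\,c_1 + \varphi\,c_2, \qquad
  \mathrm{minor} = (1-\varphi)\,a_1 + \varphi\,a_2$$

by least squares over candidate second states within one copy per allele of
the nearest state (a parsimony bound), and reports the candidate and mixing
fraction $\varphi$ with minimal residual. Fits with $\varphi$ outside
(0.05, 0.95) are rejected as indistinguishable from purity error.

Subclonal *mutations* are found by `cluster_vafs()`: a binomial mixture over
each mutation's own read counts (depth varies per site, so a binomial — not
Gaussian — component likelihood is the natural choice), fitted by EM for
$k = 1..5$ with the Bayesian information criterion selecting $k$.
Initialization is quantile-based with ten jittered restarts under a fixed
seed; each restart gets a short EM burn-in and only the best is polished to
convergence, which is the standard way to keep multi-start EM cheap without
losing the global optimum. A mutation is flagged subclonal by the simple
operational rule that its corrected VAF lies more than 0.10 (absolute, in
VAF units; the deviation could also be read as relative, and the threshold
is an argument) below the clonal expectation of its copy-number context —
one-sided, since mutations above the expectation reflect multiplicity, not
subclonality. At 105x, simulation places the detection limit for a
10%-of-mutations subclone at VAF 0.1 or below (`detection_limit()`).

## Timing estimators

Under a constant per-copy accumulation rate $\lambda$ (per Mb per unit
molecular time) on a segment of length $L$, an event at molecular time $t$
partitions mutations into multiplicity classes with Poisson means:

| event (AB →) | $E[N_2]$ | $E[N_1]$ | estimator |
|---|---|---|---|
| AA (CN-LOH + duplication) | $\lambda L t$ | $2\lambda L(1-t)$ | $\hat t = 2N_2/(2N_2+N_1)$ |
| AABB (tetrasomy / WGD) | $2\lambda L t$ | $4\lambda L(1-t)$ | $\hat t = 2N_2/(2N_2+N_1)$ |
| AAB (trisomy) | $\lambda L t$ | $\lambda L t + 3\lambda L(1-t)$ | $\hat t = 3r/(1+2r),\ r = N_2/N_1$ |

Each estimator is an algebraic identity on the expected counts (tested on a
grid of $t$) and is validated against a brute-force generative oracle.
Notes on the derivation: in CN-LOH, pre-event mutations on the lost allele
vanish, so only the retained allele contributes $N_2$; in trisomy, a
pre-event mutation on the *unduplicated* allele stays at multiplicity 1,
which is why $E[N_1]$ has a $\lambda L t$ term and why a multiplicity-1
mutation on a trisomic segment gets the uninformative interval $[0, 1]$.
CN-LOH is modeled as a single timed loss-then-duplication; the estimator is
identical if both alleles duplicated first and two copies were lost later,
so the order ambiguity does not affect $\hat t$.

Multiplicities are assigned per mutation by maximum binomial likelihood over
$m \in 1..n_{major}$ at the contamination-adjusted lattice (`assign_multiplicity()`),
with ties to the smaller $m$. Mutations flagged subclonal are excluded
before counting: subclonal mutations postdate the clonal events by
definition, and leaving them in inflates $N_1$ and biases $\hat t$ downward
(a 30% subclone shifted trisomy times by about $-0.1$ in simulation before
this filter).

Confidence intervals come from multinomial resampling of the counts
(percentile 95%, 200 resamples by default) — a pragmatic choice; there is no
canonical interval for these ratio estimators.
Segments whose state cannot be reached from AB by a single event (AAAB,
hexasomies, ...) are reported `"complex"` and left untimed rather than
guessed.

`detect_wgd()` calls whole-genome duplication when at least half the
autosomal genome (by length) is AABB-consistent after correction, times each
tetraploid chromosome independently, and reports the standard deviation of
the per-chromosome times: a single endoreduplication predicts concordant
times (SD < 0.05 in simulation at the default rates), while two independent
half-genome tetrasomies produce an SD above 0.2 and are thereby flagged.
`fusion_duplication_test()` orders a rearrangement junction against the WGD
by comparing the junction read count under binomial likelihoods at 2/4
versus 1/4 of local depth, requiring a likelihood ratio of 3 (a pragmatic
default; there is no canonical statistic for this test).

The whole framework leans on rate constancy across chromosome-scale
segments; `rate_consistency()` checks it by regressing per-chromosome
mutation counts on chromosome lengths through the origin and reporting the
squared Pearson correlation (the through-origin $R^2$ of `lm` is inflated by
construction and useless as a diagnostic, so the correlation is reported
instead). Uniform-rate simulations with ~4,000 mutations give $r^2 > 0.98$.

## Clone trees

`build_timeline()` sorts clonal events and mutation intervals (summarized at
their midpoints, i.e. the median of a uniform interval) along the trunk with
deterministic tie-breaking, and groups subclonal calls into branches by cell
fraction (fractions within 0.05 merge; a spread above 0.1 forces sibling
branches with a warning). The divergence time of a subclone is not
identifiable from one biopsy, so branches attach at the end of the trunk;
branch thickness information is carried as $\varphi$. `cohort_summary()`
assembles the lesion-by-tumor occurrence/time matrix, and `as_newick()`
serializes the tree with molecular-time branch lengths.

## The simulator, and what passing tests do and do not show

`simulate_tumor()` draws data from exactly the generative model above:
Poisson mutation counts per multiplicity stratum, binomial read counts at
the forward-model allele fractions, Poisson depth (negative-binomial
overdispersion is deliberately not the default), and germline het sites
whose alt allele lands on either parental lineage with equal probability.
Defaults mirror the study conditions the package targets: 105x mean
coverage, contamination defaulting to the cohort median 0.16 (range 0–0.33
in tests), $\lambda = 0.7$ mutations/Mb/copy/unit time (≈4,000 mutations on
a diploid full-length genome, the load of a heavily mutated
fusion-negative tumor), het density 0.5 sites/kb (typical human
heterozygosity; tests use sparser sites and 5–10%-scale genomes with
$\lambda$ scaled up so per-segment mutation counts stay at the full-scale
level — the vignette-stated problem sizes are the package's validation
choices). One branching subclone is the default topology, matching the
dominant-clone-plus-minority-subclones architecture the method assumes;
after branching, only subclone-private mutations are emitted (the dominant
lineage's private mutations are folded into the clonal set, a good
approximation when $\varphi$ is small).

What the simulator does *not* emulate — and hence what green recovery tests
cannot certify on real data: mapping and sequencing artifacts, GC and
replication-timing variation in the local mutation rate, segmentation error
upstream of the segment table, kataegis and other clustered mutational
processes, overdispersed coverage, and multi-event copy-number histories on
one segment.

A note on the LAF estimator: the naive folded per-site read ratio
$\min(v, 1-v)$ is biased downward near 0.5 ($E \approx 0.46$ at 105x for a
true 0.5), which in early testing distorted the purity objective and
spuriously flagged tetraploid segments as subclonal. `estimate_laf()`
therefore removes the binomial sampling variance by default: per site,
$(v - \tfrac12)^2 - v(1-v)/(d-1)$ is an unbiased estimate of
$(p - \tfrac12)^2$, and the segment LAF is $\tfrac12$ minus the square root
of the (depth-weighted, floored at zero) mean. The raw folded mean remains
available via `debias = FALSE`.

## Numerical choices and degenerate inputs

Zero-depth records are dropped (not errors) since real call sets contain
them; LAF values above 0.5 are mirrored; corrected VAFs above 1 are clipped
with a flag; negative corrected copy numbers are clipped with a flag in the
user-facing correction (but not inside the purity objective). EM runs at
most 500 iterations with a relative log-likelihood tolerance of $10^{-7}$
and warns if the selected model did not converge; all-identical VAFs
collapse to a degenerate single cluster. State search is bounded at total
copy number 8. All stochastic routines take explicit seeds and restore the
caller's RNG state.

## Worked example

```{r example, eval = FALSE}
fx <- make_fixture("pfn_like", dir = tempdir())
muts <- read_mutations(fx$paths$mutations)
hets <- read_het_sites(fx$paths$het_sites)
segs <- read_segments(fx$paths$segments)
res <- analyze_tumor(muts, hets, segs, seed = 1)
print(res)
as_newick(res$timeline)
```

The fixture mirrors a fusion-negative genome: uniparental disomy of chr11
and chr9 at molecular time 0.14 (with trisomy 8 at 0.08 preceding it and a
late trisomy 20 at 0.98), 12% contamination, and a 45% subclone carrying a
private chr14 gain. The analysis recovers the contamination, the event
order, and the subclone fraction; the README shows the printed output.

## Known limitations

Single-biopsy design: subclone branch times and nesting are not resolved;
mutation times are intervals, not points. Segments with multi-event
histories are flagged, not decomposed. Purity and ploidy are not jointly
optimized across samples, and tumor-in-normal contamination is out of
scope. Calendar-time conversion of molecular time requires an external
clock and is deliberately not provided.
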