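---
title: "Chromosome arm aneuploidy: calling, co-occurrence and acquisition order"
author: "caatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome arm aneuploidy: calling, co-occurrence and acquisition order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caatools)
```

# Overview

Whole chromosome arms are gained and lost in most solid tumours, and these
arm-level events - chromosome arm aneuploidies (CAAs) - behave differently
from focal amplifications and deletions: they arrive in characteristic
orders during tumour evolution, co-occur in non-random combinations, and
shift drug response in cell-line panels. `caatools` implements the
computational chain that turns segmented copy-number profiles into such
analyses:

1. an **arm-level caller** (`compute_arm_fractions()`, `call_caas()`) from
   SEG-style segment tables;
2. **whole-genome doubling** detection (`call_wgd()`) from allele-specific
   copy number;
3. exact **gain:loss bias expectations** and the associated tests
   (`expected_gl_fractions()`, `gl_bias_test()`, `gl_bias_by_burden()`);
4. a **karyotype-tree transition model** for the order in which CAAs are
   acquired (`build_karyotype_tree()`, `transition_matrix()`);
5. a combinatorial **pairwise co-occurrence model**
   (`cooccurrence_pmf()`, `pairwise_cooccurrence_scan()`);
6. a pharmacogenomic **synthetic-lethality screen** (`sl_sr_screen()`)
   over binary feature and drug-response matrices;
7. seeded **synthetic-data generators** (`sim_*()`) that emulate the
   statistical structure of each input, so the whole chain is testable
   without access to restricted tumour or cell-line cohorts.

# The arm-level caller

## Model and assumptions

The caller consumes per-sample genomic segments with log2 copy-number
ratios (the output of standard array or sequencing segmentation pipelines)
and an arm model: arm and centromere intervals per chromosome. The
built-in model covers the GRCh37/hg19 autosomes with centromeres taken
from the UCSC cytogenetic bands; 39 arms are scored (the 44 autosomal arms
minus the acrocentric short arms 13p, 14p, 15p, 21p and 22p, which carry
no unique sequence), giving 78 signed events - one gain and one loss per
arm. Sex chromosomes are excluded because their copy number is
confounded by patient sex.

Processing steps, in order:

* **Centromere filter.** Any segment overlapping a centromere interval by
  at least 1 bp is discarded outright. Segmentation output that crosses a
  centromere is almost always an artefact of joining the two arms across
  unmappable sequence.
* **Optional recentring.** Upstream pipelines usually deliver ratios that
  are already ploidy-relative, so the default is no recentring. With
  `recenter = "weighted_median"` each sample's segment means are first
  shifted by its covered-length-weighted median, a cheap guard against a
  globally shifted profile.
* **Clipping and summation.** Surviving segments are clipped to arm
  boundaries. Per sample and arm, `covered_bp` sums all clipped lengths;
  `gain_bp` sums lengths with segment mean strictly above `amp_thresh`
  (default `0.2`); `loss_bp` strictly below `del_thresh` (default
  `-0.2`). These are the conventional thresholded copy-number cut-offs on
  the log2 scale; strictness matters only for segments sitting exactly on
  the threshold, which are counted as neutral.
* **Arm call.** An arm is called gained (`+1`) when
  `gain_bp / covered_bp >= 0.9`, lost (`-1`) when the loss fraction
  reaches 0.9, else neutral. The 0.9 cut-off (inclusive) tolerates
  background noise, intra-tumour heterogeneity and focal events on an
  otherwise aneuploid arm, while `0.9 + 0.9 > 1` over a shared
  denominator makes gain and loss calls mutually exclusive by
  construction; `call_caas()` therefore refuses `call_frac <= 0.5`.
  Hemizygous and homozygous losses are deliberately not distinguished.
* **Uncallable arms.** Arms without covered length are called 0 and
  flagged, rather than dropped; `min_covered_frac` optionally raises the
  bar (default 0, i.e. no minimum beyond non-zero coverage).

Coordinates are handled internally as 0-based half-open; `read_segments()`
converts from the 1-based inclusive SEG convention by default
(`seg_dialect(one_based = FALSE)` for data already half-open).

## Whole-genome doubling

`call_wgd()` implements the majority-allele rule: a sample is WGD-positive
when strictly more than half of its autosomal covered length carries two
or more copies of the more frequent parental allele. The rule needs
allele-specific copy number (`major_allele_cn`); without it the status is
reported as `NA` rather than guessed.

# Gain:loss bias expectations

Within a tumour carrying `a` CAAs, compare the number of gained arms `G`
with the number of lost arms `L`. Under the null that each event is
independently a gain or a loss with probability 1/2,

* `P(G > L) = 1/2 - C(a, a/2) / 2^(a+1)` for even `a`, and `1/2` for odd
  `a`;
* `P(G = L) = C(a, a/2) / 2^a` for even `a`, and 0 for odd `a`;
* `P(G < L) = P(G > L)` by symmetry.

`expected_gl_fractions()` evaluates these with log-binomial coefficients;
the implementation computes the tie probability first and sets the two
strict orderings to `(1 - tie)/2`, so the three fractions sum to 1 exactly
in floating point. Cohort-level expected counts follow by scaling with the
observed burden histogram (`expected_gl_counts()`), and the comparison to
observed class counts is a Pearson goodness-of-fit chi-square without
continuity correction (`gl_bias_test()`); categories with zero expectation
are pooled into the largest remaining category. Departures from this null
- for example an excess of gain-dominated low-burden tumours - are the
signature of biased early evolution.

`gl_bias_by_burden()` conditions on the untied samples at each burden and
tests the G>L count against a symmetric binomial; the p value is the
exact two-sided tail obtained by doubling the smaller tail and capping at
1. Doubling was chosen over the minimum-likelihood two-sided convention
because it is monotone in the one-sided tail and therefore stable across
burden strata; at even burdens the tied class is excluded, so the
conditional null proportion remains 1/2.

For the paired gains-versus-losses comparison within samples
(`compare_burden(paired = TRUE)`), zero differences are dropped (the
classical signed-rank treatment) and the null distribution of the
statistic is enumerated exactly over all sign assignments when 15 or
fewer non-zero differences remain - necessary because tied absolute
differences (ubiquitous in small integer counts) invalidate the standard
exact tables; beyond that, a normal approximation on the tied-rank
variance is used.

# Ordering CAA acquisition on a karyotype tree

## The tree and the transition estimate

Each sample's karyotype is its set of signed CAA events. Karyotypes live
on a levelled tree: level `k` holds all karyotypes with `k` events, edges
add one compatible event, and each observed karyotype carries its cohort
frequency. The transition probability from event `x` to event `y` is
estimated as

```
P(x -> y) = W(x -> y) / sum_z W(x -> z)
```

where, under the default single-edge semantics, `W(x -> y)` is the summed
frequency of observed karyotypes containing both `x` and `y` (every such
karyotype is the child of an edge whose parent - the karyotype minus `y`
- contains `x`; parents need not themselves be observed). The row
denominator equals `sum over karyotypes u containing x of
freq(u) * (|u| - 1)`, so each row of the matrix sums to 1, or to 0 for
events never observed in a karyotype of size at least two. Samples with
fewer than two events contribute nothing. The gain and the loss of one
arm can never co-occur and their transitions are structurally zero. On
the default arm model the result is the 78 x 78 matrix written by
`export_transition_matrix()`.

## What the estimate can and cannot identify

A caveat that users of the transition matrix should understand: the
single-edge numerator is **symmetric** in `x` and `y`, so the comparison
of `P(A -> B)` with `P(B -> A)` is decided entirely by the two row
denominators - that is, by how much total co-event mass each event
carries - and not by any direct record of which event came first. Sets of
events contain no within-karyotype order information, and under a forward
model in which tumours truncate a preference-biased acquisition sequence,
the earlier event accumulates the *larger* denominator, which pushes the
comparison the wrong way. The package therefore also provides
`transition_matrix(semantics = "path")`, which scores multi-step paths
between *observed* karyotypes (start node observed, containing `x` and
lacking `y`; end node observed, having attained `y`; contribution
`freq(start) * freq(end)`). Conditioning on observed starting karyotypes
retains the genuine order signal in the data - the asymmetry between
karyotypes carrying `A` without `B` and karyotypes carrying `B` without
`A` - and in simulations with a planted 0.9 acquisition preference it
ranks the planted direction correctly in most cohorts, whereas the
single-edge estimate does not. The single-edge form remains the default
because it is the exact closed form of the levelled-tree edge model, is
reproducible against a brute-force edge enumeration, and keeps rows
exactly stochastic; the path variant is the recommended exploratory check
whenever directionality is the question of interest.

# Pairwise co-occurrence

The probability that two events present in `N1` and `N2` of `N` samples
share exactly `k` samples under random placement is a ratio of binomial
coefficients equal to the hypergeometric mass with population `N`, `N2`
successes and `N1` draws. `cooccurrence_pmf()` evaluates the ratio in log
space (stable to the full grid of `N <= 25` at 1e-12 and far beyond);
`cooccurrence_tails()` returns upper and lower tails, both inclusive of
the observed count - the conservative convention, since the shared mass
at `k` keeps `p_gt + p_lt >= 1`. `pairwise_cooccurrence_scan()` applies
this to all event pairs (same-arm gain/loss pairs excluded a priori),
adjusts the upper-tail and lower-tail families separately with
Benjamini-Hochberg (matching the separate tallies of positive and
negative co-occurrence; `fdr_family = "pooled"` merges them), and
classifies pairs at `alpha`. Because the null is discrete, the realised
upper-tail false-positive rate on independent data sits below the nominal
level.

# The pharmacogenomic screen

Binary feature matrices (gene mutations, focal copy-number segments, CAA
signed events) are assembled over the shared cell-line universe by
`assemble_features()`; with the conventional panel of 710 cancer
functional events plus the 78 CAAs this yields 788 features and 310,078
unordered pairs. Drugs keep only cell lines with non-missing response
calls, and drugs with fewer than 15% sensitive calls are dropped
(`filter_drugs_by_sensitivity()`) - with almost-all-resistant panels, a
minimum sensitive fraction is needed for any split into informative
training and evaluation subsets. Missing log10 IC50 values can be
completed with a weighted mean of the four nearest drug rows
(`impute_ic50_knn()`); distances are Euclidean over co-observed cell
lines scaled to a per-cell-line basis, weights are inverse distance, and
observed entries are never modified. Effect sizes use Glass' delta with
the *unaltered* group's standard deviation - the control-group convention
- so that the effect of an alteration is expressed in units of the
natural spread of unaltered lines; positive values mean higher IC50
(resistance) in altered lines.

The screen itself (`sl_sr_screen()`) tests, per feature pair, drug and
group (each cancer type plus pan-cancer), the 2 x 2 table of
pair-co-occurrence against sensitive/resistant calls with a two-sided
Fisher's exact test. Degenerate tables (a zero margin, e.g. a pair that
never co-occurs) are skipped and counted. Within each group,
Benjamini-Hochberg q values are computed over all tests performed and
reported on the *percent* scale (`fdr_pct = 100 q`); only rows with
`p < 0.05` are stored, and a stored row is classified synthetic-lethal
(or synergistic-resistance) when additionally `fdr_pct < 0.001`, i.e.
`q < 1e-5`. The percent-versus-proportion reading of an "FDR% < 0.001"
rule is genuinely ambiguous; the percent scale was adopted as the default
and both columns (`q`, `fdr_pct`) are reported so either convention can
be applied downstream. A CAA-drug hit is flagged as "explained" by focal
copy number (`focal_explains_caa()`) only when a focal hit matches it on
all four keys: arm, direction, drug and cancer type.

# Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and one seed
(byte-identical reruns, caller's RNG stream untouched), and serialises
its planted truth next to the data.

* `sim_segments()` tiles each included arm with a Poisson number of
  segments, plants whole-arm shifts of magnitude `log2(3/2) ~ 0.585` (one
  copy on a diploid background, comfortably beyond the 0.2 thresholds)
  with probability `event_rate` (default 0.15, matching the roughly 6
  arm events per solid tumour over 39 arms), focal sub-arm events of
  1-10% arm length at `focal_rate` (default 0.05), and Gaussian
  segment-mean noise (`noise_sd`, default 0.05 - the scale of residual
  array noise after segmentation). At zero noise and zero focal rate the
  caller recovers the planted truth exactly; package validation uses 200
  noisy samples, where balanced per-arm accuracy stays above 0.95.
* `sim_evolution_cohort()` draws a burden and truncates a
  preference-biased full acquisition sequence - the forward model implied
  by the levelled tree ("`A` always first" makes every non-empty
  karyotype contain `A`).
* `sim_cooccurrence_cohort()` draws independent Bernoulli event columns
  except for listed pairs, generated jointly from the 2 x 2 cell
  probabilities that match the requested marginals and odds ratio
  (`p11` solves the quadratic `OR = p11 p00 / (p10 p01)` under the
  marginal constraints; infeasible requests error).
* `sim_pharmaco()` draws Bernoulli features at marginal 0.4 - the
  frequency range of the common cancer-functional events
  (e.g. *TP53* mutation, 17p loss) that dominate synthetic-lethality
  screening, and high enough that a planted pair effect on ~16% of 200
  cell lines is detectable at the screen's stringent default threshold -
  plus binary calls whose baseline sensitive fraction is tuned by root
  finding so the overall fraction matches `sensitive_frac` (default 0.3)
  while a planted pair attains its requested odds ratio exactly in
  expectation. IC50 values are standard Gaussian with planted shifts in
  wild-type SD units.

None of the generators attempts to mimic cancer-type-specific CAA
landscapes, linkage between arms, GC-content artefacts, subclonality, or
real GDSC drug panels. Passing tests on these cohorts therefore
demonstrate the correctness of the *computations* - calling rules,
probability models, screens - under their stated assumptions, not the
biological fidelity of any particular result on real tumours.

# Numerical choices and edge-case policy

* Binomial coefficients always via `lchoose`; probabilities assembled in
  log space and exponentiated once.
* Fractions over zero covered length are `NA`, never `NaN` surprises; the
  corresponding arm calls are 0 with an `uncallable` flag.
* TSV exports of segment tables and transition matrices print doubles
  with up to 17 significant digits, so file round-trips are bit-exact.
* Ties: weighted medians use the lower-median convention; signed-rank
  ties are handled by exact enumeration (small n) or tied-rank variance.
* Degenerate tests error loudly (`df = 0` chi-square, out-of-range F1
  inputs) or return flagged `NA` (Glass' delta with fewer than two
  controls or zero control spread, identical groups returning 0).
* Completely tied Mann-Whitney comparisons report `p = 1` rather than
  `NaN`.

# Validation scale

The test-suite and the reproduction script exercise: exhaustive
enumeration oracles up to `2^12` sign vectors; the full co-occurrence
grid to `N = 25`; 200 random small cohorts against a brute-force edge
enumeration of the transition model; 20 cohorts of 500 tumours for order
recovery; 200 simulated samples for the noisy-caller check; a
1035-pair null cohort for type-I control; 20 replicate 200-cell-line
panels for screen recovery; and 1000 random p-vectors against a reference
step-up implementation of Benjamini-Hochberg. These sizes were chosen so
each check is statistically meaningful yet the whole suite runs in about
a minute on a laptop.

# Known limitations

* The arm caller assumes ploidy-relative log2 ratios; it does not infer
  purity or ploidy, and the optional weighted-median recentring is a
  heuristic, not a substitute for upstream normalisation.
* The transition model identifies acquisition order only through the
  asymmetries discussed above; on cohorts where every karyotype is
  unique (very many events, few samples) the path variant degenerates,
  and neither variant should be over-interpreted as causal timing.
* The co-occurrence null conditions on marginal event counts but assumes
  exchangeable samples; cohort substructure (cancer types with different
  event rates) can masquerade as positive co-occurrence, which is why
  scans are usually run within cancer type.
* The screen's Fisher tests treat cell lines as independent and ignore
  nested feature structure (a CAA containing a focal segment); the
  focal-explains-CAA flag is a post-hoc annotation, not a joint model.
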