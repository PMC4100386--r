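---
title: "Copy-number association testing across two cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number association testing across two cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cnvaccord` implements a case-control association workflow for copy-number
variation (CNV) measured on SNP genotyping arrays, in which a discovery
cohort is analyzed site by site, evidence is aggregated over windows of
neighboring probes, and a second, independent cohort is used to test
whether the *pattern* of association replicates — via a per-site relative
factor (Rf) — before consecutive risk loci are summarized into CNV calls.
This vignette explains the underlying models, every tunable that matters,
what the synthetic-cohort generator does and does not emulate, and the
design decisions taken where the procedure was genuinely open.

```{r setup, eval = FALSE}
library(cnvaccord)
```

## The data model

The analysis substrate is a `state_matrix`: an individuals × SNPs integer
matrix of copy-number states 0–4, where 2 is the diploid norm, 0/1 are
deletions and 3/4 amplifications, plus case/control labels. States come
either from the synthetic generator or from hidden-Markov-model decoding
of probe intensities. All genomic coordinates are 1-based and inclusive
internally; BED output converts to 0-based half-open (`start - 1`, `end`).
Only autosomes (chromosomes 1–22) are analyzed: sex chromosomes have
different baseline copy numbers in males and females, which would confound
a case-control comparison of states.

## From intensities to states

Cohorts measured in separate batches are first quantile normalized to a
common baseline (`quantile_normalize()`, delegated to
`limma::normalizeQuantiles` with tie averaging): after normalization every
individual's sorted intensity vector equals the cross-individual mean
quantile vector, so batch-level distributional differences cannot
masquerade as copy-number differences.

`fit_hmm()` / `decode_states()` implement a deliberately minimal 5-state
HMM:

* normal emissions, one (mean, sd) per state; the default means
  `-2, -1, 0, 1, 2` encode one intensity unit per copy;
* a homogeneous (distance-independent) transition matrix with a high
  self-transition probability (default diagonal 0.999, off-diagonal mass
  uniform), encoding that state changes between neighboring probes are
  rare — about one per thousand probes;
* an initial distribution concentrated on the diploid state;
* Viterbi (maximum a posteriori path) decoding per individual and per
  chromosome, in log space throughout to avoid underflow; chromosomes are
  decoded independently because adjacency across a chromosome boundary is
  meaningless.

Training is ordinary Baum–Welch with per-position scaling, pooling
sufficient statistics across individuals; emission standard deviations are
floored (`min_sd = 1e-3`) so that a state capturing a single observation
cannot collapse the likelihood. The intended use mirrors a
reference-panel design: parameters are fitted once on a designated
training cohort and frozen before the study cohorts are decoded. The
association layers consume only integer states, so pipelines may also
bypass this module and ingest state matrices directly
(`read_state_matrix()`).

Richer intensity models (a B-allele-frequency channel, GC-wave
correction, distance-dependent transitions) are intentionally out of
scope; they improve real-array calling but are orthogonal to the
association machinery this package is about.

## Per-site testing

At each SNP the 2 × 5 case/control-by-state table is collapsed into three
carrier hypotheses — loss = states {0, 1}, gain = {3, 4}, abnormal =
{0, 1, 3, 4} — and tested with:

* two-sided Fisher exact tests on the three collapsed 2 × 2 tables
  (robust at the sparse counts CNVs produce);
* a Pearson chi-square test on the 2 × K table restricted to observed
  states;
* a Cochran–Armitage trend test with the copy numbers 0–4 as scores.

Degenerate tables (a zero-variance margin) return p = 1 rather than NA so
that downstream rankings stay total. The `best_hypothesis` of a site is
the smallest of the three collapsed p-values, with ties broken in the
order loss, gain, abnormal on p-values rounded to 12 significant digits —
the rounding exists because two analytically identical p-values computed
by different routes can differ in the last ulp, and a tie-break must not
depend on that.

Two-sidedness was an open choice; two-sided tests are the conservative
default when the direction of a carrier-frequency difference is not
specified in advance.

### Vectorized engine

Permutation analyses recompute every test under shuffled labels, which
makes single-table R calls the bottleneck. The package therefore carries
an internal vectorized engine: closed-form Pearson chi-square and trend
statistics over all sites at once, and per-site Fisher p-value lookup
tables keyed by the hypergeometric margins (a label permutation changes
only the case-carrier count, not the margins, so each site's two-sided
p-value is a table lookup). The engine reproduces
`chisq.test(correct = FALSE)`, `fisher.test` (including its two-sided
rule, summing all outcome probabilities at most `1 + 1e-7` times the
observed one) and `prop.trend.test` exactly; the test suite asserts this
equality site by site, keeping the user-facing single-site functions and
the scan engine as two independent routes to the same numbers.

## Window-based testing

For each SNP-based candidate, `window_test()` aggregates evidence over
the candidate ± `half_width` consecutive SNPs (default 2, a 5-SNP
window), truncated at chromosome boundaries and wherever the gap between
two neighboring SNPs exceeds `max_gap` (default 30 kb — the same distance
that defines consecutiveness when risk loci are chained into CNVs, kept
identical for internal consistency). The window statistic is

$$S_w = \sum_{j \in \text{window}} -\log_{10} p_{h,j},$$

where $h$ is the candidate's best hypothesis and member p-values are
floored at $1/(2\times10^6)$ so the sum stays finite. This "sum of
evidence under the candidate's hypothesis" is a documented stand-in for a
window statistic whose original form is not fully specified; any
monotone aggregate of member evidence would serve the same screening
role, and the permutation FDR calibrates whatever statistic is used.

## Permutation false discovery rates

All significance is calibrated by case/control label permutation
(`permute_labels()`, default `t_pm = 100` replicates, preserving arm
sizes; one shared permutation set serves the SNP-based, window and Rf
stages). For a statistic S and threshold t,

$$\mathrm{FDR}(t) = \frac{\sum_m \#\{j : S_j^{(m)} \ge t\}}
                         {T_{pm}\,\#\{j : S_j \ge t\}},$$

clamped to [0, 1], with ties counted by `>=` throughout. The raw ratio is
not guaranteed monotone in t, so `fdr_curve()` applies the standard
q-value adjustment — the FDR reported at t is the minimum raw FDR over
thresholds at or below t, i.e. over rejection regions containing t — and
all selections use the monotone curve. Permuted window statistics re-use
the observed windows and hypotheses (the null is conditional on the
selected windows), which is the usual choice when the selection step
itself is too expensive to repeat per replicate.

Default ceilings: SNP-based candidates at FDR ≤ 0.15, window-passing
sites at FDR ≤ 0.15.

## The relative factor

The cross-cohort stage asks whether the *association pattern* replicates.
With a Reference (discovery, the larger cohort) and a Testing
(validation) dataset, four models compare state distributions at a site:
M00 Testing-cases vs Reference-cases, M11 Testing-controls vs
Reference-controls (the concordant pair), M01 Testing-cases vs
Reference-controls and M10 Testing-controls vs Reference-cases (the
discordant pair), each a Pearson chi-square p-value on the group-by-state
table. The relative factor is

$$Rf = \frac{P(M00)\,P(M11)}{P(M01)\,P(M10)}.$$

At a replicating risk site, cases resemble cases and controls resemble
controls across cohorts (large p00, p11) while cases differ from controls
across cohorts (small p01, p10), so Rf is large; swapping the Testing
labels maps Rf to 1/Rf. Model p-values are floored at `1e-12` before the
ratio so a single underflowing test cannot blow up Rf; `log10_rf` is
reported alongside.

The Rf permutation FDR counts, by default, the **high** (accordance) tail
`Rf >= rf_site`: significant sites are the concordant ones, and that is
the tail in which they live. The opposite direction remains available
(`tail = "le"`) because the counting formula can be written either way;
the default follows the semantics of the statistic. No reweighting is
applied for unequal cohort sizes beyond what the contingency tests
themselves do.

### Joint selection under a false-positive budget

`select_risk_loci()` combines the two criteria: among window-passing
sites it finds the smallest Rf threshold t such that the
permutation-estimated expected number of null sites jointly passing
(window criterion, Rf ≥ t) is below `fp_budget` (default 1), then keeps
the window-passing sites with Rf ≥ t. The expected null count is
monotone in t, so the threshold is well defined; if no threshold meets
the budget the selection is empty with a warning rather than an error.
Each selected risk locus carries its best hypothesis as the locus type.

## CNV summarization

Two distinct summarization rules operate at different levels:

* **Raw CNVs** (`call_raw_cnvs()`): per individual, maximal runs of ≥ 3
  consecutive SNPs sharing one abnormal state (runs of mixed abnormal
  states are not merged, and runs never cross chromosomes). These are
  descriptive only — `summarize_raw_cnvs()` reports per-arm averages,
  SNP counts and bp sizes — and deliberately not treated as reliable
  calls, since they reflect single-individual noise.
* **Predicted CNVs** (`blocks_to_cnvs()`): maximal chains of selected
  risk loci with successive gaps ≤ 30 kb and ≥ 3 members become CNV
  records; shorter chains are reported as singular risk loci. Record
  size in kb is `(end − start)/1000` rounded half-up to one decimal —
  the convention verified to reproduce, exactly, every printed size in
  the published 22-record CNV table shipped in
  `inst/extdata/eagle_predicted_cnvs.tsv` (half-up rounding is computed
  on integers, `floor(bp/100 + 0.5)/10`, to dodge binary-decimal
  artifacts).

The record type is decided by the member hypotheses. A strict unanimity
vote (all members `gain` → Amplification, all `loss` → Deletion,
anything else Abnormal) turned out to be wrong in practice: the abnormal
hypothesis is a *composite* of the two directions, and at a true deletion
site its collapsed table contains the same carriers as the loss table
plus symmetric background carriers, which frequently makes `p_abnm` the
smallest of the three. A pure deletion region therefore yields members
labelled loss and abnm in mixture, and unanimity would type nearly every
real region Abnormal. The adopted rule treats `abnm` members as
compatible with either direction: Amplification = at least one `gain`
and no `loss` member, Deletion = at least one `loss` and no `gain`
member, Abnormal = mixed directions or no directional member at all.

`neighboring_genes()` reports annotation intervals intersecting the
closed ±100 kb flank of any risk locus (a gene touching the boundary bp
counts), deduplicated and sorted; interval work is delegated to
`IRanges`.

## Recombination context

`recomb_level()` summarizes the recombination environment of a SNP as
log10 of the maximum map rate within a 10 kb window. Whether such a
window means ±10 kb or a 10 kb total span is ambiguous; the total span
(±5 kb) was chosen and is configurable via `window`. Rates are floored at
`1e-4` cM/Mb so the log stays finite on cold regions; SNPs outside map
coverage get NA and are excluded from group summaries. The "sum" view of
recombination levels arises at group level: `compare_recomb_groups()`
reports per-group sums and means over the four exclusive analysis-stage
groups (`not_sig` < `snp_based` < `window` < `window_Rf`, each SNP
labelled by the furthest stage it passed) and a permutation p-value for
the risk-locus group exceeding the non-significant group in mean level.
`hotspot_overlap()` counts, per CNV type, records whose closed span
shares at least one bp with a hotspot interval.

## The synthetic-cohort generator

`make_snp_map()`, `simulate_cohort()`, `emit_intensities()` and
`make_recomb_map()` provide a fully seeded test bed with known ground
truth:

* SNP spacing is exponential with configurable mean (default 3 kb at
  desk scale), with a configurable fraction of gaps (default 5%) forced
  above 30 kb so that the consecutiveness rule is actually exercised;
* risk regions are carried as whole blocks of a single state (3 for
  amplification, 1 for deletion) with separate case and control carrier
  frequencies — the simplest ground truth for recovery tests;
* background CNVs are sporadic segments, Poisson per individual
  (default rate 2 per individual at the 2,000-SNP desk scale, the same
  order as scaling a few hundred raw CNVs per genome down to a
  2,000-probe map), geometric lengths with mean 5 SNPs truncated at 3,
  states uniform on {0, 1, 3, 4}, identical in cases and controls;
* two cohorts are produced by two calls with different seeds and sizes —
  400/400 (discovery) and 160/170 (validation) by default, mirroring a
  larger discovery and smaller validation cohort;
* the recombination map tiles each padded chromosome span with a uniform
  background rate plus short hotspot intervals.

What the generator does **not** emulate: linkage disequilibrium and
genotypes (only copy-number structure), population stratification, batch
or GC-content intensity waves, partial-overlap carriage of risk regions,
and any coupling between risk loci and recombination hotspots. Passing
tests therefore demonstrate that the statistical machinery behaves as
specified under its own assumptions — valid typing and calibrated error
rates on clean copy-number signal — not that real-array confounders are
handled; on real data the normalization and HMM stages carry that burden
and stratification must be addressed by design (matched cohorts) as
assumed here. In particular, the true carrier-frequency difference at
real risk loci is unknown; the defaults (0.15 cases vs 0.03 controls in
the acceptance simulations) were chosen for testability.

## Problem sizes and runtime

The shipped validation exercises the full pipeline at 2,000 SNPs with
cohorts of 800 and 330 individuals and 100 permutations (about 8 s per
replicate on one core; the 25-replicate recovery study runs in ~3
minutes), and the null-calibration study at 5,000 sites. These sizes are
the package's desk-scale choice: large enough that carrier counts,
permutation tails and the selection funnel behave as they would
genome-wide, small enough to iterate on.

## Known limitations

* The window statistic and the HMM parameterization are documented
  stand-ins for components whose original definitions are not public in
  full; equivalence with any particular caller is not claimed.
* Permutation FDRs with `t_pm = 100` have granularity 1/100 per site
  set; very small FDR ceilings require more replicates.
* `select_risk_loci()` conditions its null on the observed window
  selection rather than repeating the whole funnel per permutation.
* No covariate adjustment: cohorts are assumed matched by design.
* Manual curation of borderline loci — merging or splitting records a
  human reviewer might adjust — is outside what the rules formalize.
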