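---
title: "Promoter-regulatory analysis of differentially expressed miRNAs: models and methods"
author: "mirprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-regulatory analysis of differentially expressed miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mirprom implements a complete analysis chain for asking which transcription
factors may drive the expression of microRNAs that differ between myeloid
cell types (monocytes and dendritic-cell subsets): a qPCR screening stage
that nominates differentially expressed miRNAs, a motif-scanning stage that
scores transcription-factor binding sites (TFBSs) in the 2 kb regions
upstream of the pre-miRNA hairpins, an enrichment stage that asks whether
the nominated promoters share more motifs than random miRNA promoters, a
conservation stage that filters sites by evolutionary conservation, and an
integration stage that checks whether the cognate factors are themselves
expressed.  This vignette records the models, the tunable parameters, the
numerical conventions, and the design decisions behind each stage, together
with what the synthetic-data generator does and does not emulate.

## The expression screen

Raw cycle-threshold values are normalized per sample against a reference
miRNA (hsa-let-7a by default): `dCt = Ct_target - Ct_reference`, so lower
dCt means higher expression.  A miRNA is *detected* when its summary dCt is
at most 12 cycles.  The summary statistic is the median across samples;
this is a deliberate choice where a per-sample or per-miRNA reading would
both be defensible — the median is robust to single undetermined wells and
monotone in the underlying expression, and a `rule = "any"` variant is
available.  The boundary is inclusive (`dCt = 12` is detected).

Detected miRNAs enter a gene-by-gene one-factor ANOVA on cell type,
with Benjamini–Hochberg FDR control across miRNAs at 0.05, followed by
Tukey HSD pairwise comparisons at 0.05 on the significant set.  The ANOVA
and Tukey computations are delegated to the standard `stats` machinery
(`oneway.test` with equal variances, `aov` + `TukeyHSD`); the package adds
only the degenerate-case conventions that matrix screens need: all values
identical gives F = 0, p = 1; zero within-group variance with distinct
means gives F = Inf, p = 0; a group with fewer than two non-missing values
makes a miRNA *untestable* (flagged, never dropped).  "Non-parametric"
readings of the pairwise comparison are accommodated by a rank-transform
flag, but the default is plain Tukey HSD on dCt — the only fully specified
interpretation.

Classification is two-staged, mirroring a screen that first compares all
cell types and then only the DC subsets: `up_in_monocytes` and `up_in_DC`
require every monocyte-versus-DC pair to be significant with a consistent
direction (remembering that lower dCt is higher expression);
`up_in_DC_subset` marks miRNAs significant only within the DC-restricted
ANOVA; everything else detected is `no_difference`.  The classes partition
the detected set.

## Motif model and instance scores

A motif is a position frequency matrix with pseudocount regularization
(`(count + pc) / (rowsum + 4 pc)`, default pc = 0.01).  The instance score
of a window is the log likelihood ratio of the window under the motif
against an i.i.d. mononucleotide background:

$$\mathrm{score}(w) = \log_2 \prod_{i=1}^{W} \frac{f_i(b_i)}{q(b_i)}.$$

The logarithm base is 2 throughout; the conventional instance threshold of
6 therefore means a likelihood ratio of at least 64.  Windows containing N
are unscorable and are skipped rather than given invented frequencies.
Scanning covers both strands (the reverse-complemented matrix is scanned
forward, so a minus-strand hit at start *s* covers the same interval
`[s, s+W)`).  The background is estimated from the promoter pool with one
pseudo-observation per base and is strand-symmetrized (A with T, C with G
pooled); symmetrization is what makes a scan of a sequence and a scan of
its reverse complement exact mirror images, which is the natural contract
for double-stranded DNA.

## Set-level over-representation: the raw score

The per-sequence statistic is the arithmetic mean of the linear-scale
likelihood ratio over all scorable windows on both strands, \(s_i \ge 0\).
The set statistic averages over all subsets of the sequence set (the empty
subset included), which collapses to a product form evaluated in log
space:

$$A = \frac{1}{2^n}\sum_{S \subseteq \{1..n\}} \prod_{i \in S} s_i
    = \prod_{i=1}^{n} \frac{1 + s_i}{2}, \qquad
  \mathrm{raw} = \log_2 A .$$

A raw score above zero signifies over-representation.  The inclusive
(empty-subset) form is used; the nonempty-only variant differs by a
vanishing term whenever any \(s_i\) is appreciable and would complicate
the clean product identity.  The raw score is compared against raw scores
of random promoter sets of equal cardinality drawn without replacement
from a background pool, with the add-one-smoothed empirical p-value
\(p = (1 + \#\{raw_{rand} \ge raw_{obs}\}) / (1 + n_{rand})\), so p is
never 0 and its floor at 1000 randomizations is about 0.001.

## The sharing statistic and promoter-set enrichment

A motif *qualifies* in a promoter set when its over-representation p is at
most 0.05 **and** it has at least one hit at the instance threshold in the
set.  The sharing profile counts, per qualifying motif, the number of
distinct promoters with at least one hit; the sharing statistic is
\(T = \sum_m n_m\), equivalently \(\sum_k k\,M_k\) over motifs shared by
exactly k promoters.  Presence counting (a motif counts once per promoter)
is the default; a multiplicity-weighted T is available behind a flag.

Enrichment re-runs the *entire* qualifying rule on each of `n_random`
random promoter sets drawn from the pool — including the per-set
over-representation test, because random miRNA promoter sets also contain
over-represented motifs and ignoring that would overstate the enrichment.
The inner randomization count defaults to 100 inside the nulls to keep the
nested test tractable; note the floor effect this creates: with `n_inner`
inner draws the smallest attainable p is `1/(n_inner+1)`, so `n_inner`
below 20 makes the default 0.05 cutoff unreachable (the function warns).
The observed set uses the same inner count as the nulls so that observed
and null statistics are exchangeable under the null.  Random sets are
drawn from the full pool without excluding the test promoters (an
exclusion flag exists); the fold is `T_observed / median(T_random)` with
midpoint-interpolated medians, reported as undefined (with a flag) when
the null median is 0.

In the conserved variant, hits are first restricted to conserved ones: the
conservation threshold is derived from the test set (the value retaining
its most conserved decile) and then held fixed while the random sets are
evaluated, so random sets are judged at the same absolute threshold.

## Conservation scoring

Per-base conservation scores in [0,1] (posterior probabilities of the
conserved state of a phylogenetic HMM, consumed as given) are attached to
hits as the *median* over the site's bases; even-length medians use the
midpoint mean, and a site with fewer than half its bases scored is
unscorable.  The percentile filter's direction deserves a note: "10th
percentile" filtering is implemented as *retaining the most conserved 10%*
(threshold at the 90th percentile of hit conservation scores, ties
retained), because a lower-tail reading would keep the least conserved
sites and contradicts the analysis intent of enriching for conserved
regulation; the literal lower-tail cut is available via
`direction = "bottom"`.

The random-block null draws, for each observed site, uniformly placed
intervals of the same width from the same promoter (blocks may overlap
sites and each other — excluding them would bias the null downward and
complicate placement in short promoters), and compares observed and null
median-conservation sets by fold of medians and a two-sided Wilcoxon
rank-sum test.  Positional structure is summarized two ways, both in
0-based promoter coordinates where position L-1 abuts the pre-miRNA start
and a hit's upstream offset is `start - L`: a histogram of start offsets
(100 bp bins tiling `[-L, 0)`) and a proximal clustering test using
midpoint offsets, which compares the fraction of hits within the 500 bp
proximal window against the uniform expectation `window/L` with a
one-sided exact binomial test.  Start offsets make histogram bins
unambiguous at the distal edge; midpoints are the fairer notion of "where
the site is" for the window test.

## TF-expression integration

Qualifying motifs map to one or more cognate TF gene symbols (heterodimer
motifs map to several).  A motif counts as expressed when *any* mapped TF
is called present (an `all` rule is available); marginal microarray calls
count as absent by default, and flipping that flag can only increase the
expressed fraction.  The sharing–expression curve bins motifs by the exact
number of promoters sharing them and correlates the expressed count with
k; a cumulative at-least-k binning is available since the exact-k choice
is a convention, not a consequence.

## The synthetic-data generator

The generator emulates every input at the scale of the motivating study
design: a 167-promoter pool standing for all profiled miRNA promoters, a
12-promoter test set standing for the DC-up-regulated miRNAs (8 for the
monocyte arm), 2 kb promoters at 41% GC, a 30-motif library standing in
for a few-hundred-motif compendium, a 5-cell-type × 3-donor Ct panel, and
Beta-distributed conservation with an elevated component over planted
sites (background Beta(1,3), planted Beta(50,1)).  Promoters are i.i.d.
mononucleotide sequences; planted sites are sampled from the motif's
frequency model and overwrite background bases (lengths are preserved),
landing in the proximal 500 bp with probability `proximal_bias` (default
0.8) and on a uniformly random strand.

Motif information content is controlled per column by a single-dominant-
base model whose dominant probability is solved to hit a target
information content.  Two ranges matter and their defaults encode an
identifiability consideration worth spelling out.  Scanning 2 kb on both
strands evaluates ~4000 windows per promoter, so any motif whose
high-scoring word count is more than ~1 in 10^4 windows will, by chance,
hit essentially every promoter — presence across a promoter set is then
saturated rather than graded.  Planted motifs therefore default to widths
10–14 at 1.9–1.95 bits per column (total ~19+ bits), which makes a planted
site specific to the promoter it was planted in and recoverable at the
instance threshold; background motifs default to widths 7–14 at 1.5–1.9
bits per column, a range whose chance-hit rate spans the graded-presence
regime (motifs present in anywhere from none to all of a 12-promoter set)
that real compendium scans display.  Narrower or weaker settings produce
degenerate sharing statistics: either every motif is everywhere or no
motif ever reaches the threshold.

The Ct model is `reference + baseline + group shift + donor effect +
residual noise` with designated miRNAs shifted by −6 cycles in the DC or
monocyte arms, a 20-cycle baseline for designed-undetected miRNAs, donor
and residual SDs of 0.5, and a dCt baseline of 8 for detected miRNAs.  TF
presence follows a logistic in the motif's true sharing level.  All
generators are pure functions of (config, seed).

What the generator does **not** emulate: dinucleotide or repeat structure
in promoters, phylogenetically realistic conservation autocorrelation,
motif-motif similarity (real libraries contain near-redundant matrices),
amplification-efficiency artifacts in Ct values, and real microarray call
noise.  Passing tests therefore demonstrate the statistical machinery is
correct and calibrated on data satisfying the model's assumptions — not
that the biological conclusions transfer to any particular real dataset.

## Numerical conventions and degenerate inputs

* Coordinates: 0-based, half-open everywhere; BED-like hit files.
* Log base 2 everywhere; thresholds are on the log2 scale.
* Empirical p-values use add-one smoothing and ties count toward the null
  (`>=`), so p is conservative and never 0.
* Medians (conservation, null folds) use R's default midpoint
  interpolation; percentile thresholds use the default type-7 quantile.
* Zero-variance correlations are flagged `defined = FALSE` rather than
  propagating NaN.
* Sequence windows containing N are excluded from both hit calling and
  per-sequence averages; an all-N promoter is an error.
* Randomized functions take an explicit `seed` and restore the caller's
  RNG state; every randomization in an enrichment run consumes one
  sequential stream derived from that seed, so results are reproducible
  and independent of evaluation order.

## Problem sizes used by the test suite

The suite exercises the full default geometry (167 × 2 kb pool, 30
motifs) for the planted-recovery and determinism checks, and scales the
calibration studies to 60 promoters × 300 bp with 99 randomizations × 200
repetitions — sizes chosen so the whole suite completes in a few minutes
on one core while keeping every statistical check adequately powered.
The acceptance script reruns the default-scale study end to end with 1000
randomizations.

## Known limitations

* The i.i.d. background model understates clumping of real sequence, so
  chance-hit rates on real promoters will differ from synthetic ones.
* The over-representation test conditions on mononucleotide composition
  only; no dinucleotide-preserving shuffle is provided.
* Conservation tracks must already be in promoter coordinates; lifting
  genome tracks is a preprocessing step outside the package.
* The nested enrichment test is exact but O(n_random × n_inner); at the
  default 1000 × 100 it runs in well under a minute at study scale, but
  very large pools or libraries may warrant lowering `n_inner`, with the
  p-floor caveat above.
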