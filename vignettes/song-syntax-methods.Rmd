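---
title: "Song syntax and syllable diversity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Song syntax and syllable diversity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songsyntax)
```

## What the package computes

`songsyntax` analyses syllable-annotated song corpora — the kind produced by
segmenting recordings in PRAAT and labelling each syllable with a type — and
quantifies song diversity and syllable syntax per individual, then compares
groups. It was built around a canonical study design in behavioural
neuroendocrinology: male and female canaries induced to sing with testosterone
(T) or testosterone plus estradiol (T+E2) implants, thirty songs per bird,
with the question of which aspects of song remain sexually differentiated.
Nothing in the package is specific to that design beyond its defaults: any
corpus of labelled syllable sequences with a two-level sex factor and a
two-level treatment factor fits.

The pipeline has four stages:

1. **IO** — PRAAT TextGrid interval tiers (long and short text dialects) or a
   plain tab-separated sequence table, into validated per-bird corpora.
2. **Diversity metrics** — eight per-bird variables: syllable-type repertoire,
   song-type repertoire, syllables/song, syllable types/song, syllable
   types/second, syllables/second, syllable versatility index (SVI), and the
   mean Levenshtein distance between songs.
3. **Syntax networks** — an undirected syllable-transition network per bird;
   average minimum path length and network density.
4. **Group statistics** — two-way ANOVA (treatment × sex) with partial
   eta-squared per metric, unrotated PCA of the standardized metrics, per-sex
   multiple regression of component scores on vocal-control-nucleus volumes,
   and Pearson correlations.

## Data model and conventions

A *syllable* is an opaque, case-sensitive type label on a time interval;
two labels are either identical or entirely different (no acoustic
similarity). A *song* is an ordered, non-overlapping sequence of labelled
intervals. The operational song definition — at least 1 s of sound bounded by
at least 0.4 s of silence — is applied only when songs must be segmented from
a continuous annotation stream (no `song_index` column); when the input
already carries song indices, segmentation happened upstream and the filters
are off by default. Both thresholds are arguments of
`read_sequence_table()`. Analyses conventionally use the first 30 songs per
bird (`truncate_corpus()`, `songs_per_bird` in `run_config()`); corpora with
fewer songs are flagged in the exclusion log but not rejected. Times are
stored in seconds and written at millisecond precision, so a write/read
round trip is exact to 1 ms.

## The diversity metrics

Per song with `n` syllables of `k` distinct types and duration `d` (last
offset − first onset): SVI = `k/n` (in (0, 1]; 1 exactly when no type
repeats), types/second = `k/d`, syllables/second = `n/d`. Per-song values
are averaged over songs, so each song contributes equally regardless of
length; rate metrics are reported as missing, never guessed, when
annotations carry no times.

Two metrics required genuine design decisions:

**Song-type repertoire.** "Number of different song types" presupposes a
rule for when two songs are the same type, and no formal rule is standard —
in practice the classification is often done by eye. The default here
classifies a song by its *phrase sequence*: the syllable-type sequence after
collapsing consecutive repeats. Canary-style song is phrase-structured
(runs of one type repeated), and repeat counts fluctuate freely from
rendition to rendition, so comparing raw sequences would make nearly every
song its own type and the metric would saturate at the number of songs. An
exact-sequence rule remains available (`song_type_rule = "exact"`) for
species without phrase structure.

**Levenshtein distance.** The minimum number of single-token insertions,
deletions and substitutions converting one syllable sequence into the other,
computed at whole-label granularity (in C, `src/levenshtein.cpp`). It
captures how much the syllable sequence varies *between successive songs*,
so the default averages the distance over consecutive pairs (1,2), (2,3), …
in recording order; an all-pairs mode exists for unordered collections. Raw
edit counts are reported by default; optional normalization divides each
distance by the longer sequence's length, which removes the (here
deliberately retained) dependence on song length.

## Syntax networks

The syllable strings of all songs are concatenated in recording order into
one string; every adjacent pair of labels is a first-order transition. Song
breaks are deliberately ignored — treating each song separately would
fragment small repertoires into disconnected networks. Types are nodes;
transitions between distinct types are undirected edges; immediate repeats
are kept as self-loops because repetition is a genuine feature of this
singing style, but they are excluded from both metrics (a self-loop can
neither shorten a path nor count as an edge between two types).

*Average path length* is the mean, over all unordered pairs of mutually
reachable nodes, of the minimum number of edges linking the pair, on the
unweighted simple graph. Unreachable pairs (dead ends) are excluded from the
average rather than assigned an arbitrary large value; if no pair is
reachable the metric is undefined and returned as `NA` with a warning.
Higher values mean types are linked through longer, more fixed chains of
transitions. *Network density* is observed edges over possible edges,
`2m / (n(n − 1))`; higher density means a larger share of possible
transitions is used — more flexible sequencing. Transition counts are kept
on the object and exported (GraphML, `export_network_graphml()`, including a
directed variant matching the usual transition-diagram figures), but all
metrics use the undirected unweighted graph.

Networks with three or fewer types are too small for either metric to mean
much — density is 1 or nearly so by construction — so such birds receive
missing network metrics and are logged (`network_metrics_for_study()`,
threshold configurable). Downstream, these birds are dropped listwise only
from analyses that involve network variables, which is why the residual df
of the network ANOVA rows can sit below the other rows.

## Group statistics

**ANOVA.** Each metric is tested with `metric ~ treatment * sex` using
Type III (marginal) sums of squares under sum-to-zero factor coding. The
groups here are unbalanced (different numbers of males and females, and
network exclusions), where sequential SS would make term tests
order-dependent; Type III is also what the commercial packages this analysis
is usually run in report. On balanced data Type III and sequential
decompositions coincide, which the test suite verifies. Effect sizes are
partial eta-squared, `SS_term / (SS_term + SS_residual)`, invariant to
affine rescaling of the response. Alpha is 0.05 throughout with no
multiple-testing correction — the metrics are deliberately redundant
views of the same construct, not independent hypotheses.

**PCA.** The per-bird metrics are standardized to mean 0, SD 1, and the
correlation matrix is eigendecomposed with no rotation (`prcomp`).
Eigenvalues sum to the number of variables; birds with any missing metric
are dropped (and recorded) so scores stay aligned. The leading three
components are carried forward by fixed count, not by an eigenvalue
threshold — the point of the reduction is a fixed low-dimensional response
set for the regressions, not model selection. Component signs are arbitrary
in any eigendecomposition; each component is flipped so its
largest-magnitude loading is positive, making outputs reproducible across
BLAS implementations.

**Regressions.** Per sex, each retained component score is regressed by OLS
on HVC, RA and Area X volumes with body mass as a covariate, reporting
per-coefficient t tests and the model F and R². Rank-deficient designs are
an error naming the collinear columns rather than a silent `NA` row.

## The synthetic-data generator

No public corpus of annotated steroid-induced canary song exists, so the
generator is a first-class module: every pipeline stage is validated on
corpora whose generating process is known. A song is built as a sequence of
phrases; each phrase is one syllable type repeated `1 + Poisson` times;
successive phrase types follow a per-bird Markov chain whose transition
matrix mixes a fixed per-bird permutation cycle (weight `stereotypy`) with a
flexible component, uniform over each type's `branching` random alternative
targets. The restricted target set matters: with unrestricted mixing, a
small repertoire sung for thirty songs visits every possible transition and
all flexible birds collapse onto density exactly 1 with zero variance —
real birds use a limited transition vocabulary even when flexible.
`stereotypy` also fixes the opening phrase with the same probability, so at
`stereotypy = 1` with a fixed phrase count a bird sings literally one song
type.

Defaults encode the emulated study: 15 males and 13 females, treatments
alternating (a null factor), 30 songs per bird, and roughly 69 syllables
per song in both sexes (57,872 syllables over 840 songs in the motivating
dataset). Sex differences are injected *only* through repertoire size
(male 15 ± 2.5 between birds, female 6 ± 1.2) and stereotypy (0.92 vs
0.45); phrase counts (23 vs 14) and repeat counts (3.0 vs 4.9) are set so
song length and tempo are matched — males reach their higher per-song type
counts through many short phrases, females repeat few types many times.
Under these settings males average ~13–14 syllable types per song and
females ~5.5, bracketing the observed contrast (≈15 vs ≈6). Body mass and
nucleus volumes are drawn independently of the song parameters, i.e. the
generator encodes a *null* brain–behaviour relation.

A second generator (`generate_metrics_table()`) emits a per-bird metrics
table directly from a three-factor latent model (diversity, tempo, song
length) around sex-specific means, for exercising the statistics stages in
isolation; the shared diversity factor is what makes the standardized
metrics concentrate their variance on few components and makes repertoire
and path length correlate within sex.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: acoustic similarity between types (labels are
symbols); the direction of the sex difference in Levenshtein distance and
song-type repertoire (both emerge from whatever the repertoire/stereotypy
settings imply, and the song-type metric saturates near the 30-song ceiling
for flexible singers); temporal phonology beyond a fixed syllable grid; and
any true dependence of song on brain measures.

## Numerical choices and degenerate inputs

Times are rounded to 1 ms on write; interval overlap is tolerated to 1 ms.
A zero-duration song with more than one syllable is a validation error. A
single-song corpus yields `NA` for Levenshtein distance (with a warning)
while all other metrics are still returned. A constant ANOVA response
yields `NA` statistics with a warning; an empty design cell is an error
naming the cell. PCA refuses constant variables by name. Correlations
require three complete pairs and non-constant inputs. All analysis stages
are deterministic; only the generator consumes random numbers, always
through an explicit seed, and per-bird seeds are derived from the study
seed so studies are reproducible end to end.

## Validation problem sizes

The test suite checks the Levenshtein implementation against character-level
edit distance on all pairs of sequences up to length 6 over a three-letter
alphabet (1093² pairs) and against a brute-force recursive oracle on shorter
and sampled pairs; network metrics against Floyd–Warshall on 200 random
graphs of up to 8 nodes; the ANOVA against an explicit model-comparison
oracle; and parameter recovery on 100 replicate 28-bird studies, where the
sex contrast on repertoire, path length and density is required in at least
90% of replicates while the matched syllables-per-song metric stays near
the nominal 5% rejection rate. These sizes keep the full suite around two
minutes on one core while leaving the stochastic assertions comfortable
margins.

## Known limitations

- The song-type rule is a proxy for a perceptual classification; on species
  without phrase structure the default may still saturate.
- Path length ignores transition frequencies by design; rarely- and
  frequently-used transitions weigh equally.
- The Type III convention matches the common commercial implementation on
  two-way crossed designs, but other marginal-SS conventions exist for more
  complex designs; only two crossed two-level factors are supported here.
- Missing data are handled by listwise deletion per analysis, not by mixed
  models.
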