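# songsyntax

Quantifying song diversity and syllable syntax from annotated birdsong
corpora, and testing group differences — built for the study design where
male and female songbirds (canaries in the motivating case) are induced to
sing with steroid implants and the question is which aspects of song differ
between the sexes. The intended users are behavioural biologists and
neuroendocrinologists who already have syllable-level annotations (PRAAT
TextGrids or tabular sequences) and want the full path from annotations to
statistics to be scripted, validated and reproducible.

## What it computes

Per bird, from its first 30 songs:

- **Diversity metrics** — syllable-type repertoire; song-type repertoire
  (songs classified by their phrase sequence, i.e. the syllable sequence
  after collapsing consecutive repeats); syllables/song; syllable
  types/song; syllable types/s; syllables/s; syllable versatility index
  `SVI = k/n` (distinct types over total syllables, per song, averaged);
  and the mean **Levenshtein distance** between successive songs — the
  minimum number of single-syllable insertions, deletions and substitutions
  turning one song's type sequence into the next's.
- **Syntax-network metrics** — syllable types become nodes and observed
  first-order transitions become undirected edges (songs concatenated,
  breaks ignored; immediate repeats kept as self-loops but excluded from
  the metrics). *Average path length* = mean shortest-path length over
  mutually reachable node pairs; *network density* = `2m / (n(n−1))`.
  Long paths and low density mean fixed, linear syllable sequencing; short
  paths and high density mean flexible transitions. Networks with ≤ 3 types
  are excluded.

At the group level: two-way ANOVA (treatment × sex, Type III sums of
squares, sum-to-zero coding) with partial eta-squared
`η²p = SS_effect / (SS_effect + SS_residual)` for each of the ten metrics;
unrotated PCA of the standardized metrics; per-sex OLS regression of the
first three component scores on HVC, RA and Area X volumes with body mass
as a covariate; and Pearson correlations. A seeded phrase-level generator
produces synthetic corpora with sex-specific repertoire size and transition
stereotypy, so the whole pipeline is testable without the original
recordings.

## Worked example

```r
library(songsyntax)

study   <- generate_study(seed = 1)              # 15 males, 13 females, 30 songs each
metrics <- compute_study_metrics(study)
netm    <- network_metrics_for_study(study)
metrics <- merge(metrics, netm[, c("bird_id", "network_path_length",
                                   "network_density")], by = "bird_id", sort = FALSE)
metrics <- merge(metrics, study_covariates(study), by = "bird_id", sort = FALSE)
stats   <- run_statistics(metrics, n_pcs = 3)
stats
```

```
Group-level statistics

Sex effects (Type III two-way ANOVA):
                    metric df df_residual         F         p partial_eta_sq
  syllable_type_repertoire  1          24  70.90939 1.259e-08       0.747127
      song_type_repertoire  1          24  19.89063 1.640e-04       0.453186
        syllables_per_song  1          24   2.46203 1.297e-01       0.093040
   syllable_types_per_song  1          24 120.43600 7.761e-11       0.833836
 syllable_types_per_second  1          24 143.49154 1.296e-11       0.856709
      syllables_per_second  1          24   0.07951 7.804e-01       0.003302
                       svi  1          24 143.49265 1.296e-11       0.856710
      levenshtein_distance  1          24  10.11662 4.025e-03       0.296531
       network_path_length  1          24 137.37093 2.033e-11       0.851274
           network_density  1          24 155.29595 5.697e-12       0.866143

PCA: first 3 components explain 93.4% of variance
Repertoire vs path length correlation: male r = 0.91, female r = 0.58
```

Reading this: the synthetic males sing from larger repertoires
(`F(1,24) = 70.9`, a very large effect, `η²p = 0.75`) with more syllable
types per song and per second, while syllables per song and per second do
not differ — the sexes sing songs of the same length and tempo that differ
in *content*. Longer male path lengths and higher female density say male
syllable transitions are more fixed, female transitions more flexible.
Within each sex, birds with larger repertoires have longer network paths.

File-based workflows go through `run_full_analysis(run_config(...))`, which
reads a sequence table, a TextGrid directory or a ready-made per-bird
metrics table, writes `metrics.csv`, `anova.csv`, PCA tables,
`regression.csv` and an exclusion log, and is byte-reproducible. A thin
command-line wrapper with `metrics` / `network` / `stats` / `simulate` /
`all` subcommands is installed at `inst/scripts/songsyntax.R`.

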