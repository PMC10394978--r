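Package: songsyntax
Title: Syllable Diversity Metrics and Transition-Network Analysis of Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing syllable-annotated song corpora from songbirds.
    Reads PRAAT TextGrid annotations or plain sequence tables, computes per-bird
    song and syllable diversity metrics (repertoire sizes, syllables and syllable
    types per song and per second, syllable versatility index, Levenshtein distance
    between successive songs), builds undirected syllable-transition networks and
    derives average path length and network density, and runs the group-level
    statistics used in steroid-induced song studies (two-way ANOVA with partial
    eta-squared, Pearson correlation, unrotated principal component analysis, and
    per-sex multiple regression of component scores on vocal-control-nucleus
    volumes). A seeded generator produces phrase-structured synthetic corpora with
    sex-specific repertoire size and transition stereotypy for validation and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    car,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
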