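DIVERSITY_METRICS <- c("syllable_type_repertoire", "song_type_repertoire",
                       "syllables_per_song", "syllable_types_per_song",
                       "syllable_types_per_second", "syllables_per_second",
                       "svi", "levenshtein_distance")
NETWORK_METRICS <- c("network_path_length", "network_density")

#' Levenshtein distance between two syllable sequences
#'
#' Minimum number of single-token insertions, deletions and substitutions
#' needed to turn one sequence of syllable-type labels into the other.
#' Comparison is at whole-label granularity: `"A1"` and `"A2"` are simply
#' different tokens, regardless of how their names are spelled.
#'
#' @param a,b character vectors of syllable-type labels (possibly empty).
#' @return Non-negative integer edit count; 0 iff the sequences are identical.
#' @examples
#' levenshtein(c("A", "A", "B"), c("A", "B", "B")) # 1
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  u <- unique(c(a, b))
  lev_int(match(a, u), match(b, u))
}

#' Pairwise Levenshtein distances for a list of sequences
#'
#' @param seqs list of character vectors (syllable label sequences).
#' @return symmetric integer matrix of edit distances.
#' @export
levenshtein_matrix <- function(seqs) {
  stopifnot(is.list(seqs))
  u <- unique(unlist(seqs, use.names = FALSE))
  coded <- lapply(seqs, function(s) match(as.character(s), u))
  d <- lev_matrix_int(coded)
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Per-song diversity metrics
#'
#' Computes, for one song: the number of syllables, the number of distinct
#' syllable types, the syllable versatility index (SVI = types / syllables,
#' in (0, 1]), and — when the song carries timing — syllable types per second
#' and syllables per second, dividing by the song duration (last offset minus
#' first onset).
#'
#' @param s a [song()] or a `data.frame` with columns `label`, `onset`,
#'   `offset`.
#' @return one-row `data.frame` with columns `n_syllables`, `n_types`, `svi`,
#'   `types_per_second`, `syllables_per_second`, `duration`. Rate columns are
#'   `NA` for untimed songs.
#' @export
compute_song_metrics <- function(s) {
  n <- nrow(s)
  if (n == 0L) stop("song has no syllables", call. = FALSE)
  k <- length(unique(s$label))
  dur <- song_duration(s)
  if (!is.na(dur) && dur <= 0 && n > 1L)
    stop("zero-duration song with more than one syllable", call. = FALSE)
  rate_ok <- !is.na(dur) && dur > 0
  data.frame(n_syllables = n, n_types = k, svi = k / n,
             types_per_second = if (rate_ok) k / dur else NA_real_,
             syllables_per_second = if (rate_ok) n / dur else NA_real_,
             duration = dur)
}

collapse_repeats <- function(labels) rle(labels)$values

song_type_key <- function(labels, rule = c("collapsed", "exact")) {
  rule <- match.arg(rule)
  if (rule == "collapsed") labels <- collapse_repeats(labels)
  paste(labels, collapse = "\x1f")
}

#' Per-bird song and syllable diversity metrics
#'
#' Aggregates a bird's corpus into the eight diversity metrics: syllable-type
#' repertoire (distinct labels over all songs), song-type repertoire (distinct
#' song types, see `song_type_rule`), mean syllables per song, mean syllable
#' types per song, mean syllable types per second, mean syllables per second,
#' mean SVI, and the mean Levenshtein distance between song syllable
#' sequences. Per-song quantities are averaged over songs, so each song
#' contributes equally regardless of its length.
#'
#' @param corpus a [bird_corpus()].
#' @param song_type_rule how two songs count as the same song type:
#'   `"collapsed"` (default) compares the phrase sequence, i.e. the label
#'   sequence after collapsing consecutive repeats — appropriate for
#'   phrase-structured song where repeat counts vary freely; `"exact"`
#'   compares raw label sequences.
#' @param levenshtein_mode `"successive"` (default) averages the distance over
#'   the consecutive song pairs (1,2), (2,3), ...; `"all_pairs"` averages over
#'   all unordered song pairs.
#' @param normalize_levenshtein if `TRUE`, each pairwise distance is divided
#'   by the longer sequence's length before averaging (default `FALSE`: raw
#'   edit counts).
#' @return one-row `data.frame` (fields above plus `bird_id`, `sex`,
#'   `treatment`, `n_songs`). `levenshtein_distance` is `NA` with a warning
#'   when the corpus holds a single song; rate metrics are `NA` when songs are
#'   untimed.
#' @export
compute_bird_metrics <- function(corpus,
                                 song_type_rule = c("collapsed", "exact"),
                                 levenshtein_mode = c("successive", "all_pairs"),
                                 normalize_levenshtein = FALSE) {
  stopifnot(inherits(corpus, "bird_corpus"))
  song_type_rule <- match.arg(song_type_rule)
  levenshtein_mode <- match.arg(levenshtein_mode)
  labs <- song_labels(corpus)
  per_song <- do.call(rbind, lapply(corpus$songs, compute_song_metrics))
  rep_types <- length(unique(unlist(labs, use.names = FALSE)))
  rep_songs <- length(unique(vapply(labs, song_type_key, character(1),
                                    rule = song_type_rule)))
  lev <- mean_levenshtein(labs, mode = levenshtein_mode,
                          normalize = normalize_levenshtein)
  data.frame(
    bird_id = corpus$bird_id, sex = corpus$sex, treatment = corpus$treatment,
    n_songs = length(labs),
    syllable_type_repertoire = rep_types,
    song_type_repertoire = rep_songs,
    syllables_per_song = mean(per_song$n_syllables),
    syllable_types_per_song = mean(per_song$n_types),
    syllable_types_per_second = mean(per_song$types_per_second),
    syllables_per_second = mean(per_song$syllables_per_second),
    svi = mean(per_song$svi),
    levenshtein_distance = lev,
    stringsAsFactors = FALSE)
}

mean_levenshtein <- function(labs, mode = "successive", normalize = FALSE) {
  n <- length(labs)
  if (n < 2L) {
    warning("Levenshtein distance needs at least 2 songs; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  u <- unique(unlist(labs, use.names = FALSE))
  coded <- lapply(labs, function(s) match(s, u))
  if (mode == "successive") {
    d <- as.numeric(lev_cross_int(coded[-n], coded[-1L]))
    if (normalize) {
      len <- lengths(labs)
      d <- d / pmax(len[-n], len[-1L])
    }
  } else {
    m <- lev_matrix_int(coded)
    d <- as.numeric(m[upper.tri(m)])
    if (normalize) {
      len <- lengths(labs)
      mx <- outer(len, len, pmax)
      d <- d / mx[upper.tri(mx)]
    }
  }
  mean(d)
}

#' Diversity metrics for every bird in a study
#'
#' @param study a `song_study` (list of [bird_corpus()]).
#' @param ... passed to [compute_bird_metrics()].
#' @return `data.frame`, one row per bird.
#' @export
compute_study_metrics <- function(study, ...) {
  rows <- lapply(study, compute_bird_metrics, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
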