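#' @keywords internal
"_PACKAGE"

#' @useDynLib songsyntax, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats complete.cases cor lm model.matrix pf prcomp pt rnorm rpois
#'   runif sd setNames var as.formula reformulate
#' @importFrom utils read.delim write.csv read.csv head
NULL

SEXES <- c("male", "female")
TREATMENTS <- c("T", "T+E2", "control")

#' Construct a song from syllable annotations
#'
#' A song is an ordered sequence of labelled syllable intervals. Labels are
#' case-sensitive opaque strings; two labels are either identical or entirely
#' different. Onset/offset times are in seconds and may be omitted (all `NA`)
#' when only the label sequence is known, in which case rate metrics are
#' unavailable downstream.
#'
#' @param label character vector of syllable-type labels (non-empty strings).
#' @param onset,offset numeric vectors of interval times in seconds, or `NULL`
#'   for label-only songs. Labelled intervals must be time-ordered and
#'   non-overlapping (`offset[i] <= onset[i+1]`, to 1 ms tolerance).
#' @return A `data.frame` of class `song` with columns `label`, `onset`,
#'   `offset`.
#' @examples
#' song(c("A", "A", "B"), onset = c(0, 0.1, 0.2), offset = c(0.1, 0.2, 0.35))
#' @export
song <- function(label, onset = NULL, offset = NULL) {
  label <- as.character(label)
  if (length(label) == 0L)
    stop("a song must contain at least one syllable", call. = FALSE)
  if (any(is.na(label)) || any(!nzchar(label)))
    stop("syllable labels must be non-empty strings", call. = FALSE)
  if (is.null(onset) != is.null(offset))
    stop("provide both onset and offset, or neither", call. = FALSE)
  if (is.null(onset)) {
    onset <- rep(NA_real_, length(label))
    offset <- rep(NA_real_, length(label))
  } else {
    onset <- as.numeric(onset)
    offset <- as.numeric(offset)
    if (length(onset) != length(label) || length(offset) != length(label))
      stop("label, onset and offset must have equal length", call. = FALSE)
    ok <- !is.na(onset) & !is.na(offset)
    if (any(offset[ok] <= onset[ok]))
      stop("every syllable must satisfy offset > onset", call. = FALSE)
    if (any(ok) && any(diff(onset[ok]) < 0))
      stop("syllable onsets must be non-decreasing within a song", call. = FALSE)
    # overlap check at 1 ms tolerance
    if (sum(ok) > 1L) {
      on <- onset[ok]; off <- offset[ok]
      if (any(on[-1L] < off[-length(off)] - 1e-3))
        stop("syllable intervals overlap within a song", call. = FALSE)
    }
  }
  out <- data.frame(label = label, onset = onset, offset = offset,
                    stringsAsFactors = FALSE)
  class(out) <- c("song", "data.frame")
  out
}

#' Song duration in seconds
#'
#' Duration is the span from the first syllable onset to the last syllable
#' offset. `NA` when the song carries no timing information.
#'
#' @param x a [song()].
#' @return numeric scalar (seconds) or `NA`.
#' @export
song_duration <- function(x) {
  if (all(is.na(x$onset)) || all(is.na(x$offset))) return(NA_real_)
  max(x$offset, na.rm = TRUE) - min(x$onset, na.rm = TRUE)
}

#' Construct an annotated corpus for one bird
#'
#' Bundles one individual's songs with its sex, treatment group and optional
#' morphological covariates. This is the unit on which all per-bird metrics
#' are computed.
#'
#' @param bird_id character identifier.
#' @param sex `"male"` or `"female"`.
#' @param treatment `"T"`, `"T+E2"` or `"control"`.
#' @param songs list of [song()] objects in recording order.
#' @param body_mass optional body mass in grams.
#' @param nucleus_volumes optional named numeric vector with elements `HVC`,
#'   `RA`, `X` (volumes of the vocal control nuclei, mm^3).
#' @return A list of class `bird_corpus`.
#' @export
bird_corpus <- function(bird_id, sex, treatment, songs,
                        body_mass = NA_real_, nucleus_volumes = NULL) {
  sex <- match.arg(sex, SEXES)
  treatment <- match.arg(treatment, TREATMENTS)
  if (!is.list(songs) || length(songs) == 0L)
    stop("songs must be a non-empty list", call. = FALSE)
  songs <- lapply(songs, function(s) {
    if (!inherits(s, "song")) s <- song(s$label, s$onset, s$offset)
    s
  })
  if (!is.null(nucleus_volumes)) {
    if (!all(c("HVC", "RA", "X") %in% names(nucleus_volumes)))
      stop("nucleus_volumes needs named elements HVC, RA and X", call. = FALSE)
    nucleus_volumes <- nucleus_volumes[c("HVC", "RA", "X")]
  }
  structure(list(bird_id = as.character(bird_id), sex = sex,
                 treatment = treatment, songs = songs,
                 body_mass = as.numeric(body_mass),
                 nucleus_volumes = nucleus_volumes),
            class = "bird_corpus")
}

#' Keep only the first n songs of a corpus
#'
#' Analyses are conventionally based on the first 30 songs each bird produced;
#' corpora holding fewer songs are kept as-is (callers may flag them).
#'
#' @param corpus a [bird_corpus()].
#' @param n maximum number of songs to retain (default 30).
#' @return the truncated corpus.
#' @export
truncate_corpus <- function(corpus, n = 30L) {
  stopifnot(inherits(corpus, "bird_corpus"), n >= 1L)
  if (length(corpus$songs) > n) corpus$songs <- corpus$songs[seq_len(n)]
  corpus
}

#' @export
print.bird_corpus <- function(x, ...) {
  n_tok <- sum(vapply(x$songs, nrow, integer(1)))
  n_typ <- length(unique(unlist(lapply(x$songs, `[[`, "label"))))
  cat(sprintf("<bird_corpus> %s (%s, %s): %d songs, %d syllables, %d syllable types\n",
              x$bird_id, x$sex, x$treatment, length(x$songs), n_tok, n_typ))
  invisible(x)
}

#' @export
print.song_study <- function(x, ...) {
  sexes <- vapply(x, `[[`, character(1), "sex")
  cat(sprintf("<song_study> %d birds (%d male, %d female)\n",
              length(x), sum(sexes == "male"), sum(sexes == "female")))
  invisible(x)
}

as_song_study <- function(corpora) {
  names(corpora) <- vapply(corpora, `[[`, character(1), "bird_id")
  structure(corpora, class = "song_study")
}

song_labels <- function(corpus) lapply(corpus$songs, `[[`, "label")

#' Extract per-bird covariates from a study
#'
#' Collects body mass and vocal-control-nucleus volumes (when present on the
#' corpora) into a per-bird table, ready to merge with a metrics table for
#' the regression stage.
#'
#' @param study a `song_study` (list of [bird_corpus()]).
#' @return `data.frame` with columns `bird_id`, `body_mass`, `hvc_volume`,
#'   `ra_volume`, `x_volume` (the latter three `NA` when absent).
#' @export
study_covariates <- function(study) {
  rows <- lapply(study, function(b) {
    v <- b$nucleus_volumes
    data.frame(bird_id = b$bird_id, body_mass = b$body_mass,
               hvc_volume = if (is.null(v)) NA_real_ else unname(v["HVC"]),
               ra_volume = if (is.null(v)) NA_real_ else unname(v["RA"]),
               x_volume = if (is.null(v)) NA_real_ else unname(v["X"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
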