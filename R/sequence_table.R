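SEQ_COLS <- c("bird_id", "sex", "treatment", "song_index", "syllable",
              "onset_s", "offset_s")

#' Read a tab-separated syllable sequence table into a study
#'
#' The sequence table is the package's plain-text exchange format: one row per
#' syllable, columns `bird_id`, `sex`, `treatment`, `song_index`, `syllable`,
#' `onset_s`, `offset_s` (the last three of `song_index`/`onset_s`/`offset_s`
#' may be absent). Rows are grouped into songs by `song_index` within bird;
#' when `song_index` is missing and times are present, songs are instead
#' segmented wherever the silent gap between consecutive syllables reaches
#' `gap_threshold`, and segments shorter than `min_duration` are discarded —
#' the conventional operational song definition (>= 1 s of sound bounded by
#' >= 0.4 s of silence).
#'
#' @param path path to the TSV file.
#' @param gap_threshold silence (s) that separates two songs when segmenting
#'   by time; only used when `song_index` is absent.
#' @param min_duration minimum song duration (s) kept when segmenting by time;
#'   only used when `song_index` is absent.
#' @return A list of [bird_corpus()] objects (class `song_study`), in order of
#'   first appearance. Corpora with fewer than 30 songs are kept (callers may
#'   flag them); an empty file yields an empty study.
#' @export
read_sequence_table <- function(path, gap_threshold = 0.4, min_duration = 1) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("bird_id", "sex", "treatment", "syllable")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sequence table lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(as_song_study(list()))
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex))
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  bad_trt <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad_trt))
    stop("unknown treatment value(s): ", paste(bad_trt, collapse = ", "),
         call. = FALSE)
  has_idx <- "song_index" %in% names(df) && !all(is.na(df$song_index))
  has_time <- all(c("onset_s", "offset_s") %in% names(df))
  if (has_time) {
    df$onset_s <- as.numeric(df$onset_s)
    df$offset_s <- as.numeric(df$offset_s)
  }
  if (!has_idx && !has_time)
    stop("sequence table needs either song_index or onset_s/offset_s columns",
         call. = FALSE)

  corpora <- list()
  for (id in unique(df$bird_id)) {
    rows <- df[df$bird_id == id, , drop = FALSE]
    sex <- unique(rows$sex); trt <- unique(rows$treatment)
    if (length(sex) > 1L || length(trt) > 1L)
      stop("bird ", id, " has inconsistent sex/treatment values", call. = FALSE)
    if (has_idx) {
      idx <- as.numeric(rows$song_index)
      if (any(is.na(idx)))
        stop("bird ", id, " has missing song_index values", call. = FALSE)
      parts <- split(rows, factor(idx, levels = unique(idx[order(idx)])))
    } else {
      if (any(is.na(rows$onset_s)))
        stop("bird ", id, ": onset times required to segment songs", call. = FALSE)
      if (any(diff(rows$onset_s) < 0))
        stop("bird ", id, ": onsets are not monotone in recording order",
             call. = FALSE)
      gap <- rows$onset_s[-1L] - rows$offset_s[-nrow(rows)]
      grp <- cumsum(c(0, gap >= gap_threshold - 1e-9))
      parts <- split(rows, grp)
      keep <- vapply(parts, function(p) {
        max(p$offset_s) - min(p$onset_s) >= min_duration - 1e-9
      }, logical(1))
      parts <- parts[keep]
    }
    if (length(parts) == 0L) next
    songs <- lapply(parts, function(p) {
      if (has_time && any(diff(p$onset_s) < 0))
        stop("bird ", id, ": onsets are not monotone within a song", call. = FALSE)
      if (has_time && !any(is.na(p$onset_s)))
        song(p$syllable, p$onset_s, p$offset_s)
      else song(p$syllable)
    })
    corpora[[id]] <- bird_corpus(id, sex, trt, unname(songs))
  }
  as_song_study(unname(corpora))
}

#' Write a study back to the sequence-table format
#'
#' Inverse of [read_sequence_table()]: times are written at millisecond
#' precision, so a read/write round trip preserves labels, song grouping and
#' times to 1 ms.
#'
#' @param study a `song_study` (list of [bird_corpus()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sequence_table <- function(study, path) {
  rows <- lapply(study, function(b) {
    do.call(rbind, lapply(seq_along(b$songs), function(i) {
      s <- b$songs[[i]]
      data.frame(bird_id = b$bird_id, sex = b$sex, treatment = b$treatment,
                 song_index = i, syllable = s$label,
                 onset_s = round(s$onset, 3), offset_s = round(s$offset, 3),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    setNames(as.data.frame(matrix(nrow = 0, ncol = 7)), SEQ_COLS)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-bird metrics table to CSV
#'
#' One row per bird; diversity columns first, then the two network metrics.
#'
#' @param metrics data.frame as produced by [compute_study_metrics()] (with or
#'   without the network columns merged in).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  lead <- intersect(c("bird_id", "sex", "treatment"), names(metrics))
  main <- intersect(c(DIVERSITY_METRICS, NETWORK_METRICS), names(metrics))
  rest <- setdiff(names(metrics), c(lead, main))
  write.csv(metrics[, c(lead, main, rest), drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL
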