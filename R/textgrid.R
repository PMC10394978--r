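#' Read syllable annotations from a PRAAT TextGrid interval tier
#'
#' Parses the PRAAT TextGrid text format, in both its long (keyword = value)
#' and short (bare values) dialects, and extracts the labelled intervals of
#' one named interval tier. Intervals with empty labels (silence) are dropped.
#' Because PRAAT imposes no tier naming convention, the tier must be named
#' explicitly.
#'
#' @param path path to a `.TextGrid` file (text, not binary).
#' @param tier_name name of the interval tier holding syllable labels.
#' @return A [song()]-shaped `data.frame` (`label`, `onset`, `offset`) with the
#'   labelled intervals in time order; zero rows when the tier holds only
#'   silence.
#' @details Labels are read verbatim (doubled quotes unescaped); times are in
#'   seconds. Overlapping labelled intervals raise a validation error; point
#'   (TextTier) tiers of the requested name raise an error since syllables are
#'   intervals.
#' @export
parse_textgrid <- function(path, tier_name) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3L || !grepl("ooTextFile", lines[1L]) ||
      !grepl("TextGrid", lines[2L]))
    stop("not a PRAAT TextGrid text file: ", path, call. = FALSE)
  body <- trimws(lines[-(1:2)])
  body <- body[nzchar(body)]
  long <- any(grepl("^item", body))
  tiers <- if (long) parse_textgrid_long(body) else parse_textgrid_short(body)
  hit <- which(vapply(tiers, function(t) identical(t$name, tier_name), logical(1)))
  if (length(hit) == 0L)
    stop(sprintf("tier '%s' not found (tiers present: %s)", tier_name,
                 paste(vapply(tiers, `[[`, character(1), "name"), collapse = ", ")),
         call. = FALSE)
  tier <- tiers[[hit[1L]]]
  if (!identical(tier$class, "IntervalTier"))
    stop(sprintf("tier '%s' is a %s, not an interval tier", tier_name, tier$class),
         call. = FALSE)
  iv <- tier$intervals
  iv <- iv[nzchar(iv$text), , drop = FALSE]
  if (nrow(iv) == 0L)
    return(song_frame(character(0), numeric(0), numeric(0)))
  iv <- iv[order(iv$xmin), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$xmin[-1L] < iv$xmax[-nrow(iv)] - 1e-6))
    stop("labelled intervals overlap in tier '", tier_name, "'", call. = FALSE)
  song_frame(iv$text, iv$xmin, iv$xmax)
}

song_frame <- function(label, onset, offset) {
  out <- data.frame(label = as.character(label), onset = as.numeric(onset),
                    offset = as.numeric(offset), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

tg_unquote <- function(x) {
  x <- sub('^"', "", sub('"$', "", x))
  gsub('""', '"', x)
}

tg_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("malformed TextGrid: expected a number, got '", x, "'",
                     call. = FALSE)
  v
}

# Long dialect: lines like 'class = "IntervalTier"', 'xmin = 0.3', 'text = "A"'.
parse_textgrid_long <- function(body) {
  kv_val <- function(line) trimws(sub("^[^=]*=", "", line))
  tiers <- list()
  cur <- NULL
  pending <- list()        # xmin/xmax/text of the interval being read
  in_interval <- FALSE
  flush_interval <- function() {
    if (in_interval && !is.null(cur)) {
      if (is.null(pending$xmin))
        stop("malformed TextGrid: interval without xmin", call. = FALSE)
      xmax <- if (is.null(pending$xmax)) pending$xmin else pending$xmax  # points
      txt <- if (is.null(pending$text)) "" else pending$text
      cur$intervals[[length(cur$intervals) + 1L]] <<-
        list(xmin = pending$xmin, xmax = xmax, text = txt)
    }
    pending <<- list(); in_interval <<- FALSE
  }
  flush_tier <- function() {
    flush_interval()
    if (!is.null(cur)) tiers[[length(tiers) + 1L]] <<- cur
    cur <<- NULL
  }
  for (line in body) {
    if (grepl("^item\\s*\\[\\s*[0-9]+\\s*\\]", line)) {
      flush_tier()
      cur <- list(class = NA_character_, name = NA_character_, intervals = list())
    } else if (grepl("^(intervals|points)\\s*\\[", line)) {
      flush_interval()
      in_interval <- TRUE
    } else if (grepl("^class\\s*=", line) && !is.null(cur) && is.na(cur$class)) {
      cur$class <- tg_unquote(kv_val(line))
    } else if (grepl("^name\\s*=", line) && !is.null(cur) && is.na(cur$name)) {
      cur$name <- tg_unquote(kv_val(line))
    } else if (grepl("^(xmin|number|time)\\s*=", line) && in_interval) {
      pending$xmin <- tg_num(kv_val(line))
    } else if (grepl("^xmax\\s*=", line) && in_interval) {
      pending$xmax <- tg_num(kv_val(line))
    } else if (grepl("^(text|mark)\\s*=", line) && in_interval) {
      pending$text <- tg_unquote(kv_val(line))
    }
  }
  flush_tier()
  lapply(tiers, finalize_tier)
}

# Short dialect: header values then, per tier, class, name, xmin, xmax, n,
# followed by n (xmin, xmax, text) triples (or n (time, mark) pairs).
parse_textgrid_short <- function(body) {
  i <- 1L
  take <- function() {
    if (i > length(body)) stop("malformed TextGrid: truncated file", call. = FALSE)
    v <- body[i]; i <<- i + 1L; v
  }
  take()                              # global xmin
  take()                              # global xmax
  flag <- take()                      # <exists> / <absent>
  if (grepl("absent", flag)) return(list())
  n_tiers <- as.integer(tg_num(take()))
  tiers <- vector("list", n_tiers)
  for (t in seq_len(n_tiers)) {
    cls <- tg_unquote(take())
    nm <- tg_unquote(take())
    take(); take()                    # tier xmin, xmax
    n <- as.integer(tg_num(take()))
    ivs <- vector("list", n)
    for (k in seq_len(n)) {
      if (identical(cls, "IntervalTier")) {
        x0 <- tg_num(take()); x1 <- tg_num(take()); txt <- tg_unquote(take())
        ivs[[k]] <- list(xmin = x0, xmax = x1, text = txt)
      } else {
        x0 <- tg_num(take()); txt <- tg_unquote(take())
        ivs[[k]] <- list(xmin = x0, xmax = x0, text = txt)
      }
    }
    tiers[[t]] <- finalize_tier(list(class = cls, name = nm, intervals = ivs))
  }
  tiers
}

finalize_tier <- function(t) {
  iv <- t$intervals
  t$intervals <- data.frame(
    xmin = vapply(iv, function(z) z$xmin, numeric(1)),
    xmax = vapply(iv, function(z) z$xmax, numeric(1)),
    text = vapply(iv, function(z) z$text, character(1)),
    stringsAsFactors = FALSE)
  t
}
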