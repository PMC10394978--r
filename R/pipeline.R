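#' Configuration for a full analysis run
#'
#' @param input input path: a sequence-table TSV, a per-bird metrics CSV, or a
#'   directory of TextGrid files containing a `manifest.tsv` (columns `file`,
#'   `bird_id`, `sex`, `treatment`, `tier`; one row per song, in recording
#'   order within bird).
#' @param input_kind one of `"sequence_table"`, `"textgrid_dir"`,
#'   `"metrics_table"`. With `"metrics_table"` the corpus stages are skipped
#'   and the statistics run directly on the supplied table.
#' @param out_dir output directory (created if needed).
#' @param songs_per_bird per-bird song cap; analyses use the first
#'   `songs_per_bird` songs in recording order (default 30).
#' @param song_type_rule,levenshtein_mode,normalize_levenshtein passed to
#'   [compute_bird_metrics()].
#' @param network_exclusion_threshold networks with at most this many
#'   syllable types get missing network metrics (default 3).
#' @param include_treatments treatment groups entering the statistics stage;
#'   defaults to the steroid groups, excluding controls (whose sparse plastic
#'   song cannot be annotated reliably).
#' @param n_pcs number of principal components carried into the regressions
#'   (default 3).
#' @return list of class `run_config`.
#' @export
run_config <- function(input,
                       input_kind = c("sequence_table", "textgrid_dir",
                                      "metrics_table"),
                       out_dir = ".",
                       songs_per_bird = 30L,
                       song_type_rule = "collapsed",
                       levenshtein_mode = "successive",
                       normalize_levenshtein = FALSE,
                       network_exclusion_threshold = 3L,
                       include_treatments = c("T", "T+E2"),
                       n_pcs = 3L) {
  input_kind <- match.arg(input_kind)
  stopifnot(network_exclusion_threshold >= 0, songs_per_bird >= 2, n_pcs >= 1)
  structure(list(input = input, input_kind = input_kind, out_dir = out_dir,
                 songs_per_bird = as.integer(songs_per_bird),
                 song_type_rule = song_type_rule,
                 levenshtein_mode = levenshtein_mode,
                 normalize_levenshtein = normalize_levenshtein,
                 network_exclusion_threshold =
                   as.integer(network_exclusion_threshold),
                 include_treatments = include_treatments,
                 n_pcs = as.integer(n_pcs)),
            class = "run_config")
}

#' Read a per-bird metrics table
#'
#' @param path CSV with columns `bird_id`, `sex`, `treatment` and any of the
#'   metric columns (see [compute_bird_metrics()]); optional covariates
#'   `body_mass`, `hvc_volume`, `ra_volume`, `x_volume`.
#' @return validated `data.frame`.
#' @export
read_metrics_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "sex", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metrics table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$sex), SEXES)
  if (length(bad)) stop("unknown sex value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad)) stop("unknown treatment value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!length(intersect(c(DIVERSITY_METRICS, NETWORK_METRICS), names(df))))
    stop("metrics table contains no recognised metric columns", call. = FALSE)
  df
}

load_textgrid_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop("textgrid_dir input needs a manifest.tsv in ", dir, call. = FALSE)
  man <- read.delim(manifest_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("file", "bird_id", "sex", "treatment", "tier")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest.tsv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  corpora <- lapply(split(man, man$bird_id)[unique(man$bird_id)], function(rows) {
    songs <- lapply(seq_len(nrow(rows)), function(i) {
      tg <- parse_textgrid(file.path(dir, rows$file[i]), rows$tier[i])
      if (nrow(tg) == 0L)
        stop("TextGrid ", rows$file[i], " has no labelled syllables",
             call. = FALSE)
      song(tg$label, tg$onset, tg$offset)
    })
    bird_corpus(rows$bird_id[1L], rows$sex[1L], rows$treatment[1L], songs)
  })
  as_song_study(unname(corpora))
}

#' Group-level statistics for a per-bird metrics table
#'
#' Runs the statistics stage on a metrics table: two-way ANOVA (treatment x
#' sex, Type III SS, partial eta-squared) for every available metric;
#' unrotated PCA of the standardized metrics (incomplete rows dropped and
#' recorded); per-sex OLS regressions of the first `n_pcs` component scores
#' on nucleus volumes and body mass when those covariates are present; and
#' the per-sex correlation between syllable-type repertoire and network path
#' length.
#'
#' @param metrics per-bird metrics `data.frame` (already restricted to the
#'   treatment groups under analysis).
#' @param n_pcs number of leading components used downstream.
#' @return list of class `syntax_stats` with elements `anova`, `pca`,
#'   `scores` (bird x PC with metadata), `regressions` (nested list
#'   sex -> PC -> `syntax_ols`), `correlations`, `notes`.
#' @export
run_statistics <- function(metrics, n_pcs = 3L) {
  if (min(table(metrics$sex)) < 2L || length(unique(metrics$sex)) < 2L)
    stop("statistics need at least 2 birds of each sex", call. = FALSE)
  notes <- character(0)
  metric_cols <- intersect(c(DIVERSITY_METRICS, NETWORK_METRICS),
                           names(metrics))
  anova_tab <- anova_table(metrics, metrics = metric_cols)

  x <- metrics[, metric_cols, drop = FALSE]
  rownames(x) <- metrics$bird_id
  pca <- pca_unrotated(x)
  if (length(pca$dropped_rows))
    notes <- c(notes, paste0("PCA dropped incomplete rows: ",
                             paste(pca$dropped_rows, collapse = ", ")))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  scores <- data.frame(bird_id = rownames(pca$scores),
                       pca$scores[, seq_len(n_pcs), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  scores <- merge(metrics[, c("bird_id", "sex", "treatment")], scores,
                  by = "bird_id", sort = FALSE)

  predictors <- intersect(c("hvc_volume", "ra_volume", "x_volume", "body_mass"),
                          names(metrics))
  regressions <- list()
  if (length(predictors) >= 1L) {
    dat <- merge(scores, metrics[, c("bird_id", predictors)], by = "bird_id",
                 sort = FALSE)
    for (sx in intersect(SEXES, unique(dat$sex))) {
      dsx <- dat[dat$sex == sx, , drop = FALSE]
      if (nrow(dsx) < length(predictors) + 2L) {
        notes <- c(notes, paste0("regressions skipped for ", sx,
                                 ": too few complete rows"))
        next
      }
      regressions[[sx]] <- lapply(setNames(nm = paste0("PC", seq_len(n_pcs))),
                                  function(pc)
        ols_regression(dsx, pc, predictors))
    }
  } else {
    notes <- c(notes, "no morphological covariates: regressions skipped")
  }

  correlations <- NULL
  if (all(c("syllable_type_repertoire", "network_path_length") %in%
          names(metrics))) {
    correlations <- vapply(intersect(SEXES, unique(metrics$sex)), function(sx) {
      m <- metrics[metrics$sex == sx, ]
      ok <- complete.cases(m[, c("syllable_type_repertoire",
                                 "network_path_length")])
      if (sum(ok) < 3L) return(NA_real_)
      tryCatch(pearson_correlation(m$syllable_type_repertoire[ok],
                                   m$network_path_length[ok]),
               error = function(e) NA_real_)   # constant within sex
    }, numeric(1))
  }

  structure(list(anova = anova_tab, pca = pca, scores = scores,
                 regressions = regressions, correlations = correlations,
                 notes = notes),
            class = "syntax_stats")
}

#' @export
print.syntax_stats <- function(x, ...) {
  cat("Group-level statistics\n\n")
  sex_rows <- x$anova[x$anova$term == "sex", ]
  cat("Sex effects (Type III two-way ANOVA):\n")
  print.data.frame(sex_rows[, c("metric", "df", "df_residual", "F", "p",
                                "partial_eta_sq")],
                   digits = 4, row.names = FALSE)
  cat(sprintf("\nPCA: first 3 components explain %.1f%% of variance\n",
              100 * x$pca$cumulative_proportion[min(3, length(x$pca$eigenvalues))]))
  if (!is.null(x$correlations)) {
    cat("Repertoire vs path length correlation:",
        paste(sprintf("%s r = %.2f", names(x$correlations), x$correlations),
              collapse = ", "), "\n")
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Flatten per-sex regressions into one table
#'
#' @param stats a [run_statistics()] result.
#' @return `data.frame`: one row per sex x component x term with estimate,
#'   SE, t, p and the model-level F, df, R-squared and p.
#' @export
regression_table <- function(stats) {
  rows <- list()
  for (sx in names(stats$regressions)) {
    for (pc in names(stats$regressions[[sx]])) {
      r <- stats$regressions[[sx]][[pc]]
      rows[[length(rows) + 1L]] <-
        cbind(sex = sx, component = pc, r$coefficients,
              model_F = r$F, model_df = r$df,
              model_df_residual = r$df_residual,
              r_squared = r$r_squared, model_p = r$p,
              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sex = character(0), component = character(0),
                      term = character(0), estimate = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      model_F = numeric(0), model_df = numeric(0),
                      model_df_residual = numeric(0), r_squared = numeric(0),
                      model_p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Corpora -> per-bird metrics -> syllable networks -> group statistics, with
#' every exclusion logged. Outputs written to `config$out_dir`: `metrics.csv`
#' (one row per bird), `anova.csv` (metric x term), `pca_summary.csv`,
#' `pca_loadings.csv`, `pca_scores.csv`, `regression.csv` and
#' `exclusions.csv`. Re-running with an identical configuration and inputs
#' reproduces all outputs byte for byte (the analysis stages draw no random
#' numbers).
#'
#' @param config a [run_config()].
#' @return (invisibly) list of class `syntax_run` with elements `metrics`,
#'   `stats` (`NULL` when skipped), `exclusions`, `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  excl <- data.frame(bird_id = character(0), stage = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  note_excl <- function(id, stage, reason)
    rbind(excl, data.frame(bird_id = id, stage = stage, reason = reason,
                           stringsAsFactors = FALSE))

  if (config$input_kind == "metrics_table") {
    metrics <- read_metrics_table(config$input)
  } else {
    study <- switch(config$input_kind,
                    sequence_table = read_sequence_table(config$input),
                    textgrid_dir = load_textgrid_dir(config$input))
    short <- vapply(study, function(b)
      length(b$songs) < config$songs_per_bird, logical(1))
    for (id in names(study)[short])
      excl <- note_excl(id, "corpus",
                        sprintf("only %d songs (< %d); kept but flagged",
                                length(study[[id]]$songs),
                                config$songs_per_bird))
    study <- as_song_study(lapply(study, truncate_corpus,
                                  n = config$songs_per_bird))
    metrics <- compute_study_metrics(
      study,
      song_type_rule = config$song_type_rule,
      levenshtein_mode = config$levenshtein_mode,
      normalize_levenshtein = config$normalize_levenshtein)
    netm <- network_metrics_for_study(
      study, exclusion_threshold = config$network_exclusion_threshold)
    for (id in netm$bird_id[netm$excluded])
      excl <- note_excl(id, "network",
                        sprintf("network has <= %d syllable types",
                                config$network_exclusion_threshold))
    metrics <- merge(metrics,
                     netm[, c("bird_id", "network_path_length",
                              "network_density")],
                     by = "bird_id", sort = FALSE)
  }

  files <- c(metrics = file.path(config$out_dir, "metrics.csv"))
  write_metrics_csv(metrics, files[["metrics"]])

  drop <- !(metrics$treatment %in% config$include_treatments)
  for (id in metrics$bird_id[drop])
    excl <- note_excl(id, "statistics",
                      sprintf("treatment '%s' not analysed",
                              metrics$treatment[metrics$bird_id == id]))
  stat_metrics <- metrics[!drop, , drop = FALSE]

  stats <- NULL
  sex_n <- table(factor(stat_metrics$sex, levels = SEXES))
  if (any(sex_n < 2L)) {
    warning("fewer than 2 birds per sex after exclusions; statistics skipped",
            call. = FALSE)
  } else {
    stats <- run_statistics(stat_metrics, n_pcs = config$n_pcs)
    files[["anova"]] <- file.path(config$out_dir, "anova.csv")
    write.csv(stats$anova, files[["anova"]], row.names = FALSE)
    files[["pca_summary"]] <- file.path(config$out_dir, "pca_summary.csv")
    write.csv(data.frame(component = colnames(stats$pca$loadings),
                         eigenvalue = stats$pca$eigenvalues,
                         proportion = stats$pca$proportion_explained,
                         cumulative = stats$pca$cumulative_proportion),
              files[["pca_summary"]], row.names = FALSE)
    files[["pca_loadings"]] <- file.path(config$out_dir, "pca_loadings.csv")
    write.csv(data.frame(metric = rownames(stats$pca$loadings),
                         stats$pca$loadings),
              files[["pca_loadings"]], row.names = FALSE)
    files[["pca_scores"]] <- file.path(config$out_dir, "pca_scores.csv")
    write.csv(stats$scores, files[["pca_scores"]], row.names = FALSE)
    files[["regression"]] <- file.path(config$out_dir, "regression.csv")
    write.csv(regression_table(stats), files[["regression"]],
              row.names = FALSE)
  }

  files[["exclusions"]] <- file.path(config$out_dir, "exclusions.csv")
  write.csv(excl, files[["exclusions"]], row.names = FALSE)

  invisible(structure(list(metrics = metrics, stats = stats,
                           exclusions = excl, files = files),
                      class = "syntax_run"))
}

#' @export
print.syntax_run <- function(x, ...) {
  cat(sprintf("<syntax_run> %d birds; %d exclusion records; outputs: %s\n",
              nrow(x$metrics), nrow(x$exclusions),
              paste(basename(unlist(x$files)), collapse = ", ")))
  invisible(x)
}
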