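#' Parameters for the synthetic song generator
#'
#' Synthetic songs are generated at the phrase level, mirroring the phrase
#' structure of canary-style song: a song is a sequence of phrases, each
#' phrase one syllable type repeated a random number of times. Successive
#' phrase types follow a per-bird first-order Markov chain whose transition
#' matrix interpolates between a flexible component (`stereotypy = 0`:
#' uniform over each type's `branching` alternative targets) and a fixed
#' per-bird permutation cycle (`stereotypy = 1`, every bird sings its types
#' in one fixed order). Repertoire size and stereotypy are independently
#' controllable, which is what separates the sexes in this study design:
#' males sing from a larger repertoire in more fixed order, females from a
#' small repertoire in flexible order, while phrase counts and repeat counts
#' are set so both sexes produce songs of matched length and tempo.
#'
#' @param repertoire_size number of syllable types available to the bird
#'   (the sex-level mean when `repertoire_sd > 0`; see [generate_study()]).
#' @param phrase_count_mean mean number of phrases per song (Poisson,
#'   truncated at 1).
#' @param repeat_mean mean within-phrase repeat count (1 + Poisson).
#' @param stereotypy weight in \[0, 1\] on the fixed transition cycle.
#' @param branching number of alternative transition targets each syllable
#'   type has besides its cycle successor (capped at `repertoire_size - 1`).
#'   The flexible component of the chain is uniform over this per-bird random
#'   target set rather than over all types: real birds use a limited set of
#'   transitions, so even flexible singers leave part of the possible
#'   transition space unused.
#' @param repertoire_sd between-bird standard deviation of repertoire size;
#'   individual repertoires are drawn as `max(2, round(N(repertoire_size,
#'   repertoire_sd)))` per bird, reflecting the substantial individual
#'   variability of real repertoires (0 = all birds identical).
#' @param fixed_phrase_count if `TRUE`, every song has exactly
#'   `round(phrase_count_mean)` phrases instead of a Poisson draw (useful for
#'   studying the chain in isolation from length variation).
#' @param syllable_duration syllable length in seconds.
#' @param gap silent gap between syllables within a song, seconds.
#' @param songs_per_bird number of songs per corpus (default 30).
#' @return list of class `synth_params`.
#' @details Stereotypy also governs the opening phrase: each song starts at
#'   the bird's characteristic cycle start with probability `stereotypy`, and
#'   at a uniformly random type otherwise. At `stereotypy = 1` with a fixed
#'   phrase count the chain is fully deterministic and the bird sings a
#'   single song type.
#' @seealso [default_synth_params()] for the sex-specific defaults.
#' @export
synth_params <- function(repertoire_size, phrase_count_mean, repeat_mean,
                         stereotypy, repertoire_sd = 0, branching = 3L,
                         fixed_phrase_count = FALSE,
                         syllable_duration = 0.08, gap = 0.02,
                         songs_per_bird = 30L) {
  stopifnot(repertoire_size >= 1, phrase_count_mean >= 1, repeat_mean >= 1,
            stereotypy >= 0, stereotypy <= 1, repertoire_sd >= 0,
            branching >= 1, syllable_duration > 0, gap >= 0,
            songs_per_bird >= 2)
  structure(list(repertoire_size = as.integer(repertoire_size),
                 phrase_count_mean = phrase_count_mean,
                 repeat_mean = repeat_mean, stereotypy = stereotypy,
                 repertoire_sd = repertoire_sd,
                 branching = as.integer(branching),
                 fixed_phrase_count = isTRUE(fixed_phrase_count),
                 syllable_duration = syllable_duration, gap = gap,
                 songs_per_bird = as.integer(songs_per_bird)),
            class = "synth_params")
}

#' Default sex-specific generator parameters
#'
#' The defaults encode the study conditions the generator emulates: males
#' draw from 15 syllable types with highly stereotyped transitions, females
#' from 6 types with flexible transitions, and phrase/repeat counts are set
#' so both sexes average roughly 69 syllables per song (matching the study's
#' 57,872 syllables over 840 songs) at the same tempo. With these settings
#' males average about 15 and females about 5-6 syllable types per song.
#'
#' @param sex `"male"` or `"female"`.
#' @return a [synth_params()] object.
#' @export
default_synth_params <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male")
    synth_params(repertoire_size = 15, phrase_count_mean = 23,
                 repeat_mean = 3.0, stereotypy = 0.92, repertoire_sd = 2.5)
  else
    synth_params(repertoire_size = 6, phrase_count_mean = 14,
                 repeat_mean = 4.9, stereotypy = 0.45, repertoire_sd = 1.2)
}

# Phrase-type transition matrix: stereotypy-weighted mix of a fixed
# permutation cycle and a flexible component that is uniform over a per-bird
# random set of `branching` alternative targets for each type.
transition_matrix <- function(K, stereotypy, branching = K - 1L) {
  if (K == 1L) return(matrix(1, 1, 1))
  perm <- sample.int(K)
  nxt <- integer(K)
  nxt[perm] <- perm[c(2:K, 1L)]
  C <- matrix(0, K, K)
  C[cbind(seq_len(K), nxt)] <- 1
  b <- min(branching, K - 1L)
  U <- matrix(0, K, K)
  for (i in seq_len(K)) {
    targets <- sample(setdiff(seq_len(K), i), b)
    U[i, targets] <- 1 / b
  }
  stereotypy * C + (1 - stereotypy) * U
}

#' Generate one bird's synthetic song corpus
#'
#' Deterministic given `seed`: the per-bird transition cycle, phrase counts,
#' repeat counts and types are all drawn from R's RNG after seeding. Syllable
#' onsets/offsets are laid out on a regular grid from `syllable_duration` and
#' `gap`, rounded to 1 ms.
#'
#' @param params a [synth_params()] object.
#' @param bird_id,sex,treatment corpus metadata (see [bird_corpus()]).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param body_mass,nucleus_volumes optional covariates stored on the corpus.
#' @return a [bird_corpus()] with `params$songs_per_bird` songs.
#' @export
generate_bird_corpus <- function(params, bird_id, sex, treatment, seed = NULL,
                                 body_mass = NA_real_, nucleus_volumes = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(seed)) set.seed(seed)
  K <- params$repertoire_size
  types <- sprintf("S%02d", seq_len(K))
  P <- transition_matrix(K, params$stereotypy, params$branching)
  start <- sample.int(K, 1L)             # the bird's characteristic opening
  step <- params$syllable_duration + params$gap
  songs <- lapply(seq_len(params$songs_per_bird), function(i) {
    n_phr <- if (params$fixed_phrase_count) max(1L, round(params$phrase_count_mean))
             else max(1L, rpois(1L, params$phrase_count_mean))
    idx <- integer(n_phr)
    idx[1L] <- if (runif(1L) < params$stereotypy) start else sample.int(K, 1L)
    if (n_phr > 1L) for (t in 2:n_phr)
      idx[t] <- sample.int(K, 1L, prob = P[idx[t - 1L], ])
    reps <- 1L + rpois(n_phr, max(0, params$repeat_mean - 1))
    lab <- rep(types[idx], times = reps)
    m <- length(lab)
    onset <- round((seq_len(m) - 1L) * step, 3)
    song(lab, onset, round(onset + params$syllable_duration, 3))
  })
  bird_corpus(bird_id, sex, treatment, songs, body_mass = body_mass,
              nucleus_volumes = nucleus_volumes)
}

#' Generate a full synthetic study
#'
#' Produces corpora for `n_male` males and `n_female` females (defaults 15
#' and 13, the analysed sample of the study design), each with the
#' sex-specific generator parameters, treatments assigned in alternation
#' within sex (treatment is a null factor: it influences nothing). Per-bird
#' seeds are derived reproducibly from `seed`, so two studies with the same
#' seed are identical. Body mass and HVC/RA/Area X volumes are drawn from
#' sex-specific normals, independent of the song parameters (a null
#' brain-behaviour relation).
#'
#' @param male_params,female_params [synth_params()] objects (defaults from
#'   [default_synth_params()]).
#' @param n_male,n_female numbers of birds per sex.
#' @param treatments treatment labels cycled over birds within sex.
#' @param seed integer study seed.
#' @return a `song_study` (named list of [bird_corpus()]).
#' @export
generate_study <- function(male_params = default_synth_params("male"),
                           female_params = default_synth_params("female"),
                           n_male = 15L, n_female = 13L,
                           treatments = c("T", "T+E2"), seed = 1L) {
  set.seed(seed)
  n <- n_male + n_female
  bird_seeds <- sample.int(.Machine$integer.max - 1L, n)
  sexes <- rep(c("male", "female"), c(n_male, n_female))
  ids <- c(if (n_male) sprintf("M%02d", seq_len(n_male)),
           if (n_female) sprintf("F%02d", seq_len(n_female)))
  trts <- c(if (n_male) rep_len(treatments, n_male),
            if (n_female) rep_len(treatments, n_female))
  morph <- draw_morphometrics(sexes)
  base <- list(male = male_params, female = female_params)
  reps <- vapply(seq_len(n), function(i) {
    p <- base[[sexes[i]]]
    max(2L, as.integer(round(rnorm(1L, p$repertoire_size, p$repertoire_sd))))
  }, integer(1))
  corpora <- lapply(seq_len(n), function(i) {
    p <- base[[sexes[i]]]
    p$repertoire_size <- reps[i]
    generate_bird_corpus(p, ids[i], sexes[i], trts[i], seed = bird_seeds[i],
                         body_mass = morph$body_mass[i],
                         nucleus_volumes = c(HVC = morph$hvc[i],
                                             RA = morph$ra[i],
                                             X = morph$x[i]))
  })
  as_song_study(corpora)
}

# Body mass (g) and song-nucleus volumes (mm^3) around typical canary values,
# with the male-biased nucleus sizes that persist under steroid treatment.
draw_morphometrics <- function(sexes) {
  n <- length(sexes)
  male <- sexes == "male"
  list(body_mass = round(rnorm(n, 21, 1.5), 1),
       hvc = round(pmax(0.05, rnorm(n, ifelse(male, 0.60, 0.35),
                                    ifelse(male, 0.08, 0.06))), 3),
       ra = round(pmax(0.02, rnorm(n, ifelse(male, 0.23, 0.14),
                                   ifelse(male, 0.03, 0.02))), 3),
       x = round(pmax(0.05, rnorm(n, ifelse(male, 0.95, 0.55),
                                  ifelse(male, 0.12, 0.08))), 3))
}

# Per-sex generative means for the direct metrics-table generator, with
# three latent factors: f1 = syllable diversity, f2 = tempo, f3 = song length.
METRICS_TABLE_SPEC <- list(
  #                     mean_m  mean_f  l1     l2    l3    resid
  syllable_type_repertoire  = c(25,    8,     3.5,   0,    0,    1.5),
  song_type_repertoire      = c(12,    5,     2.0,   0,    0,    1.0),
  syllables_per_song        = c(69,    69,    0,     0,    8,    4.0),
  syllable_types_per_song   = c(15.1,  5.7,   2.2,   0,    0,    0.8),
  syllable_types_per_second = c(1.9,   0.8,   0.25,  0.1,  0,    0.08),
  syllables_per_second      = c(8.6,   8.6,   0,     0.8,  0,    0.3),
  svi                       = c(0.22,  0.09,  0.03,  0,    0,    0.015),
  levenshtein_distance      = c(33,    27,    4,     0,    2,    4.0),
  network_path_length       = c(3.0,   1.5,   0.5,   0,    0,    0.3),
  network_density           = c(0.35,  0.75, -0.08,  0,    0,    0.06))

#' Generate a per-bird metrics table directly
#'
#' Emits a table shaped like a deposited per-bird results dataset (one row
#' per bird: the eight diversity metrics, the two network metrics, body mass
#' and nucleus volumes) without generating any songs, for exercising the
#' statistics stages in isolation. Metrics are drawn from a three-factor
#' latent model (diversity, tempo, song length) around sex-specific means, so
#' the diversity metrics are strongly intercorrelated within bird — the
#' structure that makes a principal component analysis of the standardized
#' metrics concentrate variance on few components — while syllables per song
#' and per second are matched between sexes (null rows). Repertoire counts
#' are rounded to integers; ratio metrics are clamped to (0, 1].
#'
#' @param n_male,n_female birds per sex.
#' @param treatments treatment labels cycled within sex.
#' @param seed integer seed.
#' @param means optional override for the generative spec: a named list, one
#'   element per metric, each `c(mean_male, mean_female, loading_f1,
#'   loading_f2, loading_f3, residual_sd)`.
#' @return `data.frame` with columns `bird_id`, `sex`, `treatment`, the ten
#'   metrics, `body_mass`, `hvc_volume`, `ra_volume`, `x_volume`.
#' @export
generate_metrics_table <- function(n_male = 15L, n_female = 13L,
                                   treatments = c("T", "T+E2"), seed = 1L,
                                   means = METRICS_TABLE_SPEC) {
  set.seed(seed)
  n <- n_male + n_female
  sexes <- rep(c("male", "female"), c(n_male, n_female))
  ids <- c(if (n_male) sprintf("M%02d", seq_len(n_male)),
           if (n_female) sprintf("F%02d", seq_len(n_female)))
  trts <- c(if (n_male) rep_len(treatments, n_male),
            if (n_female) rep_len(treatments, n_female))
  f <- matrix(rnorm(3L * n), n, 3L)      # latent factors per bird
  out <- data.frame(bird_id = ids, sex = sexes, treatment = trts,
                    stringsAsFactors = FALSE)
  for (m in names(means)) {
    sp <- means[[m]]
    mu <- ifelse(sexes == "male", sp[1L], sp[2L])
    val <- mu + f %*% sp[3:5] + rnorm(n, 0, sp[6L])
    val <- as.numeric(val)
    if (m %in% c("syllable_type_repertoire", "song_type_repertoire"))
      val <- pmax(1, round(val))
    if (m %in% c("svi", "network_density"))
      val <- pmin(1, pmax(0.01, val))
    out[[m]] <- val
  }
  morph <- draw_morphometrics(sexes)
  out$body_mass <- morph$body_mass
  out$hvc_volume <- morph$hvc
  out$ra_volume <- morph$ra
  out$x_volume <- morph$x
  out
}

#' Read generator settings from a key-value config file
#'
#' The config file holds one `key = value` pair per line (`#` comments
#' allowed). Recognised keys: `n_male`, `n_female`, `seed`, `treatments`
#' (comma-separated), and any [synth_params()] field prefixed with `male.` or
#' `female.` (e.g. `male.repertoire_size = 15`). Unspecified fields keep the
#' sex-specific defaults.
#'
#' @param path config file path.
#' @return list with elements `male_params`, `female_params`, `n_male`,
#'   `n_female`, `treatments`, `seed`, ready to pass to [generate_study()].
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  out <- list(male = as.list(default_synth_params("male")),
              female = as.list(default_synth_params("female")),
              n_male = 15L, n_female = 13L,
              treatments = c("T", "T+E2"), seed = 1L)
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% c("n_male", "n_female", "seed")) {
      out[[k]] <- as.integer(v)
    } else if (k == "treatments") {
      out$treatments <- trimws(strsplit(v, ",")[[1L]])
    } else if (grepl("^(male|female)\\.", k)) {
      sex <- sub("\\..*$", "", k)
      fld <- sub("^[^.]*\\.", "", k)
      if (!fld %in% names(out[[sex]]))
        stop("unknown generator field in config: ", k, call. = FALSE)
      out[[sex]][[fld]] <- if (fld == "fixed_phrase_count") as.logical(v)
                           else as.numeric(v)
    } else {
      stop("unknown config key: ", k, call. = FALSE)
    }
  }
  list(male_params = do.call(synth_params, out$male),
       female_params = do.call(synth_params, out$female),
       n_male = out$n_male, n_female = out$n_female,
       treatments = out$treatments, seed = out$seed)
}
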