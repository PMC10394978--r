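test_that("levenshtein handles identity, empty sequences and a single edit", {
  expect_equal(levenshtein(c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_equal(levenshtein(character(0), c("A", "B", "C")), 3L)
  expect_equal(levenshtein(c("A", "B", "C"), character(0)), 3L)
  expect_equal(levenshtein(c("A", "A", "B"), c("A", "B", "B")), 1L)
  expect_equal(levenshtein(c("A", "A", "B"), c("A", "B", "B")),
               lev_oracle(c("A", "A", "B"), c("A", "B", "B")))
})

test_that("levenshtein compares whole labels, not their spelling", {
  # one substitution, even though the label texts share characters
  expect_equal(levenshtein(c("A1", "A2"), c("A1", "A22")), 1L)
  expect_equal(levenshtein("AB", c("A", "B")), 2L)
})

test_that("levenshtein matches the recursive oracle exhaustively on short sequences", {
  seqs <- all_sequences(c("A", "B", "C"), 3L)
  for (a in seqs) for (b in seqs)
    expect_equal(levenshtein(a, b), lev_oracle(a, b))
})

test_that("levenshtein satisfies the metric axioms and length bounds", {
  set.seed(71)
  alph <- c("A", "B", "C", "D")
  rand_seq <- function() alph[sample.int(4, sample.int(7, 1) - 1L, replace = TRUE)]
  for (i in 1:60) {
    a <- rand_seq(); b <- rand_seq(); c <- rand_seq()
    dab <- levenshtein(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, levenshtein(b, a))
    expect_equal(dab == 0, identical(a, b))
    expect_lte(levenshtein(a, c), dab + levenshtein(b, c))
    expect_gte(dab, abs(length(a) - length(b)))
    expect_lte(dab, max(length(a), length(b)))
  }
})

test_that("levenshtein_matrix agrees with pairwise calls", {
  seqs <- list(s1 = c("A", "B"), s2 = c("B", "B", "C"), s3 = character(0))
  m <- levenshtein_matrix(seqs)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(m["s1", "s2"], levenshtein(seqs$s1, seqs$s2))
  expect_equal(m["s1", "s3"], 2L)
})

test_that("per-song metrics follow their definitions", {
  s <- song(c("A", "A", "B", "C"), c(0, 0.5, 1.0, 1.5), c(0.4, 0.9, 1.4, 2.0))
  m <- compute_song_metrics(s)
  expect_equal(m$n_syllables, 4L)
  expect_equal(m$n_types, 3L)
  expect_equal(m$svi, 0.75)
  expect_equal(m$types_per_second, 1.5)
  expect_equal(m$syllables_per_second, 2.0)

  one <- compute_song_metrics(song("A", 0, 0.5))
  expect_equal(one$svi, 1.0)
  expect_equal(one$n_syllables, 1L)

  rep4 <- compute_song_metrics(song(c("A", "A", "A", "A"),
                                    c(0, 0.5, 1, 1.5), c(0.4, 0.9, 1.4, 2)))
  expect_equal(rep4$svi, 0.25)
})

test_that("SVI lies in (0, 1] and is 1 exactly when all tokens are distinct", {
  set.seed(9)
  for (i in 1:40) {
    lab <- LETTERS[sample.int(5, sample.int(8, 1), replace = TRUE)]
    m <- compute_song_metrics(song(lab))
    expect_gt(m$svi, 0)
    expect_lte(m$svi, 1)
    expect_equal(m$svi == 1, !anyDuplicated(lab) > 0)
  }
})

test_that("untimed songs report missing rates, not guesses", {
  m <- compute_song_metrics(song(c("A", "B")))
  expect_true(is.na(m$types_per_second) && is.na(m$syllables_per_second))
})

test_that("bird metrics aggregate the worked two-song example", {
  b <- corpus_from_labels(list(c("A", "A", "B"), c("A", "B", "B")))
  m <- compute_bird_metrics(b)
  expect_equal(m$syllable_type_repertoire, 2L)
  expect_equal(m$levenshtein_distance, 1.0)
  # both songs collapse to the phrase sequence A-B: one song type
  expect_equal(m$song_type_repertoire, 1L)
  m_exact <- compute_bird_metrics(b, song_type_rule = "exact")
  expect_equal(m_exact$song_type_repertoire, 2L)
})

test_that("identical songs give one song type and zero Levenshtein distance", {
  b <- corpus_from_labels(rep(list(c("A", "B", "A")), 30))
  m <- compute_bird_metrics(b)
  expect_equal(m$song_type_repertoire, 1L)
  expect_equal(m$levenshtein_distance, 0)
})

test_that("successive and all-pairs Levenshtein modes differ as defined", {
  labs <- list(c("A", "A"), c("A", "B"), c("B", "B"))
  b <- corpus_from_labels(labs)
  succ <- compute_bird_metrics(b)$levenshtein_distance
  expect_equal(succ, mean(c(lev_oracle(labs[[1]], labs[[2]]),
                            lev_oracle(labs[[2]], labs[[3]]))))
  allp <- compute_bird_metrics(b, levenshtein_mode = "all_pairs")$levenshtein_distance
  expect_equal(allp, mean(c(1, 2, 1)))
  norm <- compute_bird_metrics(b, normalize_levenshtein = TRUE)$levenshtein_distance
  expect_equal(norm, mean(c(1 / 2, 1 / 2)))
})

test_that("a single-song corpus warns and reports NA Levenshtein only", {
  b <- corpus_from_labels(list(c("A", "B")))
  expect_warning(m <- compute_bird_metrics(b), "at least 2 songs")
  expect_true(is.na(m$levenshtein_distance))
  expect_equal(m$syllable_type_repertoire, 2L)
  expect_equal(m$syllables_per_song, 2)
})

test_that("syllable-type repertoire is monotone as songs accumulate", {
  set.seed(13)
  labs <- lapply(1:10, function(i)
    LETTERS[sample.int(8, sample.int(6, 1) + 1L, replace = TRUE)])
  reps <- vapply(2:10, function(k)
    compute_bird_metrics(corpus_from_labels(labs[1:k]))$syllable_type_repertoire,
    numeric(1))
  expect_true(all(diff(reps) >= 0))
  pooled <- length(unique(unlist(labs)))
  expect_equal(reps[length(reps)], pooled)
  # repertoire always >= max per-song type count
  per_song_types <- vapply(labs, function(l) length(unique(l)), numeric(1))
  expect_gte(reps[length(reps)], max(per_song_types))
})
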