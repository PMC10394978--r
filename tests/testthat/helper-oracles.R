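# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

# Brute-force recursive Levenshtein (memoised to keep recursion feasible).
lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(f(i - 1L, j) + 1L, f(i, j - 1L) + 1L,
             f(i - 1L, j - 1L) + as.integer(a[i] != b[j]))
    memo[[key]] <- v
    v
  }
  f(length(a), length(b))
}

# All label sequences of length 0..max_len over the given alphabet.
all_sequences <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      as.character(unlist(grid[i, ], use.names = FALSE))))
  }
  out
}

# Floyd-Warshall all-pairs shortest paths on an unweighted adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

fw_mean_path <- function(adj) {
  d <- fw_distances(adj)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

# Build a syllable_network object directly from an edge list (for graph-metric
# tests that need arbitrary topologies).
make_net <- function(nodes, from = character(0), to = character(0),
                     count = rep(1L, length(from)),
                     self_loops = integer(0)) {
  a <- pmin(from, to); b <- pmax(from, to)
  edges <- data.frame(from = a, to = b, count = as.integer(count),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 node_usage = stats::setNames(rep(1L, length(nodes)), nodes),
                 edges = edges,
                 self_loops = self_loops,
                 total_transitions = sum(count) + sum(self_loops),
                 transitions = data.frame(from = from, to = to,
                                          count = as.integer(count),
                                          stringsAsFactors = FALSE)),
            class = "syllable_network")
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- stats::rbinom(length(up), 1L, p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

adj_to_net <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  make_net(nodes, from = nodes[idx[, 1L]], to = nodes[idx[, 2L]])
}

# Type III sums of squares for a 2x2 design by explicit model comparison with
# sum-to-zero coding: SS_term = RSS(model without term) - RSS(full model).
type3_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- stats::model.matrix(~A, contrasts.arg = list(A = "contr.sum"))[, -1, drop = FALSE]
  b <- stats::model.matrix(~B, contrasts.arg = list(B = "contr.sum"))[, -1, drop = FALSE]
  ab <- a[, 1L] * b[, 1L]
  X_full <- cbind(1, a, b, ab)
  rss <- function(X) {
    fit <- qr(X)
    sum((y - X %*% qr.coef(fit, y))^2)
  }
  rss_full <- rss(X_full)
  df_res <- length(y) - ncol(X_full)
  ss <- c(A = rss(cbind(1, b, ab)) - rss_full,
          B = rss(cbind(1, a, ab)) - rss_full,
          `A:B` = rss(cbind(1, a, b)) - rss_full)
  Fv <- (ss / 1) / (rss_full / df_res)
  list(ss = ss, rss = rss_full, df_res = df_res, F = Fv,
       partial_eta_sq = ss / (ss + rss_full))
}

# Corpus construction shorthand: one corpus from a list of label vectors,
# with syllables on a regular 0.1 s grid.
corpus_from_labels <- function(labs, id = "b1", sex = "male", treatment = "T",
                               timed = TRUE) {
  songs <- lapply(labs, function(l) {
    if (timed) {
      onset <- (seq_along(l) - 1) * 0.5
      song(l, onset, onset + 0.4)
    } else song(l)
  })
  bird_corpus(id, sex, treatment, songs)
}

labels_to_string <- function(s, alphabet)
  paste(letters[match(s, alphabet)], collapse = "")
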