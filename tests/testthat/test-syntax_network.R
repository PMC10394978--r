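test_that("network construction concatenates songs and keeps song-break transitions", {
  b <- corpus_from_labels(list(c("A", "A", "B"), c("A", "C")))
  net <- build_syllable_network(b)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(net$total_transitions, 4L)
  ed <- net$edges[order(net$edges$from, net$edges$to), ]
  expect_equal(ed$from, c("A", "A"))
  expect_equal(ed$to, c("B", "C"))
  # B -> A across the song break plus A -> B inside song 1
  expect_equal(ed$count, c(2L, 1L))
  expect_equal(unname(net$self_loops["A"]), 1L)
  expect_equal(sum(net$edges$count) + sum(net$self_loops),
               net$total_transitions)
})

test_that("degenerate corpora build degenerate networks", {
  one <- build_syllable_network(corpus_from_labels(list("A")))
  expect_equal(one$nodes, "A")
  expect_equal(nrow(one$edges), 0L)
  expect_equal(one$total_transitions, 0L)

  reps <- build_syllable_network(corpus_from_labels(list(c("A", "A", "A"))))
  expect_equal(reps$nodes, "A")
  expect_equal(unname(reps$self_loops["A"]), 2L)
  expect_equal(nrow(reps$edges), 0L)
})

test_that("transition bookkeeping balances on random corpora", {
  set.seed(31)
  for (i in 1:20) {
    labs <- lapply(seq_len(sample.int(5, 1) + 1L), function(j)
      LETTERS[sample.int(6, sample.int(10, 1), replace = TRUE)])
    net <- build_syllable_network(corpus_from_labels(labs))
    expect_equal(sum(net$edges$count) + sum(net$self_loops),
                 net$total_transitions)
    expect_equal(net$total_transitions, sum(lengths(labs)) - 1L)
    expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes))
    expect_lte(nrow(net$edges),
               length(net$nodes) * (length(net$nodes) - 1) / 2)
  }
})

test_that("average path length matches hand-derived small graphs", {
  abc <- c("A", "B", "C")
  complete3 <- make_net(abc, from = c("A", "A", "B"), to = c("B", "C", "C"))
  expect_equal(average_path_length(complete3), 1.0)

  star <- make_net(c("H", "L1", "L2", "L3"),
                   from = c("H", "H", "H"), to = c("L1", "L2", "L3"))
  # three pairs at distance 1, three leaf pairs at distance 2
  expect_equal(average_path_length(star), 1.5)

  disjoint <- make_net(c("A", "B", "C", "D"),
                       from = c("A", "C"), to = c("B", "D"))
  # only the two connected pairs enter the average
  expect_equal(average_path_length(disjoint), 1.0)
})

test_that("path length is undefined without two reachable nodes", {
  lonely <- make_net("A")
  expect_warning(expect_true(is.na(average_path_length(lonely))), "< 2 nodes")
  edgeless <- make_net(c("A", "B"))
  expect_warning(expect_true(is.na(average_path_length(edgeless))),
                 "no mutually reachable")
})

test_that("network density is the simple-graph edge ratio, self-loops excluded", {
  k4 <- make_net(LETTERS[1:4],
                 from = c("A", "A", "A", "B", "B", "C"),
                 to = c("B", "C", "D", "C", "D", "D"))
  expect_equal(network_density(k4), 1.0)

  path4 <- make_net(LETTERS[1:4], from = c("A", "B", "C"), to = c("B", "C", "D"))
  expect_equal(network_density(path4), 0.5)

  withloop <- make_net(c("A", "B"), from = "A", to = "B",
                       self_loops = c(A = 3L))
  expect_equal(network_density(withloop), 1.0)

  expect_warning(expect_true(is.na(network_density(make_net("A")))),
                 "< 2 nodes")
})

test_that("path length and density agree with a Floyd-Warshall oracle", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.15, 0.9))
    net <- adj_to_net(adj)
    expect_equal(network_density(net), sum(adj) / 2 / choose(n, 2))
    oracle <- fw_mean_path(adj)
    if (is.na(oracle)) {
      expect_warning(expect_true(is.na(average_path_length(net))))
    } else {
      expect_equal(average_path_length(net), oracle)
    }
  }
})

test_that("path length is >= 1 and equals 1 exactly when reachable pairs are adjacent", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(2:7, 1)
    adj <- random_adjacency(n, 0.5)
    if (sum(adj) == 0) next
    net <- adj_to_net(adj)
    apl <- average_path_length(net)
    expect_gte(apl, 1)
    d <- fw_distances(adj)
    finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    expect_equal(apl == 1, all(finite == 1))
  }
})

test_that("small networks are excluded at the node-count threshold", {
  study <- list(
    corpus_from_labels(rep(list(c("A", "B", "C", "A")), 2), id = "small"),
    corpus_from_labels(rep(list(c("A", "B", "C", "D")), 2), id = "big"))
  names(study) <- c("small", "big")
  out <- network_metrics_for_study(study)
  expect_true(out$excluded[out$bird_id == "small"])
  expect_true(is.na(out$network_path_length[out$bird_id == "small"]))
  expect_false(out$excluded[out$bird_id == "big"])
  expect_false(is.na(out$network_density[out$bird_id == "big"]))
  expect_equal(nrow(network_metrics_for_study(list())), 0L)
})

test_that("GraphML export round-trips nodes and transition counts", {
  b <- corpus_from_labels(list(c("A", "A", "B"), c("A", "C")))
  net <- build_syllable_network(b)
  path <- tempfile(fileext = ".graphml")
  export_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_false(igraph::is_directed(g))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(sum(igraph::E(g)$count), sum(net$edges$count))
  gd <- igraph::read_graph({
    p2 <- tempfile(fileext = ".graphml")
    export_network_graphml(net, p2, directed = TRUE)
    p2
  }, format = "graphml")
  expect_true(igraph::is_directed(gd))
  expect_equal(sum(igraph::E(gd)$count), net$total_transitions)
})

test_that("higher stereotypy lengthens paths and thins the network", {
  set.seed(53)
  apl <- den <- numeric(0)
  for (s in c(0.2, 0.9)) {
    p <- synth_params(repertoire_size = 10, phrase_count_mean = 12,
                      repeat_mean = 3, stereotypy = s)
    vals <- vapply(1:8, function(i) {
      b <- generate_bird_corpus(p, "b", "male", "T",
                                seed = 1000L + i + round(1e4 * s))
      net <- build_syllable_network(b)
      c(average_path_length(net), network_density(net))
    }, numeric(2))
    apl <- c(apl, mean(vals[1, ]))
    den <- c(den, mean(vals[2, ]))
  }
  expect_gt(apl[2], apl[1])   # stereotyped birds: longer paths
  expect_lt(den[2], den[1])   # stereotyped birds: sparser networks
})
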