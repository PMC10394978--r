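#' Build a syllable-transition network for one bird
#'
#' The syllable sequences of all songs are concatenated in recording order
#' into one string of syllable types; every adjacent pair is a first-order
#' transition. Song breaks are ignored (the last syllable of one song
#' transitions to the first of the next), which avoids fragmenting the network
#' into small disconnected pieces. Syllable types become nodes; transitions
#' between two distinct types increment the count of the corresponding
#' undirected edge; immediate repeats of the same type are recorded as
#' self-loops. Self-loops are kept in the object (repeats are a genuine
#' feature of canary-style song) but are ignored by the path-length and
#' density metrics, which operate on the simple undirected graph.
#'
#' @param corpus a [bird_corpus()].
#' @return A list of class `syllable_network`: `nodes` (labels),
#'   `node_usage` (named syllable counts), `edges` (`data.frame` `from`,
#'   `to`, `count`, with `from < to`), `self_loops` (named counts),
#'   `total_transitions`, and `transitions` (the directed bigram table kept
#'   for export/visualisation).
#' @export
build_syllable_network <- function(corpus) {
  stopifnot(inherits(corpus, "bird_corpus"))
  labels <- unlist(song_labels(corpus), use.names = FALSE)
  nodes <- sort(unique(labels))
  usage <- table(factor(labels, levels = nodes))
  n <- length(labels)
  if (n < 2L) {
    trans <- data.frame(from = character(0), to = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  } else {
    from <- labels[-n]; to <- labels[-1L]
    key <- paste(from, to, sep = "\x1f")
    tab <- table(key)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    trans <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 2L),
                        count = as.integer(tab), stringsAsFactors = FALSE)
  }
  loops <- trans[trans$from == trans$to, , drop = FALSE]
  self_loops <- setNames(loops$count, loops$from)
  cross <- trans[trans$from != trans$to, , drop = FALSE]
  if (nrow(cross)) {
    a <- pmin(cross$from, cross$to); b <- pmax(cross$from, cross$to)
    agg <- tapply(cross$count, paste(a, b, sep = "\x1f"), sum)
    parts <- strsplit(names(agg), "\x1f", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 2L),
                        count = as.integer(agg), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, node_usage = usage, edges = edges,
                 self_loops = self_loops,
                 total_transitions = max(0L, n - 1L),
                 transitions = trans),
            class = "syllable_network")
}

#' @export
print.syllable_network <- function(x, ...) {
  cat(sprintf("<syllable_network> %d nodes, %d undirected edges, %d self-loop types, %d transitions\n",
              length(x$nodes), nrow(x$edges), length(x$self_loops),
              x$total_transitions))
  invisible(x)
}

#' Convert a syllable network to an igraph graph
#'
#' @param net a [build_syllable_network()] result.
#' @param directed if `TRUE`, returns the directed transition graph (including
#'   self-loops) as drawn in transition diagrams; if `FALSE` (default), the
#'   simple undirected graph used for all metrics (self-loops dropped).
#' @return an `igraph` graph with node attribute `usage` and edge attribute
#'   `count`.
#' @export
as_igraph <- function(net, directed = FALSE) {
  stopifnot(inherits(net, "syllable_network"))
  verts <- data.frame(name = net$nodes,
                      usage = as.integer(net$node_usage[net$nodes]),
                      stringsAsFactors = FALSE)
  ed <- if (directed) net$transitions else net$edges
  igraph::graph_from_data_frame(ed, directed = directed, vertices = verts)
}

#' Average minimum path length of a syllable network
#'
#' Mean, over all unordered pairs of mutually reachable nodes, of the minimum
#' number of edges (transitions) linking the pair, on the unweighted simple
#' undirected graph. Unreachable pairs (dead ends) are excluded from the
#' average; self-loops cannot shorten any path and are ignored. Higher values
#' mean syllable types are linked through longer, more fixed transition
#' chains.
#'
#' @param net a [build_syllable_network()] result.
#' @return mean shortest-path length (>= 1 whenever defined), or `NA` with a
#'   warning when the network has fewer than two nodes or no reachable pair.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "syllable_network"))
  if (length(net$nodes) < 2L) {
    warning("average path length undefined for networks with < 2 nodes",
            call. = FALSE)
    return(NA_real_)
  }
  g <- as_igraph(net, directed = FALSE)
  d <- igraph::distances(g)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    warning("no mutually reachable node pair; average path length undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(v)
}

#' Density of a syllable network
#'
#' Observed undirected edges divided by the number of possible edges given the
#' node count, `n (n - 1) / 2`. Self-loops are excluded from numerator and
#' denominator. Higher density means a larger share of possible syllable
#' transitions is actually used, i.e. more flexible sequencing.
#'
#' @param net a [build_syllable_network()] result.
#' @return ratio in \[0, 1\], or `NA` with a warning when the network has
#'   fewer than two nodes.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "syllable_network"))
  n <- length(net$nodes)
  if (n < 2L) {
    warning("network density undefined for networks with < 2 nodes",
            call. = FALSE)
    return(NA_real_)
  }
  nrow(net$edges) / (n * (n - 1) / 2)
}

#' Network metrics for every bird in a study, with small-network exclusion
#'
#' Computes average path length and density per bird. Networks with
#' `exclusion_threshold` or fewer syllable types are too small for these
#' metrics to be meaningful and receive `NA` for both, with `excluded = TRUE`.
#'
#' @param study a `song_study` (list of [bird_corpus()]).
#' @param exclusion_threshold networks with at most this many nodes are
#'   excluded (default 3).
#' @return `data.frame` with columns `bird_id`, `n_types`,
#'   `network_path_length`, `network_density`, `excluded`.
#' @export
network_metrics_for_study <- function(study, exclusion_threshold = 3L) {
  if (length(study) == 0L)
    return(data.frame(bird_id = character(0), n_types = integer(0),
                      network_path_length = numeric(0),
                      network_density = numeric(0), excluded = logical(0)))
  rows <- lapply(study, function(b) {
    net <- build_syllable_network(b)
    k <- length(net$nodes)
    if (k <= exclusion_threshold) {
      data.frame(bird_id = b$bird_id, n_types = k,
                 network_path_length = NA_real_, network_density = NA_real_,
                 excluded = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(bird_id = b$bird_id, n_types = k,
                 network_path_length = average_path_length(net),
                 network_density = network_density(net),
                 excluded = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(bird_id = character(0), n_types = integer(0),
                      network_path_length = numeric(0),
                      network_density = numeric(0), excluded = logical(0))
  out
}

#' Export a syllable network to GraphML
#'
#' Writes the network for inspection in graph tools, with node usage counts
#' and edge transition counts as attributes. The directed variant preserves
#' transition direction and self-loops, matching transition-diagram figures;
#' the undirected variant is the graph the metrics are computed on.
#'
#' @param net a [build_syllable_network()] result.
#' @param path output `.graphml` path.
#' @param directed export the directed transition graph (default `FALSE`).
#' @return `path`, invisibly.
#' @export
export_network_graphml <- function(net, path, directed = FALSE) {
  g <- as_igraph(net, directed = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
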