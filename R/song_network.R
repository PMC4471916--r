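#' Build a song-type transition network
#'
#' Translates a song sequence into a directed graph: nodes are the distinct
#' song types, edges the observed adjacent song-to-song transitions, with
#' counts. Immediate repetitions of the same type (self-loops) are excluded
#' by default because the orderliness metrics are defined over transitions
#' between different types; self-loops would distort both path lengths and
#' triad counts.
#'
#' @param seq a \code{\link{song_sequence}} of length >= 2.
#' @param drop_self_loops drop A -> A transitions (default TRUE).
#' @return Object of class \code{transition_network} with elements
#'   \code{nodes} (character), \code{edges} (data frame source/target/count)
#'   and \code{self_loops_dropped}.
#' @export
build_network <- function(seq, drop_self_loops = TRUE) {
  stopifnot(inherits(seq, "song_sequence"))
  L <- length(seq)
  if (L < 2L) stop_input("need at least 2 songs to build a transition network")
  ty <- seq$song_type
  from <- ty[-L]
  to <- ty[-1L]
  if (drop_self_loops) {
    keep <- from != to
    from <- from[keep]
    to <- to[keep]
  }
  nodes <- unique(ty)
  if (length(from) > 0L) {
    key <- paste(from, to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      source = vapply(parts, `[[`, "", 1L),
      target = vapply(parts, `[[`, "", 2L),
      count = as.integer(tab),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    edges <- data.frame(source = character(), target = character(),
                        count = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 self_loops_dropped = drop_self_loops),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("<transition_network> %d nodes, %d edges (self-loops %s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$self_loops_dropped) "dropped" else "kept"))
  invisible(x)
}

#' Average shortest path length of a transition network
#'
#' Mean hop-count geodesic over ordered node pairs (u, v), u != v, for which
#' v is reachable from u, computed by breadth-first search from every node on
#' the unweighted directed graph (edge counts are ignored; presence only).
#' The fraction of reachable ordered pairs is reported alongside, since the
#' mean is taken over reachable pairs only. High values indicate long linear
#' runs of song types ("orderly" singing).
#'
#' @param net a \code{\link{build_network}} result.
#' @return List with \code{value}, \code{fraction_reachable_pairs},
#'   \code{n_nodes}, \code{n_edges}.
#' @export
average_shortest_path <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  n <- length(net$nodes)
  if (n < 2L) stop_input("average shortest path requires >= 2 nodes")
  if (nrow(net$edges) == 0L) {
    abort_ns("network has no edges: average shortest path undefined",
             "nightsong_metric_error")
  }
  from <- match(net$edges$source, net$nodes) - 1L
  to <- match(net$edges$target, net$nodes) - 1L
  res <- cpp_geodesic_sums(n, from, to)
  if (res[2L] == 0) {
    abort_ns("no reachable ordered pairs: average shortest path undefined",
             "nightsong_metric_error")
  }
  list(value = res[1L] / res[2L],
       fraction_reachable_pairs = res[2L] / (n * (n - 1)),
       n_nodes = n, n_edges = nrow(net$edges))
}

undirected_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$source, net$nodes)
    j <- match(net$edges$target, net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  diag(A) <- 0
  A
}

#' Transitivity (global clustering coefficient) of a transition network
#'
#' Probability that two network neighbours of a node are themselves
#' connected: 3 x triangles / connected triples, computed on the undirected,
#' unweighted projection of the network (the neighbour notion underlying the
#' measure is direction-free).
#'
#' @param net a \code{\link{build_network}} result with >= 3 nodes.
#' @return Numeric in [0, 1]. Errors (rather than returning 0) when the
#'   projection has no connected triples.
#' @export
transitivity <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  n <- length(net$nodes)
  if (n < 3L) stop_input("transitivity requires >= 3 nodes")
  A <- undirected_adjacency(net)
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1)) / 2
  if (triples == 0) {
    abort_ns("no connected triples: transitivity undefined",
             "nightsong_metric_error")
  }
  closed <- sum(diag(A %*% A %*% A)) / 2  # = 3 * number of triangles
  closed / triples
}

#' Both orderliness metrics for a song sequence
#'
#' Convenience composition of \code{\link{build_network}},
#' \code{\link{average_shortest_path}} and \code{\link{transitivity}}.
#'
#' @inheritParams build_network
#' @return List of class \code{network_metrics}: \code{average_shortest_path},
#'   \code{transitivity}, \code{n_nodes}, \code{n_edges},
#'   \code{fraction_reachable_pairs}.
#' @export
network_metrics <- function(seq, drop_self_loops = TRUE) {
  net <- build_network(seq, drop_self_loops = drop_self_loops)
  asp <- average_shortest_path(net)
  structure(list(average_shortest_path = asp$value,
                 transitivity = transitivity(net),
                 n_nodes = asp$n_nodes,
                 n_edges = asp$n_edges,
                 fraction_reachable_pairs = asp$fraction_reachable_pairs),
            class = "network_metrics")
}

#' Export a transition network as a delimited edge list
#'
#' Columns source, target, count.
#'
#' @param net a \code{transition_network}.
#' @param path output file.
#' @param sep delimiter.
#' @export
write_edgelist <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "transition_network"))
  write_delim_out(net$edges, path, sep = sep)
}

#' Export a transition network as GraphML
#'
#' Minimal GraphML with a single integer edge attribute \code{count}, for
#' inspection in external graph tools.
#'
#' @param net a \code{transition_network}.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "transition_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="count" for="edge" attr.name="count" attr.type="int"/>',
    '  <graph edgedefault="directed">'
  ), con)
  for (v in net$nodes) {
    writeLines(sprintf('    <node id="%s"/>', esc(v)), con)
  }
  if (nrow(net$edges) > 0L) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="count">%d</data></edge>',
      esc(net$edges$source), esc(net$edges$target), net$edges$count), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
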