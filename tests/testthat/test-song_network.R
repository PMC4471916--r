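test_that("build_network counts adjacent transitions and applies the self-loop policy", {
  net <- build_network(make_seq(c("A", "B", "C", "A", "B")))
  e <- net$edges[order(net$edges$source), ]
  expect_equal(e$source, c("A", "B", "C"))
  expect_equal(e$target, c("B", "C", "A"))
  expect_equal(e$count[e$source == "A"], 2L)
  expect_equal(length(net$nodes), 3L)

  net2 <- build_network(make_seq(c("A", "A", "B")))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$source, "A")
  net2k <- build_network(make_seq(c("A", "A", "B")), drop_self_loops = FALSE)
  expect_equal(sum(net2k$edges$count), 2L)

  expect_error(build_network(make_seq("A")), class = "nightsong_input_error")

  # edge multiset equals a brute-force pairwise scan on a long sequence
  set.seed(21)
  ty <- simulate_sequence(sprintf("t%02d", 1:25), p = 0.5, length = 533)
  net3 <- build_network(make_seq(ty))
  pairs <- data.frame(s = ty[-length(ty)], t = ty[-1])
  pairs <- pairs[pairs$s != pairs$t, ]
  oracle <- as.data.frame(table(pairs$s, pairs$t), stringsAsFactors = FALSE)
  oracle <- oracle[oracle$Freq > 0, ]
  got <- merge(net3$edges, oracle,
               by.x = c("source", "target"), by.y = c("Var1", "Var2"), all = TRUE)
  expect_false(anyNA(got$count))
  expect_false(anyNA(got$Freq))
  expect_equal(got$count, got$Freq)
})

test_that("average shortest path matches hand enumeration and handles errors", {
  chain <- build_network(make_seq(c("A", "B", "C")))
  asp <- average_shortest_path(chain)
  expect_equal(asp$value, 4 / 3)
  expect_equal(asp$fraction_reachable_pairs, 0.5)

  # complete directed graph on 4 nodes: all geodesics are 1
  pairs <- expand.grid(s = LETTERS[1:4], t = LETTERS[1:4],
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  complete4 <- structure(list(
    nodes = LETTERS[1:4],
    edges = data.frame(source = pairs$s, target = pairs$t, count = 1L,
                       stringsAsFactors = FALSE),
    self_loops_dropped = TRUE), class = "transition_network")
  aspf <- average_shortest_path(complete4)
  expect_equal(aspf$value, 1)
  expect_equal(aspf$fraction_reachable_pairs, 1)

  empty <- build_network(make_seq(c("A", "A", "A")), drop_self_loops = TRUE)
  # one node only -> precondition fails
  expect_error(average_shortest_path(empty), class = "nightsong_input_error")
})

test_that("directed 20-cycle has mean geodesic 10", {
  ty <- rep(sprintf("c%02d", 1:20), 30)
  m <- network_metrics(make_seq(ty))
  expect_equal(m$average_shortest_path, mean(1:19))  # = 10
  expect_equal(m$fraction_reachable_pairs, 1)
})

test_that("transitivity matches hand-built triads and errors without triples", {
  tri <- build_network(make_seq(c("A", "B", "C", "A", "B", "C", "A")))
  # directed cycle A->B->C->A projects to an undirected triangle
  expect_equal(transitivity(tri), 1)

  star <- structure(list(
    nodes = c("A", "B", "C", "D"),
    edges = data.frame(source = "A", target = c("B", "C", "D"), count = 1L,
                       stringsAsFactors = FALSE),
    self_loops_dropped = TRUE), class = "transition_network")
  expect_equal(transitivity(star), 0)

  # two nodes joined: no connected triples -> error, not silent zero
  pair3 <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(source = "A", target = "B", count = 1L,
                       stringsAsFactors = FALSE),
    self_loops_dropped = TRUE), class = "transition_network")
  expect_error(transitivity(pair3), class = "nightsong_metric_error")
})

test_that("metrics agree exactly with brute-force oracles on random networks", {
  # smaller sibling of the acceptance-scale sweep; exact agreement required
  set.seed(33)
  for (i in 1:25) {
    net <- random_network(sample(5:25, 1), pr = runif(1, 0.1, 0.35))
    o <- fw_asp(net)
    a <- average_shortest_path(net)
    expect_equal(a$value, o$value, tolerance = 0)
    expect_equal(a$fraction_reachable_pairs, o$fraction_reachable_pairs,
                 tolerance = 0)
    ot <- enum_transitivity(net)
    if (is.na(ot)) {
      expect_error(transitivity(net), class = "nightsong_metric_error")
    } else {
      expect_equal(transitivity(net), ot, tolerance = 0)
    }
  }
})

test_that("network metrics are deterministic and exportable", {
  ty <- simulate_sequence(sprintf("t%02d", 1:15), p = 0.6, length = 300)
  s <- make_seq(ty)
  m1 <- network_metrics(s)
  m2 <- network_metrics(s)
  expect_identical(m1, m2)

  net <- build_network(s)
  el <- tempfile(fileext = ".csv")
  gm <- tempfile(fileext = ".graphml")
  write_edgelist(net, el)
  write_graphml(net, gm)
  back <- read.csv(el)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(any(grepl("graphml", readLines(gm))))
})

test_that("shuffling an ordered sequence does not increase path length on average", {
  set.seed(55)
  types <- sprintf("t%02d", 1:30)
  ty <- simulate_sequence(types, p = 0.9, length = 533)
  ordered_asp <- network_metrics(make_seq(ty))$average_shortest_path
  sh <- replicate(50, {
    network_metrics(make_seq(sample(ty)))$average_shortest_path
  })
  expect_lte(mean(sh), ordered_asp)
})
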