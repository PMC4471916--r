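# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: Floyd-Warshall instead of BFS, exhaustive triad
# enumeration instead of trace(A^3), two-pass moments, sort-based medians.

make_seq <- function(types, cats = NULL, male = "m01") {
  if (is.null(cats)) cats <- rep("other", length(types))
  song_sequence(male, types, cats)
}

# cyclic sequence over the first `r` of 4 categories, length L
cycle_seq <- function(L = 533) {
  ty <- rep(c("A", "B", "C", "D"), length.out = L)
  ca <- rep(c("whistle", "trill", "buzz", "other"), length.out = L)
  make_seq(ty, ca)
}

random_network <- function(n, pr = 0.15) {
  repeat {
    A <- matrix(stats::runif(n * n) < pr, n, n)
    diag(A) <- FALSE
    if (sum(A) >= 1) break
  }
  idx <- which(A, arr.ind = TRUE)
  nodes <- sprintf("v%02d", seq_len(n))
  structure(list(nodes = nodes,
                 edges = data.frame(source = nodes[idx[, 1]],
                                    target = nodes[idx[, 2]],
                                    count = 1L, stringsAsFactors = FALSE),
                 self_loops_dropped = TRUE),
            class = "transition_network")
}

# all-pairs shortest paths by Floyd-Warshall (matrix relaxation)
fw_asp <- function(net) {
  n <- length(net$nodes)
  D <- matrix(Inf, n, n)
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  D[cbind(i, j)] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  off <- D[row(D) != col(D)]
  list(value = mean(off[is.finite(off)]),
       fraction_reachable_pairs = mean(is.finite(off)))
}

# transitivity by exhaustive enumeration of node triples
enum_transitivity <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  diag(A) <- 0
  tri <- 0L
  for (a in seq_len(n - 2)) {
    for (b in seq.int(a + 1, n - 1)) {
      if (A[a, b] == 0 && sum(A[a, ]) == 0) next
      for (cc in seq.int(b + 1, n)) {
        if (A[a, b] + A[b, cc] + A[a, cc] == 3) tri <- tri + 1L
      }
    }
  }
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1)) / 2
  if (triples == 0) return(NA_real_)
  3 * tri / triples
}

# two-pass mean/SD oracle
twopass_stats <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  c(mean = m, sd = s)
}

# Pearson correlation of midranks computed from first principles
midrank_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

write_seq_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

SONG_MEASURE_NAMES <- c("repertoire_size", "whistle_repertoire",
                        "whistle_occurrence", "trill_repertoire",
                        "trill_occurrence", "buzz_repertoire",
                        "buzz_occurrence", "average_shortest_path",
                        "transitivity")

# assemble the per-male feature table + response for a simulated study
study_feature_table <- function(study, window = 533L) {
  feats <- song_features(study$sequences, window = window)
  visits <- events_to_visits(study$events, min_gap = 60)
  rates <- session_rates(visits)
  fs <- summarize_feeding(rates)
  tab <- merge(feats, study$metadata, by = "male_id", sort = TRUE)
  tab <- merge(tab, fs[, c("male_id", "median_rate")], by = "male_id", sort = TRUE)
  tab$year <- factor(tab$year)
  tab
}
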