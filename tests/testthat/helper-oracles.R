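# Independent oracles used to check the analytic implementations.

# Brute-force KS enrichment: walk every rank position, track the running
# empirical CDF of the gene set against the uniform CDF, and keep the two
# maximal deviations.
ks_oracle <- function(ranks, genes) {
  n <- length(ranks)
  hit_pos <- sort(as.integer(ranks[genes]))
  t <- length(hit_pos)
  cdf_prev <- 0
  dplus <- -Inf; dminus <- -Inf
  hits <- 0
  for (i in seq_len(n)) {
    dminus <- max(dminus, i / n - hits / t)
    if (i %in% hit_pos) hits <- hits + 1
    dplus <- max(dplus, hits / t - i / n)
  }
  if (dplus > dminus) dplus else -dminus
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled values to the two groups.
wilcoxon_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, `>`))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  u_obs <- u_stat(x, y)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# All set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_id) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (c in seq_len(next_id)) {
      rec(c(assign, c), next_id + (c == next_id))
    }
  }
  rec(integer(), 1L)
  out
}

# Best RB-modularity over every partition of a small graph.
exhaustive_best_modularity <- function(g, resolution) {
  n <- length(g$nodes)
  from <- g$edges$from; to <- g$edges$to; w <- g$edges$weight
  deg <- dctyper:::node_degrees(n, from, to, w)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- dctyper:::modularity_q(p, from, to, w, deg, resolution)
    if (q > best) best <- q
  }
  best
}

# Random small weighted graph for Louvain optimality checks.
random_small_graph <- function(n, p_edge = 0.5) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample(ncol(pairs), 1)] <- TRUE
  structure(
    list(nodes = as.character(seq_len(n)),
         edges = tibble::tibble(
           from = pairs[1, keep], to = pairs[2, keep],
           weight = stats::runif(sum(keep), 0.2, 1)
         )),
    class = "dc_graph"
  )
}

# Hand-built dc_graph from an edge matrix (1-based indices).
make_graph <- function(n, edges, weight = 1) {
  structure(
    list(nodes = as.character(seq_len(n)),
         edges = tibble::tibble(from = edges[, 1], to = edges[, 2],
                                weight = rep_len(weight, nrow(edges)))),
    class = "dc_graph"
  )
}
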