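#' Build a Jaccard-weighted k-nearest-neighbor graph
#'
#' PhenoGraph-style construction: each point's k Euclidean nearest
#' neighbors (excluding itself, ties broken by index) define its
#' neighborhood; the directed kNN relation is symmetrized and each edge is
#' weighted by the Jaccard index of the two endpoints' neighborhoods (the
#' point itself included).  Edges with weight below `prune` are dropped, so
#' spurious links between well-separated groups vanish.
#'
#' @param points Numeric matrix, one row per cell (rownames = cell ids).
#' @param k Number of nearest neighbors, `1 <= k < nrow(points)`.
#' @param prune Minimum Jaccard weight kept (default 1/15, the convention
#'   of the shared-nearest-neighbor workflow family).
#' @return A `dc_graph`: list with `nodes` (cell ids) and `edges`, a tibble
#'   of `from`, `to` (integer indices, `from < to`) and `weight` in (0, 1].
#' @export
build_jaccard_knn_graph <- function(points, k, prune = 1 / 15) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1 || k >= n) {
    abort("`k` must satisfy 1 <= k < number of cells.",
          class = "dctyper_parameter_error")
  }
  ids <- rownames(points) %||% as.character(seq_len(n))
  d <- as.matrix(dist(points))
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    neigh[[i]] <- sort(c(i, ord[seq_len(k)]))
  }
  # symmetrized directed kNN edges
  from <- rep(seq_len(n), each = k)
  to <- unlist(lapply(seq_len(n), function(i) setdiff(neigh[[i]], i)))
  a <- pmin(from, to); b <- pmax(from, to)
  key <- (a - 1) * n + b
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  w <- vapply(seq_along(a), function(e) {
    ni <- neigh[[a[e]]]; nj <- neigh[[b[e]]]
    inter <- length(intersect(ni, nj))
    inter / (length(ni) + length(nj) - inter)
  }, numeric(1))
  sel <- w >= prune & w > 0
  structure(
    list(nodes = ids,
         edges = tibble(from = a[sel], to = b[sel], weight = w[sel])),
    class = "dc_graph"
  )
}

#' @export
print.dc_graph <- function(x, ...) {
  cat("<dc_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

# RB-configuration modularity Q(gamma) = sum_c [w_in(c)/W - gamma *
# (deg(c)/(2W))^2] for an edge list with self-loops (self-loop weight
# counts once in w_in, twice in degree).
modularity_q <- function(comm, from, to, w, deg, resolution) {
  m <- sum(w)
  if (m == 0) return(0)
  intra <- comm[from] == comm[to]
  w_in <- sum(w[intra])
  deg_c <- rowsum(deg, comm)
  w_in_c <- if (any(intra)) rowsum(w[intra], comm[from[intra]]) else 0
  sum(w_in_c) / m - resolution * sum((deg_c / (2 * m))^2)
}

# One Louvain move phase: greedy node sweeps in the given order until no
# move gains more than `tol`; ties between candidate communities break by
# lowest community id.  Returns the community vector.
louvain_move_phase <- function(n, adj_idx, adj_w, deg, m, resolution,
                               comm, order_fun, tol = 1e-10) {
  cd <- rep(0, max(comm))
  tmp <- rowsum(deg, comm)
  cd[as.integer(rownames(tmp))] <- tmp[, 1]
  repeat {
    moved <- FALSE
    for (v in order_fun()) {
      cv <- comm[v]
      nb <- adj_idx[[v]]; wts <- adj_w[[v]]
      keep <- nb != v
      if (!any(keep)) next
      nbc <- comm[nb[keep]]
      l <- rowsum(wts[keep], nbc)
      cand <- as.integer(rownames(l))
      lvals <- l[, 1]
      cd[cv] <- cd[cv] - deg[v]
      if (!cv %in% cand) { cand <- c(cand, cv); lvals <- c(lvals, 0) }
      gain <- lvals / m - resolution * deg[v] * cd[cand] / (2 * m^2)
      stay <- gain[match(cv, cand)]
      best_gain <- max(gain)
      best <- min(cand[gain >= best_gain - 1e-15])
      if (best != cv && best_gain > stay + tol) {
        comm[v] <- best
        cd[best] <- cd[best] + deg[v]
        moved <- TRUE
      } else {
        cd[cv] <- cd[cv] + deg[v]
      }
    }
    if (!moved) break
  }
  comm
}

adjacency_lists <- function(n, from, to, w) {
  adj_idx <- vector("list", n)
  adj_w <- vector("list", n)
  for (v in seq_len(n)) { adj_idx[[v]] <- integer(); adj_w[[v]] <- numeric() }
  for (e in seq_along(from)) {
    i <- from[e]; j <- to[e]
    adj_idx[[i]] <- c(adj_idx[[i]], j); adj_w[[i]] <- c(adj_w[[i]], w[e])
    if (i != j) {
      adj_idx[[j]] <- c(adj_idx[[j]], i); adj_w[[j]] <- c(adj_w[[j]], w[e])
    }
  }
  list(idx = adj_idx, w = adj_w)
}

node_degrees <- function(n, from, to, w) {
  deg <- rep(0, n)
  for (e in seq_along(from)) {
    if (from[e] == to[e]) {
      deg[from[e]] <- deg[from[e]] + 2 * w[e]
    } else {
      deg[from[e]] <- deg[from[e]] + w[e]
      deg[to[e]] <- deg[to[e]] + w[e]
    }
  }
  deg
}

# Full multilevel Louvain on an edge list, followed by one node-level
# refinement pass on the flattened partition.
louvain_once <- function(n, from0, to0, w0, resolution) {
  assign_map <- seq_len(n)
  from <- from0; to <- to0; w <- w0
  n_cur <- n
  repeat {
    al <- adjacency_lists(n_cur, from, to, w)
    deg <- node_degrees(n_cur, from, to, w)
    m <- sum(w)
    if (m == 0) break
    comm <- louvain_move_phase(n_cur, al$idx, al$w, deg, m, resolution,
                               seq_len(n_cur),
                               order_fun = function() sample.int(n_cur))
    comm <- match(comm, sort(unique(comm)))
    if (max(comm) == n_cur) break
    assign_map <- comm[assign_map]
    # aggregate
    cf <- comm[from]; ct <- comm[to]
    a <- pmin(cf, ct); b <- pmax(cf, ct)
    agg <- rowsum(w, paste(a, b, sep = "_"))
    keys <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
    from <- as.integer(keys[, 1]); to <- as.integer(keys[, 2])
    w <- agg[, 1]
    n_cur <- max(comm)
    if (n_cur == 1) break
  }
  # refinement at the original node level
  al <- adjacency_lists(n, from0, to0, w0)
  deg <- node_degrees(n, from0, to0, w0)
  m <- sum(w0)
  comm <- assign_map
  if (m > 0) {
    comm <- louvain_move_phase(n, al$idx, al$w, deg, m, resolution, comm,
                               order_fun = function() sample.int(n))
  }
  match(comm, sort(unique(comm)))
}

#' Louvain community detection with a resolution parameter
#'
#' Greedy multilevel optimization of RB-configuration modularity
#' `Q(gamma) = sum_c [w_in(c)/W - gamma * (deg(c)/(2W))^2]`, with seeded
#' node-sweep order, lowest-community-id tie-breaking, a final node-level
#' refinement pass, and several seeded restarts of which the
#' highest-modularity partition is returned.  The result is deterministic
#' for a fixed seed.
#'
#' @param g A `dc_graph` from [build_jaccard_knn_graph()].
#' @param resolution Resolution `gamma > 0`; larger values favor more,
#'   smaller communities.
#' @param seed Integer seed controlling sweep orders.
#' @param n_restarts Number of seeded restarts (default 5).
#' @return A `dc_partition`: list with `membership` (named integer vector of
#'   0-based contiguous cluster ids), `modularity`, `seed` and `params`.
#' @export
louvain_partition <- function(g, resolution, seed = 0L, n_restarts = 5L) {
  stopifnot(inherits(g, "dc_graph"), resolution > 0)
  n <- length(g$nodes)
  if (n == 0) {
    abort("empty graph.", class = "dctyper_parameter_error")
  }
  from <- g$edges$from; to <- g$edges$to; w <- g$edges$weight
  if (nrow(g$edges) == 0) {
    memb <- setNames(rep(0L, n), g$nodes)
    return(structure(list(membership = memb, modularity = 0,
                          seed = seed, params = list(resolution = resolution)),
                     class = "dc_partition"))
  }
  deg <- node_degrees(n, from, to, w)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    comm <- withr::with_seed(as.integer(seed) + r - 1L,
                             louvain_once(n, from, to, w, resolution))
    q <- modularity_q(comm, from, to, w, deg, resolution)
    if (q > best_q + 1e-12) { best_q <- q; best <- comm }
  }
  # contiguous 0-based ids, numbered by first appearance in node order
  memb <- match(best, unique(best)) - 1L
  structure(
    list(membership = setNames(as.integer(memb), g$nodes),
         modularity = best_q, seed = as.integer(seed),
         params = list(resolution = resolution)),
    class = "dc_partition"
  )
}

#' @export
print.dc_partition <- function(x, ...) {
  cat("<dc_partition> ", length(x$membership), " cells in ",
      length(unique(x$membership)), " clusters; Q = ",
      format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cluster cells in one modality
#'
#' Runs the shared graph engine on either the transcriptome (HVG selection,
#' PCA embedding, kNN graph at `cfg$t_knn_k`, Louvain at
#' `cfg$t_resolution`) or the surface phenotype (arcsinh-transformed marker
#' intensities minus `cfg$marker_exclusions`, kNN graph at `cfg$p_knn_k`,
#' Louvain at resolution 1).  tdTomato is excluded from the phenotype space
#' by default, mirroring how marker-based clustering should not use the
#' reporter it is meant to validate.
#'
#' @param ds A [dc_dataset()] (with `norm` present for the transcriptome
#'   space).
#' @param space `"transcriptome"` or `"phenotype"`.
#' @param cfg A [dc_config()].
#' @param embedding Optional precomputed `dc_pca` to reuse for the
#'   transcriptome space.
#' @return A `dc_partition` with `params` recording `space`, `k` and
#'   `resolution`.
#' @export
cluster_cells <- function(ds, space = c("transcriptome", "phenotype"),
                          cfg = dc_config(), embedding = NULL) {
  space <- match.arg(space)
  stopifnot(inherits(ds, "dc_dataset"))
  if (space == "transcriptome") {
    if (is.null(embedding)) {
      hvg <- select_hvg(ds, cfg$n_hvg)
      embedding <- pca_embed(ds, hvg, cfg$n_pcs)
    }
    pts <- embedding$embedding
    k <- cfg$t_knn_k
    res <- cfg$t_resolution
  } else {
    use <- setdiff(DC_MARKER_PANEL, cfg$marker_exclusions)
    mk <- ds$markers[cell_ids(ds), use, drop = FALSE]
    if (any(!stats::complete.cases(mk))) {
      abort("cells without index-sort data in phenotype clustering; run qc_filter.",
            class = "dctyper_state_error")
    }
    pts <- asinh_transform(mk, cfg$asinh_cofactor)
    k <- cfg$p_knn_k
    res <- cfg$p_resolution
  }
  g <- build_jaccard_knn_graph(pts, k, prune = cfg$jaccard_prune)
  part <- louvain_partition(g, res, seed = cfg$seed)
  part$params <- list(space = space, k = k, resolution = res)
  part
}
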