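#' Reference bulk expression profiles
#'
#' @param expr Genes x samples numeric matrix (linear scale).
#' @param types Character vector mapping each sample (column) to a cell
#'   type; at least two replicates per type are recommended so the
#'   per-comparison test has degrees of freedom.
#' @return A `dc_reference` object.
#' @export
dc_reference <- function(expr, types) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(types), !is.null(rownames(expr)))
  structure(list(expr = expr, types = as.character(types)),
            class = "dc_reference")
}

# Vectorized per-gene Welch t-test p-values between two sample groups.
welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  p[!is.finite(p)] <- 1
  p
}

#' Derive a composite UP/DN signature from bulk reference profiles
#'
#' A gene enters the UP set only when it is higher in the target type than
#' in *every* other type (per-comparison fold change at least `fc_thr` and
#' Welch p at most `p_thr` on the replicates); the DN set is the symmetric
#' intersection of "lower than every other type".  The intersection
#' requirement makes the two sets disjoint by construction.  When a type
#' has fewer than 2 replicates the test has no degrees of freedom; a
#' warning is emitted and fold changes alone decide.
#'
#' @param ref A [dc_reference()].
#' @param target Target cell type.
#' @param others Character vector of the competing types (default: all
#'   other types in `ref`).
#' @param fc_thr Linear fold-change threshold (default 2).
#' @param p_thr P-value threshold (default 0.05).
#' @param pseudocount Added before fold computation (default 1).
#' @return A [dc_signature()] with provenance `"bulk_reference"`.
#' @export
derive_composite_signature <- function(ref, target, others = NULL,
                                       fc_thr = 2, p_thr = 0.05,
                                       pseudocount = 1) {
  stopifnot(inherits(ref, "dc_reference"))
  others <- others %||% setdiff(unique(ref$types), target)
  if (!target %in% ref$types || !all(others %in% ref$types) ||
      length(others) == 0) {
    abort("target and others must be types present in the reference.",
          class = "dctyper_parameter_error")
  }
  reps <- table(ref$types)[c(target, others)]
  fold_only <- any(reps < 2) && p_thr < 1
  if (fold_only) {
    warn("a type has < 2 replicates; falling back to fold-only selection.")
  }
  xt <- ref$expr[, ref$types == target, drop = FALSE]
  up_all <- dn_all <- rep(TRUE, nrow(ref$expr))
  for (o in others) {
    xo <- ref$expr[, ref$types == o, drop = FALSE]
    fold <- (rowMeans(xt) + pseudocount) / (rowMeans(xo) + pseudocount)
    p <- if (fold_only) rep(0, nrow(ref$expr)) else welch_p(xt, xo)
    up_all <- up_all & fold >= fc_thr & p <= p_thr
    dn_all <- dn_all & fold <= 1 / fc_thr & p <= p_thr
  }
  dc_signature(target,
               up = rownames(ref$expr)[up_all],
               down = rownames(ref$expr)[dn_all],
               provenance = "bulk_reference")
}

#' Derive a relative A-vs-B signature from annotated single cells
#'
#' UP = genes significantly higher in type `a` than type `b` by
#' [group_markers()], DN = the significantly lower genes; the signature is
#' named `"a_vs_b"`.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param labels Annotation tibble (`cell_id`, `type`) or named vector of
#'   types.
#' @param a,b The two cell types; each needs at least 3 labeled cells.
#' @param min_pct,lfc,padj DE thresholds.
#' @return A [dc_signature()] with provenance `"single_cell"`.
#' @export
derive_relative_signature <- function(ds, labels, a, b,
                                      min_pct = 0.1, lfc = 0.25,
                                      padj = 0.05) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$type, labels$cell_id)
  }
  labels <- labels[!is.na(labels)]
  if (sum(labels == a) < 3 || sum(labels == b) < 3) {
    abort("both types need at least 3 labeled cells.",
          class = "dctyper_parameter_error")
  }
  deg <- group_markers(ds, labels, a, b,
                       min_pct = min_pct, lfc = lfc, padj = padj)
  up <- deg$gene[deg$log2fc > 0]
  dn <- deg$gene[deg$log2fc < 0]
  if (length(up) + length(dn) == 0) {
    warn(paste0("no differential genes between ", a, " and ", b,
                "; signature is empty."))
    return(structure(list(name = paste0(a, "_vs_", b), up = character(),
                          down = character(), provenance = "single_cell"),
                     class = "dc_signature"))
  }
  dc_signature(paste0(a, "_vs_", b), up = up, down = dn,
               provenance = "single_cell")
}

#' Rank genes within each cell
#'
#' Produces, per cell, a strict total order of all genes by decreasing
#' log-normalized expression; ties (including the zero block) break by
#' ascending gene id, so rankings are deterministic and independent of gene
#' storage order.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @return Integer matrix of ranks (genes x cells; rank 1 = highest
#'   expression), each column a permutation of `1..n_genes`.
#' @export
rank_genes <- function(ds) {
  stopifnot(inherits(ds, "dc_dataset"))
  if (is.null(ds$norm)) {
    abort("`norm` absent; run lognormalize first.",
          class = "dctyper_state_error")
  }
  genes <- gene_ids(ds)
  gene_order <- order(genes)
  x <- ds$norm[gene_order, , drop = FALSE]
  ranks <- apply(x, 2, function(col) {
    r <- integer(length(col))
    r[order(-col, seq_along(col))] <- seq_along(col)  # ties by gene id (pre-sorted)
    r
  })
  rownames(ranks) <- genes[gene_order]
  ranks[genes, , drop = FALSE]
}

#' Kolmogorov-Smirnov enrichment of a gene set in one ranking
#'
#' The classic connectivity-map statistic.  With `p_1 < ... < p_t` the
#' ranks of the set's genes among `n` genes,
#' `a = max_j (j/t - p_j/n)` and `b = max_j (p_j/n - (j-1)/t)`; the score
#' is `a` if `a > b`, else `-b`.  Scores near +1 mean the set sits at the
#' top of the ranking, near -1 at the bottom.
#'
#' @param ranks Named integer vector: rank per gene for one cell (one
#'   column of [rank_genes()]).
#' @param genes Gene set; members absent from the ranking are dropped with
#'   a warning, and at least one must remain.
#' @return Enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(ranks, genes) {
  genes <- unique(genes)
  present <- genes %in% names(ranks)
  if (any(!present)) {
    warn(paste0(sum(!present), " signature gene(s) absent from universe."))
  }
  genes <- genes[present]
  t <- length(genes)
  if (t == 0) {
    abort("no signature gene present in the ranking.",
          class = "dctyper_parameter_error")
  }
  n <- length(ranks)
  p <- sort(as.numeric(ranks[genes]))
  j <- seq_len(t)
  a <- max(j / t - p / n)
  b <- max(p / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity score of a cell against a composite signature
#'
#' Combines the UP- and DN-set KS enrichments: when they disagree in sign
#' (the informative case) the raw score is `(ES_up - ES_down)/2`; when both
#' sets enrich in the same direction the score is 0 -- the "null score"
#' convention that flags cells a relative signature cannot place.  A
#' signature with one empty set scores as the single set's enrichment
#' (negated for a DN-only signature).
#'
#' @param ranks Named integer rank vector for one cell.
#' @param sig A [dc_signature()]; at least one of its sets must intersect
#'   the universe.
#' @return Raw connectivity score in `[-1, 1]`.
#' @export
connectivity_score <- function(ranks, sig) {
  up <- intersect(sig$up, names(ranks))
  dn <- intersect(sig$down, names(ranks))
  if (length(up) + length(dn) == 0) {
    abort(paste0("signature '", sig$name,
                 "' has no gene in the universe."),
          class = "dctyper_parameter_error")
  }
  if (length(dn) == 0) return(ks_enrichment(ranks, up))
  if (length(up) == 0) return(-ks_enrichment(ranks, dn))
  es_up <- ks_enrichment(ranks, up)
  es_dn <- ks_enrichment(ranks, dn)
  if (sign(es_up) == sign(es_dn)) 0 else (es_up - es_dn) / 2
}

#' Score every cell against every signature
#'
#' Computes raw connectivity scores for all cells and normalizes within
#' each signature across cells: positive raw scores are divided by the
#' maximum positive score, negative ones by the absolute minimum, zeros
#' stay zero.  Scores are therefore comparable within a signature and lie
#' in `[-1, 1]`.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param sigs Nonempty list of [dc_signature()] objects.
#' @param ranks Optional precomputed [rank_genes()] matrix.
#' @return A `dc_scores` tibble: `cell_id` plus one normalized score
#'   column per signature.
#' @export
score_all <- function(ds, sigs, ranks = NULL) {
  stopifnot(length(sigs) > 0)
  ranks <- ranks %||% rank_genes(ds)
  nms <- vapply(sigs, `[[`, character(1), "name")
  raw <- suppressWarnings(vapply(sigs, function(s) {
    apply(ranks, 2, connectivity_score, sig = s)
  }, numeric(ncol(ranks))))
  raw <- matrix(raw, ncol = length(sigs),
                dimnames = list(colnames(ranks), nms))
  tau <- apply(raw, 2, function(col) {
    pos <- col > 0; neg <- col < 0
    if (any(pos)) col[pos] <- col[pos] / max(col[pos])
    if (any(neg)) col[neg] <- col[neg] / abs(min(col[neg]))
    col
  })
  tau <- matrix(tau, ncol = length(sigs),
                dimnames = list(colnames(ranks), nms))
  out <- as_tibble(tau)
  out <- dplyr::bind_cols(tibble(cell_id = colnames(ranks)), out)
  class(out) <- c("dc_scores", class(out))
  out
}
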