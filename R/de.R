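#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper with the branch rule used throughout the pipeline: exact
#' enumeration when the pooled sample size is at most 16 and there are no
#' ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    abort("both groups must be nonempty.", class = "dctyper_parameter_error")
  }
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 16 && no_ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Differentially expressed genes between two cell groups
#'
#' Rank-based marker detection: a gene is tested only if it is expressed in
#' at least `min_pct` of either group and its absolute log2 fold change is
#' at least `lfc`.  Fold changes are computed on the depth-normalized scale
#' (`log2` of group means of `expm1(norm)` with pseudocount 1).  P-values
#' come from [wilcoxon_test()]; Bonferroni correction is applied over the
#' full gene universe (the convention of the standard single-cell marker
#' workflow, which keeps the family-wise error calibrated even though the
#' expression and fold filters preselect extreme genes) and records with
#' adjusted p below `padj` are returned.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param groups Named character/factor vector of group labels per cell
#'   (names = cell ids), or a `dc_partition`.
#' @param g1,g2 The two group labels to compare (`g1` over `g2`).
#' @param min_pct,lfc,padj Thresholds (defaults 0.1, 0.25, 0.05).
#' @return Tibble with `gene`, `log2fc`, `p`, `p_adj`, `pct1`, `pct2`,
#'   sorted by `p_adj` then decreasing `|log2fc|`.
#' @export
group_markers <- function(ds, groups, g1, g2,
                          min_pct = 0.1, lfc = 0.25, padj = 0.05) {
  stopifnot(inherits(ds, "dc_dataset"))
  if (is.null(ds$norm)) {
    abort("`norm` absent; run lognormalize first.",
          class = "dctyper_state_error")
  }
  if (inherits(groups, "dc_partition")) groups <- groups$membership
  cells1 <- names(groups)[!is.na(groups) & groups == g1]
  cells2 <- names(groups)[!is.na(groups) & groups == g2]
  cells1 <- intersect(cells1, cell_ids(ds))
  cells2 <- intersect(cells2, cell_ids(ds))
  if (length(cells1) == 0 || length(cells2) == 0) {
    abort("both groups must contain cells present in the dataset.",
          class = "dctyper_parameter_error")
  }
  n1 <- ds$norm[, cells1, drop = FALSE]
  n2 <- ds$norm[, cells2, drop = FALSE]
  pct1 <- rowMeans(n1 > 0)
  pct2 <- rowMeans(n2 > 0)
  log2fc <- log2(rowMeans(expm1(n1)) + 1) - log2(rowMeans(expm1(n2)) + 1)
  tested <- (pct1 >= min_pct | pct2 >= min_pct) & abs(log2fc) >= lfc
  genes <- gene_ids(ds)[tested]
  m <- nrow(ds$counts)
  if (length(genes) == 0) {
    return(tibble(gene = character(), log2fc = numeric(), p = numeric(),
                  p_adj = numeric(), pct1 = numeric(), pct2 = numeric()))
  }
  p <- vapply(genes, function(g) wilcoxon_test(n1[g, ], n2[g, ]), numeric(1))
  out <- tibble(
    gene = genes,
    log2fc = log2fc[tested],
    p = p,
    p_adj = pmin(1, p * m),
    pct1 = pct1[tested],
    pct2 = pct2[tested]
  )
  out |>
    filter(.data$p_adj < padj) |>
    arrange(.data$p_adj, desc(abs(.data$log2fc)))
}

#' Pairwise DEG counts between cell types within an activation state
#'
#' For every unordered pair of annotated DC types with at least
#' `min_cells` cells per side in the given activation stratum, counts the
#' genes passing [group_markers()] thresholds.  Pairs with insufficient
#' cells are reported as untested rather than raising.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param labels Annotation tibble with `cell_id`, `type`, `state`.
#' @param stratum Activation state to condition on (e.g. `"quiescent"`).
#' @param min_pct,lfc,padj DE thresholds, as in [group_markers()].
#' @param min_cells Minimum cells per side (default 3).
#' @return Tibble with `type1`, `type2`, `n1`, `n2`, `tested`, `n_deg`.
#' @export
pairwise_deg_counts <- function(ds, labels, stratum,
                                min_pct = 0.1, lfc = 0.25, padj = 0.05,
                                min_cells = 3) {
  stopifnot(is.data.frame(labels),
            all(c("cell_id", "type", "state") %in% names(labels)))
  strat <- labels |>
    filter(!is.na(.data$type), .data$state == stratum)
  types <- intersect(DC_TYPES, unique(strat$type))
  pairs <- if (length(types) >= 2) utils::combn(types, 2) else
    matrix(character(), nrow = 2, ncol = 0)
  grp <- setNames(strat$type, strat$cell_id)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    t1 <- pairs[1, i]; t2 <- pairs[2, i]
    n1 <- sum(grp == t1); n2 <- sum(grp == t2)
    if (n1 < min_cells || n2 < min_cells) {
      return(tibble(type1 = t1, type2 = t2, n1 = n1, n2 = n2,
                    tested = FALSE, n_deg = NA_integer_))
    }
    deg <- group_markers(ds, grp, t1, t2,
                         min_pct = min_pct, lfc = lfc, padj = padj)
    tibble(type1 = t1, type2 = t2, n1 = n1, n2 = n2,
           tested = TRUE, n_deg = nrow(deg))
  })
  bind_rows(out)
}
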