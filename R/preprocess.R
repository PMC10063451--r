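#' Quality-control filtering of cells
#'
#' Removes cells detecting fewer than `min_genes` genes, with fewer than
#' `min_umi` total UMIs, or lacking index-sorting (surface-marker) data.
#' Plate-based datasets typically lose a couple of wells to missing index
#' sort; those cells are excluded here so the phenotype modality covers
#' every retained cell.  The gene set is never altered.
#'
#' @param ds A [dc_dataset()].
#' @param min_genes,min_umi Non-negative thresholds.  Defaults (500 genes,
#'   2,000 UMIs) are typical plate-based scRNA-seq cutoffs.
#' @param require_markers Drop cells without index-sort data (default TRUE).
#' @return A list with `dataset` (the filtered [dc_dataset()]) and `report`,
#'   a tibble with per-cell `detected_genes`, `total_umi`, `kept` and
#'   `reason` (nonempty exactly when `kept` is FALSE).
#' @export
qc_filter <- function(ds, min_genes = 500, min_umi = 2000,
                      require_markers = TRUE) {
  stopifnot(inherits(ds, "dc_dataset"), min_genes >= 0, min_umi >= 0)
  detected <- colSums(ds$counts > 0)
  total <- colSums(ds$counts)
  reason <- character(n_cells(ds))
  fail_genes <- detected < min_genes
  fail_umi <- total < min_umi
  fail_mark <- require_markers & !ds$meta$has_markers
  reason[fail_umi] <- paste0("total_umi<", min_umi)
  reason[fail_genes] <- paste0("detected_genes<", min_genes)
  reason[fail_mark] <- "missing index sort"
  kept <- !nzchar(reason)
  report <- tibble(
    cell_id = cell_ids(ds),
    detected_genes = as.integer(detected),
    total_umi = as.numeric(total),
    kept = kept,
    reason = reason
  )
  if (!any(kept)) {
    abort("QC removed every cell.", class = "dctyper_empty_error")
  }
  list(dataset = subset_cells(ds, cell_ids(ds)[kept]), report = report)
}

#' Log-normalize UMI counts
#'
#' Fills the `norm` slot with `ln(1 + count * scale / total_umi)` per cell,
#' the standard depth-normalized natural-log transform.  Counts are left
#' untouched; the transform is invariant to rescaling a cell's depth and
#' strictly monotone in counts within a cell.
#'
#' @param ds A [dc_dataset()]; every cell must have total UMI > 0.
#' @param scale Scale factor (default 10,000).
#' @return The dataset with `norm` filled.
#' @export
lognormalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "dc_dataset"), scale > 0)
  total <- colSums(ds$counts)
  if (any(total == 0)) {
    abort("cell(s) with zero total UMI; run qc_filter first.",
          class = "dctyper_state_error")
  }
  ds$norm <- log1p(sweep(ds$counts, 2, scale / total, `*`))
  ds
}

#' Select highly variable genes
#'
#' Ranks expressed genes by standardized dispersion: the variance/mean ratio
#' of the log-normalized values, standardized robustly (median/MAD) within
#' 20 equal-frequency bins of mean expression so that a handful of truly
#' variable genes cannot inflate their own bin's scale.  Ties break by gene
#' id, so the selection is deterministic.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param n Number of genes to select; capped at the number of expressed
#'   genes.
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of gene ids, highest dispersion first.
#' @export
select_hvg <- function(ds, n = 2000, n_bins = 20) {
  stopifnot(inherits(ds, "dc_dataset"), n >= 1)
  if (is.null(ds$norm)) {
    abort("`norm` absent; run lognormalize first.",
          class = "dctyper_state_error")
  }
  mu <- rowMeans(ds$norm)
  v <- apply(ds$norm, 1, var)
  expressed <- mu > 0
  genes <- gene_ids(ds)[expressed]
  mu <- mu[expressed]
  disp <- v[expressed] / mu
  n_bins <- max(1L, min(n_bins, length(genes)))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- mad(disp[idx])
    if (!is.finite(s) || s == 0) s <- sd(disp[idx])
    z[idx] <- if (!is.finite(s) || s == 0) 0 else
      (disp[idx] - median(disp[idx])) / s
  }
  ord <- order(-z, genes)
  head(genes[ord], min(n, length(genes)))
}

#' Principal-component embedding of the transcriptome
#'
#' Per-gene z-scoring of the log-normalized values (clipped at +/-10),
#' followed by exact SVD.  Component signs are fixed so each component's
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param genes Gene subset to embed (typically from [select_hvg()]).
#' @param n_pcs Number of components; capped at `min(#genes, #cells - 1)`.
#' @param clip Z-score clipping bound (default 10).
#' @return A `dc_pca` object: list with `embedding` (cells x n_pcs),
#'   `loadings` (genes x n_pcs) and `explained_variance` (non-increasing).
#' @export
pca_embed <- function(ds, genes = NULL, n_pcs = 30, clip = 10) {
  stopifnot(inherits(ds, "dc_dataset"), n_pcs >= 1)
  if (is.null(ds$norm)) {
    abort("`norm` absent; run lognormalize first.",
          class = "dctyper_state_error")
  }
  if (n_cells(ds) < 2) {
    abort("PCA requires at least 2 cells.", class = "dctyper_parameter_error")
  }
  genes <- genes %||% gene_ids(ds)
  x <- ds$norm[genes, , drop = FALSE]
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  m <- t(z)                       # cells x genes
  n_pcs <- min(n_pcs, length(genes), nrow(m) - 1L)
  sv <- svd(m, nu = n_pcs, nv = n_pcs)
  d <- sv$d[seq_len(n_pcs)]
  # deterministic sign: largest-|loading| gene positive per component
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  emb <- sv$u %*% diag(d, n_pcs, n_pcs)
  dimnames(emb) <- list(cell_ids(ds), paste0("PC", seq_len(n_pcs)))
  load <- sv$v
  dimnames(load) <- list(genes, paste0("PC", seq_len(n_pcs)))
  structure(
    list(embedding = emb, loadings = load,
         explained_variance = d^2 / (nrow(m) - 1)),
    class = "dc_pca"
  )
}

#' Arcsinh transform of surface-marker intensities
#'
#' The standard cytometry compression `asinh(x / cofactor)`: linear near
#' zero (so post-compensation negative values are handled symmetrically) and
#' logarithmic for large intensities.
#'
#' @param markers Numeric matrix, cells x markers; entries must be finite.
#' @param cofactor Positive cofactor (default 100, the usual choice for
#'   fluorescence-intensity scaled values).
#' @return Transformed matrix of the same shape.
#' @export
asinh_transform <- function(markers, cofactor = 100) {
  stopifnot(cofactor > 0)
  markers <- as.matrix(markers)
  if (any(!is.finite(markers))) {
    abort("non-finite marker intensities.", class = "dctyper_integrity_error")
  }
  asinh(markers / cofactor)
}
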