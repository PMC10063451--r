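#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline.  Two modes mirror the
#' two analysis passes of the study design: `"NI"` (uninfected cells only;
#' transcriptome kNN k = 5, resolution 0.2, phenotype kNN k = 20, signature
#' confirmation required) and `"whole"` (all timepoints; k = 9, resolution
#' 0.7, phenotype k = 50, signature confirmation reported but not gating).
#'
#' @param mode `"whole"` or `"NI"`.
#' @param t_knn_k,t_resolution Transcriptome kNN size and Louvain
#'   resolution.
#' @param p_knn_k,p_resolution Phenotype kNN size and Louvain resolution
#'   (resolution fixed at 1 by default; only k is modality-specific).
#' @param asinh_cofactor Cofactor for [asinh_transform()] (default 100).
#' @param norm_scale Scale factor for [lognormalize()] (default 10,000).
#' @param n_hvg,n_pcs Highly-variable-gene count and PCA dimensionality.
#' @param de_padj,de_min_pct,de_lfc Differential-expression thresholds
#'   (adjusted p < 0.05, minimum expressing fraction 0.1, minimum absolute
#'   log2 fold change 0.25).
#' @param min_genes,min_umi QC thresholds for [qc_filter()].
#' @param seed Integer seed for every stochastic stage.
#' @param require_signature_confirmation Gate concordant calls on a
#'   positive connectivity score (default TRUE in NI mode).
#' @param marker_exclusions Markers excluded from phenotype clustering
#'   (default tdT).
#' @param jaccard_prune Minimum Jaccard edge weight kept.
#' @param margin_min Minimum mean-score margin for confident cluster
#'   labeling before the majority sort label is consulted.
#' @param z_thr Contaminant-module z-score threshold.
#' @param fc_thr,p_thr Bulk signature derivation thresholds (linear fold
#'   >= 2, p <= 0.05).
#' @return A `dc_config` list.
#' @export
dc_config <- function(mode = c("whole", "NI"),
                      t_knn_k = NULL, t_resolution = NULL,
                      p_knn_k = NULL, p_resolution = 1,
                      asinh_cofactor = 100, norm_scale = 1e4,
                      n_hvg = 2000, n_pcs = 30,
                      de_padj = 0.05, de_min_pct = 0.1, de_lfc = 0.25,
                      min_genes = 500, min_umi = 2000,
                      seed = 0L,
                      require_signature_confirmation = NULL,
                      marker_exclusions = "tdT",
                      jaccard_prune = 1 / 15,
                      margin_min = 0.05, z_thr = 2,
                      fc_thr = 2, p_thr = 0.05) {
  mode <- match.arg(mode)
  ni <- mode == "NI"
  cfg <- list(
    mode = mode,
    t_knn_k = as.integer(t_knn_k %||% if (ni) 5L else 9L),
    t_resolution = t_resolution %||% if (ni) 0.2 else 0.7,
    p_knn_k = as.integer(p_knn_k %||% if (ni) 20L else 50L),
    p_resolution = p_resolution,
    asinh_cofactor = asinh_cofactor, norm_scale = norm_scale,
    n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
    de_padj = de_padj, de_min_pct = de_min_pct, de_lfc = de_lfc,
    min_genes = as.integer(min_genes), min_umi = as.integer(min_umi),
    seed = as.integer(seed),
    require_signature_confirmation =
      require_signature_confirmation %||% ni,
    marker_exclusions = marker_exclusions,
    jaccard_prune = jaccard_prune,
    margin_min = margin_min, z_thr = z_thr,
    fc_thr = fc_thr, p_thr = p_thr
  )
  stopifnot(cfg$t_knn_k >= 1, cfg$p_knn_k >= 1,
            cfg$t_resolution > 0, cfg$p_resolution > 0,
            cfg$asinh_cofactor > 0, cfg$norm_scale > 0,
            cfg$n_hvg >= 1, cfg$n_pcs >= 1,
            cfg$de_padj > 0, cfg$de_padj < 1,
            cfg$de_min_pct >= 0, cfg$de_min_pct <= 1, cfg$de_lfc >= 0)
  structure(cfg, class = "dc_config")
}

#' @export
print.dc_config <- function(x, ...) {
  cat("<dc_config> mode=", x$mode,
      " | transcriptome k=", x$t_knn_k, " res=", x$t_resolution,
      " | phenotype k=", x$p_knn_k,
      " | seed=", x$seed, "\n", sep = "")
  invisible(x)
}
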