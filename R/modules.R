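#' Built-in gene module library
#'
#' Small curated gene sets used for contaminant detection and
#' activation-state labeling, editable by supplying a GMT file instead.
#' `ISG` marks the interferon-stimulated response shared by all activated
#' DC types; `maturation` the DC maturation/migration program (Fscn1, Ccr7,
#' Il15, Il15ra, Cd80, Cd200, Cd274, ...); `cytokine` inflammatory cytokine
#' genes; `IFN_I_III` the type I and III interferon genes themselves
#' (Ifnb1, the Ifna cluster, Ifnl2/3) whose high expression defines
#' IFN-producing pDCs; `macrophage`, `NK` and `proliferation` flag the
#' contaminant populations that slip through DC sort gates.  Modules are
#' pairwise disjoint.
#'
#' @return Named list of character vectors.
#' @export
dc_module_library <- function() {
  list(
    ISG = c("Isg15", "Ifit1", "Ifit3", "Irf7", "Oasl1", "Usp18",
            "Rsad2", "Oas3", "Ifi204", "Stat1"),
    maturation = c("Fscn1", "Ccr7", "Il15", "Il15ra", "Cd80", "Cd200",
                   "Cd274", "Cd40", "Relb", "Socs2"),
    cytokine = c("Il12b", "Tnf", "Il6", "Ccl5", "Ccl22", "Il27"),
    IFN_I_III = c("Ifnb1", "Ifna1", "Ifna2", "Ifna4", "Ifna5", "Ifna6",
                  "Ifna7", "Ifna9", "Ifna11", "Ifna12", "Ifna13",
                  "Ifna14", "Ifna16", "Ifnab", "Ifnl2", "Ifnl3"),
    macrophage = c("C1qa", "C1qb", "Cd5l", "Adgre1", "Fcgr1", "Mertk",
                   "Csf1r", "Mafb"),
    NK = c("Ncr1", "Klrb1c", "Gzma", "Gzmb", "Klrk1", "Prf1", "Eomes",
           "Klra4"),
    proliferation = c("Mki67", "Top2a", "Ccnb1", "Cdk1", "Birc5",
                      "Ube2c", "Tk1", "Aurkb")
  )
}

# Internal: module score as a named numeric vector per cell.
module_score_vec <- function(ds, genes, n_ctrl = 100, n_bins = 24,
                             seed = 0L) {
  if (is.null(ds$norm)) {
    abort("`norm` absent; run lognormalize first.",
          class = "dctyper_state_error")
  }
  genes <- intersect(genes, gene_ids(ds))
  if (length(genes) == 0) {
    abort("no module gene present in the dataset.",
          class = "dctyper_parameter_error")
  }
  avg <- rowMeans(ds$norm)
  n_bins <- max(1L, min(n_bins, nrow(ds$norm)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- gene_ids(ds)
  ctrl <- withr::with_seed(as.integer(seed), {
    unique(unlist(lapply(genes, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool <- setdiff(pool, g)
      if (length(pool) == 0) return(character())
      sample(pool, min(n_ctrl, length(pool)))
    })))
  })
  mod_mean <- colMeans(ds$norm[genes, , drop = FALSE])
  ctrl_mean <- if (length(ctrl) > 0) {
    colMeans(ds$norm[ctrl, , drop = FALSE])
  } else {
    rep(0, n_cells(ds))
  }
  mod_mean - ctrl_mean
}

#' Score cells for a gene module
#'
#' Mean log-normalized expression of the module genes minus the mean over
#' control genes sampled (seeded, hence deterministic) from matched
#' expression bins -- the standard module-score construct.  Scores are in
#' natural-log expression units; 0 means no enrichment over matched
#' background.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param module Character vector of module genes, or a name from
#'   [dc_module_library()].
#' @param n_ctrl Control genes sampled per module gene (default 100).
#' @param n_bins Expression bins for control matching (default 24).
#' @param seed Integer seed for control sampling.
#' @return Tibble with `cell_id` and `score`.
#' @export
module_score <- function(ds, module, n_ctrl = 100, n_bins = 24, seed = 0L) {
  if (is.character(module) && length(module) == 1 &&
      module %in% names(dc_module_library())) {
    module <- dc_module_library()[[module]]
  }
  tibble(cell_id = cell_ids(ds),
         score = unname(module_score_vec(ds, module, n_ctrl, n_bins, seed)))
}
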