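#' Detect and remove contaminant transcriptome clusters
#'
#' Sorted DC gates pick up small numbers of macrophages, NK cells and
#' proliferating cells; on the transcriptome these form their own clusters.
#' A cluster is flagged when its mean score for a contaminant module
#' (macrophage, NK, proliferation) is both (i) more than `z_thr` standard
#' deviations above the mean of the *other* clusters' scores and (ii) above
#' an absolute floor `min_score` (in log-expression units).  The
#' leave-one-out z-score keeps a genuine outlier cluster from inflating its
#' own baseline; the absolute floor keeps ordinary between-cluster spread
#' from ever being flagged when no contaminant is present.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param t_partition A `dc_partition` of the transcriptome covering the
#'   dataset's cells.
#' @param modules Module library (default [dc_module_library()]); only the
#'   `macrophage`, `NK` and `proliferation` entries are used.
#' @param z_thr Z-score threshold (default 2).
#' @param min_score Absolute mean-score floor (default 0.25).
#' @param seed Seed for module-score control sampling.
#' @return List with `dataset` (contaminant cells removed), `removed`
#'   (tibble of cluster, module, mean score, z) and `removed_cells`.
#' @export
remove_contaminants <- function(ds, t_partition,
                                modules = dc_module_library(),
                                z_thr = 2, min_score = 0.25, seed = 0L) {
  stopifnot(inherits(ds, "dc_dataset"), inherits(t_partition, "dc_partition"))
  memb <- t_partition$membership[cell_ids(ds)]
  if (any(is.na(memb))) {
    abort("partition does not cover every cell.",
          class = "dctyper_integrity_error")
  }
  contam <- intersect(c("macrophage", "NK", "proliferation"), names(modules))
  clusters <- sort(unique(memb))
  flagged <- list()
  for (mod in contam) {
    sc <- module_score_vec(ds, modules[[mod]], seed = seed)
    cl_mean <- vapply(clusters, function(cl) mean(sc[memb == cl]),
                      numeric(1))
    for (i in seq_along(clusters)) {
      others <- cl_mean[-i]
      if (length(others) >= 2 && is.finite(sd(others)) && sd(others) > 0) {
        z <- (cl_mean[i] - mean(others)) / sd(others)
      } else {
        z <- Inf  # too few clusters to estimate spread; floor decides
      }
      if (cl_mean[i] > min_score && z > z_thr) {
        flagged[[length(flagged) + 1]] <-
          tibble(cluster = clusters[i], module = mod,
                 mean_score = cl_mean[i],
                 z = if (is.finite(z)) z else NA_real_)
      }
    }
  }
  removed <- if (length(flagged) > 0) bind_rows(flagged) else
    tibble(cluster = integer(), module = character(),
           mean_score = numeric(), z = numeric())
  bad_clusters <- unique(removed$cluster)
  if (length(bad_clusters) == length(clusters) && length(clusters) > 0) {
    abort("every cluster was flagged as contaminant; check thresholds.",
          class = "dctyper_integrity_error")
  }
  keep <- cell_ids(ds)[!memb %in% bad_clusters]
  list(dataset = subset_cells(ds, keep),
       removed = removed,
       removed_cells = setdiff(cell_ids(ds), keep))
}

#' Assign a cell type to each cluster of one modality
#'
#' Each cluster takes the type whose signature has the highest mean
#' normalized connectivity score among the cluster's cells; the margin to
#' the runner-up measures confidence.  When the margin falls below
#' `margin_min` the cluster's majority sort label decides (sorting gates
#' map to types: the Zbtb46+Ly6D+ gate to pDC-like, tdT-negative pDCs to
#' pDC); if that too fails to break the tie the cluster stays
#' `"unresolved"`.  Signature scores therefore override the sort label
#' whenever they are decisive -- the route by which gate-drifted activated
#' tDC clusters are labeled tDC despite their pDC-like sort.
#'
#' @param partition A `dc_partition`.
#' @param scores A `dc_scores` tibble from [score_all()].
#' @param sort_labels Named character vector of sort labels per cell.
#' @param margin_min Minimum decisive margin on mean score (default 0.05).
#' @return A `ClusterTypeMap` tibble: `cluster`, `type`, `mean_score`,
#'   `margin`, `majority_sort_fraction`.
#' @export
label_clusters <- function(partition, scores, sort_labels,
                           margin_min = 0.05) {
  stopifnot(inherits(partition, "dc_partition"), is.data.frame(scores))
  memb <- partition$membership
  sig_names <- setdiff(names(scores), "cell_id")
  smat <- as.matrix(scores[sig_names])
  rownames(smat) <- scores$cell_id
  if (!all(names(memb) %in% rownames(smat))) {
    abort("scores do not cover every clustered cell.",
          class = "dctyper_integrity_error")
  }
  out <- lapply(sort(unique(memb)), function(cl) {
    cells <- names(memb)[memb == cl]
    mu <- colMeans(smat[cells, , drop = FALSE])
    ord <- order(-mu, sig_names)
    best <- sig_names[ord[1]]
    margin <- if (length(mu) > 1) mu[ord[1]] - mu[ord[2]] else Inf
    sl <- SORT_GATE_TO_TYPE[sort_labels[cells]]
    sl <- sl[!is.na(sl)]
    maj_frac <- if (length(sl) > 0) max(table(sl)) / length(cells) else 0
    type <- best
    if (mu[ord[1]] <= 0) {
      # no signature is enriched: the cluster is not one of the DC types
      type <- "unresolved"
    } else if (margin < margin_min) {
      tab <- sort(table(sl), decreasing = TRUE)
      if (length(tab) >= 1 &&
          (length(tab) == 1 || tab[1] > tab[2]) &&
          names(tab)[1] %in% sig_names) {
        type <- names(tab)[1]
      } else {
        type <- "unresolved"
      }
    }
    tibble(cluster = cl, type = type,
           mean_score = unname(mu[ord[1]]), margin = unname(margin),
           majority_sort_fraction = unname(maj_frac))
  })
  bind_rows(out)
}

#' Consensus cell-type assignment from two modalities
#'
#' The intersection rule with deductive reassignment: a cell is assigned
#' type `X` when its transcriptome cluster and its phenotype cluster are
#' both labeled `X` (optionally requiring a positive connectivity score for
#' `X` as confirmation); when the two modalities disagree but one of them
#' is `"unresolved"`, the resolved label is adopted provided the cell's
#' score for it is positive (deductive reassignment); any remaining
#' disagreement yields `NA`.  The sort label never overrides a concordant
#' call.
#'
#' @param cells Character vector of cell ids to annotate.
#' @param t_partition,p_partition The two `dc_partition`s.
#' @param t_map,p_map Cluster type maps from [label_clusters()].
#' @param scores A `dc_scores` tibble.
#' @param require_confirmation Gate concordant calls on score > 0.
#' @return Tibble with `cell_id`, `type`, `transcriptome_cluster`,
#'   `phenotype_cluster`, `best_signature`, `best_score`.
#' @export
consensus_annotate <- function(cells, t_partition, p_partition,
                               t_map, p_map, scores,
                               require_confirmation = FALSE) {
  sig_names <- setdiff(names(scores), "cell_id")
  smat <- as.matrix(scores[sig_names])
  rownames(smat) <- scores$cell_id
  t_type <- setNames(t_map$type, t_map$cluster)
  p_type <- setNames(p_map$type, p_map$cluster)
  out <- lapply(cells, function(cell) {
    tc <- t_partition$membership[[cell]]
    pc <- p_partition$membership[[cell]]
    tt <- unname(t_type[as.character(tc)])
    pt_ <- unname(p_type[as.character(pc)])
    tau <- function(type) {
      if (!is.null(type) && !is.na(type) && type %in% sig_names) {
        smat[cell, type]
      } else {
        NA_real_
      }
    }
    type <- NA_character_
    if (!is.na(tt) && !is.na(pt_)) {
      if (tt == pt_ && tt != "unresolved") {
        if (!require_confirmation || isTRUE(tau(tt) > 0)) type <- tt
      } else if (tt == "unresolved" && pt_ != "unresolved") {
        if (isTRUE(tau(pt_) > 0)) type <- pt_
      } else if (pt_ == "unresolved" && tt != "unresolved") {
        if (isTRUE(tau(tt) > 0)) type <- tt
      }
    }
    best <- sig_names[which.max(smat[cell, ])]
    tibble(cell_id = cell, type = type,
           transcriptome_cluster = tc, phenotype_cluster = pc,
           best_signature = best,
           best_score = unname(smat[cell, best]))
  })
  bind_rows(out)
}

#' Assign activation states within each annotated type
#'
#' States are assigned per (type, transcriptome cluster).  Within a type,
#' the cluster with the lowest mean ISG score is the quiescent baseline;
#' relative to that cluster's per-cell score spread, a cluster is
#' `ifn_producing` (pDCs only) when its mean type I/III interferon score
#' exceeds baseline + 3 SD, `activated` when its maturation or cytokine
#' score exceeds baseline + 2 SD, `intermediate` when only the ISG score is
#' elevated (baseline + 2 SD), and `quiescent` otherwise.  A type with a
#' single cluster is quiescent unless its absolute maturation/cytokine
#' score clears `single_cluster_floor`.  Cells without a type get state
#' `NA`; `ifn_producing` is impossible outside pDCs by construction.
#'
#' @param ds A [dc_dataset()] with `norm` present.
#' @param labels Annotation tibble with `cell_id`, `type`,
#'   `transcriptome_cluster`.
#' @param modules Module library (default [dc_module_library()]).
#' @param seed Seed for module-score control sampling.
#' @param single_cluster_floor Absolute activation score required to call a
#'   single-cluster type activated (default 0.5).
#' @return `labels` with a `state` column added.
#' @export
assign_activation_states <- function(ds, labels,
                                     modules = dc_module_library(),
                                     seed = 0L,
                                     single_cluster_floor = 0.5) {
  stopifnot(is.data.frame(labels),
            all(c("cell_id", "type", "transcriptome_cluster") %in%
                  names(labels)))
  sc <- list(
    isg = module_score_vec(ds, modules$ISG, seed = seed),
    mat = module_score_vec(ds, modules$maturation, seed = seed),
    cyt = module_score_vec(ds, modules$cytokine, seed = seed),
    ifn = module_score_vec(ds, modules$IFN_I_III, seed = seed)
  )
  labels$state <- NA_character_
  for (type in intersect(DC_TYPES, unique(labels$type))) {
    sel <- !is.na(labels$type) & labels$type == type
    clusters <- sort(unique(labels$transcriptome_cluster[sel]))
    cl_cells <- lapply(clusters, function(cl) {
      labels$cell_id[sel & labels$transcriptome_cluster == cl]
    })
    mean_of <- function(score, i) mean(score[cl_cells[[i]]])
    if (length(clusters) == 1) {
      act <- max(mean_of(sc$mat, 1), mean_of(sc$cyt, 1))
      labels$state[sel] <- if (act > single_cluster_floor) "activated" else
        "quiescent"
      next
    }
    q <- which.min(vapply(seq_along(clusters), mean_of, numeric(1),
                          score = sc$isg))
    qc_cells <- cl_cells[[q]]
    base <- lapply(sc, function(s) {
      c(mean = mean(s[qc_cells]), sd = max(sd(s[qc_cells]), 1e-6))
    })
    for (i in seq_along(clusters)) {
      m_isg <- mean_of(sc$isg, i)
      m_mat <- mean_of(sc$mat, i)
      m_cyt <- mean_of(sc$cyt, i)
      m_ifn <- mean_of(sc$ifn, i)
      state <-
        if (type == "pDC" &&
            m_ifn > base$ifn["mean"] + 3 * base$ifn["sd"]) {
          "ifn_producing"
        } else if (m_mat > base$mat["mean"] + 2 * base$mat["sd"] ||
                   m_cyt > base$cyt["mean"] + 2 * base$cyt["sd"]) {
          "activated"
        } else if (m_isg > base$isg["mean"] + 2 * base$isg["sd"]) {
          "intermediate"
        } else {
          "quiescent"
        }
      cells_i <- cl_cells[[i]]
      labels$state[labels$cell_id %in% cells_i] <- state
    }
  }
  labels$state[is.na(labels$type)] <- NA_character_
  stopifnot(all(labels$type[!is.na(labels$state) &
                              labels$state == "ifn_producing"] == "pDC"))
  labels
}
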