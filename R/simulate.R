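#' Simulation configuration
#'
#' Defines the generative model for ground-truthed index-sorted DC
#' datasets: five DC types (pDC, pDC-like, tDC, cDC1, cDC2) with
#' type-specific and shared gene programs, activation states driven by
#' ISG/maturation/cytokine/interferon modules, negative-binomial UMI counts
#' over lognormal library sizes, lognormal surface-marker intensities
#' reproducing the phenotype keys (tdT selective for pDCs, BST2 rising with
#' activation, SiglecH lost on IFN-producing pDCs, CX3CR1 lost on activated
#' tDCs), sort-gate drift of activated tDCs into the pDC-like gate, and
#' macrophage/NK/proliferating contaminants.
#'
#' The default population sizes (~940 cells) mirror the scale and the
#' type proportions of a plate-based DC survey spanning uninfected, 36 h
#' and 48 h infection timepoints.
#'
#' @param n_per_group Tibble with `type`, `state`, `n`; defaults to the
#'   built-in composition.
#' @param n_genes Gene universe size (default 2,000).
#' @param module_size Genes per type/state module (default 50).
#' @param shared_size Genes per shared lineage block (default 25).
#' @param contam_size Genes per contaminant module (default 30).
#' @param effect Log-fold induction of module genes (default 2 natural-log
#'   units, ~7.4x).
#' @param dispersion NB inverse-dispersion: `var = mu + mu^2/dispersion`
#'   (default 2).
#' @param depth_mu,depth_sigma Lognormal library-size parameters (default
#'   `log(20000)`, 0.35).
#' @param marker_sigma Lognormal sigma of marker intensities (default 0.5
#'   natural-log units).
#' @param gate_drift_rate Fraction of activated tDCs sort-labeled pDClike
#'   (default 0.5).
#' @param contaminant_fraction Per contaminant type, fraction of the DC
#'   cell total (default 0.05).
#' @param n_bulk_reps Bulk reference replicates per type (default 3).
#' @param n_missing_markers Cells whose index-sort record is dropped
#'   (default 2, mimicking occasional well loss).
#' @param flat_markers Ablation switch: TRUE erases all type/state marker
#'   structure (used to demonstrate that the phenotype modality carries
#'   signal).
#' @param seed Integer seed.
#' @return A `dc_sim_config` list.
#' @export
dc_sim_config <- function(n_per_group = NULL, n_genes = 2000,
                          module_size = 50, shared_size = 25,
                          contam_size = 30, effect = 2,
                          dispersion = 2,
                          depth_mu = log(20000), depth_sigma = 0.35,
                          marker_sigma = 0.5,
                          gate_drift_rate = 0.5,
                          contaminant_fraction = 0.05,
                          n_bulk_reps = 3, n_missing_markers = 2,
                          flat_markers = FALSE, seed = 1L) {
  n_per_group <- n_per_group %||% tibble(
    type = c(rep("pDC", 4), rep("pDClike", 2), rep("tDC", 3),
             rep("cDC1", 3), rep("cDC2", 3)),
    state = c("quiescent", "intermediate", "activated", "ifn_producing",
              "quiescent", "activated",
              "quiescent", "intermediate", "activated",
              "quiescent", "intermediate", "activated",
              "quiescent", "intermediate", "activated"),
    n = c(120L, 70L, 60L, 40L, 90L, 70L, 70L, 40L, 40L,
          60L, 30L, 30L, 50L, 25L, 25L)
  )
  stopifnot(all(n_per_group$n >= 0), dispersion > 0, depth_sigma > 0,
            marker_sigma > 0, gate_drift_rate >= 0, gate_drift_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            n_bulk_reps >= 1)
  cfg <- list(n_per_group = n_per_group, n_genes = as.integer(n_genes),
              module_size = as.integer(module_size),
              shared_size = as.integer(shared_size),
              contam_size = as.integer(contam_size),
              effect = effect, dispersion = dispersion,
              depth_mu = depth_mu, depth_sigma = depth_sigma,
              marker_sigma = marker_sigma,
              gate_drift_rate = gate_drift_rate,
              contaminant_fraction = contaminant_fraction,
              n_bulk_reps = as.integer(n_bulk_reps),
              n_missing_markers = as.integer(n_missing_markers),
              flat_markers = isTRUE(flat_markers),
              seed = as.integer(seed))
  structure(cfg, class = "dc_sim_config")
}

# Gene universe and module membership for a sim config.
sim_gene_modules <- function(cfg) {
  lib <- dc_module_library()
  anchors <- list(
    pDC = c("Ccr9", "Klk1", "Cox6a2", "Pacsin1", "Lag3"),
    pDClike = c("Ly6c2", "Apod"),
    tDC = c("Tmem176a", "Tmem176b", "Rogdi", "Cyria"),
    cDC1 = c("Xcr1", "Gpr141b", "Tlr3", "Cadm1", "Naaa"),
    cDC2 = c("Clec4a4", "Mgl2"),
    shared_pDC_pDClike = c("Siglech", "Tcf4", "Runx2"),
    shared_pDClike_tDC = c("Crip1", "Lgals3", "Vim"),
    cdc_lineage = c("Zbtb46", "Spi1", "Slamf7", "S100a11"),
    ISG = lib$ISG, maturation = lib$maturation, cytokine = lib$cytokine,
    IFN_I_III = lib$IFN_I_III,
    macrophage = lib$macrophage, NK = lib$NK,
    proliferation = lib$proliferation
  )
  sizes <- c(
    pDC = cfg$module_size, pDClike = cfg$module_size,
    tDC = cfg$module_size, cDC1 = cfg$module_size, cDC2 = cfg$module_size,
    shared_pDC_pDClike = cfg$shared_size,
    shared_pDClike_tDC = cfg$shared_size,
    cdc_lineage = cfg$shared_size,
    ISG = cfg$module_size, maturation = cfg$module_size,
    cytokine = 20L, IFN_I_III = length(lib$IFN_I_III),
    macrophage = cfg$contam_size, NK = cfg$contam_size,
    proliferation = cfg$contam_size
  )
  filler_id <- 0L
  modules <- list()
  for (nm in names(anchors)) {
    need <- sizes[[nm]] - length(anchors[[nm]])
    if (need < 0) {
      abort(paste0("module size too small for anchors of ", nm),
            class = "dctyper_config_error")
    }
    fill <- if (need > 0) sprintf("g%04d", filler_id + seq_len(need)) else
      character()
    filler_id <- filler_id + need
    modules[[nm]] <- c(anchors[[nm]], fill)
  }
  n_module_genes <- sum(lengths(modules))
  if (n_module_genes > cfg$n_genes) {
    abort("module sizes exceed the gene universe.",
          class = "dctyper_config_error")
  }
  background <- sprintf("g%04d",
                        filler_id + seq_len(cfg$n_genes - n_module_genes))
  list(modules = modules, genes = c(unlist(modules, use.names = FALSE),
                                    background))
}

# Normalized mean expression profile of one (type, state) group.
sim_group_weights <- function(cfg, mods, base_weight, type, state) {
  eff <- exp(cfg$effect)
  half <- exp(cfg$effect * 0.75)
  m <- mods$modules
  w <- base_weight
  bump <- function(genes, f) w[genes] <<- w[genes] * f
  if (type %in% DC_TYPES) {
    bump(m[[type]], eff)
    if (type %in% c("pDC", "pDClike")) bump(m$shared_pDC_pDClike, eff)
    if (type %in% c("pDClike", "tDC")) bump(m$shared_pDClike_tDC, eff)
    if (type != "pDC") bump(m$cdc_lineage, eff)
    if (state %in% c("intermediate", "activated", "ifn_producing")) {
      bump(m$ISG, eff)
    }
    if (state %in% c("activated", "ifn_producing")) {
      if (type %in% c("tDC", "cDC1", "cDC2")) {
        bump(m$maturation, eff)
        bump(m$cytokine, exp(1))
      } else {
        # pDC / pDC-like activation: moderate cytokine induction plus a
        # partial maturation program, without the full cDC-like shift
        bump(m$cytokine, half)
        bump(m$maturation, half)
      }
    }
    if (state == "ifn_producing") bump(m$IFN_I_III, exp(3))
  } else {
    contam_module <- c(macrophage = "macrophage", NK = "NK",
                       proliferating = "proliferation")[[type]]
    bump(m[[contam_module]], exp(cfg$effect + 0.5))
  }
  w / sum(w)
}

# Per-(type, state) normalized mean profiles for every simulated group.
sim_group_means <- function(cfg, mods, base_weight) {
  groups <- unique(rbind(
    cfg$n_per_group[c("type", "state")],
    tibble(type = CONTAMINANT_TYPES, state = "quiescent"),
    tibble(type = DC_TYPES, state = "quiescent")  # bulk reference baseline
  ))
  mean_list <- lapply(seq_len(nrow(groups)), function(r) {
    sim_group_weights(cfg, mods, base_weight, groups$type[r],
                      groups$state[r])
  })
  setNames(mean_list, paste(groups$type, groups$state, sep = "."))
}

# Geometric-mean marker intensity table: high 1e4 / int 1e3 / low 1e2.
sim_marker_table <- function() {
  H <- 1e4; M <- 1e3; L <- 1e2
  tab <- rbind(
    pDC          = c(GFP = L, tdT = H, B220 = H, Ly6D = H, XCR1 = L,
                     CX3CR1 = L, BST2 = H, SiglecH = H, CCR9 = H,
                     CD11b = L, CD11c = M),
    pDClike      = c(GFP = M, tdT = L, B220 = M, Ly6D = M, XCR1 = L,
                     CX3CR1 = H, BST2 = M, SiglecH = M, CCR9 = M,
                     CD11b = L, CD11c = M),
    tDC          = c(GFP = H, tdT = L, B220 = L, Ly6D = L, XCR1 = L,
                     CX3CR1 = H, BST2 = L, SiglecH = L, CCR9 = L,
                     CD11b = L, CD11c = H),
    cDC1         = c(GFP = H, tdT = L, B220 = L, Ly6D = L, XCR1 = H,
                     CX3CR1 = L, BST2 = L, SiglecH = L, CCR9 = L,
                     CD11b = L, CD11c = H),
    cDC2         = c(GFP = H, tdT = L, B220 = L, Ly6D = L, XCR1 = L,
                     CX3CR1 = M, BST2 = L, SiglecH = L, CCR9 = L,
                     CD11b = H, CD11c = H),
    macrophage   = c(GFP = L, tdT = L, B220 = L, Ly6D = L, XCR1 = L,
                     CX3CR1 = M, BST2 = M, SiglecH = L, CCR9 = L,
                     CD11b = H, CD11c = M),
    NK           = c(GFP = L, tdT = L, B220 = L, Ly6D = L, XCR1 = L,
                     CX3CR1 = L, BST2 = L, SiglecH = L, CCR9 = L,
                     CD11b = M, CD11c = L),
    proliferating = c(GFP = L, tdT = L, B220 = M, Ly6D = M, XCR1 = L,
                      CX3CR1 = L, BST2 = M, SiglecH = L, CCR9 = L,
                      CD11b = M, CD11c = M)
  )
  tab[, DC_MARKER_PANEL]
}

#' Simulate a ground-truthed index-sorted DC dataset
#'
#' Draws UMI counts from a negative binomial whose per-group means are the
#' baseline gene weights times the active module multipliers, library
#' sizes from a lognormal, and surface-marker intensities from lognormals
#' on the raw fluorescence scale with the four phenotype-key shifts (tdT
#' selective for pDCs; BST2 up 2x at intermediate and 5x at activated
#' states; SiglecH down 10x on IFN-producing pDCs; CX3CR1 down 10x on
#' activated tDCs).  Bulk reference profiles per DC type are the quiescent
#' group means (CPM scale) with lognormal replicate noise.  Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [dc_sim_config()].
#' @return List with `dataset` (a [dc_dataset()]), `truth` (tibble:
#'   `cell_id`, `true_type`, `true_state`, `drifted_sort`) and `reference`
#'   (a [dc_reference()] over the five DC types).
#' @export
simulate_dataset <- function(cfg = dc_sim_config()) {
  stopifnot(inherits(cfg, "dc_sim_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  mods <- sim_gene_modules(cfg)
  genes <- mods$genes
  base_weight <- setNames(rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1),
                          genes)
  # selective programs are near-silent outside the expressing population:
  # module genes start two log-units below the background baseline, so the
  # e^effect induction makes them unambiguous in the active groups only
  module_genes <- unlist(mods$modules, use.names = FALSE)
  base_weight[module_genes] <- base_weight[module_genes] * exp(-2)
  means <- sim_group_means(cfg, mods, base_weight)

  n_dc <- sum(cfg$n_per_group$n)
  n_contam <- floor(cfg$contaminant_fraction * n_dc)
  groups <- rbind(cfg$n_per_group,
                  tibble(type = CONTAMINANT_TYPES, state = "quiescent",
                         n = rep(n_contam, 3)))
  groups <- groups[groups$n > 0, , drop = FALSE]

  true_type <- rep(groups$type, groups$n)
  true_state <- rep(groups$state, groups$n)
  n_tot <- length(true_type)
  cells <- sprintf("cell%04d", seq_len(n_tot))

  # counts
  depth <- rlnorm(n_tot, cfg$depth_mu, cfg$depth_sigma)
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_tot,
                   dimnames = list(genes, cells))
  for (r in seq_len(nrow(groups))) {
    key <- paste(groups$type[r], groups$state[r], sep = ".")
    idx <- which(true_type == groups$type[r] &
                   true_state == groups$state[r])
    mu <- outer(means[[key]], depth[idx])
    counts[, idx] <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = cfg$dispersion),
      nrow = cfg$n_genes
    )
  }

  # markers
  tab <- sim_marker_table()
  gm <- tab[true_type, , drop = FALSE]
  act <- true_state %in% c("activated", "ifn_producing")
  intm <- true_state == "intermediate"
  dcish <- true_type %in% DC_TYPES
  gm[dcish & act, "BST2"] <- gm[dcish & act, "BST2"] * 5
  gm[dcish & intm, "BST2"] <- gm[dcish & intm, "BST2"] * 2
  gm[true_type == "pDC" & true_state == "ifn_producing", "SiglecH"] <-
    gm[true_type == "pDC" & true_state == "ifn_producing", "SiglecH"] / 10
  gm[true_type == "tDC" & true_state == "activated", "CX3CR1"] <-
    gm[true_type == "tDC" & true_state == "activated", "CX3CR1"] / 10
  if (cfg$flat_markers) gm[] <- 1e3
  markers <- matrix(
    rlnorm(length(gm), meanlog = log(as.vector(gm)),
           sdlog = cfg$marker_sigma),
    nrow = n_tot, dimnames = list(cells, DC_MARKER_PANEL)
  )

  truth <- tibble(cell_id = cells, true_type = true_type,
                  true_state = true_state, drifted_sort = FALSE)
  sl <- simulate_sort_labels(truth, cfg)
  truth <- sl$truth

  timepoint <- dplyr::case_when(
    !dcish ~ sample(TIMEPOINTS, n_tot, replace = TRUE),
    true_state == "quiescent" ~ "NI",
    true_state == "intermediate" ~ "36h",
    true_state == "ifn_producing" ~ "36h",
    TRUE ~ sample(c("36h", "48h"), n_tot, replace = TRUE)
  )
  mouse_pool <- list(NI = c("m56", "m58"), `36h` = c("m52", "m53"),
                    `48h` = c("m81", "m84"))
  mouse_id <- vapply(timepoint, function(tp) sample(mouse_pool[[tp]], 1),
                     character(1))
  meta <- tibble(
    cell_id = cells, mouse_id = mouse_id, timepoint = timepoint,
    sort_label = sl$sort_labels,
    plate = sprintf("P%02d", (seq_len(n_tot) - 1) %/% 96 + 1),
    well = sprintf("%s%02d", LETTERS[(seq_len(n_tot) - 1) %% 8 + 1],
                   (seq_len(n_tot) - 1) %/% 8 %% 12 + 1)
  )

  if (cfg$n_missing_markers > 0) {
    drop <- sample(n_tot, min(cfg$n_missing_markers, n_tot))
    markers <- markers[-drop, , drop = FALSE]
  }

  # bulk references: quiescent group means on a CPM-like scale
  ref_expr <- do.call(cbind, lapply(DC_TYPES, function(type) {
    mu <- means[[paste(type, "quiescent", sep = ".")]] * 1e6
    vapply(seq_len(cfg$n_bulk_reps), function(r) {
      mu * rlnorm(cfg$n_genes, 0, 0.15)
    }, numeric(cfg$n_genes))
  }))
  colnames(ref_expr) <- paste0(rep(DC_TYPES, each = cfg$n_bulk_reps),
                               "_rep", seq_len(cfg$n_bulk_reps))
  rownames(ref_expr) <- genes
  reference <- dc_reference(ref_expr, rep(DC_TYPES, each = cfg$n_bulk_reps))

  list(dataset = dc_dataset(counts, meta, markers),
       truth = truth, reference = reference)
}

#' Assign sort-gate labels to simulated cells
#'
#' Sort labels equal the true type, except that activated tDCs drift into
#' the pDC-like gate with probability `cfg$gate_drift_rate` (their CX3CR1
#' loss and BST2 gain push them across that gate boundary), and
#' contaminants fall uniformly into one of the five DC gates.  Drift is
#' recorded in the truth table.
#'
#' @param truth Truth tibble with `true_type`, `true_state`.
#' @param cfg A [dc_sim_config()].
#' @return List with `sort_labels` (character vector) and the updated
#'   `truth`.
#' @export
simulate_sort_labels <- function(truth, cfg) {
  labels <- truth$true_type
  contam <- truth$true_type %in% CONTAMINANT_TYPES
  labels[contam] <- sample(DC_TYPES, sum(contam), replace = TRUE)
  drift_pool <- which(truth$true_type == "tDC" &
                        truth$true_state == "activated")
  drifted <- drift_pool[as.logical(rbinom(length(drift_pool), 1,
                                          cfg$gate_drift_rate))]
  labels[drifted] <- "pDClike"
  truth$drifted_sort <- seq_len(nrow(truth)) %in% drifted
  list(sort_labels = labels, truth = truth)
}
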