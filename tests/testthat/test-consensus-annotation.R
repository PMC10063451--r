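sim_cache <- new.env()
get_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- simulate_dataset(dc_sim_config(seed = 5))
    sim_cache$ds <- lognormalize(
      qc_filter(sim_cache$sim$dataset, 500, 2000)$dataset, 1e4)
  }
  list(sim = sim_cache$sim, ds = sim_cache$ds)
}

test_that("module scores are zero-centered, spike-sensitive and seeded", {
  x <- get_sim()
  ds <- x$ds

  # all-zero module genes against all-zero controls give score 0
  flat <- dc_dataset(matrix(0:1, 10, 4,
                            dimnames = list(sprintf("g%02d", 1:10),
                                            sprintf("c%d", 1:4))),
                     tibble::tibble(cell_id = sprintf("c%d", 1:4)))
  flat$counts[1:2, ] <- 0L
  flat <- lognormalize(flat, 1e4)
  flat$norm[] <- 0
  expect_equal(module_score(flat, c("g01", "g02"), seed = 1)$score,
               rep(0, 4))

  # a +2 norm-unit spike separates spiked cells by at least 1
  spiked <- ds
  mod <- dctyper:::sim_gene_modules(dc_sim_config())$modules$ISG[1:10]
  on <- colnames(spiked$norm)[1:100]
  spiked$norm[mod, on] <- spiked$norm[mod, on] + 2
  sc <- module_score(spiked, mod, seed = 1)
  expect_gte(mean(sc$score[sc$cell_id %in% on]) -
               mean(sc$score[!sc$cell_id %in% on]), 1)

  # determinism
  expect_identical(module_score(ds, "ISG", seed = 7),
                   module_score(ds, "ISG", seed = 7))
  expect_error(module_score(ds, c("not_a_gene")),
               class = "dctyper_parameter_error")
})

test_that("contaminant clusters are removed exactly and irreversibly", {
  x <- get_sim()
  cfg <- dc_config("whole", seed = 5)
  t0 <- cluster_cells(x$ds, "transcriptome", cfg)
  rc <- remove_contaminants(x$ds, t0, z_thr = 2, seed = 5)

  truth <- x$sim$truth[match(rc$removed_cells, x$sim$truth$cell_id), ]
  expect_true(all(truth$true_type %in% dctyper:::CONTAMINANT_TYPES))
  kept_truth <- x$sim$truth[
    x$sim$truth$cell_id %in% colnames(rc$dataset$counts), ]
  expect_false(any(kept_truth$true_type %in% dctyper:::CONTAMINANT_TYPES))

  # removed cells never reappear in downstream partitions
  t1 <- cluster_cells(rc$dataset, "transcriptome", cfg)
  expect_length(intersect(names(t1$membership), rc$removed_cells), 0)
})

test_that("cluster labeling follows scores, sort majority, then gives up", {
  scores <- tibble::tibble(
    cell_id = sprintf("c%d", 1:6),
    pDC = c(0.9, 0.8, 0.85, -0.2, 0.5, 0.5),
    tDC = c(-0.5, -0.4, -0.6, 0.7, 0.5, 0.5)
  )
  part <- structure(list(
    membership = setNames(c(0L, 0L, 0L, 1L, 2L, 2L), sprintf("c%d", 1:6)),
    modularity = 0.3, seed = 1, params = list()), class = "dc_partition")
  sort_labels <- setNames(c("pDC", "pDC", "pDC", "pDClike", "pDC", "tDC"),
                          sprintf("c%d", 1:6))
  map <- label_clusters(part, scores, sort_labels)
  expect_identical(map$type[map$cluster == 0], "pDC")
  expect_gt(map$margin[map$cluster == 0], 0)
  # cluster 1: activated tDC sorted as pDC-like, scores override the sort
  expect_identical(map$type[map$cluster == 1], "tDC")
  # cluster 2: tied scores and tied sort majorities stay unresolved
  expect_identical(map$type[map$cluster == 2], "unresolved")
})

test_that("consensus assignment implements intersection plus deduction", {
  mk_part <- function(memb) {
    structure(list(membership = memb, modularity = 0, seed = 1,
                   params = list()), class = "dc_partition")
  }
  cells <- sprintf("c%d", 1:4)
  tp <- mk_part(setNames(c(0L, 0L, 1L, 2L), cells))
  pp <- mk_part(setNames(c(0L, 0L, 1L, 2L), cells))
  t_map <- tibble::tibble(cluster = 0:2,
                          type = c("pDC", "tDC", "cDC2"),
                          mean_score = 0.5, margin = 0.3,
                          majority_sort_fraction = 1)
  p_map <- tibble::tibble(cluster = 0:2,
                          type = c("pDC", "unresolved", "pDC"),
                          mean_score = 0.5, margin = 0.3,
                          majority_sort_fraction = 1)
  scores <- tibble::tibble(cell_id = cells,
                           pDC = c(0.6, -0.1, 0.1, 0.4),
                           tDC = c(0, 0, 0.5, 0.1),
                           cDC2 = c(0, 0, 0, 0.3))
  out <- consensus_annotate(cells, tp, pp, t_map, p_map, scores)
  # concordant pDC/pDC
  expect_identical(out$type[1], "pDC")
  # concordant without confirmation requirement keeps the call even at tau<0
  expect_identical(out$type[2], "pDC")
  # transcriptome resolved, phenotype unresolved, tau>0: deductive tDC
  expect_identical(out$type[3], "tDC")
  # both resolved but discordant: NA
  expect_true(is.na(out$type[4]))

  # with confirmation required, the tau<=0 concordant call becomes NA
  strict <- consensus_annotate(cells, tp, pp, t_map, p_map, scores,
                               require_confirmation = TRUE)
  expect_true(is.na(strict$type[2]))
})

test_that("activation states follow the module-score ladder", {
  x <- get_sim()
  cfg <- dc_config("whole", seed = 5)
  t0 <- cluster_cells(x$ds, "transcriptome", cfg)
  rc <- remove_contaminants(x$ds, t0, z_thr = 2, seed = 5)
  t1 <- cluster_cells(rc$dataset, "transcriptome", cfg)
  truth <- x$sim$truth
  labels <- tibble::tibble(
    cell_id = names(t1$membership),
    type = truth$true_type[match(names(t1$membership), truth$cell_id)],
    transcriptome_cluster = unname(t1$membership)
  )
  labels$type[!labels$type %in% dctyper:::DC_TYPES] <- NA
  out <- assign_activation_states(rc$dataset, labels, seed = 5)

  merged <- dplyr::left_join(out, truth, by = "cell_id")
  ok <- !is.na(merged$type)
  expect_gte(mean(merged$state[ok] == merged$true_state[ok]), 0.85)
  # the interferon-producing state never leaves the pDC compartment
  ifn <- merged[!is.na(merged$state) & merged$state == "ifn_producing", ]
  expect_true(all(ifn$type == "pDC"))
  expect_true(nrow(ifn) > 0)
  # ISG-only induction is intermediate, not activated
  inter <- merged[merged$true_state == "intermediate" & ok, ]
  expect_gte(mean(inter$state == "intermediate"), 0.85)
  # untyped cells carry no state
  expect_true(all(is.na(out$state[is.na(out$type)])))
})

test_that("an all-quiescent dataset yields only quiescent states", {
  cfgq <- dc_sim_config(seed = 9, contaminant_fraction = 0,
                        n_missing_markers = 0)
  cfgq$n_per_group <- cfgq$n_per_group[
    cfgq$n_per_group$state == "quiescent", ]
  simq <- simulate_dataset(cfgq)
  dsq <- lognormalize(simq$dataset, 1e4)
  cfg <- dc_config("whole", seed = 9)
  t1 <- cluster_cells(dsq, "transcriptome", cfg)
  labels <- tibble::tibble(
    cell_id = names(t1$membership),
    type = simq$truth$true_type[match(names(t1$membership),
                                      simq$truth$cell_id)],
    transcriptome_cluster = unname(t1$membership)
  )
  out <- assign_activation_states(dsq, labels, seed = 9)
  expect_true(all(out$state[!is.na(out$type)] == "quiescent"))
})
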