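# Small in-code fixtures shared across test files.

# Minimal dataset: deterministic counts, full marker table.
tiny_dataset <- function(n_genes = 20, n_cells = 10, seed = 42,
                         drop_markers = integer()) {
  withr::with_seed(seed, {
    genes <- sprintf("gene%02d", seq_len(n_genes))
    cells <- sprintf("c%02d", seq_len(n_cells))
    counts <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
                     dimnames = list(genes, cells))
    meta <- tibble::tibble(
      cell_id = cells, mouse_id = "m1",
      timepoint = rep(c("NI", "36h"), length.out = n_cells),
      sort_label = rep(c("pDC", "cDC1"), length.out = n_cells),
      plate = "P01", well = sprintf("A%02d", seq_len(n_cells))
    )
    markers <- matrix(rlnorm(n_cells * 11, log(1000), 0.3), n_cells, 11,
                      dimnames = list(cells, dctyper:::DC_MARKER_PANEL))
    if (length(drop_markers) > 0) {
      markers <- markers[-drop_markers, , drop = FALSE]
    }
    dc_dataset(counts, meta, markers)
  })
}

# Two-group NB expression dataset for DE tests: `planted` divergent genes,
# half induced and half repressed by `effect` natural-log units in group 1
# (balanced so library depth stays comparable between groups).
two_group_dataset <- function(n_genes, n_per_group, planted = 0,
                              effect = 2, dispersion = 2, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    n <- 2 * n_per_group
    cells <- sprintf("c%03d", seq_len(n))
    base <- rlnorm(n_genes, 1, 0.5)
    mu1 <- base
    if (planted > 0) {
      up <- seq_len(ceiling(planted / 2))
      dn <- setdiff(seq_len(planted), up)
      mu1[up] <- base[up] * exp(effect)
      mu1[dn] <- base[dn] * exp(-effect)
    }
    counts <- cbind(
      matrix(rnbinom(n_genes * n_per_group, mu = mu1, size = dispersion),
             n_genes, n_per_group),
      matrix(rnbinom(n_genes * n_per_group, mu = base, size = dispersion),
             n_genes, n_per_group)
    )
    dimnames(counts) <- list(genes, cells)
    meta <- tibble::tibble(cell_id = cells)
    ds <- dc_dataset(counts, meta)
    ds <- lognormalize(ds, 1e4)
    groups <- setNames(rep(c("A", "B"), each = n_per_group), cells)
    list(dataset = ds, groups = groups)
  })
}

random_labels_table <- function(n, seed = 7) {
  withr::with_seed(seed, {
    type <- sample(c(dctyper:::DC_TYPES, NA), n, replace = TRUE)
    state <- ifelse(is.na(type), NA_character_,
                    ifelse(type == "pDC",
                           sample(dctyper:::DC_STATES, n, replace = TRUE),
                           sample(dctyper:::DC_STATES[1:3], n,
                                  replace = TRUE)))
    tibble::tibble(
      cell_id = sprintf("cell%03d", seq_len(n)),
      type = type, state = state,
      transcriptome_cluster = sample(0:4, n, replace = TRUE),
      phenotype_cluster = sample(0:3, n, replace = TRUE),
      best_signature = sample(dctyper:::DC_TYPES, n, replace = TRUE),
      best_score = round(stats::runif(n, -1, 1), 6)
    )
  })
}
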