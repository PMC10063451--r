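make_reference <- function(seed = 1, n_genes = 60) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    types <- rep(c("A", "B", "C", "D"), each = 3)
    base <- matrix(rlnorm(n_genes * 12, 3, 0.1), n_genes, 12,
                   dimnames = list(genes, paste0(types, 1:12)))
    base[1:5, types == "A"] <- base[1:5, types == "A"] * 10       # UP in A
    base[6:10, types != "A"] <- base[6:10, types != "A"] * 10     # DN in A
    base[11:15, types %in% c("B", "C")] <-
      base[11:15, types %in% c("B", "C")] * 10                    # partial
    base[16:18, types == "B"] <- base[16:18, types == "B"] * 10   # UP in B
    dc_reference(base, types)
  })
}

test_that("bulk composite signatures require the full intersection", {
  ref <- make_reference()
  sig <- derive_composite_signature(ref, "A")
  expect_setequal(sig$up, sprintf("g%02d", 1:5))
  expect_setequal(sig$down, sprintf("g%02d", 6:10))
  # a gene higher in only 2 of 3 competitors never qualifies
  sig_b <- derive_composite_signature(ref, "B")
  expect_false(any(sprintf("g%02d", 11:15) %in% sig_b$up))

  # disjointness holds on random references
  for (s in 2:4) {
    r <- make_reference(seed = s)
    for (ty in c("A", "B", "C", "D")) {
      sg <- tryCatch(derive_composite_signature(r, ty),
                     error = function(e) NULL)
      if (!is.null(sg)) expect_length(intersect(sg$up, sg$down), 0)
    }
  }

  # single-replicate types fall back to fold-only mode with a warning
  one <- dc_reference(ref$expr[, c(1, 4, 7, 10)], c("A", "B", "C", "D"))
  expect_warning(derive_composite_signature(one, "A"), "replicates")
})

test_that("relative signatures come from DE with directional split", {
  sim <- simulate_dataset(dc_sim_config(seed = 2))
  ds <- lognormalize(sim$dataset, 1e4)
  truth_lab <- setNames(sim$truth$true_type, sim$truth$cell_id)

  sig <- derive_relative_signature(ds, truth_lab, "tDC", "cDC2")
  expect_identical(sig$name, "tDC_vs_cDC2")
  expect_true(length(sig$up) > 0 && length(sig$down) > 0)
  # the tDC-specific program lands in UP, the cDC2 program in DN
  tdc_mod <- dctyper:::sim_gene_modules(dc_sim_config())$modules$tDC
  cdc2_mod <- dctyper:::sim_gene_modules(dc_sim_config())$modules$cDC2
  expect_gte(mean(tdc_mod %in% sig$up), 0.8)
  expect_gte(mean(cdc2_mod %in% sig$down), 0.8)

  # two identical populations: empty signature with a warning
  ident <- truth_lab
  pdcs <- names(ident)[ident == "pDC"]
  ident[pdcs[1:50]] <- "Aa"; ident[pdcs[51:100]] <- "Bb"
  expect_warning(
    empty <- derive_relative_signature(ds, ident, "Aa", "Bb"),
    "empty"
  )
  expect_length(c(empty$up, empty$down), 0)

  expect_error(derive_relative_signature(ds, truth_lab[1:4], "pDC", "tDC"),
               class = "dctyper_parameter_error")
})

test_that("per-cell rankings are deterministic and storage-order invariant", {
  zero_ds <- tiny_dataset(n_genes = 8, n_cells = 3)
  zero_ds <- lognormalize(zero_ds, 1e4)
  zero_ds$norm[, 1] <- 0   # an all-zero expression profile
  ds <- lognormalize(tiny_dataset(n_genes = 8, n_cells = 3), 1e4)
  r <- rank_genes(ds)
  rz <- rank_genes(zero_ds)
  expect_identical(unname(sort(r[, 1])), 1:8)
  # all-zero cell: lexicographic gene order
  expect_identical(names(sort(rz[, 1])), sort(rownames(zero_ds$counts)))
  # unique values: rank order equals value order
  expect_identical(order(r[, 2]), order(-ds$norm[, 2], rownames(ds$norm)))

  perm <- withr::with_seed(8, sample(nrow(ds$counts)))
  ds2 <- dc_dataset(ds$counts[perm, ], ds$meta, ds$markers)
  ds2 <- lognormalize(ds2, 1e4)
  r2 <- rank_genes(ds2)
  expect_identical(r[order(rownames(r)), ], r2[order(rownames(r2)), ])
})

test_that("ks_enrichment reproduces hand-computed and closed-form cases", {
  ranks <- setNames(1:10, paste0("g", 1:10))
  expect_equal(ks_enrichment(ranks, paste0("g", 1:3)), 0.7)
  expect_equal(ks_enrichment(ranks, paste0("g", 8:10)), -0.8)
  expect_equal(ks_enrichment(ranks, "g1"), 0.9)   # 1 - 1/n
  expect_warning(es <- ks_enrichment(ranks, c("g1", "none")), "absent")
  expect_equal(es, 0.9)
  expect_error(suppressWarnings(ks_enrichment(ranks, "none")),
               class = "dctyper_parameter_error")
})

test_that("ks_enrichment equals the running-sum oracle everywhere", {
  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(5:50, 1)
      t <- sample(seq_len(min(10, n - 1)), 1)
      ranks <- setNames(sample(n), paste0("g", seq_len(n)))
      set <- sample(names(ranks), t)
    })
    expect_identical(ks_enrichment(ranks, set), ks_oracle(ranks, set))
  }
})

test_that("ks_enrichment is antisymmetric under ranking reversal", {
  # Reversal swaps the two one-sided deviations up to a 1/n grid shift
  # (a_rev = b - 1/n, b_rev = a + 1/n), so the signed score negates within
  # 1/n whenever one deviation clearly dominates; near-tied deviations can
  # keep the same sign, which is the statistic's documented asymmetry.
  n_checked <- 0
  for (s in 1:100) {
    withr::with_seed(300 + s, {
      n <- sample(10:50, 1)
      t <- sample(2:8, 1)
      ranks <- setNames(sample(n), paste0("g", seq_len(n)))
      set <- sample(names(ranks), t)
    })
    rev_ranks <- setNames(n + 1 - ranks, names(ranks))
    p <- sort(ranks[set]); j <- seq_len(t)
    a <- max(j / t - p / n); b <- max(p / n - (j - 1) / t)
    if (abs(a - b) > 2 / n) {
      expect_lte(abs(ks_enrichment(ranks, set) +
                       ks_enrichment(rev_ranks, set)), 1 / n + 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("connectivity_score combines UP/DN with the null convention", {
  ranks <- setNames(1:100, sprintf("g%03d", 1:100))
  # UP at the top, DN at the bottom: strongly positive
  sig <- dc_signature("top", up = sprintf("g%03d", 1:10),
                      down = sprintf("g%03d", 91:100))
  expect_gt(connectivity_score(ranks, sig), 0.9)
  # both sets at the top: same sign, null score
  sig0 <- dc_signature("null", up = sprintf("g%03d", 1:10),
                       down = sprintf("g%03d", 11:20))
  expect_identical(connectivity_score(ranks, sig0), 0)
  # formula on a constructed case: ES_up = 0.7, ES_down = -0.8
  r10 <- setNames(1:10, paste0("g", 1:10))
  sig2 <- dc_signature("mix", up = paste0("g", 1:3),
                       down = paste0("g", 8:10))
  expect_equal(connectivity_score(r10, sig2), 0.75)
  # up-only and down-only forms
  up_only <- dc_signature("u", up = paste0("g", 1:3))
  expect_equal(connectivity_score(r10, up_only), 0.7)
  dn_only <- dc_signature("d", down = paste0("g", 1:3))
  expect_equal(connectivity_score(r10, dn_only), -0.7)
  expect_error(connectivity_score(r10, dc_signature("x", up = "zz")),
               class = "dctyper_parameter_error")
})

test_that("random rankings score near zero on average", {
  sig <- dc_signature("s", up = sprintf("g%03d", sample(1:100, 10)),
                      down = sprintf("g%03d", sample(101:200, 10)))
  taus <- vapply(1:500, function(s) {
    ranks <- withr::with_seed(s, setNames(sample(200),
                                          sprintf("g%03d", 1:200)))
    connectivity_score(ranks, sig)
  }, numeric(1))
  expect_lt(abs(median(taus)), 0.1)
})

test_that("score_all normalizes per signature and separates types", {
  sim <- simulate_dataset(dc_sim_config(seed = 3))
  ds <- lognormalize(sim$dataset, 1e4)
  sigs <- lapply(dctyper:::DC_TYPES, function(ty) {
    derive_composite_signature(sim$reference, ty)
  })
  sc <- score_all(ds, sigs)
  mat <- as.matrix(sc[dctyper:::DC_TYPES])
  expect_true(all(mat >= -1 & mat <= 1))

  truth <- sim$truth[match(sc$cell_id, sim$truth$cell_id), ]
  for (ty in dctyper:::DC_TYPES) {
    own <- colMeans(mat[truth$true_type == ty, , drop = FALSE])
    expect_identical(names(which.max(own)), ty)
  }

  # single cell, single signature: tau collapses to {-1, 0, 1}
  one <- subset_cells(ds, colnames(ds$counts)[1])
  tau1 <- score_all(one, sigs[1])[[2]]
  expect_true(tau1 %in% c(-1, 0, 1))
})
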