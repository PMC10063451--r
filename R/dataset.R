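#' Build an index-sorted expression dataset
#'
#' The central container of the pipeline: a genes x cells UMI count matrix,
#' a per-cell metadata table, and the cells x 11 surface-marker intensity
#' matrix recorded by the index sorter.  Cells are columns and genes are rows
#' everywhere; ordering follows the count matrix.
#'
#' @param counts Non-negative integer matrix, genes in rows, cells in
#'   columns, with unique row and column names.
#' @param meta Data frame with one row per cell.  Must contain `cell_id`;
#'   `mouse_id`, `timepoint` (`NI`, `36h`, `48h`), `sort_label`, `plate` and
#'   `well` are carried along when present.
#' @param markers Numeric matrix of surface-marker intensities with one row
#'   per cell (rownames = cell ids) and the panel
#'   `r paste(DC_MARKER_PANEL, collapse = ", ")` as columns.  Cells missing
#'   from `markers` are kept but flagged `has_markers = FALSE` so QC can
#'   drop them (index-sorting data can be lost for individual wells).
#' @param norm Optional genes x cells matrix of log-normalized expression
#'   with dimensions and dimnames identical to `counts`.
#'
#' @return A `dc_dataset` object: a list with elements `counts`, `meta`
#'   (tibble, includes the logical `has_markers` column), `markers` and
#'   `norm`.
#' @export
dc_dataset <- function(counts, meta, markers = NULL, norm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene rownames and cell colnames.",
          class = "dctyper_format_error")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate gene ids in `counts`.", class = "dctyper_integrity_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate cell ids in `counts`.", class = "dctyper_integrity_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("`counts` entries must be finite non-negative integers.",
          class = "dctyper_integrity_error")
  }
  if (!is.integer(counts)) storage.mode(counts) <- "integer"
  cell_ids <- colnames(counts)

  meta <- as_tibble(meta)
  if (!"cell_id" %in% names(meta)) {
    abort("`meta` must contain a `cell_id` column.",
          class = "dctyper_format_error")
  }
  missing_meta <- setdiff(cell_ids, meta$cell_id)
  if (length(missing_meta) > 0) {
    abort(paste0("cells present in counts but absent from meta: ",
                 paste(head(missing_meta, 5), collapse = ", ")),
          class = "dctyper_integrity_error")
  }
  meta <- meta[match(cell_ids, meta$cell_id), , drop = FALSE]
  for (col in c("mouse_id", "timepoint", "sort_label", "plate", "well")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  bad_tp <- setdiff(unique(stats::na.omit(meta$timepoint)), TIMEPOINTS)
  if (length(bad_tp) > 0) {
    abort(paste0("unknown timepoint(s): ", paste(bad_tp, collapse = ", ")),
          class = "dctyper_integrity_error")
  }

  full_markers <- matrix(NA_real_, nrow = length(cell_ids),
                         ncol = length(DC_MARKER_PANEL),
                         dimnames = list(cell_ids, DC_MARKER_PANEL))
  if (!is.null(markers)) {
    markers <- as.matrix(markers)
    if (is.null(rownames(markers))) {
      abort("`markers` must have cell ids as rownames.",
            class = "dctyper_format_error")
    }
    missing_cols <- setdiff(DC_MARKER_PANEL, colnames(markers))
    if (length(missing_cols) > 0) {
      abort(paste0("markers table lacks panel column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "dctyper_format_error")
    }
    keep <- intersect(cell_ids, rownames(markers))
    full_markers[keep, ] <- markers[keep, DC_MARKER_PANEL, drop = FALSE]
  }
  meta$has_markers <- stats::complete.cases(full_markers)

  if (!is.null(norm)) {
    norm <- as.matrix(norm)
    if (!identical(dim(norm), dim(counts)) ||
        !identical(dimnames(norm), dimnames(counts))) {
      abort("`norm` must mirror the shape and dimnames of `counts`.",
            class = "dctyper_integrity_error")
    }
  }

  structure(
    list(counts = counts, meta = meta, markers = full_markers, norm = norm),
    class = "dc_dataset"
  )
}

#' @export
print.dc_dataset <- function(x, ...) {
  cat("<dc_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  cat("  markers present for ", sum(x$meta$has_markers), " cells; norm ",
      if (is.null(x$norm)) "absent" else "present", "\n", sep = "")
  tp <- table(x$meta$timepoint, useNA = "ifany")
  cat("  timepoints: ",
      paste(names(tp), as.integer(tp), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.dc_dataset <- function(x) dim(x$counts)

n_cells <- function(ds) ncol(ds$counts)
gene_ids <- function(ds) rownames(ds$counts)
cell_ids <- function(ds) colnames(ds$counts)

#' Subset a dataset to a set of cells
#'
#' @param ds A `dc_dataset`.
#' @param cells Character vector of cell ids to keep (order preserved).
#' @return A `dc_dataset` restricted to `cells`.
#' @export
subset_cells <- function(ds, cells) {
  stopifnot(inherits(ds, "dc_dataset"))
  missing <- setdiff(cells, cell_ids(ds))
  if (length(missing) > 0) {
    abort(paste0("unknown cell id(s): ", paste(head(missing, 5),
                                               collapse = ", ")),
          class = "dctyper_integrity_error")
  }
  if (length(cells) == 0) {
    abort("cell subset is empty.", class = "dctyper_empty_error")
  }
  dc_dataset(
    counts = ds$counts[, cells, drop = FALSE],
    meta = ds$meta[match(cells, ds$meta$cell_id), , drop = FALSE],
    markers = ds$markers[rownames(ds$markers) %in% cells, , drop = FALSE],
    norm = if (is.null(ds$norm)) NULL else ds$norm[, cells, drop = FALSE]
  )
}

#' A composite UP/DN gene signature
#'
#' @param name Signature name (a cell type, or a relative `A_vs_B` form).
#' @param up,down Character vectors of gene symbols; must be disjoint and
#'   not both empty.
#' @param provenance One of `"bulk_reference"`, `"single_cell"`,
#'   `"external"`.
#' @return A `dc_signature` object.
#' @export
dc_signature <- function(name, up = character(), down = character(),
                         provenance = "external") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) {
    abort(paste0("signature '", name, "' has gene(s) in both UP and DN: ",
                 paste(head(intersect(up, down), 5), collapse = ", ")),
          class = "dctyper_integrity_error")
  }
  if (length(up) + length(down) == 0) {
    abort(paste0("signature '", name, "' is empty."),
          class = "dctyper_integrity_error")
  }
  if (any(!nzchar(c(up, down)))) {
    abort("signature genes must be nonempty identifiers.",
          class = "dctyper_integrity_error")
  }
  provenance <- match.arg(provenance,
                          c("bulk_reference", "single_cell", "external"))
  structure(list(name = name, up = up, down = down,
                 provenance = provenance),
            class = "dc_signature")
}

#' @export
print.dc_signature <- function(x, ...) {
  cat("<dc_signature> ", x$name, ": ", length(x$up), " UP / ",
      length(x$down), " DN genes (", x$provenance, ")\n", sep = "")
  invisible(x)
}
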