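#' Read an index-sorted expression dataset from disk
#'
#' Loads a genes x cells UMI count matrix (Matrix Market with gene/cell TSV
#' sidecars, or a dense CSV/TSV with gene rownames and cell column headers),
#' a per-cell metadata table and a per-cell surface-marker table, and
#' assembles them into a [dc_dataset()].  Cells present in the counts but
#' missing from the marker table are kept and flagged (index-sort data can
#' be lost for individual wells); cells missing from the metadata are an
#' error.
#'
#' Delimiters are sniffed (comma vs tab) and a header line is detected, so
#' repository-style exports with slightly different dialects load without
#' configuration.
#'
#' @param counts_path Path to the `.mtx` file or the dense matrix file.
#' @param meta_path Path to the per-cell metadata table (must contain a
#'   `cell_id` column).
#' @param markers_path Path to the per-cell marker intensity table
#'   (`cell_id` column plus the 11 panel markers).  `NULL` to skip.
#' @param format `"mtx"` or `"csv"`.
#' @param genes_path,cells_path Sidecar files for `format = "mtx"`; default
#'   to `features.tsv` / `barcodes.tsv` next to the matrix.
#' @return A [dc_dataset()].
#' @export
read_expression_dataset <- function(counts_path, meta_path,
                                    markers_path = NULL,
                                    format = c("mtx", "csv"),
                                    genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  for (p in c(counts_path, meta_path, markers_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("file not found: ", p), class = "dctyper_io_error")
    }
  }
  if (format == "mtx") {
    dir <- dirname(counts_path)
    genes_path <- genes_path %||% file.path(dir, "features.tsv")
    cells_path <- cells_path %||% file.path(dir, "barcodes.tsv")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) {
        abort(paste0("MTX sidecar not found: ", p),
              class = "dctyper_io_error")
      }
    }
    m <- tryCatch(as.matrix(Matrix::readMM(counts_path)),
                  error = function(e) {
                    abort(paste0("malformed MTX file: ", conditionMessage(e)),
                          class = "dctyper_format_error")
                  })
    genes <- read_id_column(genes_path)
    cells <- read_id_column(cells_path)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort("sidecar lengths do not match matrix dimensions.",
            class = "dctyper_format_error")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- read_delim_sniffed(counts_path, row_names = 1)
    m <- as.matrix(tab)
  }
  meta <- as_tibble(read_delim_sniffed(meta_path))
  markers <- NULL
  if (!is.null(markers_path)) {
    mk <- read_delim_sniffed(markers_path)
    if (!"cell_id" %in% names(mk)) {
      abort("markers table must contain a `cell_id` column.",
            class = "dctyper_format_error")
    }
    markers <- as.matrix(mk[setdiff(names(mk), "cell_id")])
    rownames(markers) <- mk$cell_id
  }
  ds <- dc_dataset(m, meta, markers)
  n_missing <- sum(!ds$meta$has_markers)
  if (n_missing > 0) {
    inform(paste0(n_missing,
                  " cell(s) lack index-sorting data and are flagged."))
  }
  ds
}

# First column of a TSV sidecar (features.tsv / barcodes.tsv), no header.
read_id_column <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  as.character(x[[1]])
}

# Tab/comma sniffing + header detection, tolerant of deposit dialects.
read_delim_sniffed <- function(path, row_names = NULL) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    abort(paste0("empty file: ", path), class = "dctyper_format_error")
  }
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  args <- list(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
  if (!is.null(row_names)) args$row.names <- row_names
  do.call(read.delim, args)
}

#' Read composite UP/DN signatures from a GMT file
#'
#' GMT lines are `NAME<TAB>description<TAB>gene1<TAB>gene2...`.  Records are
#' paired by name: `SigA_UP` and `SigA_DN` become one signature `SigA`; a
#' name with only an `_UP` (or only `_DN`) record yields a signature with
#' the other set empty.  A gene listed in both halves of a pair is an
#' integrity error.
#'
#' @param path Path to the GMT file.
#' @param provenance Provenance tag stored on each signature.
#' @return A named list of [dc_signature()] objects.
#' @export
read_signatures_gmt <- function(path, provenance = "external") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dctyper_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("malformed GMT line: ", substr(l, 1, 60)),
            class = "dctyper_format_error")
    }
    list(name = parts[1], genes = unique(parts[-(1:2)]))
  })
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  base_names <- unique(sub("_(UP|DN)$", "", names(recs)))
  sigs <- lapply(base_names, function(nm) {
    up <- recs[[paste0(nm, "_UP")]]$genes %||% character()
    dn <- recs[[paste0(nm, "_DN")]]$genes %||% character()
    if (length(up) + length(dn) == 0) {
      # a record without the _UP/_DN convention: treat as UP-only
      up <- recs[[nm]]$genes %||% character()
    }
    dc_signature(nm, up = up, down = dn, provenance = provenance)
  })
  setNames(sigs, base_names)
}

#' Write composite signatures to a GMT file
#'
#' Inverse of [read_signatures_gmt()]: each signature becomes a `NAME_UP`
#' and (when nonempty) a `NAME_DN` record.
#'
#' @param sigs A list of [dc_signature()] objects.
#' @param path Output path.
#' @export
write_signatures_gmt <- function(sigs, path) {
  lines <- unlist(lapply(sigs, function(s) {
    out <- character()
    if (length(s$up) > 0) {
      out <- c(out, paste(c(paste0(s$name, "_UP"), s$provenance, s$up),
                          collapse = "\t"))
    }
    if (length(s$down) > 0) {
      out <- c(out, paste(c(paste0(s$name, "_DN"), s$provenance, s$down),
                          collapse = "\t"))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write consensus annotations to a TSV file
#'
#' One row per cell with a stable column order:
#' `cell_id, type, state, transcriptome_cluster, phenotype_cluster,
#' best_signature, best_score`.  [read_annotations()] round-trips the file.
#'
#' @param labels Tibble of consensus labels (as produced by the pipeline).
#' @param path Output path.
#' @export
write_annotations <- function(labels, path) {
  stopifnot(is.data.frame(labels), nrow(labels) > 0)
  cols <- c("cell_id", "type", "state", "transcriptome_cluster",
            "phenotype_cluster", "best_signature", "best_score")
  missing <- setdiff(cols, names(labels))
  if (length(missing) > 0) {
    abort(paste0("labels lack column(s): ", paste(missing, collapse = ", ")),
          class = "dctyper_format_error")
  }
  ok <- tryCatch({
    write.table(as.data.frame(labels[cols]), path, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort(paste0("cannot write annotations to ", path),
          class = "dctyper_io_error")
  }
  invisible(path)
}

#' @rdname write_annotations
#' @return `read_annotations()` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dctyper_io_error")
  }
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = c(cell_id = "character", type = "character",
                                   state = "character",
                                   best_signature = "character"))
  out <- as_tibble(tab)
  out$transcriptome_cluster <- as.integer(out$transcriptome_cluster)
  out$phenotype_cluster <- as.integer(out$phenotype_cluster)
  out$best_score <- as.numeric(out$best_score)
  out
}
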