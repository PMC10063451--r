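#' Tidy a clustering partition
#'
#' @param x A `dc_partition`.
#' @param ... Unused.
#' @return Tibble with `cell_id` and `cluster`.
#' @method tidy dc_partition
#' @export
tidy.dc_partition <- function(x, ...) {
  tibble(cell_id = names(x$membership), cluster = unname(x$membership))
}

#' @rdname tidy.dc_partition
#' @return `glance()` returns a one-row run summary.
#' @method glance dc_partition
#' @export
glance.dc_partition <- function(x, ...) {
  tibble(n_cells = length(x$membership),
         n_clusters = length(unique(x$membership)),
         modularity = x$modularity,
         k = x$params$k %||% NA_integer_,
         resolution = x$params$resolution,
         seed = x$seed)
}

#' Tidy a composite signature
#'
#' @param x A `dc_signature`.
#' @param ... Unused.
#' @return Tibble with `signature`, `gene`, `direction` (`"up"`/`"down"`).
#' @method tidy dc_signature
#' @export
tidy.dc_signature <- function(x, ...) {
  bind_rows(
    tibble(signature = x$name, gene = x$up, direction = "up"),
    tibble(signature = x$name, gene = x$down, direction = "down")
  )
}

#' Tidy a connectivity score table
#'
#' @param x A `dc_scores` tibble (wide).
#' @param ... Unused.
#' @return Long tibble with `cell_id`, `signature`, `tau`.
#' @method tidy dc_scores
#' @export
tidy.dc_scores <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), -"cell_id",
                      names_to = "signature", values_to = "tau")
}

#' Tidy a pipeline annotation
#'
#' @param x A `dc_annotation`.
#' @param ... Unused.
#' @return The per-cell annotation tibble (`cell_id`, `type`, `state`,
#'   cluster memberships, best signature and score).
#' @method tidy dc_annotation
#' @export
tidy.dc_annotation <- function(x, ...) {
  x$labels
}

#' @rdname tidy.dc_annotation
#' @return `glance()` returns a one-row summary of the run.
#' @method glance dc_annotation
#' @export
glance.dc_annotation <- function(x, ...) {
  tibble(
    n_input = nrow(x$qc_report),
    n_qc_pass = sum(x$qc_report$kept),
    n_contaminant_removed = length(x$removed_cells),
    n_retained = nrow(x$labels),
    n_annotated = sum(!is.na(x$labels$type)),
    na_fraction = mean(is.na(x$labels$type)),
    t_clusters = length(unique(x$t_partition$membership)),
    p_clusters = length(unique(x$p_partition$membership)),
    t_modularity = x$t_partition$modularity,
    p_modularity = x$p_partition$modularity
  )
}
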