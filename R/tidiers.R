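# broom-style tidiers for the pipeline's result objects.

#' Tidy a pipeline run into per-gene fold-change records
#'
#' @param x An `mf_run`.
#' @param ... Unused.
#' @return The combined fold-change tibble (one row per gene and phase).
#' @method tidy mf_run
#' @export
tidy.mf_run <- function(x, ...) x$fold_changes

#' One-row summary of a pipeline run
#'
#' @param x An `mf_run`.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, total up/down DE calls, mean
#'   concordance R across phases, seed.
#' @method glance mf_run
#' @export
glance.mf_run <- function(x, ...) {
  tibble::tibble(
    n_genes = dplyr::n_distinct(x$probes$gene_id),
    n_phases = nrow(x$summary),
    total_up = sum(x$summary$n_up),
    total_down = sum(x$summary$n_down),
    mean_concordance_r = mean(x$summary$concordance_r, na.rm = TRUE),
    seed = x$params$seed
  )
}

#' @rdname tidy.mf_run
#' @method tidy mf_de_calls
#' @export
tidy.mf_de_calls <- function(x, ...) x$records

#' @rdname glance.mf_run
#' @method glance mf_de_calls
#' @export
glance.mf_de_calls <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, strict = x$strict,
    n_up = nrow(x$up), n_down = nrow(x$down),
    n_none = nrow(x$records) - nrow(x$up) - nrow(x$down)
  )
}

#' @rdname tidy.mf_run
#' @method tidy mf_concordance
#' @export
tidy.mf_concordance <- function(x, ...) x$data

#' @rdname glance.mf_run
#' @method glance mf_concordance
#' @export
glance.mf_concordance <- function(x, ...) {
  tibble::tibble(r = x$r, n = x$n, slope = x$slope,
                 intercept = x$intercept, scale = x$scale)
}

#' @rdname tidy.mf_run
#' @method tidy mf_ref_stability
#' @export
tidy.mf_ref_stability <- function(x, ...) x$per_condition

#' @rdname glance.mf_run
#' @method glance mf_ref_stability
#' @export
glance.mf_ref_stability <- function(x, ...) {
  tibble::tibble(reference_gene = x$reference_gene, max_diff = x$max_diff,
                 tolerance = x$tolerance, pass = x$pass)
}
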