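# Over-representation testing of DE gene lists against term annotations:
# one-sided upper-tail hypergeometric p-values (Fisher) with the EASE
# variant (one observed gene removed before taking the tail), and
# Benjamini-Hochberg correction.

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` members of a size-`K` term in a
#' size-`n` DE list from a size-`N` universe, `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. `method = "ease"` substitutes `k - 1`
#' (floored at 0) for `k` before taking the tail, the conservative EASE
#' score used by DAVID.
#'
#' @param k Observed overlap count(s).
#' @param K Term size(s) within the universe.
#' @param n DE list size.
#' @param N Universe size.
#' @param method `"fisher"` or `"ease"`.
#' @return P-value(s) in (0, 1].
#' @export
hyper_enrichment_p <- function(k, K, n, N, method = c("fisher", "ease")) {
  method <- match.arg(method)
  if (any(k < 0) || any(k > pmin(K, n))) {
    abort("overlap k must satisfy 0 <= k <= min(K, n)")
  }
  k_eff <- if (method == "ease") pmax(k - 1, 0) else k
  phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation test for a DE gene list
#'
#' Tests each annotation term for over-representation in a DE gene list
#' relative to a background universe, using the upper-tail hypergeometric
#' test (equivalent to a one-sided Fisher exact test) or its EASE variant.
#' Term memberships are intersected with the background before counting;
#' terms with no background members are dropped. Results carry
#' Benjamini-Hochberg adjusted p-values and are sorted by p ascending, ties
#' broken by term id.
#'
#' @param de_genes Character vector of DE gene ids (must all be in
#'   `background`; an absent gene is a hard error, preventing a silent
#'   universe mismatch).
#' @param background Character vector: the gene universe (typically all
#'   genes with a defined expression ratio).
#' @param annotation Long-format tibble `term_id`, `term_label`, `gene_id`.
#' @param method `"fisher"` (default) or `"ease"`.
#' @return A tibble of class `mf_enrichment`: `term_id`, `term_label`, `k`
#'   (overlap), `K` (term size), `n` (DE list size), `N` (universe size),
#'   `fold_enrichment` = (k/n)/(K/N), `p_value`, `adjusted_p`.
#' @export
term_enrichment <- function(de_genes, background,
                            annotation, method = c("fisher", "ease")) {
  method <- match.arg(method)
  background <- unique(as.character(background))
  de_genes <- unique(as.character(de_genes))
  if (length(background) == 0) abort("background universe is empty")
  absent <- setdiff(de_genes, background)
  if (length(absent) > 0) {
    abort(paste0("DE gene(s) absent from the background universe: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  ann <- annotation[annotation$gene_id %in% background, ]
  ann <- dplyr::distinct(ann, .data$term_id, .data$term_label, .data$gene_id)
  if (nrow(ann) == 0) {
    return(empty_enrichment())
  }
  N <- length(background)
  n <- length(de_genes)
  per_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term_id, .data$term_label),
    K = dplyr::n(),
    k = sum(.data$gene_id %in% de_genes),
    .groups = "drop")
  res <- dplyr::mutate(per_term,
    n = n, N = N,
    fold_enrichment = ifelse(n > 0, (.data$k / n) / (.data$K / N), NA_real_),
    p_value = hyper_enrichment_p(.data$k, .data$K, n, N, method = method))
  res$adjusted_p <- adjust_pvalues(res$p_value)
  res <- dplyr::arrange(res, .data$p_value, .data$term_id)
  res <- res[, c("term_id", "term_label", "k", "K", "n", "N",
                 "fold_enrichment", "p_value", "adjusted_p")]
  class(res) <- c("mf_enrichment", class(res))
  res
}

empty_enrichment <- function() {
  res <- tibble::tibble(term_id = character(), term_label = character(),
                        k = integer(), K = integer(), n = integer(),
                        N = integer(), fold_enrichment = double(),
                        p_value = double(), adjusted_p = double())
  class(res) <- c("mf_enrichment", class(res))
  res
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method Only `"bh"` is offered.
#' @return Adjusted p-values, componentwise >= `p`.
#' @export
adjust_pvalues <- function(p, method = "bh") {
  method <- match.arg(tolower(method), "bh")
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}
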