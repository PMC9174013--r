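#' Upper tail of the hypergeometric distribution
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N, n)`.
#' Computed exactly (no normal approximation). This is the one-sided
#' over-representation p-value of Fisher's exact test.
#'
#' @param k Observed overlap (query genes carrying the annotation).
#' @param K Universe genes carrying the annotation.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The tail probability, vectorized over its arguments.
#' @examples
#' hypergeom_tail(2, 3, 3, 10)  # 22/120
#' @export
hypergeom_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(k < 0 | K < 0 | n < 0 | N < 0)) abort("counts must be nonnegative.")
  if (any(K > N) || any(n > N)) abort("K and n must not exceed N.")
  if (any(k > pmin(K, n))) abort("k must not exceed min(K, n).")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

# minimal common-length recycling for scalar-or-equal-length args
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == len) x
    else if (length(x) == 1L) rep(x, len)
    else abort("arguments must be length 1 or a common length.")
  })
}

#' Over-representation analysis of a gene list
#'
#' Tests each annotation term for enrichment of the query list via
#' [hypergeom_tail()], adjusts p-values with Benjamini-Hochberg within
#' each category, keeps terms with raw `p < alpha` (the screening rule;
#' the adjusted p is reported but not used for filtering), and reports
#' the `top_k` terms per category, ranked by ascending p with ties broken
#' by larger overlap then term id. Terms with no query overlap are
#' dropped.
#'
#' @param query Character vector of gene ids. Genes outside the universe
#'   are dropped with a warning.
#' @param collection Data frame with columns `term_id`, `term_name`,
#'   `category` (e.g. `BP`, `CC`, `MF`, `pathway`) and `gene_id`
#'   (one row per term membership).
#' @param universe Character vector of background gene ids; defaults to
#'   all genes in the collection.
#' @param alpha Raw-p screening threshold (default 0.05).
#' @param top_k Terms reported per category (default 15).
#' @return Tibble of class `cerna_enrichment` with columns `term_id`,
#'   `term_name`, `category`, `k`, `K`, `n`, `N`, `gene_ratio`, `p_value`,
#'   `adj_p`, `genes` (list of overlapping gene ids).
#' @export
enrich_terms <- function(query, collection, universe = NULL,
                         alpha = 0.05, top_k = 15L) {
  collection <- as_tibble(collection)
  need <- c("term_id", "term_name", "category", "gene_id")
  if (!all(need %in% names(collection))) {
    abort("`collection` must have columns term_id, term_name, category, gene_id.")
  }
  if (is.null(universe)) universe <- unique(collection$gene_id)
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe.")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped."))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- collection |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$category) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      genes = list(sort(intersect(unique(.data$gene_id), query))),
      .groups = "drop"
    ) |>
    mutate(k = lengths(.data$genes)) |>
    dplyr::filter(.data$k >= 1L) |>
    mutate(
      n = n, N = N,
      gene_ratio = .data$k / n,
      p_value = hypergeom_tail(.data$k, .data$K, n, N)
    ) |>
    dplyr::group_by(.data$category) |>
    mutate(adj_p = bh_adjust(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$p_value < alpha) |>
    arrange(.data$category, .data$p_value, dplyr::desc(.data$k), .data$term_id) |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup() |>
    select("term_id", "term_name", "category", "k", "K", "n", "N",
           "gene_ratio", "p_value", "adj_p", "genes")
  class(rows) <- c("cerna_enrichment", class(rows))
  rows
}

#' Dot plot of enrichment results
#'
#' @param object A [enrich_terms()] result.
#' @param ... Unused.
#' @return A ggplot: terms on the y axis ordered by p-value, gene ratio on
#'   x, point size the overlap count, colour the raw p-value, faceted by
#'   category.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(term = stats::reorder(paste0(.data$term_name), -.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$term,
                                   size = .data$k, colour = .data$p_value)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "gene ratio (k / n)", y = NULL,
                  size = "overlap", colour = "p value")
}
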