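#' Build a confidence-filtered protein-protein interaction graph
#'
#' Restricts a scored interaction table to a gene whitelist (typically the
#' mRNAs of the assembled ceRNA network), keeps edges with confidence
#' strictly above `min_confidence` (the "medium confidence" convention),
#' drops self-loops, and collapses duplicate unordered pairs keeping the
#' maximum confidence.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `confidence`
#'   (scores in \[0, 1\]).
#' @param gene_whitelist Character vector; both endpoints must belong to
#'   it. `NULL` keeps all genes.
#' @param min_confidence Strict lower bound on edge confidence
#'   (default 0.4).
#' @return Object of class `ppi_graph`: list with tibbles `edges`
#'   (`gene_a` < `gene_b` lexicographically, `confidence`) and `nodes`
#'   (`gene_id`).
#' @export
build_ppi_graph <- function(edges, gene_whitelist = NULL, min_confidence = 0.4) {
  edges <- as_tibble(edges)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% names(edges))) {
    abort("`edges` must have columns gene_a, gene_b, confidence.")
  }
  if (any(!is.finite(edges$confidence)) ||
      any(edges$confidence < 0 | edges$confidence > 1)) {
    abort("confidence scores must lie in [0, 1].")
  }
  kept <- edges |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::rename(gene_a = "a", gene_b = "b")
  if (!is.null(gene_whitelist)) {
    kept <- dplyr::filter(kept, .data$gene_a %in% gene_whitelist,
                          .data$gene_b %in% gene_whitelist)
  }
  kept <- kept |>
    dplyr::filter(.data$confidence > min_confidence) |>
    arrange(.data$gene_a, .data$gene_b)
  nodes <- tibble(gene_id = sort(unique(c(kept$gene_a, kept$gene_b))))
  structure(list(edges = kept, nodes = nodes), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("<ppi_graph> ", nrow(x$nodes), " genes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Rank hub genes by interaction degree
#'
#' Computes each gene's degree in the filtered PPI graph, keeps genes with
#' degree at least `min_degree`, and ranks by degree descending with
#' lexicographic tie-breaking.
#'
#' @param graph A [build_ppi_graph()] result.
#' @param min_degree Minimum retained degree (default 2).
#' @return Tibble with columns `gene_id`, `degree`.
#' @export
hub_genes <- function(graph, min_degree = 2L) {
  stopifnot(inherits(graph, "ppi_graph"))
  tibble(gene_id = c(graph$edges$gene_a, graph$edges$gene_b)) |>
    dplyr::count(.data$gene_id, name = "degree") |>
    dplyr::filter(.data$degree >= min_degree) |>
    arrange(dplyr::desc(.data$degree), .data$gene_id)
}

#' Restrict a ceRNA network to hub-gene triads
#'
#' Keeps the triads whose mRNA is a hub gene and prunes nodes and edges to
#' the survivors — the circRNA-miRNA-hub-gene subnetwork.
#'
#' @param network A `cerna_network`.
#' @param hubs Character vector of hub gene ids (or a [hub_genes()]
#'   tibble).
#' @return A `cerna_network` whose triads are a subset of the input's.
#' @export
hub_subnetwork <- function(network, hubs) {
  stopifnot(inherits(network, "cerna_network"))
  if (is.data.frame(hubs)) hubs <- hubs$gene_id
  new_cerna_network(dplyr::filter(network$triads, .data$mrna_id %in% hubs))
}
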