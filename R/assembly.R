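PARADIGMS <- c("up-down-up", "down-up-down")

# direction pattern (circ, mirna, mrna) per sponge paradigm
paradigm_directions <- function(paradigm) {
  switch(paradigm,
         "up-down-up" = c(circ = "up", mirna = "down", mrna = "up"),
         "down-up-down" = c(circ = "down", mirna = "up", mrna = "down"),
         abort(paste0("unknown paradigm: ", paradigm)))
}

check_direction_map <- function(x, what, normalize_mirna = FALSE) {
  x <- as_tibble(x)
  if (!all(c("feature_id", "direction") %in% names(x))) {
    abort(paste0("`", what, "` must have columns feature_id and direction."))
  }
  x <- select(x, "feature_id", "direction")
  if (normalize_mirna) x$feature_id <- normalize_mirna_id(x$feature_id)
  if (!all(x$direction %in% c("up", "down"))) {
    abort(paste0("`", what, "` may contain only up/down directions ",
                 "(drop ns features first)."))
  }
  x <- dplyr::distinct(x)
  if (anyDuplicated(x$feature_id)) {
    dup <- unique(x$feature_id[duplicated(x$feature_id)])
    abort(paste0("inconsistent directions in `", what, "` for: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  x
}

pair_edge_table <- function(pairs, what) {
  pairs <- as_tibble(pairs)
  if (!all(c("source_id", "target_id") %in% names(pairs))) {
    abort(paste0("`", what, "` must have columns source_id and target_id."))
  }
  dplyr::distinct(pairs, .data$source_id, .data$target_id)
}

#' Assemble the direction-consistent ceRNA network
#'
#' Joins the circRNA-miRNA and miRNA-mRNA pair catalogs on shared miRNAs,
#' crosschecks all three members against the supplied differential-
#' expression direction calls, and keeps exactly the triads whose
#' directions follow one of the two sponge paradigms: an upregulated
#' circRNA sequesters a downregulated miRNA, derepressing an upregulated
#' mRNA (`up-down-up`), or the mirror case (`down-up-down`). miRNA ids are
#' normalized on both the pair and direction sides before joining.
#'
#' @param circ_mirna Data frame of circRNA-to-miRNA pairs
#'   (columns `source_id`, `target_id`).
#' @param mirna_mrna Data frame of miRNA-to-mRNA pairs
#'   (columns `source_id`, `target_id`).
#' @param circ_de,mirna_de,mrna_de Direction maps: data frames with
#'   columns `feature_id` and `direction` (`up`/`down` only; features not
#'   called DE must be absent). Inconsistent duplicate entries are an
#'   error.
#' @return A `cerna_network`: list with tibbles `nodes`
#'   (`id`, `type`, `direction`), `edges` (`source`, `target`,
#'   `type_pair`) and `triads` (`circ_id`, `mirna_id`, `mrna_id`,
#'   `paradigm`), each sorted lexicographically.
#' @examples
#' net <- assemble_cerna(
#'   tibble::tibble(source_id = "circ1", target_id = "mir1"),
#'   tibble::tibble(source_id = "mir1", target_id = "geneA"),
#'   tibble::tibble(feature_id = "circ1", direction = "up"),
#'   tibble::tibble(feature_id = "mir1", direction = "down"),
#'   tibble::tibble(feature_id = "geneA", direction = "up"))
#' glance(net)
#' @export
assemble_cerna <- function(circ_mirna, mirna_mrna, circ_de, mirna_de, mrna_de) {
  cm <- pair_edge_table(circ_mirna, "circ_mirna")
  mm <- pair_edge_table(mirna_mrna, "mirna_mrna")
  cm$target_id <- normalize_mirna_id(cm$target_id)
  mm$source_id <- normalize_mirna_id(mm$source_id)
  circ_de <- check_direction_map(circ_de, "circ_de")
  mirna_de <- check_direction_map(mirna_de, "mirna_de", normalize_mirna = TRUE)
  mrna_de <- check_direction_map(mrna_de, "mrna_de")

  triads <- cm |>
    dplyr::rename(circ_id = "source_id", mirna_id = "target_id") |>
    dplyr::inner_join(
      dplyr::rename(mm, mirna_id = "source_id", mrna_id = "target_id"),
      by = "mirna_id", relationship = "many-to-many") |>
    dplyr::inner_join(dplyr::rename(circ_de, circ_id = "feature_id",
                                    circ_dir = "direction"), by = "circ_id") |>
    dplyr::inner_join(dplyr::rename(mirna_de, mirna_id = "feature_id",
                                    mirna_dir = "direction"), by = "mirna_id") |>
    dplyr::inner_join(dplyr::rename(mrna_de, mrna_id = "feature_id",
                                    mrna_dir = "direction"), by = "mrna_id") |>
    mutate(paradigm = dplyr::case_when(
      .data$circ_dir == "up" & .data$mirna_dir == "down" & .data$mrna_dir == "up" ~
        "up-down-up",
      .data$circ_dir == "down" & .data$mirna_dir == "up" & .data$mrna_dir == "down" ~
        "down-up-down",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$paradigm)) |>
    dplyr::distinct(.data$circ_id, .data$mirna_id, .data$mrna_id, .data$paradigm) |>
    arrange(.data$circ_id, .data$mirna_id, .data$mrna_id)

  new_cerna_network(triads)
}

# build the node/edge tables a triad set implies
new_cerna_network <- function(triads) {
  if (is.null(triads) || nrow(triads) == 0) {
    triads <- tibble(circ_id = character(), mirna_id = character(),
                     mrna_id = character(), paradigm = character())
  }
  # plain tibble: drop any attributes inherited from upstream catalogs
  triads <- tibble(circ_id = triads$circ_id, mirna_id = triads$mirna_id,
                   mrna_id = triads$mrna_id, paradigm = triads$paradigm)
  dirs <- purrr::map(triads$paradigm, paradigm_directions)
  nodes <- dplyr::bind_rows(
    tibble(id = triads$circ_id, type = "circRNA",
           direction = map_chr(dirs, "circ")),
    tibble(id = triads$mirna_id, type = "miRNA",
           direction = map_chr(dirs, "mirna")),
    tibble(id = triads$mrna_id, type = "mRNA",
           direction = map_chr(dirs, "mrna"))
  ) |>
    dplyr::distinct() |>
    arrange(.data$type, .data$id)
  edges <- dplyr::bind_rows(
    tibble(source = triads$circ_id, target = triads$mirna_id,
           type_pair = "circRNA-miRNA"),
    tibble(source = triads$mirna_id, target = triads$mrna_id,
           type_pair = "miRNA-mRNA")
  ) |>
    dplyr::distinct() |>
    arrange(.data$type_pair, .data$source, .data$target)
  structure(list(nodes = nodes, edges = edges,
                 triads = arrange(triads, .data$circ_id, .data$mirna_id,
                                  .data$mrna_id)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- glance(x)
  cat("<cerna_network> ", s$n_circ, " circRNA / ", s$n_mirna, " miRNA / ",
      s$n_mrna, " mRNA nodes; ", s$n_triads, " triads (",
      s$n_up_down_up, " up-down-up, ", s$n_down_up_down,
      " down-up-down)\n", sep = "")
  invisible(x)
}

#' @describeIn assemble_cerna Tidy a network into its triad tibble.
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cerna_network <- function(x, ...) x$triads

#' @describeIn assemble_cerna One-row summary: distinct node counts per
#'   molecule class, triad count, and paradigm breakdown.
#' @exportS3Method generics::glance
glance.cerna_network <- function(x, ...) {
  tibble(
    n_circ = sum(x$nodes$type == "circRNA"),
    n_mirna = sum(x$nodes$type == "miRNA"),
    n_mrna = sum(x$nodes$type == "mRNA"),
    n_edges = nrow(x$edges),
    n_triads = nrow(x$triads),
    n_up_down_up = sum(x$triads$paradigm == "up-down-up"),
    n_down_up_down = sum(x$triads$paradigm == "down-up-down")
  )
}

#' @export
summary.cerna_network <- function(object, ...) glance(object)

as_igraph_cerna <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("source", "target", "type_pair")],
    directed = TRUE,
    vertices = network$nodes[, c("id", "type", "direction")]
  )
  g
}

#' Export a ceRNA network
#'
#' Writes either GraphML (node attributes `type` and `direction`, edge
#' attribute `type_pair`) or a triad TSV (`circ_id`, `mirna_id`,
#' `mrna_id`, `paradigm`). Both formats round-trip through
#' [import_network()]: re-importing reproduces the network exactly,
#' because a direction-consistent network is fully determined by its
#' typed, direction-labelled edges.
#'
#' @param network A `cerna_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- rlang::arg_match(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph_cerna(network), path, format = "graphml")
  } else {
    readr::write_tsv(network$triads, path, progress = FALSE)
  }
  invisible(path)
}

#' Import a ceRNA network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"tsv"`.
#' @return A `cerna_network`.
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- rlang::arg_match(format)
  if (format == "tsv") {
    triads <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                              progress = FALSE)
    if (nrow(triads) > 0 && !all(triads$paradigm %in% PARADIGMS)) {
      abort("triad TSV contains unknown paradigms.")
    }
    return(new_cerna_network(triads))
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) return(new_cerna_network(NULL))
  nodes <- tibble(
    id = igraph::V(g)$name,
    type = igraph::V(g)$type,
    direction = igraph::V(g)$direction
  )
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(source = el$from, target = el$to, type_pair = el$type_pair)
  # reconstruct triads: every circ->mirna edge joined to every mirna->mrna
  # edge through the shared miRNA is a triad of the network by construction
  cm <- dplyr::filter(edges, .data$type_pair == "circRNA-miRNA")
  mm <- dplyr::filter(edges, .data$type_pair == "miRNA-mRNA")
  dir_of <- setNames(nodes$direction, nodes$id)
  triads <- cm |>
    select(circ_id = "source", mirna_id = "target") |>
    dplyr::inner_join(select(mm, mirna_id = "source", mrna_id = "target"),
                      by = "mirna_id", relationship = "many-to-many") |>
    mutate(paradigm = unname(ifelse(dir_of[.data$circ_id] == "up",
                                    "up-down-up", "down-up-down")))
  new_cerna_network(triads)
}
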