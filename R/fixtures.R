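#' Locate a packaged worked-example table
#'
#' Three small reference tables ship with the package for worked examples
#' and tests: `table1` (11 differentially expressed circRNAs of gastric
#' cancer with genomic positions and regulation direction), `table2`
#' (16 PPI hub genes with their interaction degree) and `table3` (the
#' circRNA-miRNA-hub-gene subnetwork, one row per triad, stored verbatim
#' including the source's "has-" spelling of the hsa- miRNA prefix).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return Path to the packaged TSV.
#' @export
fixture_path <- function(name = c("table1", "table2", "table3")) {
  name <- rlang::arg_match(name)
  file <- switch(name,
                 table1 = "table1_decircrnas.tsv",
                 table2 = "table2_hub_genes.tsv",
                 table3 = "table3_subnetwork.tsv")
  path <- system.file("extdata", file, package = "cernet")
  if (path == "") abort(paste0("fixture ", name, " not found."))
  path
}

#' Parse a genomic position string
#'
#' Splits `"chr12:27867712-27877119"` into chromosome and integer
#' coordinates and derives the genomic length as `end - start`, the
#' convention the packaged circRNA table follows.
#'
#' @param position Character vector of `chrN:start-end` strings.
#' @return Tibble with columns `chrom`, `start`, `end`, `genomic_length`.
#' @examples
#' parse_position("chr12:27867712-27877119")
#' @export
parse_position <- function(position) {
  m <- stringr::str_match(position, "^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(paste0("malformed position string(s): ",
                 paste(head(position[bad], 5), collapse = ", ")))
  }
  start <- as.integer(m[, 3])
  end <- as.integer(m[, 4])
  if (any(end <= start)) {
    abort(paste0("end must exceed start in: ",
                 paste(head(position[end <= start], 5), collapse = ", ")))
  }
  tibble(chrom = m[, 2], start = start, end = end,
         genomic_length = end - start)
}

#' Load the differentially expressed circRNA table
#'
#' Reads the packaged circRNA characteristics table and parses the
#' position column with [parse_position()].
#'
#' @return Tibble with one row per circRNA: `circ_id`, `chrom`, `start`,
#'   `end`, `genomic_length` (as printed), `length_check` (recomputed
#'   `end - start`), `strand`, `transcript`, `gene_symbol`, `regulation`
#'   (`up`/`down`).
#' @export
load_table1 <- function() {
  raw <- readr::read_tsv(fixture_path("table1"),
                         col_types = readr::cols(genomic_length = "i",
                                                 .default = "c"),
                         progress = FALSE)
  pos <- parse_position(raw$position)
  tibble(
    circ_id = raw$circ_id,
    chrom = pos$chrom, start = pos$start, end = pos$end,
    genomic_length = raw$genomic_length,
    length_check = pos$genomic_length,
    strand = raw$strand,
    transcript = raw$transcript,
    gene_symbol = raw$gene_symbol,
    regulation = tolower(raw$regulation)
  )
}

#' Load the hub-gene table
#'
#' @return Tibble with columns `gene_id` and `degree` (the printed
#'   interaction degree), ranked as printed.
#' @export
load_table2 <- function() {
  readr::read_tsv(fixture_path("table2"),
                  col_types = readr::cols(freq = "i", .default = "c"),
                  progress = FALSE) |>
    select(gene_id = "gene_name", degree = "freq")
}

#' Decompose the printed ceRNA subnetwork into pipeline inputs
#'
#' Reads the packaged triad table, normalizes miRNA ids (mapping the
#' "has-" typo to the canonical spelling via [normalize_mirna_id()]), and
#' decomposes it into the unique circRNA-miRNA and miRNA-mRNA edge lists
#' plus the triads in printed order — the inputs a re-assembly worked
#' example needs.
#'
#' @return List with elements `circ_mirna` (tibble `source_id`,
#'   `target_id`), `mirna_mrna` (likewise) and `triads` (tibble `circ_id`,
#'   `mirna_id`, `mrna_id`).
#' @export
load_table3 <- function() {
  raw <- readr::read_tsv(fixture_path("table3"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE) |>
    mutate(mirna_id = normalize_mirna_id(.data$mirna_id))
  list(
    circ_mirna = dplyr::distinct(raw, source_id = .data$circ_id,
                                 target_id = .data$mirna_id),
    mirna_mrna = dplyr::distinct(raw, source_id = .data$mirna_id,
                                 target_id = .data$mrna_id),
    triads = raw
  )
}
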