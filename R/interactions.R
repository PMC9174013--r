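ALLOWED_PAIR_TYPES <- list(
  c("circRNA", "miRNA"),
  c("miRNA", "mRNA")
)

#' Normalize a miRNA identifier
#'
#' Case-folds and strips the species prefix so that spelling variants of
#' the same miRNA ("hsa-miR-326", "has-miR-326", "MIR-326") match. The
#' frequent "has-" typo for "hsa-" in published tables is handled.
#'
#' @param x Character vector of miRNA ids.
#' @return Normalized ids (lower case, no species prefix).
#' @examples
#' normalize_mirna_id(c("hsa-miR-326", "has-miR-326"))
#' @export
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(x))
  stringr::str_remove(x, "^(hsa|has)-")
}

#' Merge an interaction-pair table
#'
#' Collapses rows with identical (source, target) into one pair whose
#' `databases` field is the union of the attesting databases. Only the
#' two typed edges of the sponge model are allowed: circRNA to miRNA and
#' miRNA to mRNA. miRNA ids are normalized via [normalize_mirna_id()].
#'
#' @param pairs Data frame with columns `source_id`, `target_id`,
#'   `database` (one row per attestation).
#' @param source_type,target_type Node types; one of `"circRNA"`,
#'   `"miRNA"`, `"mRNA"`.
#' @return Tibble with columns `source_id`, `target_id`, `databases`
#'   (list of character vectors), `n_databases`, sorted by source then
#'   target; carries attributes `source_type`/`target_type`.
#' @export
merge_pairs <- function(pairs, source_type, target_type) {
  check_pair_types(source_type, target_type)
  pairs <- as_tibble(pairs)
  need <- c("source_id", "target_id", "database")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` must have columns source_id, target_id, database.")
  }
  bad <- which(is.na(pairs$source_id) | pairs$source_id == "" |
               is.na(pairs$target_id) | pairs$target_id == "")
  if (length(bad)) {
    abort(paste0("malformed pair rows (missing ids) at line(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  if (source_type == "miRNA") pairs$source_id <- normalize_mirna_id(pairs$source_id)
  if (target_type == "miRNA") pairs$target_id <- normalize_mirna_id(pairs$target_id)
  out <- pairs |>
    dplyr::distinct(.data$source_id, .data$target_id, .data$database) |>
    dplyr::group_by(.data$source_id, .data$target_id) |>
    dplyr::summarise(databases = list(sort(unique(.data$database))),
                     .groups = "drop") |>
    mutate(n_databases = lengths(.data$databases)) |>
    arrange(.data$source_id, .data$target_id)
  attr(out, "source_type") <- source_type
  attr(out, "target_type") <- target_type
  out
}

check_pair_types <- function(source_type, target_type) {
  ok <- any(vapply(ALLOWED_PAIR_TYPES,
                   function(tt) identical(tt, c(source_type, target_type)),
                   logical(1)))
  if (!ok) {
    abort(paste0("disallowed pair type ", source_type, " -> ", target_type,
                 "; allowed: circRNA->miRNA, miRNA->mRNA."))
  }
  invisible(TRUE)
}

#' Read an interaction-pair TSV
#'
#' Reads a tab-separated catalog (columns `source_id`, `target_id`,
#' `database`; one row per attestation) and merges it with
#' [merge_pairs()]. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the TSV file.
#' @inheritParams merge_pairs
#' @return Merged pair tibble (see [merge_pairs()]); empty file gives an
#'   empty tibble.
#' @export
load_pairs <- function(path, source_type, target_type) {
  check_pair_types(source_type, target_type)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    out <- tibble(source_id = character(), target_id = character(),
                  databases = list(), n_databases = integer())
    attr(out, "source_type") <- source_type
    attr(out, "target_type") <- target_type
    return(out)
  }
  merge_pairs(raw, source_type, target_type)
}

#' Multi-database consensus filter
#'
#' Keeps miRNA-to-mRNA target pairs attested by at least `min_databases`
#' prediction databases. With `min_databases = 1` (the default reading of
#' combining several target databases) this is the union and the filter is
#' the identity on a merged catalog.
#'
#' @param pairs Merged pair tibble from [merge_pairs()]/[load_pairs()]
#'   with miRNA source and mRNA target.
#' @param min_databases Minimum number of attesting databases (>= 1).
#' @return Filtered pair tibble.
#' @export
consensus_filter <- function(pairs, min_databases = 1L) {
  pairs <- as_tibble(pairs)
  if (!is.numeric(min_databases) || min_databases < 1) {
    abort("`min_databases` must be an integer >= 1.")
  }
  if (!"n_databases" %in% names(pairs)) {
    abort("`pairs` must be a merged catalog with an n_databases column.")
  }
  n_known <- length(unique(unlist(pairs$databases)))
  if (nrow(pairs) > 0 && min_databases > n_known) {
    warn(paste0("min_databases (", min_databases, ") exceeds the ",
                n_known, " database(s) present; result may be empty."))
  }
  dplyr::filter(pairs, .data$n_databases >= min_databases)
}

#' Write a merged pair catalog back to attestation TSV
#'
#' Inverse of [load_pairs()]: one row per (pair, database) attestation.
#'
#' @param pairs Merged pair tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  long <- pairs |>
    select("source_id", "target_id", "databases") |>
    tidyr::unnest(cols = "databases") |>
    dplyr::rename(database = "databases")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
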