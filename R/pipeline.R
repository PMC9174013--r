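#' Pipeline parameters
#'
#' Collects the stage thresholds of the end-to-end analysis with the
#' field-standard defaults: strict |log2 fold change| > 1.5 with
#' BH-adjusted p < 0.05 for differential expression, the relaxed
#' |logFC| > 0 rule for the second circRNA dataset before intersection,
#' database union (`min_databases = 1`) for target consensus, strict
#' STRING-style confidence > 0.4 for PPI edges, hub degree >= 2, and
#' raw p < 0.05 with top-15 reporting for enrichment.
#'
#' @param lfc_circ Log2 fold-change cutoff for the first circRNA dataset.
#' @param lfc_circ_relaxed Cutoff for the second circRNA dataset (0 keeps
#'   any significant shift, the relaxed rule).
#' @param lfc_mirna,lfc_mrna Cutoffs for the miRNA and mRNA studies.
#' @param alpha Adjusted-p threshold for DE calls.
#' @param paired_circ,paired_mirna,paired_mrna Use the paired design per
#'   study (small matched circRNA cohorts are paired; large unmatched
#'   tumor collections are not).
#' @param min_databases Consensus filter for miRNA-mRNA pairs.
#' @param min_confidence PPI edge confidence cutoff (strict).
#' @param min_degree Minimum hub degree.
#' @param enrich_alpha Raw-p screening threshold for enrichment.
#' @param top_k Enriched terms reported per category.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(lfc_circ = 1.5, lfc_circ_relaxed = 0,
                            lfc_mirna = 1.5, lfc_mrna = 1.5, alpha = 0.05,
                            paired_circ = TRUE, paired_mirna = FALSE,
                            paired_mrna = FALSE,
                            min_databases = 1L, min_confidence = 0.4,
                            min_degree = 2L, enrich_alpha = 0.05,
                            top_k = 15L) {
  cfg <- as.list(environment())
  if (alpha <= 0 || alpha >= 1 || enrich_alpha <= 0 || enrich_alpha >= 1) {
    abort("alpha thresholds must be in (0, 1).")
  }
  if (min_confidence < 0 || min_confidence > 1) {
    abort("min_confidence must be in [0, 1].")
  }
  if (any(c(lfc_circ, lfc_circ_relaxed, lfc_mirna, lfc_mrna) < 0)) {
    abort("fold-change cutoffs must be >= 0.")
  }
  structure(cfg, class = "pipeline_config")
}

de_direction_map <- function(de) {
  de |>
    dplyr::filter(.data$direction %in% c("up", "down")) |>
    select("feature_id", "direction")
}

#' Run the full ceRNA inference pipeline
#'
#' Executes every stage on a study bundle (typically a [generate_study()]
#' result): differential expression per study, sign-consistent
#' intersection of the two circRNA datasets, miRNA target consensus
#' filtering, direction-consistent triad assembly, over-representation
#' analysis of the network mRNAs, PPI hub extraction restricted to
#' network mRNAs, the hub subnetwork, and ddCt quantification of the Ct
#' table. When `out_dir` is given every intermediate is written as TSV,
#' both networks as GraphML, the stage counts as `summary.json`, and a
#' timestamped `log.txt`; an identical input bundle yields an identical
#' summary.
#'
#' @param sim A `cerna_sim` bundle (or any list with the same elements).
#' @param params A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `cerna_run`: list with `de` (list of per-study
#'   DE tibbles), `circ_overlap`, `mirna_mrna_filtered`, `network`,
#'   `enrichment`, `ppi`, `hubs`, `subnetwork`, `relquant`, `summary`
#'   (named list of stage counts), `params`.
#' @export
run_cerna_pipeline <- function(sim, params = pipeline_config(),
                               out_dir = NULL) {
  stopifnot(inherits(params, "pipeline_config"))
  log_lines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    inform(paste0(...))
  }
  fail <- function(stage, e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  note("differential expression: circRNA dataset 1 (cutoff ",
       params$lfc_circ, ")")
  de_circ1 <- stage("de_circ1", de_analysis(
    sim$circ_studies[[1]], paired = params$paired_circ,
    lfc_cutoff = params$lfc_circ, alpha = params$alpha))
  note("differential expression: circRNA dataset 2 (relaxed cutoff ",
       params$lfc_circ_relaxed, ")")
  de_circ2 <- stage("de_circ2", de_analysis(
    sim$circ_studies[[2]], paired = params$paired_circ,
    lfc_cutoff = params$lfc_circ_relaxed, alpha = params$alpha))
  note("differential expression: miRNA and mRNA studies")
  de_mirna <- stage("de_mirna", de_analysis(
    sim$mirna_study, paired = params$paired_mirna,
    lfc_cutoff = params$lfc_mirna, alpha = params$alpha))
  de_mrna <- stage("de_mrna", de_analysis(
    sim$mrna_study, paired = params$paired_mrna,
    lfc_cutoff = params$lfc_mrna, alpha = params$alpha))

  note("sign-consistent intersection of circRNA datasets")
  circ_overlap <- stage("intersect", intersect_de(de_circ1, de_circ2))

  note("interaction catalogs: merge and consensus (min_databases = ",
       params$min_databases, ")")
  cm <- stage("pairs", merge_pairs(sim$circ_mirna_pairs, "circRNA", "miRNA"))
  mm <- stage("pairs", merge_pairs(sim$mirna_mrna_pairs, "miRNA", "mRNA"))
  mm_filtered <- stage("consensus", consensus_filter(mm, params$min_databases))

  note("ceRNA triad assembly")
  network <- stage("assemble", assemble_cerna(
    cm, mm_filtered,
    circ_de = circ_overlap,
    mirna_de = de_direction_map(de_mirna),
    mrna_de = de_direction_map(de_mrna)))
  network_genes <- network$nodes$id[network$nodes$type == "mRNA"]

  note("over-representation analysis of ", length(network_genes),
       " network mRNAs")
  enr <- if (length(network_genes) > 0 && !is.null(sim$annotations)) {
    stage("enrich", enrich_terms(network_genes, sim$annotations,
                                 alpha = params$enrich_alpha,
                                 top_k = params$top_k))
  } else NULL

  note("PPI graph and hub genes (confidence > ", params$min_confidence,
       ", degree >= ", params$min_degree, ")")
  ppi <- stage("ppi", build_ppi_graph(sim$ppi_edges,
                                      gene_whitelist = network_genes,
                                      min_confidence = params$min_confidence))
  hubs <- stage("hubs", hub_genes(ppi, min_degree = params$min_degree))
  subnet <- stage("subnetwork", hub_subnetwork(network, hubs))

  relquant <- if (!is.null(sim$ct_table) && nrow(sim$ct_table) > 0) {
    note("ddCt quantification of the Ct table")
    stage("qpcr", delta_delta_ct(sim$ct_table))
  } else NULL

  net_counts <- glance(network)
  sub_counts <- glance(subnet)
  summary <- list(
    n_de_circ1 = sum(de_circ1$direction != "ns"),
    n_de_circ2 = sum(de_circ2$direction != "ns"),
    n_de_mirna = sum(de_mirna$direction != "ns"),
    n_de_mrna = sum(de_mrna$direction != "ns"),
    n_circ_overlap_up = sum(circ_overlap$direction == "up"),
    n_circ_overlap_down = sum(circ_overlap$direction == "down"),
    n_circ_mirna_pairs = nrow(cm),
    n_mirna_mrna_pairs = nrow(mm_filtered),
    n_network_circ = net_counts$n_circ,
    n_network_mirna = net_counts$n_mirna,
    n_network_mrna = net_counts$n_mrna,
    n_triads = net_counts$n_triads,
    n_enriched_terms = if (is.null(enr)) 0L else nrow(enr),
    n_ppi_edges = nrow(ppi$edges),
    n_hub_genes = nrow(hubs),
    n_subnetwork_triads = sub_counts$n_triads
  )

  run <- structure(list(
    de = list(circ1 = de_circ1, circ2 = de_circ2,
              mirna = de_mirna, mrna = de_mrna),
    circ_overlap = circ_overlap,
    circ_mirna = cm, mirna_mrna_filtered = mm_filtered,
    network = network, enrichment = enr,
    ppi = ppi, hubs = hubs, subnetwork = subnet,
    relquant = relquant, summary = summary, params = params
  ), class = "cerna_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(run$de)) {
      write_de_table(run$de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
    }
    readr::write_tsv(circ_overlap, file.path(out_dir, "circ_overlap.tsv"),
                     progress = FALSE)
    write_pairs(cm, file.path(out_dir, "circ_mirna_pairs.tsv"))
    write_pairs(mm_filtered, file.path(out_dir, "mirna_mrna_pairs.tsv"))
    export_network(network, file.path(out_dir, "cerna_network.graphml"),
                   "graphml")
    export_network(network, file.path(out_dir, "cerna_triads.tsv"), "tsv")
    if (!is.null(enr)) {
      readr::write_tsv(select(as_tibble(enr), -"genes"),
                       file.path(out_dir, "enrichment.tsv"), progress = FALSE)
    }
    readr::write_tsv(ppi$edges, file.path(out_dir, "ppi_edges_filtered.tsv"),
                     progress = FALSE)
    readr::write_tsv(hubs, file.path(out_dir, "hub_genes.tsv"),
                     progress = FALSE)
    export_network(subnet, file.path(out_dir, "hub_subnetwork.graphml"),
                   "graphml")
    export_network(subnet, file.path(out_dir, "hub_subnetwork_triads.tsv"),
                   "tsv")
    if (!is.null(relquant)) {
      readr::write_tsv(relquant$summary, file.path(out_dir, "qpcr_summary.tsv"),
                       progress = FALSE)
      readr::write_tsv(relquant$per_patient,
                       file.path(out_dir, "qpcr_per_patient.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    note("outputs written to ", out_dir)
    writeLines(c(paste0("cernet ",
                        as.character(utils::packageVersion("cernet")),
                        " / R ", getRversion()),
                 paste0("params: ",
                        jsonlite::toJSON(unclass(params), auto_unbox = TRUE)),
                 log_lines),
               file.path(out_dir, "log.txt"))
  }
  run
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("<cerna_run>\n")
  for (nm in names(x$summary)) cat("  ", nm, ": ", x$summary[[nm]], "\n",
                                   sep = "")
  invisible(x)
}

#' @describeIn run_cerna_pipeline One-row tibble of the stage counts.
#' @param x A `cerna_run`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cerna_run <- function(x, ...) as_tibble(x$summary)

#' Write a differential-expression table as TSV
#'
#' Columns: `feature_id`, `logFC`, `t`, `p`, `adj_p`, `direction`.
#'
#' @param de A [de_analysis()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(
    select(de, "feature_id", logFC = "log_fc", t = "t_stat",
           p = "p_value", "adj_p", "direction"),
    path, progress = FALSE)
  invisible(path)
}

#' Read a differential-expression TSV written by [write_de_table()]
#'
#' @param path File path.
#' @return Tibble with columns `feature_id`, `log_fc`, `t_stat`,
#'   `p_value`, `adj_p`, `direction`.
#' @export
read_de_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(feature_id = "c",
                                                direction = "c",
                                                .default = "d"),
                  progress = FALSE) |>
    select("feature_id", log_fc = "logFC", t_stat = "t",
           p_value = "p", "adj_p", "direction")
}
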