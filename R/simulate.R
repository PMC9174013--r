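#' Configuration for a synthetic ceRNA study
#'
#' Defines the generative regime of [generate_study()]: paired
#' tumor/normal profiling of circRNAs in two independent datasets plus one
#' miRNA and one mRNA study, planted differential expression with known
#' directions, interaction catalogs containing direction-consistent triads
#' and direction-agnostic decoys spread over several pseudo-databases, a
#' PPI graph with a planted high-confidence hub clique, annotation sets
#' enriched for the planted genes, and a qPCR Ct table encoding the
#' planted circRNA fold changes.
#'
#' @param n_pairs_per_dataset Tumor/normal sample pairs per expression
#'   dataset (default 5, the paired-profiling regime of small circRNA
#'   cohorts).
#' @param n_circ,n_mirna,n_mrna Feature counts per molecule class.
#' @param frac_de Fraction of features planted differentially expressed
#'   per class (split evenly between up and down), in (0, 1).
#' @param effect_lfc Planted absolute log2 fold change (tumor vs normal).
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param n_true_triads Planted direction-consistent triads (alternating
#'   paradigms, disjoint feature sets).
#' @param decoy_pair_rate Expected decoy interaction pairs per source
#'   feature (direction-agnostic random pairs).
#' @param n_databases Pseudo miRNA-target databases (default 5).
#' @param db_detect_prob Probability each database independently reports a
#'   true miRNA-mRNA pair.
#' @param ppi_clique_size Size of the planted hub clique (upregulated
#'   triad mRNAs, edges at confidence 0.9).
#' @param ppi_background_edge_prob Probability of a background PPI edge
#'   between two planted DE mRNAs (confidence Uniform(0, 1)).
#' @param n_qpcr_patients Patients in the synthetic Ct table (default 52).
#' @param qpcr_noise_sd Additive normal noise per Ct measurement.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs_per_dataset = 5L,
                       n_circ = 300L, n_mirna = 200L, n_mrna = 800L,
                       frac_de = 0.1, effect_lfc = 2, noise_sd = 0.5,
                       n_true_triads = 20L, decoy_pair_rate = 2,
                       n_databases = 5L, db_detect_prob = 0.9,
                       ppi_clique_size = 6L, ppi_background_edge_prob = 0.05,
                       n_qpcr_patients = 52L, qpcr_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- list(n_pairs_per_dataset = as.integer(n_pairs_per_dataset),
              n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna), frac_de = frac_de,
              effect_lfc = effect_lfc, noise_sd = noise_sd,
              n_true_triads = as.integer(n_true_triads),
              decoy_pair_rate = decoy_pair_rate,
              n_databases = as.integer(n_databases),
              db_detect_prob = db_detect_prob,
              ppi_clique_size = as.integer(ppi_clique_size),
              ppi_background_edge_prob = ppi_background_edge_prob,
              n_qpcr_patients = as.integer(n_qpcr_patients),
              qpcr_noise_sd = qpcr_noise_sd,
              seed = as.integer(seed))
  counts <- c("n_pairs_per_dataset", "n_circ", "n_mirna", "n_mrna",
              "n_databases", "n_qpcr_patients")
  if (any(unlist(cfg[counts]) <= 0)) abort("all counts must be > 0.")
  if (cfg$n_true_triads < 0) abort("n_true_triads must be >= 0.")
  if (cfg$frac_de <= 0 || cfg$frac_de >= 1) abort("frac_de must be in (0, 1).")
  if (cfg$db_detect_prob < 0 || cfg$db_detect_prob > 1) {
    abort("db_detect_prob must be in [0, 1].")
  }
  if (cfg$effect_lfc <= 0) abort("effect_lfc must be > 0.")
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0.")
  structure(cfg, class = "sim_config")
}

sim_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

# planted DE map for one class: first half of the DE block up, rest down
plant_de <- function(ids, frac_de) {
  n_de <- max(2L, round(frac_de * length(ids)))
  n_up <- ceiling(n_de / 2)
  tibble(feature_id = ids[seq_len(n_de)],
         direction = c(rep("up", n_up), rep("down", n_de - n_up)))
}

simulate_expression <- function(ids, shifts, n_pairs, baseline, noise_sd) {
  n <- length(ids)
  pair_ids <- sprintf("pair_%02d", seq_len(n_pairs))
  pair_eff <- matrix(rnorm(n * n_pairs, 0, 0.5 * noise_sd), nrow = n)
  tumor <- baseline + shifts + pair_eff +
    matrix(rnorm(n * n_pairs, 0, noise_sd), nrow = n)
  normal <- baseline + pair_eff +
    matrix(rnorm(n * n_pairs, 0, noise_sd), nrow = n)
  colnames(tumor) <- paste0("tumor_", pair_ids)
  colnames(normal) <- paste0("normal_", pair_ids)
  expr <- dplyr::bind_cols(tibble(feature_id = ids),
                           as_tibble(tumor), as_tibble(normal))
  design <- tibble(
    sample_id = c(colnames(tumor), colnames(normal)),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(pair_ids, 2)
  )
  expression_study(expr, design)
}

decoy_pairs <- function(source_ids, target_ids, rate, databases) {
  n <- round(rate * length(source_ids))
  if (n <= 0) {
    return(tibble(source_id = character(), target_id = character(),
                  database = character()))
  }
  tibble(
    source_id = sample(source_ids, n, replace = TRUE),
    target_id = sample(target_ids, n, replace = TRUE),
    database = sample(databases, n, replace = TRUE)
  ) |> dplyr::distinct()
}

#' Generate a seeded synthetic ceRNA study with ground truth
#'
#' Draws per-feature baselines from Normal(8, 2) on the log2 scale, adds a
#' condition shift of +/- `effect_lfc` to planted DE features (sign per
#' planted direction), a per-feature-per-pair effect Normal(0,
#' 0.5 * noise_sd), and Normal(0, noise_sd) residual noise. Two circRNA
#' datasets share the planted truth but have independent noise, supporting
#' the cross-dataset intersection step. Planted triads satisfy one of the
#' two sponge paradigms by construction and use disjoint features;
#' their circRNA-miRNA edges enter the catalog deterministically while
#' each true miRNA-mRNA pair is reported by each pseudo-database
#' independently with `db_detect_prob`. Decoy pairs connect random
#' features without direction constraints. The PPI table holds the edges
#' of a clique planted on upregulated triad mRNAs at confidence 0.9 plus
#' Uniform(0, 1)-scored background edges between planted DE mRNAs. The Ct
#' table encodes the planted fold change of the first two upregulated
#' triad circRNAs via the ddCt identity with additive Ct noise.
#'
#' @param config A [sim_config()].
#' @return List of class `cerna_sim` with elements `circ_studies` (list of
#'   two [expression_study()]s), `mirna_study`, `mrna_study`,
#'   `circ_mirna_pairs` and `mirna_mrna_pairs` (attestation tables:
#'   `source_id`, `target_id`, `database`), `ppi_edges` (`gene_a`,
#'   `gene_b`, `confidence`), `annotations` (`term_id`, `term_name`,
#'   `category`, `gene_id`), `ct_table`, `truth` (list: `de_features`
#'   tibble with `feature_id`, `class`, `direction`; `true_triads` tibble
#'   with paradigm; `hub_genes` character), and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  circ_ids <- sim_ids("circ", config$n_circ)
  mir_ids <- sim_ids("mir", config$n_mirna)
  gene_ids <- sim_ids("gene", config$n_mrna)

  circ_de <- plant_de(circ_ids, config$frac_de)
  mir_de <- plant_de(mir_ids, config$frac_de)
  gene_de <- plant_de(gene_ids, config$frac_de)

  # planted triads: alternating paradigms over disjoint DE features
  n_up_triads <- ceiling(config$n_true_triads / 2)
  n_down_triads <- config$n_true_triads - n_up_triads
  pools <- list(
    circ_up = circ_de$feature_id[circ_de$direction == "up"],
    circ_down = circ_de$feature_id[circ_de$direction == "down"],
    mir_up = mir_de$feature_id[mir_de$direction == "up"],
    mir_down = mir_de$feature_id[mir_de$direction == "down"],
    gene_up = gene_de$feature_id[gene_de$direction == "up"],
    gene_down = gene_de$feature_id[gene_de$direction == "down"]
  )
  if (n_up_triads > min(length(pools$circ_up), length(pools$mir_down),
                        length(pools$gene_up)) ||
      n_down_triads > min(length(pools$circ_down), length(pools$mir_up),
                          length(pools$gene_down))) {
    abort("n_true_triads exceeds the available planted DE features.")
  }
  true_triads <- dplyr::bind_rows(
    tibble(circ_id = pools$circ_up[seq_len(n_up_triads)],
           mirna_id = pools$mir_down[seq_len(n_up_triads)],
           mrna_id = pools$gene_up[seq_len(n_up_triads)],
           paradigm = "up-down-up"),
    tibble(circ_id = pools$circ_down[seq_len(n_down_triads)],
           mirna_id = pools$mir_up[seq_len(n_down_triads)],
           mrna_id = pools$gene_down[seq_len(n_down_triads)],
           paradigm = "down-up-down")
  )

  # clique lives on upregulated mRNAs, preferring triad members so the
  # hub genes survive the network-mRNA whitelist downstream
  clique_pool <- unique(c(true_triads$mrna_id[true_triads$paradigm == "up-down-up"],
                          pools$gene_up))
  if (config$ppi_clique_size > length(clique_pool)) {
    abort("ppi_clique_size exceeds the planted upregulated mRNAs.")
  }
  hub_genes <- clique_pool[seq_len(config$ppi_clique_size)]

  shift_of <- function(ids, de) {
    s <- setNames(rep(0, length(ids)), ids)
    s[de$feature_id] <- ifelse(de$direction == "up",
                               config$effect_lfc, -config$effect_lfc)
    unname(s)
  }
  baselines <- list(circ = rnorm(config$n_circ, 8, 2),
                    mir = rnorm(config$n_mirna, 8, 2),
                    gene = rnorm(config$n_mrna, 8, 2))
  circ_studies <- purrr::map(1:2, function(i) {
    simulate_expression(circ_ids, shift_of(circ_ids, circ_de),
                        config$n_pairs_per_dataset, baselines$circ,
                        config$noise_sd)
  })
  mirna_study <- simulate_expression(mir_ids, shift_of(mir_ids, mir_de),
                                     config$n_pairs_per_dataset,
                                     baselines$mir, config$noise_sd)
  mrna_study <- simulate_expression(gene_ids, shift_of(gene_ids, gene_de),
                                    config$n_pairs_per_dataset,
                                    baselines$gene, config$noise_sd)

  dbs <- sprintf("db_%d", seq_len(config$n_databases))
  cm_true <- tibble(source_id = true_triads$circ_id,
                    target_id = true_triads$mirna_id,
                    database = "circ_catalog")
  mm_true <- tidyr::expand_grid(
    idx = seq_len(nrow(true_triads)), database = dbs) |>
    mutate(source_id = true_triads$mirna_id[.data$idx],
           target_id = true_triads$mrna_id[.data$idx]) |>
    dplyr::filter(runif(dplyr::n()) < config$db_detect_prob) |>
    select("source_id", "target_id", "database")
  circ_mirna_pairs <- dplyr::bind_rows(
    cm_true,
    decoy_pairs(circ_ids, mir_ids, config$decoy_pair_rate, "circ_catalog"))
  mirna_mrna_pairs <- dplyr::bind_rows(
    mm_true,
    decoy_pairs(mir_ids, gene_ids, config$decoy_pair_rate, dbs))

  # PPI: clique on the hub genes at 0.9, background among planted DE mRNAs
  clique_edges <- if (length(hub_genes) >= 2) {
    t(utils::combn(hub_genes, 2))
  } else {
    matrix(character(), ncol = 2)
  }
  all_de_genes <- gene_de$feature_id
  bg <- t(utils::combn(all_de_genes, 2))
  keep <- runif(nrow(bg)) < config$ppi_background_edge_prob
  ppi_edges <- dplyr::bind_rows(
    tibble(gene_a = clique_edges[, 1], gene_b = clique_edges[, 2],
           confidence = 0.9),
    tibble(gene_a = bg[keep, 1], gene_b = bg[keep, 2],
           confidence = runif(sum(keep)))
  ) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)

  annotations <- simulate_annotations(gene_ids, true_triads$mrna_id)

  qpcr_targets <- utils::head(true_triads$circ_id[
    true_triads$paradigm == "up-down-up"], 2)
  ct_table <- simulate_ct_table(
    targets = qpcr_targets,
    delta_delta_ct = rep(-config$effect_lfc, length(qpcr_targets)),
    n_patients = config$n_qpcr_patients,
    noise_sd = config$qpcr_noise_sd)

  truth <- list(
    de_features = dplyr::bind_rows(
      mutate(circ_de, class = "circRNA"),
      mutate(mir_de, class = "miRNA"),
      mutate(gene_de, class = "mRNA")) |>
      select("feature_id", "class", "direction"),
    true_triads = true_triads,
    hub_genes = hub_genes
  )
  structure(list(circ_studies = circ_studies, mirna_study = mirna_study,
                 mrna_study = mrna_study,
                 circ_mirna_pairs = circ_mirna_pairs,
                 mirna_mrna_pairs = mirna_mrna_pairs,
                 ppi_edges = ppi_edges, annotations = annotations,
                 ct_table = ct_table, truth = truth, config = config),
            class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("<cerna_sim> seed ", x$config$seed, ": ",
      x$config$n_circ, " circRNAs x2 datasets, ",
      x$config$n_mirna, " miRNAs, ", x$config$n_mrna, " mRNAs, ",
      nrow(x$truth$true_triads), " planted triads, ",
      length(x$truth$hub_genes), " hub genes\n", sep = "")
  invisible(x)
}

# annotation collection: random terms per category plus terms loaded with
# the planted network genes so enrichment has signal to find
simulate_annotations <- function(gene_ids, planted_genes,
                                 n_random_terms = 10L) {
  categories <- c("BP", "CC", "MF", "pathway")
  random_terms <- tidyr::expand_grid(category = categories,
                                     i = seq_len(n_random_terms)) |>
    pmap(function(category, i) {
      size <- sample(20:50, 1)
      tibble(term_id = sprintf("%s_rand_%02d", category, i),
             term_name = sprintf("random %s set %02d", category, i),
             category = category,
             gene_id = sample(gene_ids, size))
    }) |>
    list_rbind()
  planted_terms <- purrr::map(categories, function(cat) {
    filler <- sample(setdiff(gene_ids, planted_genes),
                     max(5L, 30L - length(planted_genes)))
    tibble(term_id = paste0(cat, "_planted"),
           term_name = paste0("planted ", cat, " set"),
           category = cat,
           gene_id = unique(c(planted_genes, filler)))
  }) |> list_rbind()
  dplyr::bind_rows(random_terms, planted_terms)
}

#' Simulate a qPCR Ct table with a planted ddCt
#'
#' Each patient contributes one tumor and one normal record per target.
#' Reference-gene Ct values sit near 15 cycles; the target's tissue dCt is
#' 8 cycles in normal tissue and `8 + delta_delta_ct` in tumor, so the
#' planted relative expression is `2^-delta_delta_ct`. Independent
#' Normal(0, noise_sd) noise is added to every Ct measurement.
#'
#' @param targets Character vector of target feature ids.
#' @param delta_delta_ct Planted ddCt per target (negative means
#'   upregulated in tumor).
#' @param n_patients Number of matched tumor/normal patients.
#' @param noise_sd Ct measurement noise SD (cycles).
#' @return Tibble with columns `patient_id`, `tissue`, `target_gene`,
#'   `ct_target`, `ct_reference` (reference gene GAPDH-like).
#' @export
simulate_ct_table <- function(targets, delta_delta_ct, n_patients = 52L,
                              noise_sd = 0.2) {
  stopifnot(length(delta_delta_ct) == length(targets))
  grid <- tidyr::expand_grid(
    target_idx = seq_along(targets),
    patient_id = sprintf("patient_%02d", seq_len(n_patients)),
    tissue = c("tumor", "normal"))
  dct_true <- ifelse(grid$tissue == "tumor",
                     8 + delta_delta_ct[grid$target_idx], 8)
  n <- nrow(grid)
  tibble(
    patient_id = grid$patient_id,
    tissue = grid$tissue,
    target_gene = targets[grid$target_idx],
    ct_target = 15 + dct_true + rnorm(n, 0, noise_sd),
    ct_reference = 15 + rnorm(n, 0, noise_sd)
  )
}

#' Write a synthetic study to a directory of TSV files
#'
#' Emits the same formats the pipeline reads: per-study expression and
#' design TSVs, interaction attestation TSVs, the PPI edge table, the
#' annotation table, the Ct table, and one ground-truth TSV
#' (`truth_de_features.tsv`, `truth_triads.tsv`, `truth_hub_genes.tsv`).
#'
#' @param sim A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name),
                                          progress = FALSE)
  for (i in 1:2) {
    w(sim$circ_studies[[i]]$expr, sprintf("circ%d_expr.tsv", i))
    w(sim$circ_studies[[i]]$design, sprintf("circ%d_design.tsv", i))
  }
  w(sim$mirna_study$expr, "mirna_expr.tsv")
  w(sim$mirna_study$design, "mirna_design.tsv")
  w(sim$mrna_study$expr, "mrna_expr.tsv")
  w(sim$mrna_study$design, "mrna_design.tsv")
  w(sim$circ_mirna_pairs, "circ_mirna_pairs.tsv")
  w(sim$mirna_mrna_pairs, "mirna_mrna_pairs.tsv")
  w(sim$ppi_edges, "ppi_edges.tsv")
  w(sim$annotations, "annotations.tsv")
  w(sim$ct_table, "ct_table.tsv")
  w(sim$truth$de_features, "truth_de_features.tsv")
  w(sim$truth$true_triads, "truth_triads.tsv")
  w(tibble(gene_id = sim$truth$hub_genes), "truth_hub_genes.tsv")
  invisible(dir)
}

#' Read an expression study from TSV files
#'
#' Counterpart of the files [write_sim()] emits: a wide expression TSV
#' (first column the feature id, one column per sample) and a design TSV
#' (`sample_id`, `condition`, optional `pair_id`).
#'
#' @param expr_path,design_path File paths.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expr_path, design_path) {
  expr <- readr::read_tsv(expr_path, col_types = readr::cols(),
                          progress = FALSE)
  design <- readr::read_tsv(design_path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  expression_study(expr, design)
}
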