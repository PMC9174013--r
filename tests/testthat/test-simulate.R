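small_cfg <- function(...) {
  args <- list(n_circ = 80, n_mirna = 60, n_mrna = 150, n_true_triads = 6,
               ppi_clique_size = 3, n_qpcr_patients = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_study(small_cfg(seed = 1))
  b <- generate_study(small_cfg(seed = 1))
  expect_equal(a[setdiff(names(a), "config")], b[setdiff(names(b), "config")])
  c <- generate_study(small_cfg(seed = 2))
  expect_false(identical(a$mrna_study$expr, c$mrna_study$expr))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_de = 0), "frac_de")
  expect_error(sim_config(effect_lfc = -1), "effect_lfc")
  expect_error(sim_config(db_detect_prob = 2), "db_detect_prob")
  expect_error(sim_config(n_circ = 0), "counts")
  # infeasible triad plans are rejected
  expect_error(generate_study(sim_config(n_circ = 20, frac_de = 0.1,
                                         n_true_triads = 50)),
               "exceeds")
})

test_that("planted triads pass the direction filter given true directions", {
  sim <- generate_study(small_cfg(seed = 3))
  truth_dir <- function(cls) sim$truth$de_features |>
    dplyr::filter(class == cls) |>
    dplyr::select(feature_id, direction)
  net <- assemble_cerna(sim$circ_mirna_pairs, sim$mirna_mrna_pairs,
                        truth_dir("circRNA"), truth_dir("miRNA"),
                        truth_dir("mRNA"))
  planted <- do.call(paste, sim$truth$true_triads)
  # a true miRNA-mRNA pair can only be absent if no database reported it
  reported <- paste(sim$truth$true_triads$mirna_id,
                    sim$truth$true_triads$mrna_id) %in%
    paste(sim$mirna_mrna_pairs$source_id, sim$mirna_mrna_pairs$target_id)
  expect_true(all(planted[reported] %in% do.call(paste, tidy(net))))
  # and every reported triad satisfies its paradigm by construction
  dirs <- sim$truth$de_features
  for (i in seq_len(nrow(net$triads))) {
    tr <- net$triads[i, ]
    expected <- if (tr$paradigm == "up-down-up") c("up", "down", "up")
                else c("down", "up", "down")
    got <- dirs$direction[match(c(tr$circ_id, tr$mirna_id, tr$mrna_id),
                                dirs$feature_id)]
    expect_equal(got, expected)
  }
})

test_that("no planted triads and no decoys yield an empty network", {
  sim <- generate_study(small_cfg(seed = 4, n_true_triads = 0,
                                  decoy_pair_rate = 0, ppi_clique_size = 3))
  truth_dir <- function(cls) sim$truth$de_features |>
    dplyr::filter(class == cls) |>
    dplyr::select(feature_id, direction)
  net <- assemble_cerna(sim$circ_mirna_pairs, sim$mirna_mrna_pairs,
                        truth_dir("circRNA"), truth_dir("miRNA"),
                        truth_dir("mRNA"))
  expect_equal(nrow(net$triads), 0)
})

test_that("marginal tumor-normal difference converges to the planted effect", {
  cfg <- sim_config(n_pairs_per_dataset = 60, n_circ = 50, n_mirna = 30,
                    n_mrna = 60, n_true_triads = 2, ppi_clique_size = 2,
                    effect_lfc = 1.5, noise_sd = 0.6, seed = 5)
  sim <- generate_study(cfg)
  study <- sim$circ_studies[[1]]
  up <- sim$truth$de_features |>
    dplyr::filter(class == "circRNA", direction == "up")
  mat <- as.matrix(study$expr[-1])
  rownames(mat) <- study$expr$feature_id
  tu <- study$design$condition == "tumor"
  diffs <- rowMeans(mat[up$feature_id, tu, drop = FALSE]) -
    rowMeans(mat[up$feature_id, !tu, drop = FALSE])
  tol <- 3 * cfg$noise_sd / sqrt(cfg$n_pairs_per_dataset)
  expect_true(all(abs(diffs - cfg$effect_lfc) < 3 * tol))
  expect_lt(abs(mean(diffs) - cfg$effect_lfc), tol)
})

test_that("hub genes are upregulated triad mRNAs with full clique degree", {
  sim <- generate_study(small_cfg(seed = 6))
  up_genes <- sim$truth$de_features |>
    dplyr::filter(class == "mRNA", direction == "up")
  expect_true(all(sim$truth$hub_genes %in% up_genes$feature_id))
  deg <- tibble::tibble(g = c(sim$ppi_edges$gene_a, sim$ppi_edges$gene_b)) |>
    dplyr::count(g)
  k <- length(sim$truth$hub_genes)
  expect_true(all(deg$n[deg$g %in% sim$truth$hub_genes] >= k - 1))
})

test_that("written studies round-trip through the TSV readers", {
  sim <- generate_study(small_cfg(seed = 7))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  st <- read_expression_study(file.path(dir, "mirna_expr.tsv"),
                              file.path(dir, "mirna_design.tsv"))
  expect_equal(st$expr, sim$mirna_study$expr, tolerance = 1e-12)
  expect_equal(st$design, sim$mirna_study$design)
  pairs <- load_pairs(file.path(dir, "circ_mirna_pairs.tsv"),
                      "circRNA", "miRNA")
  expect_equal(pairs, merge_pairs(sim$circ_mirna_pairs, "circRNA", "miRNA"),
               ignore_attr = TRUE)
})
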