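one_triad_inputs <- function(circ_dir = "up", mir_dir = "down",
                             gene_dir = "up") {
  list(
    cm = tibble::tibble(source_id = "c1", target_id = "m1"),
    mm = tibble::tibble(source_id = "m1", target_id = "g1"),
    cd = tibble::tibble(feature_id = "c1", direction = circ_dir),
    md = tibble::tibble(feature_id = "m1", direction = mir_dir),
    gd = tibble::tibble(feature_id = "g1", direction = gene_dir))
}

test_that("assembly keeps exactly the paradigm-consistent triads", {
  x <- one_triad_inputs("up", "down", "up")
  net <- assemble_cerna(x$cm, x$mm, x$cd, x$md, x$gd)
  expect_equal(nrow(net$triads), 1)
  expect_equal(net$triads$paradigm, "up-down-up")

  bad <- one_triad_inputs("up", "up", "up")
  net0 <- assemble_cerna(bad$cm, bad$mm, bad$cd, bad$md, bad$gd)
  expect_equal(nrow(net0$triads), 0)

  mirror <- one_triad_inputs("down", "up", "down")
  netm <- assemble_cerna(mirror$cm, mirror$mm, mirror$cd, mirror$md, mirror$gd)
  expect_equal(netm$triads$paradigm, "down-up-down")
})

test_that("inconsistent direction entries are an input error", {
  x <- one_triad_inputs()
  bad_md <- tibble::tibble(feature_id = c("m1", "m1"),
                           direction = c("up", "down"))
  expect_error(assemble_cerna(x$cm, x$mm, x$cd, bad_md, x$gd), "inconsistent")
  ns <- tibble::tibble(feature_id = "m1", direction = "ns")
  expect_error(assemble_cerna(x$cm, x$mm, x$cd, ns, x$gd), "up/down")
})

test_that("assembly matches the triple-loop oracle on random catalogs", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    circ <- sprintf("c%02d", 1:n)
    mir <- sprintf("m%02d", 1:n)
    gene <- sprintf("g%02d", 1:n)
    cm <- tibble::tibble(source_id = sample(circ, 4 * n, replace = TRUE),
                         target_id = sample(mir, 4 * n, replace = TRUE))
    mm <- tibble::tibble(source_id = sample(mir, 4 * n, replace = TRUE),
                         target_id = sample(gene, 4 * n, replace = TRUE))
    dirs <- function(ids) tibble::tibble(
      feature_id = sample(ids, round(length(ids) * 0.7)),
      direction = sample(c("up", "down"), round(length(ids) * 0.7),
                         replace = TRUE))
    cd <- dirs(circ); md <- dirs(mir); gd <- dirs(gene)
    net <- assemble_cerna(cm, mm, cd, md, gd)
    oracle <- assemble_brute(cm, mm, cd, md, gd) |>
      dplyr::arrange(circ_id, mirna_id, mrna_id)
    expect_equal(net$triads, oracle)
  }
})

test_that("assembly is monotone in pairs and DE features", {
  set.seed(14)
  x <- list(
    cm = tibble::tibble(source_id = c("c1", "c2"), target_id = c("m1", "m2")),
    mm = tibble::tibble(source_id = c("m1", "m2"), target_id = c("g1", "g2")),
    cd = tibble::tibble(feature_id = c("c1", "c2"), direction = c("up", "down")),
    md = tibble::tibble(feature_id = c("m1", "m2"), direction = c("down", "up")),
    gd = tibble::tibble(feature_id = c("g1", "g2"), direction = c("up", "down")))
  base <- assemble_cerna(x$cm, x$mm, x$cd, x$md, x$gd)
  # adding a pair never removes a triad
  more <- assemble_cerna(dplyr::bind_rows(x$cm, tibble::tibble(
    source_id = "c1", target_id = "m2")), x$mm, x$cd, x$md, x$gd)
  expect_true(all(do.call(paste, base$triads) %in% do.call(paste, more$triads)))
  # removing a DE feature removes exactly the triads containing it
  smaller <- assemble_cerna(x$cm, x$mm, x$cd[-1, ], x$md, x$gd)
  lost <- dplyr::anti_join(base$triads, smaller$triads,
                           by = names(base$triads))
  expect_true(all(lost$circ_id == "c1"))
  expect_false(any(smaller$triads$circ_id == "c1"))
})

test_that("duplicate triads from multi-database pairs collapse to one", {
  x <- one_triad_inputs()
  cm_dup <- dplyr::bind_rows(x$cm, x$cm)
  mm_dup <- dplyr::bind_rows(x$mm, x$mm)
  net <- assemble_cerna(cm_dup, mm_dup, x$cd, x$md, x$gd)
  expect_equal(nrow(net$triads), 1)
})

test_that("network summaries count distinct nodes and paradigms", {
  empty <- assemble_cerna(
    tibble::tibble(source_id = character(), target_id = character()),
    tibble::tibble(source_id = character(), target_id = character()),
    tibble::tibble(feature_id = character(), direction = character()),
    tibble::tibble(feature_id = character(), direction = character()),
    tibble::tibble(feature_id = character(), direction = character()))
  g <- glance(empty)
  expect_true(all(unlist(g) == 0))
  expect_equal(summary(empty), g)
})

test_that("networks round-trip through GraphML and TSV", {
  set.seed(15)
  cm <- tibble::tibble(source_id = rep(c("c1", "c2"), 3),
                       target_id = sample(c("m1", "m2", "m3"), 6, replace = TRUE))
  mm <- tibble::tibble(source_id = rep(c("m1", "m2", "m3"), 2),
                       target_id = sample(c("g1", "g2"), 6, replace = TRUE))
  net <- assemble_cerna(
    cm, mm,
    tibble::tibble(feature_id = c("c1", "c2"), direction = c("up", "down")),
    tibble::tibble(feature_id = c("m1", "m2", "m3"),
                   direction = c("down", "up", "down")),
    tibble::tibble(feature_id = c("g1", "g2"), direction = c("up", "down")))
  for (fmt in c("graphml", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, f, fmt)
    expect_network_equal(import_network(f, fmt), net)
  }
  # TSV line count = triads + header
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "tsv")
  expect_equal(length(readLines(f)), nrow(net$triads) + 1)
  # empty networks export to valid documents
  empty <- hub_subnetwork(net, character())
  for (fmt in c("graphml", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(empty, f, fmt)
    expect_equal(nrow(import_network(f, fmt)$triads), 0)
  }
  expect_error(export_network(net, "x.foo", "foo"))
})

test_that("tidy returns the triad table", {
  x <- one_triad_inputs()
  net <- assemble_cerna(x$cm, x$mm, x$cd, x$md, x$gd)
  expect_equal(tidy(net), net$triads)
})
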