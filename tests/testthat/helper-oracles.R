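# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths so that agreement is evidence, not tautology.

# BH step-up by direct min-scan over the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_tail_enum <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# triad assembly by triple loop over all combinations
assemble_brute <- function(cm, mm, circ_de, mirna_de, mrna_de) {
  cm_set <- paste(cm$source_id, cm$target_id)
  mm_set <- paste(mm$source_id, mm$target_id)
  cdir <- setNames(circ_de$direction, circ_de$feature_id)
  mdir <- setNames(mirna_de$direction, mirna_de$feature_id)
  gdir <- setNames(mrna_de$direction, mrna_de$feature_id)
  out <- list()
  for (c_id in sort(names(cdir))) {
    for (m_id in sort(names(mdir))) {
      for (g_id in sort(names(gdir))) {
        if (!paste(c_id, m_id) %in% cm_set) next
        if (!paste(m_id, g_id) %in% mm_set) next
        par <- if (cdir[c_id] == "up" && mdir[m_id] == "down" &&
                   gdir[g_id] == "up") "up-down-up"
               else if (cdir[c_id] == "down" && mdir[m_id] == "up" &&
                        gdir[g_id] == "down") "down-up-down"
               else NA_character_
        if (!is.na(par)) {
          out[[length(out) + 1]] <- tibble::tibble(
            circ_id = c_id, mirna_id = m_id, mrna_id = g_id, paradigm = par)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(circ_id = character(), mirna_id = character(),
                          mrna_id = character(), paradigm = character()))
  }
  dplyr::bind_rows(out)
}

# random small study for property tests
random_study <- function(n_features = 20, n_pairs = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("f%02d", seq_len(n_features))
  samples <- c(paste0("t", seq_len(n_pairs)), paste0("n", seq_len(n_pairs)))
  mat <- matrix(rnorm(n_features * 2 * n_pairs, 8, 1), nrow = n_features,
                dimnames = list(ids, samples))
  expr <- dplyr::bind_cols(tibble::tibble(feature_id = ids),
                           tibble::as_tibble(mat))
  design <- tibble::tibble(
    sample_id = samples,
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(paste0("p", seq_len(n_pairs)), 2))
  expression_study(expr, design)
}

expect_network_equal <- function(a, b) {
  expect_equal(a$triads, b$triads)
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$edges, b$edges)
}
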