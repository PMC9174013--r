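test_that("log2_normalize matches hand values and preserves ordering", {
  x <- tibble::tibble(feature_id = c("a", "b"), s1 = c(0, 7), s2 = c(7, 0))
  out <- log2_normalize(x, pseudocount = 1)
  expect_equal(out$s1, c(0, 3))
  expect_equal(out$s2, c(3, 0))

  set.seed(42)
  m <- matrix(rexp(60, 0.1), nrow = 10)
  lm2 <- log2_normalize(m, 1)
  for (j in seq_len(ncol(m))) {
    expect_equal(order(lm2[, j]), order(m[, j]))
  }
  expect_error(log2_normalize(matrix(c(-1, 2), 1)), "negative")
  expect_error(log2_normalize(m, pseudocount = 0), "positive")
})

test_that("variance prior: equal variances give an infinite-d0 prior", {
  pr <- fit_variance_prior(rep(2.5, 10), df = 4)
  expect_identical(pr$d0, Inf)
  expect_gt(pr$s0_sq, 0)
})

test_that("variance prior recovers planted hyperparameters from simulation", {
  # scaled inverse-chi-square truth: s^2 | sigma^2 ~ sigma^2 * chisq_df / df,
  # sigma^2 ~ d0 * s0^2 / chisq_d0 with d0 = 4, s0^2 = 1
  set.seed(7)
  d0 <- 4; s0_sq <- 1; df <- 4; n <- 10000
  sigma_sq <- d0 * s0_sq / rchisq(n, df = d0)
  s_sq <- sigma_sq * rchisq(n, df = df) / df
  pr <- fit_variance_prior(s_sq, df = df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.2)
  expect_lt(abs(pr$s0_sq - s0_sq) / s0_sq, 0.2)
})

test_that("variance prior solves the moment equation (bisection oracle)", {
  s_sq <- c(1, exp(2))
  df <- 50
  pr <- fit_variance_prior(s_sq, df = df)
  # oracle: bisection on trigamma(d0/2) = var(log s_sq) - trigamma(df/2)
  target <- var(log(s_sq)) - trigamma(df / 2)
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) - target > 0) lo <- mid else hi <- mid
  }
  expect_gt(pr$d0, 0)
  expect_lt(abs(pr$d0 - lo), 1e-3)
  expect_error(fit_variance_prior(c(2), df = 4), class = "cernet_prior_unavailable")
})

test_that("moderated t with no prior equals the classical t-test", {
  study <- random_study(n_features = 25, n_pairs = 5, seed = 3)
  mat <- as.matrix(study$expr[-1])
  for (paired in c(FALSE, TRUE)) {
    res <- moderated_t_test(study, prior = NULL, paired = paired)
    for (i in c(1, 7, 25)) {
      tt <- t.test(mat[i, study$design$condition == "tumor"],
                   mat[i, study$design$condition == "normal"],
                   paired = paired, var.equal = TRUE)
      expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
      expect_equal(res$df_total[i], unname(tt$parameter))
    }
  }
})

test_that("moderated t limit cases behave as stated", {
  study <- random_study(n_features = 10, n_pairs = 4, seed = 5)
  # d0 = Inf: every feature uses s0^2 exactly
  pr <- structure(list(d0 = Inf, s0_sq = 2), class = "variance_prior")
  res <- moderated_t_test(study, prior = pr, paired = TRUE)
  fs <- res$log_fc / (sqrt(2) * sqrt(1 / 4))
  expect_equal(res$t_stat, fs, tolerance = 1e-12)
  expect_true(all(is.infinite(res$df_total)))
  # hand example: 3 pairs, within-pair differences {1,2,3}
  expr <- tibble::tibble(feature_id = "f1",
                         t1 = 9, t2 = 10, t3 = 11, n1 = 8, n2 = 8, n3 = 8)
  design <- tibble::tibble(sample_id = c("t1", "t2", "t3", "n1", "n2", "n3"),
                           condition = rep(c("tumor", "normal"), each = 3),
                           pair_id = rep(c("p1", "p2", "p3"), 2))
  res2 <- moderated_t_test(
    expression_study(dplyr::bind_rows(expr, dplyr::mutate(expr, feature_id = "f2")),
                     design),
    prior = NULL, paired = TRUE)
  expect_equal(res2$t_stat[1], 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(res2$t_stat[1], 3.464, tolerance = 1e-3)
  expect_equal(res2$df_total[1], 2)
})

test_that("moderated t agrees with the limma reference on a random study", {
  skip_if_not_installed("limma")
  study <- random_study(n_features = 60, n_pairs = 6, seed = 9)
  mat <- as.matrix(study$expr[-1])
  rownames(mat) <- study$expr$feature_id
  fs_var <- apply(mat[, study$design$condition == "tumor"], 1, var)
  fs <- local({
    tu <- study$design$condition == "tumor"
    v1 <- apply(mat[, tu], 1, var); v2 <- apply(mat[, !tu], 1, var)
    ((sum(tu) - 1) * v1 + (sum(!tu) - 1) * v2) / (ncol(mat) - 2)
  })
  prior <- fit_variance_prior(fs, df = ncol(mat) - 2)
  res <- moderated_t_test(study, prior = prior, paired = FALSE)
  design <- cbind(1, as.integer(study$design$condition == "tumor"))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(prior$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("zero-variance features are flagged, not dropped", {
  expr <- tibble::tibble(feature_id = c("flat", "ok"),
                         t1 = c(5, 8.2), t2 = c(5, 9.1),
                         n1 = c(5, 7.4), n2 = c(5, 7.9))
  design <- tibble::tibble(sample_id = c("t1", "t2", "n1", "n2"),
                           condition = c("tumor", "tumor", "normal", "normal"))
  expect_warning(res <- moderated_t_test(expression_study(expr, design)),
                 "zero residual variance")
  expect_equal(nrow(res), 2)
  expect_true(res$zero_variance[res$feature_id == "flat"])
  expect_true(is.na(res$p_value[res$feature_id == "flat"]))
  expect_false(is.na(res$p_value[res$feature_id == "ok"]))
})

test_that("BH adjustment matches hand values and the brute-force min-scan", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(101)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("direction calls use strict thresholds and partition features", {
  de <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                       log_fc = c(2, 1.5, -2, 0.4),
                       adj_p = c(0.01, 0.01, 0.04, 0.2))
  out <- call_directions(de, lfc_cutoff = 1.5, alpha = 0.05)
  expect_equal(out$direction, c("up", "ns", "down", "ns"))
  relaxed <- call_directions(de, lfc_cutoff = 0, alpha = 0.05)
  expect_equal(relaxed$direction, c("up", "up", "down", "ns"))
  set.seed(2)
  rnd <- tibble::tibble(feature_id = sprintf("f%d", 1:100),
                        log_fc = rnorm(100, 0, 2), adj_p = runif(100))
  counts <- table(call_directions(rnd)$direction)
  expect_equal(sum(counts), 100)
})

test_that("intersection keeps sign-consistent calls only", {
  a <- tibble::tibble(feature_id = c("x", "y", "w"),
                      direction = c("up", "up", "down"))
  b <- tibble::tibble(feature_id = c("y", "z", "w"),
                      direction = c("up", "up", "up"))
  ov <- intersect_de(a, b)
  expect_equal(ov$feature_id, "y")
  expect_equal(ov$direction, "up")
  expect_false("w" %in% ov$feature_id) # conflicting signs excluded
})

test_that("planted directions are recovered on strong-effect synthetic data", {
  sim <- generate_study(sim_config(n_pairs_per_dataset = 10, frac_de = 0.2,
                                   effect_lfc = 2, noise_sd = 0.5,
                                   n_circ = 150, n_mirna = 100, n_mrna = 200,
                                   seed = 4))
  de <- de_analysis(sim$circ_studies[[1]], paired = TRUE)
  truth <- sim$truth$de_features |>
    dplyr::filter(class == "circRNA")
  joined <- dplyr::inner_join(truth, de, by = "feature_id")
  expect_gte(mean(joined$direction.x == joined$direction.y), 0.95)
  non_de <- de |> dplyr::filter(!feature_id %in% truth$feature_id)
  expect_lte(mean(non_de$direction != "ns"), 0.05 * 2)
})
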