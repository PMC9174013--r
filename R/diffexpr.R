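#' Construct an expression study
#'
#' Bundles a log2 expression table with its sample design. The expression
#' table is wide: first column `feature_id`, one further column per sample.
#' The design table has one row per sample with the condition label
#' (`tumor` or `normal`) and, for paired designs, a pair identifier linking
#' each tumor sample to its matched normal.
#'
#' @param expr Data frame; first column `feature_id` (unique strings),
#'   remaining columns numeric log2 expression, named by sample id.
#' @param design Data frame with columns `sample_id`, `condition`
#'   (values `tumor`/`normal`) and optionally `pair_id`.
#' @return An object of class `expression_study` with elements `expr`
#'   (tibble) and `design` (tibble).
#' @examples
#' expr <- tibble::tibble(feature_id = c("g1", "g2"),
#'                        s1 = c(1, 2), s2 = c(3, 4))
#' design <- tibble::tibble(sample_id = c("s1", "s2"),
#'                          condition = c("tumor", "normal"))
#' expression_study(expr, design)
#' @export
expression_study <- function(expr, design) {
  expr <- as_tibble(expr)
  design <- as_tibble(design)
  if (ncol(expr) < 3L) {
    abort("`expr` needs a feature_id column plus at least two sample columns.")
  }
  names(expr)[1] <- "feature_id"
  if (anyDuplicated(expr$feature_id)) {
    abort("duplicate feature ids in `expr`.")
  }
  sample_ids <- names(expr)[-1]
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids in `expr`.")
  if (!all(c("sample_id", "condition") %in% names(design))) {
    abort("`design` must have columns sample_id and condition.")
  }
  if (!setequal(design$sample_id, sample_ids)) {
    abort("design sample ids do not match expression columns.")
  }
  if (!all(design$condition %in% c("tumor", "normal"))) {
    abort("condition must be 'tumor' or 'normal'.")
  }
  if (any(table(design$condition)[c("tumor", "normal")] < 2L) ||
      length(unique(design$condition)) < 2L) {
    abort("need at least 2 samples per condition.")
  }
  if ("pair_id" %in% names(design) && !all(is.na(design$pair_id))) {
    bad <- design |>
      dplyr::count(.data$pair_id, .data$condition) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "n",
                         values_fill = 0L) |>
      dplyr::filter(.data$tumor != 1L | .data$normal != 1L)
    if (nrow(bad) > 0) {
      abort("each pair_id must have exactly one tumor and one normal sample.")
    }
  }
  design <- design[match(sample_ids, design$sample_id), ]
  structure(list(expr = expr, design = design), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", nrow(x$expr), " features x ",
      nrow(x$design), " samples (",
      sum(x$design$condition == "tumor"), " tumor / ",
      sum(x$design$condition == "normal"), " normal",
      if ("pair_id" %in% names(x$design)) ", paired" else "", ")\n", sep = "")
  invisible(x)
}

#' Log2-transform a raw expression table
#'
#' Applies `log2(x + pseudocount)` to every expression value. The
#' transformation is monotone, so within-sample orderings are preserved.
#'
#' @param raw Data frame with first column `feature_id` and nonnegative
#'   numeric sample columns, or a nonnegative numeric matrix.
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return Object of the same shape with transformed values.
#' @examples
#' log2_normalize(tibble::tibble(feature_id = "g1", s1 = 7, s2 = 0))
#' @export
log2_normalize <- function(raw, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a positive scalar.")
  }
  if (is.matrix(raw)) {
    if (any(raw < 0, na.rm = TRUE)) abort("negative expression values are not allowed.")
    return(log2(raw + pseudocount))
  }
  raw <- as_tibble(raw)
  vals <- raw[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("sample columns must be numeric.")
  }
  if (any(unlist(vals) < 0, na.rm = TRUE)) {
    abort("negative expression values are not allowed.")
  }
  dplyr::mutate(raw, dplyr::across(-1, ~ log2(.x + pseudocount)))
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matches a scaled inverse-chi-square prior to the observed
#' per-feature sample variances, on the log scale. With `z = log(s_sq)`,
#' the prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = var(z) - trigamma(df/2)` (monotone root-finding), and
#' the prior variance is
#' `s0_sq = exp(mean(z) - digamma(df/2) + digamma(d0/2) + log(df/d0))`.
#' When the observed spread of `z` does not exceed what sampling alone
#' explains (`var(z) <= trigamma(df/2)`), the prior is degenerate:
#' `d0 = Inf` with `s0_sq = exp(mean(z) - digamma(df/2) + log(df/2))`,
#' the continuous limit of the finite-`d0` expression.
#'
#' @param s_sq Numeric vector of per-feature sample variances (> 0;
#'   zero-variance features must be excluded by the caller).
#' @param df Residual degrees of freedom of each variance (>= 1).
#' @return Object of class `variance_prior`: list with `d0` (prior degrees
#'   of freedom, possibly `Inf`) and `s0_sq` (prior variance).
#' @export
fit_variance_prior <- function(s_sq, df) {
  s_sq <- s_sq[!is.na(s_sq)]
  if (length(s_sq) < 2L) {
    abort("need at least 2 positive variances to fit a prior.",
          class = "cernet_prior_unavailable")
  }
  if (any(s_sq <= 0)) abort("all variances must be > 0; exclude zero-variance features.")
  if (!is.numeric(df) || length(df) != 1L || df < 1) abort("`df` must be a scalar >= 1.")
  z <- log(s_sq)
  excess <- var(z) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    # trigamma(d0/2) is strictly decreasing in d0; bracket and root-find
    f <- function(d0) trigamma(d0 / 2) - excess
    lo <- 1e-6
    hi <- 1
    while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
    d0 <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    s0_sq <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) + log(df / d0))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("<variance_prior> d0 =", format(x$d0, digits = 4),
      " s0_sq =", format(x$s0_sq, digits = 4), "\n")
  invisible(x)
}

# per-feature effect and variance summaries for a two-condition study
feature_stats <- function(study, paired = FALSE) {
  mat <- as.matrix(study$expr[-1])
  rownames(mat) <- study$expr$feature_id
  design <- study$design
  if (paired) {
    if (!"pair_id" %in% names(design) || anyNA(design$pair_id)) {
      abort("paired analysis requires pair ids for every sample.")
    }
    tm <- design$sample_id[design$condition == "tumor"]
    tm <- tm[order(design$pair_id[match(tm, design$sample_id)])]
    nm <- design$sample_id[design$condition == "normal"]
    nm <- nm[order(design$pair_id[match(nm, design$sample_id)])]
    d <- mat[, tm, drop = FALSE] - mat[, nm, drop = FALSE]
    n <- length(tm)
    tibble(
      feature_id = rownames(mat),
      log_fc = unname(rowMeans(d)),
      s_sq = unname(apply(d, 1, var)),
      df = n - 1,
      se_scale = sqrt(1 / n)
    )
  } else {
    tu <- design$condition == "tumor"
    no <- design$condition == "normal"
    n1 <- sum(tu); n2 <- sum(no)
    v1 <- apply(mat[, tu, drop = FALSE], 1, var)
    v2 <- apply(mat[, no, drop = FALSE], 1, var)
    tibble(
      feature_id = rownames(mat),
      log_fc = unname(rowMeans(mat[, tu, drop = FALSE]) -
                        rowMeans(mat[, no, drop = FALSE])),
      s_sq = unname(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)),
      df = n1 + n2 - 2,
      se_scale = sqrt(1 / n1 + 1 / n2)
    )
  }
}

#' Moderated t-test for differential expression
#'
#' Tests each feature for a tumor-vs-normal shift in log2 expression using
#' a t-statistic whose variance is shrunk toward the empirical-Bayes prior:
#' `s_tilde^2 = (d0 * s0_sq + df * s^2) / (d0 + df)`, with total degrees of
#' freedom `df + d0`. With `prior = NULL` (or `d0 = 0`) this is the
#' ordinary two-sample (or paired) t-test. Features with zero residual
#' variance and no prior cannot be tested; they are retained with
#' `zero_variance = TRUE` and `NA` statistics rather than dropped.
#'
#' @param study An [expression_study()].
#' @param prior A [fit_variance_prior()] result, or `NULL` for the
#'   ordinary t-test.
#' @param paired Use within-pair differences (requires pair ids).
#' @return Tibble with one row per feature: `feature_id`, `log_fc`
#'   (log2 tumor minus normal), `t_stat`, `df_total`, `p_value`, `adj_p`
#'   (Benjamini-Hochberg), `zero_variance`.
#' @seealso [de_analysis()] for the fit-prior-then-test convenience wrapper.
#' @export
moderated_t_test <- function(study, prior = NULL, paired = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.null(prior) && !inherits(prior, "variance_prior")) {
    abort("`prior` must be NULL or a variance_prior.")
  }
  fs <- feature_stats(study, paired = paired)
  d0 <- if (is.null(prior)) 0 else prior$d0
  s0_sq <- if (is.null(prior)) 0 else prior$s0_sq
  if (is.infinite(d0)) {
    s_tilde_sq <- rep(s0_sq, nrow(fs))
    df_total <- rep(Inf, nrow(fs))
  } else {
    s_tilde_sq <- (d0 * s0_sq + fs$df * fs$s_sq) / (d0 + fs$df)
    df_total <- fs$df + d0
  }
  out <- fs |>
    mutate(
      zero_variance = s_tilde_sq <= 0,
      t_stat = ifelse(.data$zero_variance, NA_real_,
                      .data$log_fc / (sqrt(s_tilde_sq) * .data$se_scale)),
      df_total = df_total,
      p_value = 2 * pt(-abs(.data$t_stat), df = df_total)
    ) |>
    select("feature_id", "log_fc", "t_stat", "df_total", "p_value",
           "zero_variance")
  out$adj_p <- NA_real_
  ok <- !is.na(out$p_value)
  out$adj_p[ok] <- bh_adjust(out$p_value[ok])
  if (any(out$zero_variance)) {
    warn(paste0(sum(out$zero_variance),
                " feature(s) with zero residual variance and no prior; ",
                "statistics set to NA."))
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false-discovery rate: with p-values sorted ascending,
#' `adj_(i) = min_{j >= i}(p_(j) * m / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differential-expression directions
#'
#' Labels each feature `up` (log fold change strictly above the cutoff and
#' adjusted p strictly below alpha), `down` (the mirror), or `ns`.
#' Boundary values are `ns`: the inequalities are strict. A cutoff of 0
#' gives the relaxed rule (any nonzero shift with significant adjusted p).
#'
#' @param de Data frame with columns `log_fc` and `adj_p`
#'   (as produced by [moderated_t_test()]).
#' @param lfc_cutoff Nonnegative log2 fold-change cutoff (default 1.5).
#' @param alpha Adjusted-p threshold in (0, 1) (default 0.05).
#' @return The input with a `direction` column (`up`/`down`/`ns`).
#' @export
call_directions <- function(de, lfc_cutoff = 1.5, alpha = 0.05) {
  de <- as_tibble(de)
  stopifnot(all(c("log_fc", "adj_p") %in% names(de)))
  if (lfc_cutoff < 0) abort("`lfc_cutoff` must be >= 0.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  de |>
    mutate(direction = dplyr::case_when(
      !is.na(.data$adj_p) & .data$log_fc > lfc_cutoff & .data$adj_p < alpha ~ "up",
      !is.na(.data$adj_p) & .data$log_fc < -lfc_cutoff & .data$adj_p < alpha ~ "down",
      TRUE ~ "ns"
    ))
}

#' Sign-consistent intersection of two DE tables
#'
#' Keeps features called in the same direction in both studies (the Venn
#' overlap step). Features with conflicting directions are excluded from
#' both sets.
#'
#' @param a,b Data frames with columns `feature_id` and `direction`.
#' @return Tibble with columns `feature_id` and `direction` (`up`/`down`
#'   only), sorted by id; doubles as a direction map for
#'   [assemble_cerna()].
#' @export
intersect_de <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  stopifnot(all(c("feature_id", "direction") %in% names(a)),
            all(c("feature_id", "direction") %in% names(b)))
  dplyr::inner_join(
    dplyr::filter(a, .data$direction %in% c("up", "down")) |>
      select("feature_id", "direction"),
    dplyr::filter(b, .data$direction %in% c("up", "down")) |>
      select("feature_id", "direction"),
    by = c("feature_id", "direction")
  ) |>
    arrange(.data$feature_id)
}

#' Full differential-expression analysis of one study
#'
#' Convenience wrapper: computes per-feature variances, fits the
#' empirical-Bayes prior (zero-variance features excluded from the fit),
#' runs the moderated t-test, and calls directions. If the prior cannot be
#' fitted the ordinary t-test is used with a warning.
#'
#' @inheritParams moderated_t_test
#' @inheritParams call_directions
#' @param moderate Fit and use the variance prior (default `TRUE`).
#' @return Tibble as from [moderated_t_test()] plus `direction`.
#' @export
de_analysis <- function(study, paired = FALSE, lfc_cutoff = 1.5, alpha = 0.05,
                        moderate = TRUE) {
  prior <- NULL
  if (moderate) {
    fs <- feature_stats(study, paired = paired)
    prior <- tryCatch(
      fit_variance_prior(fs$s_sq[fs$s_sq > 0], df = fs$df[1]),
      cernet_prior_unavailable = function(e) {
        warn("variance prior unavailable; falling back to ordinary t.")
        NULL
      }
    )
  }
  moderated_t_test(study, prior = prior, paired = paired) |>
    call_directions(lfc_cutoff = lfc_cutoff, alpha = alpha)
}
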