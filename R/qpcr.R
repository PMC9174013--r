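#' Relative quantification by the 2^-ddCt method
#'
#' For each patient and target gene, the target Ct is normalized to the
#' reference gene within each tissue (`dCt = ct_target - ct_reference`),
#' the tumor value is contrasted with the matched normal
#' (`ddCt = dCt_tumor - dCt_normal`), and relative expression is
#' `2^-ddCt`. Technical replicates (multiple rows per patient, tissue and
#' target) are averaged on the Ct scale first. Patients missing either
#' tissue are reported and excluded. The tumor-vs-normal comparison is a
#' paired t-test on the per-patient dCt values (two-sided).
#'
#' @param records Data frame with columns `patient_id`, `tissue`
#'   (`tumor`/`normal`), `target_gene`, `ct_target`, `ct_reference`
#'   (cycle numbers > 0).
#' @return Object of class `relquant`: list with `per_patient` (tibble of
#'   `target_gene`, `patient_id`, `dct_tumor`, `dct_normal`, `ddct`,
#'   `fold_change`) and `summary` (tibble per target gene: `n`,
#'   `mean_fold_change`, `sd_fold_change`, `mean_ddct`, `t_stat`, `df`,
#'   `p_value`).
#' @examples
#' ct <- tibble::tibble(
#'   patient_id = rep(c("p1", "p2"), each = 2),
#'   tissue = rep(c("tumor", "normal"), 2),
#'   target_gene = "circX",
#'   ct_target = c(20, 24, 21, 24.5),
#'   ct_reference = c(15, 15, 15.5, 15))
#' delta_delta_ct(ct)
#' @export
delta_delta_ct <- function(records) {
  records <- as_tibble(records)
  need <- c("patient_id", "tissue", "target_gene", "ct_target", "ct_reference")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (!all(records$tissue %in% c("tumor", "normal"))) {
    abort("tissue must be 'tumor' or 'normal'.")
  }
  if (any(records$ct_target <= 0 | records$ct_reference <= 0)) {
    abort("Ct values must be positive.")
  }
  dct <- records |>
    dplyr::group_by(.data$target_gene, .data$patient_id, .data$tissue) |>
    dplyr::summarise(dct = mean(.data$ct_target) - mean(.data$ct_reference),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "dct",
                       names_prefix = "dct_")
  if (!all(c("dct_tumor", "dct_normal") %in% names(dct))) {
    abort("no complete tumor/normal pairs found.")
  }
  incomplete <- dplyr::filter(dct, is.na(.data$dct_tumor) | is.na(.data$dct_normal))
  if (nrow(incomplete) > 0) {
    warn(paste0(nrow(incomplete), " patient/target record(s) missing one ",
                "tissue excluded: ",
                paste(head(paste0(incomplete$patient_id, "/",
                                  incomplete$target_gene), 5),
                      collapse = ", ")))
  }
  per_patient <- dct |>
    dplyr::filter(!is.na(.data$dct_tumor), !is.na(.data$dct_normal)) |>
    mutate(ddct = .data$dct_tumor - .data$dct_normal,
           fold_change = 2^(-.data$ddct)) |>
    arrange(.data$target_gene, .data$patient_id)
  if (nrow(per_patient) == 0) abort("no complete tumor/normal pairs found.")
  summary <- per_patient |>
    dplyr::group_by(.data$target_gene) |>
    dplyr::group_modify(function(d, key) {
      tt <- if (nrow(d) >= 2 && sd(d$ddct) > 0) {
        paired_t(d$dct_tumor, d$dct_normal)
      } else {
        tibble(t_stat = NA_real_, df = nrow(d) - 1, p_value = NA_real_)
      }
      tibble(n = nrow(d),
             mean_fold_change = mean(d$fold_change),
             sd_fold_change = sd(d$fold_change),
             mean_ddct = mean(d$ddct),
             t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value)
    }) |>
    dplyr::ungroup()
  structure(list(per_patient = per_patient, summary = summary),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat("<relquant> 2^-ddCt quantification,",
      dplyr::n_distinct(x$per_patient$target_gene), "target gene(s),",
      dplyr::n_distinct(x$per_patient$patient_id), "patients\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn delta_delta_ct Per-patient dCt/ddCt/fold-change tibble.
#' @param x A `relquant` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.relquant <- function(x, ...) x$per_patient

#' @describeIn delta_delta_ct Per-target summary with the paired-t result.
#' @exportS3Method generics::glance
glance.relquant <- function(x, ...) x$summary

#' @describeIn delta_delta_ct Per-patient fold changes on a log2 scale
#'   with the group mean, one panel per target gene.
#' @param object A `relquant` object.
#' @exportS3Method ggplot2::autoplot
autoplot.relquant <- function(object, ...) {
  ggplot2::ggplot(object$per_patient,
                  ggplot2::aes(x = .data$target_gene, y = .data$fold_change)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)")
}

#' Paired t-test
#'
#' Two-sided paired t-test: with `d = x - y`,
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom.
#' All-zero or constant differences have no sampling variance and are an
#' error rather than a silent `NaN`.
#'
#' @param x,y Numeric vectors of equal length >= 2 (matched observations).
#' @return Tibble with columns `t_stat`, `df`, `p_value`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))  # d = {1,2,3}: t = 3.464, df = 2
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least 2 pairs.")
  d <- x - y
  if (sd(d) == 0) {
    abort("all pairwise differences are identical; t is undefined.",
          class = "cernet_degenerate_t")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}
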