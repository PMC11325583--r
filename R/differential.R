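#' Per-protein condition means
#'
#' Means of log2 LFQ values per condition, computed over observed (non-`NA`)
#' values only. Proteins with fewer than `min_obs` observations in either
#' condition are flagged unquantified and excluded from downstream testing.
#'
#' @param abundance An `abundance_tbl` (proteins x samples, log2 scale).
#' @param design Sample design table (`sample_id`, `tissue`, `condition`).
#' @param min_obs Minimum observed values per condition for a protein to
#'   count as quantified (default 2).
#' @return Tibble with columns `protein`, `mean_warm`, `mean_cold`,
#'   `n_warm`, `n_cold`, `quantified`.
#' @export
group_means <- function(abundance, design, min_obs = 2) {
  validate_design(design)
  tissue <- attr(abundance, "tissue")
  if (!is.null(tissue)) design <- dplyr::filter(design, .data$tissue == !!tissue)
  design <- dplyr::filter(design, .data$sample_id %in% names(abundance))
  n_cond <- table(factor(design$condition, levels = condition_levels))
  if (any(n_cond == 0)) {
    abort(paste0("Condition with zero samples: ",
                 paste(names(n_cond)[n_cond == 0], collapse = ", ")))
  }

  long <- abundance |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(-"protein", names_to = "sample_id", values_to = "value") |>
    dplyr::inner_join(design, by = "sample_id")

  long |>
    dplyr::group_by(.data$protein, .data$condition) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop") |>
    dplyr::mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean)) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean", "n"),
                       names_sep = "_",
                       values_fill = list(n = 0L)) |>
    dplyr::mutate(
      n_warm = .data$n_warm %||% 0L, n_cold = .data$n_cold %||% 0L,
      quantified = .data$n_warm >= min_obs & .data$n_cold >= min_obs
    ) |>
    dplyr::select("protein", "mean_warm", "mean_cold", "n_warm", "n_cold",
                  "quantified")
}

# Welch two-sample p-value with the degenerate-input conventions used for
# LFQ data: equal means are "no change" (p = 1) even when both groups are
# constant; constant groups with different means are an unambiguous change
# (p -> 0).
welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (mean(x) == mean(y)) return(1)
  if (stats::var(x) == 0 && stats::var(y) == 0) return(0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Differential abundance table (Welch test on log2 values)
#'
#' For every quantified protein, computes condition means, the log2 fold
#' change (cold minus warm), the linear fold change, a two-sided Welch
#' two-sample p-value, Benjamini-Hochberg q-values (reported for reference;
#' never used for classing), and a regulation class: `up` when
#' `p < alpha` and `log2fc > fc_cut`, `down` when `p < alpha` and
#' `log2fc < -fc_cut`, otherwise `not_significant`.
#'
#' @inheritParams group_means
#' @param alpha Raw p-value significance cutoff (default 0.05).
#' @param fc_cut log2 fold-change cutoff, applied strictly (default 0.5).
#' @return A tibble of class `tt_de`, sorted by p ascending, with columns
#'   `protein`, `mean_warm`, `mean_cold`, `n_warm`, `n_cold`, `log2fc`,
#'   `fold_change`, `p_value`, `q_value`, `reg_class`. Attributes carry the
#'   tissue label, `alpha`, `fc_cut` and the number of unquantified proteins
#'   excluded.
#' @examples
#' study <- fixture_study_small()
#' de <- differential_table(study$bat, study$design)
#' glance(de)
#' @export
differential_table <- function(abundance, design, alpha = 0.05, fc_cut = 0.5,
                               min_obs = 2) {
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  stopifnot_scalar_number(fc_cut, "fc_cut")
  gm <- group_means(abundance, design, min_obs = min_obs)
  n_excluded <- sum(!gm$quantified)
  gm <- dplyr::filter(gm, .data$quantified)

  tissue <- attr(abundance, "tissue")
  design_t <- if (is.null(tissue)) design else
    dplyr::filter(design, .data$tissue == !!tissue)
  warm_ids <- design_t$sample_id[design_t$condition == "warm"]
  cold_ids <- design_t$sample_id[design_t$condition == "cold"]
  warm_ids <- intersect(warm_ids, names(abundance))
  cold_ids <- intersect(cold_ids, names(abundance))

  ab <- tibble::as_tibble(abundance)
  rows <- match(gm$protein, ab$protein)
  wmat <- as.matrix(ab[rows, warm_ids, drop = FALSE])
  cmat <- as.matrix(ab[rows, cold_ids, drop = FALSE])
  p <- purrr::map_dbl(seq_len(nrow(gm)), function(i) {
    welch_p(wmat[i, ], cmat[i, ])
  })

  out <- gm |>
    dplyr::mutate(
      log2fc = .data$mean_cold - .data$mean_warm,
      fold_change = 2^.data$log2fc,
      p_value = p,
      q_value = p.adjust(p, method = "BH"),
      reg_class = dplyr::case_when(
        p_value < alpha & log2fc > fc_cut ~ "up",
        p_value < alpha & log2fc < -fc_cut ~ "down",
        .default = "not_significant"
      )
    ) |>
    dplyr::select(-"quantified") |>
    dplyr::arrange(.data$p_value, .data$protein)

  structure(out, class = c("tt_de", class(out)),
            tissue = tissue, alpha = alpha, fc_cut = fc_cut,
            n_excluded = n_excluded)
}

#' @export
print.tt_de <- function(x, ...) {
  cat(sprintf("# Differential abundance (%s): %d proteins tested, alpha %g, |log2FC| > %g\n",
              attr(x, "tissue") %||% "?", nrow(x), attr(x, "alpha"),
              attr(x, "fc_cut")))
  NextMethod()
}

#' @rdname differential_table
#' @param x A `tt_de` object.
#' @param ... Unused.
#' @method tidy tt_de
#' @export
tidy.tt_de <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' @rdname differential_table
#' @method glance tt_de
#' @export
glance.tt_de <- function(x, ...) {
  alpha <- attr(x, "alpha")
  tibble::tibble(
    tissue = attr(x, "tissue") %||% NA_character_,
    n_tested = nrow(x),
    n_excluded = attr(x, "n_excluded") %||% 0L,
    n_significant = sum(x$p_value < alpha),
    n_up = sum(x$reg_class == "up"),
    n_down = sum(x$reg_class == "down"),
    alpha = alpha,
    fc_cut = attr(x, "fc_cut")
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("tt_de", "tt_crosstalk", "tt_regcalls",
                                  "abundance_tbl"))
  x
}

#' Volcano-plot table
#'
#' Exports `(protein, log2fc, neg_log10_p, reg_class)` for volcano plotting;
#' p-values are floored at 1e-300 so every ordinate is finite.
#'
#' @param de A `tt_de` differential table.
#' @return A tibble with one row per tested protein.
#' @export
volcano_table <- function(de) {
  if (nrow(de) == 0) abort("Differential table is empty.")
  tibble::tibble(
    protein = de$protein,
    log2fc = de$log2fc,
    neg_log10_p = -log10(pmax(de$p_value, 1e-300)),
    reg_class = de$reg_class
  )
}

#' Relative expression by the 2^-ddCT method
#'
#' Classic qPCR relative quantification: fold change of a target gene in a
#' test sample relative to a control sample, each normalized to a reference
#' gene, computed as `2^-((ct_target_test - ct_ref_test) -
#' (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl PCR cycle
#'   threshold (CT) values; vectors recycle in the usual way.
#' @return Fold change (dimensionless).
#' @examples
#' ddct_relative_expression(25, 20, 27, 20) # 4
#' @export
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- list(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(purrr::map_lgl(cts, function(v) all(is.finite(v))))) {
    abort("All CT values must be finite.")
  }
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
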