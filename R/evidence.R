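#' Human genetic evidence (HuGE) tier of a score
#'
#' Maps a HuGE score — a summary of common- and rare-variant genetic support
#' for a gene-phenotype link — to its evidence tier by natural-log
#' thresholds, all inclusive: `moderate` at `ln(score) >= 1.09` (i.e. score
#' about 3), `strong` at `>= 2.30`, `extreme` at `>= 4.60`, `compelling` at
#' `>= 5.86`; anything lower is `below_moderate`.
#'
#' @param huge_score Positive HuGE score(s).
#' @return Character vector of tier labels.
#' @examples
#' tier_of(c(1, 3, 12, 400))
#' @export
tier_of <- function(huge_score) {
  if (any(!is.finite(huge_score)) || any(huge_score <= 0)) {
    abort("HuGE scores must be positive finite numbers.")
  }
  lh <- log(huge_score)
  dplyr::case_when(
    lh >= 5.86 ~ "compelling",
    lh >= 4.60 ~ "extreme",
    lh >= 2.30 ~ "strong",
    lh >= 1.09 ~ "moderate",
    .default = "below_moderate"
  )
}

#' Evidence table filtered to at least moderate genetic support
#'
#' @param records Data frame with columns `gene`, `phenotype`, `huge_score`.
#' @return Tibble `(gene, phenotype, huge_score, log_huge, tier)` with rows
#'   below the moderate tier dropped, sorted by `log_huge` descending.
#' @export
tier_table <- function(records) {
  req <- c("gene", "phenotype", "huge_score")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    abort(paste0("Evidence table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(gene = character(), phenotype = character(),
                          huge_score = double(), log_huge = double(),
                          tier = character()))
  }
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(gene = norm_symbol(.data$gene),
                  log_huge = log(.data$huge_score),
                  tier = tier_of(.data$huge_score)) |>
    dplyr::filter(.data$tier != "below_moderate") |>
    dplyr::arrange(dplyr::desc(.data$log_huge)) |>
    dplyr::select("gene", "phenotype", "huge_score", "log_huge", "tier")
}
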