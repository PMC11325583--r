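#' Regularized product ligand-receptor score
#'
#' Bounded score combining a ligand's and a receptor's mean log2 abundance,
#' `sqrt(l * r) / (mu + sqrt(l * r))`. It is 0 when either abundance is 0,
#' strictly increasing in the product `l * r`, strictly decreasing in the
#' regularization constant `mu`, and approaches 1 for abundances far above
#' `mu`.
#'
#' @param l,r Mean log2 LFQ abundances (non-negative); vectors recycle.
#' @param mu Regularization constant, positive, on the same log2 scale.
#' @return Score(s) in `[0, 1)`.
#' @examples
#' lr_score(10, 10, mu = 10) # 0.5
#' @export
lr_score <- function(l, r, mu) {
  stopifnot_scalar_number(mu, "mu", positive = TRUE)
  if (any(l < 0, na.rm = TRUE) || any(r < 0, na.rm = TRUE)) {
    abort("Abundances must be non-negative (log2 LFQ values are >= 0 here).")
  }
  g <- sqrt(l * r)
  g / (mu + g)
}

#' Regularization constant from the data
#'
#' Default `mu` for [lr_score()]: the mean of all per-protein overall mean
#' abundances, pooled across the supplied matrices. Exposed so the pooling
#' choice (per tissue, pooled, or fixed) stays configurable.
#'
#' @param ... One or more `abundance_tbl` objects.
#' @return A single positive number.
#' @export
auto_mu <- function(...) {
  mats <- list(...)
  per_protein <- purrr::map(mats, function(m) {
    ab <- tibble::as_tibble(m)
    rowMeans(as.matrix(ab[, setdiff(names(ab), "protein")]), na.rm = TRUE)
  })
  mu <- mean(unlist(per_protein), na.rm = TRUE)
  stopifnot_scalar_number(mu, "mu", positive = TRUE)
  mu
}

#' Pair candidate ligands with receptors and score crosstalk
#'
#' Matches secreted, induced ligands of the sending tissue (BAT) against
#' receptors quantified in the receiving tissue (liver) through one or more
#' ligand-receptor databases, and scores each pair per condition with the
#' regularized product score. Reported per pair:
#'
#' * `fold_change` — the ligand's linear fold change in the sending tissue;
#' * `n_lrdb` — number of databases documenting the pair;
#' * `lr_warm`, `lr_cold` — [lr_score()] of (ligand mean in BAT, receptor
#'   mean in liver) per condition;
#' * `delta_lr` — `lr_cold - lr_warm`;
#' * `delta_sum` — change in the summed mean log2 levels,
#'   `(l_cold + r_cold) - (l_warm + r_warm)`.
#'
#' Receptors not quantified in the receiving tissue are dropped (a zero mean
#' would be indistinguishable from missingness on the log2 scale); ligands
#' with no database partner are silently absent.
#'
#' @param ligands Character vector of candidate ligand symbols (typically
#'   from [secreted_induced_ligands()]).
#' @param bat_de,liver_de `tt_de` differential tables for the sending and
#'   receiving tissue.
#' @param lr_dbs Ligand-receptor database tibble from [load_lr_databases()]
#'   (columns `db`, `ligand`, `receptor`).
#' @param mu Regularization constant; `"auto"` requires `mu_value` computed
#'   beforehand via [auto_mu()] and passed as a number.
#' @return A tibble of class `tt_crosstalk`, sorted by `delta_lr`
#'   descending, ties by `delta_sum` descending then ligand/receptor
#'   alphabetically, with a `selected` column initialized to `FALSE`.
#' @export
pair_and_score <- function(ligands, bat_de, liver_de, lr_dbs, mu) {
  stopifnot_scalar_number(mu, "mu", positive = TRUE)
  ligands <- norm_symbol(ligands)

  pairs <- lr_dbs |>
    dplyr::filter(.data$ligand %in% ligands) |>
    dplyr::count(.data$ligand, .data$receptor, name = "n_lrdb")

  dropped <- setdiff(ligands, pairs$ligand)
  if (length(dropped) > 0) {
    inform(paste0("Ligand(s) without database partner: ",
                  paste(dropped, collapse = ", ")))
  }

  lig_tbl <- tibble::tibble(ligand = bat_de$protein,
                            l_warm = bat_de$mean_warm,
                            l_cold = bat_de$mean_cold,
                            fold_change = bat_de$fold_change)
  rec_tbl <- tibble::tibble(receptor = liver_de$protein,
                            r_warm = liver_de$mean_warm,
                            r_cold = liver_de$mean_cold)

  scored <- pairs |>
    dplyr::inner_join(lig_tbl, by = "ligand") |>
    dplyr::inner_join(rec_tbl, by = "receptor") |>
    dplyr::mutate(
      lr_warm = lr_score(.data$l_warm, .data$r_warm, mu),
      lr_cold = lr_score(.data$l_cold, .data$r_cold, mu),
      delta_lr = .data$lr_cold - .data$lr_warm,
      delta_sum = (.data$l_cold + .data$r_cold) -
        (.data$l_warm + .data$r_warm),
      selected = FALSE
    ) |>
    dplyr::arrange(dplyr::desc(.data$delta_lr), dplyr::desc(.data$delta_sum),
                   .data$ligand, .data$receptor) |>
    dplyr::select("ligand", "receptor", "fold_change", "n_lrdb",
                  "lr_warm", "lr_cold", "delta_lr", "delta_sum", "selected")

  structure(scored, class = c("tt_crosstalk", class(scored)), mu = mu)
}

#' Select crosstalk candidates by the published thresholds
#'
#' Flags pairs whose ligand shows a fold change strictly above `fc_min` in
#' the sending tissue and whose pair shows `delta_sum` strictly above
#' `dsum_min`, with `delta_lr` at least `dlr_min` when compared at 3
#' decimals (so a pair printed as 0.020 passes the 0.02 gate).
#'
#' @param scores Crosstalk score table: output of [pair_and_score()] or any
#'   data frame with columns `fold_change`, `delta_lr`, `delta_sum`.
#' @param fc_min Minimum ligand fold change, strict (default 2).
#' @param dsum_min Minimum `delta_sum`, strict (default 2).
#' @param dlr_min Minimum `delta_lr`, compared at 3 decimals (default 0.02).
#' @param keep_all Return all rows with the `selected` flag set
#'   (`TRUE`), or only the selected rows in rank order (default).
#' @return The selected rows (or all flagged rows) as a tibble.
#' @examples
#' select_candidates(lr_reference_scores())
#' @export
select_candidates <- function(scores, fc_min = 2.0, dsum_min = 2.0,
                              dlr_min = 0.02, keep_all = FALSE) {
  req <- c("fold_change", "delta_lr", "delta_sum")
  miss <- setdiff(req, names(scores))
  if (length(miss) > 0) {
    abort(paste0("Score table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  flagged <- scores |>
    dplyr::mutate(selected = .data$fold_change > fc_min &
                    .data$delta_sum > dsum_min &
                    round(.data$delta_lr, 3) >= dlr_min)
  if (keep_all) flagged else dplyr::filter(flagged, .data$selected)
}

#' @export
print.tt_crosstalk <- function(x, ...) {
  cat(sprintf("# Crosstalk scores: %d ligand-receptor pairs (mu = %.4g)\n",
              nrow(x), attr(x, "mu")))
  NextMethod()
}

#' @rdname pair_and_score
#' @param x A `tt_crosstalk` object.
#' @param ... Unused.
#' @method tidy tt_crosstalk
#' @export
tidy.tt_crosstalk <- function(x, ...) tibble::as_tibble(unclass_keep_tbl(x))

#' @rdname pair_and_score
#' @method glance tt_crosstalk
#' @export
glance.tt_crosstalk <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_ligands = dplyr::n_distinct(x$ligand),
    n_selected = sum(x$selected),
    mu = attr(x, "mu")
  )
}
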