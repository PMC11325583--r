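#' Activation z-score for one upstream regulator
#'
#' Predicts whether a transcription factor or miRNA is activated or
#' inhibited from the signed behavior of its known targets among the
#' dysregulated proteins. For each prior target that is significant in the
#' differential table (`p < alpha`), the agreement is
#' `a = effect_sign * sign(log2fc)`; the activation z-score is
#' `z = sum(a) / sqrt(n)` over the `n` overlapping targets (the
#' equal-weight form of the activation z-score). States: `activated` when
#' `z >= 2`, `inhibited` when `z <= -2`, otherwise `undetermined`.
#' Regulators with fewer than `min_overlap` overlapping targets are reported
#' `undetermined` with `z = NA`.
#'
#' Overlap enrichment (`p_overlap`) is a one-tailed hypergeometric test of
#' the regulator's prior targets among the significant proteins, with the
#' quantified proteins of the differential table as the universe.
#'
#' @param prior Regulator prior table (`regulator`, `kind`, `target`,
#'   `sign`, optional `cluster`); see [read_regulator_prior()].
#' @param de A `tt_de` differential table.
#' @param regulator Regulator symbol to score (must appear in `prior`).
#' @param alpha Significance cutoff defining dysregulated targets
#'   (default 0.05).
#' @param min_overlap Minimum overlapping targets for a determinate call
#'   (default 3).
#' @return One-row tibble: `regulator`, `kind`, `z`, `p_overlap`,
#'   `n_overlap`, `state`.
#' @export
activation_z <- function(prior, de, regulator, alpha = 0.05, min_overlap = 3) {
  prior <- validate_prior(prior)
  rows <- dplyr::filter(prior, .data$regulator == !!regulator)
  if (nrow(rows) == 0) {
    abort(sprintf("Regulator '%s' is not in the prior table.", regulator))
  }

  universe <- de$protein
  sig <- de$protein[de$p_value < alpha]
  targets_in_universe <- intersect(rows$target, universe)

  hits <- rows |>
    dplyr::inner_join(
      tibble::tibble(target = de$protein, log2fc = de$log2fc,
                     p_value = de$p_value),
      by = "target") |>
    dplyr::filter(.data$p_value < alpha)

  n <- nrow(hits)
  p_overlap <- phyper(n - 1, length(sig), length(universe) - length(sig),
                      length(targets_in_universe), lower.tail = FALSE)

  if (n < min_overlap) {
    z <- NA_real_
    state <- "undetermined"
  } else {
    a <- hits$sign * sign(hits$log2fc)
    z <- sum(a) / sqrt(n)
    state <- if (z >= 2) "activated" else if (z <= -2) "inhibited"
             else "undetermined"
  }
  tibble::tibble(regulator = regulator,
                 kind = rows$kind[1],
                 z = z, p_overlap = p_overlap, n_overlap = n, state = state)
}

#' Score every regulator in a prior table
#'
#' Applies [activation_z()] to each regulator and returns the calls in a
#' deterministic order (z descending, `NA` last, regulator symbol
#' ascending).
#'
#' @inheritParams activation_z
#' @return A tibble of class `tt_regcalls` with one row per regulator.
#' @examples
#' study <- fixture_study_small()
#' de <- differential_table(study$bat, study$design)
#' call_all_regulators(study$prior, de)
#' @export
call_all_regulators <- function(prior, de, alpha = 0.05, min_overlap = 3) {
  prior <- validate_prior(prior)
  regs <- unique(prior$regulator)
  calls <- purrr::map(regs, activation_z, prior = prior, de = de,
                      alpha = alpha, min_overlap = min_overlap) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$z), .data$regulator)
  structure(calls, class = c("tt_regcalls", class(calls)),
            alpha = alpha, min_overlap = min_overlap)
}

#' @rdname call_all_regulators
#' @param x A `tt_regcalls` object.
#' @param ... Unused.
#' @method tidy tt_regcalls
#' @export
tidy.tt_regcalls <- function(x, ...) tibble::as_tibble(unclass_keep_tbl(x))

#' @rdname call_all_regulators
#' @method glance tt_regcalls
#' @export
glance.tt_regcalls <- function(x, ...) {
  tibble::tibble(
    n_regulators = nrow(x),
    n_activated = sum(x$state == "activated"),
    n_inhibited = sum(x$state == "inhibited"),
    n_undetermined = sum(x$state == "undetermined"),
    alpha = attr(x, "alpha"),
    min_overlap = attr(x, "min_overlap")
  )
}

#' Build the regulator-target network
#'
#' Directed bipartite graph of the regulators with a determinate activation
#' call (`|z| >= 2`) and their significant targets: one signed edge per
#' prior (regulator, target) pair whose regulator qualifies and whose target
#' is significant in the differential table. Regulators whose targets are
#' all non-significant end up with no incident edge and are excluded.
#'
#' @param calls Regulator calls ([call_all_regulators()]), possibly
#'   pre-filtered; only rows with state `activated`/`inhibited` are used.
#' @param prior Regulator prior table.
#' @param de A `tt_de` differential table.
#' @param alpha Significance cutoff for targets (default 0.05).
#' @return An `igraph` graph; vertices carry `kind` (`TF`, `miRNA` or
#'   `target`) and regulators also `state`; edges carry `sign`.
#' @export
build_network <- function(calls, prior, de, alpha = 0.05) {
  prior <- validate_prior(prior)
  qual <- dplyr::filter(calls, .data$state %in% c("activated", "inhibited"))
  sig <- de$protein[de$p_value < alpha]
  edges <- prior |>
    dplyr::filter(.data$regulator %in% qual$regulator,
                  .data$target %in% sig)
  if (nrow(edges) == 0) {
    warn("No qualifying regulator-target edges; returning an empty network.")
    return(igraph::make_empty_graph(directed = TRUE))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target", "sign")], directed = TRUE)
  kind <- ifelse(igraph::V(g)$name %in% edges$regulator,
                 edges$kind[match(igraph::V(g)$name, edges$regulator)],
                 "target")
  igraph::V(g)$kind <- ifelse(is.na(kind), "regulator", kind)
  igraph::V(g)$state <- qual$state[match(igraph::V(g)$name, qual$regulator)]
  g
}

#' Hub report: top-degree network nodes
#'
#' @param net An `igraph` network from [build_network()].
#' @param top_k Number of nodes to report (default 10).
#' @return Tibble `(node, kind, degree)`, degree descending, ties broken
#'   alphabetically.
#' @export
hub_report <- function(net, top_k = 10) {
  if (igraph::vcount(net) == 0) {
    return(tibble::tibble(node = character(), kind = character(),
                          degree = integer()))
  }
  tibble::tibble(
    node = igraph::V(net)$name,
    kind = igraph::V(net)$kind %||% NA_character_,
    degree = as.integer(igraph::degree(net, mode = "all"))
  ) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node) |>
    dplyr::slice_head(n = top_k)
}

#' Co-called regulator clusters (polycistrons)
#'
#' Groups regulators that share a cluster annotation (e.g. a polycistronic
#' miRNA cluster, co-transcribed as one unit) *and* the same determinate
#' activation state. Only groups of two or more are reported; cluster
#' membership is an input annotation, not an inference.
#'
#' @param calls Regulator calls ([call_all_regulators()]).
#' @param prior Regulator prior table carrying a `cluster` column.
#' @return Tibble `(cluster, state, n, regulators)` with `regulators` a
#'   comma-joined, sorted symbol list; empty when no cluster annotations.
#' @export
cluster_groups <- function(calls, prior) {
  prior <- validate_prior(prior)
  membership <- prior |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::distinct(.data$regulator, .data$cluster)
  if (nrow(membership) == 0) {
    return(tibble::tibble(cluster = character(), state = character(),
                          n = integer(), regulators = character()))
  }
  calls |>
    dplyr::filter(.data$state %in% c("activated", "inhibited")) |>
    dplyr::inner_join(membership, by = "regulator",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$cluster, .data$state) |>
    dplyr::summarise(n = dplyr::n(),
                     regulators = paste(sort(.data$regulator), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::arrange(.data$cluster, .data$state)
}

#' Export a regulator-target network
#'
#' @param net An `igraph` network from [build_network()].
#' @param path Output path; format by extension: `.graphml` (GraphML via
#'   igraph) or `.sif` (simple interaction format, one
#'   `regulator <sign> target` line per edge).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else if (ext == "sif") {
    if (igraph::ecount(net) == 0) {
      writeLines(character(), path)
    } else {
      el <- igraph::as_edgelist(net)
      sign <- igraph::E(net)$sign
      writeLines(paste(el[, 1],
                       ifelse(sign >= 0, "activates", "represses"),
                       el[, 2], sep = "\t"), path)
    }
  } else {
    abort("Unsupported network format; use .graphml or .sif.")
  }
  invisible(path)
}
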