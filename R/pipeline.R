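#' Run the full crosstalk analysis chain and write its artifacts
#'
#' Orchestrates every stage on a study bundle (as produced by
#' [simulate_study()], or assembled from files with the `read_*` helpers):
#' differential tables for both tissues, secretion calls, crosstalk scores
#' and selected candidates, regulator calls, the regulator-target network
#' (GraphML and SIF), optional evidence tiers, and a JSON manifest with an
#' MD5 content hash per artifact. Stage outputs are pure functions of the
#' inputs and configuration, so a rerun produces bit-identical files.
#'
#' @param study A list with elements `bat`, `liver` (`abundance_tbl`),
#'   `design`, `annotations`, `lr_dbs`, and optionally `prior` and
#'   `huge_scores` (a `(gene, phenotype, huge_score)` table).
#' @param out_dir Output directory (created if needed).
#' @param alpha,fc_cut Differential-stage thresholds (defaults 0.05, 0.5).
#' @param fc_min,dsum_min,dlr_min Crosstalk selection thresholds (defaults
#'   2, 2, 0.02).
#' @param mu `"auto"` (regularization constant from [auto_mu()] over both
#'   matrices) or a fixed positive number.
#' @param min_overlap Minimum overlap for regulator calls (default 3).
#' @param top_k Hub report size (default 10).
#' @return Invisibly, a tibble manifest `(artifact, file, md5)`; also
#'   written as `manifest.json`.
#' @examples
#' \donttest{
#' study <- fixture_study_small()
#' manifest <- run_pipeline(study, tempfile("run"))
#' }
#' @export
run_pipeline <- function(study, out_dir,
                         alpha = 0.05, fc_cut = 0.5,
                         fc_min = 2.0, dsum_min = 2.0, dlr_min = 0.02,
                         mu = "auto", min_overlap = 3, top_k = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  emit <- function(name, file, writer) {
    path <- file.path(out_dir, file)
    writer(path)
    artifacts[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  de_bat <- stage("differential", {
    differential_table(study$bat, study$design, alpha = alpha,
                       fc_cut = fc_cut)
  })
  de_liver <- stage("differential", {
    differential_table(study$liver, study$design, alpha = alpha,
                       fc_cut = fc_cut)
  })
  emit("de_bat", "de_bat.tsv", function(p) write_num_tsv(tidy(de_bat), p))
  emit("de_liver", "de_liver.tsv", function(p) write_num_tsv(tidy(de_liver), p))

  calls <- stage("secretome", call_secretion(study$annotations))
  emit("secretion_calls", "secretion_calls.tsv",
       function(p) write_num_tsv(calls, p))
  ligands <- stage("secretome", secreted_induced_ligands(de_bat, calls))

  scores <- stage("crosstalk", {
    if (!all(c("db", "ligand", "receptor") %in% names(study$lr_dbs))) {
      abort("lr_dbs must have columns db, ligand, receptor.")
    }
    mu_val <- if (identical(mu, "auto")) auto_mu(study$bat, study$liver)
              else mu
    pair_and_score(ligands, de_bat, de_liver, study$lr_dbs, mu = mu_val)
  })
  flagged <- stage("crosstalk", {
    select_candidates(scores, fc_min = fc_min, dsum_min = dsum_min,
                      dlr_min = dlr_min, keep_all = TRUE)
  })
  emit("crosstalk_scores", "crosstalk_scores.tsv",
       function(p) write_num_tsv(tibble::as_tibble(flagged), p))
  emit("crosstalk_selected", "crosstalk_selected.tsv", function(p) {
    write_num_tsv(dplyr::filter(tibble::as_tibble(flagged), .data$selected), p)
  })

  if (!is.null(study$prior)) {
    reg_calls <- stage("regulators", {
      call_all_regulators(study$prior, de_bat, alpha = alpha,
                          min_overlap = min_overlap)
    })
    emit("regulator_calls", "regulator_calls.tsv",
         function(p) write_num_tsv(tidy(reg_calls), p))
    net <- stage("regulators", {
      suppressWarnings(build_network(reg_calls, study$prior, de_bat,
                                     alpha = alpha))
    })
    emit("network_sif", "network.sif", function(p) write_network(net, p))
    emit("network_graphml", "network.graphml",
         function(p) write_network(net, p))
    emit("hubs", "hubs.tsv",
         function(p) write_num_tsv(hub_report(net, top_k = top_k), p))
    emit("clusters", "clusters.tsv",
         function(p) write_num_tsv(cluster_groups(reg_calls, study$prior), p))
  }

  if (!is.null(study$huge_scores)) {
    tiers <- stage("evidence", tier_table(study$huge_scores))
    emit("evidence_tiers", "evidence_tiers.tsv",
         function(p) write_num_tsv(tiers, p))
  }

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    file = basename(unlist(artifacts)),
    md5 = unname(tools::md5sum(unlist(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Fixed-precision serialization (6 significant digits) keeps golden files
# and manifest hashes stable across platforms.
write_num_tsv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), function(x) signif(x, 6)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
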