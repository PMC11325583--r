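#' Configuration for the synthetic two-tissue cold-exposure study
#'
#' Parameters of the in-silico study generator. Defaults mirror the design
#' the analysis assumes: two tissues (BAT, liver), two housing conditions
#' (warm 22 vs cold 5 degrees C), n = 6 animals per group, log-normal
#' intensity noise (normal on the log2 scale), planted cold-induced secreted
#' BAT ligands with responding liver receptors, nine ligand-receptor
#' databases, and a regulator prior with a planted activation state per
#' regulator.
#'
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @param n_proteins_per_tissue Proteins per tissue matrix (default 500).
#' @param n_samples_per_group Samples per condition per tissue (default 6).
#' @param baseline_mean,baseline_sd Per-protein baseline abundance
#'   distribution, log2 units (defaults 20 and 2).
#' @param noise_sd Within-group measurement noise, log2 units (default 0.3).
#' @param n_de_up,n_de_down Planted differentially abundant proteins per
#'   tissue and direction (default 40 each).
#' @param de_effect Planted cold effect, log2 units (default 1.5).
#' @param n_crosstalk_pairs Planted secreted-ligand/receptor pairs
#'   (default 5); ligands count towards `n_de_up` in BAT, receptors towards
#'   `n_de_up` in liver.
#' @param n_lr_dbs Number of ligand-receptor databases (default 9).
#' @param db_coverage_prob Probability that a true pair appears in each
#'   database (default 0.4); every pair is forced into at least one.
#' @param n_decoy_pairs Decoy pairs among non-regulated proteins added to
#'   the databases (default 5).
#' @param n_regulators Regulators in the prior (default 20; half TFs, half
#'   miRNAs).
#' @param targets_per_regulator Prior targets per regulator (default 10).
#' @param consistent_fraction Probability that a prior edge sign agrees with
#'   the regulator's planted state (default 0.9).
#' @param missing_prob Completely-at-random missingness rate (default 0).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins_per_tissue = 500L,
                             n_samples_per_group = 6L,
                             baseline_mean = 20,
                             baseline_sd = 2,
                             noise_sd = 0.3,
                             n_de_up = 40L,
                             n_de_down = 40L,
                             de_effect = 1.5,
                             n_crosstalk_pairs = 5L,
                             n_lr_dbs = 9L,
                             db_coverage_prob = 0.4,
                             n_decoy_pairs = 5L,
                             n_regulators = 20L,
                             targets_per_regulator = 10L,
                             consistent_fraction = 0.9,
                             missing_prob = 0) {
  cfg <- list(seed = as.integer(seed),
              n_proteins_per_tissue = as.integer(n_proteins_per_tissue),
              n_samples_per_group = as.integer(n_samples_per_group),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd,
              n_de_up = as.integer(n_de_up), n_de_down = as.integer(n_de_down),
              de_effect = de_effect,
              n_crosstalk_pairs = as.integer(n_crosstalk_pairs),
              n_lr_dbs = as.integer(n_lr_dbs),
              db_coverage_prob = db_coverage_prob,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              consistent_fraction = consistent_fraction,
              missing_prob = missing_prob)
  counts <- c("n_proteins_per_tissue", "n_samples_per_group", "n_lr_dbs")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("`%s` must be positive.", nm))
  }
  for (nm in c("n_de_up", "n_de_down", "n_crosstalk_pairs", "n_decoy_pairs",
               "n_regulators", "targets_per_regulator")) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be non-negative.", nm))
  }
  for (nm in c("db_coverage_prob", "consistent_fraction", "missing_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", nm))
    }
  }
  if (cfg$n_crosstalk_pairs > max(cfg$n_de_up, 0)) {
    abort("`n_crosstalk_pairs` cannot exceed `n_de_up`.")
  }
  if (cfg$n_de_up + cfg$n_de_down + cfg$n_decoy_pairs >
      cfg$n_proteins_per_tissue) {
    abort("More planted proteins than proteins per tissue.")
  }
  if (!is.finite(cfg$de_effect) || !is.finite(cfg$noise_sd) ||
      cfg$noise_sd < 0 || cfg$baseline_sd < 0) {
    abort("Effects must be finite and dispersions non-negative.")
  }
  structure(cfg, class = "synthetic_config")
}

sim_matrix <- function(proteins, baseline, effect, cfg, prefix) {
  n <- cfg$n_samples_per_group
  ids <- c(sprintf("%s_W%d", prefix, seq_len(n)),
           sprintf("%s_C%d", prefix, seq_len(n)))
  cold <- rep(c(0, 1), each = n)
  vals <- vapply(seq_along(ids), function(j) {
    baseline + effect * cold[j] + rnorm(length(proteins), 0, cfg$noise_sd)
  }, numeric(length(proteins)))
  if (cfg$missing_prob > 0) {
    vals[runif(length(vals)) < cfg$missing_prob] <- NA_real_
  }
  colnames(vals) <- ids
  tibble::tibble(protein = proteins) |> dplyr::bind_cols(tibble::as_tibble(vals))
}

#' Simulate a complete two-tissue cold-exposure proteome study
#'
#' Generates every input the analysis chain consumes — BAT and liver
#' abundance matrices, the sample design, secretion annotations,
#' ligand-receptor databases, a regulator prior — together with a ground
#' truth manifest for recovery testing. Per-protein baselines are
#' `Normal(baseline_mean, baseline_sd)`; each sample value adds the
#' condition effect and `Normal(0, noise_sd)` noise. Planted up/down
#' proteins shift by `+/- de_effect` in the cold condition. Planted
#' crosstalk ligands are secreted (signal peptide, no exclusion label) and
#' up in BAT; their receptors are up in liver. True and decoy pairs enter
#' each database independently with `db_coverage_prob`, forced into at least
#' one. Regulator priors draw targets from the planted BAT proteins with
#' `consistent_fraction` sign agreement with the regulator's planted state;
#' inhibited miRNAs are grouped into two polycistron-style clusters.
#'
#' A single RNG stream keyed by `cfg$seed` drives the whole simulation:
#' identical configurations give bit-identical outputs.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_study`: `bat`, `liver`
#'   (`abundance_tbl`), `design`, `annotations`, `lr_dbs`, `prior`, `truth`
#'   (list of planted sets), and `config`.
#' @examples
#' study <- simulate_study(synthetic_config(seed = 1, n_proteins_per_tissue = 60,
#'                                          n_de_up = 6, n_de_down = 6,
#'                                          n_crosstalk_pairs = 2,
#'                                          n_regulators = 4,
#'                                          targets_per_regulator = 4))
#' names(study)
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  set.seed(cfg$seed)
  np <- cfg$n_proteins_per_tissue

  bat_proteins <- sprintf("BATP%04d", seq_len(np))
  liv_proteins <- sprintf("LIVP%04d", seq_len(np))

  # Planted sets (disjoint within each tissue).
  bat_pick <- sample(bat_proteins, cfg$n_de_up + cfg$n_de_down + cfg$n_decoy_pairs)
  bat_up <- bat_pick[seq_len(cfg$n_de_up)]
  bat_down <- bat_pick[cfg$n_de_up + seq_len(cfg$n_de_down)]
  bat_decoy <- bat_pick[cfg$n_de_up + cfg$n_de_down + seq_len(cfg$n_decoy_pairs)]
  ligands <- bat_up[seq_len(cfg$n_crosstalk_pairs)]

  liv_pick <- sample(liv_proteins, cfg$n_de_up + cfg$n_de_down + cfg$n_decoy_pairs)
  liv_up <- liv_pick[seq_len(cfg$n_de_up)]
  liv_down <- liv_pick[cfg$n_de_up + seq_len(cfg$n_de_down)]
  liv_decoy <- liv_pick[cfg$n_de_up + cfg$n_de_down + seq_len(cfg$n_decoy_pairs)]
  receptors <- liv_up[seq_len(cfg$n_crosstalk_pairs)]

  effect_of <- function(proteins, up, down) {
    cfg$de_effect * (proteins %in% up) - cfg$de_effect * (proteins %in% down)
  }

  bat_base <- rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
  liv_base <- rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
  bat <- sim_matrix(bat_proteins, bat_base,
                    effect_of(bat_proteins, bat_up, bat_down), cfg, "BAT")
  liver <- sim_matrix(liv_proteins, liv_base,
                      effect_of(liv_proteins, liv_up, liv_down), cfg, "LIV")

  design <- tibble::tibble(
    sample_id = c(names(bat)[-1], names(liver)[-1]),
    tissue = rep(c("BAT", "LIV"), each = 2 * cfg$n_samples_per_group),
    condition = rep(rep(condition_levels, each = cfg$n_samples_per_group), 2)
  )

  # Secretion annotations for BAT proteins: planted ligands and decoy
  # ligands carry clean secretion evidence; everything else is mostly
  # intracellular with occasional conflicting evidence to exercise the
  # exclusion override.
  secreted_set <- c(ligands, bat_decoy)
  conflicted <- sample(setdiff(bat_proteins, secreted_set),
                       max(1L, np %/% 50))
  annotations <- tibble::tibble(
    protein = bat_proteins,
    signal_peptide = bat_proteins %in% secreted_set,
    secretomep = ifelse(bat_proteins %in% secreted_set, NA,
                        runif(np, 0, 0.5)),
    loctree3 = NA_character_,
    uniprot_locations = dplyr::case_when(
      bat_proteins %in% secreted_set ~ "secreted",
      bat_proteins %in% conflicted ~ "secreted|mitochondrion",
      .default = sample(c("cytoplasm", "mitochondrion", ""), np,
                        replace = TRUE)
    )
  )

  # Ligand-receptor databases: true pairs, decoy pairs among non-regulated
  # proteins, and random filler pairs; each pair enters each database
  # independently, forced into >= 1.
  true_pairs <- tibble::tibble(ligand = ligands, receptor = receptors)
  decoy_pairs <- tibble::tibble(ligand = bat_decoy, receptor = liv_decoy)
  filler_n <- max(5L, np %/% 25)
  filler_pairs <- tibble::tibble(
    ligand = sample(setdiff(bat_proteins, c(ligands, bat_decoy)), filler_n),
    receptor = sample(setdiff(liv_proteins, c(receptors, liv_decoy)), filler_n)
  )
  all_pairs <- dplyr::bind_rows(true_pairs, decoy_pairs, filler_pairs)
  membership <- matrix(runif(nrow(all_pairs) * cfg$n_lr_dbs) <
                         cfg$db_coverage_prob,
                       nrow = nrow(all_pairs))
  none <- which(rowSums(membership) == 0)
  for (i in none) {
    membership[i, sample.int(cfg$n_lr_dbs, 1)] <- TRUE
  }
  lr_dbs <- purrr::map(seq_len(cfg$n_lr_dbs), function(d) {
    keep <- membership[, d]
    tibble::tibble(db = sprintf("lrdb%02d", d),
                   ligand = all_pairs$ligand[keep],
                   receptor = all_pairs$receptor[keep])
  }) |> purrr::list_rbind()

  # Regulator prior over BAT planted proteins, with planted states.
  prior <- NULL
  reg_truth <- tibble::tibble(regulator = character(), kind = character(),
                              state = character(), cluster = NA_character_)
  if (cfg$n_regulators > 0 && targets_available(bat_up, bat_down,
                                                cfg$targets_per_regulator)) {
    regs <- sprintf("REG%03d", seq_len(cfg$n_regulators))
    kinds <- rep(c("TF", "miRNA"), length.out = cfg$n_regulators)
    states <- rep(c("activated", "inhibited"), length.out = cfg$n_regulators)
    de_pool <- c(bat_up, bat_down)
    pool_dir <- c(rep(1L, length(bat_up)), rep(-1L, length(bat_down)))
    prior <- purrr::map(seq_along(regs), function(i) {
      idx <- sample.int(length(de_pool), cfg$targets_per_regulator)
      s <- if (states[i] == "activated") 1L else -1L
      consistent <- runif(cfg$targets_per_regulator) < cfg$consistent_fraction
      tibble::tibble(
        regulator = regs[i], kind = kinds[i],
        target = de_pool[idx],
        sign = ifelse(consistent, s * pool_dir[idx], -s * pool_dir[idx]),
        cluster = NA_character_
      )
    }) |> purrr::list_rbind() |>
      dplyr::distinct(.data$regulator, .data$target, .keep_all = TRUE)

    # Two polycistron-style clusters among inhibited miRNAs (when present).
    inh_mir <- regs[kinds == "miRNA" & states == "inhibited"]
    clusters <- split(inh_mir,
                      rep(c("CLUSTER1", "CLUSTER2"),
                          length.out = length(inh_mir)))
    clusters <- clusters[lengths(clusters) >= 2]
    cl_map <- purrr::imap(clusters, function(members, nm) {
      tibble::tibble(regulator = members, cluster = nm)
    }) |> purrr::list_rbind()
    if (!is.null(cl_map) && nrow(cl_map) > 0) {
      prior$cluster <- cl_map$cluster[match(prior$regulator,
                                            cl_map$regulator)]
    }
    reg_truth <- tibble::tibble(
      regulator = regs, kind = kinds, state = states,
      cluster = if (is.null(cl_map) || nrow(cl_map) == 0) NA_character_
                else cl_map$cluster[match(regs, cl_map$regulator)]
    )
    prior <- validate_prior(prior)
  }

  truth <- list(
    bat_up = sort(bat_up), bat_down = sort(bat_down),
    liver_up = sort(liv_up), liver_down = sort(liv_down),
    secreted = sort(secreted_set),
    crosstalk_pairs = true_pairs,
    decoy_pairs = decoy_pairs,
    regulators = reg_truth
  )

  structure(list(bat = new_abundance_tbl(bat, "BAT"),
                 liver = new_abundance_tbl(liver, "LIV"),
                 design = design,
                 annotations = annotations,
                 lr_dbs = lr_dbs,
                 prior = prior,
                 truth = truth,
                 config = cfg),
            class = "synthetic_study")
}

targets_available <- function(up, down, k) length(c(up, down)) >= k

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("# Synthetic cold-exposure study (seed %d): %d proteins",
                     "/tissue, %d+%d samples/tissue,\n",
                     "#   %d up / %d down planted per tissue, %d crosstalk ",
                     "pairs, %d LR databases, %d regulators\n"),
              cfg$seed, cfg$n_proteins_per_tissue,
              cfg$n_samples_per_group, cfg$n_samples_per_group,
              cfg$n_de_up, cfg$n_de_down, cfg$n_crosstalk_pairs,
              cfg$n_lr_dbs, cfg$n_regulators))
  invisible(x)
}

#' Small deterministic fixture study
#'
#' A fixed, fast configuration (50 proteins per tissue, 3 planted crosstalk
#' pairs, 6 regulators, internal seed) used for quick end-to-end runs.
#'
#' @return A `synthetic_study` list; see [simulate_study()].
#' @export
fixture_study_small <- function() {
  simulate_study(synthetic_config(
    seed = 20L, n_proteins_per_tissue = 50L, n_de_up = 8L, n_de_down = 8L,
    n_crosstalk_pairs = 3L, n_decoy_pairs = 3L,
    n_regulators = 6L, targets_per_regulator = 5L
  ))
}
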