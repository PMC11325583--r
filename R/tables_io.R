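#' Read a protein abundance matrix (log2 LFQ) for one tissue
#'
#' Reads a delimited text file of log2 label-free quantitation intensities
#' with one protein-identifier column and one column per sample, validates it
#' against a sample design table, and returns a tidy abundance table.
#'
#' Protein identifiers are uppercased gene symbols. Duplicate symbol rows are
#' collapsed by keeping the row with the maximum mean intensity across
#' samples (a deterministic symbol-level collapse). Missing values stay
#' `NA` — never zero, which would corrupt means on the log2 scale.
#'
#' @param path Path to a `.tsv` (tab) or `.csv` (comma) file with a header
#'   row. The protein-identifier column is `protein` if present, otherwise
#'   the first column.
#' @param design A data frame with columns `sample_id`, `tissue`,
#'   `condition` (`"warm"`/`"cold"`, i.e. 22 vs 5 degrees C housing).
#' @param tissue Tissue label for this matrix; defaults to the single tissue
#'   present in `design` (required explicitly when the design covers several).
#'
#' @return A tibble with a `protein` column and one numeric column per
#'   designed sample of the tissue, of class `abundance_tbl`, carrying the
#'   tissue label as the `"tissue"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(
#'   tibble::tibble(protein = c("Fga", "Clu"), s1 = c(20, 21), s2 = c(20.5, 21.2)),
#'   tf
#' )
#' design <- tibble::tibble(
#'   sample_id = c("s1", "s2"), tissue = "BAT", condition = c("warm", "cold")
#' )
#' read_abundance_matrix(tf, design)
#' @export
read_abundance_matrix <- function(path, design, tissue = NULL) {
  validate_design(design)
  if (is.null(tissue)) {
    tis <- unique(design$tissue)
    if (length(tis) != 1) {
      abort("`design` covers several tissues; pass `tissue` explicitly.")
    }
    tissue <- tis
  }
  design <- dplyr::filter(design, .data$tissue == !!tissue)
  if (nrow(design) == 0) {
    abort(sprintf("No samples for tissue '%s' in the design.", tissue))
  }

  raw <- reader_for(path)(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) abort(sprintf("'%s' has no data rows.", path))
  id_col <- find_col(raw, "protein") %||% names(raw)[1]

  missing_cols <- setdiff(design$sample_id, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Abundance file '", basename(path),
                 "' is missing designed sample column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  mat <- raw[, c(id_col, design$sample_id)]
  names(mat)[1] <- "protein"
  mat$protein <- norm_symbol(mat$protein)

  for (sc in design$sample_id) {
    v <- mat[[sc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' in column '%s', row %d of '%s'.",
                    v[bad[1]], sc, bad[1], basename(path)))
    }
    num[!is.na(v) & (v == "" | v == "NA")] <- NA_real_
    if (any(is.infinite(num))) {
      abort(sprintf("Non-finite value in column '%s' of '%s'.", sc,
                    basename(path)))
    }
    mat[[sc]] <- num
  }

  # Collapse duplicate symbols: keep the row with the largest mean intensity.
  if (anyDuplicated(mat$protein)) {
    mat <- mat |>
      dplyr::mutate(.mean = rowMeans(dplyr::pick(dplyr::all_of(design$sample_id)),
                                     na.rm = TRUE)) |>
      dplyr::group_by(.data$protein) |>
      dplyr::slice_max(.data$.mean, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".mean")
  }

  new_abundance_tbl(tibble::as_tibble(mat), tissue)
}

new_abundance_tbl <- function(tbl, tissue) {
  structure(tbl, tissue = tissue,
            class = c("abundance_tbl", class(tibble::as_tibble(tbl))))
}

#' @export
print.abundance_tbl <- function(x, ...) {
  cat(sprintf("# Abundance matrix: tissue %s, %d proteins x %d samples\n",
              attr(x, "tissue") %||% "?", nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Write an abundance table back to delimited text
#'
#' Values are serialized with shortest round-trip doubles so a
#' write-then-read cycle reproduces them bit-exactly.
#'
#' @param abundance An `abundance_tbl` (see [read_abundance_matrix()]).
#' @param path Output path; `.tsv` writes tabs, `.csv` commas.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(abundance, path) {
  writer_for(path)(tibble::as_tibble(abundance), path, progress = FALSE)
  invisible(path)
}

#' Load ligand-receptor interaction databases
#'
#' Each file contributes one database of (ligand, receptor) pairs. Symbols
#' are uppercased and duplicate pairs within one database are dropped, so a
#' pair can count at most once per database towards its evidence count.
#'
#' @param paths Character vector of `.tsv`/`.csv` files with ligand and
#'   receptor columns (matched case-insensitively by name; otherwise the
#'   first two columns are used).
#' @param db_names Optional database labels; defaults to file base names
#'   (made unique).
#' @return A tibble with columns `db`, `ligand`, `receptor`; one row per
#'   retained pair per database. An empty file yields a warning and
#'   contributes no rows (its evidence contribution is 0).
#' @export
load_lr_databases <- function(paths, db_names = NULL) {
  if (is.null(db_names)) {
    db_names <- make.unique(tools::file_path_sans_ext(basename(paths)))
  }
  stopifnot(length(db_names) == length(paths))
  purrr::map2(paths, db_names, function(p, nm) {
    df <- reader_for(p)(p)
    if (nrow(df) == 0) {
      warn(sprintf("Ligand-receptor database '%s' is empty.", nm))
      return(tibble::tibble(db = character(), ligand = character(),
                            receptor = character()))
    }
    lig_col <- find_col(df, c("ligand", "ligand_symbol", "from")) %||% names(df)[1]
    rec_col <- find_col(df, c("receptor", "receptor_symbol", "to")) %||% names(df)[2]
    tibble::tibble(db = nm,
                   ligand = norm_symbol(df[[lig_col]]),
                   receptor = norm_symbol(df[[rec_col]])) |>
      dplyr::distinct()
  }) |>
    purrr::list_rbind()
}

#' Published reference table of BAT-to-liver ligand-receptor scores
#'
#' The packaged reference table of ligand-receptor crosstalk candidates
#' between cold-exposed brown adipose tissue (BAT) and liver: for each
#' (ligand, receptor) pair the ligand's fold change in BAT upon cold
#' induction, the change in regularized product score (`delta_lr`), the
#' change in summed normalized log2 levels (`delta_sum`), and the number of
#' ligand-receptor databases (out of nine) documenting the pair (`n_lrdb`).
#'
#' @return A 17-row tibble with columns `ligand`, `fold_change`, `receptor`,
#'   `delta_lr`, `delta_sum`, `n_lrdb`.
#' @seealso [select_candidates()] for the published selection thresholds.
#' @export
lr_reference_scores <- function() {
  p <- system.file("extdata", "lr_crosstalk_reference.tsv",
                   package = "tissuetalk", mustWork = TRUE)
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE,
                  col_types = "cdcddi")
}

#' Published reference table of dysregulated miRNA activation calls
#'
#' Packaged reference list of miRNAs with predicted activation states in BAT
#' and liver after cold exposure: activation z-score, predicted state, and
#' overlap p-value, as reported by upstream-regulator analysis.
#'
#' @return A tibble with columns `tissue`, `name`, `z`, `state`, `p_value`.
#' @export
mirna_reference_calls <- function() {
  p <- system.file("extdata", "mirna_activation_reference.tsv",
                   package = "tissuetalk", mustWork = TRUE)
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccdcd")
}

#' Read secretion annotation table
#'
#' @param path `.tsv`/`.csv` with columns `protein`, `signal_peptide`
#'   (logical), `secretomep` (numeric or blank), `loctree3` (label or blank),
#'   `uniprot_locations` (pipe-separated labels, possibly empty).
#' @return A tibble with those columns, symbols uppercased.
#' @export
read_secretion_annotations <- function(path) {
  df <- reader_for(path)(path,
    col_types = readr::cols(
      protein = readr::col_character(),
      signal_peptide = readr::col_logical(),
      secretomep = readr::col_double(),
      loctree3 = readr::col_character(),
      uniprot_locations = readr::col_character()
    ))
  df$protein <- norm_symbol(df$protein)
  tibble::as_tibble(df)
}

#' Read a regulator-to-target prior table
#'
#' @param path `.tsv`/`.csv` with columns `regulator`, `kind` (`TF` or
#'   `miRNA`), `target`, `sign` (+1 activating / -1 repressing) and optional
#'   `cluster` (polycistron label).
#' @return Tibble with columns `regulator`, `kind`, `target`, `sign`,
#'   `cluster`; target symbols uppercased.
#' @export
read_regulator_prior <- function(path) {
  df <- reader_for(path)(path)
  validate_prior(tibble::tibble(
    regulator = as.character(df$regulator),
    kind = as.character(df$kind),
    target = norm_symbol(df$target),
    sign = as.integer(df$sign),
    cluster = if ("cluster" %in% names(df)) as.character(df$cluster)
              else NA_character_
  ))
}

validate_prior <- function(prior) {
  req <- c("regulator", "target", "sign")
  miss <- setdiff(req, names(prior))
  if (length(miss) > 0) {
    abort(paste0("Regulator prior is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(prior$sign %in% c(-1L, 1L))) {
    abort("Prior `sign` must be +1 (activating) or -1 (repressing).")
  }
  if (anyDuplicated(prior[, c("regulator", "target")])) {
    abort("Prior (regulator, target) pairs must be unique.")
  }
  if (!"kind" %in% names(prior)) prior$kind <- NA_character_
  if (!"cluster" %in% names(prior)) prior$cluster <- NA_character_
  tibble::as_tibble(prior)
}
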