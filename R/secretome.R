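#' Call secreted proteins from annotation evidence
#'
#' Applies the four-criterion secretome definition used for cold-induced
#' batokine discovery. A protein is called secreted when at least one
#' inclusion criterion fires and no exclusion label is present:
#'
#' * **i** — a signal peptide is predicted (classical secretion);
#' * **ii** — non-classical secretion score strictly greater than 0.6;
#' * **iii** — localization predictor class is `secreted` or `extracellular`;
#' * **iv** — curated subcellular localization includes `secreted` or
#'   `secretory vesicle`.
#'
#' Proteins with a curated localization of `mitochondrion`,
#' `endoplasmic reticulum`, or `cytoplasm` are considered non-secreted
#' regardless of the inclusion evidence (exclusion wins over inclusion).
#' Label matching is case-insensitive.
#'
#' @param annotations A data frame with columns `protein`, `signal_peptide`
#'   (logical), `secretomep` (score in \[0,1\] or `NA`), `loctree3` (class
#'   label or `NA`), `uniprot_locations` (pipe-separated labels, `NA` or ""
#'   for none).
#' @return A tibble with columns `protein`, `secreted`, `fired_criteria`
#'   (comma-joined subset of `i,ii,iii,iv`, "" when none) and `excluded_by`
#'   (comma-joined offending labels, "" when none).
#' @examples
#' ann <- tibble::tibble(
#'   protein = c("FGA", "CYCS"),
#'   signal_peptide = c(TRUE, FALSE),
#'   secretomep = c(NA, 0.9),
#'   loctree3 = NA_character_,
#'   uniprot_locations = c("secreted", "mitochondrion")
#' )
#' call_secretion(ann)
#' @export
call_secretion <- function(annotations) {
  req <- c("protein", "signal_peptide", "secretomep", "loctree3",
           "uniprot_locations")
  miss <- setdiff(req, names(annotations))
  if (length(miss) > 0) {
    abort(paste0("Annotation table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  sp <- annotations$secretomep
  if (any(!is.na(sp) & (sp < 0 | sp > 1))) {
    abort("`secretomep` scores must lie in [0, 1].")
  }

  locs <- purrr::map(annotations$uniprot_locations, parse_locations)
  excl_labels <- c("mitochondrion", "endoplasmic reticulum", "cytoplasm")
  incl_labels <- c("secreted", "secretory vesicle")

  crit_i <- !is.na(annotations$signal_peptide) & annotations$signal_peptide
  crit_ii <- !is.na(sp) & sp > 0.6
  crit_iii <- !is.na(annotations$loctree3) &
    tolower(trimws(annotations$loctree3)) %in% c("secreted", "extracellular")
  crit_iv <- purrr::map_lgl(locs, function(l) any(l %in% incl_labels))
  excluded <- purrr::map(locs, function(l) intersect(excl_labels, l))

  fired <- purrr::pmap_chr(
    list(crit_i, crit_ii, crit_iii, crit_iv),
    function(a, b, c, d) paste(c("i", "ii", "iii", "iv")[c(a, b, c, d)],
                               collapse = ",")
  )
  tibble::tibble(
    protein = norm_symbol(annotations$protein),
    secreted = (crit_i | crit_ii | crit_iii | crit_iv) &
      lengths(excluded) == 0,
    fired_criteria = fired,
    excluded_by = purrr::map_chr(excluded, paste, collapse = ",")
  )
}

parse_locations <- function(x) {
  if (is.na(x) || x == "") return(character())
  tolower(trimws(strsplit(x, "|", fixed = TRUE)[[1]]))
}

#' Secreted, significantly induced ligand candidates
#'
#' Intersects the upregulated proteins of a differential table (class `up`:
#' p below alpha and log2FC above the fold-change gate) with the proteins
#' called secreted, yielding the candidate ligand set for crosstalk pairing.
#'
#' @param de A `tt_de` differential table for the ligand tissue (BAT).
#' @param calls Output of [call_secretion()].
#' @return Sorted character vector of ligand symbols (possibly empty).
#' @export
secreted_induced_ligands <- function(de, calls) {
  up <- de$protein[de$reg_class == "up"]
  secreted <- calls$protein[calls$secreted]
  sort(intersect(up, secreted))
}
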