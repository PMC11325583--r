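# Internal helpers shared across modules.

# Uppercase gene symbols; all identifier matching in the package happens in
# this space (the published surfaces use symbols like FGA, ITGB1).
norm_symbol <- function(x) toupper(trimws(as.character(x)))

# Delimiter by extension: .tsv/.txt tab, .csv comma.
reader_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    function(p, ...) readr::read_csv(p, show_col_types = FALSE,
                                     progress = FALSE, ...)
  } else {
    function(p, ...) readr::read_tsv(p, show_col_types = FALSE,
                                     progress = FALSE, ...)
  }
}

writer_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") readr::write_csv else readr::write_tsv
}

# Locate a column by candidate names, case-insensitively; NULL if absent.
find_col <- function(df, candidates) {
  hit <- match(tolower(candidates), tolower(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NULL else names(df)[hit[1]]
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

condition_levels <- c("warm", "cold")

# Validate a sample design tibble: sample_id, tissue, condition (warm/cold).
validate_design <- function(design) {
  req <- c("sample_id", "tissue", "condition")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) {
    abort(paste0("Design table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(design$condition), condition_levels)
  if (length(bad) > 0) {
    abort(paste0("Design conditions must be 'warm' or 'cold'; found: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("Design sample_ids must be unique.")
  }
  invisible(design)
}
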