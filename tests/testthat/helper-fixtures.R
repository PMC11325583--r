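# Shared builders and independent oracles for the test suite.

toy_design <- function(n = 2, tissue = "BAT", prefix = "S") {
  tibble::tibble(
    sample_id = c(sprintf("%sW%d", prefix, seq_len(n)),
                  sprintf("%sC%d", prefix, seq_len(n))),
    tissue = tissue,
    condition = rep(c("warm", "cold"), each = n)
  )
}

# Abundance tibble straight from a matrix of values (proteins x samples).
toy_abundance <- function(values, proteins, design, tissue = "BAT") {
  stopifnot(nrow(values) == length(proteins),
            ncol(values) == nrow(design))
  tbl <- tibble::as_tibble(values, .name_repair = "minimal")
  names(tbl) <- design$sample_id
  tbl <- dplyr::bind_cols(tibble::tibble(protein = proteins), tbl)
  tissuetalk:::new_abundance_tbl(tbl, tissue)
}

# Independent Welch two-sample oracle: direct formula with the
# Welch-Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  vx <- stats::var(x) / m
  vy <- stats::var(y) / n
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (m - 1) + vy^2 / (n - 1))
  2 * stats::pt(-abs(tstat), df)
}

# One-row annotation with the four inclusion criteria switched on or off
# and optional exclusion labels.
make_ann <- function(i = FALSE, ii = FALSE, iii = FALSE, iv = FALSE,
                     excl = character()) {
  locs <- c(if (iv) "secretory vesicle", excl)
  tibble::tibble(
    protein = "P1",
    signal_peptide = i,
    secretomep = if (ii) 0.7 else 0.2,
    loctree3 = if (iii) "secreted" else NA_character_,
    uniprot_locations = paste(locs, collapse = "|")
  )
}

# Hand-written secretion oracle over explicit evidence bits.
secretion_oracle <- function(i, ii, iii, iv, excluded) {
  (i || ii || iii || iv) && !excluded
}

# Minimal differential-like table for regulator tests: columns are all the
# regulator module reads.
toy_de <- function(protein, log2fc, p_value = 0.001) {
  tibble::tibble(protein = protein, log2fc = log2fc,
                 p_value = rep_len(p_value, length(protein)))
}

write_lr_db_file <- function(pairs, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(pairs, path, progress = FALSE)
  path
}
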