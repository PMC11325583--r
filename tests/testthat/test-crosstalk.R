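test_that("regularized product score has its analytic values", {
  expect_equal(lr_score(10, 10, mu = 10), 0.5)
  expect_equal(lr_score(0, 7, mu = 3), 0)
  expect_equal(lr_score(16, 4, mu = 6), 8 / 14)
  expect_error(lr_score(-1, 2, mu = 1), "non-negative")
  expect_error(lr_score(1, 2, mu = 0), "positive")
})

test_that("score is monotone in the abundance product and in mu", {
  set.seed(5)
  l <- sort(stats::runif(50, 0.1, 40))
  s <- lr_score(l, l, mu = 12)
  expect_true(all(diff(s) > 0))
  mus <- sort(stats::runif(20, 1, 50))
  s_mu <- vapply(mus, function(m) lr_score(18, 22, m), numeric(1))
  expect_true(all(diff(s_mu) < 0))
})

test_that("auto_mu pools per-protein means across matrices", {
  design <- toy_design(2)
  a <- toy_abundance(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 2),
                     c("A", "B"), design)
  b <- toy_abundance(matrix(rep(10, 8), nrow = 2), c("C", "D"), design,
                     tissue = "LIV")
  # per-protein means: A = 4, B = 5 (rows of a), C = D = 10
  expect_equal(auto_mu(a, b), mean(c(4, 5, 10, 10)))
})

test_that("pairing scores every database partner and counts evidence", {
  design <- toy_design(3)
  bat <- toy_abundance(rbind(c(10, 10, 10, 12, 12, 12)), "LIG", design)
  liver <- toy_abundance(rbind(c(8, 8, 8, 9, 9, 9),
                               c(6, 6, 6, 6, 6, 6)),
                         c("R1", "R2"), design, tissue = "LIV")
  ldesign <- dplyr::mutate(design, tissue = "LIV",
                           sample_id = paste0("L", sample_id))
  names(liver)[-1] <- ldesign$sample_id
  both <- dplyr::bind_rows(design, ldesign)
  de_bat <- differential_table(bat, both)
  de_liv <- differential_table(liver, both)
  dbs <- tibble::tibble(db = c("d1", "d1", "d2"),
                        ligand = "LIG", receptor = c("R1", "R2", "R1"))
  sc <- pair_and_score("LIG", de_bat, de_liv, dbs, mu = 10)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$n_lrdb[sc$receptor == "R1"], 2L)
  expect_equal(sc$n_lrdb[sc$receptor == "R2"], 1L)

  # delta_sum equals the independent recomputation from group means
  expect_equal(sc$delta_sum[sc$receptor == "R1"], (12 + 9) - (10 + 8),
               tolerance = 1e-12)
  expect_equal(sc$delta_sum[sc$receptor == "R2"], (12 + 6) - (10 + 6),
               tolerance = 1e-12)
  expect_equal(sc$delta_lr[sc$receptor == "R1"],
               lr_score(12, 9, 10) - lr_score(10, 8, 10), tolerance = 1e-12)

  # receptor missing from the liver table is dropped
  dbs2 <- dplyr::bind_rows(dbs, tibble::tibble(db = "d3", ligand = "LIG",
                                               receptor = "GHOST"))
  sc2 <- pair_and_score("LIG", de_bat, de_liv, dbs2, mu = 10)
  expect_false("GHOST" %in% sc2$receptor)
})

test_that("identical conditions give exactly zero deltas and empty selection", {
  design <- toy_design(3)
  set.seed(8)
  half <- matrix(rnorm(5 * 3, 20, 1), nrow = 5)
  vals <- cbind(half, half) # cold columns identical to warm columns
  bat <- toy_abundance(vals, paste0("LG", 1:5), design)
  liver_design <- toy_design(3, tissue = "LIV", prefix = "L")
  liver <- toy_abundance(cbind(half, half), paste0("RC", 1:5), liver_design,
                         tissue = "LIV")
  both <- dplyr::bind_rows(design, liver_design)
  de_bat <- differential_table(bat, both)
  de_liv <- differential_table(liver, both)
  dbs <- tibble::tibble(db = "d1", ligand = paste0("LG", 1:5),
                        receptor = paste0("RC", 1:5))
  sc <- pair_and_score(paste0("LG", 1:5), de_bat, de_liv, dbs, mu = 20)
  expect_true(all(sc$delta_lr == 0))
  expect_true(all(sc$delta_sum == 0))
  expect_equal(nrow(select_candidates(sc)), 0)
})

test_that("selection thresholds are strict with 3-decimal dLR comparison", {
  sc <- tibble::tibble(
    ligand = c("A", "B", "C", "D"), receptor = paste0("R", 1:4),
    fold_change = c(2.0, 2.5, 2.5, 2.5),
    delta_lr = c(0.05, 0.0195, 0.0194, 0.05),
    delta_sum = c(3, 3, 3, 2.0)
  )
  sel <- select_candidates(sc)
  # A: fold change exactly 2 -> rejected (strict >)
  # B: delta_lr 0.0195 rounds to 0.02 -> kept
  # C: 0.0194 rounds to 0.019 -> rejected
  # D: delta_sum exactly 2 -> rejected (strict >)
  expect_identical(sel$ligand, "B")
  flagged <- select_candidates(sc, keep_all = TRUE)
  expect_identical(flagged$selected, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("a planted crosstalk pair ranks first among decoys", {
  study <- fixture_study_small()
  de_bat <- differential_table(study$bat, study$design)
  de_liv <- differential_table(study$liver, study$design)
  calls <- call_secretion(study$annotations)
  lig <- secreted_induced_ligands(de_bat, calls)
  mu <- auto_mu(study$bat, study$liver)
  sc <- suppressMessages(
    pair_and_score(lig, de_bat, de_liv, study$lr_dbs, mu))
  truth <- study$truth$crosstalk_pairs
  top <- paste(sc$ligand[1], sc$receptor[1])
  expect_true(top %in% paste(truth$ligand, truth$receptor))
  # every scored pair involves a candidate ligand
  expect_true(all(sc$ligand %in% lig))
})

test_that("glance summarises a crosstalk table", {
  sel <- select_candidates(lr_reference_scores(), keep_all = TRUE)
  sel <- structure(sel, class = c("tt_crosstalk", class(sel)), mu = 1)
  g <- glance(sel)
  expect_equal(g$n_pairs, 17)
  expect_equal(g$n_selected, 5)
})
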