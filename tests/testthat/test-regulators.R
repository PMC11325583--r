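test_that("activation z-score matches the signed-agreement formula", {
  # 4 targets all consistent with repression -> z = -4 / sqrt(4) = -2
  prior <- tibble::tibble(regulator = "R", kind = "miRNA",
                          target = paste0("T", 1:4), sign = -1L)
  de <- toy_de(paste0("T", 1:4), log2fc = c(1, 1, 1, 1))
  call <- activation_z(prior, de, "R")
  expect_equal(call$z, -2)
  expect_equal(call$state, "inhibited")
  expect_equal(call$n_overlap, 4)

  # 2 consistent, 2 inconsistent -> z = 0
  de2 <- toy_de(paste0("T", 1:4), log2fc = c(1, 1, -1, -1))
  expect_equal(activation_z(prior, de2, "R")$z, 0)
  expect_equal(activation_z(prior, de2, "R")$state, "undetermined")

  # 9 upregulated targets of an activator -> z = 3, activated
  prior3 <- tibble::tibble(regulator = "A", kind = "TF",
                           target = paste0("U", 1:9), sign = 1L)
  de3 <- toy_de(paste0("U", 1:9), log2fc = rep(2, 9))
  call3 <- activation_z(prior3, de3, "A")
  expect_equal(call3$z, 3)
  expect_equal(call3$state, "activated")
})

test_that("non-significant targets and small overlaps are handled", {
  prior <- tibble::tibble(regulator = "R", kind = "TF",
                          target = paste0("T", 1:5), sign = 1L)
  de <- toy_de(paste0("T", 1:5), log2fc = rep(1, 5),
               p_value = c(0.001, 0.001, 0.5, 0.5, 0.5))
  call <- activation_z(prior, de, "R", min_overlap = 3)
  expect_equal(call$n_overlap, 2)
  expect_true(is.na(call$z))
  expect_equal(call$state, "undetermined")

  expect_error(activation_z(prior, de, "MISSING"), "not in the prior")
})

test_that("z is antisymmetric and bounded by sqrt(n)", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    prior <- tibble::tibble(regulator = "R", kind = "TF",
                            target = paste0("T", 1:n),
                            sign = sample(c(-1L, 1L), n, replace = TRUE))
    de <- toy_de(paste0("T", 1:n),
                 log2fc = stats::rnorm(n))
    z <- activation_z(prior, de, "R", min_overlap = 1)$z
    de_flip <- dplyr::mutate(de, log2fc = -log2fc)
    z_flip <- activation_z(prior, de_flip, "R", min_overlap = 1)$z
    expect_identical(z_flip, -z)
    expect_lte(abs(z), sqrt(n) * (1 + 1e-12))
  }
  # |z| = sqrt(n) exactly iff agreements are unanimous
  prior <- tibble::tibble(regulator = "R", kind = "TF",
                          target = paste0("T", 1:7), sign = 1L)
  z_unan <- activation_z(prior, toy_de(paste0("T", 1:7), rep(1, 7)), "R")$z
  expect_equal(z_unan, sqrt(7))
  z_mixed <- activation_z(prior,
                          toy_de(paste0("T", 1:7), c(rep(1, 6), -1)), "R")$z
  expect_lt(abs(z_mixed), sqrt(7))
})

test_that("overlap enrichment p follows the hypergeometric", {
  # universe 20 proteins, 10 significant, 4 prior targets all significant
  prior <- tibble::tibble(regulator = "R", kind = "TF",
                          target = paste0("P", 1:4), sign = 1L)
  de <- toy_de(paste0("P", 1:20), log2fc = rep(1, 20),
               p_value = c(rep(0.01, 10), rep(0.5, 10)))
  call <- activation_z(prior, de, "R")
  expect_equal(call$p_overlap,
               stats::phyper(3, 10, 10, 4, lower.tail = FALSE))
})

test_that("call_all_regulators orders deterministically and tidies", {
  prior <- dplyr::bind_rows(
    tibble::tibble(regulator = "UP", kind = "TF",
                   target = paste0("T", 1:4), sign = 1L),
    tibble::tibble(regulator = "DN", kind = "miRNA",
                   target = paste0("T", 1:4), sign = -1L),
    tibble::tibble(regulator = "WEAK", kind = "TF",
                   target = paste0("T", 1:2), sign = 1L)
  )
  de <- toy_de(paste0("T", 1:4), log2fc = rep(1, 4))
  calls <- call_all_regulators(prior, de)
  expect_equal(calls$regulator, c("UP", "DN", "WEAK"))
  expect_equal(calls$state, c("activated", "inhibited", "undetermined"))
  g <- glance(calls)
  expect_equal(g$n_activated, 1)
  expect_equal(g$n_inhibited, 1)
  expect_equal(g$n_undetermined, 1)
})

test_that("network edges equal the brute-force prior intersection", {
  set.seed(33)
  for (rep in 1:25) {
    n_reg <- sample(2:5, 1)
    n_prot <- 30
    prior <- purrr::map(seq_len(n_reg), function(i) {
      tibble::tibble(
        regulator = paste0("R", i), kind = "TF",
        target = sample(paste0("P", 1:n_prot), sample(4:8, 1)),
        sign = sample(c(-1L, 1L), 1)
      )
    }) |> purrr::list_rbind()
    de <- toy_de(paste0("P", 1:n_prot),
                 log2fc = sample(c(-2, 2), n_prot, replace = TRUE),
                 p_value = stats::runif(n_prot, 0, 0.2))
    calls <- call_all_regulators(prior, de, min_overlap = 1)
    net <- suppressWarnings(build_network(calls, prior, de))

    qual <- calls$regulator[calls$state != "undetermined"]
    sig <- de$protein[de$p_value < 0.05]
    want <- prior[prior$regulator %in% qual & prior$target %in% sig, ]
    got <- if (igraph::ecount(net) == 0) {
      character()
    } else {
      el <- igraph::as_edgelist(net)
      sort(paste(el[, 1], el[, 2]))
    }
    expect_identical(got, sort(paste(want$regulator, want$target)))
  }
})

test_that("shared targets, hubs and disconnected regulators behave", {
  prior <- dplyr::bind_rows(
    tibble::tibble(regulator = "R1", kind = "TF",
                   target = c("HUB", "A", "B", "C"), sign = 1L),
    tibble::tibble(regulator = "R2", kind = "miRNA",
                   target = c("HUB", "D", "E", "F"), sign = 1L),
    tibble::tibble(regulator = "R3", kind = "TF",
                   target = c("X", "Y", "Z"), sign = 1L)
  )
  de <- toy_de(c("HUB", "A", "B", "C", "D", "E", "F", "X", "Y", "Z"),
               log2fc = rep(1, 10),
               p_value = c(rep(0.001, 7), rep(0.9, 3))) # R3 targets not sig.
  calls <- call_all_regulators(prior, de)
  net <- suppressWarnings(build_network(calls, prior, de))
  expect_false("R3" %in% igraph::V(net)$name)
  # R1 and R2 have degree 4 each (tie broken alphabetically), HUB degree 2
  hubs <- hub_report(net, top_k = 3)
  expect_equal(hubs$node, c("R1", "R2", "HUB"))
  deg <- hub_report(net, top_k = 10)
  expect_equal(deg$degree[deg$node == "HUB"], 2L)
})

test_that("cluster groups require shared cluster and matching state", {
  prior <- purrr::map(1:4, function(i) {
    tibble::tibble(regulator = paste0("M", i), kind = "miRNA",
                   target = paste0("T", 1:4), sign = -1L,
                   cluster = if (i <= 3) "DLK1-DIO3" else NA_character_)
  }) |> purrr::list_rbind()
  # all four see the same 4 upregulated targets with repressive priors
  de <- toy_de(paste0("T", 1:4), log2fc = rep(1, 4))
  calls <- call_all_regulators(prior, de)
  groups <- cluster_groups(calls, prior)
  expect_equal(nrow(groups), 1)
  expect_equal(groups$n, 3)
  expect_equal(groups$state, "inhibited")
  expect_equal(groups$regulators, "M1,M2,M3")

  # a two-member cluster with opposite states yields no group
  prior2 <- purrr::map(1:2, function(i) {
    tibble::tibble(regulator = paste0("M", i), kind = "miRNA",
                   target = paste0("T", 1:4),
                   sign = if (i == 1) -1L else 1L,
                   cluster = "MIR17-92")
  }) |> purrr::list_rbind()
  calls2 <- call_all_regulators(prior2, de)
  expect_equal(nrow(cluster_groups(calls2, prior2)), 0)

  # no cluster annotations at all -> empty result
  plain <- dplyr::mutate(prior, cluster = NA_character_)
  expect_equal(nrow(cluster_groups(calls, plain)), 0)
})

test_that("network export writes GraphML and SIF", {
  prior <- tibble::tibble(regulator = "R1", kind = "TF",
                          target = c("A", "B", "C", "D"),
                          sign = c(1L, 1L, -1L, -1L))
  de <- toy_de(c("A", "B", "C", "D"), log2fc = c(1, 1, -1, -1),
               p_value = 0.001) # unanimous agreement: z = 2, activated
  calls <- call_all_regulators(prior, de)
  net <- build_network(calls, prior, de)
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, sif)
  write_network(net, gml)
  lines <- sort(readLines(sif))
  expect_equal(lines, sort(c("R1\tactivates\tA", "R1\tactivates\tB",
                             "R1\trepresses\tC", "R1\trepresses\tD")))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 5)
  expect_error(write_network(net, tempfile(fileext = ".xyz")), "format")
})
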