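test_that("empty inputs give an empty network with N = 0", {
  net <- tripartite_network()
  expect_s3_class(net, "tripartite_network")
  expect_equal(network_size(net), 0L)
  expect_equal(nrow(net$chem_gene) + nrow(net$gene_disease) + nrow(net$chem_disease), 0L)
})

test_that("duplicate pairs collapse to binary edges and degrees add up", {
  net <- tripartite_network(
    chem_gene = data.frame(c = c("X", "X", "X"), g = c("g1", "g1", "g2")),
    gene_disease = data.frame(g = "g1", d = "Y")
  )
  expect_equal(nrow(net$chem_gene) + nrow(net$gene_disease), 3L)
  expect_equal(network_size(net), 4L)
  expect_equal(net_degree(net, "X"), 2L)
})

test_that("layer filters and isolated declared nodes behave", {
  net <- tripartite_network(
    chem_gene = data.frame(c = c("X", "X"), g = c("g1", "g2")),
    chem_disease = data.frame(c = "X", d = "Y"),
    nodes = data.frame(kind = "gene", id = "lonely")
  )
  expect_equal(net_degree(net, "X"), 3L)
  expect_equal(net_degree(net, "X", layer = "chem_gene"), 2L)
  expect_equal(net_degree(net, "lonely"), 0L)
  expect_equal(network_size(net), 4L)  # the isolated gene does not count
  expect_error(net_degree(net, "nope"), "unknown node")
})

test_that("identifier collisions across kinds are rejected", {
  expect_error(
    tripartite_network(
      chem_gene = data.frame(c = "shared", g = "g1"),
      gene_disease = data.frame(g = "shared", d = "Y")
    ),
    "collision"
  )
})

test_that("degrees match a brute-force incidence count on random pairs", {
  set.seed(11)
  ids <- paste0("n", 1:30)
  cg <- random_pairs(100, ids[1:10], ids[11:20])
  gd <- random_pairs(100, ids[11:20], ids[21:30])
  cd <- random_pairs(100, ids[1:10], ids[21:30])
  net <- tripartite_network(cg, gd, cd)
  all_edges <- rbind(as.matrix(dplyr::distinct(cg)), as.matrix(dplyr::distinct(gd)),
                     as.matrix(dplyr::distinct(cd)))
  for (v in sample(ids, 12)) {
    expect_equal(net_degree(net, v), sum(all_edges == v),
                 info = paste("node", v))
  }
  # degree conservation: total degree = 2 x edge count
  expect_equal(sum(degree_table(net)$degree), 2L * nrow(all_edges))
})

test_that("load_network reads pairs files, dedups, and errors on bad rows", {
  dir <- withr::local_tempdir()
  cg <- file.path(dir, "cg.tsv"); gd <- file.path(dir, "gd.tsv")
  cd <- file.path(dir, "cd.tsv")
  writeLines(c("# comment", "X\tg1", "X\tg1", "X\tg2"), cg)
  writeLines("g1\tY", gd)
  writeLines(character(), cd)
  net <- suppressMessages(load_network(cg, gd, cd))
  expect_equal(nrow(net$chem_gene), 2L)
  expect_equal(network_size(net), 4L)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("X\tg1", "lonefield"), bad)
  expect_error(suppressMessages(load_network(bad, gd, cd)), "line 2")
  expect_error(suppressMessages(load_network(file.path(dir, "none.tsv"), gd, cd)),
               "not found")
})

test_that("ctd_export dialect maps named columns", {
  dir <- withr::local_tempdir()
  cg <- file.path(dir, "cg.tsv")
  readr::write_tsv(tibble::tibble(ChemicalID = c("X", "X"), Extra = 1:2,
                                  GeneSymbol = c("g1", "g2")), cg)
  gd <- file.path(dir, "gd.tsv")
  readr::write_tsv(tibble::tibble(GeneSymbol = "g1", DiseaseID = "Y"), gd)
  net <- suppressMessages(load_network(
    cg, gd, NA, dialect = "ctd_export",
    col_map = list(chem_gene = c("ChemicalID", "GeneSymbol"),
                   gene_disease = c("GeneSymbol", "DiseaseID"))
  ))
  expect_equal(net_degree(net, "X"), 2L)
  expect_error(suppressMessages(load_network(
    cg, gd, NA, dialect = "ctd_export",
    col_map = list(chem_gene = c("Missing", "GeneSymbol"),
                   gene_disease = c("GeneSymbol", "DiseaseID"))
  )), "not present")
})

test_that("write -> load round trip preserves edges and N", {
  net <- random_network(seed = 21)
  dir <- withr::local_tempdir()
  write_network(net, dir)
  back <- suppressMessages(load_network(
    file.path(dir, "chem_gene.tsv"), file.path(dir, "gene_disease.tsv"),
    file.path(dir, "chem_disease.tsv")
  ))
  for (layer in c("chem_gene", "gene_disease", "chem_disease")) {
    expect_equal(dplyr::arrange_all(back[[layer]]), dplyr::arrange_all(net[[layer]]))
  }
  expect_equal(network_size(back), network_size(net))
})

test_that("power-law fit recovers an exact line and rejects degenerate input", {
  d <- 1:50
  degrees <- rep(d, times = round(1e4 * d^-1.5))
  fit <- fit_powerlaw(degrees)
  expect_equal(fit$slope, -1.5, tolerance = 2e-3)
  expect_gt(fit$r_squared, 0.9999)
  expect_error(fit_powerlaw(rep(7, 100)), "degenerate")
  expect_named(glance(fit), c("slope", "intercept", "r.squared", "n_degrees", "n_nodes"))
  expect_equal(tidy(fit)$estimate[2], fit$slope)
})
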