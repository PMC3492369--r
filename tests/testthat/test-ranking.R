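make_score_table <- function(...) {
  tibble::tibble(...)
}

base_table <- function() {
  tibble::tibble(
    chemical = c("A", "A", "A", "B", "B"),
    disease = c("d1", "d2", "d3", "d1", "d4"),
    m = c(2L, 3L, 1L, 2L, 2L),
    curated = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    c_xy = c(5, 9, 1, 3, 3),
    p1 = c(5, 9, 1, 3, 3),
    p2 = c(10, 12, 2, 8, 8),
    s_xya = c(7.5, 10.5, 1.5, 5.5, 5.5),
    w_xya = c(5, 9, 7, 3, 3),
    w_bonferroni = c(4, 8, 6, 2, 2)
  )
}

test_that("curated rows lead their group regardless of score", {
  ranked <- rank_inferences(base_table(), group_by = "chemical")
  a <- ranked[ranked$chemical == "A", ]
  expect_equal(a$disease[a$rank == 1], "d3")  # curated, despite w = 7 < 9
  expect_equal(a$disease[order(a$rank)], c("d3", "d2", "d1"))
})

test_that("novel rows order by descending score with deterministic ties", {
  tab <- make_score_table(
    chemical = "A", disease = c("d1", "d2", "d3"),
    m = c(1L, 1L, 1L), curated = FALSE,
    c_xy = 0, p1 = 0, p2 = 0, s_xya = 0,
    w_xya = c(5, 9, 7), w_bonferroni = c(5, 9, 7)
  )
  ranked <- rank_inferences(tab)
  expect_equal(ranked$disease[order(ranked$rank)], c("d2", "d3", "d1"))
  # permuting the input leaves the ranking unchanged (total order)
  perm <- tab[c(3, 1, 2), ]
  expect_equal(rank_inferences(perm)$disease[order(rank_inferences(perm)$rank)],
               c("d2", "d3", "d1"))
})

test_that("ranking matches an independent stable-sort oracle", {
  set.seed(41)
  net <- random_network(12, 25, 8, p = 0.15, seed = 41)
  sc <- score_inferences(net)
  ranked <- rank_inferences(sc, sort_score = "w_xya")
  for (chem in unique(sc$chemical)) {
    sub <- sc[sc$chemical == chem, ]
    o <- order(-sub$curated, -sub$w_xya, -sub$m, sub$disease)
    expect_equal(ranked$disease[ranked$chemical == chem][order(ranked$rank[ranked$chemical == chem])],
                 sub$disease[o])
  }
  expect_error(rank_inferences(sc, sort_score = "nope"), "unknown statistic")
})

test_that("tie counting matches the worked examples", {
  tab <- make_score_table(
    chemical = "A", disease = c("d1", "d2", "d3"),
    m = 1L, curated = FALSE, c_xy = 0, p1 = 0, p2 = 0,
    s_xya = c(3.00, 3.00, 5.00), w_xya = 0, w_bonferroni = 0
  )
  ties <- count_ties(tab, "s_xya")
  expect_equal(ties$n_tied_inferences, 2L)
  expect_equal(ties$n_chemicals_with_ties, 1L)
  distinct_tab <- dplyr::mutate(tab, s_xya = c(1, 2, 3))
  expect_equal(count_ties(distinct_tab, "s_xya")$n_tied_inferences, 0L)
})

test_that("display-rounding ties dominate numeric ties", {
  set.seed(43)
  tab <- make_score_table(
    chemical = rep(c("A", "B"), each = 25),
    disease = paste0("d", 1:50), m = 1L, curated = FALSE,
    c_xy = 0, p1 = 0, p2 = 0,
    s_xya = round(runif(50, 0, 3), 2) + sample(c(0, 1e-12), 50, replace = TRUE),
    w_xya = 0, w_bonferroni = 0
  )
  disp <- count_ties(tab, "s_xya", "exact_display")
  num <- count_ties(tab, "s_xya", "numeric")
  expect_gte(disp$n_tied_inferences, num$n_tied_inferences)
})

test_that("median-threshold classifier follows its definition", {
  res <- median_threshold_classifier(c(1, 2, 3), c(0, 2.5, 5))
  expect_equal(res$threshold, 2)
  expect_equal(res$novel_above_fraction, 2 / 3)
  expect_equal(res$curated_sensitivity, 1 / 3)
  # even n: mean of the middle two
  expect_equal(median_threshold_classifier(c(1, 2, 3, 4), 5)$threshold, 2.5)
  # all-equal curated scores: zero sensitivity under strict inequality
  expect_equal(median_threshold_classifier(rep(2, 5), c(1, 3))$curated_sensitivity, 0)
  expect_error(median_threshold_classifier(numeric(), 1), "non-empty")
})

test_that("classifier separates distributions with the reported moments", {
  # curated and novel scores drawn with the published means/sds (truncated
  # at zero); the novel fraction above the curated median stays below 1/2
  set.seed(47)
  curated <- pmax(0, rnorm(1e4, 12.46, 17.85))
  novel <- pmax(0, rnorm(1e4, 5.81, 3.76))
  res <- median_threshold_classifier(curated, novel)
  expect_equal(res$curated_sensitivity, 0.5, tolerance = 0.02)
  # under the normal approximation the expected fraction is
  # pnorm((5.81 - 12.46) / 3.76) ~= 0.04: well below one half, above zero
  expect_lt(res$novel_above_fraction, 0.5)
  expect_gt(res$novel_above_fraction, 0.01)
})

test_that("top-k curated overlap counts by pure score order", {
  tab <- make_score_table(
    chemical = "A", disease = paste0("d", 1:10),
    m = 1L, curated = c(rep(TRUE, 4), rep(FALSE, 6)),
    c_xy = 0, p1 = 0, p2 = 0, s_xya = 0,
    w_xya = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), w_bonferroni = 0
  )
  expect_equal(top_k_curated_overlap(tab, 5), 4L)
  expect_error(top_k_curated_overlap(tab, 0), "at least 1")
  expect_warning(res <- top_k_curated_overlap(tab, 99), "exceeds")
  expect_equal(res, 4L)
})
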