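test_that("log_choose handles small and large arguments", {
  expect_equal(log_choose(5, 2), log(10))
  expect_equal(log_choose(c(10, 1000), 0), c(0, 0))
  # frozen from an exact big-integer computation
  expect_equal(log_choose(1000, 400), 669.352145125545, tolerance = 1e-12)
  expect_error(log_choose(3, 4), "exceed")
  expect_error(log_choose(-1, 0), "non-negative")
})

test_that("c_xy reproduces exact small-case tail probabilities", {
  expect_equal(c_xy(2, 2, 0, 4), 0)                      # certain event
  expect_equal(c_xy(2, 2, 2, 4), -log10(1 / 6), tolerance = 1e-12)
  expect_equal(c_xy(7, 5, 3, 20), 0.68448024168856, tolerance = 1e-10)
  expect_error(c_xy(2, 2, 3, 10), "min")
  expect_error(c_xy(5, 2, 1, 5), "exceed")
})

test_that("p1 reproduces exact point probabilities and dominates c_xy", {
  expect_equal(p1_score(3, 3, 2, 6), -log10(9 / 20), tolerance = 1e-12)
  expect_equal(p1_score(7, 5, 3, 20), 0.75428111266593, tolerance = 1e-10)
  set.seed(31)
  for (i in 1:50) {
    x <- random_score_inputs()
    expect_gte(p1_score(x$n_x, x$n_y, x$m, x$N) + 1e-12,
               c_xy(x$n_x, x$n_y, x$m, x$N))
  }
})

test_that("p2 matches the exact rational value and is additive over gene sets", {
  expect_equal(p2_score(7, 50), 1.76591679396663, tolerance = 1e-10)
  expect_equal(p2_score(c(4, 9), 100),
               -log10((4 * 3 / (100 * 99)) * (9 * 8 / (100 * 99))),
               tolerance = 1e-12)
  set.seed(17)
  for (i in 1:25) {
    N <- sample(100:400, 1)
    a <- sample(2:50, sample(1:4, 1), replace = TRUE)
    b <- sample(2:50, sample(1:4, 1), replace = TRUE)
    expect_equal(p2_score(c(a, b), N), p2_score(a, N) + p2_score(b, N),
                 tolerance = 1e-10)
  }
  expect_error(p2_score(c(5, 1), 50), ">= 2")
  expect_error(p2_score(integer(), 50), "non-empty")
})

test_that("opinion pool identities hold", {
  expect_equal(opinion_pool(17.30, 40.32, pool_weights("equal")), 28.81)
  expect_equal(opinion_pool(0, 0, pool_weights("equal")), 0)
  set.seed(2)
  a <- runif(20, 0, 50); b <- runif(20, 0, 50)
  expect_equal(s_score(a, b), (a + b) / 2)
  expect_equal(s_score(a, a), a)
  expect_error(opinion_pool(1, 2, list(w1 = -0.1, w2 = 0.5)), "non-negative")
})

test_that("m-weighted pool shifts weight onto p1 as the gene count grows", {
  w <- purrr::map(1:12, \(m) pool_weights("m_weighted", m))
  w1 <- purrr::map_dbl(w, "w1"); w2 <- purrr::map_dbl(w, "w2")
  expect_true(all(diff(w1) > 0))
  expect_true(all(diff(w2) < 0))
  expect_equal(w1 + w2, rep(1, 12))
  expect_error(w_score(1, 2, 0), ">= 1")
  # with p2 > p1, growing m pulls W towards p1
  ws <- purrr::map_dbl(1:12, \(m) w_score(5, 30, m))
  expect_true(all(diff(ws) < 0))
  expect_true(all(ws > 5))
})

test_that("Bonferroni correction caps at probability one", {
  expect_equal(bonferroni_correct(10, 100), 8)
  expect_equal(bonferroni_correct(1, 100), 0)
  expect_equal(bonferroni_correct(3.30103, 2), 3.0, tolerance = 1e-5)
  expect_error(bonferroni_correct(5, 0), "at least 1")
  set.seed(8)
  s <- runif(50, 0, 20); n <- sample(1:1e6, 50)
  expect_true(all(bonferroni_correct(s, n) <= s))
  expect_equal(bonferroni_correct(s, 1), s)
})

test_that("geometric mean degree matches closed form", {
  expect_equal(geometric_mean_degree(c(4, 9)), 6)
  expect_error(geometric_mean_degree(numeric()), "non-empty")
  expect_error(geometric_mean_degree(c(3, 0)), ">= 1")
})

test_that("statistics agree with the Pascal-triangle oracle to 1e-9 relative", {
  choose_fun <- pascal_choose(500L)
  set.seed(99)
  for (i in 1:60) {
    x <- random_score_inputs()
    ref <- oracle_stats(x$n_x, x$n_y, x$m, x$N, x$gene_degrees, choose_fun)
    expect_equal(c_xy(x$n_x, x$n_y, x$m, x$N), ref$c_xy, tolerance = 1e-9)
    expect_equal(p1_score(x$n_x, x$n_y, x$m, x$N), ref$p1, tolerance = 1e-9)
    expect_equal(p2_score(x$gene_degrees, x$N), ref$p2, tolerance = 1e-9)
  }
})

test_that("hub endpoints are penalised and shared genes rewarded", {
  set.seed(55)
  for (i in 1:40) {
    x <- random_score_inputs()
    # c_xy decreases as an endpoint degree grows at fixed m, N
    if (x$n_x + 5L < x$N %/% 5L) {
      expect_lt(c_xy(x$n_x + 5L, x$n_y, x$m, x$N),
                c_xy(x$n_x, x$n_y, x$m, x$N))
    }
    # c_xy and p1 non-decreasing in m (sparse regime: mode below m)
    if (x$m + 1L <= min(x$n_x, x$n_y)) {
      expect_gte(c_xy(x$n_x, x$n_y, x$m + 1L, x$N),
                 c_xy(x$n_x, x$n_y, x$m, x$N))
      expect_gte(p1_score(x$n_x, x$n_y, x$m + 1L, x$N) + 1e-12,
                 p1_score(x$n_x, x$n_y, x$m, x$N))
    }
    # p2 strictly decreasing when any gene degree grows
    gd <- x$gene_degrees
    j <- sample(length(gd), 1)
    if (gd[j] + 1L < x$N) {
      gd2 <- gd; gd2[j] <- gd2[j] + 1L
      expect_lt(p2_score(gd2, x$N), p2_score(gd, x$N))
    }
  }
})
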