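#' Log binomial coefficient
#'
#' Natural-log binomial coefficient computed through the log-gamma function,
#' so that the factorials of network-scale arguments (tens of thousands of
#' nodes, degrees in the hundreds) never overflow.
#'
#' @param n,r Non-negative integer vectors (recycled), with `r <= n`.
#' @return `log(choose(n, r))` as a numeric vector.
#' @examples
#' log_choose(5, 2)  # log(10)
#' @export
log_choose <- function(n, r) {
  if (any(n < 0 | r < 0)) abort("`n` and `r` must be non-negative")
  if (any(r > n)) abort("`r` must not exceed `n`")
  lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
}

# log10 binomial coefficient
l10_choose <- function(n, r) log_choose(n, r) / log(10)

# numerically stable log10(sum(10^x))
l10_sum_exp <- function(x) {
  mx <- max(x)
  mx + log10(sum(10^(x - mx)))
}

# log10 hypergeometric pmf: P(overlap == m) for degrees n_x, n_y among N nodes
l10_hyper_pmf <- function(n_x, n_y, m, N) {
  l10_choose(n_x, m) + l10_choose(N - n_x, n_y - m) - l10_choose(N, n_y)
}

# shared validation for the degree/count tuple feeding the statistics
validate_score_inputs <- function(n_x, n_y, m, N, gene_degrees = NULL,
                                  allow_m0 = FALSE) {
  lo <- if (allow_m0) 0L else 1L
  if (any(m < lo) || any(m > pmin(n_x, n_y))) {
    abort("`m` must satisfy 1 <= m <= min(n_x, n_y)")
  }
  if (any(N <= pmax(n_x, n_y))) {
    abort("`N` must exceed both endpoint degrees")
  }
  if (!is.null(gene_degrees)) {
    if (length(gene_degrees) != m) {
      abort("`gene_degrees` must have exactly `m` entries")
    }
    if (any(gene_degrees < 2)) {
      abort("every connecting gene must have degree >= 2 (it touches both endpoints)")
    }
    if (any(N <= gene_degrees)) abort("`N` must exceed every gene degree")
  }
  invisible(TRUE)
}

#' Hypergeometric mutual clustering coefficient
#'
#' The probability that a chemical with `n_x` edges and a disease with `n_y`
#' edges share at least `m` neighbours by chance, when neighbourhoods are
#' uniform random subsets of the `N` connected nodes, reported as
#' `-log10`. The upper tail runs from `m` to `min(n_x, n_y)`, the largest
#' combinatorially possible overlap. Hub endpoints make large overlaps
#' likely, so the statistic discounts them.
#'
#' @param n_x,n_y Total degrees of the two endpoints.
#' @param m Observed number of shared neighbours (`m = 0` is allowed here
#'   and gives 0: an overlap of at least zero is certain).
#' @param N Network size, from [network_size()].
#' @return `-log10` tail probability (vectorised over the inputs).
#' @examples
#' c_xy(2, 2, 2, 4)  # -log10(1/6)
#' @export
c_xy <- function(n_x, n_y, m, N) {
  validate_score_inputs(n_x, n_y, m, N, allow_m0 = TRUE)
  args <- vctrs_recycle(n_x, n_y, m, N)
  purrr::pmap_dbl(args, function(n_x, n_y, m, N) {
    if (m == 0) return(0)
    i <- m:min(n_x, n_y)
    -l10_sum_exp(l10_hyper_pmf(n_x, n_y, i, N))
  })
}

# recycle scalar/vector arguments to common length, as a list of vectors
vctrs_recycle <- function(n_x, n_y, m, N) {
  len <- max(length(n_x), length(n_y), length(m), length(N))
  list(n_x = rep_len(n_x, len), n_y = rep_len(n_y, len),
       m = rep_len(m, len), N = rep_len(N, len))
}

#' Endpoint common-neighbour statistic
#'
#' The probability of observing exactly `m` common neighbours for endpoints
#' of degree `n_x` and `n_y` among `N` nodes (the hypergeometric point
#' probability), as `-log10`. It uses the endpoint degrees and the count of
#' shared genes but not the genes' own connectivity.
#'
#' Because the point probability can never exceed the upper tail that
#' contains it, `p1_score() >= c_xy()` on any valid input.
#'
#' @inheritParams c_xy
#' @param m Number of shared neighbours, at least 1.
#' @return `-log10` probability (vectorised).
#' @examples
#' p1_score(3, 3, 2, 6)  # -log10(9/20)
#' @export
p1_score <- function(n_x, n_y, m, N) {
  validate_score_inputs(n_x, n_y, m, N)
  args <- vctrs_recycle(n_x, n_y, m, N)
  -l10_hyper_pmf(args$n_x, args$n_y, args$m, args$N)
}

#' Gene-degree common-neighbour statistic
#'
#' The probability that every gene in the connecting set `A` is linked to
#' both endpoints by chance, given each gene's own degree: a gene with
#' `n_i` edges, wired to a uniform random neighbourhood, hits two fixed
#' nodes with probability `n_i (n_i - 1) / (N (N - 1))`. The statistic is
#' the `-log10` of the product over `A`, hence additive over disjoint gene
#' subsets, and is the only one of the five that penalises hub *genes*.
#'
#' @param gene_degrees Integer vector of connecting-gene degrees (each at
#'   least 2, since a connecting gene touches both endpoints).
#' @param N Network size.
#' @return A single `-log10` probability.
#' @examples
#' p2_score(c(4, 9), N = 100)
#' @export
p2_score <- function(gene_degrees, N) {
  if (!length(gene_degrees)) abort("`gene_degrees` must be non-empty")
  if (any(gene_degrees < 2)) {
    abort("every connecting gene must have degree >= 2 (it touches both endpoints)")
  }
  if (any(N <= gene_degrees)) abort("`N` must exceed every gene degree")
  sum(log10(N) + log10(N - 1) - log10(gene_degrees) - log10(gene_degrees - 1))
}

#' Logarithmic opinion pool of the two common-neighbour statistics
#'
#' Aggregates the two `-log10` probabilities as a weighted product of the
#' underlying probabilities (with normalisation constant `k = 1`), which on
#' the log scale is simply `w1 * p1 + w2 * p2`.
#'
#' `pool_weights()` constructs the weight pair: `"equal"` gives
#' `w1 = w2 = 1/2` (the aggregate statistic `S_XYA`); `"m_weighted"` gives
#' the gene-count-dependent pair used by `W_XYA`, where
#' `w2(m) = (1 - 1/sqrt(2)) / 2^m` and `w1 = 1 - w2`: the more genes
#' support an inference, the more weight shifts onto the endpoint statistic
#' `p1`, preventing the gene-degree term from dominating inferences backed
#' by many genes.
#'
#' @param p1,p2 The two `-log10` statistics.
#' @param weights A list with elements `w1`, `w2` as returned by
#'   [pool_weights()].
#' @return The pooled `-log10` score (vectorised).
#' @examples
#' opinion_pool(17.30, 40.32, pool_weights("equal"))  # 28.81
#' @export
opinion_pool <- function(p1, p2, weights) {
  if (!is.list(weights) || !all(c("w1", "w2") %in% names(weights))) {
    abort("`weights` must be a list with elements `w1` and `w2`")
  }
  if (any(weights$w1 < 0) || any(weights$w2 < 0)) {
    abort("pool weights must be non-negative")
  }
  weights$w1 * p1 + weights$w2 * p2
}

#' @rdname opinion_pool
#' @param mode `"equal"` or `"m_weighted"`.
#' @param m Connecting-gene count, required for `"m_weighted"`.
#' @export
pool_weights <- function(mode = c("equal", "m_weighted"), m = NULL) {
  mode <- rlang::arg_match(mode)
  if (mode == "equal") return(list(w1 = 0.5, w2 = 0.5))
  if (is.null(m) || any(m < 1)) abort("`m` must be >= 1 for m-weighted pooling")
  w2 <- (1 - 1 / sqrt(2)) * 2^(-m)
  list(w1 = 1 - w2, w2 = w2)
}

#' Aggregate scores S and W
#'
#' `s_score()` is the equal-weight opinion pool, the arithmetic mean of the
#' two component statistics on the `-log10` scale. `w_score()` is the
#' m-weighted pool (see [pool_weights()]); as `m` grows its weight on the
#' endpoint statistic approaches 1.
#'
#' @inheritParams opinion_pool
#' @param m Connecting-gene count (`w_score()` only), at least 1.
#' @return The pooled score (vectorised).
#' @examples
#' s_score(17.30, 40.32)      # 28.81
#' w_score(17.30, 40.32, 9)
#' @export
s_score <- function(p1, p2) {
  opinion_pool(p1, p2, pool_weights("equal"))
}

#' @rdname s_score
#' @export
w_score <- function(p1, p2, m) {
  opinion_pool(p1, p2, pool_weights("m_weighted", m = m))
}

#' Bonferroni correction on the -log10 scale
#'
#' Multiplies the underlying probability by the number of tests and caps it
#' at 1, i.e. `max(0, score - log10(n_tests))`.
#'
#' @param score A `-log10` score (vectorised).
#' @param n_tests Number of inferences scored in the family (at least 1).
#' @return The corrected `-log10` score; never exceeds `score`.
#' @examples
#' bonferroni_correct(10, 100)  # 8
#' @export
bonferroni_correct <- function(score, n_tests) {
  if (any(n_tests < 1)) abort("`n_tests` must be at least 1")
  if (any(score < 0)) abort("`score` must be non-negative")
  pmax(0, score - log10(n_tests))
}

#' Geometric mean of node degrees
#'
#' Companion diagnostic for a gene set's overall connectivity; inference
#' networks built from low-degree genes have small geometric mean degree
#' and score high on the gene-degree statistic.
#'
#' @param degrees Positive numeric vector of degrees.
#' @return `exp(mean(log(degrees)))`.
#' @examples
#' geometric_mean_degree(c(4, 9))  # 6
#' @export
geometric_mean_degree <- function(degrees) {
  if (!length(degrees)) abort("`degrees` must be non-empty")
  if (any(degrees < 1)) abort("all degrees must be >= 1")
  exp(mean(log(degrees)))
}
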