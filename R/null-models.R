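#' Degree-preserving shuffle of the chemical-gene layer
#'
#' Randomises which genes each chemical interacts with while exactly
#' preserving every node's chemical-gene degree, by repeated pairwise edge
#' swaps: two edges (c1, g1) and (c2, g2) are drawn at random and their
#' genes exchanged, giving (c1, g2) and (c2, g1). Because each node keeps
#' its edge count, the scale-free degree distribution survives while the
#' specific co-association structure is destroyed. The gene-disease and
#' chemical-disease layers are untouched.
#'
#' A proposed swap that would duplicate an existing edge, or that involves
#' two edges sharing a chemical or a gene (which would either create a
#' duplicate or change nothing), is rejected and redrawn without counting
#' towards `n_swaps`; only applied swaps count, so mixing depth is
#' comparable across network densities.
#'
#' @param net A [tripartite_network()] with at least 2 chemical-gene edges.
#' @param n_swaps Number of applied swaps.
#' @param seed Optional integer seed for reproducibility.
#' @return A new `tripartite_network` with the shuffled layer; attributes
#'   `shuffle_applied`, `shuffle_attempted` and `shuffle_seed` record the
#'   run.
#' @examples
#' net <- make_fixture("toy_triangle")$network
#' shuf <- shuffle_network(net, n_swaps = 2, seed = 1)
#' @export
shuffle_network <- function(net, n_swaps = 1e6, seed = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  edges <- net$chem_gene
  if (nrow(edges) < 2L) abort("shuffling needs at least 2 chemical-gene edges")
  if (!is.null(seed)) set.seed(seed)

  chems <- sort(unique(edges$chemical))
  genes <- sort(unique(edges$gene))
  ci <- match(edges$chemical, chems)
  gi <- match(edges$gene, genes)
  ng <- length(genes)
  # O(1) membership test; index kept in double to avoid integer overflow
  has <- logical(length(chems) * ng)
  key <- function(c, g) (c - 1) * ng + g
  has[key(ci, gi)] <- TRUE

  n_edges <- length(ci)
  applied <- 0L
  attempted <- 0L
  max_attempts <- max(1e4, 200 * n_swaps)
  while (applied < n_swaps) {
    attempted <- attempted + 1L
    if (attempted > max_attempts) {
      abort("shuffle stalled: network too constrained to realise the requested swaps")
    }
    e <- sample.int(n_edges, 2L)
    c1 <- ci[e[1L]]; g1 <- gi[e[1L]]
    c2 <- ci[e[2L]]; g2 <- gi[e[2L]]
    if (c1 == c2 || g1 == g2) next
    if (has[key(c1, g2)] || has[key(c2, g1)]) next
    has[key(c1, g1)] <- FALSE
    has[key(c2, g2)] <- FALSE
    has[key(c1, g2)] <- TRUE
    has[key(c2, g1)] <- TRUE
    gi[e[1L]] <- g2
    gi[e[2L]] <- g1
    applied <- applied + 1L
  }

  out <- tripartite_network(
    chem_gene = tibble(chemical = chems[ci], gene = genes[gi]),
    gene_disease = net$gene_disease,
    chem_disease = net$chem_disease,
    nodes = net$nodes
  )
  attr(out, "shuffle_applied") <- applied
  attr(out, "shuffle_attempted") <- attempted
  attr(out, "shuffle_seed") <- seed
  out
}

#' @rdname shuffle_network
#' @param n_replicates Number of independent shuffled replicates.
#' @return `shuffle_replicates()`: a list of shuffled networks, seeded
#'   `seed + 0:(n_replicates-1)`.
#' @export
shuffle_replicates <- function(net, n_swaps = 1e6, n_replicates = 3L,
                               seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), n_replicates) else seed + seq_len(n_replicates) - 1L
  purrr::map(seq_len(n_replicates), \(i) shuffle_network(net, n_swaps, seeds[[i]]))
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t-test with the Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, as used to compare score distributions between real
#' and shuffled networks. Thin wrapper over [stats::t.test()] returning a
#' tidy one-row tibble.
#'
#' @param sample_a,sample_b Numeric vectors of length at least 2; at least
#'   one must have nonzero variance.
#' @return A tibble with `t_statistic`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs at least 2 observations")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      return(tibble(t_statistic = 0, df = NA_real_, p_value = 1))
    }
    abort("both samples are constant; Welch's test is undefined")
  }
  fit <- t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(t_statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value)
}

#' Compare real and shuffled inference scores
#'
#' Matches inferences between a real and a shuffled score table on the
#' (chemical, disease) identifier pair — gene sets may differ — and, within
#' each stratum (curated, novel, and total), reports the mean score
#' difference (real minus shuffled) over matched pairs together with a
#' Welch's t-test comparing the matched score samples. A positive mean
#' difference indicates that inferences in the real network score higher
#' than the same chemical-disease pairs re-derived after degree-preserving
#' randomisation.
#'
#' @param real_scores,shuffled_scores Tibbles from [score_inferences()].
#' @param statistic Score column compared (default `"w_xya"`).
#' @param paired Use a paired t-test on the matched differences instead of
#'   the two-sample Welch test.
#' @return A tibble of class `shuffle_comparison`, one row per stratum:
#'   `stratum`, `n_real`, `n_shuffled`, `n_matching`, `mean_difference`,
#'   `t_statistic`, `p_value`, `test_defined`. An empty intersection is
#'   flagged (`test_defined = FALSE`, statistics `NA`), never silently zero.
#' @export
compare_real_vs_shuffled <- function(real_scores, shuffled_scores,
                                     statistic = "w_xya", paired = FALSE) {
  for (tab in list(real_scores, shuffled_scores)) {
    if (!statistic %in% names(tab)) {
      abort(sprintf("score column '%s' not present", statistic))
    }
  }
  key <- names(real_scores)[c(1L, 2L)]
  matched <- inner_join(
    select(real_scores, dplyr::all_of(c(key, "curated", statistic))),
    select(shuffled_scores, dplyr::all_of(c(key, statistic))),
    by = key, suffix = c("_real", "_shuffled")
  )
  if (nrow(matched) == 0L) {
    warn("no matching inferences between the real and shuffled tables")
  }
  real_col <- paste0(statistic, "_real")
  shuf_col <- paste0(statistic, "_shuffled")

  one_stratum <- function(stratum) {
    keep_real <- switch(stratum, total = rep(TRUE, nrow(real_scores)),
                        curated = real_scores$curated, novel = !real_scores$curated)
    keep_shuf <- switch(stratum, total = rep(TRUE, nrow(shuffled_scores)),
                        curated = shuffled_scores$curated, novel = !shuffled_scores$curated)
    keep_m <- switch(stratum, total = rep(TRUE, nrow(matched)),
                     curated = matched$curated, novel = !matched$curated)
    sub <- matched[keep_m, , drop = FALSE]
    a <- sub[[real_col]]; b <- sub[[shuf_col]]
    defined <- nrow(sub) >= 2L && (stats::var(a) > 0 || stats::var(b) > 0)
    test <- if (!defined) {
      tibble(t_statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    } else if (paired) {
      fit <- t.test(a, b, paired = TRUE)
      tibble(t_statistic = unname(fit$statistic), df = unname(fit$parameter),
             p_value = fit$p.value)
    } else {
      welch_t_test(a, b)
    }
    tibble(
      stratum = stratum,
      n_real = sum(keep_real), n_shuffled = sum(keep_shuf),
      n_matching = nrow(sub),
      mean_difference = if (nrow(sub)) mean(a - b) else NA_real_,
      t_statistic = test$t_statistic, p_value = test$p_value,
      test_defined = defined
    )
  }
  out <- bind_rows(purrr::map(c("curated", "novel", "total"), one_stratum))
  class(out) <- c("shuffle_comparison", class(out))
  attr(out, "statistic") <- statistic
  out
}

#' @exportS3Method generics::glance
glance.shuffle_comparison <- function(x, ...) {
  tot <- x[x$stratum == "total", ]
  tibble(n_matching = tot$n_matching, mean_difference = tot$mean_difference,
         p_value = tot$p_value, statistic = attr(x, "statistic"))
}
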