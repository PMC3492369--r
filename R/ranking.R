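#' Rank scored inferences within chemicals or diseases
#'
#' Orders the inferences of each group the way the score is meant to be
#' consumed: curated relationships first, then descending chosen score.
#' Remaining ties are broken by larger `m`, then by partner identifier, so
#' the ranking is a deterministic total order; `rank` is the 1-based
#' position within the group.
#'
#' @param scores Tibble from [score_inferences()] (non-empty).
#' @param group_by `"chemical"` or `"disease"`: the entity whose inference
#'   list is being ranked.
#' @param sort_score Statistic used for ordering: one of `"c_xy"`, `"p1"`,
#'   `"p2"`, `"s_xya"`, `"w_xya"`, `"w_bonferroni"`.
#' @return The input tibble with a `rank` column, arranged by group and
#'   rank.
#' @export
rank_inferences <- function(scores, group_by = c("chemical", "disease"),
                            sort_score = "w_xya") {
  if (!nrow(scores)) abort("`scores` must be non-empty")
  group_by <- rlang::arg_match(group_by)
  check_statistic(scores, sort_score)
  key <- names(scores)[c(1L, 2L)]
  grp <- if (group_by == "chemical") key[1L] else key[2L]
  partner <- setdiff(key, grp)
  scores |>
    group_by(dplyr::pick(dplyr::all_of(grp))) |>
    arrange(desc(.data$curated), desc(.data[[sort_score]]), desc(.data$m),
            .data[[partner]], .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}

check_statistic <- function(scores, statistic) {
  valid <- intersect(c("c_xy", "p1", "p2", "s_xya", "w_xya", "w_bonferroni"),
                     names(scores))
  if (!statistic %in% valid) {
    abort(sprintf("unknown statistic '%s'; available: %s", statistic,
                  paste(valid, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Count tied inferences per chemical
#'
#' A row counts as tied when another inference of the same chemical has an
#' equal value of the chosen statistic. Statistics that ignore gene
#' identity (the clustering coefficient and the endpoint statistic) tie
#' whenever two diseases have the same degree and gene count; the
#' aggregate scores, which see the gene degrees, tie far less often —
#' fewer ties means more usable rankings.
#'
#' @param scores Tibble from [score_inferences()].
#' @param statistic Score column to examine.
#' @param tolerance_mode `"exact_display"` counts equality after rounding
#'   to the 2-decimal display precision; `"numeric"` counts values within
#'   `1e-9` of each other.
#' @return A one-row tibble: `statistic`, `n_tied_inferences`,
#'   `n_chemicals_with_ties`.
#' @export
count_ties <- function(scores, statistic = "s_xya",
                       tolerance_mode = c("exact_display", "numeric")) {
  tolerance_mode <- rlang::arg_match(tolerance_mode)
  if (!nrow(scores)) {
    return(tibble(statistic = statistic, n_tied_inferences = 0L,
                  n_chemicals_with_ties = 0L))
  }
  check_statistic(scores, statistic)
  chem_col <- names(scores)[1L]
  vals <- scores[[statistic]]
  tied <- logical(nrow(scores))
  for (idx in split(seq_len(nrow(scores)), scores[[chem_col]])) {
    v <- vals[idx]
    in_tie <- if (tolerance_mode == "exact_display") {
      r <- round(v, 2)
      r %in% r[duplicated(r)]
    } else {
      # cluster sorted values whose successive gaps are <= 1e-9
      o <- order(v)
      grp <- cumsum(c(0, diff(v[o]) > 1e-9))
      sizes <- table(grp)
      (sizes[as.character(grp)] > 1)[order(o)]
    }
    tied[idx] <- in_tie
  }
  tibble(
    statistic = statistic,
    n_tied_inferences = sum(tied),
    n_chemicals_with_ties = dplyr::n_distinct(scores[[chem_col]][tied])
  )
}

#' Median-threshold classifier for novel inferences
#'
#' Flags the novel inferences most like curated ones: the threshold is the
#' median weighted score of the curated inferences, and a novel inference
#' passes when its score is strictly greater. Applied back to the curated
#' scores themselves, a strict threshold at the median gives a sensitivity
#' of one half by construction (for odd-sized samples of distinct values).
#'
#' @param curated_w Non-empty numeric vector of curated-inference scores.
#' @param novel_w Numeric vector of novel-inference scores.
#' @return A one-row tibble: `threshold`, `novel_above_fraction`,
#'   `curated_sensitivity`, `n_curated`, `n_novel`.
#' @examples
#' median_threshold_classifier(c(1, 2, 3), c(0, 2.5, 5))
#' @export
median_threshold_classifier <- function(curated_w, novel_w) {
  if (!length(curated_w)) abort("`curated_w` must be non-empty")
  thr <- median(curated_w)
  tibble(
    threshold = thr,
    novel_above_fraction = if (length(novel_w)) mean(novel_w > thr) else NA_real_,
    curated_sensitivity = mean(curated_w > thr),
    n_curated = length(curated_w),
    n_novel = length(novel_w)
  )
}

#' Curated inferences among the global top k
#'
#' Counts how many of the k best-scoring inferences (pure score order,
#' ignoring the curated-first display rule) carry independent curated
#' support — the enrichment read-out used to compare aggregate statistics.
#'
#' @param scores Tibble from [score_inferences()].
#' @param k Number of top rows to inspect (`k >= 1`); when `k` exceeds the
#'   table size the whole table is used, with a warning.
#' @param statistic Score column used for ordering.
#' @return Integer count of curated rows among the top `k`.
#' @export
top_k_curated_overlap <- function(scores, k, statistic = "w_xya") {
  if (k < 1) abort("`k` must be at least 1")
  check_statistic(scores, statistic)
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds table size %d; using all rows", k, nrow(scores)))
    k <- nrow(scores)
  }
  key <- names(scores)[c(1L, 2L)]
  top <- scores |>
    arrange(desc(.data[[statistic]]), .data[[key[1L]]], .data[[key[2L]]]) |>
    head(k)
  sum(top$curated)
}
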