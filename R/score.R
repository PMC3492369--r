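#' Score an inference table against its network
#'
#' Assembles, for every inference, the degree/count tuple
#' `(n_x, n_y, m, N, {n_i})` from the network's degree index and evaluates
#' all five topology statistics plus the Bonferroni-corrected weighted
#' score. Degrees are total degrees pooled over the three layers.
#'
#' @param net A [tripartite_network()].
#' @param inferences Tibble from [enumerate_inferences()]; enumerated from
#'   `net` when `NULL`.
#' @param n_override Optional integer replacing [network_size()] as the
#'   universe size `N`. The published reference scores depend on the exact
#'   database snapshot behind `N`, so analyses that must match an external
#'   run can pin it explicitly.
#' @param n_tests Bonferroni family size; defaults to the number of
#'   inferences scored in this run.
#' @return A tibble: the inference key columns plus `m`, `curated`, `c_xy`,
#'   `p1`, `p2`, `s_xya`, `w_xya`, `w_bonferroni`.
#' @examples
#' net <- make_fixture("toy_triangle")$network
#' score_inferences(net)
#' @export
score_inferences <- function(net, inferences = NULL, n_override = NULL,
                             n_tests = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  if (is.null(inferences)) inferences <- enumerate_inferences(net)
  key <- names(inferences)[c(1L, 2L)]
  via_col <- names(inferences)[5L]
  n_tests <- n_tests %||% max(1L, nrow(inferences))
  N <- n_override %||% network_size(net)

  if (!nrow(inferences)) {
    return(tibble(!!key[1L] := character(), !!key[2L] := character(),
                  m = integer(), curated = logical(), c_xy = double(),
                  p1 = double(), p2 = double(), s_xya = double(),
                  w_xya = double(), w_bonferroni = double()))
  }

  n_x <- net_degree(net, inferences[[1L]])
  n_y <- net_degree(net, inferences[[2L]])
  rows <- purrr::pmap(
    list(inferences[[1L]], inferences[[2L]], n_x, n_y,
         inferences$m, inferences[[via_col]]),
    function(src, tgt, n_x, n_y, m, via) {
      tryCatch({
        gd <- net_degree(net, via)
        p1 <- p1_score(n_x, n_y, m, N)
        p2 <- p2_score(gd, N)
        tibble(
          c_xy = c_xy(n_x, n_y, m, N), p1 = p1, p2 = p2,
          s_xya = s_score(p1, p2), w_xya = w_score(p1, p2, m)
        )
      }, error = function(e) {
        abort(sprintf("scoring inference %s ~ %s failed: %s",
                      src, tgt, conditionMessage(e)))
      })
    }
  )
  dplyr::bind_cols(
    inferences[, c(key, "m", "curated")],
    bind_rows(rows)
  ) |>
    mutate(w_bonferroni = bonferroni_correct(.data$w_xya, n_tests))
}

#' Write or read a score table as TSV
#'
#' @param scores Tibble from [score_inferences()].
#' @param path File path.
#' @param display Round statistics to 2 decimals for display (the internal
#'   representation is always full precision; comparisons should use the
#'   full-precision variant).
#' @return `write_score_table()`: `path`, invisibly; `read_score_table()`:
#'   the tibble.
#' @export
write_score_table <- function(scores, path, display = FALSE) {
  if (display) {
    scores <- mutate(scores, across(dplyr::where(is.double), \(x) round(x, 2)))
  }
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' End-to-end scoring run
#'
#' Load the three association files, enumerate inferences, score them, and
#' write the score table plus a small run manifest (seed, `N`, family size,
#' package version) to `out_dir`.
#'
#' @inheritParams load_network
#' @inheritParams score_inferences
#' @param out_dir Output directory.
#' @param seed Optional integer seed recorded in the manifest (the scoring
#'   path itself is deterministic).
#' @return The score table, invisibly.
#' @export
run_score <- function(chem_gene_path, gene_disease_path, chem_disease_path,
                      out_dir, dialect = "pairs", col_map = NULL,
                      n_override = NULL, n_tests = NULL, seed = NULL,
                      quiet = FALSE) {
  net <- load_network(chem_gene_path, gene_disease_path, chem_disease_path,
                      dialect = dialect, col_map = col_map, quiet = quiet)
  inf <- enumerate_inferences(net)
  scores <- score_inferences(net, inf, n_override = n_override,
                             n_tests = n_tests)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_score_table(scores, file.path(out_dir, "scores.tsv"))
  manifest <- c(
    sprintf("cdscore_version: %s", as.character(utils::packageVersion("cdscore"))),
    sprintf("N: %d", n_override %||% network_size(net)),
    sprintf("n_tests: %d", (n_tests %||% max(1L, nrow(inf)))),
    sprintf("n_inferences: %d", nrow(inf)),
    sprintf("seed: %s", if (is.null(seed)) "none" else as.character(seed))
  )
  writeLines(manifest, file.path(out_dir, "manifest.dcf"))
  invisible(scores)
}
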