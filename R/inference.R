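#' Enumerate transitive inferences
#'
#' A transitive chemical-disease inference exists wherever a chemical
#' interacts with one or more genes that are also associated with a disease.
#' The connecting genes form the set `A` of the inference, of size `m`. An
#' inference is *curated* when the chemical-disease pair additionally has a
#' direct association edge; curated inferences are still enumerated and
#' scored — the flag records independent support, it does not filter.
#'
#' In `gene_disease` mode the roles rotate: a gene-disease inference is made
#' when one or more chemicals interact with the gene and are associated with
#' the disease, and the shared-neighbour set consists of chemicals.
#'
#' @param net A [tripartite_network()].
#' @param mode `"chem_disease"` (default) or `"gene_disease"`.
#' @param chunk_size Number of source entities processed per batch.
#'   Enumeration proceeds chunkwise over chemicals (or genes) so that the
#'   full (source, neighbour, target) cross product is never materialised at
#'   once; hub chemicals with over a thousand gene partners stay affordable.
#' @return A tibble with one row per inferred pair, ordered by source then
#'   target id: columns `chemical`, `disease` (or `gene`, `disease`), `m`,
#'   `curated`, and the list-column `genes` (or `chemicals`) holding the
#'   sorted shared-neighbour identifiers.
#' @examples
#' net <- make_fixture("toy_triangle")$network
#' enumerate_inferences(net)
#' @export
enumerate_inferences <- function(net, mode = c("chem_disease", "gene_disease"),
                                 chunk_size = 200L) {
  stopifnot(inherits(net, "tripartite_network"))
  mode <- rlang::arg_match(mode)

  if (mode == "chem_disease") {
    src_edges <- rename(net$chem_gene, source = "chemical", via = "gene")
    tgt_edges <- rename(net$gene_disease, via = "gene", target = "disease")
    direct <- rename(net$chem_disease, source = "chemical", target = "disease")
    out_names <- c(source = "chemical", target = "disease", via = "genes")
  } else {
    src_edges <- rename(net$chem_gene, via = "chemical", source = "gene")
    tgt_edges <- rename(net$chem_disease, via = "chemical", target = "disease")
    direct <- rename(net$gene_disease, source = "gene", target = "disease")
    out_names <- c(source = "gene", target = "disease", via = "chemicals")
  }

  sources <- sort(unique(src_edges$source))
  if (!length(sources) || !nrow(tgt_edges)) {
    out <- tibble(source = character(), target = character(), m = integer(),
                  curated = logical(), via = list())
    names(out) <- c(out_names[c("source", "target")], "m", "curated", out_names[["via"]])
    return(out)
  }

  chunks <- split(sources, ceiling(seq_along(sources) / chunk_size))
  res <- purrr::map(chunks, function(chunk) {
    src_edges |>
      filter(.data$source %in% chunk) |>
      inner_join(tgt_edges, by = "via", relationship = "many-to-many") |>
      group_by(.data$source, .data$target) |>
      summarise(m = dplyr::n_distinct(.data$via),
                via = list(sort(unique(.data$via))), .groups = "drop")
  })
  out <- bind_rows(res) |>
    left_join(mutate(direct, curated = TRUE), by = c("source", "target")) |>
    mutate(curated = !is.na(.data$curated)) |>
    arrange(.data$source, .data$target) |>
    select("source", "target", "m", "curated", "via")
  names(out) <- c(out_names[c("source", "target")], "m", "curated", out_names[["via"]])
  out
}

#' Summarise an inference table
#'
#' Counts total, curated and novel inferences, plus a per-chemical (or
#' per-gene) breakdown.
#'
#' @param inferences A tibble from [enumerate_inferences()].
#' @return A list with `n_total`, `n_curated`, `n_novel`, and `per_chemical`,
#'   a tibble of counts keyed by the source entity.
#' @export
classify_counts <- function(inferences) {
  key <- names(inferences)[1L]
  per <- inferences |>
    group_by(dplyr::pick(dplyr::all_of(key))) |>
    summarise(n_total = n(), n_curated = sum(.data$curated),
              n_novel = sum(!.data$curated), .groups = "drop")
  list(
    n_total = nrow(inferences),
    n_curated = sum(inferences$curated),
    n_novel = sum(!inferences$curated),
    per_chemical = per
  )
}

#' Write or read an inference table as TSV
#'
#' The shared-neighbour list-column is serialised as semicolon-joined ids.
#'
#' @param inferences Tibble from [enumerate_inferences()].
#' @param path Output/input file path.
#' @return `write_inferences()`: `path` invisibly; `read_inferences()`: the
#'   tibble with the list-column restored.
#' @export
write_inferences <- function(inferences, path) {
  via_col <- names(inferences)[5L]
  flat <- inferences
  flat[[via_col]] <- vapply(flat[[via_col]], paste, character(1), collapse = ";")
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_inferences
#' @export
read_inferences <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  via_col <- names(tab)[5L]
  tab[[via_col]] <- strsplit(tab[[via_col]], ";", fixed = TRUE)
  tab
}
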