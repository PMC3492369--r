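#' Build a tripartite chemical-gene-disease network
#'
#' Constructs the binary tripartite association network at the heart of the
#' package: chemicals, genes and diseases are nodes; curated associations are
#' undirected binary edges confined to three layers (chemical-gene,
#' gene-disease, chemical-disease). Duplicate pairs within a layer collapse
#' to a single edge, because associations are modelled as present/absent,
#' not weighted by report count.
#'
#' @param chem_gene,gene_disease,chem_disease Data frames (or tibbles) whose
#'   first two columns give the node identifiers of each edge. Extra columns
#'   are ignored. Any of them may be `NULL` or zero-row.
#' @param nodes Optional tibble with columns `kind` and `id` declaring nodes
#'   (including isolated ones) beyond those appearing in the edge layers.
#'
#' @return An object of class `tripartite_network`: a list with the three
#'   edge layer tibbles (canonical column names), a `nodes` tibble, and a
#'   precomputed `degree_index` tibble with per-layer and total degrees.
#'
#' @details The network size `N` used by the scoring statistics is the
#'   number of nodes with at least one edge in any layer; isolated declared
#'   nodes do not count towards it (see [network_size()]).
#'
#' @examples
#' net <- tripartite_network(
#'   chem_gene    = data.frame(chemical = "X", gene = c("g1", "g2")),
#'   gene_disease = data.frame(gene = c("g1", "g2"), disease = "Y")
#' )
#' network_size(net)
#' @export
tripartite_network <- function(chem_gene = NULL, gene_disease = NULL,
                               chem_disease = NULL, nodes = NULL) {
  layers <- list(chem_gene = chem_gene, gene_disease = gene_disease,
                 chem_disease = chem_disease)
  layers <- purrr::imap(layers, clean_layer)

  declared <- if (is.null(nodes)) {
    tibble(kind = character(), id = character())
  } else {
    nodes <- as_tibble(nodes)
    stopifnot(all(c("kind", "id") %in% names(nodes)))
    nodes |>
      mutate(kind = as.character(.data$kind), id = trimws(as.character(.data$id))) |>
      select("kind", "id") |>
      distinct()
  }
  if (nrow(declared) && !all(declared$kind %in% NODE_KINDS)) {
    abort("`nodes$kind` must be one of: chemical, gene, disease")
  }

  net <- structure(
    c(layers, list(nodes = declared)),
    class = "tripartite_network"
  )
  net$degree_index <- build_degree_index(net)
  check_kind_collisions(net)
  net
}

# normalise one edge layer: two character id columns, trimmed, deduplicated
clean_layer <- function(x, layer) {
  kinds <- LAYERS[[layer]]
  if (is.null(x) || nrow(as.data.frame(x)) == 0L) {
    out <- tibble(a = character(), b = character())
    names(out) <- kinds
    return(out)
  }
  x <- as_tibble(x)
  if (ncol(x) < 2L) abort(sprintf("layer '%s' needs two identifier columns", layer))
  out <- tibble(a = trimws(as.character(x[[1L]])), b = trimws(as.character(x[[2L]])))
  if (any(out$a == "" | out$b == "" | is.na(out$a) | is.na(out$b))) {
    abort(sprintf("layer '%s' contains empty or missing identifiers", layer))
  }
  names(out) <- kinds
  distinct(out)
}

# per-node, per-layer and total degree; one row per node that appears anywhere
build_degree_index <- function(net) {
  per_layer <- purrr::imap(LAYERS, function(kinds, layer) {
    edges <- net[[layer]]
    bind_rows(
      tibble(kind = kinds[1L], id = edges[[1L]]),
      tibble(kind = kinds[2L], id = edges[[2L]])
    ) |>
      count(.data$kind, .data$id, name = layer)
  })
  idx <- purrr::reduce(
    c(per_layer, list(mutate(net$nodes, .declared = TRUE))),
    \(x, y) dplyr::full_join(x, y, by = c("kind", "id"))
  )
  for (layer in names(LAYERS)) {
    if (!layer %in% names(idx)) idx[[layer]] <- integer(nrow(idx))
    idx[[layer]][is.na(idx[[layer]])] <- 0L
  }
  idx |>
    mutate(degree = .data$chem_gene + .data$gene_disease + .data$chem_disease) |>
    select("kind", "id", "chem_gene", "gene_disease", "chem_disease", "degree") |>
    arrange(.data$kind, .data$id)
}

check_kind_collisions <- function(net) {
  dup <- net$degree_index |>
    distinct(.data$kind, .data$id) |>
    count(.data$id) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "identifier collision: id(s) %s appear under more than one node kind",
      paste(utils::head(dup$id, 5L), collapse = ", ")
    ))
  }
  invisible(net)
}

#' @export
print.tripartite_network <- function(x, ...) {
  counts <- vapply(names(LAYERS), \(l) nrow(x[[l]]), integer(1))
  cat("<tripartite_network>\n")
  cat(sprintf("  edges: chem-gene %d, gene-disease %d, chem-disease %d\n",
              counts[1], counts[2], counts[3]))
  cat(sprintf("  nodes with >=1 edge (N): %d\n", network_size(x)))
  invisible(x)
}

#' Number of connected nodes in a network
#'
#' The universe size `N` entering every topology statistic: the number of
#' chemicals, genes and diseases with at least one association in any layer.
#'
#' @param net A [tripartite_network()].
#' @return A single integer.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  sum(net$degree_index$degree >= 1L)
}

#' Node degree queries
#'
#' `net_degree()` returns the degree of one or more nodes; by default the
#' total degree pooled over all three layers (the quantity used by the
#' scoring statistics), optionally restricted to a single layer.
#' `degree_table()` returns the full per-node degree index as a tibble.
#'
#' @param net A [tripartite_network()].
#' @param id Character vector of node identifiers.
#' @param layer Optional layer name (`"chem_gene"`, `"gene_disease"`,
#'   `"chem_disease"`) restricting the count to that layer.
#' @return `net_degree()`: an integer vector aligned with `id`;
#'   `degree_table()`: a tibble with columns `kind`, `id`, one column per
#'   layer, and `degree`.
#' @examples
#' net <- make_fixture("toy_triangle")$network
#' net_degree(net, "X")
#' net_degree(net, "X", layer = "chem_gene")
#' @export
net_degree <- function(net, id, layer = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  idx <- net$degree_index
  pos <- match(id, idx$id)
  if (anyNA(pos)) {
    abort(sprintf("unknown node id(s): %s",
                  paste(utils::head(id[is.na(pos)], 5L), collapse = ", ")))
  }
  col <- if (is.null(layer)) "degree" else rlang::arg_match(layer, names(LAYERS))
  as.integer(idx[[col]][pos])
}

#' @rdname net_degree
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  net$degree_index
}

#' Read a tripartite network from three delimited association files
#'
#' Loads one file per edge layer. The `pairs` dialect expects two
#' tab-separated identifier columns per row, with `#`-prefixed comment lines
#' ignored; the `ctd_export` dialect expects a header row and takes the two
#' identifier columns by name via `col_map`, accommodating export headers
#' that change across releases. Duplicate pairs are collapsed to one binary
#' edge and the row counts before and after deduplication are reported.
#'
#' @param chem_gene_path,gene_disease_path,chem_disease_path File paths
#'   (plain or gzipped). `NA` skips a layer.
#' @param dialect `"pairs"` (default) or `"ctd_export"`.
#' @param col_map For `ctd_export`: a named list giving, per layer, the
#'   two source column names, e.g.
#'   `list(chem_gene = c("ChemicalID", "GeneSymbol"), ...)`.
#' @param quiet Suppress the per-file dedup messages.
#' @return A [tripartite_network()].
#' @export
load_network <- function(chem_gene_path, gene_disease_path, chem_disease_path,
                         dialect = c("pairs", "ctd_export"), col_map = NULL,
                         quiet = FALSE) {
  dialect <- rlang::arg_match(dialect)
  paths <- list(chem_gene = chem_gene_path, gene_disease = gene_disease_path,
                chem_disease = chem_disease_path)
  layers <- purrr::imap(paths, function(path, layer) {
    if (is.null(path) || (length(path) == 1L && is.na(path))) return(NULL)
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    raw <- switch(dialect,
      pairs = read_pairs_file(path),
      ctd_export = read_ctd_export_file(path, col_map[[layer]], layer)
    )
    kept <- nrow(distinct(raw))
    if (!quiet) {
      inform(sprintf("%s: %d rows, %d unique pairs", basename(path), nrow(raw), kept))
    }
    raw
  })
  tripartite_network(chem_gene = layers$chem_gene,
                     gene_disease = layers$gene_disease,
                     chem_disease = layers$chem_disease)
}

read_pairs_file <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- seq_along(lines)[keep]
  bad <- vapply(fields, \(f) length(f) < 2L || any(trimws(f[1:2]) == ""), logical(1))
  if (any(bad)) {
    abort(sprintf("malformed row in %s at line %d: expected two tab-separated ids",
                  path, lineno[which(bad)[1L]]))
  }
  tibble(
    a = vapply(fields, \(f) trimws(f[[1L]]), character(1)),
    b = vapply(fields, \(f) trimws(f[[2L]]), character(1))
  )
}

read_ctd_export_file <- function(path, cols, layer) {
  if (is.null(cols) || length(cols) != 2L) {
    abort(sprintf("ctd_export dialect needs col_map$%s = c(<id col>, <id col>)", layer))
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    abort(sprintf("%s: column(s) %s not present", path,
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(a = as.character(tab[[cols[1L]]]), b = as.character(tab[[cols[2L]]]))
  bad <- which(is.na(out$a) | is.na(out$b) | trimws(out$a) == "" | trimws(out$b) == "")
  if (length(bad)) {
    abort(sprintf("malformed row in %s at data line %d: missing identifier",
                  path, bad[1L]))
  }
  out
}

#' Write a network to a directory of TSV layers
#'
#' Saves the three edge layers as tab-separated pair files plus a small
#' `header.dcf` recording the node/edge counts and `N`, so a saved network
#' round-trips through [load_network()] unchanged.
#'
#' @param net A [tripartite_network()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "tripartite_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(LAYERS)) {
    readr::write_tsv(net[[layer]], file.path(dir, paste0(layer, ".tsv")),
                     col_names = FALSE)
  }
  hdr <- c(
    sprintf("N: %d", network_size(net)),
    sprintf("edges_%s: %d", names(LAYERS),
            vapply(names(LAYERS), \(l) nrow(net[[l]]), integer(1))),
    "dialect: pairs"
  )
  writeLines(hdr, file.path(dir, "header.dcf"))
  invisible(dir)
}

#' Fit a power law to the pooled degree distribution
#'
#' Biological association networks are scale free: plotted on log-log axes,
#' the frequency of nodes with a given total degree falls on an
#' approximately straight line. This fits that line by least squares on
#' log10(degree) versus log10(frequency), using unit-width degree bins and
#' dropping zero-frequency degrees before the log transform.
#'
#' @param x A [tripartite_network()] or a numeric vector of node degrees.
#' @return An object of class `powerlaw_fit` with elements `slope`,
#'   `intercept`, `r_squared`, and the binned `data`. [tidy()] and
#'   [glance()] methods are provided, as is [ggplot2::autoplot()].
#' @examples
#' d <- rep(1:20, times = round(200 * (1:20)^-1.5))
#' fit_powerlaw(d)$slope
#' @export
fit_powerlaw <- function(x) {
  degrees <- if (inherits(x, "tripartite_network")) {
    degree_table(x)$degree
  } else {
    as.numeric(x)
  }
  degrees <- degrees[degrees >= 1]
  freq <- count(tibble(degree = degrees), .data$degree, name = "freq")
  if (nrow(freq) < 3L) {
    abort("degenerate fit: need at least 3 distinct observed degree values")
  }
  fit <- lm(log10(freq) ~ log10(degree), data = freq)
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = summary(fit)$r.squared,
      data = freq,
      n_nodes = length(degrees)
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> slope %.3f, intercept %.3f, r^2 %.3f (%d nodes)\n",
              x$slope, x$intercept, x$r_squared, x$n_nodes))
  invisible(x)
}

#' @rdname fit_powerlaw
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @rdname fit_powerlaw
#' @exportS3Method generics::glance
glance.powerlaw_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
         n_degrees = nrow(x$data), n_nodes = x$n_nodes)
}
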