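#' Specify a synthetic scale-free tripartite network
#'
#' Bundles and validates the parameters of the synthetic generator. The
#' generator emulates the gross topology of curated chemical-gene-disease
#' content: three binary association layers over a shared node universe
#' whose pooled degree distribution is approximately power-law with a
#' shallow slope (about -0.8 on log-log axes), i.e. a few heavily curated
#' hubs and a long tail of sparsely connected entities.
#'
#' @param n_chemicals,n_genes,n_diseases Node counts per kind (>= 1).
#' @param edges_per_layer Named integer vector with entries `chem_gene`,
#'   `gene_disease`, `chem_disease`; defaults scale with the node counts
#'   roughly like curated content (chemical-gene the densest layer).
#' @param target_exponent Magnitude of the power-law slope targeted for the
#'   pooled degree distribution (default 0.8).
#' @param planted List of [planted_inference()] specs.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chemicals, n_genes, n_diseases,
                           edges_per_layer = NULL, target_exponent = 0.8,
                           planted = list(), seed = 1L) {
  stopifnot(n_chemicals >= 1, n_genes >= 1, n_diseases >= 1,
            target_exponent > 0)
  if (is.null(edges_per_layer)) {
    edges_per_layer <- c(
      chem_gene = 6L * max(n_chemicals, n_genes),
      gene_disease = 2L * max(n_genes %/% 4L, n_diseases),
      chem_disease = max(n_chemicals %/% 2L, n_diseases)
    )
  }
  stopifnot(all(c("chem_gene", "gene_disease", "chem_disease") %in%
                  names(edges_per_layer)))
  for (p in planted) {
    if (!inherits(p, "planted_inference")) {
      abort("`planted` must be a list of planted_inference() specs")
    }
    if (p$m > n_genes) abort("unsatisfiable plant: m exceeds the gene count")
  }
  structure(
    list(n_chemicals = n_chemicals, n_genes = n_genes, n_diseases = n_diseases,
         edges_per_layer = edges_per_layer, target_exponent = target_exponent,
         planted = planted, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @param m Number of connecting genes to wire (>= 1).
#' @param gene_degree_profile Which degree stratum the connecting genes are
#'   drawn from: `"low"` (bottom third), `"hub"` (top third), `"mixed"`.
#' @param curated Also add the direct chemical-disease edge.
#' @export
planted_inference <- function(m, gene_degree_profile = c("low", "hub", "mixed"),
                              curated = FALSE) {
  stopifnot(m >= 1)
  structure(list(m = as.integer(m),
                 gene_degree_profile = rlang::arg_match(gene_degree_profile),
                 curated = curated),
            class = "planted_inference")
}

# heavy-tailed target degrees for one node kind, emulating curated
# association content: a Poisson bulk (most entities carry a handful of
# associations, few have exactly one) plus a curation-priority minority
# whose degrees follow a truncated zeta reaching hub scale. the pooled
# log-log frequency cloud is convex with a long sparse hub tail, and the
# least-squares line through it has slope close to -alpha - the same shape
# real curated networks show. targets are binomially thinned to the layer
# stub budget, which preserves the shape.
powerlaw_degree_targets <- function(n, budget, alpha, d_max,
                                    hub_fraction = 0.15, bulk_mean = 4,
                                    min_degree = 2L) {
  budget <- max(budget, n)
  d_max <- max(4L, d_max)
  # empirical map from the requested fitted slope to the sampled tail
  # exponent; wiring losses (duplicate collapse, layer caps) steepen the
  # realised cloud, so the sampled tail is drawn heavier than the target
  gamma <- max(0.3, alpha - 0.2)
  hub <- stats::runif(n) < hub_fraction
  deg <- integer(n)
  deg[!hub] <- min_degree + stats::rpois(sum(!hub),
                                         max(0.5, bulk_mean - min_degree))
  deg[hub] <- sample(seq_len(d_max), sum(hub), replace = TRUE,
                     prob = seq_len(d_max)^(-gamma))
  total <- sum(deg)
  if (total > budget) {
    deg <- stats::rbinom(n, deg, budget / total)
  } else if (total < budget) {
    deg <- as.integer(round(deg * budget / total))
  }
  deg
}

# realise a simple bipartite layer from per-side stub counts by random
# pairing; duplicate pairs collapse, so hubs land slightly under target
realize_bipartite <- function(a_ids, a_deg, b_ids, b_deg) {
  stubs_a <- rep(a_ids, times = a_deg)
  stubs_b <- rep(b_ids, times = b_deg)
  n <- min(length(stubs_a), length(stubs_b))
  distinct(tibble(a = sample(stubs_a)[seq_len(n)], b = sample(stubs_b)[seq_len(n)]))
}

#' Generate a synthetic tripartite network with planted inferences
#'
#' Builds each layer by degree-targeted stub pairing: per-node target
#' degrees are drawn from a truncated discrete power law with the requested
#' exponent, and endpoints are paired at random, collapsing duplicates so
#' the realised graph is simple. Planted inferences are then inserted by
#' wiring `m` genes from the requested degree stratum to a dedicated
#' chemical and disease (plus the direct edge when curated), providing
#' ground truth for recovery and hub-penalty experiments.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `network` (a [tripartite_network()]) and
#'   `ground_truth` (tibble: `chemical`, `disease`, `m`, `profile`,
#'   `curated`, list-column `genes`; zero rows when nothing is planted).
#' @examples
#' out <- generate_tripartite(synthetic_spec(50, 200, 30, seed = 42))
#' out$network
#' @export
generate_tripartite <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  chems <- sprintf("C%04d", seq_len(spec$n_chemicals))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  diseases <- sprintf("D%04d", seq_len(spec$n_diseases))
  alpha <- spec$target_exponent
  e <- spec$edges_per_layer

  # each kind's total-degree targets follow the power law; a node's stubs
  # are then split between its two permitted layers in proportion to the
  # layer budgets, so the *pooled* degree keeps the target shape
  n_nodes <- spec$n_chemicals + spec$n_genes + spec$n_diseases
  kind_targets <- function(ids, budget) {
    setNames(powerlaw_degree_targets(length(ids), budget, alpha, n_nodes), ids)
  }
  split_stubs <- function(total, share) {
    first <- stats::rbinom(length(total), size = total, prob = share)
    cbind(first, total - first)
  }
  chem_t <- kind_targets(chems, e[["chem_gene"]] + e[["chem_disease"]])
  gene_t <- kind_targets(genes, e[["chem_gene"]] + e[["gene_disease"]])
  dis_t <- kind_targets(diseases, e[["gene_disease"]] + e[["chem_disease"]])
  chem_s <- split_stubs(chem_t, e[["chem_gene"]] / (e[["chem_gene"]] + e[["chem_disease"]]))
  gene_s <- split_stubs(gene_t, e[["chem_gene"]] / (e[["chem_gene"]] + e[["gene_disease"]]))
  dis_s <- split_stubs(dis_t, e[["gene_disease"]] / (e[["gene_disease"]] + e[["chem_disease"]]))

  cg <- realize_bipartite(chems, chem_s[, 1L], genes, gene_s[, 1L])
  gd <- realize_bipartite(genes, gene_s[, 2L], diseases, dis_s[, 1L])
  cd <- realize_bipartite(chems, chem_s[, 2L], diseases, dis_s[, 2L])
  names(cg) <- c("chemical", "gene")
  names(gd) <- c("gene", "disease")
  names(cd) <- c("chemical", "disease")

  nodes <- bind_rows(
    tibble(kind = "chemical", id = chems),
    tibble(kind = "gene", id = genes),
    tibble(kind = "disease", id = diseases)
  )

  net <- tripartite_network(chem_gene = cg, gene_disease = gd,
                            chem_disease = cd, nodes = nodes)

  truth <- tibble(chemical = character(), disease = character(),
                  m = integer(), profile = character(), curated = logical(),
                  genes = list())
  if (length(spec$planted)) {
    n_plant <- length(spec$planted)
    if (n_plant > min(spec$n_chemicals, spec$n_diseases)) {
      abort("more planted inferences than available chemical/disease pairs")
    }
    plant_chems <- sample(chems, n_plant)
    plant_dis <- sample(diseases, n_plant)
    for (i in seq_len(n_plant)) {
      p <- spec$planted[[i]]
      planted <- plant_inference(net, plant_chems[i], plant_dis[i], m = p$m,
                                 gene_degree_profile = p$gene_degree_profile,
                                 curated = p$curated)
      net <- planted$network
      truth <- bind_rows(truth, planted$record)
    }
  }

  list(network = net, ground_truth = truth)
}

#' Wire a ground-truth inference into a network
#'
#' Adds the edges of one transitive inference to designated endpoints:
#' `m` genes, drawn from the requested degree stratum (preferring genes not
#' yet adjacent to either endpoint, so the endpoint degrees grow by exactly
#' `m` each), are connected to the chemical and to the disease; a direct
#' chemical-disease edge is added when `curated`. Used by
#' [generate_tripartite()], and directly when an experiment needs matched
#' endpoints (for example, contrasting a low-degree-gene plant with a
#' hub-gene plant between endpoints of equal degree, so that the
#' gene-degree statistic is the only discriminating term).
#'
#' @param net A [tripartite_network()].
#' @param chemical,disease Endpoint node identifiers (must exist in `net`).
#' @param m Number of connecting genes.
#' @param gene_degree_profile `"low"`, `"hub"` or `"mixed"` stratum from
#'   which connecting genes are sampled (by current total degree).
#' @param curated Also add the direct chemical-disease edge.
#' @param genes Optional explicit gene identifiers overriding the stratum
#'   draw.
#' @return A list with the augmented `network` and a one-row `record`
#'   tibble (`chemical`, `disease`, `m`, `profile`, `curated`, `genes`).
#' @export
plant_inference <- function(net, chemical, disease, m,
                            gene_degree_profile = c("low", "hub", "mixed"),
                            curated = FALSE, genes = NULL) {
  stopifnot(inherits(net, "tripartite_network"))
  gene_degree_profile <- rlang::arg_match(gene_degree_profile)
  idx <- net$degree_index
  if (!chemical %in% idx$id[idx$kind == "chemical"] ||
      !disease %in% idx$id[idx$kind == "disease"]) {
    abort("plant endpoints must be existing chemical and disease nodes")
  }
  if (is.null(genes)) {
    gene_deg <- arrange(filter(idx, .data$kind == "gene"), .data$degree, .data$id)
    adjacent <- union(net$chem_gene$gene[net$chem_gene$chemical == chemical],
                      net$gene_disease$gene[net$gene_disease$disease == disease])
    third <- max(1L, nrow(gene_deg) %/% 3L)
    pool <- switch(gene_degree_profile,
      low = head(gene_deg$id, third),
      hub = utils::tail(gene_deg$id, third),
      mixed = c(head(gene_deg$id, third), utils::tail(gene_deg$id, third))
    )
    fresh <- setdiff(pool, adjacent)
    if (length(fresh) >= m) pool <- fresh
    if (length(pool) < m) abort("unsatisfiable plant: stratum too small")
    genes <- sample(pool, m)
  } else if (length(genes) != m) {
    abort("`genes` must have exactly `m` entries")
  }
  cg <- distinct(bind_rows(net$chem_gene, tibble(chemical = chemical, gene = genes)))
  gd <- distinct(bind_rows(net$gene_disease, tibble(gene = genes, disease = disease)))
  cd <- net$chem_disease
  if (curated) {
    cd <- distinct(bind_rows(cd, tibble(chemical = chemical, disease = disease)))
  }
  list(
    network = tripartite_network(chem_gene = cg, gene_disease = gd,
                                 chem_disease = cd, nodes = net$nodes),
    record = tibble(chemical = chemical, disease = disease, m = as.integer(m),
                    profile = gene_degree_profile, curated = curated,
                    genes = list(sort(genes)))
  )
}

#' Built-in worked fixtures
#'
#' Small, fully specified inputs used throughout the documentation and
#' tests:
#'
#' * `"toy_triangle"`: the minimal four-node network (one chemical, two
#'   genes, one disease) carrying exactly one inference with `m = 2`.
#' * `"bpa_five_gene"`: the reference table of 21 bisphenol-A disease
#'   inferences, each via five genes, from a July 2011 CTD snapshot:
#'   per-row disease degrees, gene degrees, and the published values of the
#'   five statistics. The chemical degree is 1247; the snapshot universe
#'   size implied jointly by the published clustering-coefficient values
#'   is `snapshot_n = 38940` (least-squares over the table itself).
#'   Degrees are carried as metadata, so statistics can be evaluated
#'   without reconstructing the full 30k-node network.
#' * `"malathion_pioglitazone"`: the matched pair of breast-neoplasm
#'   inference inputs (nine genes each, similar endpoint degrees, very
#'   different gene connectivity) used to illustrate the gene-degree
#'   penalty, with published reference scores. The published values for
#'   this pair mix database snapshots and are indicative rather than
#'   exactly reproducible.
#'
#' @param name Fixture name.
#' @return A list; see Details. `toy_triangle` has elements `network` and
#'   `expected`; the other two return the parsed reference tables plus
#'   metadata.
#' @examples
#' make_fixture("toy_triangle")$expected
#' @export
make_fixture <- function(name = c("toy_triangle", "bpa_five_gene",
                                  "malathion_pioglitazone")) {
  name <- rlang::arg_match(name)
  if (name == "toy_triangle") {
    net <- tripartite_network(
      chem_gene = tibble(chemical = "X", gene = c("g1", "g2")),
      gene_disease = tibble(gene = c("g1", "g2"), disease = "Y")
    )
    return(list(
      network = net,
      expected = list(n_inferences = 1L, chemical = "X", disease = "Y",
                      m = 2L, curated = FALSE, N = 4L)
    ))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cdscore",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$gene_degrees <- purrr::map(
    strsplit(tab$gene_degrees, ";", fixed = TRUE),
    \(x) {
      parts <- strsplit(x, ":", fixed = TRUE)
      setNames(as.integer(vapply(parts, `[[`, character(1), 2L)),
               vapply(parts, `[[`, character(1), 1L))
    }
  )
  if (name == "bpa_five_gene") {
    list(table = tab, chemical = "Bisphenol A", chemical_degree = 1247L,
         m = 5L, snapshot_n = 38940L)
  } else {
    list(table = tab, snapshot_n = NA_integer_)
  }
}
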