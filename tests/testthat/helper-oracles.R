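# Independent oracles and small network builders used across the suite.

# Binomial coefficients by Pascal's recurrence (addition only), independent
# of the log-gamma path used by the package. Exact in double precision up
# to 2^53 and accurate to ~1e-13 relative beyond; ample for N <= 500.
pascal_choose <- function(n_max) {
  tri <- matrix(0, n_max + 1L, n_max + 1L)
  tri[, 1L] <- 1
  for (n in seq_len(n_max)) {
    for (r in seq_len(n)) {
      tri[n + 1L, r + 1L] <- tri[n, r] + tri[n, r + 1L]
    }
  }
  function(n, r) tri[n + 1L, r + 1L]
}

# exact-summation reference for the three probability statistics
oracle_stats <- function(n_x, n_y, m, N, gene_degrees = NULL, choose_fun) {
  pmf <- function(i) {
    choose_fun(n_x, i) * choose_fun(N - n_x, n_y - i) / choose_fun(N, n_y)
  }
  tail <- sum(vapply(m:min(n_x, n_y), pmf, numeric(1)))
  out <- list(c_xy = -log10(tail), p1 = -log10(pmf(m)))
  if (!is.null(gene_degrees)) {
    out$p2 <- -log10(prod(gene_degrees * (gene_degrees - 1) / (N * (N - 1))))
  }
  out
}

# random sparse instance in the regime the statistics are designed for:
# degrees well below N, expected overlap below the observed one
random_score_inputs <- function(N_max = 500L) {
  N <- sample(50:N_max, 1L)
  cap <- max(3L, as.integer(floor(sqrt(N))))  # n_x * n_y <= N: mode <= 1 <= m
  n_x <- sample(2:cap, 1L)
  n_y <- sample(2:cap, 1L)
  m <- sample(seq_len(min(n_x, n_y, 6L)), 1L)
  gene_degrees <- sample(2:min(N - 1L, 50L), m, replace = TRUE)
  list(N = N, n_x = n_x, n_y = n_y, m = m, gene_degrees = gene_degrees)
}

# uniform random pair tables over small id universes
random_pairs <- function(n, a_ids, b_ids) {
  tibble::tibble(a = sample(a_ids, n, replace = TRUE),
                 b = sample(b_ids, n, replace = TRUE))
}

random_network <- function(n_chem = 20L, n_gene = 40L, n_dis = 10L,
                           p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chems <- paste0("c", seq_len(n_chem))
  genes <- paste0("g", seq_len(n_gene))
  dis <- paste0("d", seq_len(n_dis))
  pick <- function(a, b) {
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < p, ]
  }
  tripartite_network(
    chem_gene = pick(chems, genes),
    gene_disease = pick(genes, dis),
    chem_disease = pick(chems, dis),
    nodes = dplyr::bind_rows(
      tibble::tibble(kind = "chemical", id = chems),
      tibble::tibble(kind = "gene", id = genes),
      tibble::tibble(kind = "disease", id = dis)
    )
  )
}

# exhaustive triple-loop inference enumeration (no joins), used as the
# reference for enumerate_inferences()
brute_force_inferences <- function(net) {
  cg <- net$chem_gene; gd <- net$gene_disease; cd <- net$chem_disease
  out <- list()
  for (chem in sort(unique(cg$chemical))) {
    for (dis in sort(unique(gd$disease))) {
      shared <- character()
      for (gene in unique(cg$gene[cg$chemical == chem])) {
        if (any(gd$gene == gene & gd$disease == dis)) shared <- c(shared, gene)
      }
      if (length(shared)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chemical = chem, disease = dis, m = length(shared),
          curated = any(cd$chemical == chem & cd$disease == dis),
          genes = list(sort(shared))
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chemical = character(), disease = character(),
                          m = integer(), curated = logical(), genes = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chemical, disease)
}
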