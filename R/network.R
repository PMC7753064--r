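#' Build a PPI graph from an edge list
#'
#' Deduplicates edges and drops self-loops.
#'
#' @param edges data.frame whose first two columns are gene ids; an optional
#'   third column is kept as edge weight.
#' @return an undirected \code{igraph} graph.
#' @export
ppi_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Degree and harmonic closeness centralities
#'
#' Closeness is the harmonic variant, \code{sum over reachable v of
#' 1/d(u,v)}, with unreachable nodes contributing 0. Unlike the normalized
#' [0,1] closeness it grows with network size, which is why hub screens on
#' networks of a few hundred nodes can use cutoffs like 130.
#'
#' @param g \code{igraph} graph or edge data.frame.
#' @return data.frame (gene, degree, closeness), one row per node.
#' @export
centralities <- function(g) {
  if (!igraph::is_igraph(g)) g <- ppi_graph(g)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  data.frame(
    gene = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    closeness = as.numeric(
      igraph::harmonic_centrality(g, normalized = FALSE, weights = NA)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hub-gene screen
#'
#' Keeps genes whose harmonic closeness exceeds \code{closeness_min}
#' (strictly); among those, retains every underexpressed candidate plus the
#' top \code{ceiling(top_frac * n)} overexpressed candidates ranked by
#' degree (ties broken by closeness, then gene id).
#'
#' @param cent centrality table from \code{\link{centralities}}.
#' @param overexpressed,underexpressed disjoint candidate gene vectors.
#' @param closeness_min closeness cutoff (default 130, strict \code{>}).
#' @param top_frac fraction of passing overexpressed genes kept (default
#'   0.30).
#' @return sorted unique character vector of hub gene ids.
#' @export
hub_filter <- function(cent, overexpressed, underexpressed,
                       closeness_min = 130, top_frac = 0.30) {
  if (length(intersect(overexpressed, underexpressed)))
    stop("candidate lists must be disjoint")
  if (!length(overexpressed) && !length(underexpressed)) {
    warning("empty candidate lists")
    return(character(0))
  }
  pass <- cent[cent$closeness > closeness_min, , drop = FALSE]
  under_keep <- intersect(underexpressed, pass$gene)
  over_pass <- pass[pass$gene %in% overexpressed, , drop = FALSE]
  over_keep <- character(0)
  if (nrow(over_pass)) {
    o <- order(-over_pass$degree, -over_pass$closeness, over_pass$gene)
    k <- ceiling(top_frac * nrow(over_pass))
    over_keep <- over_pass$gene[o][seq_len(k)]
  }
  sort(unique(c(under_keep, over_keep)))
}

#' Cohen's kappa between two gene sets
#'
#' Agreement of the two binary membership vectors over a gene universe:
#' \code{po = (n11 + n00) / N}, \code{pe = (row1*col1 + row0*col0) / N^2},
#' \code{kappa = (po - pe) / (1 - pe)}. Identical sets give 1. When
#' \code{pe = 1} (both sets empty or both equal to the universe) kappa is
#' undefined and \code{NA} is returned.
#'
#' @param a,b character vectors (gene sets), subsets of \code{universe}.
#' @param universe character vector, the gene universe (length >= 2).
#' @return kappa in [-1, 1], or \code{NA} when undefined.
#' @export
kappa_score <- function(a, b, universe) {
  stopifnot(length(universe) >= 2L)
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("gene sets must be subsets of the universe")
  N <- length(universe)
  ina <- universe %in% a; inb <- universe %in% b
  n11 <- sum(ina & inb); n00 <- sum(!ina & !inb)
  po <- (n11 + n00) / N
  pe <- (sum(ina) * sum(inb) + sum(!ina) * sum(!inb)) / N^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Group gene-set terms by kappa agreement
#'
#' Builds a term graph with an edge wherever the pairwise kappa over the
#' universe meets \code{threshold}, and returns its connected components as
#' functional groups, ordered by each group's smallest term id.
#'
#' @param terms named list of gene-set character vectors (names = term ids),
#'   or a list of lists with \code{term_id} and \code{genes}.
#' @param universe gene universe.
#' @param threshold kappa cutoff (default 0.4, \code{>=}).
#' @return list of character vectors of term ids (each sorted).
#' @export
kappa_grouping <- function(terms, universe, threshold = 0.4) {
  if (length(terms) == 0L) return(list())
  if (is.list(terms[[1L]]) && !is.null(terms[[1L]]$genes)) {
    ids <- vapply(terms, function(t) t$term_id, "")
    terms <- setNames(lapply(terms, function(t) t$genes), ids)
  }
  ids <- names(terms)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    k <- kappa_score(terms[[i]], terms[[j]], universe)
    adj[i, j] <- adj[j, i] <- !is.na(k) && k >= threshold
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- unname(split(ids, comp))
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, function(g) g[1L], ""))]
}

#' Over-representation test (hypergeometric upper tail)
#'
#' Generic enrichment of a query gene set in a term, over a finite
#' universe: \code{p = P(X >= k)} for the hypergeometric overlap count, and
#' fold enrichment = observed / expected overlap. Multiple-testing
#' adjustment across terms is the caller's responsibility.
#'
#' @param query character vector, subset of \code{universe}.
#' @param term_genes character vector, the term's gene set.
#' @param universe gene universe (non-empty).
#' @return list with \code{p}, \code{fold_enrichment}, \code{overlap}.
#' @export
ora_hypergeometric <- function(query, term_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query); term_genes <- intersect(unique(term_genes),
                                                  universe)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe); K <- length(term_genes); n <- length(query)
  k <- length(intersect(query, term_genes))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  list(p = p, fold_enrichment = if (expected > 0) k / expected else NA_real_,
       overlap = k)
}
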