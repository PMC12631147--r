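# Bibliometric networks: incidence matrices, co-authorship (M'M),
# bibliographic coupling (CC'), country aggregation, centrality, clusters,
# chord-diagram tables. Edge weights are integer counts end-to-end;
# renderers do any scaling.

#' Build a binary paper-by-entity incidence matrix
#'
#' Rows are papers, columns the distinct normalized entities (authors,
#' countries, or cited-reference keys) in first-appearance order; an entry
#' is 1 iff the entity occurs on the paper (duplicates collapse to a single
#' 1).
#'
#' @param records Bibliography tibble from [read_bibliography()].
#' @param mode `"author"`, `"country"`, or `"reference"`.
#' @return A binary integer matrix with paper/entity dimnames, class
#'   `evimap_incidence`, attribute `mode`.
#' @export
build_incidence <- function(records, mode = c("author", "country",
                                              "reference")) {
  mode <- match.arg(mode)
  field <- switch(mode, author = "authors", country = "countries",
                  reference = "references")
  lists <- records[[field]]
  entities <- unique(unlist(lists, use.names = FALSE))
  if (!length(entities)) {
    abort(sprintf("no usable entities for mode '%s'", mode))
  }
  M <- matrix(0L, nrow(records), length(entities),
              dimnames = list(records$paper_id, entities))
  for (i in seq_len(nrow(records))) {
    M[i, unique(lists[[i]])] <- 1L
  }
  structure(M, mode = mode, class = c("evimap_incidence", "matrix"))
}

.new_network <- function(W, nodes, kind) {
  diag_counts <- diag(W)
  diag(W) <- 0L
  structure(list(weights = W, nodes = nodes, kind = kind),
            class = "evimap_network", diag = diag_counts)
}

#' @export
print.evimap_network <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<evimap_network: %s> %d nodes, %d edges\n", x$kind, n, m))
  invisible(x)
}

#' Co-authorship network from an author incidence matrix
#'
#' Collaboration analysis by the matrix product (Author x Paper) times
#' (Paper x Author): the off-diagonal of `M'M` counts the papers two
#' authors share; the diagonal (papers per author) is stored as the node
#' attribute `papers`.
#'
#' @param M Author-mode incidence matrix from [build_incidence()].
#' @return An `evimap_network` (kind `"coauthorship"`): symmetric integer
#'   weight matrix with zero diagonal plus a `nodes` tibble.
#' @export
coauthorship_network <- function(M) {
  if (!identical(attr(M, "mode"), "author")) {
    abort("M must be an author-mode incidence matrix")
  }
  W <- crossprod(unclass(M))          # authors x authors
  nodes <- tibble::tibble(label = colnames(W), papers = as.integer(diag(W)))
  .new_network(W, nodes, "coauthorship")
}

#' Paper-level bibliographic-coupling network
#'
#' Two papers are coupled when their reference lists share citations;
#' the off-diagonal of `C C'` counts shared cited references, and the
#' diagonal (references per paper) is stored as the node attribute `refs`.
#'
#' @param C Reference-mode incidence matrix from [build_incidence()].
#' @return An `evimap_network` (kind `"coupling_paper"`).
#' @export
coupling_network <- function(C) {
  if (!identical(attr(C, "mode"), "reference")) {
    abort("C must be a reference-mode incidence matrix")
  }
  W <- tcrossprod(unclass(C))         # papers x papers
  nodes <- tibble::tibble(label = rownames(W), refs = as.integer(diag(W)))
  .new_network(W, nodes, "coupling_paper")
}

#' Aggregate paper coupling to the country level
#'
#' `weight(X, Y)` for distinct countries sums the paper-level coupling over
#' all pairs of papers affiliated with X and Y respectively; a multi-country
#' paper contributes to every listed country (set `countries = "first"` to
#' restrict to the first affiliation). Within-country coupling (over
#' unordered paper pairs) is stored as the node attribute `self_coupling`.
#' Papers without country data are excluded with a message.
#'
#' @param paper_net Paper-level coupling network from [coupling_network()].
#' @param records Bibliography tibble aligned by `paper_id`.
#' @param countries `"all"` (default) or `"first"`.
#' @return An `evimap_network` (kind `"coupling_country"`).
#' @export
aggregate_country_coupling <- function(paper_net, records,
                                       countries = c("all", "first")) {
  countries <- match.arg(countries)
  W <- paper_net$weights
  papers <- rownames(W)
  cl <- records$countries[match(papers, records$paper_id)]
  if (countries == "first") {
    cl <- lapply(cl, function(x) if (length(x)) x[1] else character(0))
  }
  no_country <- lengths(cl) == 0
  if (any(no_country)) {
    inform(sprintf("excluded %d paper(s) with no country data",
                   sum(no_country)))
  }
  keep <- which(!no_country)
  if (!length(keep)) abort("no papers carry country data")
  all_countries <- unique(unlist(cl[keep], use.names = FALSE))
  A <- matrix(0L, length(papers), length(all_countries),
              dimnames = list(papers, all_countries))
  for (i in keep) A[i, cl[[i]]] <- 1L
  G <- t(A) %*% W %*% A                    # includes within-country (diag)
  self <- diag(G) / 2                      # unordered within-country pairs
  nodes <- tibble::tibble(label = colnames(G),
                          papers = as.integer(colSums(A)),
                          self_coupling = as.numeric(self))
  diag(G) <- 0
  structure(list(weights = G, nodes = nodes, kind = "coupling_country"),
            class = "evimap_network")
}

#' Degree centrality or strength
#'
#' Unweighted: number of neighbours divided by `n - 1` (0 for a single-node
#' network). Weighted: strength, the sum of incident edge weights.
#'
#' @param net An `evimap_network`.
#' @param weighted Use edge weights (strength) instead of neighbour counts.
#' @return Named numeric vector over nodes.
#' @export
degree_centrality <- function(net, weighted = FALSE) {
  W <- net$weights
  n <- nrow(W)
  if (weighted) {
    rowSums(W)
  } else if (n <= 1) {
    setNames(rep(0, n), rownames(W))
  } else {
    rowSums(W > 0) / (n - 1)
  }
}

#' Author clusters (research groups)
#'
#' Partitions the co-authorship network into clusters: connected components
#' (deterministic, the default) or Louvain modularity communities under a
#' fixed seed. Cluster ids are assigned by decreasing size, ties broken by
#' the lexicographically smallest member label.
#'
#' @param net A co-authorship `evimap_network`.
#' @param method `"components"` or `"louvain"`.
#' @param seed Integer seed for Louvain (recorded in the result).
#' @return A list with `membership` (named integer vector), `summary`
#'   tibble (`n_clusters`, `mean_size`, `max_size`), `method`, `seed`.
#' @export
author_clusters <- function(net, method = c("components", "louvain"),
                            seed = 1L) {
  method <- match.arg(method)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (method == "components") {
    mem <- igraph::components(g)$membership
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    mem <- igraph::membership(igraph::cluster_louvain(g))
  }
  mem <- setNames(as.integer(mem), rownames(net$weights))
  # relabel: decreasing size, ties by smallest member label
  sizes <- table(mem)
  firsts <- tapply(names(mem), mem, function(x) min(x))
  ord <- order(-as.integer(sizes), firsts[names(sizes)])
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  mem <- setNames(relabel[as.character(mem)], names(mem))
  list(
    membership = mem,
    summary = tibble::tibble(n_clusters = length(sizes),
                             mean_size = mean(as.integer(sizes)),
                             max_size = max(as.integer(sizes))),
    method = method,
    seed = if (method == "louvain") seed else NA_integer_
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Chord-diagram edge list
#'
#' Upper-triangle edge list sorted by descending weight (ties by labels)
#' plus per-node totals (strengths), which a renderer turns into arc
#' lengths proportional to each node's share of the circle perimeter.
#'
#' @param net An `evimap_network` (typically country-level coupling).
#' @return A list with `edges` tibble `(from, to, weight)` and `totals`
#'   tibble `(label, total)`.
#' @export
chord_data <- function(net) {
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(W)[idx[, 1]],
    to = colnames(W)[idx[, 2]],
    weight = W[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$from, .data$to)
  totals <- tibble::tibble(label = rownames(W), total = rowSums(W))
  list(edges = edges, totals = totals)
}
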