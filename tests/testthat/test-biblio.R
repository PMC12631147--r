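test_that("incidence matrices binarize occurrences in appearance order", {
  bib <- tibble::tibble(
    paper_id = c("P1", "P2"),
    authors = list(c("A", "B"), c("B", "B")),  # duplicate collapses
    countries = list("US", character(0)),
    references = list(character(0), character(0)))
  M <- build_incidence(bib, "author")
  expect_equal(unclass(M),
               matrix(c(1L, 0L, 1L, 1L), 2, 2,
                      dimnames = list(c("P1", "P2"), c("A", "B"))),
               ignore_attr = TRUE)
  expect_error(build_incidence(bib, "reference"), "reference")
})

test_that("co-authorship weights equal brute-force pair counting", {
  bib <- tibble::tibble(
    paper_id = c("P1", "P2", "P3"),
    authors = list(c("A", "B", "C"), c("B", "C"), c("C")))
  net <- coauthorship_network(build_incidence(bib, "author"))
  W <- net$weights
  expect_equal(W["A", "B"], 1L)
  expect_equal(W["A", "C"], 1L)
  expect_equal(W["B", "C"], 2L)
  expect_equal(net$nodes$papers[match(c("A", "B", "C"), net$nodes$label)],
               c(1L, 2L, 3L))
  expect_equal(diag(W), setNames(rep(0L, 3), c("A", "B", "C")))
  # intersection bound
  for (a in c("A", "B")) for (b in c("B", "C")) {
    if (a == b) next
    pa <- net$nodes$papers[net$nodes$label == a]
    pb <- net$nodes$papers[net$nodes$label == b]
    expect_lte(W[a, b], min(pa, pb))
  }
  # single-author corpus: edgeless but attributes populated
  solo <- coauthorship_network(build_incidence(
    tibble::tibble(paper_id = c("P1", "P2"),
                   authors = list("A", "A")), "author"))
  expect_true(all(solo$weights == 0))
  expect_equal(solo$nodes$papers, 2L)
})

test_that("matrix-product weights equal set-intersection oracles on random fixtures", {
  set.seed(101)
  for (rep in 1:20) {
    bib <- random_bibliography(sample(3:12, 1))
    net <- coauthorship_network(build_incidence(bib, "author"))
    W <- net$weights
    labs <- rownames(W)
    for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
      expect_identical(as.integer(W[i, j]),
                       oracle_pair_count(bib$authors, labs[i], labs[j]))
    }
    with_refs <- bib[lengths(bib$references) > 0, ]
    if (nrow(with_refs) >= 2) {
      C <- build_incidence(with_refs, "reference")
      cn <- coupling_network(C)
      for (i in seq_len(nrow(with_refs))) for (j in seq_len(i - 1)) {
        expect_identical(
          as.integer(cn$weights[with_refs$paper_id[i],
                                with_refs$paper_id[j]]),
          oracle_coupling(with_refs$references[[i]],
                          with_refs$references[[j]]))
      }
    }
  }
})

test_that("coupling network matches the stated examples", {
  bib <- tibble::tibble(
    paper_id = c("P1", "P2", "P3"),
    authors = list("A", "B", "C"),
    references = list(c("r1", "r2", "r3"), c("r2", "r3"), c("r4")))
  net <- coupling_network(build_incidence(bib, "reference"))
  expect_equal(net$weights["P1", "P2"], 2L)
  expect_equal(net$weights["P1", "P3"], 0L)
  expect_equal(net$nodes$refs, c(3L, 2L, 1L))
  # identical lists couple at the full list length
  bib2 <- tibble::tibble(paper_id = c("Q1", "Q2"), authors = list("A", "B"),
                         references = list(c("r1", "r2"), c("r1", "r2")))
  expect_equal(coupling_network(
    build_incidence(bib2, "reference"))$weights["Q1", "Q2"], 2L)
})

test_that("country aggregation sums paper couplings and conserves mass", {
  bib <- toy_bibliography()  # P1{US}, P2{US,GB}, P3{GB}
  paper_net <- coupling_network(build_incidence(bib, "reference"))
  net <- aggregate_country_coupling(paper_net, bib)
  # coupling(P1,P2)=2; P2 is both US and GB -> US-GB gets P1-P2 (2) + P2-P3 (0)
  expect_equal(net$weights["US", "GB"], net$weights["GB", "US"])
  expect_equal(net$weights["US", "GB"],
               2 +                               # P1(US) x P2(GB)
               0 +                               # P1(US) x P3(GB)
               0)                                # P2(US) x P3(GB)
  # single-country fixture conserves total coupling mass exactly
  bib_sc <- bib
  bib_sc$countries <- list("US", "US", "GB")
  net_sc <- aggregate_country_coupling(paper_net, bib_sc)
  total_pairs <- sum(paper_net$weights[upper.tri(paper_net$weights)])
  expect_equal(sum(net_sc$weights[upper.tri(net_sc$weights)]) +
                 sum(net_sc$nodes$self_coupling),
               total_pairs)
  # papers with no country are excluded with a message
  bib_nc <- bib
  bib_nc$countries <- list("US", character(0), "GB")
  expect_message(aggregate_country_coupling(paper_net, bib_nc), "excluded")
})

test_that("degree centrality follows the classic formulas", {
  tri <- tibble::tibble(paper_id = "P1", authors = list(c("A", "B", "C")))
  net <- coauthorship_network(build_incidence(tri, "author"))
  expect_equal(degree_centrality(net), c(A = 1, B = 1, C = 1))
  expect_equal(degree_centrality(net, weighted = TRUE), c(A = 2, B = 2, C = 2))
  # star of 4: hub 1, leaves 1/3
  star <- tibble::tibble(paper_id = paste0("P", 1:3),
                         authors = list(c("H", "L1"), c("H", "L2"),
                                        c("H", "L3")))
  snet <- coauthorship_network(build_incidence(star, "author"))
  cen <- degree_centrality(snet)
  expect_equal(cen[["H"]], 1)
  expect_equal(cen[["L1"]], 1 / 3)
  # adding an edge never decreases strength
  s0 <- degree_centrality(snet, weighted = TRUE)
  star2 <- dplyr::bind_rows(star,
                            tibble::tibble(paper_id = "P4",
                                           authors = list(c("L1", "L2"))))
  s1 <- degree_centrality(coauthorship_network(
    build_incidence(star2, "author")), weighted = TRUE)
  expect_true(all(s1[names(s0)] >= s0))
})

test_that("component clustering matches flood fill and the stated summaries", {
  two_tri <- tibble::tibble(
    paper_id = paste0("P", 1:2),
    authors = list(c("A", "B", "C"), c("D", "E", "F")))
  net <- coauthorship_network(build_incidence(two_tri, "author"))
  cl <- author_clusters(net, method = "components")
  expect_equal(cl$summary$n_clusters, 2)
  expect_equal(cl$summary$mean_size, 3)
  expect_equal(cl$summary$max_size, 3)
  # ids by decreasing size, ties by smallest member label: A's cluster first
  expect_equal(cl$membership[["A"]], 1L)
  expect_equal(cl$membership[["D"]], 2L)

  set.seed(55)
  for (i in 1:10) {
    bib <- random_bibliography(sample(3:10, 1))
    net <- coauthorship_network(build_incidence(bib, "author"))
    cl <- author_clusters(net, method = "components")
    ref <- oracle_components(net$weights)
    # same partition up to relabeling
    expect_equal(length(unique(cl$membership)), length(unique(ref)))
    expect_true(all(tapply(cl$membership, ref,
                           function(x) length(unique(x))) == 1))
  }
  # louvain runs deterministically under a fixed seed
  bib <- random_bibliography(8)
  net <- coauthorship_network(build_incidence(bib, "author"))
  l1 <- author_clusters(net, method = "louvain", seed = 3)
  l2 <- author_clusters(net, method = "louvain", seed = 3)
  expect_identical(l1$membership, l2$membership)
})

test_that("component partition is invariant to node relabeling", {
  bib <- random_bibliography(6)
  net <- coauthorship_network(build_incidence(bib, "author"))
  cl <- author_clusters(net)
  perm <- sample(nrow(net$weights))
  net2 <- net
  net2$weights <- net$weights[perm, perm]
  net2$nodes <- net$nodes[perm, ]
  cl2 <- author_clusters(net2)
  # same nodes grouped together regardless of order
  sig <- function(m) sort(vapply(split(names(m), m), function(s)
    paste(sort(s), collapse = ","), character(1)), method = "radix")
  expect_identical(unname(sig(cl$membership)), unname(sig(cl2$membership)))
})

test_that("chord data lists edges by weight and conserves strengths", {
  bib <- toy_bibliography()
  net <- coupling_network(build_incidence(bib, "reference"))
  cd <- chord_data(net)
  expect_equal(nrow(cd$edges), 1)
  expect_equal(cd$edges$weight, 2L)
  expect_equal(cd$totals$total, rowSums(net$weights), ignore_attr = TRUE)
  # totals equal twice the edge mass
  expect_equal(sum(cd$totals$total), 2 * sum(cd$edges$weight))
})
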