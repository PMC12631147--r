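# Shared fixtures and independent brute-force oracles.

# A small hand-built evidence base: 5 effects, 3 studies, two moderators.
toy_dataset <- function() {
  eff <- tibble::tibble(
    study_id  = c("s1", "s1", "s2", "s2", "s3"),
    effect_id = paste0("e", 1:5),
    yi = c(0.2, 0.4, 0.5, 0.1, -0.3),
    vi = c(0.04, 0.05, 0.02, 0.08, 0.10),
    intervention = c("CM", "CM", "PSM", "PSM", "CM"),
    outcome = c("QoL", "AQLQ", "QoL", "QoL", NA)
  )
  evimap_dataset(eff)
}

# Three papers with overlapping authors / references / countries.
toy_bibliography <- function() {
  tibble::tibble(
    paper_id = c("P1", "P2", "P3"),
    doi = c("10.1/a", "10.1/b", "10.1/c"),
    authors = list(c("a", "b", "c"), c("b", "c"), c("c")),
    countries = list("US", c("US", "GB"), "GB"),
    year = c(2001L, 2002L, 2003L),
    journal = c("J1", "J1", "J2"),
    funder = NA_character_,
    references = list(c("r1", "r2", "r3"), c("r2", "r3"), c("r4"))
  )
}

# Oracle: inverse-variance / GLS pooling by explicit matrix inversion.
oracle_gls <- function(y, V) {
  Vi <- solve(V)
  ones <- rep(1, length(y))
  est <- as.numeric(t(ones) %*% Vi %*% y) / as.numeric(t(ones) %*% Vi %*% ones)
  se <- sqrt(1 / as.numeric(t(ones) %*% Vi %*% ones))
  list(estimate = est, se = se)
}

# Oracle: co-authorship weight by brute-force pair counting over papers.
oracle_pair_count <- function(author_lists, a, b) {
  sum(vapply(author_lists, function(x) a %in% x && b %in% x, logical(1)))
}

# Oracle: coupling weight as reference-set intersection size.
oracle_coupling <- function(refs_p, refs_q) {
  length(intersect(unique(refs_p), unique(refs_q)))
}

# Oracle: connected components by flood fill on the adjacency matrix.
oracle_components <- function(W) {
  n <- nrow(W)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(W[v, ] > 0 & is.na(comp)))
    }
  }
  stats::setNames(comp, rownames(W))
}

# Random bibliography fixture for network property tests.
random_bibliography <- function(n_papers, n_authors = 10, n_refs = 15) {
  tibble::tibble(
    paper_id = sprintf("P%02d", seq_len(n_papers)),
    doi = sprintf("10.9/%02d", seq_len(n_papers)),
    authors = lapply(seq_len(n_papers), function(i)
      sample(paste0("au", seq_len(n_authors)), sample(1:4, 1))),
    countries = lapply(seq_len(n_papers), function(i)
      sample(c("US", "GB", "DE"), sample(1:2, 1))),
    year = sample(2000:2020, n_papers, replace = TRUE),
    journal = "J",
    funder = NA_character_,
    references = lapply(seq_len(n_papers), function(i)
      sample(paste0("r", seq_len(n_refs)), sample(0:6, 1)))
  )
}
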