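# Grafen branch lengths, Brownian-motion correlation, per-species pooling.
#
# Trees are `ape::phylo` objects throughout; input branch lengths are
# ignored and recomputed by the Grafen rule.

#' Parse a Newick tree
#'
#' @param text Newick string, or the path of a file containing one.
#' @return A rooted `phylo` object (polytomies permitted).
#' @export
parse_newick <- function(text) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr)) {
    abort(sprintf("malformed Newick string: %s",
                  substr(text, 1, 60)))
  }
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicate tip label(s): %s",
                  paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                        collapse = ", ")))
  }
  # the basal node of the Newick string is taken as the root; a basal
  # polytomy is a rooted star, not an unrooted tree
  tr
}

# number of descendant tips per node (tips themselves count 1)
.n_desc_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cnt <- c(rep(1L, n_tip), rep(0L, tree$Nnode))
  # accumulate child counts up the (topologically ordered) edge list
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    cnt[ord$edge[i, 1]] <- cnt[ord$edge[i, 1]] + cnt[ord$edge[i, 2]]
  }
  cnt
}

#' Assign Grafen branch lengths
#'
#' Each node's raw height is `(number of descendant tips - 1) / (N - 1)`
#' (`N` tips in total), putting tips at height 0 and the root at 1; heights
#' are raised to `power` and each branch length is the parent height minus
#' the child height. The result is ultrametric with tip depth exactly 1.
#'
#' @param tree A rooted `phylo` with >= 2 tips.
#' @param power Exponent applied to the normalized heights (> 0); `1` gives
#'   the plain Grafen heights.
#' @return The tree with `edge.length` set and a `node_height` attribute
#'   (heights indexed by node number).
#' @export
grafen_lengths <- function(tree, power = 1) {
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) abort("tree needs >= 2 tips")
  if (!is.numeric(power) || power <= 0) abort("power must be > 0")
  cnt <- .n_desc_tips(tree)
  h <- ((cnt - 1) / (n_tip - 1))^power
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  attr(tree, "node_height") <- h
  tree
}

#' Brownian-motion correlation matrix from a tree
#'
#' Under Brownian trait evolution the covariance between two tips equals the
#' depth (root-to-node path length) of their most recent common ancestor;
#' the correlation scales that by the tip depths. After [grafen_lengths()]
#' the tips sit at depth 1, so entries lie in `[0, 1]` with a unit diagonal.
#'
#' @param tree A rooted `phylo` with branch lengths (e.g. from
#'   [grafen_lengths()]).
#' @return A symmetric positive-semidefinite correlation matrix with tip
#'   labels as dimnames.
#' @export
brownian_corr <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object")
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; run grafen_lengths() first")
  }
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root, all nodes
  mrca <- ape::mrca(tree)                      # tip x tip MRCA node numbers
  cov <- matrix(depth[mrca], n_tip, n_tip,
                dimnames = list(tree$tip.label, tree$tip.label))
  diag(cov) <- depth[seq_len(n_tip)]
  stats::cov2cor(cov)
}

#' Per-species pooled effects for tree-aligned forest display
#'
#' For every species, builds the within-species sampling VCV at the assumed
#' correlation `rho` and pools by fixed-effect GLS with a Wald (z) 95% CI;
#' a single-effect species passes its effect and `sqrt(vi)` through. When a
#' tree is supplied, rows follow the tree's tip order and species present in
#' only one of data/tree are reported via attributes and a message.
#'
#' @param dataset An [evimap_dataset()] whose effects carry `species`, `yi`,
#'   `vi`.
#' @param rho Assumed within-species sampling correlation in `[0, 1)`.
#' @param tree Optional `phylo` whose tip labels are species names.
#' @return A tibble `(species, n_effects, estimate, se, ci_low, ci_high)`
#'   with attributes `missing_in_tree` and `missing_in_data`.
#' @export
species_means <- function(dataset, rho = 0.5, tree = NULL) {
  eff <- dataset$effects
  if (!"species" %in% names(eff) || all(is.na(eff$species))) {
    abort("dataset has no species column")
  }
  if (any(is.na(eff$yi) | is.na(eff$vi))) {
    abort("yi/vi must be filled first (see fill_effect_sizes)")
  }
  eff <- eff[!is.na(eff$species), ]
  sp <- unique(eff$species)
  rows <- lapply(sp, function(s) {
    inn <- eff$species == s
    y <- eff$yi[inn]; v <- eff$vi[inn]
    if (sum(inn) == 1) {
      est <- y; se <- sqrt(v)
    } else {
      V <- build_vcv(v, cluster = rep(s, length(v)), rho = rho)
      p <- pool_fixed_gls(y, V)
      est <- p$estimate; se <- p$se
    }
    tibble::tibble(species = s, n_effects = sum(inn), estimate = est,
                   se = se, ci_low = est - .z975 * se,
                   ci_high = est + .z975 * se)
  })
  out <- dplyr::bind_rows(rows)
  missing_in_tree <- character(0); missing_in_data <- character(0)
  if (!is.null(tree)) {
    missing_in_tree <- setdiff(out$species, tree$tip.label)
    missing_in_data <- setdiff(tree$tip.label, out$species)
    if (length(missing_in_tree) || length(missing_in_data)) {
      inform(sprintf(
        "species mismatch: %d in data only, %d in tree only",
        length(missing_in_tree), length(missing_in_data)))
    }
    ord <- match(tree$tip.label, out$species)
    out <- dplyr::bind_rows(out[ord[!is.na(ord)], ],
                            out[out$species %in% missing_in_tree, ])
  }
  attr(out, "missing_in_tree") <- missing_in_tree
  attr(out, "missing_in_data") <- missing_in_data
  out
}
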