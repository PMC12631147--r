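# Effect-size computation and pooling.
#
# Estimators implemented here:
#   * Hedges' g with small-sample correction J = 1 - 3/(4*df - 1)
#   * block-diagonal sampling variance-covariance matrices under an assumed
#     within-cluster sampling correlation rho
#   * fixed-effect GLS pooling (inverse of the full VCV as the weight matrix)
#   * DerSimonian-Laird random effects (method-of-moments tau^2)
#   * CR1-type cluster-robust (sandwich) variance with t(m-1) reference
#   * leave-one-cluster-out sensitivity analysis

.z975 <- 1.959964

#' Hedges' g from two-group summaries
#'
#' Standardized mean difference with the small-sample correction
#' `J = 1 - 3/(4*df - 1)`, `df = n1 + n2 - 2`:
#' `g = J * (m1 - m2) / s_p` with pooled SD
#' `s_p = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / df)`, and sampling variance
#' `vg = J^2 * ((n1+n2)/(n1*n2) + d^2/(2*df))`.
#'
#' @param m1,s1,n1 Treatment-group mean, SD (> 0) and size (>= 2).
#' @param m2,s2,n2 Control-group mean, SD (> 0) and size (>= 2).
#' @return A tibble with columns `g` and `vg`. Vectorized.
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (any(s1 <= 0 | s2 <= 0, na.rm = TRUE)) {
    abort("group SDs must be > 0")
  }
  if (any(n1 < 2 | n2 < 2, na.rm = TRUE)) {
    abort("group sizes must be >= 2")
  }
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (any(sp == 0, na.rm = TRUE)) {
    abort("degenerate input: pooled SD is zero (identical constant groups)")
  }
  d <- (m1 - m2) / sp
  J <- 1 - 3 / (4 * df - 1)
  tibble::tibble(g = J * d,
                 vg = J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * df)))
}

#' Fill yi/vi from raw outcomes where missing
#'
#' Applies [hedges_g()] to rows whose effect size is absent but whose raw
#' two-group summaries are present.
#'
#' @param dataset An [evimap_dataset()].
#' @return The dataset with `yi`, `vi` completed.
#' @export
fill_effect_sizes <- function(dataset) {
  eff <- dataset$effects
  if (!"yi" %in% names(eff)) eff$yi <- NA_real_
  if (!"vi" %in% names(eff)) eff$vi <- NA_real_
  need <- is.na(eff$yi) & !is.na(eff$m1)
  if (any(need)) {
    gv <- hedges_g(eff$m1[need], eff$s1[need], eff$n1[need],
                   eff$m2[need], eff$s2[need], eff$n2[need])
    eff$yi[need] <- gv$g
    eff$vi[need] <- gv$vg
  }
  dataset$effects <- eff
  dataset
}

#' Sampling variance-covariance matrix under assumed correlation
#'
#' Block-diagonal by cluster: within a cluster
#' `cov(i, j) = rho * sqrt(vi * vj)`; zero across clusters; diagonal `vi`.
#' The default `rho = 0.5` follows the convention of guesstimating the
#' sampling correlation when ancillary data are unavailable.
#'
#' @param vi Sampling variances (> 0).
#' @param cluster Cluster labels (same length as `vi`); a single common
#'   cluster when omitted.
#' @param rho Assumed within-cluster sampling correlation in `[0, 1)`.
#' @param labels Effect IDs for dimnames.
#' @return A symmetric matrix of class `evimap_vcv` with attributes `rho`
#'   and `cluster`.
#' @export
build_vcv <- function(vi, cluster = NULL, rho = 0.5, labels = NULL) {
  if (any(is.na(vi)) || any(vi <= 0)) abort("all vi must be present and > 0")
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    abort("rho must lie in [0, 1)")
  }
  k <- length(vi)
  if (is.null(cluster)) cluster <- rep("all", k)
  cluster <- as.character(cluster)
  sd <- sqrt(vi)
  same <- outer(cluster, cluster, "==")
  V <- rho * outer(sd, sd) * same
  diag(V) <- vi
  if (is.null(labels)) labels <- as.character(seq_len(k))
  dimnames(V) <- list(labels, labels)
  structure(V, rho = rho, cluster = cluster, class = c("evimap_vcv", "matrix"))
}

.pooled_estimate <- function(estimate, se, crit, n_studies, n_effects, method,
                             degenerate = FALSE) {
  tibble::tibble(
    estimate = estimate, se = se,
    ci_low = estimate - crit * se, ci_high = estimate + crit * se,
    n_studies = as.integer(n_studies), n_effects = as.integer(n_effects),
    method = method, degenerate = degenerate
  )
}

#' Fixed-effect GLS pooling
#'
#' Weighted mean using the inverse of the full sampling VCV:
#' `estimate = (1' V^-1 y) / (1' V^-1 1)`, `se = sqrt(1 / (1' V^-1 1))`,
#' Wald 95% CI with `z = 1.959964`. With a diagonal `V` this reduces to the
#' classic inverse-variance weighted mean.
#'
#' @param y Effect sizes, aligned with the rows of `V`.
#' @param V VCV matrix from [build_vcv()] (or any positive-definite matrix).
#' @param n_studies Number of distinct studies behind `y` (defaults to the
#'   number of distinct clusters recorded in `V`, else `length(y)`).
#' @return A one-row `PooledEstimate` tibble.
#' @export
pool_fixed_gls <- function(y, V, n_studies = NULL) {
  k <- length(y)
  if (k != nrow(V)) abort("y and V are not aligned")
  ch <- tryCatch(chol(V), error = function(e)
    abort("V is not positive definite; try a smaller rho"))
  Vinv <- chol2inv(ch)
  w <- rowSums(Vinv)
  sw <- sum(w)
  est <- sum(w * y) / sw
  se <- sqrt(1 / sw)
  if (is.null(n_studies)) {
    cl <- attr(V, "cluster")
    n_studies <- if (!is.null(cl)) length(unique(cl)) else k
  }
  .pooled_estimate(est, se, .z975, n_studies, k, "fixed_gls")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance:
#' `Q = sum w (y - ybar_w)^2` with `w = 1/v`;
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`;
#' then inverse-variance weights `1 / (v + tau2)` and a Wald 95% CI.
#'
#' @param y Effect sizes (k >= 2).
#' @param v Sampling variances (> 0).
#' @param n_studies See [pool_fixed_gls()].
#' @return A one-row tibble with the pooled estimate plus `tau2` and `Q`.
#' @export
pool_random_dl <- function(y, v, n_studies = length(y)) {
  k <- length(y)
  if (k < 2) abort("random-effects pooling needs at least 2 effects")
  if (any(v <= 0)) abort("all vi must be > 0")
  w <- 1 / v
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (Q - (k - 1)) / denom) else 0
  wstar <- 1 / (v + tau2)
  est <- sum(wstar * y) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  out <- .pooled_estimate(est, se, .z975, n_studies, k, "random_dl")
  out$tau2 <- tau2
  out$Q <- Q
  out
}

#' Cluster-robust (sandwich) variance for the GLS pooled mean
#'
#' Point estimate from [pool_fixed_gls()]; the variance is a CR1-type
#' sandwich over clusters: with scalar weights `w_i` = row sums of `V^-1`
#' and residuals `e_i = y_i - estimate`,
#' `se^2 = m/(m-1) * sum_c (sum_{i in c} w_i e_i)^2 / (sum w)^2`,
#' with a 95% CI from the t distribution on `m - 1` degrees of freedom
#' (`m` = number of clusters). A zero residual vector yields `se = 0` and is
#' flagged `degenerate`.
#'
#' @param y Effect sizes.
#' @param V VCV matrix from [build_vcv()].
#' @param clusters Cluster labels (default: those recorded in `V`).
#' @return A one-row `PooledEstimate` tibble (`method = "robust"`).
#' @export
robust_variance <- function(y, V, clusters = attr(V, "cluster")) {
  if (is.null(clusters)) abort("cluster labels are required")
  clusters <- as.character(clusters)
  m <- length(unique(clusters))
  if (m < 2) {
    abort("cluster-robust variance needs >= 2 clusters (independence across clusters is the identifying assumption)")
  }
  fe <- pool_fixed_gls(y, V, n_studies = m)
  Vinv <- chol2inv(chol(V))
  w <- rowSums(Vinv)
  e <- y - fe$estimate
  S <- tapply(w * e, clusters, sum)
  se2 <- (m / (m - 1)) * sum(S^2) / sum(w)^2
  se <- sqrt(se2)
  crit <- qt(0.975, df = m - 1)
  .pooled_estimate(fe$estimate, se, crit, m, length(y), "robust",
                   degenerate = se == 0)
}

# Internal dispatcher used by grids / orchard / leave-one-out.
# Single effects pass through with their own se and a z interval.
pool_effects <- function(y, v, cluster = NULL, method = c("robust",
                                                          "fixed_gls",
                                                          "random_dl"),
                         rho = 0.5) {
  method <- match.arg(method)
  k <- length(y)
  if (is.null(cluster)) cluster <- as.character(seq_len(k))
  n_studies <- length(unique(cluster))
  if (k == 1) {
    return(.pooled_estimate(y, sqrt(v), .z975, 1L, 1L, "single_effect"))
  }
  V <- build_vcv(v, cluster = cluster, rho = rho)
  switch(method,
    fixed_gls = pool_fixed_gls(y, V, n_studies = n_studies),
    random_dl = pool_random_dl(y, v, n_studies = n_studies),
    robust = if (n_studies >= 2) robust_variance(y, V)
             else pool_fixed_gls(y, V, n_studies = n_studies)
  )
}

#' Leave-one-cluster-out sensitivity analysis
#'
#' For each cluster (study or research group), pools the remaining effects
#' and, separately, the held-out cluster alone, so dominant clusters can be
#' compared against the rest of the evidence base.
#'
#' @param dataset An [evimap_dataset()] with `yi`, `vi` filled.
#' @param cluster_by Column holding cluster labels (default
#'   `"author_cluster"`, falling back to `"study_id"`).
#' @param method Pooling method for both fits, see [pool_effects()].
#' @param rho Assumed within-study sampling correlation.
#' @return A tibble with one row per cluster: held-out label, sizes, the
#'   complement's pooled estimate (`rest_*`) and the cluster's own
#'   (`own_*`).
#' @export
leave_one_cluster_out <- function(dataset, cluster_by = NULL,
                                  method = "fixed_gls", rho = 0.5) {
  eff <- dataset$effects
  if (is.null(cluster_by)) {
    cluster_by <- if ("author_cluster" %in% names(eff) &&
                      !all(is.na(eff$author_cluster))) "author_cluster"
                  else "study_id"
  }
  if (!cluster_by %in% names(eff)) {
    abort(sprintf("cluster column '%s' not found", cluster_by))
  }
  if (any(is.na(eff$yi) | is.na(eff$vi))) {
    abort("yi/vi must be filled first (see fill_effect_sizes)")
  }
  cl <- as.character(eff[[cluster_by]])
  labs <- unique(cl)
  if (length(labs) < 2) abort("leave-one-out needs >= 2 clusters")
  rows <- lapply(labs, function(lab) {
    inn <- cl == lab
    rest <- pool_effects(eff$yi[!inn], eff$vi[!inn],
                         cluster = eff$study_id[!inn],
                         method = method, rho = rho)
    own <- pool_effects(eff$yi[inn], eff$vi[inn],
                        cluster = eff$study_id[inn],
                        method = method, rho = rho)
    tibble::tibble(
      cluster = lab, n_effects_held = sum(inn),
      rest_estimate = rest$estimate, rest_se = rest$se,
      rest_ci_low = rest$ci_low, rest_ci_high = rest$ci_high,
      own_estimate = own$estimate, own_se = own$se,
      own_ci_low = own$ci_low, own_ci_high = own$ci_high
    )
  })
  dplyr::bind_rows(rows)
}
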