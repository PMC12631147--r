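# Seeded synthetic evidence bases with known truth: effect tables with raw
# two-group outcomes, random species trees, clustered bibliographies, and
# altmetric fixtures. One named pseudo-random substream per generator, so
# adding a generator never perturbs existing fixtures.

# deterministic substream seed below 2^31, derived from seed + stream name
.stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.with_stream <- function(seed, name, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.stream_seed(seed, name))
  force(code)
}

#' Synthetic-evidence-base configuration
#'
#' Defaults describe a mid-sized clinical/ecological evidence base: 30
#' studies contributing 1-3 effects each, a global true mean of 0.5 on the
#' standardized-mean-difference scale with no between-study heterogeneity,
#' group sizes of 20-40 per arm, two crossed moderators, three disjoint
#' research groups, and log-normal altmetric attention.
#'
#' @param seed Integer master seed; every generator derives its own named
#'   substream from it.
#' @param n_studies Number of studies.
#' @param effects_per_study Integer range `c(min, max)` of effects drawn per
#'   study.
#' @param moderators Named list; each element is a list with `levels`
#'   (character) and optional `effects` (additive true shifts per level,
#'   default 0).
#' @param true_mu Global true mean effect.
#' @param tau2 Between-study variance of the true effects.
#' @param group_n Range of per-arm sample sizes for the raw outcomes.
#' @param n_species Number of species (0 = no species labels).
#' @param tree_signal `"none"` or `"brownian"` (species deviations drawn
#'   along the generated tree under Brownian motion with variance
#'   `species_sigma2`).
#' @param species_sigma2 Variance of the Brownian species deviations.
#' @param n_author_clusters,authors_per_cluster Research-group structure of
#'   the generated bibliography.
#' @param refs_pool_size Size of each cluster's shared reference pool.
#' @param shared_ref_rate Probability in `[0, 1]` that a cited reference is
#'   drawn from the cluster's shared pool (0 gives disjoint reference
#'   lists, hence an empty coupling network).
#' @param country_pool Candidate affiliation countries (one dominant per
#'   cluster).
#' @param country_dominance Probability a paper carries its cluster's
#'   dominant country (otherwise a random one).
#' @param alt_meanlog,alt_sdlog Log-normal parameters of the Altmetric
#'   score.
#' @param policy_rate,patent_rate Poisson means of policy and patent
#'   citation counts.
#' @return A validated list of class `evimap_synth_config`.
#' @export
synth_config <- function(seed = 1L, n_studies = 30L,
                         effects_per_study = c(1L, 3L),
                         moderators = list(
                           intervention = list(levels = c("CM", "PSM", "SSM")),
                           outcome = list(levels = c("QoL", "AQLQ"))
                         ),
                         true_mu = 0.5, tau2 = 0,
                         group_n = c(20L, 40L),
                         n_species = 0L, tree_signal = c("none", "brownian"),
                         species_sigma2 = 0.1,
                         n_author_clusters = 3L,
                         authors_per_cluster = c(4L, 8L),
                         refs_pool_size = 30L, shared_ref_rate = 0.5,
                         country_pool = c("US", "GB", "DE", "AU", "CN"),
                         country_dominance = 0.8,
                         alt_meanlog = 2, alt_sdlog = 1,
                         policy_rate = 2, patent_rate = 1) {
  tree_signal <- match.arg(tree_signal)
  stopifnot(n_studies >= 1, all(effects_per_study >= 1),
            effects_per_study[1] <= effects_per_study[2],
            tau2 >= 0, all(group_n >= 2),
            n_species >= 0, n_author_clusters >= 1,
            all(authors_per_cluster >= 1), refs_pool_size >= 1,
            shared_ref_rate >= 0, shared_ref_rate <= 1,
            country_dominance >= 0, country_dominance <= 1,
            policy_rate >= 0, patent_rate >= 0)
  if (n_studies < n_author_clusters) {
    abort("infeasible config: fewer studies than author clusters")
  }
  structure(as.list(environment()), class = "evimap_synth_config")
}

.rint <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# summary statistics of a normal sample, drawn exactly:
# mean ~ N(mu, 1/n), var ~ sigma2 * chisq(n-1)/(n-1)
.rsummary <- function(n, mu) {
  list(m = rnorm(length(n), mu, 1 / sqrt(n)),
       s = sqrt(rchisq(length(n), n - 1) / (n - 1)))
}

#' Generate a synthetic effect table with known truth
#'
#' Study true effects are `theta_s ~ Normal(mu_cell, tau2)` where `mu_cell`
#' adds the configured moderator shifts to `true_mu` (plus a Brownian
#' species deviation when `tree_signal = "brownian"`). Each effect carries
#' raw two-group summaries: a control arm `Normal(0, 1)` and a treatment
#' arm `Normal(theta_s, 1)` with per-arm sizes from `group_n`, so that
#' Hedges' g recovers `theta_s` in expectation. All effects of a study
#' share the study's single control arm, which induces a genuine
#' within-study sampling correlation of roughly `n2 / (n1 + n2)` (about 0.5
#' at equal arm sizes) — the structure the pooling default `rho = 0.5`
#' assumes. Moderators and species are assigned at the study level.
#'
#' @param config A [synth_config()].
#' @return An [evimap_dataset()] with raw outcomes (`yi`, `vi` empty; run
#'   [fill_effect_sizes()]), plus attributes `true_theta` (per study) and
#'   `tree` (Newick, when species are generated).
#' @export
gen_effects <- function(config) {
  cfg <- config
  tree_text <- NULL
  sp_dev <- NULL
  species_names <- NULL
  if (cfg$n_species > 0) {
    tree_text <- gen_tree(cfg$n_species, cfg$seed)
    species_names <- paste0("sp", seq_len(cfg$n_species))
    if (cfg$tree_signal == "brownian") {
      tr <- grafen_lengths(parse_newick(tree_text), power = 1)
      R <- brownian_corr(tr)[species_names, species_names]
      sp_dev <- .with_stream(cfg$seed, "species", {
        L <- chol(R + diag(1e-10, nrow(R)))
        as.numeric(t(L) %*% rnorm(nrow(R))) * sqrt(cfg$species_sigma2)
      })
    } else {
      sp_dev <- rep(0, cfg$n_species)
    }
    names(sp_dev) <- species_names
  }
  .with_stream(cfg$seed, "effects", {
    S <- cfg$n_studies
    study_id <- sprintf("study%03d", seq_len(S))
    k_eff <- .rint(S, cfg$effects_per_study)
    mod_levels <- lapply(cfg$moderators, function(m) {
      sample(m$levels, S, replace = TRUE)
    })
    mod_shift <- rep(0, S)
    for (nm in names(cfg$moderators)) {
      effv <- cfg$moderators[[nm]]$effects
      if (!is.null(effv)) {
        if (length(effv) != length(cfg$moderators[[nm]]$levels)) {
          abort(sprintf("moderator '%s': effects and levels differ in length",
                        nm))
        }
        mod_shift <- mod_shift +
          effv[match(mod_levels[[nm]], cfg$moderators[[nm]]$levels)]
      }
    }
    study_species <- if (!is.null(species_names)) {
      sample(species_names, S, replace = TRUE)
    } else rep(NA_character_, S)
    theta <- cfg$true_mu + mod_shift +
      (if (!is.null(sp_dev)) sp_dev[study_species] else 0) +
      rnorm(S, 0, sqrt(cfg$tau2))
    # one shared control arm per study; treatment arms vectorized over all
    # effects at once
    n2 <- .rint(S, cfg$group_n)
    ctrl <- .rsummary(n2, 0)
    idx <- rep(seq_len(S), k_eff)
    n1 <- .rint(length(idx), cfg$group_n)
    trt <- .rsummary(n1, theta[idx])
    sid <- study_id[idx]
    eid <- sprintf("%s_e%d", sid, sequence(k_eff))
    eff <- tibble::tibble(
      study_id = sid, effect_id = eid,
      m1 = trt$m, s1 = trt$s, n1 = n1,
      m2 = ctrl$m[idx], s2 = ctrl$s[idx], n2 = n2[idx],
      species = study_species[idx]
    )
    for (nm in names(mod_levels)) {
      eff[[nm]] <- mod_levels[[nm]][match(eff$study_id, study_id)]
    }
    schema <- lapply(cfg$moderators, function(m) m$levels)
    # keep only levels that can occur plus any observed ones, in declared order
    ds <- evimap_dataset(eff, moderators = names(cfg$moderators),
                         schema = schema)
    attr(ds, "true_theta") <- setNames(theta, study_id)
    attr(ds, "tree") <- tree_text
    ds
  })
}

#' Generate a random rooted binary species tree
#'
#' Random topology with tips `sp1..spN` and no branch lengths (the Grafen
#' rule assigns them downstream). Deterministic for a fixed seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A Newick string.
#' @export
gen_tree <- function(n_species, seed = 1L) {
  if (n_species < 2) abort("a tree needs >= 2 species")
  .with_stream(seed, "tree", {
    tr <- ape::rtree(n_species, br = NULL,
                     tip.label = paste0("sp", seq_len(n_species)))
    ape::write.tree(tr)
  })
}

#' Generate a clustered synthetic bibliography
#'
#' The author pool is partitioned into `n_author_clusters` disjoint research
#' groups; every paper draws all its authors from exactly one group, with a
#' group "hub" author on every paper and the remaining members rotated in,
#' so the true co-authorship components equal the declared groups for every
#' seed. Cited references mix a per-cluster shared pool (probability
#' `shared_ref_rate`) with paper-unique keys; each cluster has a dominant
#' affiliation country. DOIs are synthetic (`10.5555/synth.<study>`).
#'
#' @param config A [synth_config()].
#' @param dataset The [gen_effects()] dataset the papers belong to.
#' @return A bibliography tibble (one record per study) with attribute
#'   `true_clusters` (named cluster id per author).
#' @export
gen_bibliography <- function(config, dataset) {
  cfg <- config
  studies <- unique(dataset$effects$study_id)
  P <- length(studies)
  .with_stream(cfg$seed, "bibliography", {
    K <- cfg$n_author_clusters
    sizes <- .rint(K, cfg$authors_per_cluster)
    # names are fixed points of normalize_author(), so CSV/BibTeX
    # round-trips preserve author identity
    authors <- lapply(seq_len(K), function(k) {
      sprintf("c%dauthor %s", k, letters[seq_len(sizes[k])])
    })
    cluster_of_paper <- rep(seq_len(K), length.out = P)  # every cluster used
    country_of <- cfg$country_pool[
      ((seq_len(K) - 1) %% length(cfg$country_pool)) + 1]
    ref_pools <- lapply(seq_len(K), function(k) {
      sprintf("ref_c%d_%03d", k, seq_len(cfg$refs_pool_size))
    })
    # rotate non-hub members across the cluster's papers so every author
    # appears on at least one paper (keeps true components = clusters)
    rotation <- vector("list", P)
    for (k in seq_len(K)) {
      mem <- authors[[k]][-1]
      papers_k <- which(cluster_of_paper == k)
      for (i in seq_along(mem)) {
        p <- papers_k[((i - 1) %% length(papers_k)) + 1]
        rotation[[p]] <- c(rotation[[p]], mem[i])
      }
    }
    recs <- lapply(seq_len(P), function(p) {
      k <- cluster_of_paper[p]
      hub <- authors[[k]][1]
      rot <- rotation[[p]]
      extra <- setdiff(authors[[k]], c(hub, rot))
      n_extra <- if (length(extra))
        sample(0:min(2, length(extra)), 1) else 0
      aut <- unique(c(hub, rot,
                      if (n_extra > 0) sample(extra, n_extra)))
      n_refs <- sample(5:10, 1)
      shared <- runif(n_refs) < cfg$shared_ref_rate
      refs <- character(n_refs)
      if (any(shared)) {
        refs[shared] <- sample(ref_pools[[k]], sum(shared), replace = TRUE)
      }
      if (any(!shared)) {
        refs[!shared] <- sprintf("ref_%s_%02d", studies[p],
                                 which(!shared))
      }
      ctry <- if (runif(1) < cfg$country_dominance) country_of[k]
              else sample(cfg$country_pool, 1)
      tibble::tibble(
        paper_id = studies[p],
        doi = paste0("10.5555/synth.", tolower(studies[p])),
        authors = list(aut),
        countries = list(ctry),
        year = sample(2000:2023, 1),
        journal = sprintf("Journal %d", k),
        funder = NA_character_,
        references = list(unique(refs))
      )
    })
    bib <- dplyr::bind_rows(recs)
    truth <- unlist(lapply(seq_len(K), function(k) {
      setNames(rep(k, length(authors[[k]])), authors[[k]])
    }))
    attr(bib, "true_clusters") <- truth
    bib
  })
}

#' Generate an altmetric fixture covering every DOI
#'
#' Scores are log-normal, policy and patent counts Poisson, per the config.
#'
#' @param dataset Unused except for API symmetry; may be `NULL`.
#' @param bibliography Bibliography tibble (its DOIs are covered).
#' @param config A [synth_config()].
#' @return A fixture tibble `(doi, score, policy_citations,
#'   patent_citations)` suitable for [metric_client()].
#' @export
gen_altmetric_fixture <- function(dataset, bibliography, config) {
  cfg <- config
  dois <- tolower(bibliography$doi)
  .with_stream(cfg$seed, "altmetrics", {
    tibble::tibble(
      doi = dois,
      score = round(rlnorm(length(dois), cfg$alt_meanlog, cfg$alt_sdlog), 1),
      policy_citations = rpois(length(dois), cfg$policy_rate),
      patent_citations = rpois(length(dois), cfg$patent_rate)
    )
  })
}
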