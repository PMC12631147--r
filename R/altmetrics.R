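# Alternative impact metrics: retrieval (offline fixture / cache / live
# API), joining to the evidence base, orchard-plot and impact-grid data.

#' Construct a metric client
#'
#' The client either reads a local fixture table (`offline = TRUE`, the
#' default — it never touches the network), or queries the public Altmetric
#' details endpoint per DOI with caching and a rate limit. Every response is
#' cached by DOI, so repeated calls are idempotent.
#'
#' @param offline Never touch the network; resolve from `fixture` + cache.
#' @param fixture Path to (or tibble of) a fixture table with columns
#'   `doi`, `score`, `policy_citations`, `patent_citations` (optionally
#'   `retrieved_at`).
#' @param cache_dir Directory for per-DOI JSON cache files.
#' @param base_url Live endpoint (DOI is appended).
#' @param api_key Optional API key appended as `?key=`.
#' @param rate_limit Maximum requests per second for the live path.
#' @return A list of class `evimap_metric_client`.
#' @export
metric_client <- function(offline = TRUE, fixture = NULL, cache_dir = NULL,
                          base_url = "https://api.altmetric.com/v1/doi/",
                          api_key = NULL, rate_limit = 1) {
  fix <- NULL
  if (!is.null(fixture)) {
    fix <- if (is.character(fixture)) {
      readr::read_csv(fixture, show_col_types = FALSE, progress = FALSE)
    } else tibble::as_tibble(fixture)
    need <- c("doi", "score", "policy_citations", "patent_citations")
    miss <- setdiff(need, names(fix))
    if (length(miss)) {
      abort(sprintf("fixture is missing column(s): %s",
                    paste(miss, collapse = ", ")))
    }
    fix$doi <- tolower(fix$doi)
  }
  structure(list(offline = offline, fixture = fix, cache_dir = cache_dir,
                 base_url = base_url, api_key = api_key,
                 rate_limit = rate_limit),
            class = "evimap_metric_client")
}

.cache_path <- function(client, doi) {
  file.path(client$cache_dir,
            paste0(gsub("[^a-z0-9.]+", "_", doi), ".json"))
}

.zero_record <- function(doi, not_found = TRUE) {
  tibble::tibble(doi = doi, score = 0, policy_citations = 0L,
                 patent_citations = 0L, retrieved_at = NA_character_,
                 not_found = not_found)
}

#' Retrieve altmetric records for a set of DOIs
#'
#' Resolution order per DOI: fixture, then cache, then (online clients
#' only) the live endpoint. A DOI unknown to the source yields a record with
#' zero counts and `not_found = TRUE`; in offline mode a DOI covered by
#' neither fixture nor cache is an error listing the uncovered DOIs —
#' unless a fixture was supplied, in which case absence from the fixture is
#' treated as "unknown to the service".
#'
#' @param dois Character vector of DOIs (case-insensitive).
#' @param client A [metric_client()].
#' @return A tibble with one row per DOI: `doi`, `score`,
#'   `policy_citations`, `patent_citations`, `retrieved_at`, `not_found`.
#' @export
fetch_metrics <- function(dois, client = metric_client()) {
  dois <- tolower(dois)
  rows <- vector("list", length(dois))
  uncovered <- character(0)
  for (i in seq_along(dois)) {
    doi <- dois[i]
    rec <- NULL
    if (!is.null(client$fixture)) {
      hit <- client$fixture[client$fixture$doi == doi, ]
      if (nrow(hit)) {
        rec <- tibble::tibble(
          doi = doi, score = as.numeric(hit$score[1]),
          policy_citations = as.integer(hit$policy_citations[1]),
          patent_citations = as.integer(hit$patent_citations[1]),
          retrieved_at = if ("retrieved_at" %in% names(hit))
            as.character(hit$retrieved_at[1]) else NA_character_,
          not_found = FALSE)
      } else if (client$offline) {
        rec <- .zero_record(doi)
      }
    }
    if (is.null(rec) && !is.null(client$cache_dir)) {
      cp <- .cache_path(client, doi)
      if (file.exists(cp)) {
        j <- jsonlite::read_json(cp, simplifyVector = TRUE)
        rec <- tibble::tibble(doi = doi, score = as.numeric(j$score),
                              policy_citations = as.integer(j$policy_citations),
                              patent_citations = as.integer(j$patent_citations),
                              retrieved_at = as.character(j$retrieved_at),
                              not_found = isTRUE(j$not_found))
      }
    }
    if (is.null(rec)) {
      if (client$offline) {
        uncovered <- c(uncovered, doi)
        rec <- .zero_record(doi)
      } else {
        rec <- .fetch_live(doi, client)
        if (!is.null(client$cache_dir)) {
          dir.create(client$cache_dir, showWarnings = FALSE, recursive = TRUE)
          jsonlite::write_json(as.list(rec[1, ]), .cache_path(client, doi),
                               auto_unbox = TRUE)
        }
      }
    }
    rows[[i]] <- rec
  }
  if (length(uncovered)) {
    abort(sprintf("offline mode: no fixture or cache covers DOI(s): %s",
                  paste(uncovered, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

# Live retrieval from the Altmetric details endpoint; used only by online
# clients. Fields consumed: score, cited_by_policies_count,
# cited_by_patents_count. A failed request (after one retry) yields a
# zero record flagged not_found so the batch continues.
.fetch_live <- function(doi, client) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    abort("live retrieval requires the 'curl' package")
  }
  url <- paste0(client$base_url, utils::URLencode(doi, reserved = FALSE))
  if (!is.null(client$api_key)) url <- paste0(url, "?key=", client$api_key)
  for (attempt in 1:2) {
    res <- tryCatch(curl::curl_fetch_memory(url), error = function(e) NULL)
    if (!is.null(res) && res$status_code == 200) {
      j <- jsonlite::fromJSON(rawToChar(res$content))
      Sys.sleep(1 / client$rate_limit)
      return(tibble::tibble(
        doi = doi, score = as.numeric(j$score %||% 0),
        policy_citations = as.integer(j$cited_by_policies_count %||% 0L),
        patent_citations = as.integer(j$cited_by_patents_count %||% 0L),
        retrieved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        not_found = FALSE))
    }
    if (!is.null(res) && res$status_code == 404) break
    Sys.sleep(2^attempt / client$rate_limit)
  }
  out <- .zero_record(doi)
  out$retrieved_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out
}

#' Join altmetric records to the evidence base (study level)
#'
#' Left join on the lower-cased DOI from the dataset's bibliography; one
#' output row per study regardless of match rate. Unmatched studies carry
#' `NA` metrics and are counted in a message.
#'
#' @param dataset An [evimap_dataset()] with a bibliography.
#' @param records Tibble from [fetch_metrics()].
#' @return A tibble `(study_id, doi, score, policy_citations,
#'   patent_citations, matched)`.
#' @export
join_metrics <- function(dataset, records) {
  studies <- unique(dataset$effects$study_id)
  bib <- dataset$bibliography
  if (is.null(bib)) {
    warn("dataset has no bibliography; all metrics empty")
    doi <- rep(NA_character_, length(studies))
  } else {
    doi <- tolower(bib$doi[match(studies, bib$paper_id)])
  }
  out <- tibble::tibble(study_id = studies, doi = doi) |>
    dplyr::left_join(
      dplyr::select(records, "doi", "score", "policy_citations",
                    "patent_citations"),
      by = "doi")
  out$matched <- !is.na(out$doi) & !is.na(out$score)
  n_un <- sum(!out$matched)
  if (n_un > 0) inform(sprintf("%d stud(ies) without matched metrics", n_un))
  out
}

#' Orchard-plot data: group estimates plus metric-sized effect bubbles
#'
#' Pools each moderator group (cluster-robust variance when the group spans
#' two or more studies) and attaches one point per effect whose bubble size
#' is the chosen metric of the effect's study. Bubbles above `cap` are
#' flagged `overflow` (rendered grey with the size capped).
#'
#' @param dataset An [evimap_dataset()] with `yi`, `vi` filled.
#' @param joined Study-level metrics from [join_metrics()].
#' @param group_mod Moderator defining the groups.
#' @param bubble_metric `"score"`, `"policy"`, `"patent"`, or
#'   `"policy_patent"` (their sum).
#' @param cap Overflow threshold for bubble sizes (default `Inf`).
#' @param method,rho Pooling options, see [pool_effects()].
#' @return A list of class `evimap_orchard` with `groups` (pooled estimates
#'   per declared group level) and `points` tibbles, plus `metric`, `cap`.
#' @export
orchard_data <- function(dataset, joined, group_mod,
                         bubble_metric = c("score", "policy", "patent",
                                           "policy_patent"),
                         cap = Inf, method = "robust", rho = 0.5) {
  bubble_metric <- match.arg(bubble_metric)
  if (!group_mod %in% dataset$moderators) {
    abort(sprintf("unknown moderator '%s'", group_mod))
  }
  eff <- dataset$effects
  if (any(is.na(eff$yi) | is.na(eff$vi))) {
    abort("yi/vi must be filled first (see fill_effect_sizes)")
  }
  metric_of <- function(tb) {
    switch(bubble_metric,
           score = tb$score,
           policy = tb$policy_citations,
           patent = tb$patent_citations,
           policy_patent = tb$policy_citations + tb$patent_citations)
  }
  mvals <- metric_of(joined)[match(eff$study_id, joined$study_id)]
  mvals[is.na(mvals)] <- 0
  levels <- dataset$schema[[group_mod]]
  groups <- list(); keep_levels <- character(0)
  for (lv in levels) {
    inn <- eff[[group_mod]] == lv
    if (!any(inn)) {
      warn(sprintf("group '%s' is empty; omitted", lv))
      next
    }
    p <- pool_effects(eff$yi[inn], eff$vi[inn], cluster = eff$study_id[inn],
                      method = method, rho = rho)
    groups[[lv]] <- dplyr::mutate(p, group = lv, .before = 1)
    keep_levels <- c(keep_levels, lv)
  }
  points <- tibble::tibble(
    effect_id = eff$effect_id, group = eff[[group_mod]],
    yi = eff$yi, vi = eff$vi, bubble = as.numeric(mvals),
    overflow = mvals > cap
  )
  points <- points[points$group %in% keep_levels, ]
  structure(list(groups = dplyr::bind_rows(groups), points = points,
                 metric = bubble_metric, cap = cap),
            class = "evimap_orchard")
}

#' Impact grid: altmetric totals at moderator intersections
#'
#' Cross-tabulates two moderators and reports, per cell, total policy and
#' patent citations and the mean Altmetric score over the cell's distinct
#' studies. Empty cells are kept as zero rows so gaps stay visible.
#'
#' @param dataset An [evimap_dataset()].
#' @param joined Study-level metrics from [join_metrics()].
#' @param row_mod,col_mod Moderator names.
#' @return A tibble of class `evimap_impact_grid` with columns `row_level`,
#'   `col_level`, `n_studies`, `policy_citations`, `patent_citations`,
#'   `mean_score`.
#' @export
impact_grid <- function(dataset, joined, row_mod, col_mod) {
  grid <- cross_tabulate(dataset, row_mod, col_mod)
  eff <- dataset$effects
  res <- lapply(seq_len(nrow(grid)), function(i) {
    inn <- eff[[row_mod]] == grid$row_level[i] &
           eff[[col_mod]] == grid$col_level[i]
    studies <- unique(eff$study_id[inn])
    tb <- joined[joined$study_id %in% studies, ]
    tibble::tibble(
      policy_citations = sum(tb$policy_citations, na.rm = TRUE),
      patent_citations = sum(tb$patent_citations, na.rm = TRUE),
      mean_score = if (nrow(tb)) mean(tb$score, na.rm = TRUE) else NA_real_
    )
  })
  out <- dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(grid), "row_level", "col_level",
                  "n_studies"),
    dplyr::bind_rows(res))
  structure(out, class = c("evimap_impact_grid", class(tibble::tibble())),
            row_mod = row_mod, col_mod = col_mod)
}
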