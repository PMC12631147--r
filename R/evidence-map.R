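# Evidence-gap-map grids, alluvial flows, and geographic counts.

#' Cross-tabulate two moderators into an evidence-map grid
#'
#' One cell per (row level, column level) pair of the moderator schema,
#' including empty cells with zero counts — the gaps are the point of the
#' map. `n_studies` counts distinct studies per cell (a study spanning
#' several cells is counted in each), `n_effects` counts effect rows.
#'
#' @param dataset An [evimap_dataset()].
#' @param row_mod,col_mod Moderator names from the schema.
#' @param shape_mod Optional third moderator; the cell's modal label is
#'   reported with a `mixed` flag when the cell mixes labels.
#' @return A tibble of class `evimap_grid` with columns `row_level`,
#'   `col_level`, `n_studies`, `n_effects` (and `shape_label`, `shape_mixed`
#'   when `shape_mod` is given), ordered by schema.
#' @export
cross_tabulate <- function(dataset, row_mod, col_mod, shape_mod = NULL) {
  for (m in c(row_mod, col_mod, shape_mod)) {
    if (!m %in% dataset$moderators) {
      abort(sprintf("unknown moderator '%s'; available: %s", m,
                    paste(dataset$moderators, collapse = ", ")))
    }
  }
  eff <- dataset$effects
  grid <- tidyr::expand_grid(
    row_level = dataset$schema[[row_mod]],
    col_level = dataset$schema[[col_mod]]
  )
  counts <- eff |>
    dplyr::group_by(row_level = .data[[row_mod]],
                    col_level = .data[[col_mod]]) |>
    dplyr::summarise(n_studies = dplyr::n_distinct(.data$study_id),
                     n_effects = dplyr::n(), .groups = "drop")
  grid <- grid |>
    dplyr::left_join(counts, by = c("row_level", "col_level")) |>
    dplyr::mutate(n_studies = as.integer(tidyr::replace_na(.data$n_studies, 0L)),
                  n_effects = as.integer(tidyr::replace_na(.data$n_effects, 0L)))
  if (!is.null(shape_mod)) {
    modal <- eff |>
      dplyr::group_by(row_level = .data[[row_mod]],
                      col_level = .data[[col_mod]]) |>
      dplyr::summarise(
        shape_label = names(sort(table(.data[[shape_mod]]),
                                 decreasing = TRUE))[1],
        shape_mixed = dplyr::n_distinct(.data[[shape_mod]]) > 1L,
        .groups = "drop")
    grid <- dplyr::left_join(grid, modal, by = c("row_level", "col_level"))
  }
  structure(grid, class = c("evimap_grid", class(grid)),
            row_mod = row_mod, col_mod = col_mod, shape_mod = shape_mod)
}

#' Pool effects within each grid cell
#'
#' Adds a pooled estimate to every non-empty cell. The default pipeline is
#' fixed-effect GLS on a study-clustered VCV at the assumed sampling
#' correlation, with cluster-robust variance when a cell holds two or more
#' studies; a single-effect cell passes its own effect and standard error
#' through. A cell whose pooling fails is reported with `NA` estimates, not
#' fatally.
#'
#' @param grid Output of [cross_tabulate()].
#' @param dataset The dataset the grid was built from (with `yi`, `vi`).
#' @param method,rho Pooling options, see [pool_effects()].
#' @return The grid with `estimate`, `se`, `ci_low`, `ci_high`,
#'   `pool_method` columns.
#' @export
pool_cells <- function(grid, dataset, method = "robust", rho = 0.5) {
  row_mod <- attr(grid, "row_mod"); col_mod <- attr(grid, "col_mod")
  eff <- dataset$effects
  if (any(is.na(eff$yi) | is.na(eff$vi))) {
    abort("yi/vi must be filled first (see fill_effect_sizes)")
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    inn <- eff[[row_mod]] == grid$row_level[i] &
           eff[[col_mod]] == grid$col_level[i]
    if (!any(inn)) {
      return(tibble::tibble(estimate = NA_real_, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            pool_method = NA_character_))
    }
    p <- tryCatch(
      pool_effects(eff$yi[inn], eff$vi[inn], cluster = eff$study_id[inn],
                   method = method, rho = rho),
      error = function(e) {
        warn(sprintf("cell (%s, %s) failed to pool: %s",
                     grid$row_level[i], grid$col_level[i],
                     conditionMessage(e)))
        NULL
      })
    if (is.null(p)) {
      return(tibble::tibble(estimate = NA_real_, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            pool_method = "failed"))
    }
    tibble::tibble(estimate = p$estimate, se = p$se,
                   ci_low = p$ci_low, ci_high = p$ci_high,
                   pool_method = p$method)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
  structure(out, class = c("evimap_grid", class(tibble::tibble())),
            row_mod = row_mod, col_mod = col_mod,
            shape_mod = attr(grid, "shape_mod"))
}

#' Alluvial flow counts across moderators
#'
#' Counts effects per unique tuple of moderator labels across two or more
#' axes; the `"Unknown"` stratum is included so missingness patterns remain
#' visible. Per-axis marginal sums over flows are equal by construction.
#'
#' @param dataset An [evimap_dataset()].
#' @param mods Ordered character vector of >= 2 moderator names.
#' @return A tibble of class `evimap_alluvial` with one column per moderator
#'   plus `n`; attribute `axes` records the axis order and `strata` the
#'   per-axis levels.
#' @export
alluvial_flows <- function(dataset, mods) {
  if (length(mods) < 2) {
    abort("alluvial flows need >= 2 moderators; for a single moderator use cross_tabulate")
  }
  for (m in mods) {
    if (!m %in% dataset$moderators) {
      abort(sprintf("unknown moderator '%s'; available: %s", m,
                    paste(dataset$moderators, collapse = ", ")))
    }
  }
  flows <- dataset$effects |>
    dplyr::count(dplyr::across(dplyr::all_of(mods)), name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n),
                   dplyr::across(dplyr::all_of(mods)))
  structure(flows, class = c("evimap_alluvial", class(flows)),
            axes = mods, strata = dataset$schema[mods])
}

#' Per-country study and effect counts
#'
#' Counts distinct studies and effects per country, taken either from a
#' moderator column or from the bibliography's affiliation countries. With
#' `countries = "all"` a multi-country paper is counted once per listed
#' country; `"first"` restricts to the first affiliation.
#'
#' @param dataset An [evimap_dataset()].
#' @param source `"moderator"` or `"bibliography"`.
#' @param moderator Moderator name when `source = "moderator"`.
#' @param countries `"all"` (default) or `"first"`.
#' @return A tibble `(country, n_studies, n_effects)` sorted by descending
#'   `n_studies`; empty (with a warning) when no country data exist.
#' @export
geo_counts <- function(dataset, source = c("bibliography", "moderator"),
                       moderator = NULL, countries = c("all", "first")) {
  source <- match.arg(source)
  countries <- match.arg(countries)
  eff <- dataset$effects
  if (source == "moderator") {
    if (is.null(moderator) || !moderator %in% names(eff)) {
      abort("source = 'moderator' needs a valid moderator name")
    }
    map <- tibble::tibble(study_id = eff$study_id,
                          effect_id = eff$effect_id,
                          country = as.character(eff[[moderator]]))
  } else {
    bib <- dataset$bibliography
    if (is.null(bib)) abort("dataset has no bibliography")
    cl <- bib$countries
    if (countries == "first") {
      cl <- lapply(cl, function(x) if (length(x)) x[1] else character(0))
    }
    link <- tibble::tibble(study_id = rep(bib$paper_id, lengths(cl)),
                           country = unlist(cl, use.names = FALSE))
    map <- dplyr::inner_join(
      tibble::tibble(study_id = eff$study_id, effect_id = eff$effect_id),
      link, by = "study_id", relationship = "many-to-many")
  }
  map <- map[!is.na(map$country) & nzchar(map$country), ]
  if (!nrow(map)) {
    warn("no country information available; returning an empty table")
    return(tibble::tibble(country = character(0), n_studies = integer(0),
                          n_effects = integer(0)))
  }
  map |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(n_studies = dplyr::n_distinct(.data$study_id),
                     n_effects = dplyr::n_distinct(.data$effect_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_studies), .data$country)
}
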