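#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats qnorm qt rnorm rchisq rpois rlnorm runif setNames
#' @importFrom utils head tail
NULL

# Reserved (non-moderator) columns of an effects table.
.effect_core_cols <- c(
  "study_id", "effect_id", "yi", "vi", "species", "author_cluster",
  "m1", "s1", "n1", "m2", "s2", "n2"
)

#' Assemble an evidence-base dataset
#'
#' An `evimap_dataset` bundles the effect-size table (one row per effect),
#' an optional bibliography keyed to `study_id`, and the moderator schema
#' (ordered category levels per moderator). Missing moderator values are
#' retained as an explicit `"Unknown"` level so that maps and alluvial
#' diagrams can display missingness patterns rather than silently dropping
#' rows.
#'
#' @param effects Tibble with at least `study_id`, `effect_id` and either
#'   `yi` + `vi` or the raw two-group summaries `m1,s1,n1,m2,s2,n2`.
#'   Additional columns named in `moderators` are categorical moderators;
#'   `species` and `author_cluster` are recognised clustering labels.
#' @param moderators Character vector naming the moderator columns. Defaults
#'   to every non-reserved column.
#' @param bibliography Optional tibble of bibliographic records (see
#'   [read_bibliography()]); `paper_id` must match `study_id`.
#' @param schema Optional named list giving the ordered levels of each
#'   moderator; inferred from first appearance when omitted.
#' @return An object of class `evimap_dataset`: a list with elements
#'   `effects`, `bibliography`, `moderators`, `schema`.
#' @export
evimap_dataset <- function(effects, moderators = NULL, bibliography = NULL,
                           schema = NULL) {
  effects <- tibble::as_tibble(effects)
  if (!all(c("study_id", "effect_id") %in% names(effects))) {
    abort("effects must contain 'study_id' and 'effect_id' columns")
  }
  effects$study_id <- as.character(effects$study_id)
  effects$effect_id <- as.character(effects$effect_id)
  if (anyDuplicated(effects$effect_id)) {
    abort("effect_id values must be unique within a dataset")
  }
  has_yi <- "yi" %in% names(effects)
  has_raw <- all(c("m1", "s1", "n1", "m2", "s2", "n2") %in% names(effects))
  if (!has_yi && !has_raw) {
    abort("effects must carry either yi/vi or raw outcomes m1,s1,n1,m2,s2,n2")
  }
  if (has_yi) {
    if (!"vi" %in% names(effects)) {
      abort("effects with yi must also carry vi")
    }
    bad <- which(!is.na(effects$vi) & effects$vi <= 0)
    if (length(bad)) {
      abort(sprintf("sampling variance vi must be > 0 (violated at row %s)",
                    paste(bad, collapse = ", ")))
    }
    nf <- which(!is.na(effects$yi) & !is.finite(effects$yi))
    if (length(nf)) {
      abort(sprintf("yi must be finite (violated at row %s)",
                    paste(nf, collapse = ", ")))
    }
  }
  if (is.null(moderators)) {
    moderators <- setdiff(names(effects), .effect_core_cols)
  }
  missing_mods <- setdiff(moderators, names(effects))
  if (length(missing_mods)) {
    abort(sprintf("moderator column(s) not found: %s",
                  paste(missing_mods, collapse = ", ")))
  }
  for (m in moderators) {
    v <- as.character(effects[[m]])
    v[is.na(v) | v == ""] <- "Unknown"
    effects[[m]] <- v
  }
  if (is.null(schema)) {
    schema <- lapply(setNames(moderators, moderators), function(m) {
      lv <- unique(effects[[m]])
      # "Unknown" is kept as the trailing level for stable display order
      c(setdiff(lv, "Unknown"), intersect("Unknown", lv))
    })
  } else {
    for (m in moderators) {
      lv <- schema[[m]]
      if (is.null(lv)) abort(sprintf("schema is missing moderator '%s'", m))
      extra <- setdiff(unique(effects[[m]]), c(lv, "Unknown"))
      if (length(extra)) {
        abort(sprintf("moderator '%s' has values outside the schema: %s",
                      m, paste(extra, collapse = ", ")))
      }
      if ("Unknown" %in% effects[[m]] && !("Unknown" %in% lv)) {
        schema[[m]] <- c(lv, "Unknown")
      }
    }
    schema <- schema[moderators]
  }
  if (!is.null(bibliography)) {
    bibliography <- tibble::as_tibble(bibliography)
    if (anyDuplicated(bibliography$paper_id)) {
      abort("bibliography paper_id values must be unique")
    }
  }
  structure(
    list(effects = effects, bibliography = bibliography,
         moderators = moderators, schema = schema),
    class = "evimap_dataset"
  )
}

#' @export
print.evimap_dataset <- function(x, ...) {
  cat(sprintf("<evimap_dataset> %d effects / %d studies\n",
              nrow(x$effects), dplyr::n_distinct(x$effects$study_id)))
  cat("moderators:", if (length(x$moderators))
    paste(x$moderators, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$bibliography)) {
    cat(sprintf("bibliography: %d records\n", nrow(x$bibliography)))
  }
  invisible(x)
}

#' Read an effect-size table from delimited text
#'
#' Reads a CSV/TSV effects table (RFC-4180 quoting, UTF-8) into an
#' [evimap_dataset()]. Columns can be renamed through `column_map`. When the
#' file carries raw two-group summaries but no `yi`, effect sizes are left
#' empty for [fill_effect_sizes()] to compute.
#'
#' @param path File path to delimited text with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`study_id`, `effect_id`, `yi`, `vi`, `m1`, ..., `species`,
#'   `author_cluster`) to the file's column names. Identity by default.
#' @param moderators Character vector of moderator columns (file names,
#'   post-mapping). Default: all unreserved columns.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param schema Optional moderator schema, see [evimap_dataset()].
#' @return An `evimap_dataset`.
#' @export
read_effects <- function(path, column_map = NULL, moderators = NULL,
                         delim = ",", schema = NULL) {
  if (!file.exists(path)) abort(sprintf("effects file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        abort(sprintf("column_map names missing column '%s' (for '%s')",
                      src, canon))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  for (col in c("study_id", "effect_id")) {
    if (!col %in% names(raw)) {
      abort(sprintf("mandatory column '%s' is missing", col))
    }
  }
  if ("vi" %in% names(raw) && !is.numeric(raw$vi)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$vi))) & !is.na(raw$vi))
    abort(sprintf("non-numeric vi at row %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  evimap_dataset(raw, moderators = moderators, schema = schema)
}

#' Write a tabular result as CSV
#'
#' All toolkit writers emit UTF-8 CSV with a header and deterministic column
#' order; an empty result yields a header-only file.
#'
#' @param result A data frame / tibble produced by the toolkit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  result <- as.data.frame(result)
  # flatten list-columns (e.g. authors) to ";"-separated text
  for (col in names(result)) {
    if (is.list(result[[col]])) {
      result[[col]] <- vapply(result[[col]], function(x)
        paste(x, collapse = ";"), character(1))
    }
  }
  readr::write_csv(tibble::as_tibble(result), path, progress = FALSE)
  invisible(path)
}

#' Normalize author names
#'
#' Lower-cases, strips accents, and collapses `"Surname, Initials"` (or
#' `"surname tokens"`) to `"surname initials"`; idempotent.
#'
#' @param x Character vector of author names.
#' @return Character vector of normalized names.
#' @export
normalize_author <- function(x) {
  vapply(x, function(s) {
    s <- iconv(s, from = "", to = "ASCII//TRANSLIT")
    s <- tolower(trimws(s))
    s <- gsub("[.]", " ", s)
    # transliteration may leave accent marks as quotes/carets; drop anything
    # that is not part of a name
    s <- gsub("[^a-z0-9, -]", "", s)
    if (grepl(",", s, fixed = TRUE)) {
      # "Surname(s), Given tokens": initials = first letters of the givens
      parts <- strsplit(s, ",", fixed = TRUE)[[1]]
      surname <- trimws(parts[1])
      given <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "[[:space:]]+")[[1]]
      initials <- paste(substr(given[nzchar(given)], 1, 1), collapse = "")
    } else {
      # already-normalized "surname(s) initials" form: the last token is the
      # initials block (kept whole when short), so the map is idempotent
      toks <- strsplit(s, "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) return("")
      if (length(toks) == 1) return(toks)
      surname <- paste(toks[-length(toks)], collapse = " ")
      last <- toks[length(toks)]
      initials <- if (nchar(last) <= 3) last else substr(last, 1, 1)
    }
    surname <- gsub("[[:space:]]+", " ", trimws(surname))
    paste(c(surname, if (nzchar(initials)) initials), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# --- minimal brace-aware BibTeX entry scanner -------------------------------

.parse_bibtex_text <- function(text) {
  entries <- list()
  n <- nchar(text)
  i <- 1L
  while (i <= n) {
    at <- regexpr("@", substr(text, i, n), fixed = TRUE)
    if (at < 0) break
    start <- i + at - 1L
    m <- regexpr("^@[A-Za-z]+\\s*\\{", substr(text, start, n))
    if (m < 0) { i <- start + 1L; next }
    body_start <- start + attr(m, "match.length")
    # scan to matching closing brace
    depth <- 1L; j <- body_start
    while (j <= n && depth > 0L) {
      ch <- substr(text, j, j)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
      j <- j + 1L
    }
    if (depth != 0L) {
      warn(sprintf("unbalanced braces in BibTeX entry at position %d; skipped",
                   start))
      break
    }
    body <- substr(text, body_start, j - 2L)
    comma <- regexpr(",", body, fixed = TRUE)
    key <- trimws(if (comma > 0) substr(body, 1, comma - 1L) else body)
    fields <- if (comma > 0)
      .parse_bibtex_fields(substr(body, comma + 1L, nchar(body)))
    else list()
    entries[[length(entries) + 1L]] <- c(list(.key = key), fields)
    i <- j
  }
  entries
}

.parse_bibtex_fields <- function(body) {
  out <- list()
  n <- nchar(body)
  i <- 1L
  while (i <= n) {
    rest <- substr(body, i, n)
    m <- regexpr("^[\\s,]*([A-Za-z][A-Za-z0-9_-]*)\\s*=\\s*", rest, perl = TRUE)
    if (m < 0) break
    matched <- regmatches(rest, m)
    name <- tolower(gsub("[=,[:space:]]", "", matched))
    i <- i + attr(m, "match.length")
    ch <- substr(body, i, i)
    if (ch == "{") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        cj <- substr(body, j, j)
        if (cj == "{") depth <- depth + 1L
        if (cj == "}") depth <- depth - 1L
        j <- j + 1L
      }
      val <- substr(body, i + 1L, j - 2L)
      i <- j
    } else if (ch == '"') {
      j <- i + 1L
      while (j <= n && substr(body, j, j) != '"') j <- j + 1L
      val <- substr(body, i + 1L, j - 1L)
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(body, j, j) %in% c(",", "\n")) j <- j + 1L
      val <- substr(body, i, j - 1L)
      i <- j
    }
    out[[name]] <- gsub("[{}]", "", gsub("\\s+", " ", trimws(val)))
  }
  out
}

.split_semicolons <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

#' Read bibliographic records
#'
#' Reads BibTeX or delimited bibliographic metadata into a tibble of records
#' with normalized author names (see [normalize_author()]), lower-cased DOIs,
#' ISO country codes and cited-reference keys. Records sharing a non-empty
#' DOI are deduplicated (first kept) with a message; unparseable BibTeX
#' entries are skipped with a warning.
#'
#' @param path File path.
#' @param format `"bibtex"` or `"delimited"`. Delimited files need columns
#'   `paper_id`, `authors` (";"-separated), and optionally `countries`,
#'   `references`, `doi`, `year`, `journal`, `funder`.
#' @param delim Delimiter for the delimited format.
#' @return A tibble with one row per paper: `paper_id`, `doi`, `authors`
#'   (list), `countries` (list), `year`, `journal`, `funder`, `references`
#'   (list).
#' @export
read_bibliography <- function(path, format = c("bibtex", "delimited"),
                              delim = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("bibliography file not found: %s", path))
  if (format == "bibtex") {
    entries <- .parse_bibtex_text(paste(readLines(path, warn = FALSE,
                                                  encoding = "UTF-8"),
                                        collapse = "\n"))
    skipped <- 0L
    rows <- lapply(entries, function(e) {
      authors <- e[["author"]] %||% ""
      alist <- trimws(strsplit(authors, "\\s+and\\s+")[[1]])
      alist <- alist[nzchar(alist)]
      if (!length(alist)) { skipped <<- skipped + 1L; return(NULL) }
      tibble::tibble(
        paper_id = e$.key,
        doi = tolower(e[["doi"]] %||% NA_character_),
        authors = list(normalize_author(alist)),
        countries = list(toupper(.split_semicolons(
          e[["countries"]] %||% e[["country"]] %||% NA_character_))),
        year = suppressWarnings(as.integer(e[["year"]] %||% NA)),
        journal = e[["journal"]] %||% NA_character_,
        funder = e[["funder"]] %||% NA_character_,
        references = list(.split_semicolons(
          e[["references"]] %||% e[["cited-references"]] %||% NA_character_))
      )
    })
    if (skipped > 0L) {
      warn(sprintf("skipped %d BibTeX entr%s with no parseable authors",
                   skipped, if (skipped == 1L) "y" else "ies"))
    }
    recs <- dplyr::bind_rows(rows)
  } else {
    raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    if (!all(c("paper_id", "authors") %in% names(raw))) {
      abort("delimited bibliography needs 'paper_id' and 'authors' columns")
    }
    get_chr <- function(col) {
      if (col %in% names(raw)) as.character(raw[[col]]) else
        rep(NA_character_, nrow(raw))
    }
    recs <- tibble::tibble(
      paper_id = as.character(raw$paper_id),
      doi = tolower(get_chr("doi")),
      authors = lapply(get_chr("authors"),
                       function(a) normalize_author(.split_semicolons(a))),
      countries = lapply(get_chr("countries"),
                         function(c) toupper(.split_semicolons(c))),
      year = suppressWarnings(as.integer(get_chr("year"))),
      journal = get_chr("journal"),
      funder = get_chr("funder"),
      references = lapply(get_chr("references"), .split_semicolons)
    )
  }
  if (!nrow(recs)) abort("no bibliographic records could be parsed")
  if (anyDuplicated(recs$paper_id)) {
    abort(sprintf("duplicate paper_id in bibliography: %s",
                  paste(unique(recs$paper_id[duplicated(recs$paper_id)]),
                        collapse = ", ")))
  }
  has_doi <- !is.na(recs$doi) & nzchar(recs$doi)
  dup_doi <- has_doi & duplicated(recs$doi)
  if (any(dup_doi)) {
    inform(sprintf("deduplicated %d record(s) sharing a DOI", sum(dup_doi)))
    recs <- recs[!dup_doi, ]
  }
  recs
}
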