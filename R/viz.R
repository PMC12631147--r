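# Figure rendering. Every renderer writes (1) a static figure and (2) a
# machine-readable JSON sidecar (same basename, ".sidecar.json") recording
# every plotted value, so tests assert on the sidecar rather than pixels.
# No renderer computes statistics: every sidecar number comes verbatim from
# the input tables.

.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * 96, height = height * 96,
                         res = 96),
    pdf = grDevices::pdf(path, width = width, height = height),
    abort(sprintf("unsupported figure format '%s' (use svg, png or pdf)", ext))
  )
}

.write_sidecar <- function(path, payload) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".sidecar.json")
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  sidecar
}

.check_columns <- function(data, cols, what) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(sprintf("%s: encoding column(s) missing before drawing: %s",
                  what, paste(miss, collapse = ", ")))
  }
}

#' Render a figure with a machine-readable sidecar
#'
#' Dispatches on `kind` to the matching renderer. The figure format follows
#' the file extension (`svg` default, `png`, `pdf`); alongside it a
#' `<basename>.sidecar.json` lists every plotted value. Rendering twice
#' from the same tables yields identical sidecars.
#'
#' @param data The matching module's output (see Details of each kind).
#' @param kind One of `"grid_map"`, `"alluvial"`, `"phylo_forest"`,
#'   `"coauthor_net"`, `"chord"`, `"orchard"`.
#' @param path Output figure path.
#' @param ... Encoding options passed to the kind-specific renderer:
#'   `bubble` (`"n_studies"` or `"n_effects"`, grid_map), `tree` and
#'   `estimates` (phylo_forest), `clusters` and `layout_seed`
#'   (coauthor_net), `cap` (orchard), `width`/`height` in inches.
#' @return Invisibly, a list with `figure` and `sidecar` paths.
#' @export
render_figure <- function(data, kind = c("grid_map", "alluvial",
                                         "phylo_forest", "coauthor_net",
                                         "chord", "orchard"),
                          path, ...) {
  kind <- match.arg(kind)
  fn <- switch(kind,
    grid_map = .render_grid_map, alluvial = .render_alluvial,
    phylo_forest = .render_phylo_forest, coauthor_net = .render_coauthor,
    chord = .render_chord, orchard = .render_orchard)
  fn(data, path, ...)
}

# --- grid map ---------------------------------------------------------------
# Bubbles at moderator intersections; bubble AREA scales with the count,
# colour with the pooled estimate when present; empty cells are outlined
# gaps.
.render_grid_map <- function(grid, path, bubble = "n_studies",
                             width = 7, height = 5) {
  .check_columns(grid, c("row_level", "col_level", bubble), "grid_map")
  g <- tibble::as_tibble(grid)
  has_est <- "estimate" %in% names(g)
  g$row_level <- factor(g$row_level, levels = unique(g$row_level))
  g$col_level <- factor(g$col_level, levels = unique(g$col_level))
  filled <- g[g$n_effects > 0, ]
  empty <- g[g$n_effects == 0, ]
  p <- ggplot2::ggplot(filled,
                       ggplot2::aes(x = .data$row_level, y = .data$col_level)) +
    ggplot2::geom_tile(data = empty, fill = NA, colour = "grey70",
                       linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(size = .data[[bubble]],
                                     colour = if (has_est) .data$estimate
                                              else NULL)) +
    ggplot2::scale_size_area(max_size = 14) +
    ggplot2::labs(x = attr(grid, "row_mod"), y = attr(grid, "col_mod"),
                  size = bubble, colour = if (has_est) "estimate" else NULL) +
    ggplot2::theme_minimal()
  .open_device(path, width, height)
  print(p)
  grDevices::dev.off()
  sidecar <- .write_sidecar(path, list(
    kind = "grid_map", bubble_metric = bubble,
    cells = as.data.frame(g)))
  invisible(list(figure = path, sidecar = sidecar))
}

# --- alluvial ---------------------------------------------------------------
# Stacked strata per axis joined by ribbons; strata in schema order, flows
# by descending count (deterministic layout, no ggalluvial dependency).
.render_alluvial <- function(flows, path, width = 8, height = 5) {
  axes <- attr(flows, "axes")
  strata <- attr(flows, "strata")
  .check_columns(flows, c(axes, "n"), "alluvial")
  fl <- tibble::as_tibble(flows)
  total <- sum(fl$n)
  # vertical position of each flow within each axis' stacked strata
  seg <- list(); rects <- list()
  for (a in seq_along(axes)) {
    ax <- axes[a]
    lv <- strata[[ax]]
    ord <- order(match(fl[[ax]], lv))
    y1o <- cumsum(fl$n[ord]); y0o <- y1o - fl$n[ord]
    y0 <- y1 <- numeric(nrow(fl))
    y0[ord] <- y0o; y1[ord] <- y1o
    seg[[ax]] <- tibble::tibble(flow = seq_len(nrow(fl)), y0 = y0, y1 = y1)
    agg <- fl[ord, ] |> dplyr::group_by(level = .data[[ax]]) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::arrange(match(.data$level, lv))
    yy1 <- cumsum(agg$n); yy0 <- yy1 - agg$n
    rects[[ax]] <- tibble::tibble(axis = a, level = agg$level,
                                  y0 = yy0, y1 = yy1)
  }
  rect_df <- dplyr::bind_rows(rects)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = rect_df,
                       ggplot2::aes(xmin = .data$axis - 0.05,
                                    xmax = .data$axis + 0.05,
                                    ymin = .data$y0, ymax = .data$y1,
                                    fill = .data$level),
                       colour = "white", show.legend = FALSE)
  for (a in seq_len(length(axes) - 1)) {
    left <- seg[[a]]; right <- seg[[a + 1]]
    ribbon <- tibble::tibble(
      x = rep(c(a + 0.05, a + 0.95), each = nrow(fl)),
      flow = rep(seq_len(nrow(fl)), 2),
      ymin = c(left$y0, right$y0), ymax = c(left$y1, right$y1))
    p <- p + ggplot2::geom_ribbon(
      data = ribbon,
      ggplot2::aes(x = .data$x, ymin = .data$ymin, ymax = .data$ymax,
                   group = .data$flow),
      alpha = 0.4, fill = "steelblue")
  }
  p <- p + ggplot2::scale_x_continuous(breaks = seq_along(axes),
                                       labels = axes) +
    ggplot2::labs(x = NULL, y = "effects") + ggplot2::theme_minimal()
  .open_device(path, width, height)
  print(p)
  grDevices::dev.off()
  sidecar <- .write_sidecar(path, list(
    kind = "alluvial", axes = axes, strata = strata,
    flows = as.data.frame(fl), total_effects = total))
  invisible(list(figure = path, sidecar = sidecar))
}

# --- phylo forest -----------------------------------------------------------
# Tree on the left, per-species estimates with 95% whiskers aligned with
# the tips on the right; species order equals tip traversal order.
.render_phylo_forest <- function(estimates, path, tree, width = 8,
                                 height = 6) {
  .check_columns(estimates, c("species", "estimate", "ci_low", "ci_high"),
                 "phylo_forest")
  est <- tibble::as_tibble(estimates)
  est <- est[match(tree$tip.label, est$species), ]
  est <- est[!is.na(est$species), ]
  .open_device(path, width, height)
  graphics::layout(matrix(1:2, 1, 2), widths = c(1.2, 1))
  graphics::par(mar = c(3, 1, 2, 0))
  ape::plot.phylo(tree, cex = 0.7, no.margin = FALSE)
  graphics::par(mar = c(3, 0, 2, 1))
  n <- nrow(est)
  graphics::plot(NULL, xlim = range(c(est$ci_low, est$ci_high, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", xlab = "effect size",
                 ylab = "")
  graphics::abline(v = 0, lty = 3, col = "grey60")
  graphics::segments(est$ci_low, seq_len(n), est$ci_high, seq_len(n))
  graphics::points(est$estimate, seq_len(n), pch = 16)
  grDevices::dev.off()
  sidecar <- .write_sidecar(path, list(
    kind = "phylo_forest", species_order = est$species,
    estimates = as.data.frame(est)))
  invisible(list(figure = path, sidecar = sidecar))
}

# --- co-authorship network --------------------------------------------------
.render_coauthor <- function(net, path, clusters = NULL, layout_seed = 1L,
                             width = 7, height = 7) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(layout_seed)
  lay <- igraph::layout_with_fr(g)
  cols <- if (!is.null(clusters)) {
    mem <- clusters$membership[igraph::V(g)$name]
    grDevices::rainbow(max(mem))[mem]
  } else "steelblue"
  .open_device(path, width, height)
  graphics::par(mar = c(0, 0, 0, 0))
  igraph::plot.igraph(g, layout = lay, vertex.size = 4,
                      vertex.label = NA, vertex.color = cols,
                      edge.width = igraph::E(g)$weight)
  grDevices::dev.off()
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  sidecar <- .write_sidecar(path, list(
    kind = "coauthor_net",
    nodes = as.data.frame(dplyr::mutate(
      net$nodes,
      cluster = if (!is.null(clusters))
        as.integer(clusters$membership[net$nodes$label]) else NA_integer_)),
    edges = data.frame(from = rownames(W)[idx[, 1]],
                       to = colnames(W)[idx[, 2]], weight = W[idx]),
    layout_seed = layout_seed))
  invisible(list(figure = path, sidecar = sidecar))
}

# --- chord ------------------------------------------------------------------
# Circular layout: node arcs proportional to strength share of the
# perimeter, edges drawn as Bezier-ish chords between arc midpoints.
.render_chord <- function(net, path, width = 7, height = 7) {
  cd <- chord_data(net)
  totals <- cd$totals
  share <- if (sum(totals$total) > 0) totals$total / sum(totals$total)
           else rep(1 / nrow(totals), nrow(totals))
  ang1 <- cumsum(share) * 2 * pi
  ang0 <- ang1 - share * 2 * pi
  mid <- (ang0 + ang1) / 2
  .open_device(path, width, height)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NULL, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  for (i in seq_len(nrow(totals))) {
    tt <- seq(ang0[i], ang1[i], length.out = 30)
    graphics::lines(cos(tt), sin(tt), lwd = 6,
                    col = grDevices::rainbow(nrow(totals))[i])
    graphics::text(1.18 * cos(mid[i]), 1.18 * sin(mid[i]),
                   totals$label[i], cex = 0.7)
  }
  if (nrow(cd$edges)) {
    wmax <- max(cd$edges$weight)
    for (i in seq_len(nrow(cd$edges))) {
      a <- mid[match(cd$edges$from[i], totals$label)]
      b <- mid[match(cd$edges$to[i], totals$label)]
      t <- seq(0, 1, length.out = 50)
      # quadratic curve through the centre
      x <- (1 - t)^2 * cos(a) + t^2 * cos(b)
      y <- (1 - t)^2 * sin(a) + t^2 * sin(b)
      graphics::lines(x, y, col = grDevices::adjustcolor("grey40", 0.6),
                      lwd = 0.5 + 3 * cd$edges$weight[i] / wmax)
    }
  }
  grDevices::dev.off()
  sidecar <- .write_sidecar(path, list(
    kind = "chord", edges = as.data.frame(cd$edges),
    totals = as.data.frame(cd$totals),
    perimeter_share = as.numeric(share)))
  invisible(list(figure = path, sidecar = sidecar))
}

# --- orchard ----------------------------------------------------------------
# Group pooled estimates with whiskers; individual effects as bubbles whose
# size is the chosen metric; bubbles over the cap drawn grey and flagged.
.render_orchard <- function(orchard, path, width = 7, height = 5) {
  groups <- orchard$groups
  points <- orchard$points
  points$group_idx <- match(points$group, groups$group)
  groups$group_idx <- seq_len(nrow(groups))
  points$size_capped <- pmin(points$bubble, orchard$cap)
  p <- ggplot2::ggplot() +
    ggplot2::geom_jitter(
      data = points,
      ggplot2::aes(x = .data$yi, y = .data$group_idx,
                   size = .data$size_capped,
                   colour = .data$overflow),
      height = 0.15, width = 0, alpha = 0.6,
      show.legend = c(size = TRUE, colour = TRUE)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "darkorange",
                                            `TRUE` = "grey50")) +
    ggplot2::geom_errorbarh(
      data = groups,
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high,
                   y = .data$group_idx), height = 0.1) +
    ggplot2::geom_point(data = groups,
                        ggplot2::aes(x = .data$estimate,
                                     y = .data$group_idx), size = 3) +
    ggplot2::scale_y_continuous(breaks = groups$group_idx,
                                labels = groups$group) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(x = "effect size", y = NULL, size = orchard$metric) +
    ggplot2::theme_minimal()
  .open_device(path, width, height)
  print(p)
  grDevices::dev.off()
  sidecar <- .write_sidecar(path, list(
    kind = "orchard", bubble_metric = orchard$metric, cap = orchard$cap,
    groups = as.data.frame(dplyr::select(groups, -"group_idx")),
    points = as.data.frame(dplyr::select(points, -"group_idx",
                                         -"size_capped")),
    n_overflow = sum(points$overflow)))
  invisible(list(figure = path, sidecar = sidecar))
}
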