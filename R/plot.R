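# Diverging response palette: saturated blue at -100 through white at 0 to
# saturated red at +100.
response_color <- function(response, missing_color = "grey80") {
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  out <- rep(missing_color, length(response))
  ok <- !is.na(response)
  x <- pmin(pmax(response[ok], -100), 100)
  rgb <- ramp((x + 100) / 200)
  out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3],
                            maxColorValue = 255)
  out
}

annotation_palette <- function(annotations) {
  cats <- sort(unique(annotations[!is.na(annotations)]))
  if (length(cats) == 0L) return(character(0))
  stats::setNames(grDevices::hcl.colors(length(cats), palette = "Dark 3"),
                  cats)
}

#' Draw a fixed-position fingerprint grid plot
#'
#' Renders one cohort fingerprint on the repertoire's fixed grid: one cell
#' per (aggregate row, column) position, a red spot for a predominantly
#' increased module, a blue spot for a predominantly decreased one, spot
#' radius scaling linearly with |response| up to the cell radius at 100.
#' Cells of modules that could not be evaluated (low coverage) get a gray
#' background; evaluable-but-unchanged modules stay white. Responses below
#' `min_display` are not drawn as spots, so only predominant changes are
#' visible. Because positions are fixed by the layout, any two
#' fingerprints rendered with the same layout are directly comparable cell
#' by cell.
#'
#' Output is SVG (vector, byte-stable across runs for identical input).
#'
#' @param fp A `fingerprint` (carries aggregate/column positions).
#' @param out Output SVG path.
#' @param min_display Minimum |response| rendered as a spot; default 15.
#' @param annotate Logical; overlay a per-module annotation colour tick
#'   (needs an `annotation` column or a `layout` with one). Default FALSE.
#' @param layout Optional layout data.frame supplying positions and
#'   annotations when `fp` lacks them; module ids must match.
#' @param title Plot title; default the fingerprint's cohort label.
#' @return Invisibly, the cell geometry: data.frame with `module_id`,
#'   `aggregate`, `column`, `x`, `y`, `radius`, `color`, `background`.
#' @export
plot_fingerprint_grid <- function(fp, out, min_display = 15,
                                  annotate = FALSE, layout = NULL,
                                  title = NULL) {
  df <- as.data.frame(fp)
  if (!is.null(layout)) {
    if (inherits(layout, "module_repertoire")) layout <- layout$layout
    missing_ids <- setdiff(df$module_id, layout$module_id)
    if (length(missing_ids) > 0L) {
      stop("Fingerprint module(s) missing from the layout: ",
           paste(missing_ids, collapse = ", "))
    }
    idx <- match(df$module_id, layout$module_id)
    df$aggregate <- layout$aggregate[idx]
    df$column <- layout$column[idx]
    if ("annotation" %in% names(layout)) {
      df$annotation <- layout$annotation[idx]
    }
  }
  if (!all(c("aggregate", "column") %in% names(df))) {
    stop("Fingerprint carries no grid positions; supply a layout")
  }
  aggs <- sort(unique(df$aggregate))
  n_rows <- length(aggs)
  n_cols <- max(df$column)
  # grid coordinates: row 1 at the top, columns left to right
  df$x <- df$column
  df$y <- n_rows - match(df$aggregate, aggs) + 1L
  df$radius <- ifelse(is.na(df$response) | abs(df$response) < min_display,
                      0, 0.45 * abs(df$response) / 100)
  df$color <- ifelse(df$radius == 0, NA_character_,
                     ifelse(df$response > 0, "#B2182B", "#2166AC"))
  df$background <- ifelse(df$low_coverage, "grey75", "white")

  if (is.null(title)) title <- attr(fp, "cohort") %||% ""
  grDevices::svg(out, width = max(4, 0.45 * n_cols + 1.6),
                 height = max(2.4, 0.45 * n_rows + 1.4))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1.5, 4, 2.5, 1))
  graphics::plot(NULL, xlim = c(0.5, n_cols + 0.5),
                 ylim = c(0.5, n_rows + 0.5),
                 xlab = "", ylab = "", axes = FALSE, asp = 1,
                 main = title)
  graphics::rect(df$x - 0.5, df$y - 0.5, df$x + 0.5, df$y + 0.5,
                 col = df$background, border = "grey55", lwd = 0.5)
  spots <- df[df$radius > 0, , drop = FALSE]
  if (nrow(spots) > 0L) {
    graphics::symbols(spots$x, spots$y, circles = spots$radius,
                      inches = FALSE, add = TRUE, fg = spots$color,
                      bg = spots$color)
  }
  if (annotate && "annotation" %in% names(df)) {
    pal <- annotation_palette(df$annotation)
    ann_col <- pal[df$annotation]
    ok <- !is.na(ann_col)
    graphics::rect(df$x[ok] - 0.5, df$y[ok] - 0.5, df$x[ok] + 0.5,
                   df$y[ok] - 0.38, col = ann_col[ok], border = NA)
  }
  graphics::axis(2, at = rev(seq_len(n_rows)), labels = aggs, las = 2,
                 tick = FALSE, cex.axis = 0.8)
  invisible(df[, c("module_id", "aggregate", "column", "x", "y",
                   "radius", "color", "background")])
}

#' Draw a clustered fingerprint heatmap
#'
#' Renders a cohorts x modules fingerprint matrix with rows and columns in
#' the supplied (or freshly computed) co-clustered order, a diverging
#' red/white/blue scale symmetric about 0 with bounds at +/-100, missing
#' (low-coverage) cells in gray, and marginal dendrograms where an axis
#' was clustered. Output is SVG.
#'
#' @param fm A `fingerprint_matrix`.
#' @param out Output SVG path.
#' @param ordering Optional `cluster_ordering` from [cocluster_matrix()];
#'   computed from `fm` when NULL.
#' @param missing_color Colour of missing cells; default `"grey80"`.
#' @param title Plot title.
#' @return Invisibly, a list with the drawn `row_order` and `col_order`.
#' @export
plot_fingerprint_heatmap <- function(fm, out, ordering = NULL,
                                     missing_color = "grey80",
                                     title = "") {
  mat <- unclass(fm)
  if (is.null(ordering)) {
    ordering <- cocluster_matrix(fm)
  }
  if (!setequal(ordering$row_order, rownames(mat)) ||
      !setequal(ordering$col_order, colnames(mat))) {
    stop("Ordering labels do not match the matrix dimnames")
  }
  mat <- mat[ordering$row_order, ordering$col_order, drop = FALSE]
  nr <- nrow(mat)
  nc <- ncol(mat)
  cols <- matrix(response_color(as.vector(mat), missing_color), nrow = nr)

  grDevices::svg(out, width = max(5, 0.32 * nc + 2.6),
                 height = max(3.5, 0.32 * nr + 2.2))
  on.exit(grDevices::dev.off(), add = TRUE)
  has_rt <- !is.null(ordering$row_tree)
  has_ct <- !is.null(ordering$col_tree)
  graphics::layout(matrix(c(0, 2, 3, 1), nrow = 2, byrow = TRUE),
                   widths = c(1, 4), heights = c(1, 4))
  graphics::par(mar = c(4.5, 0.5, 0.5, 4.5))
  graphics::plot(NULL, xlim = c(0, nc), ylim = c(0, nr), axes = FALSE,
                 xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  for (i in seq_len(nr)) {
    graphics::rect(seq_len(nc) - 1, nr - i, seq_len(nc), nr - i + 1,
                   col = cols[i, ], border = NA)
  }
  graphics::axis(1, at = seq_len(nc) - 0.5, labels = colnames(mat),
                 las = 2, tick = FALSE, cex.axis = 0.7)
  graphics::axis(4, at = nr - seq_len(nr) + 0.5, labels = rownames(mat),
                 las = 2, tick = FALSE, cex.axis = 0.7)
  graphics::par(mar = c(0.2, 0.5, 1.5, 4.5))
  if (has_ct) {
    graphics::plot(stats::as.dendrogram(ordering$col_tree), leaflab = "none",
                   axes = FALSE, xaxs = "i", main = title)
  } else {
    graphics::plot.new()
    graphics::title(main = title)
  }
  graphics::par(mar = c(4.5, 1.5, 0.5, 0.2))
  if (has_rt) {
    graphics::plot(stats::as.dendrogram(ordering$row_tree), leaflab = "none",
                   axes = FALSE, horiz = TRUE, yaxs = "i")
  } else {
    graphics::plot.new()
  }
  invisible(list(row_order = ordering$row_order,
                 col_order = ordering$col_order))
}
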