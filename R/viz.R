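#' Dendrogram segment coordinates
#'
#' Converts an [stats::hclust] tree into a tibble of line segments (x, y,
#' xend, yend) with leaves at integer positions 1..n (in `tree$order`) and
#' heights on the y axis, suitable for drawing with
#' [ggplot2::geom_segment()].
#'
#' @param tree An [stats::hclust] tree.
#' @return A tibble of segments.
#' @export
dendrogram_segments <- function(tree) {
  n <- length(tree$order)
  pos <- numeric(2 * n - 1) # leaf and internal-node x positions (node = n + merge row)
  hei <- numeric(2 * n - 1)
  pos[seq_len(n)] <- order(tree$order)
  segs <- vector("list", nrow(tree$merge))
  node_h <- function(id) if (id < 0) 0 else hei[n + id]
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]
    b <- tree$merge[i, 2]
    xa <- if (a < 0) pos[-a] else pos[n + a]
    xb <- if (b < 0) pos[-b] else pos[n + b]
    ha <- node_h(a)
    hb <- node_h(b)
    h <- tree$height[i]
    pos[n + i] <- (xa + xb) / 2
    hei[n + i] <- h
    segs[[i]] <- tibble::tibble(
      x = c(xa, xb, min(xa, xb)),
      y = c(ha, hb, h),
      xend = c(xa, xb, max(xa, xb)),
      yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}

heatmap_palettes <- list(
  quantitative = c("#DEEBF7", "#08306B"), # blue sequential
  ordinal = c("#E5F5E0", "#00441B"), # green sequential
  nominal = c("#FEE0D2", "#99000D"), # red shades
  missing = "#FFFFFF"
)

#' Cell-level data for the integrative mixed heatmap
#'
#' Computes, for every (variable, sample) cell, the color used by
#' [plot_mixed_heatmap()]: quantitative rows on a blue sequential scale after
#' row-wise min-max scaling, ordinal rows on a green sequential scale by level
#' order, nominal/binary rows on red categorical shades, missing cells white.
#'
#' @inheritParams gower_dist
#' @return A tibble with columns `variable`, `sample`, `value` (display
#'   value), `family` (scale family) and `color` (hex).
#' @export
mixed_heatmap_data <- function(data, spec = NULL) {
  cm <- compile_mixed(data, spec)
  purrr::map_dfr(cm$vars, function(v) {
    x <- v$x
    family <- if (v$scale == "quantitative") {
      "quantitative"
    } else if (v$scale == "ordinal") {
      "ordinal"
    } else {
      "nominal"
    }
    col <- rep(heatmap_palettes$missing, length(x))
    if (family == "quantitative") {
      rng <- suppressWarnings(range(x, na.rm = TRUE))
      z <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0.5, length(x))
      ramp <- grDevices::colorRampPalette(heatmap_palettes$quantitative)(101)
      ok <- !is.na(z)
      col[ok] <- ramp[round(z[ok] * 100) + 1]
      val <- as.character(x)
    } else {
      k <- nlevels(x)
      pal <- grDevices::colorRampPalette(heatmap_palettes[[family]])(max(k, 2))
      ok <- !is.na(x)
      col[ok] <- pal[as.integer(x[ok])]
      val <- as.character(x)
    }
    tibble::tibble(
      variable = v$name, sample = cm$ids,
      value = val, family = family, color = col
    )
  })
}

#' Integrative heatmap of a mixed-type table
#'
#' Draws the samples-by-variables table with dendrograms on both axes and a
#' separate color family per variable scale: blue for quantitative rows
#' (row-wise min-max scaled), green for ordinal rows (by level order), red
#' shades for nominal/binary rows; missing cells are white. Rows are
#' variables, columns are samples, both ordered by their trees. The display is
#' limited to 200 variables.
#'
#' @inheritParams gower_dist
#' @param sample_tree,var_tree [stats::hclust] trees over exactly the
#'   dataset's samples/variables; computed from [gower_dist()] and the method
#'   in `vars_method` when `NULL`.
#' @param vars_method `"ama"` or `"dcor"`, used when `var_tree` is `NULL`.
#' @param file Optional PNG path; when given the plot is also written there.
#' @param width,height Device size in inches for `file`.
#' @return A patchwork/ggplot object, invisibly when `file` is given.
#' @export
plot_mixed_heatmap <- function(data, spec = NULL, sample_tree = NULL, var_tree = NULL,
                               vars_method = c("ama", "dcor"), file = NULL,
                               width = 8, height = 6) {
  vars_method <- match.arg(vars_method)
  cm <- compile_mixed(data, spec)
  if (cm$p > 200) {
    stop("heatmap is limited to a maximum of 200 variables (got ", cm$p, ")", call. = FALSE)
  }
  if (is.null(sample_tree)) {
    sample_tree <- cluster_tree(gower_dist(data, spec), "ward")
  }
  if (is.null(var_tree)) {
    d <- if (vars_method == "ama") {
      suppressWarnings(ama_dist(data, spec))
    } else {
      suppressMessages(suppressWarnings(dcor_dist(data, spec)))
    }
    var_tree <- cluster_tree(d, "ward")
  }
  sample_labels <- sample_tree$labels %||% cm$ids
  var_labels <- var_tree$labels %||% names(cm$vars)
  if (!setequal(sample_labels, cm$ids) || !setequal(var_labels, names(cm$vars))) {
    stop("trees must cover exactly the dataset's samples and variables", call. = FALSE)
  }
  cells <- mixed_heatmap_data(data, spec)
  sample_order <- sample_labels[sample_tree$order]
  var_order <- var_labels[var_tree$order]
  cells$sample <- factor(cells$sample, levels = sample_order)
  cells$variable <- factor(cells$variable, levels = rev(var_order))
  main <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$sample, y = .data$variable)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$color), color = NA) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1, size = 6),
      panel.grid = ggplot2::element_blank()
    )
  top <- dendro_panel(dendrogram_segments(sample_tree), flip = FALSE)
  left <- dendro_panel(dendrogram_segments(var_tree), flip = TRUE)
  p <- patchwork::wrap_plots(
    patchwork::plot_spacer(), top, left, main,
    ncol = 2, widths = c(1, 5), heights = c(1, 5)
  )
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 100)
    return(invisible(p))
  }
  p
}

dendro_panel <- function(segs, flip = FALSE) {
  if (flip) {
    # variables run top to bottom on the y axis; heights extend leftwards
    segs <- tibble::tibble(
      x = -segs$y, y = max(segs$xend) + 1 - segs$x,
      xend = -segs$yend, yend = max(segs$xend) + 1 - segs$xend
    )
  }
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, y = .data$y,
      xend = .data$xend, yend = .data$yend
    ), linewidth = 0.3) +
    ggplot2::theme_void()
}

#' Heatmap of a variable similarity matrix
#'
#' Symmetric heatmap of pairwise variable similarities, ordered by a
#' hierarchical tree; stronger relationships appear as darker blue cells and
#' shorter dendrogram distances.
#'
#' @param s A [similarity_matrix()].
#' @param tree Optional [stats::hclust] over the same labels; computed by Ward
#'   clustering of `sqrt(1 - s)` when `NULL`.
#' @param file Optional PNG path.
#' @param width,height Device size in inches for `file`.
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_similarity_heatmap <- function(s, tree = NULL, file = NULL, width = 7, height = 6) {
  m <- as.matrix(s)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square", call. = FALSE)
  if (is.null(tree)) {
    tree <- cluster_tree(distance_matrix(sqrt(pmax(1 - m, 0)), axis = "variables"), "ward")
  }
  labs <- tree$labels %||% rownames(m)
  if (!setequal(labs, rownames(m))) stop("tree and matrix labels differ", call. = FALSE)
  ord <- labs[tree$order]
  long <- tidy.mixed_mat(similarity_matrix(m,
    axis = attr(s, "axis") %||% "variables",
    method = attr(s, "method") %||% "custom"
  ))
  long <- dplyr::bind_rows(
    long,
    tibble::tibble(item1 = long$item2, item2 = long$item1, value = long$value),
    tibble::tibble(item1 = rownames(m), item2 = rownames(m), value = diag(m))
  )
  long$item1 <- factor(long$item1, levels = ord)
  long$item2 <- factor(long$item2, levels = rev(ord))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$item1, .data$item2, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "#F7FBFF", high = "#08306B",
      limits = c(min(0, min(long$value)), 1), name = "similarity"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1),
      panel.grid = ggplot2::element_blank()
    )
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 100)
    return(invisible(p))
  }
  p
}

#' Coordinates for the predictor-outcome similarity scatter
#'
#' For each variable other than the chosen outcome and predictor, the point
#' (similarity to predictor, similarity to outcome) is extracted from the
#' similarity matrix. The outcome itself is placed at
#' `(s(outcome, predictor), 1)` and the predictor at
#' `(1, s(outcome, predictor))`.
#'
#' @param s A [similarity_matrix()] over variables.
#' @param outcome,predictor Distinct variable labels present in `s`.
#' @param spec Optional [mixed_spec()] used to tag variables as numerical or
#'   categorical.
#' @return A tibble with columns `variable`, `x`, `y`, `family`.
#' @export
similarity_scatter_data <- function(s, outcome, predictor, spec = NULL) {
  m <- as.matrix(s)
  labs <- rownames(m)
  if (!outcome %in% labs) stop("unknown outcome label: ", outcome, call. = FALSE)
  if (!predictor %in% labs) stop("unknown predictor label: ", predictor, call. = FALSE)
  if (identical(outcome, predictor)) stop("outcome and predictor must differ", call. = FALSE)
  sop <- m[outcome, predictor]
  others <- setdiff(labs, c(outcome, predictor))
  out <- tibble::tibble(
    variable = c(others, outcome, predictor),
    x = c(m[others, predictor], sop, 1),
    y = c(m[others, outcome], 1, sop)
  )
  fam <- rep("numerical", nrow(out))
  if (!is.null(spec)) {
    spec <- as_mixed_spec(spec)
    cat_vars <- spec$variable[spec$scale != "quantitative"]
    fam <- ifelse(out$variable %in% cat_vars, "categorical", "numerical")
  }
  out$family <- fam
  out
}

#' Predictor-outcome similarity scatter plot
#'
#' Plots every variable's similarity to a chosen predictor (x) against its
#' similarity to a chosen outcome (y), with variable names as plotting
#' symbols; numerical variables in black, categorical in purple. Points near
#' the top are outcome-related (candidate predictors or surrogate outcomes),
#' points near the right are collinear with the predictor, and the top right
#' corner flags potential confounders.
#'
#' @inheritParams similarity_scatter_data
#' @param file Optional PNG path.
#' @param width,height Device size in inches for `file`.
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_similarity_scatter <- function(s, outcome, predictor, spec = NULL, file = NULL,
                                    width = 7, height = 6) {
  pts <- similarity_scatter_data(s, outcome, predictor, spec)
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
    label = .data$variable, color = .data$family
  )) +
    ggplot2::geom_text(size = 3) +
    ggplot2::scale_color_manual(
      values = c(numerical = "black", categorical = "purple4"),
      name = NULL
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1.05), ylim = c(0, 1.05)) +
    ggplot2::labs(
      x = paste0("similarity to ", predictor),
      y = paste0("similarity to ", outcome)
    ) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 100)
    return(invisible(p))
  }
  p
}

#' @rdname plot_similarity_heatmap
#' @param object,... `autoplot` method arguments (a `mixed_sim` matrix).
#' @exportS3Method ggplot2::autoplot
autoplot.mixed_sim <- function(object, ...) plot_similarity_heatmap(object, ...)
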