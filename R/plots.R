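# ggplot2 display helpers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_tile geom_path geom_text geom_vline labs theme_minimal
#'   scale_fill_gradient2 coord_equal
#' @export
ggplot2::autoplot

#' Plot an ear with its detected kernel outlines
#'
#' Raster of the aligned ear class masks with kernel centroids overlaid,
#' in physical units.
#'
#' @param ear An [ear_instance()].
#' @param kernels Optional [detect_kernels()] table to overlay.
#' @return A ggplot object.
#' @export
plot_ear <- function(ear, kernels = NULL) {
  stopifnot(inherits(ear, "ear_instance"))
  ppc <- ear$px_per_cm
  cls <- matrix("background", nrow(ear$ear_mask), ncol(ear$ear_mask))
  cls[ear$cob_mask] <- "cob"
  cls[ear$kernel_mask] <- "kernel"
  df <- tibble(
    y = rep((seq_len(nrow(cls)) - 0.5) / ppc, times = ncol(cls)),
    x = rep((seq_len(ncol(cls)) - 0.5) / ppc, each = nrow(cls)),
    class = as.vector(cls))
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$class)) +
    geom_tile() +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          cob = "sienna4",
                                          kernel = "goldenrod1")) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "transverse (cm)", y = "axial from tip (cm)",
         title = sprintf("Ear %d", ear$ear_index)) +
    theme_minimal()
  if (!is.null(kernels) && nrow(kernels)) {
    p <- p + geom_point(data = kernels,
                        aes(x = .data$centroid_x_cm, y = .data$centroid_y_cm),
                        inherit.aes = FALSE, shape = 3, size = 0.8,
                        colour = "black")
  }
  p
}

#' @rdname trait_pca
#' @param object A `trait_pca` object.
#' @param components Two components to display. Default `c(1, 2)`.
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, components = c(1, 2), ...) {
  ld <- object$loadings
  df <- tibble(trait = rownames(ld),
               x = ld[, components[1]], y = ld[, components[2]])
  ggplot(df, aes(x = .data$x, y = .data$y, label = .data$trait)) +
    geom_point(colour = "steelblue") +
    geom_text(vjust = -0.6, size = 3) +
    labs(x = sprintf("PC%d (%.1f%%)", components[1],
                     object$pct_var[components[1]]),
         y = sprintf("PC%d (%.1f%%)", components[2],
                     object$pct_var[components[2]]),
         title = "Trait PCA loadings") +
    theme_minimal()
}

#' @rdname cluster_traits
#' @param object A `trait_clusters` object.
#' @param ... Unused.
#' @method autoplot trait_clusters
#' @export
autoplot.trait_clusters <- function(object, ...) {
  ggplot(object$bh, aes(x = .data$k, y = .data$index)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_vline(xintercept = object$k, linetype = 2, colour = "firebrick") +
    labs(x = "number of clusters k", y = "Ball-Hall index",
         title = sprintf("Ball-Hall curve (selected k = %d)", object$k)) +
    theme_minimal()
}

#' @rdname compare_groups
#' @param object A `group_comparison` object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$table
  ggplot(df, aes(x = stats::reorder(.data$group, -.data$mean),
                 y = .data$mean)) +
    geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(aes(ymin = .data$min, ymax = .data$max),
                           width = 0.15) +
    geom_text(aes(label = .data$letter, y = .data$max), vjust = -0.5) +
    labs(x = NULL, y = "BLUP",
         title = sprintf("Group comparison (%s)", object$sig)) +
    theme_minimal()
}
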