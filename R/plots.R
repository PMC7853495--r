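# ggplot2 visualization helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reconstructed EIT image
#'
#' @param object An `eit_image`.
#' @param title Optional plot title.
#' @param ... Unused.
#' @return A ggplot object (raster heatmap of the disk).
#' @export
autoplot.eit_image <- function(object, title = NULL, ...) {
  N <- nrow(object$grid)
  xs <- seq(-1 + 1 / N, 1 - 1 / N, length.out = N)
  df <- data.frame(x = rep(xs, times = N), y = rep(xs, each = N),
                   value = as.vector(object$grid),
                   inside = as.vector(object$disk_mask))
  df$value[!df$inside] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey95",
                                  midpoint = stats::median(
                                    df$value[df$inside])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot training curves of a fit
#'
#' @param object An `eitsep_fit`.
#' @param ... Unused.
#' @return A ggplot object of train/validation loss per epoch.
#' @export
autoplot.eitsep_fit <- function(object, ...) {
  h <- tidy_history(object)
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, curve = "train",
               phase = h$phase),
    data.frame(epoch = h$epoch, loss = h$val_loss, curve = "validation",
               phase = h$phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$curve,
                                   linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "weighted BCE loss") +
    ggplot2::theme_minimal()
}

#' Side-by-side panel of a triplet and model predictions
#'
#' @param triplet_images Named list of `eit_image`s (e.g. mixed, targets,
#'   predictions).
#' @return A patchwork-free list of ggplots, or a combined plot via
#'   facets.
#' @export
plot_image_panel <- function(triplet_images) {
  dfs <- lapply(names(triplet_images), function(nm) {
    im <- triplet_images[[nm]]
    N <- nrow(im$grid)
    xs <- seq(-1 + 1 / N, 1 - 1 / N, length.out = N)
    data.frame(x = rep(xs, times = N), y = rep(xs, each = N),
               value = ifelse(as.vector(im$disk_mask),
                              as.vector(im$grid), NA),
               panel = nm)
  })
  df <- do.call(rbind, dfs)
  df$panel <- factor(df$panel, levels = names(triplet_images))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::theme_minimal()
}
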