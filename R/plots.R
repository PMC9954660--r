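# ggplot2 views of training curves, QC overlays and phantoms.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training curves
#'
#' Loss and pixel accuracy per epoch for the training and validation sets.
#'
#' @param object An `rda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rda_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$loss, metric = "loss", set = "train"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss, metric = "loss", set = "validation"),
    tibble::tibble(epoch = h$epoch, value = h$acc, metric = "accuracy", set = "train"),
    tibble::tibble(epoch = h$epoch, value = h$val_acc, metric = "accuracy", set = "validation")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an overlay quality check
#'
#' Windowed image as a grayscale raster with the mask outline superimposed.
#'
#' @param object An `overlay_check` from [overlay_check()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlay_check <- function(object, ...) {
  p <- object$pair
  H <- nrow(p$image); W <- ncol(p$image)
  df <- tibble::tibble(
    x = rep(seq_len(W), each = H),
    y = rep(seq_len(H), times = W),
    intensity = as.vector(p$image),
    mask = as.vector(p$mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s  coverage %.3f", p$slice_id,
                                  object$coverage),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a phantom with its masks
#'
#' @param x Output of [generate_phantom()].
#' @param window The [hu_window()] used for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_phantom <- function(x, window = hu_window(), ...) {
  img <- apply_hu_window(x$slice, window)
  H <- nrow(img); W <- ncol(img)
  df <- tibble::tibble(
    x = rep(seq_len(W), each = H),
    y = rep(seq_len(H), times = W),
    intensity = as.vector(img),
    organ = as.vector(x$organ_mask),
    lesion = as.vector(x$lesion_mask)
  )
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$organ), breaks = 0.5,
                          colour = "cyan", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (sum(x$lesion_mask) > 0) {
    g <- g + ggplot2::geom_contour(ggplot2::aes(z = .data$lesion), breaks = 0.5,
                                   colour = "red", linewidth = 0.3)
  }
  g
}
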