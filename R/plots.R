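need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the ggplot2 package is required for plotting")
  }
}

#' Plot an axial slice of a parameter map
#'
#' @param maps a [match_images()] result or named list of 3D arrays.
#' @param parameter map name (e.g. `"k_ck"`).
#' @param slice z index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_maps <- function(maps, parameter = "k_ck", slice = NULL) {
  need_ggplot()
  m <- if (inherits(maps, "cki_maps")) maps$maps else maps
  if (!parameter %in% names(m)) {
    stop("unknown map '", parameter, "'; available: ",
         paste(names(m), collapse = ", "))
  }
  vol <- m[[parameter]]
  if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
  sl <- vol[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (slice %d)", parameter, slice),
                  fill = parameter) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cki_maps <- function(object, parameter = "k_ck", slice = NULL,
                              ...) {
  plot_maps(object, parameter = parameter, slice = slice)
}

#' Plot a simulated or measured signal evolution
#'
#' Magnitude of the complex samples against the excitation index, coloured
#' by the targeted metabolite.
#'
#' @param evolution a `cki_evolution`.
#' @return A ggplot object.
#' @export
plot_evolution <- function(evolution) {
  need_ggplot()
  df <- data.frame(index = seq_along(evolution$samples),
                   magnitude = Mod(evolution$samples),
                   target = evolution$target)
  ggplot2::ggplot(df, ggplot2::aes(x = index, y = magnitude,
                                   colour = target)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation index", y = "|signal| (M0 ATP units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cki_evolution <- function(object, ...) plot_evolution(object)

#' Plot the flip-angle pattern
#'
#' @param config a [cki_config()].
#' @return A ggplot object.
#' @export
plot_fa_pattern <- function(config = cki_config()) {
  need_ggplot()
  pat <- build_fa_pattern(config)
  ggplot2::ggplot(pat, ggplot2::aes(x = index, y = flip_deg,
                                    colour = target)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation index", y = "flip angle (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detected activation clusters on a slice
#'
#' @param clusters a [detect_clusters()] result.
#' @param slice z index (default: slice with the most cluster voxels).
#' @return A ggplot object.
#' @export
plot_clusters <- function(clusters, slice = NULL) {
  need_ggplot()
  lab <- clusters$label_map
  if (is.null(slice)) {
    slice <- which.max(apply(lab > 0, 3, sum))
  }
  sl <- lab[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$cluster <- factor(ifelse(as.vector(sl) > 0, as.vector(sl), NA))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   fill = cluster)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("activation clusters (slice %d)", slice),
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cki_clusters <- function(object, slice = NULL, ...) {
  plot_clusters(object, slice = slice)
}
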