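#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

slice_tibble <- function(vol, grid, k) {
  d <- dim(vol)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  sl <- vol[, , k]
  tibble::tibble(
    i = rep(seq_len(d[1]), times = d[2]),
    j = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(sl)
  )
}

#' Plot an axial slice of a frequency map
#'
#' @param object a `freq_map`.
#' @param k axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.freq_map <- function(object, k = NULL, ...) {
  df <- slice_tibble(object$counts, object$grid, k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno",
                                  name = "patients") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Lesion frequency", x = "x (voxel)",
                  y = "y (voxel)") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a voxel-wise Z-map
#'
#' @param object a `stat_map`.
#' @param k axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stat_map <- function(object, k = NULL, ...) {
  df <- slice_tibble(stat_map_volume(object, "z")$data, object$grid, k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95",
                                  high = "firebrick", name = "z") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Voxel-wise Z-map", x = "x (voxel)",
                  y = "y (voxel)") +
    ggplot2::theme_minimal()
}

#' Plot significant voxels of a correction result over the lesion counts
#'
#' @param object a `correction_result`.
#' @param k axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.correction_result <- function(object, k = NULL, ...) {
  d <- object$grid$shape
  if (is.null(k)) k <- ceiling(d[3] / 2)
  df <- slice_tibble(array(as.integer(object$significant), dim = d),
                     object$grid, k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "firebrick"),
                               name = "significant", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Significant voxels (", object$method,
                                 ", alpha = ", object$alpha, ")"),
                  x = "x (voxel)", y = "y (voxel)") +
    ggplot2::theme_minimal()
}

#' Null-distribution diagnostic for a permutation correction
#'
#' Histogram of the permutation maxima with the observed map maximum and
#' the critical value marked.
#'
#' @param result a `correction_result` from [permutation_correct()].
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(result) {
  if (is.null(result$null_max)) {
    stop("plot_null_distribution: result has no permutation null",
         call. = FALSE)
  }
  ok <- !result$voxels$degenerate
  obs_max <- max(result$voxels$score[ok], 0)
  df <- tibble::tibble(null_max = result$null_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_max)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = result$critical_value,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = obs_max, color = "firebrick") +
    ggplot2::labs(title = paste0("Permutation null (", result$method, ")"),
                  x = "max statistic per permutation", y = "count") +
    ggplot2::theme_minimal()
}
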