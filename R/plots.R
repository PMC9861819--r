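# ggplot2 visualisations of training runs and complexity reports.

#' Plot a training run
#'
#' Loss per optimisation step, with the evaluated whole-tumor Dice overlaid
#' where the run logged it.
#'
#' @param object An `hmnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmnet_fit <- function(object, ...) {
  lg <- object$log
  p <- ggplot2::ggplot(lg, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "step", y = "Dice + BCE loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
  ev <- dplyr::filter(lg, !is.na(.data$dice_wt))
  if (nrow(ev)) {
    p <- p + ggplot2::geom_point(
      data = ev, ggplot2::aes(y = 1 - .data$dice_wt),
      color = "firebrick", shape = 17) +
      ggplot2::labs(subtitle = "triangles: 1 - Dice(WT) at evaluation steps")
  }
  p
}

#' Plot where a model spends parameters and operations
#'
#' Per-layer operation counts against parameters, grouped by network
#' section (stem / stages / head).
#'
#' @param object An `hmnet_complexity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmnet_complexity <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(section = dplyr::case_when(
      grepl("^stem", .data$layer) ~ "stem",
      grepl("^head", .data$layer) ~ "head",
      TRUE ~ sub("^(stage[0-9]+).*", "\\1", .data$layer)
    ))
  agg <- df |>
    dplyr::group_by(.data$section) |>
    dplyr::summarise(params = sum(.data$n_params), flops = sum(.data$flops))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$params / 1e3,
                                    y = .data$flops / 1e9,
                                    label = .data$section)) +
    ggplot2::geom_point(size = 3, color = "steelblue") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "parameters (k)", y = "operations (G)",
                  title = sprintf("Complexity by section at %d^3 input",
                                  object$input_size)) +
    ggplot2::theme_minimal()
}

#' Plot an axial cross-section of a case
#'
#' Shows one modality slice with the label boundaries overlaid, a quick
#' visual check of phantoms and predictions.
#'
#' @param sample A `brats_case`.
#' @param modality Modality index (1 = FLAIR).
#' @param slice Axial slice index; default the middle slice.
#' @return A ggplot object.
#' @export
plot_case_slice <- function(sample, modality = 1L, slice = NULL) {
  d <- dim(sample$image)
  if (is.null(slice)) slice <- ceiling(d[4] / 2)
  img <- sample$image[modality, , , slice]
  df <- expand.grid(x = seq_len(d[2]), y = seq_len(d[3]))
  df$intensity <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %s slice %d", sample$case_id,
                                  BRATS_MODALITIES[modality], slice)) +
    ggplot2::theme_void()
  if (!is.null(sample$label)) {
    lab <- sample$label[, , slice]
    ldf <- df[as.vector(lab) > 0, ]
    ldf$label <- factor(as.vector(lab)[as.vector(lab) > 0])
    if (nrow(ldf))
      p <- p + ggplot2::geom_point(data = ldf,
                                   ggplot2::aes(color = .data$label),
                                   size = 0.3, alpha = 0.4) +
      ggplot2::scale_color_manual(values = c(`1` = "red", `2` = "green",
                                             `4` = "yellow"))
  }
  p
}
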