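# ggplot2 autoplot methods for the main result types.

#' Plot an axial slice of a voxel grid
#'
#' @param object A [voxel_grid].
#' @param slice Axial (third-axis) slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_grid <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x <- (df$i - 1) * object$spacing[1] + object$origin[1]
  df$y <- (df$j - 1) * object$spacing[2] + object$origin[2]
  df$value <- as.vector(object$values[, , slice])[
    (df$j - 1) * d[1] + df$i]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = if (object$modality == "PET") "SUV" else "intensity") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s, axial slice %d", object$modality, slice)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' Step curves per group with the log-rank p in the subtitle.
#'
#' @param object A `km_result` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_result <- function(object, ...) {
  cv <- object$curves
  # prepend time-zero anchors per group
  anchors <- dplyr::distinct(cv, .data$group)
  anchors$time <- 0; anchors$surv <- 1
  cv2 <- dplyr::bind_rows(anchors, cv[, c("group", "time", "surv")])
  ggplot2::ggplot(cv2, ggplot2::aes(.data$time, .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability",
                  title = sprintf("Kaplan-Meier, %s", toupper(object$endpoint)),
                  subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve with its Youden-optimal operating point
#'
#' @param object A `roc_result` from [roc_cutoff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(1 - .data$specificity,
                                      .data$sensitivity)) +
    ggplot2::geom_abline(linetype = "dotted", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("%s: AUC %.3f, cutoff %.3g",
                                  object$variable, object$auc, object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Forest plot of Cox hazard ratios
#'
#' @param object A `cox_screen` tibble from [cox_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cox_screen <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$converged)
  df$label <- ifelse(df$scale_note == "", df$term,
                     paste0(df$term, " (", df$scale_note, ")"))
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~analysis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "hazard ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
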