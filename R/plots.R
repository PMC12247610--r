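#' Plot a laminar connectivity profile
#'
#' Mean connectivity strength per cortical depth with an SEM ribbon, depth
#' 1 = deep/white, depth D = superficial/pial.
#'
#' @param profile tibble from [extract_profile()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_laminar_profile <- function(profile, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$depth, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "cortical depth (deep → superficial)",
                  y = "connectivity strength (mean positive Fisher z)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot the cluster mean profiles of a laminar parcellation
#'
#' @param parc a `laminar_parcellation`.
#' @return A ggplot object: one line per anchored cluster (label 1 =
#'   middle-peak / feedforward-like, label 2 = superficial-peak /
#'   feedback-like).
#' @export
plot_parcellation_profiles <- function(parc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  k <- nrow(parc$centers)
  df <- tibble::tibble(
    depth = rep(seq_len(ncol(parc$centers)), times = k),
    value = as.vector(t(parc$centers)),
    cluster = factor(rep(seq_len(k), each = ncol(parc$centers))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$value,
                                   color = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cortical depth (deep → superficial)",
                  y = "mean cluster FCS",
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.laminar_parcellation <- function(object, ...) {
  plot_parcellation_profiles(object)
}

#' @exportS3Method ggplot2::autoplot
autoplot.laminar_reliability <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- tibble::tibble(
    dice = c(object$dice_values, object$null_dice),
    source = rep(c("observed", "null"),
                 c(length(object$dice_values), length(object$null_dice))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$dice)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "Dice similarity coefficient", x = NULL) +
    ggplot2::theme_minimal()
}
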