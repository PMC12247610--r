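#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a laminar parcellation
#'
#' One row per region vertex with its anchored cluster label (1 =
#' middle-peak / feedforward-like, 2 = superficial-peak / feedback-like,
#' 0 = unclassified).
#'
#' @param x a `laminar_parcellation`.
#' @param ... unused.
#' @return A tibble with columns `vertex`, `label`.
#' @export
tidy.laminar_parcellation <- function(x, ...) {
  idx <- which(x$region)
  tibble::tibble(vertex = idx, label = x$labels[idx])
}

#' @rdname tidy.laminar_parcellation
#' @return `glance()` returns a one-row tibble with `k`, `n_vertices`, and
#'   per-label counts.
#' @export
glance.laminar_parcellation <- function(x, ...) {
  lab <- x$labels[x$region]
  tibble::tibble(k = x$k, n_vertices = sum(x$region),
                 n_label1 = sum(lab == 1L, na.rm = TRUE),
                 n_label2 = sum(lab == 2L, na.rm = TRUE),
                 n_unclassified = sum(lab == 0L, na.rm = TRUE))
}

#' Tidy a reliability result
#'
#' @param x a `laminar_reliability`.
#' @param ... unused.
#' @return One row per split-half repeat and null pair, with columns
#'   `pair`, `dice`, `source`.
#' @export
tidy.laminar_reliability <- function(x, ...) {
  tibble::tibble(
    pair = c(seq_along(x$dice_values), seq_along(x$null_dice)),
    dice = c(x$dice_values, x$null_dice),
    source = rep(c("observed", "null"),
                 c(length(x$dice_values), length(x$null_dice))))
}

#' @rdname tidy.laminar_reliability
#' @return `glance()` returns a one-row tibble with the Dice summary and
#'   the two-sample t-test against the null.
#' @export
glance.laminar_reliability <- function(x, ...) {
  tibble::tibble(mean_dice = mean(x$dice_values),
                 sd_dice = stats::sd(x$dice_values),
                 mean_null = mean(x$null_dice),
                 sd_null = stats::sd(x$null_dice),
                 t_stat = x$t_stat, p_value = x$p_value,
                 n_pairs = x$n_pairs)
}
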