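# Tidiers and plots for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training trace
#'
#' @param x A `nutrinet_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and metric (`epoch`, `metric`,
#'   `value`).
#' @method tidy nutrinet_model
#' @export
tidy.nutrinet_model <- function(x, ...) {
  x$record$epochs |>
    tidyr::pivot_longer(c("train_wmae", "val_wmae"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("epoch", "metric", "value")
}

#' One-row summary of a fitted model
#'
#' @param x A `nutrinet_model`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs, final train/validation
#'   WMAE, tokens asleep at the end, seed.
#' @method glance nutrinet_model
#' @export
glance.nutrinet_model <- function(x, ...) {
  ep <- x$record$epochs
  last <- if (nrow(ep) > 0) ep[nrow(ep), ] else
    tibble::tibble(train_wmae = NA_real_, val_wmae = NA_real_, n_asleep = NA_integer_)
  tibble::tibble(
    n_params = x$record$n_params,
    epochs = nrow(ep),
    train_wmae = last$train_wmae,
    val_wmae = last$val_wmae,
    n_asleep = last$n_asleep,
    seed = x$seed
  )
}

#' Plot the training trace of a fitted model
#'
#' @param object A `nutrinet_model`.
#' @param ... Unused.
#' @return A ggplot of WMAE against epoch, one line per split.
#' @method autoplot nutrinet_model
#' @export
autoplot.nutrinet_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "WMAE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy an EFE stability ablation
#'
#' @param x An `efe_ablation` from [ablate_efe()].
#' @param ... Unused.
#' @return The per-arm, per-nutrient median-variance tibble.
#' @method tidy efe_ablation
#' @export
tidy.efe_ablation <- function(x, ...) x$report

#' Plot an EFE stability ablation
#'
#' @param object An `efe_ablation`.
#' @param ... Unused.
#' @return A ggplot comparing per-nutrient median prediction variance across
#'   the two arms.
#' @method autoplot efe_ablation
#' @export
autoplot.efe_ablation <- function(object, ...) {
  object$report |>
    ggplot2::ggplot(ggplot2::aes(x = .data$nutrient, y = .data$median_variance,
                                 fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "median prediction variance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Tidy a decoder-depth ablation
#'
#' @param x A `depth_ablation` from [ablate_depth()].
#' @param ... Unused.
#' @return The per-depth report tibble.
#' @method tidy depth_ablation
#' @export
tidy.depth_ablation <- function(x, ...) x$report

#' @importFrom rlang .data
NULL
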