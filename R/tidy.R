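#' Tidy a federated run into its round log
#'
#' @param x A `pcr_fed` object.
#' @param ... Unused.
#' @return Tibble with one row per (round, client): `round`, `client`, `n_k`,
#'   `loss_sup`, `loss_con`, `loss_total`, `dice_val`.
#' @export
tidy.pcr_fed <- function(x, ...) {
  tibble::as_tibble(x$log)
}

#' One-row summary of a federated run
#'
#' @param x A `pcr_fed` object.
#' @param ... Unused.
#' @return Tibble with `clients`, `rounds`, `alpha`, `tau`,
#'   `n_total`, `mean_val_dice` (final round, unweighted over clients) and
#'   `min_val_dice`.
#' @export
glance.pcr_fed <- function(x, ...) {
  last <- x$log[x$log$round == max(x$log$round), ]
  tibble::tibble(
    clients = length(x$clients),
    rounds = x$server$round,
    alpha = x$fed$loss$alpha,
    tau = x$fed$loss$tau,
    n_total = x$server$N,
    mean_val_dice = mean(last$dice_val),
    min_val_dice = min(last$dice_val)
  )
}

#' Plot the training trajectory of a federated run
#'
#' Validation Dice per client across communication rounds, with the
#' unweighted client mean overlaid.
#'
#' @param object A `pcr_fed` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcr_fed <- function(object, ...) {
  log <- object$log
  mean_df <- dplyr::summarise(
    dplyr::group_by(log, .data$round),
    dice_val = mean(.data$dice_val), .groups = "drop"
  )
  ggplot2::ggplot(log, ggplot2::aes(
    x = .data$round, y = .data$dice_val,
    group = factor(.data$client),
    colour = factor(.data$client)
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(
      data = mean_df,
      ggplot2::aes(x = .data$round, y = .data$dice_val),
      inherit.aes = FALSE, linewidth = 1
    ) +
    ggplot2::labs(
      x = "communication round", y = "validation Dice",
      colour = "client",
      title = "Per-client validation Dice (thick line: client mean)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter sweep
#'
#' Unweighted client-mean test Dice against the swept value.
#'
#' @param object A `pcr_sweep` tibble from [sweep_hyperparameter()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcr_sweep <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object, .data$parameter, .data$value),
    mean_dice = mean(.data$dice), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$mean_dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = unique(df$parameter), y = "mean test Dice",
      title = "Hyperparameter sweep"
    ) +
    ggplot2::theme_minimal()
}

#' Display a sample as an image/mask panel
#'
#' @param sample `list(image, mask)`.
#' @return A ggplot with the image in grayscale and the mask outline overlaid.
#' @export
plot_sample <- function(sample) {
  H <- nrow(sample$image)
  W <- ncol(sample$image)
  df <- tibble::tibble(
    row = rep(seq_len(H), W),
    col = rep(seq_len(W), each = H),
    intensity = as.vector(sample$image),
    mask = as.vector(sample$mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask),
      breaks = 0.5,
      colour = "red", linewidth = 0.4
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
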