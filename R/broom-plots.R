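#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training history
#'
#' @param x A `gancmlae_history` (from [train()]).
#' @param ... Unused.
#' @return A long tibble with `step`, `loss` (component name) and `value`.
#' @export
tidy.gancmlae_history <- function(x, ...) {
  comps <- setdiff(names(x), "step")
  out <- lapply(comps, function(cn)
    tibble::tibble(step = x$step, loss = cn, value = x[[cn]]))
  out <- do.call(rbind, out)
  out[!is.na(out$value), ]
}

#' One-row summary of a training history
#'
#' @inheritParams tidy.gancmlae_history
#' @return A tibble with the executed steps, critic updates and final loss
#'   components.
#' @export
glance.gancmlae_history <- function(x, ...) {
  last <- nrow(x)
  tibble::tibble(steps = last,
                 critic_updates = attr(x, "critic_updates") %||% NA_integer_,
                 loss_variant = attr(x, "loss_variant") %||% NA_character_,
                 final_total = x$total[last], final_l2 = x$l2[last],
                 final_l3 = x$l3[last])
}

#' One-row summary of a model
#'
#' @param x A `gancmlae_model`.
#' @param ... Unused.
#' @return A tibble with architecture accounting and training state.
#' @export
glance.gancmlae_model <- function(x, ...) {
  info <- encoder_flatten_info(x$spec)
  np <- sum(vapply(c(net_params(x$encoder), net_params(x$decoder),
                     net_params(x$critic)), length, integer(1)))
  tibble::tibble(input_size = x$spec$input_size,
                 bottleneck_side = info$side,
                 bottleneck_channels = info$channels,
                 n_flatten_features = info$n_features,
                 latent_dim = x$spec$latent_dim,
                 n_parameters = np, trained = x$trained, step = x$step)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot training loss curves
#'
#' @param object A `gancmlae_history`.
#' @param ... Unused.
#' @return A ggplot object (one facet-free line per loss component).
#' @export
autoplot.gancmlae_history <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generator step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` (from [roc_auc()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume or residual map
#'
#' @param x A 3D array or a `residual_map`.
#' @param k Axial slice index (default: middle slice).
#' @param channel For residual maps, `"signed"` or `"magnitude"`.
#' @return A ggplot object.
#' @export
plot_slice <- function(x, k = NULL, channel = c("signed", "magnitude")) {
  channel <- match.arg(channel)
  v <- if (inherits(x, "residual_map")) x[[channel]] else x
  d <- dim(v)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  s <- v[, , k]
  df <- expand.grid(x = seq_len(nrow(s)), y = seq_len(ncol(s)))
  df$value <- as.vector(s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "black", high = "yellow") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("axial slice", k)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
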