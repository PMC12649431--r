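# Broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.q_agent <- function(x, ...) x$episodes

#' @export
glance.q_agent <- function(x, ...) {
  er <- x$episodes$total_reward
  k <- min(10L, length(er))
  tibble::tibble(
    episodes = nrow(x$episodes),
    states_visited = length(ls(x$q$table)),
    mean_reward = mean(er),
    mean_reward_first10 = mean(utils::head(er, k)),
    mean_reward_last10 = mean(utils::tail(er, k))
  )
}

#' Reward-per-episode training curve
#'
#' @param object a `q_agent`.
#' @param ... unused.
#' @return A ggplot of total reward against episode.
#' @export
autoplot.q_agent <- function(object, ...) {
  ggplot2::ggplot(object$episodes,
                  ggplot2::aes(x = .data$episode, y = .data$total_reward)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.4) +
    ggplot2::labs(x = "Episode", y = "Total reward",
                  title = "Q-learning reward per episode") +
    ggplot2::theme_minimal()
}

#' @export
tidy.gastroq_cnn <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble() else x$history
}

#' @export
tidy.gastroq_unet <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble() else x$history
}

#' @export
glance.gastroq_unet <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) return(tibble::tibble(epochs = 0L))
  out <- tibble::tibble(epochs = nrow(h), final_loss = h$loss[nrow(h)])
  if ("val_dice" %in% names(h)) {
    out$final_val_loss <- h$val_loss[nrow(h)]
    out$final_val_dice <- h$val_dice[nrow(h)]
    out$best_val_dice <- max(h$val_dice)
  }
  out
}

#' Segmentation training curves
#'
#' @param object a trained `gastroq_unet`.
#' @param ... unused.
#' @return A ggplot of training (and validation) loss per epoch.
#' @export
autoplot.gastroq_unet <- function(object, ...) {
  h <- object$history
  if (is.null(h) || !nrow(h)) stop("model has no training history")
  long <- tibble::tibble(epoch = rep(h$epoch, 2),
                         curve = rep(c("train", "validation"), each = nrow(h)),
                         loss = c(h$loss,
                                  if ("val_loss" %in% names(h)) h$val_loss
                                  else rep(NA_real_, nrow(h))))
  ggplot2::ggplot(long[!is.na(long$loss), ],
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy",
                  title = "Segmenter training history", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return A ggplot heat map of the confusion matrix (rows = truth).
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "grey85", high = "steelblue4") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.2f%%)",
                                  object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
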