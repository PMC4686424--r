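#' Stop / no-go probability curve
#'
#' Reactive designs: probability of successfully stopping at each SSD.
#' Proactive designs: probability of a no-go decision at each
#' go-probability cue.
#'
#' @param summary A `behavior_summary` (or a trial table plus `design`).
#' @param design Required when `summary` is a raw trial table.
#' @return A ggplot object.
#' @export
plot_stop_curve <- function(summary, design = NULL) {
  if (!inherits(summary, "behavior_summary")) {
    if (is.null(design)) rlang::abort("supply `design` with a raw table")
    summary <- summarize_trials(summary, design)
  }
  s <- summary$stats
  if (summary$task == "reactive") {
    df <- purrr::map_dfr(seq_len(nrow(s)), function(i) {
      tibble::tibble(condition = s$condition[i],
                     x = as.numeric(names(s$p_stop[[i]])),
                     p = s$p_stop[[i]])
    })
    xlab <- "stop-signal delay (s)"
    ylab <- "P(stop)"
  } else {
    df <- purrr::map_dfr(seq_len(nrow(s)), function(i) {
      tibble::tibble(condition = s$condition[i],
                     x = as.numeric(names(s$p_resp[[i]])),
                     p = 1 - s$p_resp[[i]])
    })
    xlab <- "go-trial probability cue"
    ylab <- "P(no-go)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$p,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted fit diagnostics
#'
#' Two-panel diagnostic: the stop (or no-go) probability curve and the RT
#' quantiles, observed against model-predicted.
#'
#' @param object A `race_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.race_fit <- function(object, ...) {
  obs <- object$obs$stats
  pred <- object$pred$stats
  if (object$task == "reactive") {
    curve <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
      dplyr::bind_rows(
        tibble::tibble(condition = obs$condition[i], source = "observed",
                       x = as.numeric(names(obs$p_stop[[i]])),
                       p = obs$p_stop[[i]]),
        tibble::tibble(condition = pred$condition[i],
                       source = "predicted",
                       x = as.numeric(names(pred$p_stop[[i]])),
                       p = pred$p_stop[[i]]))
    })
    xlab <- "stop-signal delay (s)"
    ylab <- "P(stop)"
  } else {
    curve <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
      dplyr::bind_rows(
        tibble::tibble(condition = obs$condition[i], source = "observed",
                       x = as.numeric(names(obs$p_resp[[i]])),
                       p = obs$p_resp[[i]]),
        tibble::tibble(condition = pred$condition[i],
                       source = "predicted",
                       x = as.numeric(names(pred$p_resp[[i]])),
                       p = pred$p_resp[[i]]))
    })
    xlab <- "go-trial probability cue"
    ylab <- "P(response)"
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$p,
                                      colour = .data$source,
                                      linetype = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = ylab,
                  title = paste(object$model, "fit")) +
    ggplot2::theme_minimal()
}

#' Predicted BOLD magnitudes by cue and outcome
#'
#' @param pred Output of [predict_bold()].
#' @return A ggplot object.
#' @export
plot_bold <- function(pred) {
  df <- pred[pred$bin == "cue", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cue, y = .data$mean_auc,
                                   colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "go-trial probability cue",
                  y = "mean cumulative-sum AUC (evidence s)") +
    ggplot2::theme_minimal()
}
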