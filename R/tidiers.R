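#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers and plots for fitted and report objects
#'
#' `tidy()` returns the object's long-form table (per-class metrics, loss
#' trace, convergence trace, tuning report); `glance()` a one-row summary;
#' `autoplot()` the standard diagnostic plot.
#'
#' @param x a `metrics_report`, `sdl_fit`, `lstm_fit`, `ibes_result`, or
#'   `tune_result`.
#' @param ... unused.
#' @name histosdl-tidiers
NULL

#' @rdname histosdl-tidiers
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname histosdl-tidiers
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...)
  dplyr::bind_cols(x$macro, tibble::tibble(n = x$n))

#' @rdname histosdl-tidiers
#' @method tidy sdl_fit
#' @export
tidy.sdl_fit <- function(x, ...)
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "loss",
                      values_to = "value")

#' @rdname histosdl-tidiers
#' @method glance sdl_fit
#' @export
glance.sdl_fit <- function(x, ...) {
  tibble::tibble(k = x$config$k, num_classes = x$config$num_classes,
                 lambda = x$config$lambda, epochs = x$config$epochs,
                 final_ce = utils::tail(x$trace$ce_loss, 1),
                 final_synergic = utils::tail(x$trace$synergic_loss, 1))
}

#' @rdname histosdl-tidiers
#' @method tidy lstm_fit
#' @export
tidy.lstm_fit <- function(x, ...) x$trace

#' @rdname histosdl-tidiers
#' @method glance lstm_fit
#' @export
glance.lstm_fit <- function(x, ...) {
  tibble::tibble(hidden_size = x$params$hidden_size,
                 num_classes = x$params$num_classes, loss = x$loss,
                 epochs = nrow(x$trace),
                 final_loss = utils::tail(x$trace$loss, 1))
}

#' @rdname histosdl-tidiers
#' @method tidy ibes_result
#' @export
tidy.ibes_result <- function(x, ...) x$trace

#' @rdname histosdl-tidiers
#' @method glance ibes_result
#' @export
glance.ibes_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness, n_evals = x$n_evals,
                 n_pop = x$params$n_pop, max_iter = x$params$max_iter,
                 obl = x$obl)
}

#' @rdname histosdl-tidiers
#' @method tidy tune_result
#' @export
tidy.tune_result <- function(x, ...) x$report

#' @rdname histosdl-tidiers
#' @method glance tune_result
#' @export
glance.tune_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_fitness = x$best_fitness,
                   n_evals = nrow(x$report)),
    tibble::as_tibble(lapply(x$best_params, as.numeric)))
}

#' @rdname histosdl-tidiers
#' @param object object to plot.
#' @method autoplot ibes_result
#' @export
autoplot.ibes_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$f_best)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = "Bald eagle search convergence") +
    ggplot2::theme_minimal()
}

#' @rdname histosdl-tidiers
#' @method autoplot sdl_fit
#' @export
autoplot.sdl_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Synergic ensemble training") +
    ggplot2::theme_minimal()
}

#' @rdname histosdl-tidiers
#' @method autoplot lstm_fit
#' @export
autoplot.lstm_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", title = "LSTM head training") +
    ggplot2::theme_minimal()
}

#' @rdname histosdl-tidiers
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "estimate", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' @rdname histosdl-tidiers
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class, -c("class", "support"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = "percent", title = "Per-class metrics") +
    ggplot2::theme_minimal()
}
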