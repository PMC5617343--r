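# Tidiers and plot methods for the fitted objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted models
#'
#' For the neural models, `tidy()` summarizes each parameter group (size
#' and L2 norm) and `glance()` gives a one-row fit summary. For the lasso
#' baseline, `tidy()` returns the (standardized-scale) coefficients per
#' term and `glance()` the selected lambda and sparsity.
#'
#' @param x A fitted `debate_model`, `stance_model` or `lr_baseline`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

param_group_summary <- function(par) {
  rows <- lapply(names(par), function(nm) {
    el <- par[[nm]]
    if (nm == "widths") return(NULL)
    if (is.list(el)) el <- unlist(el)
    tibble(group = nm, n_parameters = length(el), l2_norm = sqrt(sum(el^2)))
  })
  bind_rows(rows)
}

#' @rdname tidiers
#' @method tidy debate_model
#' @export
tidy.debate_model <- function(x, ...) param_group_summary(x$par)

#' @rdname tidiers
#' @method tidy stance_model
#' @export
tidy.stance_model <- function(x, ...) param_group_summary(x$par)

#' @rdname tidiers
#' @method glance debate_model
#' @export
glance.debate_model <- function(x, ...) {
  tibble(
    task = x$task, n_classes = length(x$classes),
    vocab_size = length(x$vocab),
    n_parameters = sum(param_group_summary(x$par)$n_parameters),
    epochs = x$config$epochs,
    initial_nll = x$loss_trace[1],
    final_nll = utils::tail(x$loss_trace, 1)
  )
}

#' @rdname tidiers
#' @method glance stance_model
#' @export
glance.stance_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), vocab_size = length(x$vocab),
    n_parameters = sum(param_group_summary(x$par)$n_parameters),
    epochs = x$config$epochs,
    initial_nll = x$loss_trace[1],
    final_nll = utils::tail(x$loss_trace, 1)
  )
}

#' @rdname tidiers
#' @method tidy lr_baseline
#' @export
tidy.lr_baseline <- function(x, ...) {
  cl <- coef_list(x)
  if (length(cl) == 1) {
    out <- cl[[1]]
    out$class <- x$classes[2]
  } else {
    out <- bind_rows(lapply(names(cl), function(nm) {
      cc <- cl[[nm]]
      cc$class <- nm
      cc
    }))
  }
  out[, c("class", "term", "estimate")]
}

#' @rdname tidiers
#' @method glance lr_baseline
#' @export
glance.lr_baseline <- function(x, ...) {
  cf <- tidy.lr_baseline(x)
  tibble(
    family = x$family, lambda = x$lambda,
    n_features = length(x$feature_names),
    n_nonzero = sum(cf$estimate != 0 & cf$term != "(Intercept)")
  )
}

#' Plot the training loss trace of a neural model
#'
#' @param object A `debate_model` or `stance_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot debate_model
#' @export
autoplot.debate_model <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trace), nll = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$nll)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = "Mean NLL per labeled post",
      title = "Training loss")
}

#' @rdname autoplot.debate_model
#' @method autoplot stance_model
#' @export
autoplot.stance_model <- autoplot.debate_model

#' Plot cross-validation metrics
#'
#' One point per fold and class (faceted by model when the tibble carries a
#' `model` column, as in [run_debate_benchmark()] output).
#'
#' @param object A `ts_cv_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ts_cv_metrics
#' @export
autoplot.ts_cv_metrics <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$f,
    colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fold", y = "F score (%)", colour = "Class",
      title = "Cross-validated F by fold")
  if ("model" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~model)
  }
  p
}
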