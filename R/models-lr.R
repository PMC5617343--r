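# Lasso logistic-regression baseline over the engineered features.
# Fitting is delegated to glmnet (L1-penalized maximum likelihood);
# features are z-scored with training-set statistics before the penalty so
# the regularization treats all features on a common scale.

drop_id_cols <- function(features) {
  features[setdiff(names(features), c("post_id", "thread_id"))]
}

#' Train the lasso logistic-regression baseline
#'
#' Features are standardized (z-score, training statistics only), then an
#' L1-penalized logistic (or multinomial, for the 4-class debate task)
#' model is fitted. When `lambda` is not supplied it is chosen by inner
#' cross-validation on the training data over glmnet's default grid.
#'
#' @param features A feature tibble from [feature_matrix()] (id columns
#'   `post_id`/`thread_id` are ignored for fitting).
#' @param y Character vector of labels, one per row of `features`.
#' @param lambda Optional fixed regularization strength.
#' @param classes Optional class ordering (first class wins probability
#'   ties at prediction). Defaults to sorted unique labels with
#'   `NON_DEBATE` or `PRO_CAM` first when present.
#' @param nfolds Inner CV folds for the lambda grid.
#' @param seed Seed for the inner CV fold assignment.
#' @return An object of class `lr_baseline`.
#' @export
train_lr_baseline <- function(features, y, lambda = NULL, classes = NULL,
                              nfolds = 5L, seed = 1L) {
  X <- as.matrix(drop_id_cols(features))
  if (nrow(X) != length(y)) abort("features and labels differ in length")
  if (length(unique(y)) < 2) abort("labels are constant; nothing to fit")
  if (is.null(classes)) {
    classes <- sort(unique(y))
    for (first in c("NON_DEBATE", "PRO_CAM")) {
      if (first %in% classes) classes <- c(first, setdiff(classes, first))
    }
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  yf <- factor(y, levels = classes)
  family <- if (length(classes) == 2) "binomial" else "multinomial"
  fit_lambda <- lambda
  if (is.null(fit_lambda)) {
    foldid <- withr::with_seed(seed, sample(rep(seq_len(nfolds), length.out = nrow(Xs))))
    cv <- glmnet::cv.glmnet(Xs, yf, family = family, foldid = foldid,
      standardize = FALSE)
    fit_lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(Xs, yf, family = family, lambda = fit_lambda,
    standardize = FALSE, thresh = 1e-10)
  structure(list(
    fit = fit, lambda = fit_lambda, center = center, scale = scale_,
    feature_names = colnames(X), classes = classes, family = family
  ), class = "lr_baseline")
}

#' @rdname train_lr_baseline
#' @param model An `lr_baseline` object.
#' @return For `predict_lr()`: a tibble with `post_id` (when present in
#'   `features`), `label` and one probability column per class.
#' @export
predict_lr <- function(model, features) {
  X <- as.matrix(drop_id_cols(features)[, model$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pr <- predict(model$fit, newx = Xs, s = model$lambda, type = "response")
  if (model$family == "binomial") {
    p2 <- as.vector(pr)
    probs <- cbind(1 - p2, p2)
  } else {
    probs <- pr[, , 1]
    probs <- probs[, model$classes, drop = FALSE]
  }
  colnames(probs) <- paste0("p_", model$classes)
  out <- bind_cols(
    tibble(label = model$classes[max.col(probs, ties.method = "first")]),
    as_tibble(probs)
  )
  if ("post_id" %in% names(features)) {
    out <- bind_cols(tibble(post_id = features$post_id), out)
  }
  out
}

#' @export
print.lr_baseline <- function(x, ...) {
  nz <- sum(unlist(lapply(coef_list(x), function(cc) cc$estimate != 0)))
  cat("Lasso logistic-regression baseline (", x$family, ")\n", sep = "")
  cat("  lambda =", signif(x$lambda, 4), ", non-zero coefficients:", nz, "\n")
  invisible(x)
}

# coefficients on the standardized scale, one tibble per response class
coef_list <- function(model) {
  cf <- glmnet::coef.glmnet(model$fit, s = model$lambda)
  if (!is.list(cf)) cf <- list(cf)
  lapply(cf, function(m) {
    tibble(term = rownames(m), estimate = as.vector(m))
  })
}
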