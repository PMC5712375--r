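#' Train the epoch classifier
#'
#' Fits a radial-basis-kernel support vector machine on standardised band
#' features. Standardisation statistics (per-feature mean and standard
#' deviation) are estimated on the training set only and stored in the
#' model, so test epochs are scaled without leakage; zero-variance
#' features are dropped and recorded. Class weights are balanced by
#' inverse class frequency because pseudo-online non-active spans contain
#' many more epochs than the 4-s active windows.
#'
#' @param features Tibble from [epoch_features()]: a `state` column (0/1)
#'   plus numeric feature columns.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / n_features` on the
#'   standardised scale.
#' @param class_weight "balanced" (default) or NULL for unweighted.
#' @return A `gait_svm` model object.
#' @export
train_classifier <- function(features, cost = 1, gamma = NULL,
                             class_weight = "balanced") {
  fx <- feature_matrix(features)
  y <- features$state
  if (length(unique(y)) < 2) {
    stop_gaitbci("training data must contain both classes",
                 "gaitbci_training_error")
  }
  mu <- colMeans(fx)
  sd_ <- apply(fx, 2, stats::sd)
  keep <- sd_ > 0
  dropped <- colnames(fx)[!keep]
  xs <- scale(fx[, keep, drop = FALSE], center = mu[keep], scale = sd_[keep])
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  cw <- NULL
  if (identical(class_weight, "balanced")) {
    tab <- table(factor(y, levels = c(0, 1)))
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  }
  fit <- e1071::svm(x = xs, y = factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    class.weights = cw)
  structure(list(fit = fit, center = mu[keep], scale = sd_[keep],
                 features = colnames(fx)[keep], dropped = dropped,
                 cost = cost, gamma = gamma),
            class = "gait_svm")
}

feature_matrix <- function(features) {
  meta <- intersect(c("epoch_id", "window_id", "state", "t_begin"),
                    names(features))
  fx <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  assert_finite(fx, "features")
  fx
}

#' Classify epochs
#'
#' Deterministically labels each epoch 0 (non-active) or 1 (intention)
#' with a trained model; features are standardised with the training
#' statistics stored in the model.
#'
#' @param model A `gait_svm` from [train_classifier()].
#' @param features Tibble with the model's feature columns (extra
#'   metadata columns are ignored).
#' @return Integer vector of 0/1 labels, one per row.
#' @export
classify_epochs <- function(model, features) {
  stopifnot(inherits(model, "gait_svm"))
  fx <- feature_matrix(features)
  missing <- setdiff(model$features, colnames(fx))
  if (length(missing) > 0) {
    stop_gaitbci("features missing columns used at training time",
                 "gaitbci_validation_error")
  }
  xs <- scale(fx[, model$features, drop = FALSE],
              center = model$center, scale = model$scale)
  as.integer(as.character(predict(model$fit, xs)))
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf(
    "<gait_svm: RBF SVM, %d features (%d dropped), C=%g, gamma=%g, %d SVs>\n",
    length(x$features), length(x$dropped), x$cost, x$gamma,
    x$fit$tot.nSV))
  invisible(x)
}
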