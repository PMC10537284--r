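# Training objective and the regression-style evaluation metrics.

#' Weighted mean absolute error
#'
#' \deqn{\mathrm{WMAE} = \frac{1}{\sum_i w_i} \sum_i w_i\,|y^{pred}_i - y^{true}_i|}
#' Weights express the relative importance of each nutrient; with uniform
#' weights this reduces to the plain MAE.
#'
#' @param w Positive weight vector.
#' @param y_pred,y_true Numeric vectors of the same length as `w`.
#' @return A nonnegative scalar.
#' @examples
#' wmae(c(2, 1), c(1, 0), c(0, 2))  # 4/3
#' @export
wmae <- function(w, y_pred, y_true) {
  if (length(w) != length(y_pred) || length(w) != length(y_true))
    dimension_error("w, y_pred and y_true must share one length")
  if (any(w <= 0)) validation_error("all weights must be positive")
  sum(w * abs(y_pred - y_true)) / sum(w)
}

# Subgradient of wmae in y_pred (sign convention: 0 at the kink).
wmae_grad <- function(w, y_pred, y_true) {
  w * sign(y_pred - y_true) / sum(w)
}

#' Gaussian error linear unit
#'
#' \eqn{\mathrm{GELU}(x) = x\,\Phi(x)} with \eqn{\Phi} the exact standard
#' normal cumulative distribution function (erf-based, not the tanh
#' approximation).
#'
#' @param x Numeric vector, matrix or array.
#' @return Same shape as `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Regression top-1 accuracy for one prediction
#'
#' Scores the content value of the most probable predicted class against its
#' reference: \eqn{\max(0,\ 1 - |X_p - X_r| / X_r)}. Predictions farther than
#' one reference unit away (including a nutrient predicted absent) score 0.
#'
#' @param Xp Predicted content of the top class.
#' @param Xr Reference content of that class; must be positive.
#' @return A scalar in `[0, 1]`.
#' @examples
#' top1_acc(6.090, 7.280)
#' @export
top1_acc <- function(Xp, Xr) {
  if (length(Xp) != 1L || length(Xr) != 1L)
    dimension_error("top1_acc() scores a single class; see top5_acc() for five")
  if (Xr <= 0) metric_error("reference content Xr must be positive")
  max(0, 1 - abs(Xp - Xr) / Xr)
}

#' Regression top-5 accuracy
#'
#' The mean of the per-class clamped scores
#' \eqn{\max(0,\ 1 - |X^p_i - X^r_i| / X^r_i)} over the five classes with the
#' largest predicted probability.
#'
#' @param Xp,Xr Length-5 vectors of predicted and reference contents
#'   (reference entries must be positive).
#' @return A scalar in `[0, 1]`.
#' @export
top5_acc <- function(Xp, Xr) {
  if (length(Xp) != 5L || length(Xr) != 5L)
    metric_error("top5_acc() requires exactly five paired classes")
  if (any(Xr <= 0)) metric_error("all reference contents must be positive")
  mean(pmax(0, 1 - abs(Xp - Xr) / Xr))
}

#' Background-stability variance of repeated predictions
#'
#' For one foreground photographed (or rendered) over several backgrounds,
#' computes the population variance of the predicted content per nutrient
#' class across the background variants. Smaller variance means better
#' resistance to environmental interference.
#'
#' @param preds A list of numeric nutrient vectors (equal lengths), or a
#'   matrix with one prediction per row; at least two.
#' @return A named numeric vector of per-class population variances.
#' @export
stability_variance <- function(preds) {
  if (is.list(preds)) {
    if (length(preds) < 2L) metric_error("stability requires at least two predictions")
    preds <- do.call(rbind, lapply(preds, as.numeric))
  }
  if (!is.matrix(preds) || nrow(preds) < 2L)
    metric_error("stability requires at least two predictions")
  n <- nrow(preds)
  v <- apply(preds, 2, function(x) mean((x - mean(x))^2))
  stats::setNames(v, colnames(preds))
}

#' Score a set of predictions against reference nutrient vectors
#'
#' Computes the per-sample regression top-1 / top-5 accuracies and WMAE, and
#' their means. The top-1 score compares the content of the class with the
#' largest predicted probability; the top-5 score averages over the five most
#' probable classes.
#'
#' @param preds Matrix of predicted nutrient vectors (rows = samples).
#' @param truths Matrix of reference vectors, same shape.
#' @param w Loss weight vector; default uniform.
#' @return A list with `summary` (tibble: mean top1, top5, wmae),
#'   `per_sample` (tibble) and `per_nutrient` (tibble of mean absolute error
#'   by class).
#' @export
metrics_report <- function(preds, truths, w = NULL) {
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  if (is.null(dim(truths))) truths <- matrix(truths, nrow = 1)
  if (!all(dim(preds) == dim(truths)))
    dimension_error("preds and truths must have identical shapes")
  if (nrow(preds) == 0L) metric_error("empty evaluation set")
  n_class <- ncol(preds)
  if (is.null(w)) w <- rep(1, n_class)
  per <- lapply(seq_len(nrow(preds)), function(i) {
    p <- preds[i, ]; r <- truths[i, ]
    top_idx <- order(p, decreasing = TRUE)
    t1 <- top1_acc(p[top_idx[1L]], r[top_idx[1L]])
    t5 <- if (n_class >= 5L) top5_acc(p[top_idx[1:5]], r[top_idx[1:5]]) else NA_real_
    c(top1 = t1, top5 = t5, wmae = wmae(w, p, r))
  })
  per <- do.call(rbind, per)
  classes <- colnames(preds) %||% paste0("class_", seq_len(n_class))
  list(
    summary = tibble::tibble(
      top1 = mean(per[, "top1"]),
      top5 = mean(per[, "top5"]),
      wmae = mean(per[, "wmae"]),
      n = nrow(preds)
    ),
    per_sample = tibble::as_tibble(per),
    per_nutrient = tibble::tibble(
      nutrient = classes,
      mae = colMeans(abs(preds - truths))
    )
  )
}
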