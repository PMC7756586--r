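#' Adam optimizer configuration
#'
#' The moment parameters default to beta1 = 0.9, beta2 = 0.999 and
#' epsilon = 1e-8, the values used to train every model in the cascade.
#'
#' @param lr learning rate.
#' @param epochs number of full-batch update steps.
#' @param beta1,beta2,epsilon Adam moment/stabilisation parameters.
#' @param seed RNG seed for any stochastic part of training.
#' @return An object of class `adam_config`.
#' @export
adam_config <- function(lr = 0.1, epochs = 200, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, seed = 1L) {
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, epsilon > 0,
            lr > 0, epochs >= 1)
  structure(list(algorithm = "adam", lr = lr, epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "adam_config")
}

# generic full-batch Adam loop; grad_fn(par) returns list(loss, grad)
adam_optimize <- function(par, grad_fn, cfg) {
  m <- v <- par * 0
  trace <- numeric(cfg$epochs)
  for (t in seq_len(cfg$epochs)) {
    g <- grad_fn(par)
    trace[t] <- g$loss
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g$grad
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g$grad^2
    mhat <- m / (1 - cfg$beta1^t)
    vhat <- v / (1 - cfg$beta2^t)
    par <- par - cfg$lr * mhat / (sqrt(vhat) + cfg$epsilon)
  }
  list(par = par, trace = trace)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)` with
#' smoothing `s = 1` in numerator and denominator, the segmentation training
#' loss of the cascade. On binary inputs it equals `1 - DSC` up to the
#' smoothing term, and it is always in `[0, 1]`.
#'
#' @param pred numeric array of probabilities in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param smooth smoothing constant (default 1).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("soft_dice_loss: pred and target shapes differ")
  if (min(pred) < 0 || max(pred) > 1)
    stop("soft_dice_loss: pred must lie in [0, 1]")
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Weighted binary cross-entropy
#'
#' `-mean(w * y * log(p) + (1 - y) * log(1 - p))`, the presence-classifier
#' loss. The positive-class weight compensates for slice imbalance; under the
#' automatic rule it is the ratio of absent to present slices. Probabilities
#' are clamped to `[eps, 1 - eps]` so the loss is never NaN.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param w positive-class weight (> 0); `w = 1` recovers plain cross-entropy.
#' @param eps clamping constant (default 1e-7).
#' @return Scalar loss.
#' @export
weighted_ce_loss <- function(probs, labels, w = 1, eps = 1e-7) {
  if (length(probs) != length(labels))
    stop("weighted_ce_loss: probs and labels lengths differ")
  if (w <= 0) stop("weighted_ce_loss: weight must be positive")
  if (!all(labels %in% c(0, 1))) stop("weighted_ce_loss: labels must be binary")
  p <- clamp(probs, eps, 1 - eps)
  -mean(w * labels * log(p) + (1 - labels) * log(1 - p))
}

#' Positive-class weight from label counts
#'
#' @param labels binary vector.
#' @return `number of absences / number of presences`.
#' @export
auto_class_weight <- function(labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("auto_class_weight: no positive labels")
  n_neg <- sum(labels == 0)
  if (n_neg == 0) return(1)
  n_neg / n_pos
}

# Fit a (possibly multi-output) logistic model by Adam.
# X: n x p design (including intercept column); Y: n-vector or n x K binary
# matrix; loss "wce" (weighted cross-entropy, weight w) or "dice" (soft Dice,
# averaged over output channels). Returns p x K weight matrix and loss trace.
fit_logistic <- function(X, Y, loss = c("wce", "dice"), w = 1,
                         cfg = adam_config()) {
  loss <- match.arg(loss)
  Y <- as.matrix(Y)
  K <- ncol(Y)
  n <- nrow(X)
  W0 <- matrix(0, ncol(X), K)
  grad_fn <- function(W) {
    Z <- X %*% W
    P <- sigmoid(Z)
    if (loss == "wce") {
      l <- mean(vapply(seq_len(K), function(k)
        weighted_ce_loss(P[, k], Y[, k], w), numeric(1)))
      dZ <- (P * (1 + (w - 1) * Y) - w * Y) / (n * K)
    } else {
      eps <- 1
      Sp <- colSums(P); Sy <- colSums(Y); Spy <- colSums(P * Y)
      num <- 2 * Spy + eps; den <- Sp + Sy + eps
      l <- mean(1 - num / den)
      # d/dP of the per-channel loss, then chain through the sigmoid
      dP <- -(sweep(2 * Y, 2, den, `*`) - matrix(num, n, K, byrow = TRUE)) /
        matrix(den^2, n, K, byrow = TRUE)
      dZ <- dP * P * (1 - P) / K
    }
    list(loss = l, grad = crossprod(X, dZ))
  }
  fit <- adam_optimize(W0, grad_fn, cfg)
  list(weights = fit$par, trace = fit$trace)
}
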