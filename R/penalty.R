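#' Build a misclassification penalty matrix
#'
#' Constructs the base cost matrix `W` (unit diagonal by convention;
#' `W[i, j]` is the cost of predicting class `i` when the true class is
#' `j`) and its corrected form `W'` with zero diagonal and off-diagonal
#' entries incremented by one. The default off-diagonal rule is the
#' absolute grade distance `|i - j|`, so costs grow with the ordinal
#' deviation between predicted and true class; for binary problems this
#' reduces to a single off-diagonal cost. Asymmetric costs (for instance a
#' heavier price for calling an injured exam healthy) can be injected with
#' `overrides`.
#'
#' @param n number of classes (>= 2).
#' @param base_rule `"absolute-distance"` (default) or `"custom"`; with
#'   `"custom"` the off-diagonal entries of `base` are taken verbatim.
#' @param base optional `n x n` matrix of non-negative costs used when
#'   `base_rule = "custom"`; its diagonal is forced to 1.
#' @param overrides optional data frame (or 3-column matrix) with columns
#'   `predicted`, `true`, `cost` (1-based class indices) overriding single
#'   off-diagonal cells of the base matrix.
#' @return object of class `penalty_matrix` with fields `n`, `base`,
#'   `corrected`.
#' @export
#' @examples
#' pm <- penalty_matrix(2)
#' pm$corrected          # matrix(c(0, 2, 2, 0), 2)
penalty_matrix <- function(n = 2, base_rule = c("absolute-distance", "custom"),
                           base = NULL, overrides = NULL) {
  base_rule <- match.arg(base_rule)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  n <- as.integer(n)
  if (base_rule == "absolute-distance") {
    base <- abs(outer(seq_len(n), seq_len(n), "-"))
  } else {
    if (is.null(base) || !is.matrix(base) || !all(dim(base) == n))
      stop("`base` must be an n x n matrix when base_rule = 'custom'",
           call. = FALSE)
    base <- base * 1.0
  }
  diag(base) <- 1
  if (!is.null(overrides)) {
    ov <- as.data.frame(overrides)
    names(ov) <- c("predicted", "true", "cost")
    for (r in seq_len(nrow(ov))) {
      i <- ov$predicted[r]; j <- ov$true[r]
      if (i < 1 || i > n || j < 1 || j > n || i == j)
        stop("overrides must address off-diagonal cells within 1..n",
             call. = FALSE)
      base[i, j] <- ov$cost[r]
    }
  }
  stop_if_not_finite(base, "base")
  if (any(base < 0)) stop("penalty costs must be non-negative", call. = FALSE)
  corrected <- base + 1
  diag(corrected) <- 0
  structure(list(n = n, base = base, corrected = corrected),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("penalty matrix, %d classes\nbase W:\n", x$n))
  print(x$base)
  cat("corrected W':\n")
  print(x$corrected)
  invisible(x)
}

check_probs <- function(p, n) {
  stop_if_not_finite(p, "probs")
  if (length(p) != n)
    stop("probability vector length must equal the class count", call. = FALSE)
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("`probs` must lie on the probability simplex", call. = FALSE)
  p <- pmax(p, 1e-12)
  p / sum(p)
}

check_true_class <- function(j, n) {
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > n || j != round(j))
    stop("`true_class` must be a class index in 1..n", call. = FALSE)
  as.integer(j)
}

#' Penalty-weight loss, base form
#'
#' The base-form expected cost `sum_i W[i, j] * q_i` with the true class
#' `j`, where `q_i = p_i` for `i != j` and `q_j = 1 - p_j`, so the
#' objective decreases as probability mass moves onto the true class.
#' Algebraically identical to [penalty_loss_corrected()] whenever the base
#' matrix has a unit diagonal.
#'
#' @param probs probability vector of length `n` (softmax output).
#' @param true_class 1-based true class index.
#' @param pm a [penalty_matrix()].
#' @return non-negative scalar loss.
#' @export
penalty_loss_q <- function(probs, true_class, pm) {
  j <- check_true_class(true_class, pm$n)
  p <- check_probs(probs, pm$n)
  q <- p
  q[j] <- 1 - p[j]
  sum(pm$base[, j] * q)
}

#' Penalty-weight loss, corrected form
#'
#' The simplified drop-in loss `sum_i W'[i, j] * p_i`: the expected
#' misclassification cost of the softmax output under the corrected
#' penalty matrix. Zero exactly when all probability mass sits on the true
#' class, and linear in every wrong-class probability with slope
#' `W'[i, j]`.
#'
#' @inheritParams penalty_loss_q
#' @return non-negative scalar loss.
#' @export
penalty_loss_corrected <- function(probs, true_class, pm) {
  j <- check_true_class(true_class, pm$n)
  p <- check_probs(probs, pm$n)
  sum(pm$corrected[, j] * p)
}

#' Batch penalty-weight loss
#'
#' @param probs matrix of probabilities, one row per example (`m x n`).
#' @param true_classes integer vector of 1-based true class indices.
#' @param pm a [penalty_matrix()].
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @export
penalty_batch_loss <- function(probs, true_classes, pm,
                               reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  probs <- as.matrix(probs)
  if (nrow(probs) == 0L) stop("empty batch", call. = FALSE)
  if (length(true_classes) != nrow(probs))
    stop("one true class per row of `probs` required", call. = FALSE)
  losses <- vapply(seq_len(nrow(probs)), function(i)
    penalty_loss_corrected(probs[i, ], true_classes[i], pm), numeric(1))
  if (reduction == "mean") mean(losses) else sum(losses)
}

#' Penalty-weight loss and its gradient with respect to pre-softmax scores
#'
#' For `p = softmax(z)` and loss `L = sum_i c_i p_i` with `c = W'[, j]`,
#' the gradient is `dL/dz_k = p_k (c_k - L)`.
#'
#' @param logits numeric vector of pre-softmax scores (length `n`).
#' @param true_class 1-based true class index.
#' @param pm a [penalty_matrix()].
#' @return list with `loss`, `grad` (gradient w.r.t. `logits`), `probs`.
#' @export
penalty_loss_grad <- function(logits, true_class, pm) {
  j <- check_true_class(true_class, pm$n)
  stop_if_not_finite(logits, "logits")
  p <- softmax_vec(logits)
  cc <- pm$corrected[, j]
  L <- sum(cc * p)
  list(loss = L, grad = p * (cc - L), probs = p)
}
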