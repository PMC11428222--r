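#' Assemble a slice-stack classifier
#'
#' Builds the full model: a convolutional backbone applied to every slice,
#' optional Student-t slice attention on the resulting feature-map stack,
#' per-slice global average pooling, coordinatewise max fusion across
#' slices, and a fully connected softmax head. The attention toggle and
#' the loss choice are the only differences between the four ablation
#' variants; neither changes the number of learned parameters.
#'
#' @param backbone registry name, see [backbone_registry()].
#' @param attention logical; apply the slice-attention module.
#' @param loss `"cross_entropy"` or `"penalty_weight"`.
#' @param penalty a [penalty_matrix()] used when `loss = "penalty_weight"`
#'   (default: binary absolute-distance matrix).
#' @param image_size square input resolution expected by the model; stacks
#'   of a different resolution are resampled.
#' @param in_channels 1 keeps grayscale input; 3 replicates the gray
#'   channel for RGB-shaped backbones.
#' @param n_classes number of output classes (binary by default).
#' @param nu_fixed,nu_min,nu_max Student-t fit controls, see
#'   [fit_t_params()].
#' @param weight_rescale how the simplex attention weights are scaled when
#'   applied to the features: `"mean_one"` (default) multiplies by `S` so
#'   the average slice keeps unit gain and exams with different slice
#'   counts stay on a common score scale; `"sum_one"` applies the simplex
#'   weights verbatim.
#' @param head_norm classification head: `"cosine"` (default) scores each
#'   class by the cosine between the L2-normalized exam vector and an
#'   L2-normalized class weight vector times a fixed scale, bounding the
#'   logits (keeps gradients of the linear penalty loss alive and removes
#'   scale differences between exams); `"l2"` normalizes only the exam
#'   vector before an affine head; `"none"` is a plain affine head.
#' @param logit_scale fixed multiplier on the cosine logits (only used
#'   with `head_norm = "cosine"`).
#' @param seed RNG seed for weight initialization.
#' @return object of class `slice_model`.
#' @export
slice_model <- function(backbone = "tiny", attention = TRUE,
                        loss = c("cross_entropy", "penalty_weight"),
                        penalty = penalty_matrix(2),
                        image_size = 64L, in_channels = 1L, n_classes = 2L,
                        nu_fixed = NULL, nu_min = 2.05, nu_max = 200,
                        weight_rescale = c("mean_one", "sum_one"),
                        head_norm = c("cosine", "l2", "none"),
                        logit_scale = 4,
                        seed = 1L) {
  loss <- match.arg(loss)
  weight_rescale <- match.arg(weight_rescale)
  head_norm <- match.arg(head_norm)
  reg <- backbone_registry()
  if (!backbone %in% names(reg))
    stop(sprintf("unknown backbone '%s'; registry has: %s", backbone,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  layers <- reg[[backbone]]$layers
  shape <- trace_backbone_shape(layers, image_size, in_channels)
  params <- with_seed(seed, {
    bb <- init_backbone_params(layers, in_channels)
    fc <- list(W = matrix(rnorm(shape$C * n_classes, 0, sqrt(1 / shape$C)),
                          shape$C, n_classes))
    # the cosine head is bias-free (a bias can absorb the class prior and
    # freeze the linear penalty loss at a majority-collapse plateau)
    if (head_norm != "cosine") fc$b <- rep(0, n_classes)
    list(backbone = bb, fc = fc)
  })
  structure(list(backbone = backbone, layers = layers, params = params,
                 feature_shape = shape, attention = isTRUE(attention),
                 loss = loss, penalty = penalty,
                 image_size = as.integer(image_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 nu_fixed = nu_fixed, nu_min = nu_min, nu_max = nu_max,
                 weight_rescale = weight_rescale, head_norm = head_norm,
                 logit_scale = logit_scale,
                 seed = as.integer(seed)),
            class = "slice_model")
}

#' @export
print.slice_model <- function(x, ...) {
  cat(sprintf("slice model: backbone '%s' (%d params), attention %s, loss %s\n",
              x$backbone, count_params(x),
              if (x$attention) "on" else "off", x$loss))
  cat(sprintf("  input %dx%d, features %d x %d x %d\n", x$image_size,
              x$image_size, x$feature_shape$C, x$feature_shape$H,
              x$feature_shape$W))
  invisible(x)
}

#' Number of learned parameters of a model
#' @param model a `slice_model`.
#' @return integer parameter count (backbone plus head).
#' @export
count_params <- function(model) n_params(model$params)

#' Coordinatewise maximum over per-slice vectors
#'
#' Fuses `S` per-slice feature vectors into one exam-level vector by
#' taking the maximum in every coordinate.
#'
#' @param vectors an `S x K` matrix (one row per slice) or a list of
#'   equal-length numeric vectors.
#' @return numeric vector of length `K`.
#' @export
aggregate_max <- function(vectors) {
  if (is.list(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L)
      stop("ragged input: all slice vectors must have equal length",
           call. = FALSE)
    vectors <- do.call(rbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 1L) stop("at least one slice required", call. = FALSE)
  apply(vectors, 2L, max)
}

# nearest-neighbour resampling of an S x H x W stack to a square target
resize_stack <- function(slices, target) {
  d <- dim(slices)
  if (d[2] == target && d[3] == target) return(slices)
  ri <- pmin(pmax(round(seq(1, d[2], length.out = target)), 1), d[2])
  ci <- pmin(pmax(round(seq(1, d[3], length.out = target)), 1), d[3])
  slices[, ri, ci, drop = FALSE]
}

# stack (slice_stack or S x H x W array) -> (H, W, Cin*S) array, the S
# slices stacked along the channel axis for the batched backbone engine
prep_stack <- function(model, stack) {
  slices <- if (inherits(stack, "slice_stack")) stack$slices else stack
  if (!is.array(slices) || length(dim(slices)) != 3L)
    stop("a stack must be an S x H x W array", call. = FALSE)
  if (dim(slices)[1] < 1L) stop("empty stack", call. = FALSE)
  slices <- resize_stack(slices, model$image_size)
  S <- dim(slices)[1]
  n <- model$image_size
  a <- aperm(slices, c(2, 3, 1))            # (H, W, S)
  if (model$in_channels == 1L) {
    dim(a) <- c(n, n, S)
    return(a)
  }
  a4 <- array(0, c(n, n, model$in_channels, S))
  for (ch in seq_len(model$in_channels)) a4[, , ch, ] <- a
  dim(a4) <- c(n, n, model$in_channels * S)
  a4
}

# Full forward pass; keep_cache retains everything backward needs.
# Global average pooling is linear, so weighting the feature maps by the
# attention weights and then pooling equals pooling first and weighting
# the per-slice vectors; the model exploits that and never materializes
# the weighted 4-D stack.
model_forward <- function(model, stack, keep_cache = FALSE) {
  x <- prep_stack(model, stack)
  sh <- model$feature_shape
  S <- dim(x)[3L] / model$in_channels
  bb <- backbone_forward(model$layers, model$params$backbone, x,
                         model$in_channels, keep_cache)
  mm <- matrix(bb$out, sh$H * sh$W, sh$C * S)
  avg <- t(matrix(colMeans(mm), sh$C, S))                    # S x C
  mx <- t(matrix(do.call(pmax, asplit(mm, 1L)), sh$C, S))    # S x C
  att <- NULL
  w <- rep(1, S)
  if (model$attention) {
    p <- structure(list(avg = avg, max = mx), class = "pooled_descriptors")
    sp <- similarity_pair(p)
    iw <- initial_weights(sp)
    tp <- fit_t_params(iw, nu_fixed = model$nu_fixed,
                       nu_min = model$nu_min, nu_max = model$nu_max)
    aw <- slice_weights(S, tp)
    w <- aw$w
    if (model$weight_rescale == "mean_one") w <- w * S
    att <- structure(list(pooled = p, similarity = sp, initial = iw,
                          t_params = tp, weights = aw),
                     class = "attention_state")
  }
  u <- avg * w                               # weighted per-slice vectors
  v <- aggregate_max(u)
  amax <- max.col(t(u), ties.method = "first")  # argmax slice per coordinate
  # Normalized heads keep exam vectors of different slice counts and
  # attention scalings on one scale; the cosine head also bounds the
  # logits so training gradients stay alive under the linear penalty loss
  vnorm <- sqrt(sum(v^2))
  vn <- if (model$head_norm %in% c("cosine", "l2")) v / max(vnorm, 1e-8) else v
  if (model$head_norm == "cosine") {
    Wn <- sqrt(colSums(model$params$fc$W^2))
    Wn <- pmax(Wn, 1e-8)
    logits <- model$logit_scale *
      drop(crossprod(model$params$fc$W, vn)) / Wn
  } else {
    Wn <- NULL
    logits <- drop(crossprod(model$params$fc$W, vn)) + model$params$fc$b
  }
  probs <- softmax_vec(logits)
  out <- list(S = S, probs = probs, logits = logits, score = probs[2L],
              attention = att, weights = w)
  if (keep_cache) {
    out$bb <- bb
    out$out_dim <- dim(bb$out)
    out$v <- v
    out$vn <- vn
    out$vnorm <- vnorm
    out$Wn <- Wn
    out$amax <- amax
  }
  out
}

# backward pass from d(loss)/d(logits); attention weights are treated as
# constants (the t fit is a statistics step, not a learned layer)
model_backward <- function(model, fwd, dlogits) {
  sh <- model$feature_shape
  S <- fwd$S
  if (model$head_norm == "cosine") {
    # z_k = s * cos(W_k, v) + b_k;  d z_k / d W_k = s (v^ - cos_k W^_k)/|W_k|
    s <- model$logit_scale
    What <- sweep(model$params$fc$W, 2L, fwd$Wn, "/")
    cosk <- drop(crossprod(What, fwd$vn))
    gW <- (outer(fwd$vn, dlogits) -
             sweep(What, 2L, cosk * dlogits, "*"))
    gW <- sweep(gW, 2L, s / fwd$Wn, "*")
    gfc <- list(W = gW)
    dvn <- s * drop(What %*% dlogits)
  } else {
    gfc <- list(W = outer(fwd$vn, dlogits), b = dlogits)
    dvn <- drop(model$params$fc$W %*% dlogits)
  }
  if (model$head_norm %in% c("cosine", "l2")) {
    nrm <- max(fwd$vnorm, 1e-8)
    vhat <- fwd$v / nrm
    dv <- (dvn - vhat * sum(vhat * dvn)) / nrm
  } else {
    dv <- dvn
  }
  du <- matrix(0, S, sh$C)
  du[cbind(fwd$amax, seq_len(sh$C))] <- dv
  du <- du * fwd$weights                     # constant attention weighting
  # undo global average pooling: spread over the spatial grid
  davg_cs <- as.vector(t(du))                # (channel, slice) order
  dout <- array(rep(davg_cs, each = sh$H * sh$W) / (sh$H * sh$W),
                fwd$out_dim)
  bw <- backbone_backward(model$layers, model$params$backbone,
                          fwd$bb$cache, dout)
  list(backbone = bw$grads, fc = gfc)
}

# loss value and gradient w.r.t. logits for the configured objective
model_loss_grad <- function(model, logits, true_class) {
  if (model$loss == "cross_entropy") {
    p <- softmax_vec(logits)
    onehot <- rep(0, length(p)); onehot[true_class] <- 1
    list(loss = -log(max(p[true_class], 1e-12)), grad = p - onehot)
  } else {
    penalty_loss_grad(logits, true_class, model$penalty)
  }
}

#' Classify one exam
#'
#' Runs the full forward pass on a slice stack and returns the positive
#' class score and softmax probabilities.
#'
#' @param model a [slice_model()].
#' @param stack a `slice_stack` or an `S x H x W` array.
#' @param attention_state if `TRUE`, attach the full attention state
#'   (pooled descriptors, similarity matrices, fitted t-parameters and
#'   weights) to the prediction.
#' @return object of class `exam_prediction`: `exam_id`, `score`
#'   (positive-class probability), `probs`, and optionally `attention`.
#' @export
predict_exam <- function(model, stack, attention_state = FALSE) {
  fwd <- model_forward(model, stack)
  structure(list(
    exam_id = if (inherits(stack, "slice_stack")) stack$exam_id else NA,
    score = fwd$score, probs = fwd$probs,
    attention = if (attention_state) fwd$attention else NULL),
    class = "exam_prediction")
}

#' @export
print.exam_prediction <- function(x, ...) {
  cat(sprintf("exam %s: positive-class score %.4f\n", x$exam_id, x$score))
  invisible(x)
}

# positive-class scores for a set of exams
score_exams <- function(model, dataset, ids) {
  vapply(ids, function(id) model_forward(model, dataset$exams[[id]])$score,
         numeric(1))
}

#' Save a model checkpoint
#'
#' Single-file archive holding the weights, the full configuration, and
#' optional metadata such as per-exam attention statistics.
#'
#' @param model a `slice_model`.
#' @param file target path.
#' @param meta optional list of metadata stored alongside the model.
#' @return invisibly, `file`.
#' @export
save_checkpoint <- function(model, file, meta = list()) {
  saveRDS(list(model = model, meta = meta), file)
  invisible(file)
}

#' Load a model checkpoint
#' @param file path written by [save_checkpoint()].
#' @return the `slice_model` (metadata attached as attribute `meta`).
#' @export
load_checkpoint <- function(file) {
  if (!file.exists(file)) stop("checkpoint not found: ", file, call. = FALSE)
  ck <- readRDS(file)
  m <- ck$model
  attr(m, "meta") <- ck$meta
  m
}
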