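#' Training configuration
#'
#' Bundles every knob of the training protocol. The default learning rate
#' of 1e-3 targets the randomly initialized desk-scale backbones used
#' here; for ImageNet-scale pretrained networks the canonical setting of
#' this protocol is 1e-5. Optimization is Adam with one exam per step
#' (batch size 1), up to `max_epochs` epochs, with early stopping when the
#' mean training loss of an epoch falls below `early_stop_epsilon`.
#'
#' @param backbone registry name (see [backbone_registry()]).
#' @param attention logical; include the slice-attention module.
#' @param loss `"cross_entropy"` or `"penalty_weight"`.
#' @param penalty_rule,penalty_overrides forwarded to [penalty_matrix()]
#'   when `loss = "penalty_weight"`. When no overrides are given the
#'   trainer applies a class-balanced default: the cost of predicting
#'   healthy on a true tear is set to the negative:positive ratio of the
#'   training split (capped at 10), counterweighting class imbalance.
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs maximum number of epochs (>= 1), default 50.
#' @param batch_size exams per optimization step, default 1.
#' @param early_stop_epsilon stop once the epoch-mean training loss drops
#'   below this value.
#' @param grad_clip clip each step's gradient to this global L2 norm
#'   (`Inf` disables); a standard stabilizer against occasional
#'   divergence of single runs.
#' @param seed seed controlling initialization and batch order.
#' @param split_ratios train/val/test ratios, default `c(0.8, 0.1, 0.1)`.
#' @param image_size,in_channels input geometry, see [slice_model()].
#' @param nu_fixed,nu_min,nu_max Student-t fit controls.
#' @param weight_rescale,head_norm,logit_scale model head and attention
#'   scaling options, see [slice_model()].
#' @param output_dir optional directory for checkpoints and reports.
#' @return object of class `train_config`.
#' @export
train_config <- function(backbone = "tiny", attention = TRUE,
                         loss = c("cross_entropy", "penalty_weight"),
                         penalty_rule = "absolute-distance",
                         penalty_overrides = NULL,
                         learning_rate = 1e-3, max_epochs = 50L,
                         batch_size = 1L, early_stop_epsilon = 1e-4,
                         grad_clip = 5,
                         seed = 1L, split_ratios = c(0.8, 0.1, 0.1),
                         image_size = 64L, in_channels = 1L,
                         nu_fixed = NULL, nu_min = 2.05, nu_max = 200,
                         weight_rescale = "mean_one", head_norm = "cosine",
                         logit_scale = 4, output_dir = NULL) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("`max_epochs` must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(list(backbone = backbone, attention = isTRUE(attention),
                 loss = loss, penalty_rule = penalty_rule,
                 penalty_overrides = penalty_overrides,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_epsilon = early_stop_epsilon,
                 grad_clip = grad_clip,
                 seed = as.integer(seed), split_ratios = split_ratios,
                 image_size = as.integer(image_size),
                 in_channels = as.integer(in_channels),
                 nu_fixed = nu_fixed, nu_min = nu_min, nu_max = nu_max,
                 weight_rescale = weight_rescale, head_norm = head_norm,
                 logit_scale = logit_scale, output_dir = output_dir),
            class = "train_config")
}

check_split_classes <- function(dataset, split) {
  for (part in c("train", "val", "test")) {
    ids <- split[[part]]
    if (length(ids) == 0L)
      stop(sprintf("split part '%s' is empty", part), call. = FALSE)
    if (length(unique(dataset$labels[ids])) < 2L)
      stop(sprintf("split part '%s' contains a single class", part),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a slice-stack classifier
#'
#' Runs the full protocol: Adam updates with `batch_size` exams per step
#' (default one) in a per-epoch shuffled order, per-epoch validation AUC,
#' selection of the best-validation-AUC epoch (earliest on ties) whose
#' weights are kept, and early stopping once the epoch-mean training loss
#' drops below `early_stop_epsilon`. Fully reproducible: a fixed config
#' and seed give an identical loss trajectory and selected epoch.
#'
#' @param dataset an `exam_dataset`.
#' @param split a [stratified_split()] with all three parts; every part
#'   must contain both classes.
#' @param config a [train_config()].
#' @param quiet suppress the per-epoch progress line.
#' @return object of class `run_record`: per-epoch `train_loss` and
#'   `val_auc`, `selected_epoch`, `best_model`, `final_model`, the
#'   `config` and `split`.
#' @export
train_model <- function(dataset, split, config = train_config(),
                        quiet = TRUE) {
  check_split_classes(dataset, split)
  pov <- config$penalty_overrides
  if (config$loss == "penalty_weight" && is.null(pov)) {
    # class-balanced default: missing the minority (tear) class costs the
    # negative:positive ratio of the training split, capped at 10 — the
    # imbalance counterweight the penalty loss exists to provide
    tr <- dataset$labels[split$train]
    r <- min(max(sum(tr == 0) / max(sum(tr == 1), 1), 1), 10)
    pov <- data.frame(predicted = 1, true = 2, cost = r)
  }
  pm <- penalty_matrix(2, base_rule = config$penalty_rule, overrides = pov)
  model <- slice_model(backbone = config$backbone,
                       attention = config$attention, loss = config$loss,
                       penalty = pm, image_size = config$image_size,
                       in_channels = config$in_channels,
                       nu_fixed = config$nu_fixed, nu_min = config$nu_min,
                       nu_max = config$nu_max,
                       weight_rescale = config$weight_rescale %||% "mean_one",
                       head_norm = config$head_norm %||% "cosine",
                       logit_scale = config$logit_scale %||% 4,
                       seed = config$seed)
  opt <- adam_init(model$params)
  train_ids <- split$train
  val_labels <- as.numeric(dataset$labels[split$val])
  train_loss <- numeric(0)
  val_auc <- numeric(0)
  best_auc <- -Inf
  best_params <- model$params
  best_epoch <- 1L
  epochs_run <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      order_ids <- sample(train_ids)
      losses <- numeric(length(order_ids))
      i <- 1L
      while (i <= length(order_ids)) {
        batch <- order_ids[seq(i, min(i + config$batch_size - 1L,
                                      length(order_ids)))]
        gacc <- NULL
        for (id in batch) {
          stack <- dataset$exams[[id]]
          fwd <- model_forward(model, stack, keep_cache = TRUE)
          lg <- model_loss_grad(model, fwd$logits,
                                dataset$labels[[id]] + 1L)
          losses[i] <- lg$loss
          g <- model_backward(model, fwd, lg$grad)
          gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
          i <- i + 1L
        }
        if (length(batch) > 1L)
          gacc <- tree_map(function(x, ...) x / length(batch), gacc)
        clip <- config$grad_clip %||% Inf
        if (is.finite(clip)) {
          gn <- tree_global_norm(gacc)
          if (gn > clip)
            gacc <- tree_map(function(x, ...) x * (clip / gn), gacc)
        }
        st <- adam_step(model$params, gacc, opt, config$learning_rate)
        model$params <- st$params
        opt <- st$state
      }
      epochs_run <- epoch
      train_loss[epoch] <- mean(losses)
      vs <- score_exams(model, dataset, split$val)
      val_auc[epoch] <- roc_auc(vs, val_labels)$auc
      if (!quiet)
        message(sprintf("epoch %d: train loss %.4f, val AUC %.4f",
                        epoch, train_loss[epoch], val_auc[epoch]))
      if (val_auc[epoch] > best_auc) {
        best_auc <- val_auc[epoch]
        best_params <- model$params
        best_epoch <- epoch
      }
      if (train_loss[epoch] < config$early_stop_epsilon) break
    }
  })
  selected <- select_best_epoch(val_auc)
  stopifnot(selected == best_epoch)
  best_model <- model
  best_model$params <- best_params
  structure(list(train_loss = train_loss, val_auc = val_auc,
                 selected_epoch = selected, epochs_run = epochs_run,
                 best_model = best_model, final_model = model,
                 config = config, split = split,
                 seed = config$seed),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("training run: %d epochs, selected epoch %d (val AUC %.4f)\n",
              x$epochs_run, x$selected_epoch, x$val_auc[x$selected_epoch]))
  invisible(x)
}

#' Evaluate a trained run on one split part
#'
#' Fits the accuracy-maximizing threshold on the validation scores of the
#' best-epoch model, then applies that frozen threshold to the requested
#' part. The threshold never sees the evaluated part's labels (leakage
#' guard: it is computed from validation scores only, and its provenance
#' is recorded on the report).
#'
#' @param record a `run_record` from [train_model()].
#' @param dataset the `exam_dataset` the record was trained on.
#' @param part `"test"` (default), `"val"`, or `"train"`.
#' @return an [eval_report()] with attribute `threshold_source =
#'   "validation"`.
#' @export
evaluate_model <- function(record, dataset, part = c("test", "val", "train")) {
  part <- match.arg(part)
  model <- record$best_model
  split <- record$split
  val_scores <- score_exams(model, dataset, split$val)
  threshold <- adaptive_threshold(val_scores,
                                  as.numeric(dataset$labels[split$val]))
  ids <- split[[part]]
  scores <- if (part == "val") val_scores else score_exams(model, dataset, ids)
  report <- eval_report(scores, as.numeric(dataset$labels[ids]),
                        threshold = threshold, exam_ids = ids)
  attr(report, "threshold_source") <- "validation"
  report
}

#' Run the 2x2 ablation grid
#'
#' Trains and evaluates the four model variants — baseline (cross-entropy,
#' no attention), slice attention only, penalty loss only, and both — with
#' a shared seed and split, so the variants differ only in the attention
#' toggle and the configured loss.
#'
#' @param dataset an `exam_dataset`.
#' @param split a [stratified_split()].
#' @param config base [train_config()]; its `attention`/`loss` fields are
#'   overridden per variant.
#' @param quiet suppress progress output.
#' @return object of class `ablation_result`: `records`, `reports`, and a
#'   comparison `table` (one row per variant: AUC, ACC, Precision, Recall,
#'   Specificity, F1).
#' @export
ablate <- function(dataset, split, config = train_config(), quiet = TRUE) {
  variants <- list(
    CE = list(attention = FALSE, loss = "cross_entropy"),
    Slice = list(attention = TRUE, loss = "cross_entropy"),
    Weight = list(attention = FALSE, loss = "penalty_weight"),
    `Slice-Weight` = list(attention = TRUE, loss = "penalty_weight"))
  names(variants) <- paste(config$backbone, names(variants), sep = "-")
  records <- list()
  reports <- list()
  for (nm in names(variants)) {
    cfg <- config
    cfg$attention <- variants[[nm]]$attention
    cfg$loss <- variants[[nm]]$loss
    if (!quiet) message("training variant ", nm)
    records[[nm]] <- train_model(dataset, split, cfg, quiet = quiet)
    reports[[nm]] <- evaluate_model(records[[nm]], dataset, "test")
  }
  tab <- data.frame(
    Model = names(reports),
    AUC = vapply(reports, function(r) r$auc, numeric(1)),
    ACC = vapply(reports, function(r) r$acc, numeric(1)),
    Precision = vapply(reports, function(r) r$precision, numeric(1)),
    Recall = vapply(reports, function(r) r$recall, numeric(1)),
    Specificity = vapply(reports, function(r) r$specificity, numeric(1)),
    F1 = vapply(reports, function(r) r$f1, numeric(1)),
    row.names = NULL)
  structure(list(records = records, reports = reports, table = tab),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("ablation grid (test-set metrics):\n")
  print(x$table, digits = 4)
  invisible(x)
}
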