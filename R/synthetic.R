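#' Specification of the synthetic exam generator
#'
#' Parameters of the phantom generator that emulates MRNet-like knee-MRI
#' exams: a variable number of grayscale slices per exam, smooth anatomy
#' shared across slices with slice-to-slice drift, pure-noise slices at
#' both ends of the stack, and (for positive exams) a bright circular
#' lesion stamped into a contiguous run of central slices.
#'
#' @param n_exams number of exams to generate.
#' @param prevalence positive-class probability in (0, 1); default 0.2,
#'   matching the roughly one-in-five injury fraction of real knee-MRI
#'   cohorts.
#' @param slice_count_range integer interval for the per-exam slice count,
#'   default `c(17, 61)`.
#' @param image_size slice resolution in pixels (square), default 64.
#' @param lesion_center_sd standard deviation (in slices) of the lesion
#'   center position around `S / 2`.
#' @param lesion_radius lesion radius in pixels.
#' @param lesion_contrast added intensity of the lesion (image intensities
#'   live in \[0, 1\]).
#' @param lesion_extent number of contiguous slices the lesion spans.
#' @param anatomy_blob_count number of smooth background anatomy blobs.
#' @param anatomy_scale blob radius scale as a fraction of the image size.
#' @param noise_sd Gaussian pixel-noise standard deviation on anatomy
#'   slices; end slices use three times this value.
#' @param end_noise_slices number of pure-noise slices at each end.
#' @param seed RNG seed making the whole dataset reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_exams = 200,
                           prevalence = 0.2,
                           slice_count_range = c(17L, 61L),
                           image_size = 64L,
                           lesion_center_sd = 1.5,
                           lesion_radius = 6,
                           lesion_contrast = 0.35,
                           lesion_extent = 5L,
                           anatomy_blob_count = 6L,
                           anatomy_scale = 0.15,
                           noise_sd = 0.08,
                           end_noise_slices = 2L,
                           seed = 42L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  if (length(slice_count_range) != 2L ||
      slice_count_range[1] < 1 || slice_count_range[2] > 512 ||
      slice_count_range[1] > slice_count_range[2])
    stop("`slice_count_range` must be an increasing interval within [1, 512]",
         call. = FALSE)
  if (lesion_center_sd < 0 || noise_sd < 0 || anatomy_scale < 0)
    stop("standard deviations and scales must be >= 0", call. = FALSE)
  if (n_exams < 1) stop("`n_exams` must be >= 1", call. = FALSE)
  structure(list(n_exams = as.integer(n_exams), prevalence = prevalence,
                 slice_count_range = as.integer(slice_count_range),
                 image_size = as.integer(image_size),
                 lesion_center_sd = lesion_center_sd,
                 lesion_radius = lesion_radius,
                 lesion_contrast = lesion_contrast,
                 lesion_extent = as.integer(lesion_extent),
                 anatomy_blob_count = as.integer(anatomy_blob_count),
                 anatomy_scale = anatomy_scale,
                 noise_sd = noise_sd,
                 end_noise_slices = as.integer(end_noise_slices),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

new_slice_stack <- function(exam_id, slices, label, truth = NULL) {
  if (!is.array(slices) || length(dim(slices)) != 3L)
    stop("`slices` must be a 3-D array S x H x W", call. = FALSE)
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1", call. = FALSE)
  structure(list(exam_id = exam_id, slices = slices,
                 label = as.integer(label), truth = truth),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("slice stack %s: %d slices of %dx%d, label %d\n",
              x$exam_id, d[1], d[2], d[3], x$label))
  invisible(x)
}

#' Generate a single synthetic exam
#'
#' Draws the slice count uniformly from the configured range, renders
#' smooth anatomy blobs shared across slices with a small per-slice random
#' drift plus Gaussian pixel noise, replaces the first and last
#' `end_noise_slices` slices with pure noise, and — for positive exams —
#' stamps a circular lesion into a contiguous run of slices whose center
#' slice is drawn from `Normal(S / 2, lesion_center_sd)` and clamped to
#' the informative (non-end) range. Intensities are clipped to \[0, 1\].
#' Uses the current RNG state; seed control belongs to the caller (see
#' [generate_dataset()]).
#'
#' @param spec a [synthetic_spec()].
#' @param label 0 (healthy) or 1 (lesion present).
#' @param exam_id identifier stored in the stack.
#' @return a `slice_stack`; for positive exams `truth` records the lesion
#'   center slice, the slice run, the in-plane center and the radius.
#' @export
generate_exam <- function(spec, label, exam_id = "exam") {
  if (!inherits(spec, "synthetic_spec")) stop("invalid spec", call. = FALSE)
  n <- spec$image_size
  counts <- seq(spec$slice_count_range[1], spec$slice_count_range[2])
  S <- counts[sample.int(length(counts), 1L)]   # safe for degenerate ranges
  e <- min(spec$end_noise_slices, floor((S - 1) / 2))
  gx <- matrix(seq_len(n), n, n)
  gy <- t(gx)

  # shared anatomy: smooth blobs with per-slice center drift
  nb <- spec$anatomy_blob_count
  bx <- runif(nb, 0.2 * n, 0.8 * n)
  by <- runif(nb, 0.2 * n, 0.8 * n)
  br <- runif(nb, 0.5, 1.5) * spec$anatomy_scale * n
  ba <- runif(nb, 0.08, 0.2)
  drift_x <- apply(matrix(rnorm(S * nb, 0, 0.01 * n), S, nb), 2, cumsum)
  drift_y <- apply(matrix(rnorm(S * nb, 0, 0.01 * n), S, nb), 2, cumsum)

  slices <- array(0, c(S, n, n))
  for (s in seq_len(S)) {
    img <- matrix(0.3, n, n)
    for (b in seq_len(nb)) {
      d2 <- (gx - (bx[b] + drift_x[s, b]))^2 + (gy - (by[b] + drift_y[s, b]))^2
      img <- img + ba[b] * exp(-d2 / (2 * br[b]^2))
    }
    img <- img + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
    slices[s, , ] <- img
  }

  truth <- NULL
  if (label == 1) {
    lo <- e + 1L; hi <- S - e
    center <- round(rnorm(1, S / 2, spec$lesion_center_sd))
    center <- min(max(center, lo), hi)
    half <- floor(spec$lesion_extent / 2)
    run <- max(lo, center - half):min(hi, center + half)
    lx <- runif(1, 0.3 * n, 0.7 * n)
    ly <- runif(1, 0.3 * n, 0.7 * n)
    d2 <- (gx - lx)^2 + (gy - ly)^2
    mask <- exp(-d2 / (2 * (spec$lesion_radius / 1.5)^2))
    for (s in run) {
      taper <- 1 - (abs(s - center) / (half + 1))^2
      slices[s, , ] <- slices[s, , ] + spec$lesion_contrast * taper * mask
    }
    truth <- list(center_slice = center, slices = run,
                  center_xy = c(lx, ly), radius = spec$lesion_radius)
  }

  # End slices override everything else: irrelevant content unrelated to
  # the label — heavy pixel noise plus bright pseudo-lesion artifacts
  # (vessels, fat, coil flare) drawn from the same morphology law as a
  # true lesion.  Without positional context they are indistinguishable
  # from pathology, which is exactly what makes unfiltered max fusion
  # misfire and slice filtering necessary.
  if (e > 0) {
    for (s in c(seq_len(e), seq(S - e + 1L, S))) {
      img <- matrix(rnorm(n * n, 0.4, 2 * spec$noise_sd), n, n)
      for (b in seq_len(sample(1:2, 1))) {
        ax <- runif(1, 0.15 * n, 0.85 * n); ay <- runif(1, 0.15 * n, 0.85 * n)
        aa <- spec$lesion_contrast * runif(1, 0.8, 1.2)
        img <- img + aa * exp(-((gx - ax)^2 + (gy - ay)^2) /
                                (2 * (spec$lesion_radius / 1.5)^2))
      }
      slices[s, , ] <- img
    }
  }

  slices[slices < 0] <- 0
  slices[slices > 1] <- 1
  new_slice_stack(exam_id, slices, label, truth)
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n_exams` labels from `Bernoulli(prevalence)` and renders one
#' exam per label. The whole procedure runs under `spec$seed`, so an
#' identical spec yields a bit-identical dataset; the caller's RNG state
#' is restored afterwards.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `exam_dataset`: named list `exams` of
#'   `slice_stack`s, named integer vector `labels`, and the `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("invalid spec", call. = FALSE)
  with_seed(spec$seed, {
    labels <- rbinom(spec$n_exams, 1L, spec$prevalence)
    ids <- sprintf("exam_%04d", seq_len(spec$n_exams))
    exams <- vector("list", spec$n_exams)
    for (i in seq_len(spec$n_exams))
      exams[[i]] <- generate_exam(spec, labels[i], ids[i])
    names(exams) <- ids
    names(labels) <- ids
    structure(list(exams = exams, labels = labels, spec = spec),
              class = "exam_dataset")
  })
}

#' @export
print.exam_dataset <- function(x, ...) {
  cat(sprintf("exam dataset: %d exams, %d positive (%.1f%%), image %dx%d\n",
              length(x$exams), sum(x$labels),
              100 * mean(x$labels), x$spec$image_size, x$spec$image_size))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Shuffles each class independently under the given seed and allocates it
#' to the three parts at the given ratios (rounded per class, remainder to
#' training), so the class prevalence of every part tracks the overall
#' prevalence.
#'
#' @param labels named binary vector (names are exam ids).
#' @param ratios length-3 vector (train, val, test) summing to 1;
#'   default `c(0.8, 0.1, 0.1)`.
#' @param seed RNG seed for the per-class shuffles.
#' @return object of class `dataset_split`: exam-id vectors `train`,
#'   `val`, `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("`ratios` must be 3 non-negative values summing to 1", call. = FALSE)
  if (is.null(names(labels))) names(labels) <- as.character(seq_along(labels))
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("both classes must be present", call. = FALSE)
  nparts <- sum(ratios > 0)
  parts <- list(train = character(0), val = character(0), test = character(0))
  with_seed(seed, {
    for (cl in sort(classes)) {
      ids <- sample(names(labels)[labels == cl])
      ncl <- length(ids)
      if (ncl < nparts)
        stop(sprintf("class %s has %d members, fewer than the %d split parts",
                     cl, ncl, nparts), call. = FALSE)
      n_test <- round(ncl * ratios[3])
      n_val <- round(ncl * ratios[2])
      n_train <- ncl - n_val - n_test
      parts$train <- c(parts$train, ids[seq_len(n_train)])
      if (n_val > 0)
        parts$val <- c(parts$val, ids[n_train + seq_len(n_val)])
      if (n_test > 0)
        parts$test <- c(parts$test, ids[n_train + n_val + seq_len(n_test)])
    }
  })
  structure(parts, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("split: %d train / %d val / %d test\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Write an exam dataset to an MRNet-style directory
#'
#' One binary array file per exam (`<exam_id>.rds`, the R array container,
#' holding the `S x H x W` stack), a two-column `labels.csv`, and — when
#' lesion truth metadata is present — a `truth.json` sidecar.
#'
#' @param dataset an `exam_dataset` (or list with `exams` and `labels`).
#' @param path target directory, created if needed.
#' @return invisibly, `path`.
#' @export
write_exam_dir <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ex in dataset$exams)
    saveRDS(ex$slices, file.path(path, paste0(ex$exam_id, ".rds")))
  write.csv(data.frame(exam_id = names(dataset$labels),
                       label = as.integer(dataset$labels)),
            file.path(path, "labels.csv"), row.names = FALSE)
  truths <- Filter(Negate(is.null), lapply(dataset$exams, `[[`, "truth"))
  if (length(truths) > 0)
    jsonlite::write_json(truths, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MRNet-style exam directory
#'
#' Inverse of [write_exam_dir()]: reads `labels.csv` and one stack file per
#' listed exam. Errors name the offending exam when a labelled stack file
#' is missing, when a stack file on disk has no label row, and when a
#' stack is not a numeric 3-D array (ragged or non-grayscale data).
#'
#' @param path directory written by [write_exam_dir()] (or following the
#'   same layout).
#' @return an `exam_dataset` (with `spec = NULL` and any truth sidecar
#'   attached to the stacks).
#' @export
read_exam_dir <- function(path) {
  label_file <- file.path(path, "labels.csv")
  if (!file.exists(label_file))
    stop(sprintf("no labels.csv in %s", path), call. = FALSE)
  tab <- read.csv(label_file, stringsAsFactors = FALSE)
  if (!all(c("exam_id", "label") %in% names(tab)))
    stop("labels.csv must have columns exam_id, label", call. = FALSE)
  stack_files <- list.files(path, pattern = "\\.rds$")
  on_disk <- sub("\\.rds$", "", stack_files)
  unlabelled <- setdiff(on_disk, tab$exam_id)
  if (length(unlabelled) > 0)
    stop(sprintf("stack file(s) without a label row: %s",
                 paste(unlabelled, collapse = ", ")), call. = FALSE)
  truth <- NULL
  truth_file <- file.path(path, "truth.json")
  if (file.exists(truth_file))
    truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  exams <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$exam_id[i]
    f <- file.path(path, paste0(id, ".rds"))
    if (!file.exists(f))
      stop(sprintf("labelled exam '%s' has no stack file on disk", id),
           call. = FALSE)
    arr <- readRDS(f)
    if (!is.numeric(arr) || !is.array(arr) || length(dim(arr)) != 3L)
      stop(sprintf("exam '%s': stack must be a numeric 3-D array (grayscale S x H x W)",
                   id), call. = FALSE)
    tr <- if (!is.null(truth) && id %in% names(truth)) truth[[id]] else NULL
    exams[[i]] <- new_slice_stack(id, arr, tab$label[i], tr)
  }
  names(exams) <- tab$exam_id
  labels <- as.integer(tab$label)
  names(labels) <- tab$exam_id
  structure(list(exams = exams, labels = labels, spec = NULL),
            class = "exam_dataset")
}
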