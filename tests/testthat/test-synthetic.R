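small_spec <- function(...) {
  synthetic_spec(n_exams = 8, slice_count_range = c(6, 10), image_size = 16,
                 lesion_radius = 2, end_noise_slices = 1, seed = 5, ...)
}

test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(prevalence = 0), "prevalence")
  expect_error(synthetic_spec(prevalence = 1.2), "prevalence")
  expect_error(synthetic_spec(slice_count_range = c(10, 5)), "interval")
  expect_error(synthetic_spec(slice_count_range = c(0, 5)), "interval")
  expect_error(synthetic_spec(noise_sd = -1), ">= 0")
})

test_that("negative exams carry no lesion and positives record truth", {
  spec <- small_spec()
  set.seed(1)
  neg <- generate_exam(spec, 0, "n1")
  expect_null(neg$truth)
  expect_true(all(neg$slices >= 0 & neg$slices <= 1))

  pos <- generate_exam(spec, 1, "p1")
  expect_false(is.null(pos$truth))
  expect_true(pos$truth$center_slice %in% seq_len(dim(pos$slices)[1]))
  expect_true(all(diff(pos$truth$slices) == 1))   # contiguous run
})

test_that("a zero placement spread pins the lesion center to mid-stack", {
  spec <- small_spec(lesion_center_sd = 0)
  set.seed(2)
  for (rep in 1:10) {
    ex <- generate_exam(spec, 1)
    S <- dim(ex$slices)[1]
    expect_equal(ex$truth$center_slice, round(S / 2))
  }
})

test_that("lesion centers concentrate at the middle of the stack", {
  # Monte-Carlo check of the placement law: center slice ~ N(S/2, sd),
  # so center/S should average one half
  spec <- synthetic_spec(n_exams = 1, image_size = 16, lesion_radius = 2,
                         seed = 1)
  set.seed(3)
  fr <- replicate(400, {
    ex <- generate_exam(spec, 1)
    ex$truth$center_slice / dim(ex$slices)[1]
  })
  expect_lt(abs(mean(fr) - 0.5), 0.02)
})

test_that("datasets are reproducible and labels track the prevalence", {
  spec <- small_spec()
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)

  spec_lab <- synthetic_spec(n_exams = 1000, prevalence = 0.2,
                             slice_count_range = c(3, 4), image_size = 8,
                             lesion_radius = 1, end_noise_slices = 1,
                             seed = 77)
  dl <- generate_dataset(spec_lab)
  # central 99% binomial interval for n = 1000, p = 0.2
  expect_gte(sum(dl$labels), qbinom(0.005, 1000, 0.2))
  expect_lte(sum(dl$labels), qbinom(0.995, 1000, 0.2))
  expect_true(all(dl$labels %in% c(0, 1)))
})

test_that("stratified splits keep the class mix and are exact on round numbers", {
  labels <- c(rep(0, 80), rep(1, 20))
  names(labels) <- sprintf("e%03d", 1:100)
  sp <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(length(sp$test), 10)
  expect_equal(sum(labels[sp$test]), 2)
  expect_equal(sum(labels[sp$val]), 2)
  expect_equal(sum(labels[sp$train]), 16)
  expect_setequal(c(sp$train, sp$val, sp$test), names(labels))
  expect_equal(anyDuplicated(c(sp$train, sp$val, sp$test)), 0)

  all_train <- stratified_split(labels, c(1, 0, 0), seed = 4)
  expect_setequal(all_train$train, names(labels))

  set.seed(5)
  big <- rbinom(500, 1, 0.2)
  names(big) <- sprintf("x%03d", 1:500)
  spb <- stratified_split(big, c(0.8, 0.1, 0.1), seed = 6)
  for (part in c("train", "val", "test")) {
    ids <- spb[[part]]
    expect_lte(abs(sum(big[ids]) - mean(big) * length(ids)), 2)
  }

  # deterministic under seed
  expect_identical(stratified_split(big, seed = 9),
                   stratified_split(big, seed = 9))

  tiny <- c(a = 0, b = 0, c = 0, d = 1)
  expect_error(stratified_split(tiny, c(0.5, 0.25, 0.25), seed = 1),
               "fewer than")
})

test_that("exam directories round-trip bit-exactly and validate their layout", {
  spec <- small_spec()
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_exam_dir(ds, dir)
  back <- read_exam_dir(dir)
  expect_identical(names(back$exams), names(ds$exams))
  for (id in names(ds$exams))
    expect_identical(back$exams[[id]]$slices, ds$exams[[id]]$slices)
  expect_identical(as.integer(back$labels), as.integer(ds$labels))

  # labelled exam with no stack file -> error naming the id
  file.remove(file.path(dir, paste0(names(ds$exams)[2], ".rds")))
  expect_error(read_exam_dir(dir), names(ds$exams)[2])

  # stack file with no label row -> error naming the file
  dir2 <- withr::local_tempdir()
  write_exam_dir(ds, dir2)
  saveRDS(ds$exams[[1]]$slices, file.path(dir2, "orphan.rds"))
  expect_error(read_exam_dir(dir2), "orphan")

  # ragged / non-3-D stack -> descriptive error
  dir3 <- withr::local_tempdir()
  write_exam_dir(ds, dir3)
  saveRDS(matrix(0, 4, 4), file.path(dir3, paste0(names(ds$exams)[1], ".rds")))
  expect_error(read_exam_dir(dir3), "3-D")
})

test_that("boundary slice counts parse without resampling", {
  for (S in c(17, 61)) {
    spec <- synthetic_spec(n_exams = 1, slice_count_range = c(S, S),
                           image_size = 16, lesion_radius = 2, seed = S)
    ds <- generate_dataset(spec)
    dir <- withr::local_tempdir()
    write_exam_dir(ds, dir)
    back <- read_exam_dir(dir)
    expect_equal(dim(back$exams[[1]]$slices)[1], S)
  }
})

test_that("central slices are more informative than end slices for a linear probe", {
  # the structural premise: a probe predicting the exam label from one
  # slice succeeds on central slices of positive exams (where the lesion
  # lives) and fails on their end slices (which carry no label signal)
  spec <- synthetic_spec(n_exams = 120, prevalence = 0.5,
                         slice_count_range = c(9, 15), image_size = 32,
                         lesion_radius = 3, seed = 404)
  ds <- generate_dataset(spec)
  slice_feats <- function(img) c(max(img), mean(img), sd(img),
                                 quantile(img, 0.99))
  rows <- list(); lab <- c(); zone <- c(); exam <- c()
  for (ex in ds$exams) {
    S <- dim(ex$slices)[1]
    for (s in seq_len(S)) {
      rows[[length(rows) + 1]] <- slice_feats(ex$slices[s, , ])
      lab <- c(lab, ex$label)
      zone <- c(zone, if (s <= 2 || s > S - 2) "end"
                else if (s > S / 3 && s <= 2 * S / 3) "central" else "other")
      exam <- c(exam, ex$exam_id)
    }
  }
  X <- do.call(rbind, rows)
  train_ids <- names(ds$exams)[seq_len(60)]
  tr <- exam %in% train_ids
  fit <- suppressWarnings(glm.fit(cbind(1, X[tr, ]), lab[tr],
                                  family = binomial()))
  pred <- as.numeric(cbind(1, X[!tr, ]) %*% fit$coefficients) > 0
  # detection rate on held-out positive exams, by slice zone
  det <- tapply(pred, list(zone[!tr], lab[!tr]), mean)
  expect_gt(det["central", "1"], det["end", "1"])
})
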