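test_that("max fusion takes coordinatewise maxima", {
  expect_equal(aggregate_max(rbind(c(1, 5), c(4, 2))), c(4, 5))
  m <- rbind(c(2, 7, 1), c(2, 7, 1))
  expect_equal(aggregate_max(m), c(2, 7, 1))      # idempotent on duplicates
  expect_equal(aggregate_max(matrix(c(3, 9), 1)), c(3, 9))  # single slice

  set.seed(61)
  mm <- matrix(rnorm(160), 10, 16)
  loop <- sapply(1:16, function(j) max(mm[, j]))
  expect_equal(aggregate_max(mm), loop, tolerance = 1e-15)

  expect_error(aggregate_max(list(c(1, 2), c(1, 2, 3))), "ragged")
})

test_that("model construction validates the registry and counts parameters", {
  expect_error(slice_model(backbone = "alexnet"), "unknown backbone")
  mod <- slice_model(seed = 1)
  expect_equal(count_params(mod), 3600)
  # the four ablation variants share one parameter count
  counts <- sapply(list(
    slice_model(attention = FALSE, loss = "cross_entropy", seed = 1),
    slice_model(attention = TRUE, loss = "cross_entropy", seed = 1),
    slice_model(attention = FALSE, loss = "penalty_weight", seed = 1),
    slice_model(attention = TRUE, loss = "penalty_weight", seed = 1)),
    count_params)
  expect_equal(length(unique(counts)), 1L)
})

test_that("predictions live on the simplex and reject empty stacks", {
  mod <- slice_model(image_size = 16, seed = 2)
  p <- predict_exam(mod, random_stack(4, 16))
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
  expect_true(all(p$probs >= 0))
  expect_equal(p$score, p$probs[2])
  expect_error(predict_exam(mod, array(0, c(0, 16, 16))), "empty")
})

test_that("attention-off predictions are invariant to slice permutation", {
  set.seed(62)
  mod <- slice_model(image_size = 16, attention = FALSE, seed = 3)
  stack <- random_stack(6, 16)
  p1 <- predict_exam(mod, stack)
  p2 <- predict_exam(mod, stack[sample(6), , ])
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
})

test_that("the forward pass matches a dense step-by-step reference", {
  set.seed(63)
  mod <- slice_model(image_size = 16, attention = FALSE, seed = 5)
  stack <- random_stack(3, 16)
  # independent reference: per-slice dense backbone, global average pool,
  # coordinatewise max over slices, linear head, softmax
  u <- t(sapply(1:3, function(s) {
    f <- ref_tiny_backbone(stack[s, , ], mod$params$backbone)
    apply(f, 3, mean)
  }))
  v <- apply(u, 2, max)
  v <- v / sqrt(sum(v^2))                  # cosine head: normalized vector,
  Wn <- sqrt(colSums(mod$params$fc$W^2))   # normalized class weights, scale
  logits <- 4 * drop(v %*% mod$params$fc$W) / Wn
  probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
  got <- predict_exam(mod, stack)
  expect_lt(max(abs(got$probs - probs)), 1e-6)

  # with attention on, the model must agree with the module chain applied
  # to the reference feature stack (weighting commutes with mean pooling)
  mod_a <- mod; mod_a$attention <- TRUE
  feats <- lapply(1:3, function(s) ref_tiny_backbone(stack[s, , ],
                                                     mod$params$backbone))
  M <- array(0, c(3, 16, 4, 4))
  for (s in 1:3) M[s, , , ] <- aperm(feats[[s]], c(3, 1, 2))
  st <- slice_attention(M, return_weighted = FALSE)
  w <- st$weights$w * 3                    # mean-one rescale used by the model
  ua <- u * w
  va <- apply(ua, 2, max)
  va <- va / sqrt(sum(va^2))
  logits_a <- 4 * drop(va %*% mod$params$fc$W) / Wn
  probs_a <- exp(logits_a - max(logits_a)); probs_a <- probs_a / sum(probs_a)
  got_a <- predict_exam(mod_a, stack, attention_state = TRUE)
  expect_lt(max(abs(got_a$probs - probs_a)), 1e-6)
  expect_equal(got_a$attention$weights$w, st$weights$w, tolerance = 1e-8)
})

test_that("scaling an end slice moves the prediction less than a middle slice", {
  set.seed(64)
  deltas <- replicate(6, {
    mod <- slice_model(image_size = 16, seed = sample(1e4, 1))
    stack <- random_stack(9, 16)
    base <- predict_exam(mod, stack)$score
    st_end <- stack; st_end[1, , ] <- pmin(1.5 * st_end[1, , ], 1)
    st_mid <- stack; st_mid[5, , ] <- pmin(1.5 * st_mid[5, , ], 1)
    c(end = abs(predict_exam(mod, st_end)$score - base),
      mid = abs(predict_exam(mod, st_mid)$score - base))
  })
  expect_gt(mean(deltas["mid", ] - deltas["end", ]), 0)
})

test_that("checkpoints round-trip weights and configuration", {
  mod <- slice_model(image_size = 16, seed = 7)
  stack <- random_stack(3, 16)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mod, f, meta = list(note = "unit"))
  back <- load_checkpoint(f)
  expect_equal(predict_exam(back, stack)$probs,
               predict_exam(mod, stack)$probs, tolerance = 1e-15)
  expect_equal(attr(back, "meta")$note, "unit")
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "not found")
})

test_that("stacks at a different resolution are resampled to the model size", {
  mod <- slice_model(image_size = 16, seed = 8)
  p <- predict_exam(mod, random_stack(3, 24))
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
})
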