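test_that("pooled descriptors match their definitions", {
  m <- array(3.5, c(2, 1, 3, 3))
  p <- pool_slice_features(m)
  expect_equal(p$avg, matrix(3.5, 2, 1))
  expect_equal(p$max, matrix(3.5, 2, 1))

  m2 <- array(0, c(2, 1, 2, 2))
  m2[1, 1, 1, 2] <- 8
  p2 <- pool_slice_features(m2)
  expect_equal(p2$avg[1, 1], 2)
  expect_equal(p2$max[1, 1], 8)
  expect_equal(p2$avg[2, 1], 0)

  set.seed(41)
  m3 <- array(rnorm(4 * 3 * 5 * 5), c(4, 3, 5, 5))
  p3 <- pool_slice_features(m3)
  r3 <- ref_pool(m3)
  expect_lt(max(abs(p3$avg - r3$avg)), 1e-10)
  expect_lt(max(abs(p3$max - r3$max)), 1e-10)
  expect_true(all(p3$max >= p3$avg))

  m3[2, 1, 1, 1] <- NaN
  expect_error(pool_slice_features(m3), "finite")
})

test_that("similarity matrices are row-stochastic and match the softmax oracle", {
  p1 <- list(avg = matrix(1.3, 1, 2), max = matrix(2.1, 1, 2))
  sp1 <- similarity_pair(p1)
  expect_equal(sp1$s1, matrix(1), ignore_attr = TRUE)
  expect_equal(sp1$s2, matrix(1), ignore_attr = TRUE)

  # identical slices -> uniform rows
  pid <- list(avg = matrix(rep(c(1, 2), each = 4), 4, 2),
              max = matrix(rep(c(3, 4), each = 4), 4, 2))
  spid <- similarity_pair(pid)
  expect_equal(spid$s1, matrix(1 / 4, 4, 4), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:20) {
    S <- sample(2:6, 1); C <- sample(1:4, 1)
    p <- list(avg = matrix(rnorm(S * C), S, C), max = matrix(rnorm(S * C), S, C))
    sp <- similarity_pair(p)
    r <- ref_similarity(p)
    expect_lt(max(abs(sp$s1 - r$s1)), 1e-10)
    expect_lt(max(abs(sp$s2 - r$s2)), 1e-10)
    expect_true(all(abs(rowSums(sp$s1) - 1) < 1e-9))
    expect_true(all(abs(rowSums(sp$s2) - 1) < 1e-9))
    expect_true(all(sp$s1 > 0 & sp$s1 < 1))
  }

  expect_error(similarity_pair(list(avg = matrix(0, 2, 2),
                                    max = matrix(0, 2, 3))), "shape")
})

test_that("initial weights use the column reduction and normalize", {
  # identical slices -> uniform omega
  pid <- list(avg = matrix(1, 3, 2), max = matrix(2, 3, 2))
  iw <- initial_weights(similarity_pair(pid))
  expect_equal(iw$omega, rep(1 / 3, 3), tolerance = 1e-12)

  # hand-computed: d with both rows (0.9, 0.1) -> omega = (0.9, 0.1)
  sp <- structure(list(s1 = matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2),
                       s2 = matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2)),
                  class = "similarity_pair")
  expect_equal(initial_weights(sp)$omega, c(0.9, 0.1), tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:10) {
    S <- sample(2:6, 1)
    p <- list(avg = matrix(rnorm(S * 3), S, 3), max = matrix(rnorm(S * 3), S, 3))
    iw <- initial_weights(similarity_pair(p))
    r <- ref_initial(ref_similarity(p))
    expect_lt(max(abs(iw$omega - r$omega)), 1e-10)
    expect_equal(sum(iw$omega), 1, tolerance = 1e-9)
    expect_true(all(iw$omega >= 0))
  }
})

test_that("the row-index reduction of the averaged similarity is degenerate", {
  # row sums of a row-stochastic matrix are identically one, so summing d
  # over its column index gives uniform weights on every input
  set.seed(9)
  for (rep in 1:10) {
    S <- sample(2:8, 1)
    p <- list(avg = matrix(rnorm(S * 2, sd = 3), S, 2),
              max = matrix(rnorm(S * 2, sd = 3), S, 2))
    alt <- tsliceattn:::initial_weights_rowsum(similarity_pair(p))
    expect_lt(max(abs(alt$omega - 1 / S)), 1e-12)
  }
})

test_that("t-parameter fit matches the moment formulas and handles degeneracy", {
  iw5 <- list(omega = rep(0.2, 5))
  tp <- fit_t_params(iw5)
  expect_equal(tp$mu, 3)

  onehot <- list(omega = c(0, 0, 1, 0, 0))
  tp1 <- fit_t_params(onehot)
  expect_equal(tp1$mu, 3)
  expect_equal(tp1$v, 0)
  expect_equal(tp1$nu, 200)

  # hand-computed: v = 1.2, nu = 2 * 1.2 / 0.2 = 12
  tp2 <- fit_t_params(list(omega = c(0.1, 0.2, 0.4, 0.2, 0.1)))
  expect_equal(tp2$mu, 3)
  expect_equal(tp2$v, 1.2, tolerance = 1e-12)
  expect_equal(tp2$nu, 12, tolerance = 1e-12)

  expect_equal(fit_t_params(iw5, nu_fixed = 1.5)$nu, 1.5)
  expect_error(fit_t_params(iw5, nu_fixed = -1), "positive")

  tps <- fit_t_params(list(omega = 1))          # single slice
  expect_equal(tps$mu, 1)
  expect_equal(tps$nu, 200)
})

test_that("the t density matches known closed forms and stats::dt", {
  xs <- seq(-8, 8, by = 0.25)
  cauchy <- 1 / (pi * (1 + xs^2))
  expect_lt(max(abs(t_pdf(xs + 2, list(mu = 2, nu = 1)) - cauchy)), 1e-12)

  for (nu in c(0.7, 2.5, 5, 30)) {
    tp <- list(mu = 4.2, nu = nu)
    expect_lt(max(abs(t_pdf(xs, tp) - dt(xs - 4.2, df = nu))), 1e-12)
    # symmetry about mu
    expect_equal(t_pdf(4.2 + 1.7, tp), t_pdf(4.2 - 1.7, tp), tolerance = 1e-14)
    # normalization by quadrature over a nu-appropriate wide interval
    # (tails heavier than nu ~ 2 need impractically wide grids)
    if (nu >= 2.5) {
      lim <- if (nu < 3) 1e5 else 1e3
      q <- integrate(function(x) t_pdf(x, tp), 4.2 - lim, 4.2 + lim,
                     rel.tol = 1e-10)
      expect_equal(q$value, 1, tolerance = 1e-6)
    }
  }
  expect_error(t_pdf(0, list(mu = 0, nu = 0)), "positive")
})

test_that("slice weights normalize the t density over integer positions", {
  expect_equal(slice_weights(1, list(mu = 1, nu = 5))$w, 1)

  tp <- list(mu = 3, nu = 4.4)
  w <- slice_weights(5, tp)$w
  dens <- ref_tpdf(1:5, 3, 4.4)
  expect_lt(max(abs(w - dens / sum(dens))), 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))

  # symmetric and unimodal around a central location; for even S the two
  # central slices tie at the mode
  for (S in c(3, 5, 8, 11)) for (nu in c(2.5, 5, 30)) {
    w <- slice_weights(S, list(mu = (S + 1) / 2, nu = nu))$w
    expect_equal(w, rev(w), tolerance = 1e-12)
    hi <- floor(S / 2) + 1L
    expect_true(all(diff(w[hi:S]) < 0))
    expect_gt(w[hi], w[1])
  }
})

test_that("applying weights rescales each slice and preserves structure", {
  set.seed(10)
  m <- array(rnorm(4 * 2 * 3 * 3), c(4, 2, 3, 3))
  u <- apply_weights(m, rep(1 / 4, 4))
  expect_equal(u, m / 4, tolerance = 1e-14)

  w0 <- c(0.5, 0, 0.3, 0.2)        # constructed zero, bypassing positivity
  z <- apply_weights(m, w0)
  expect_true(all(z[2, , , ] == 0))
  expect_lt(max(abs(z - ref_apply_weights(m, w0))), 1e-12)
  expect_equal(sign(z[1, , , ]), sign(m[1, , , ]))

  expect_error(apply_weights(m, c(1, 2)), "slices")
})

test_that("full chain matches the straight-loop reference and permutes covariantly", {
  set.seed(11)
  for (rep in 1:25) {
    S <- sample(2:6, 1); C <- sample(1:4, 1); HW <- sample(2:4, 1)
    m <- array(rnorm(S * C * HW * HW), c(S, C, HW, HW))
    st <- slice_attention(m)
    expect_lt(max(abs(st$weights$w - ref_chain_weights(m))), 1e-8)
    expect_lt(max(abs(st$weighted - ref_apply_weights(m, st$weights$w))), 1e-12)

    # omega is permutation-covariant (before the position-sensitive t fit)
    perm <- sample(S)
    st_p <- slice_attention(m[perm, , , , drop = FALSE], return_weighted = FALSE)
    expect_equal(st_p$initial$omega, st$initial$omega[perm], tolerance = 1e-10)
  }
})

test_that("uniform initial weights center the t location mid-stack", {
  for (S in c(3, 7, 20)) {
    tp <- fit_t_params(list(omega = rep(1 / S, S)))
    expect_equal(tp$mu, (S + 1) / 2, tolerance = 1e-12)
    w <- slice_weights(S, tp)$w
    expect_gt(w[ceiling(S / 2)], w[1])
    expect_gt(w[ceiling(S / 2)], w[S])
  }
})
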