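#' Pool per-slice feature maps into average and maximum descriptors
#'
#' Collapses the spatial axes of a stack of feature maps. The average
#' descriptor captures global context of each slice, while the maximum
#' descriptor captures its most salient local response; the pair feeds the
#' cross-similarity step of the slice-attention module.
#'
#' @param m numeric 4-D array of shape `S x C x H x W` (slices, channels,
#'   spatial rows, spatial columns). All values must be finite.
#' @return list with class `pooled_descriptors`: `avg` and `max`, each an
#'   `S x C` matrix.
#' @export
#' @examples
#' m <- array(rnorm(3 * 2 * 4 * 4), c(3, 2, 4, 4))
#' p <- pool_slice_features(m)
#' dim(p$avg)
pool_slice_features <- function(m) {
  if (!is.array(m) || length(dim(m)) != 4L)
    stop("`m` must be a 4-D array S x C x H x W", call. = FALSE)
  stop_if_not_finite(m, "m")
  d <- dim(m)
  S <- d[1L]; C <- d[2L]
  mm <- matrix(m, nrow = S * C)             # rows = (slice, channel) pairs
  avg <- matrix(rowMeans(mm), S, C)
  mx  <- matrix(mm[cbind(seq_len(S * C), max.col(mm, ties.method = "first"))],
                S, C)
  structure(list(avg = avg, max = mx), class = "pooled_descriptors")
}

#' Cross-similarity matrices between slices
#'
#' Builds two `S x S` row-stochastic similarity matrices from the pooled
#' descriptors: `s1` is the row-wise softmax of `avg %*% t(max)` and `s2`
#' the row-wise softmax of `max %*% t(avg)`. Each row is an attention
#' distribution of one slice over all slices.
#'
#' @param p a `pooled_descriptors` object (or list with `avg`, `max`
#'   matrices of identical shape).
#' @return list with class `similarity_pair`: matrices `s1` and `s2`.
#' @export
similarity_pair <- function(p) {
  avg <- as.matrix(p$avg); mx <- as.matrix(p$max)
  if (!identical(dim(avg), dim(mx)))
    stop("`avg` and `max` must have identical shape", call. = FALSE)
  stop_if_not_finite(avg, "avg"); stop_if_not_finite(mx, "max")
  s1 <- softmax_rows(avg %*% t(mx))
  s2 <- softmax_rows(mx %*% t(avg))
  structure(list(s1 = s1, s2 = s2), class = "similarity_pair")
}

#' Initial per-slice weights from the averaged similarity matrix
#'
#' Averages the two similarity matrices into `d = (s1 + s2) / 2` and reduces
#' `d` to one weight per slice by taking column means (how much attention
#' slice `s` receives from all slices), then normalizes to the simplex.
#' Summing over the other (row) index is degenerate: row sums of a
#' row-stochastic matrix are identically 1, which would force uniform
#' weights regardless of the input.
#'
#' @param sp a `similarity_pair` object.
#' @return list with class `initial_weights`: matrix `d` and normalized
#'   weight vector `omega` (sums to 1).
#' @export
initial_weights <- function(sp) {
  s1 <- sp$s1; s2 <- sp$s2
  if (!identical(dim(s1), dim(s2)) || nrow(s1) != ncol(s1))
    stop("similarity matrices must be square and of identical shape",
         call. = FALSE)
  d <- (s1 + s2) / 2
  raw <- colMeans(d)
  structure(list(d = d, omega = raw / sum(raw)), class = "initial_weights")
}

# Degenerate alternative reading: reduce d over its column index (row means).
# Row-stochasticity forces the result to be exactly uniform for any input;
# kept as an internal diagnostic of why the column reduction is the only
# informative one.
initial_weights_rowsum <- function(sp) {
  d <- (sp$s1 + sp$s2) / 2
  raw <- rowMeans(d)
  list(d = d, omega = raw / sum(raw))
}

#' Fit the location and degrees of freedom of the slice-position t-density
#'
#' Treats the initial weights as a probability mass over slice positions
#' `1..S` and moment-matches a Student-t: the location is the weighted mean
#' position `mu = sum(omega * s)`; the degrees of freedom come from the
#' weighted position variance `v` via `nu = 2 v / (v - 1)` (the t variance
#' identity `v = nu / (nu - 2)` inverted), clamped to `[nu_min, nu_max]`.
#' A variance `v <= 1` has no moment-matched solution with `nu > 2` and maps
#' to `nu_max` (a near-point weighting); `S = 1` is likewise degenerate.
#'
#' @param iw an `initial_weights` object (or list with `omega`).
#' @param nu_fixed optional positive value; when supplied it is used
#'   verbatim and no moment matching is performed.
#' @param nu_min,nu_max clamping bounds for the fitted degrees of freedom.
#'   The lower bound keeps the implied variance finite (`nu > 2`); the upper
#'   bound keeps the density away from a point spike.
#' @return list with class `t_params`: `mu`, `nu`, and the weighted
#'   position variance `v`.
#' @export
fit_t_params <- function(iw, nu_fixed = NULL, nu_min = 2.05, nu_max = 200) {
  omega <- iw$omega
  stop_if_not_finite(omega, "omega")
  if (any(omega < 0) || abs(sum(omega) - 1) > 1e-6)
    stop("`omega` must be a probability vector", call. = FALSE)
  S <- length(omega)
  pos <- seq_len(S)
  mu <- sum(omega * pos)
  v <- sum(omega * (pos - mu)^2)
  if (!is.null(nu_fixed)) {
    if (!is.numeric(nu_fixed) || nu_fixed <= 0)
      stop("`nu_fixed` must be positive", call. = FALSE)
    nu <- nu_fixed
  } else if (S == 1L || v <= 1) {
    nu <- nu_max
  } else {
    nu <- min(max(2 * v / (v - 1), nu_min), nu_max)
  }
  structure(list(mu = mu, nu = nu, v = v), class = "t_params")
}

#' Student-t probability density over slice positions
#'
#' The unit-scale, location-shifted Student-t density
#' \deqn{T(x; \mu, \nu) = \frac{\Gamma((\nu+1)/2)}{\Gamma(\nu/2)\sqrt{\nu\pi}}
#'   \left(1 + \frac{(x-\mu)^2}{\nu}\right)^{-(\nu+1)/2}.}
#' Evaluated through log-gamma for numerical stability. At `nu = 1` this is
#' the Cauchy density; as `nu` grows it approaches the unit normal.
#'
#' @param x numeric vector of evaluation points (slice positions).
#' @param tp a `t_params` object, or a list with `mu` and `nu`.
#' @return numeric vector of densities.
#' @export
t_pdf <- function(x, tp) {
  mu <- tp$mu; nu <- tp$nu
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("`nu` must be a positive finite scalar", call. = FALSE)
  stop_if_not_finite(x, "x")
  lc <- lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi)
  exp(lc - (nu + 1) / 2 * log1p((x - mu)^2 / nu))
}

#' Final attention weights from the fitted t-density
#'
#' Evaluates the fitted Student-t density at the integer slice positions
#' `1..s` and normalizes, so central slices (near the fitted location)
#' receive higher weight than end slices.
#'
#' @param s number of slices (>= 1).
#' @param tp a `t_params` object.
#' @return list with class `attention_weights`: weight vector `w`
#'   (positive, sums to 1) and the `t_params` used.
#' @export
slice_weights <- function(s, tp) {
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s))
    stop("`s` must be a positive integer", call. = FALSE)
  if (s == 1L) {
    w <- 1.0
  } else {
    dens <- t_pdf(seq_len(s), tp)
    w <- dens / sum(dens)
  }
  structure(list(w = w, t_params = tp), class = "attention_weights")
}

#' Re-weight a feature-map stack by per-slice attention weights
#'
#' Multiplies slice `s` of the feature map by `w[s]`, broadcasting over the
#' channel and spatial axes.
#'
#' @param m numeric 4-D array `S x C x H x W`.
#' @param aw an `attention_weights` object, or a numeric vector of length `S`.
#' @return array of the same shape as `m`.
#' @export
apply_weights <- function(m, aw) {
  w <- if (is.list(aw)) aw$w else aw
  if (!is.array(m) || length(dim(m)) != 4L)
    stop("`m` must be a 4-D array S x C x H x W", call. = FALSE)
  if (length(w) != dim(m)[1L])
    stop("length of weights must equal the number of slices", call. = FALSE)
  m * as.numeric(w)   # slice is the fastest-varying dimension
}

#' Full slice-attention chain
#'
#' Runs pooling, cross-similarity, initial weighting, the t fit, and the
#' final position weighting on one stack of per-slice feature maps, and
#' (optionally) returns the re-weighted stack.
#'
#' @param m numeric 4-D array `S x C x H x W` of backbone features.
#' @param nu_fixed,nu_min,nu_max passed to [fit_t_params()].
#' @param return_weighted if `TRUE` (default) include the re-weighted map.
#' @return list with class `attention_state`: `pooled`, `similarity`,
#'   `initial`, `t_params`, `weights`, and optionally `weighted`.
#' @export
slice_attention <- function(m, nu_fixed = NULL, nu_min = 2.05, nu_max = 200,
                            return_weighted = TRUE) {
  p  <- pool_slice_features(m)
  sp <- similarity_pair(p)
  iw <- initial_weights(sp)
  tp <- fit_t_params(iw, nu_fixed = nu_fixed, nu_min = nu_min, nu_max = nu_max)
  aw <- slice_weights(dim(m)[1L], tp)
  out <- list(pooled = p, similarity = sp, initial = iw,
              t_params = tp, weights = aw)
  if (return_weighted) out$weighted <- apply_weights(m, aw)
  structure(out, class = "attention_state")
}

#' @export
print.attention_state <- function(x, ...) {
  S <- length(x$weights$w)
  cat(sprintf("slice-attention state: S = %d, mu = %.3f, nu = %.3f\n",
              S, x$t_params$mu, x$t_params$nu))
  cat("weights:", format(round(x$weights$w, 4)), "\n")
  invisible(x)
}
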