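# Desk-scale convolutional backbone engine.
#
# A slice travels through the backbone as an H x W x C array (spatial
# first, channels last) so it maps directly onto the arma::cube layout of
# the compiled primitives.  Backbones are flat layer lists; the only
# stateful layers are 3x3 "same" convolutions and residual blocks.

#' Registry of available backbones
#'
#' All registry entries are small CPU-trainable networks: `tiny` (the
#' default; three conv blocks, ~3.6k parameters), `vgg_small` (VGG-style
#' double-conv blocks) and `resnet_small` (residual blocks). They are
#' initialized randomly; no pretrained weights are shipped.
#'
#' @return named list of backbone definitions (layer lists plus a
#'   one-line description).
#' @export
backbone_registry <- function() {
  list(
    tiny = list(
      description = "avgpool/4 + 3 conv blocks (8-16-16 channels)",
      layers = list(
        list(type = "avgpool", k = 4L),
        list(type = "conv", out = 8L), list(type = "relu"),
        list(type = "maxpool"),
        list(type = "conv", out = 16L), list(type = "relu"),
        list(type = "maxpool"),
        list(type = "conv", out = 16L), list(type = "relu"))),
    vgg_small = list(
      description = "VGG-style double-conv blocks (8-16-32 channels)",
      layers = list(
        list(type = "avgpool", k = 2L),
        list(type = "conv", out = 8L), list(type = "relu"),
        list(type = "conv", out = 8L), list(type = "relu"),
        list(type = "maxpool"),
        list(type = "conv", out = 16L), list(type = "relu"),
        list(type = "conv", out = 16L), list(type = "relu"),
        list(type = "maxpool"),
        list(type = "conv", out = 32L), list(type = "relu"))),
    resnet_small = list(
      description = "stem conv + two residual blocks (16 channels)",
      layers = list(
        list(type = "avgpool", k = 4L),
        list(type = "conv", out = 16L), list(type = "relu"),
        list(type = "resblock", ch = 16L),
        list(type = "maxpool"),
        list(type = "resblock", ch = 16L))))
}

# walk the layer list, tracking (H, W, C); errors on indivisible pooling
trace_backbone_shape <- function(layers, image_size, in_channels) {
  H <- image_size; W <- image_size; C <- in_channels
  for (ly in layers) {
    if (ly$type == "avgpool") {
      if (H %% ly$k != 0 || W %% ly$k != 0)
        stop("image size not divisible by avgpool factor", call. = FALSE)
      H <- H %/% ly$k; W <- W %/% ly$k
    } else if (ly$type == "maxpool") {
      if (H %% 2 != 0 || W %% 2 != 0)
        stop("image size not divisible by maxpool factor", call. = FALSE)
      H <- H %/% 2; W <- W %/% 2
    } else if (ly$type == "conv") {
      C <- ly$out
    } else if (ly$type == "resblock") {
      if (C != ly$ch) stop("resblock channel mismatch", call. = FALSE)
    }
  }
  list(C = C, H = H, W = W)
}

he_init <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout)
}

# one params entry per layer (NULL for stateless layers); uses current RNG
init_backbone_params <- function(layers, in_channels) {
  C <- in_channels
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      params[[i]] <- list(W = he_init(C, ly$out), b = rep(0, ly$out))
      C <- ly$out
    } else if (ly$type == "resblock") {
      params[[i]] <- list(W1 = he_init(ly$ch, ly$ch), b1 = rep(0, ly$ch),
                          W2 = he_init(ly$ch, ly$ch), b2 = rep(0, ly$ch))
    }
  }
  params
}

# Forward over a whole exam at once: `x` is an (H, W, C*S) array, the S
# slices stacked along the channel axis; `in_channels` is the per-slice
# channel count at the input.  Pooling and relu act per 2-D plane and need
# no knowledge of the grouping; convolutions are told the per-slice
# channel count so each slice keeps its own receptive field.
backbone_forward <- function(layers, params, x, in_channels,
                             keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  C <- in_channels
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (keep_cache) cache[[i]] <- list(x = x, cin = C)
      x <- cpp_conv3x3_fwd(x, C, params[[i]]$W, params[[i]]$b)
      C <- ly$out
    } else if (ly$type == "relu") {
      if (keep_cache) cache[[i]] <- list(mask = x > 0)
      x <- pmax(x, 0)
    } else if (ly$type == "maxpool") {
      mp <- cpp_maxpool2_fwd(x)
      if (keep_cache) cache[[i]] <- list(idx = mp$idx, H = dim(x)[1], W = dim(x)[2])
      x <- mp$Y
    } else if (ly$type == "avgpool") {
      if (keep_cache) cache[[i]] <- list(H = dim(x)[1], W = dim(x)[2])
      x <- cpp_avgpool_fwd(x, ly$k)
    } else if (ly$type == "resblock") {
      p <- params[[i]]
      a1 <- cpp_conv3x3_fwd(x, C, p$W1, p$b1)
      r1 <- pmax(a1, 0)
      a2 <- cpp_conv3x3_fwd(r1, C, p$W2, p$b2)
      pre <- x + a2
      if (keep_cache) cache[[i]] <- list(x = x, cin = C, mask1 = a1 > 0,
                                         r1 = r1, mask_out = pre > 0)
      x <- pmax(pre, 0)
    } else stop("unknown layer type: ", ly$type, call. = FALSE)
  }
  list(out = x, cache = cache)
}

backbone_backward <- function(layers, params, cache, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; cc <- cache[[i]]
    if (ly$type == "conv") {
      bw <- cpp_conv3x3_bwd(cc$x, cc$cin, params[[i]]$W, dy)
      grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
      dy <- bw$dX
    } else if (ly$type == "relu") {
      dy <- dy * cc$mask
    } else if (ly$type == "maxpool") {
      dy <- cpp_maxpool2_bwd(cc$idx, dy, cc$H, cc$W)
    } else if (ly$type == "avgpool") {
      dy <- cpp_avgpool_bwd(dy, ly$k, cc$H, cc$W)
    } else if (ly$type == "resblock") {
      p <- params[[i]]
      dpre <- dy * cc$mask_out
      bw2 <- cpp_conv3x3_bwd(cc$r1, cc$cin, p$W2, dpre)
      da1 <- bw2$dX * cc$mask1
      bw1 <- cpp_conv3x3_bwd(cc$x, cc$cin, p$W1, da1)
      grads[[i]] <- list(W1 = bw1$dW, b1 = as.numeric(bw1$db),
                         W2 = bw2$dW, b2 = as.numeric(bw2$db))
      dy <- dpre + bw1$dX
    }
  }
  list(dx = dy, grads = grads)
}

# ---- generic param-tree arithmetic (params are nested lists of numerics)

tree_map <- function(f, a, b = NULL) {
  if (is.null(a)) return(NULL)
  if (is.list(a))
    return(mapply(function(x, y) tree_map(f, x, y),
                  a, if (is.null(b)) vector("list", length(a)) else b,
                  SIMPLIFY = FALSE))
  f(a, b)
}

tree_zeros <- function(params) tree_map(function(a, b) a * 0, params)

tree_add <- function(a, b) tree_map(function(x, y) x + y, a, b)

tree_sum_abs <- function(a) {
  s <- 0
  walk <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) { lapply(x, walk); return(invisible(NULL)) }
    s <<- s + sum(abs(x))
    invisible(NULL)
  }
  walk(a)
  s
}

tree_global_norm <- function(a) {
  s <- 0
  walk <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) { lapply(x, walk); return(invisible(NULL)) }
    s <<- s + sum(x^2)
    invisible(NULL)
  }
  walk(a)
  sqrt(s)
}

n_params <- function(params) {
  s <- 0
  walk <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) { lapply(x, walk); return(invisible(NULL)) }
    s <<- s + length(x)
    invisible(NULL)
  }
  walk(params)
  s
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                  state$m, state$v)
  params <- tree_map(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}
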