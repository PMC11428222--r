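# Straight-loop reference implementations used as independent oracles.
# Deliberately written with explicit loops and without reusing any package
# internals, so they stay independent of the code paths they check.

ref_pool <- function(m) {
  d <- dim(m)
  avg <- matrix(0, d[1], d[2])
  mx <- matrix(-Inf, d[1], d[2])
  for (s in seq_len(d[1])) for (cc in seq_len(d[2])) {
    acc <- 0
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      acc <- acc + m[s, cc, h, w]
      if (m[s, cc, h, w] > mx[s, cc]) mx[s, cc] <- m[s, cc, h, w]
    }
    avg[s, cc] <- acc / (d[3] * d[4])
  }
  list(avg = avg, max = mx)
}

ref_softmax_rows <- function(z) {
  out <- z
  for (i in seq_len(nrow(z))) {
    e <- exp(z[i, ] - max(z[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

ref_similarity <- function(p) {
  list(s1 = ref_softmax_rows(p$avg %*% t(p$max)),
       s2 = ref_softmax_rows(p$max %*% t(p$avg)))
}

ref_initial <- function(sp) {
  d <- (sp$s1 + sp$s2) / 2
  S <- nrow(d)
  raw <- numeric(S)
  for (s in seq_len(S)) {
    acc <- 0
    for (k in seq_len(S)) acc <- acc + d[k, s]
    raw[s] <- acc / S
  }
  list(d = d, omega = raw / sum(raw))
}

ref_tpdf <- function(x, mu, nu) {
  gamma((nu + 1) / 2) / (gamma(nu / 2) * sqrt(nu * pi)) *
    (1 + (x - mu)^2 / nu)^(-(nu + 1) / 2)
}

ref_fit <- function(omega, nu_min = 2.05, nu_max = 200) {
  S <- length(omega)
  mu <- sum(omega * seq_len(S))
  v <- sum(omega * (seq_len(S) - mu)^2)
  nu <- if (S == 1 || v <= 1) nu_max else min(max(2 * v / (v - 1), nu_min), nu_max)
  list(mu = mu, nu = nu)
}

ref_chain_weights <- function(m) {
  p <- ref_pool(m)
  sp <- ref_similarity(p)
  iw <- ref_initial(sp)
  tp <- ref_fit(iw$omega)
  S <- dim(m)[1]
  dens <- ref_tpdf(seq_len(S), tp$mu, tp$nu)
  dens / sum(dens)
}

ref_apply_weights <- function(m, w) {
  out <- m
  d <- dim(m)
  for (s in seq_len(d[1])) out[s, , , ] <- w[s] * m[s, , , ]
  out
}

# O(n^2) pairwise (Mann-Whitney) AUC with ties counted one half
ref_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(pos) * length(neg))
}

# exhaustive accuracy search over all midpoint thresholds
ref_adaptive_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_t <- cands[1]
  best_a <- -1
  for (t in cands) {
    a <- mean((scores > t) == labels)
    if (a > best_a + 1e-15) { best_a <- a; best_t <- t }
  }
  best_t
}

# independent dense forward pass of the tiny backbone on one slice
# (H x W matrix input, single input channel), explicit loops throughout
ref_conv3x3 <- function(x, W, b) {
  # x: H x W x Cin, W: (9*Cin) x Cout with column index (c-1)*9 + (dj+1)*3 + di + 2
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(W)
  out <- array(0, c(H, Wd, Cout))
  for (k in seq_len(Cout)) {
    for (i in seq_len(H)) for (j in seq_len(Wd)) {
      acc <- b[k]
      for (cc in seq_len(Cin)) for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
          row <- (cc - 1) * 9 + (dj + 1) * 3 + (di + 1) + 1
          acc <- acc + x[ii, jj, cc] * W[row, k]
        }
      }
      out[i, j, k] <- acc
    }
  }
  out
}

ref_maxpool2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (cc in seq_len(d[3]))
    for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2))
      out[i, j, cc] <- max(x[2 * i - 1:0, 2 * j - 1:0, cc])
  out
}

ref_avgpool <- function(x, k) {
  d <- dim(x)
  out <- array(0, c(d[1] / k, d[2] / k, d[3]))
  for (cc in seq_len(d[3]))
    for (i in seq_len(d[1] / k)) for (j in seq_len(d[2] / k))
      out[i, j, cc] <- mean(x[(k * (i - 1) + 1):(k * i),
                              (k * (j - 1) + 1):(k * j), cc])
  out
}

# reference forward of the 'tiny' backbone for a single-channel slice
ref_tiny_backbone <- function(img, params) {
  x <- array(img, c(dim(img), 1))
  x <- ref_avgpool(x, 4)
  x <- ref_conv3x3(x, params[[2]]$W, params[[2]]$b); x <- pmax(x, 0)
  x <- ref_maxpool2(x)
  x <- ref_conv3x3(x, params[[5]]$W, params[[5]]$b); x <- pmax(x, 0)
  x <- ref_maxpool2(x)
  x <- ref_conv3x3(x, params[[8]]$W, params[[8]]$b); x <- pmax(x, 0)
  x
}

# small random stack helper
random_stack <- function(S, n = 16) array(runif(S * n * n), c(S, n, n))
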