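# Independent oracles used across tests.

# Direct triple-loop 3D convolution, independent of the im2col kernel.
# x: (C,H,W,D,B); w: (C,KH,KW,KD,Cout); b: length Cout or NULL.
naive_conv3d <- function(x, w, b, stride, pad) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; D <- d[4]; B <- d[5]
  K <- dim(w)[2:4]; Cout <- dim(w)[5]; S <- stride; P <- pad
  OH <- (H + 2 * P[1] - K[1]) %/% S[1] + 1
  OW <- (W + 2 * P[2] - K[2]) %/% S[2] + 1
  OD <- (D + 2 * P[3] - K[3]) %/% S[3] + 1
  out <- array(0, c(Cout, OH, OW, OD, B))
  for (bb in seq_len(B)) for (co in seq_len(Cout))
    for (oh in seq_len(OH)) for (ow in seq_len(OW)) for (od in seq_len(OD)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (kh in seq_len(K[1])) for (kw in seq_len(K[2])) for (kd in seq_len(K[3])) {
        ih <- (oh - 1) * S[1] - P[1] + kh
        iw <- (ow - 1) * S[2] - P[2] + kw
        id <- (od - 1) * S[3] - P[3] + kd
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W && id >= 1 && id <= D)
          acc <- acc + sum(x[, ih, iw, id, bb] * w[, kh, kw, kd, co])
      }
      out[co, oh, ow, od, bb] <- acc
    }
  out
}

# Textbook product-moment correlation (no shortcuts), for oracle use.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) 0 else num / den
}

# Central-difference gradient of scalar function f at x (a numeric array),
# evaluated at the linear indices `at`.
numeric_grad <- function(f, x, at, eps = 1e-6) {
  vapply(at, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Small random BOLD volume + matching blocky atlas.
make_toy_volume <- function(grid = c(6, 6, 6), nt = 10, seed = 1) {
  set.seed(seed)
  volume4d(array(rnorm(prod(grid) * nt), c(grid, nt)))
}
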