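# Independent oracles used to check the package's linear algebra. They
# deliberately take different computational routes from the implementation:
# SVD pseudoinverse normal equations instead of QR projection, explicit
# residualization instead of the subtraction scheme, scalar loops instead
# of vectorized distance code.

# Moore-Penrose pseudoinverse via SVD
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# rank via SVD
svd_rank <- function(A, tol = 1e-8) {
  if (ncol(A) == 0) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * max(d, 1))
}

# unadjusted R2 by explicit normal equations (fit each response column)
oracle_r2 <- function(Y, X) {
  Y <- as.matrix(Y)
  if (is.null(X) || ncol(as.matrix(X)) == 0) return(0)
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X), "-")
  B <- pinv(Xc) %*% Y
  fit <- Xc %*% B
  sum(fit^2) / sum(Y^2)
}

# residual of Y after regressing out block X (explicit pinv fit)
oracle_residualize <- function(Y, X) {
  Y <- as.matrix(Y)
  if (is.null(X) || ncol(as.matrix(X)) == 0) return(Y)
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X), "-")
  Y - Xc %*% (pinv(Xc) %*% Y)
}

# two-component partition fractions via explicit residualization: the
# semipartial increment R2(X | W) is computed by regressing the residuals
# of Y on W onto the residualized X, never by subtracting full-model R2s.
oracle_varpart <- function(Yt, X, W) {
  Yt <- as.matrix(Yt)
  n <- nrow(Yt)
  tot <- sum(Yt^2)
  Xm <- as.matrix(X); Wm <- as.matrix(W)
  Xc <- sweep(Xm, 2, colMeans(Xm), "-")
  Wc <- sweep(Wm, 2, colMeans(Wm), "-")
  r2x <- oracle_r2(Yt, Xc)
  r2w <- oracle_r2(Yt, Wc)
  Yres_w <- oracle_residualize(Yt, Wc)
  Xres_w <- oracle_residualize(Xc, Wc)
  inc_x_given_w <- sum((Xres_w %*% (pinv(Xres_w) %*% Yres_w))^2) / tot
  r2_full <- r2w + inc_x_given_w
  mx <- svd_rank(Xc); mw <- svd_rank(Wc); mf <- svd_rank(cbind(Xc, Wc))
  adj <- function(r2, m) if (m == 0) r2 else 1 - (1 - r2) * (n - 1) / (n - m - 1)
  A <- adj(r2x, mx); C <- adj(r2w, mw); Tt <- adj(r2_full, mf)
  c(frac_a = Tt - C, frac_b = A + C - Tt, frac_c = Tt - A, frac_d = 1 - Tt)
}

# brute-force Prim: scan all crossing edges at every step
oracle_prim_max_edge <- function(D) {
  n <- nrow(D)
  intree <- 1L
  maxe <- 0
  while (length(intree) < n) {
    best <- Inf; bj <- NA
    for (i in intree) for (j in setdiff(seq_len(n), intree)) {
      if (D[i, j] < best) { best <- D[i, j]; bj <- j }
    }
    maxe <- max(maxe, best)
    intree <- c(intree, bj)
  }
  maxe
}

# dense PCNM oracle: explicit centering matrix H = I - 11'/n, G = H A H
oracle_pcnm <- function(D, truncation) {
  n <- nrow(D)
  Dstar <- D
  Dstar[D > truncation] <- 4 * truncation
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  H <- diag(n) - matrix(1 / n, n, n)
  G <- H %*% A %*% H
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  V <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(vectors = V, values = e$values[keep])
}

# compare two bases column-by-column up to sign
expect_basis_equal <- function(V1, V2, tol = 1e-8) {
  expect_equal(dim(V1), dim(V2))
  for (j in seq_len(ncol(V1))) {
    d <- min(max(abs(V1[, j] - V2[, j])), max(abs(V1[, j] + V2[, j])))
    expect_lt(d, tol)
  }
}

# small random test instances (fixed-seed draws)
random_instance <- function(seed, n = 30, p = 5, mx = 2, mw = 2) {
  set.seed(seed)
  Y <- matrix(rnorm(n * p), n, p)
  Yt <- sweep(Y, 2, colMeans(Y), "-")
  list(Yt = Yt,
       X = matrix(rnorm(n * mx), n, mx),
       W = matrix(rnorm(n * mw), n, mw))
}

# a tiny valid community matrix fixture
tiny_community <- function(seed = 1, n = 10, S = 6) {
  set.seed(seed)
  m <- matrix(rpois(n * S, 4) + 1, n, S,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("sp", seq_len(S))))
  community_matrix(m)
}
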