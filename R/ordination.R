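# Redundancy analysis, Ezekiel-adjusted R2, and the two-component variation
# partition (pure environment [a], shared [b], pure space [c], residual [d]).
#
# RDA reduces to multivariate least squares: R2 = SS(fitted)/SS(total) with
# the fitted values the projection of the centered response onto the column
# space of the centered (and here standardized) predictor block. Fractions
# are differences of Ezekiel-adjusted R2 of the three nested models.

#' Transform a community matrix for ordination
#'
#' Applies the selected abundance transform and then column-centers, yielding
#' a response suitable for least-squares ordination. Under `"hellinger"` each
#' cell becomes the square root of its relative abundance within the site;
#' rows whose total is zero are left all-zero with a warning. Under
#' `"presence_absence"` cells become 0/1.
#'
#' @param Y a [community_matrix] (or plain non-negative matrix).
#' @param mode `"hellinger"`, `"presence_absence"` or `"none"`.
#' @return a column-centered numeric matrix with attribute `transform_used`.
#' @export
transform_response <- function(Y, mode = c("hellinger", "presence_absence",
                                           "none")) {
  mode <- match.arg(mode)
  Y <- unclass(as.matrix(Y))
  storage.mode(Y) <- "double"
  V <- switch(mode,
    hellinger = {
      rt <- rowSums(Y)
      zero <- rt == 0
      if (any(zero))
        warning("hellinger: ", sum(zero), " site(s) with zero total left all-zero")
      rt[zero] <- 1
      sqrt(sweep(Y, 1, rt, "/"))
    },
    presence_absence = (Y > 0) * 1.0,
    none = Y)
  ctr <- colMeans(V)
  V <- sweep(V, 2, ctr, "-")
  attr(V, "transform_used") <- mode
  V
}

# Center, drop (numerically) constant columns, scale the rest to unit sd.
# R2 is invariant to this; it only stabilizes conditioning.
.prep_block <- function(X, n) {
  X <- .as_block(X, n)
  if (ncol(X) == 0L) return(X)
  if (nrow(X) != n) stop("predictor block has ", nrow(X), " rows, expected ", n)
  X <- sweep(X, 2, colMeans(X), "-")
  ss <- sqrt(colSums(X^2) / (n - 1))
  keep <- ss > 1e-12 * max(ss, 1)
  X <- X[, keep, drop = FALSE]
  if (ncol(X)) X <- sweep(X, 2, ss[keep], "/")
  X
}

# Coerce the block types the package produces into a plain numeric matrix.
.as_block <- function(X, n) {
  if (is.null(X)) return(matrix(numeric(0), n, 0))
  if (inherits(X, "pcnm_basis")) X <- X$vectors
  if (inherits(X, "pca_axes")) X <- X$scores
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
  X <- unclass(as.matrix(X))
  storage.mode(X) <- "double"
  X
}

# Projection R2 of a centered response onto a predictor block's column space.
.project_r2 <- function(Yt, X) {
  n <- nrow(Yt)
  tot <- sum(Yt^2)
  if (tot <= 0) stop("zero-variance response (all-constant community)")
  Xs <- .prep_block(X, n)
  if (ncol(Xs) == 0L) return(list(r2 = 0, rank = 0L))
  qx <- qr(Xs)
  r <- qx$rank
  if (n <= r + 1)
    stop("saturated model: ", n, " sites for a predictor block of rank ", r)
  fit <- qr.fitted(qx, Yt)
  list(r2 = sum(fit^2) / tot, rank = as.integer(r))
}

#' Unadjusted RDA R-squared
#'
#' Fraction of the total sum of squares of a column-centered response
#' explained by least-squares projection onto the column space of the
#' predictor block. Rank-deficient blocks are handled by projecting onto the
#' effective column space. An empty block (zero columns) returns 0.
#'
#' @param Yt a column-centered response matrix (see [transform_response()]).
#' @param X predictor block: matrix, data frame, [pcnm] basis or [pca_reduce]
#'   axes; `NULL` or zero columns give the null model.
#' @return a proportion in \[0, 1\].
#' @export
rda_r2 <- function(Yt, X) {
  .project_r2(as.matrix(Yt), X)$r2
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - m - 1)`, the small-sample correction that
#' makes explained fractions from models of different sizes comparable.
#' With `m = 0` the input is returned unchanged.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of sites.
#' @param m number of (effective) predictors.
#' @return the adjusted value; can be negative.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (m < 0) stop("m must be non-negative")
  if (m == 0) return(r2)
  if (n <= m + 1) stop("adjusted_r2 undefined: n <= m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Two-component variation partitioning by partial RDA
#'
#' Partitions the variance of a transformed community matrix between an
#' environmental block `X` and a spatial block `W`. With `A`, `C`, `T` the
#' Ezekiel-adjusted R-squared of the models `Y ~ X`, `Y ~ W` and `Y ~ X+W`
#' (each adjusted with the effective rank of its block), the fractions are
#' `a = T - C` (pure environment), `c = T - A` (pure space),
#' `b = A + C - T` (shared), `d = 1 - T` (residual). Negative adjusted
#' fractions are reported as-is, flagged, never clamped, so
#' `a + b + c + d = 1` holds exactly.
#'
#' @param Yt transformed response from [transform_response()].
#' @param X environmental predictor block.
#' @param W spatial predictor block.
#' @return an object of class `"varpart2"`: unadjusted `r2_env`, `r2_space`,
#'   `r2_full`; adjusted `adj_r2_env`, `adj_r2_space`, `adj_r2_full`;
#'   fractions `frac_a`, `frac_b`, `frac_c`, `frac_d`; sizes `n_sites`,
#'   `m_env`, `m_space`, `m_full`; `negative_fractions` flag vector.
#' @export
varpart2 <- function(Yt, X, W) {
  Yt <- as.matrix(Yt)
  n <- nrow(Yt)
  Xb <- .as_block(X, n); Wb <- .as_block(W, n)
  pX <- .project_r2(Yt, Xb)
  pW <- .project_r2(Yt, Wb)
  pT <- .project_r2(Yt, cbind(Xb, Wb))
  A <- adjusted_r2(pX$r2, n, pX$rank)
  C <- adjusted_r2(pW$r2, n, pW$rank)
  Tt <- adjusted_r2(pT$r2, n, pT$rank)
  fr <- c(frac_a = Tt - C, frac_b = A + C - Tt, frac_c = Tt - A,
          frac_d = 1 - Tt)
  out <- list(
    r2_env = pX$r2, r2_space = pW$r2, r2_full = pT$r2,
    adj_r2_env = A, adj_r2_space = C, adj_r2_full = Tt,
    frac_a = fr[["frac_a"]], frac_b = fr[["frac_b"]],
    frac_c = fr[["frac_c"]], frac_d = fr[["frac_d"]],
    n_sites = n, m_env = pX$rank, m_space = pW$rank, m_full = pT$rank,
    negative_fractions = names(fr)[fr < 0],
    transform = attr(Yt, "transform_used") %||% NA_character_
  )
  class(out) <- "varpart2"
  out
}

#' @export
print.varpart2 <- function(x, digits = 4, ...) {
  cat("Two-component variation partitioning (pRDA)\n")
  cat(sprintf("  n = %d sites, %d env / %d spatial predictors (effective rank)\n",
              x$n_sites, x$m_env, x$m_space))
  cat(sprintf("  R2 (unadjusted): env %.*f  space %.*f  full %.*f\n",
              digits, x$r2_env, digits, x$r2_space, digits, x$r2_full))
  tab <- data.frame(
    fraction = c("[a] pure environment", "[b] shared",
                 "[c] pure space", "[d] residual"),
    adjusted = round(c(x$frac_a, x$frac_b, x$frac_c, x$frac_d), digits)
  )
  print(tab, row.names = FALSE)
  if (length(x$negative_fractions))
    cat("  note: negative adjusted fraction(s): ",
        paste(x$negative_fractions, collapse = ", "), "\n", sep = "")
  invisible(x)
}
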