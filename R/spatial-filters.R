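# PCNM spatial eigenvectors: principal coordinates of a truncated inter-site
# distance matrix. Distances above the truncation are set to 4*t; the
# truncated matrix is Gower-centered and eigendecomposed; positive-eigenvalue
# vectors become the spatial predictor block.

#' Pairwise inter-site distances
#'
#' Euclidean distances for planar coordinates; great-circle (haversine)
#' distances in kilometres for longitude/latitude, with Earth radius
#' 6371.0088 km.
#'
#' @param coords a [site_coords] object.
#' @return a symmetric distance matrix with zero diagonal, labelled by site.
#' @export
pairwise_distances <- function(coords) {
  if (!inherits(coords, "site_coords"))
    stop("coords must be a site_coords object")
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 sites")
  xy <- cbind(coords$x, coords$y)
  if (attr(coords, "crs_mode") == "lonlat") {
    ii <- rep(seq_len(n), times = n)
    jj <- rep(seq_len(n), each = n)
    d <- geosphere::distHaversine(xy[ii, , drop = FALSE],
                                  xy[jj, , drop = FALSE],
                                  r = 6371.0088)
    D <- matrix(d, n, n)
    D[cbind(seq_len(n), seq_len(n))] <- 0
  } else {
    D <- as.matrix(stats::dist(xy))
  }
  off <- D[upper.tri(D)]
  if (any(off == 0)) stop("coincident sites in distance matrix")
  dimnames(D) <- list(coords$site, coords$site)
  D
}

#' Default PCNM truncation distance
#'
#' The longest edge of a minimum spanning tree over the complete distance
#' graph — the smallest threshold keeping all sites connected. Prim's
#' algorithm with smallest-index tie-breaking, so the result is
#' deterministic for tied edge weights.
#'
#' @param dist a symmetric distance matrix.
#' @return the maximum MST edge weight.
#' @export
mst_truncation <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 sites")
  intree <- logical(n)
  intree[1L] <- TRUE
  best <- D[1L, ]
  best[1L] <- Inf
  maxedge <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    maxedge <- max(maxedge, best[j])
    intree[j] <- TRUE
    upd <- !intree & D[j, ] < best  # strict '<' keeps the earlier parent on ties
    best[upd] <- D[j, upd]
  }
  maxedge
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Builds spatial eigenvector predictors from a distance matrix. Distances
#' above the truncation `t` (default: longest MST edge) are replaced by
#' `4 t`; the result is Gower-centered (`-D*^2 / 2`, double-centered) and
#' eigendecomposed. Eigenvectors with eigenvalue greater than
#' `1e-9 * max(eigenvalue)` are kept, each scaled to norm
#' `sqrt(eigenvalue)`. Columns are centered and mutually orthogonal; any
#' column's sign is arbitrary, and downstream R-squared values are invariant
#' to sign flips.
#'
#' @param dist symmetric distance matrix (see [pairwise_distances()]).
#' @param truncation truncation distance; `NULL` for the MST default.
#' @param metric label recorded in the result (`"euclidean"` or
#'   `"haversine_km"`).
#' @return an object of class `"pcnm_basis"`: `vectors` (sites x k),
#'   `values` (descending positive eigenvalues), `truncation`,
#'   `metric_used`.
#' @export
pcnm <- function(dist, truncation = NULL, metric = "euclidean") {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 sites")
  if (is.null(truncation)) truncation <- mst_truncation(D)
  if (truncation <= 0) stop("truncation must be positive")
  Dstar <- ifelse(D <= truncation, D, 4 * truncation)
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  G <- sweep(sweep(A, 1, rowMeans(A), "-"), 2, colMeans(A), "-") + mean(A)
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  if (!any(keep)) stop("degenerate geometry: no positive eigenvalue")
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lam), nrow = length(lam))
  dimnames(V) <- list(rownames(D), paste0("V", seq_along(lam)))
  structure(list(vectors = V, values = lam, truncation = truncation,
                 metric_used = metric),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d vectors over %d sites (%s)\n",
              ncol(x$vectors), nrow(x$vectors), x$metric_used))
  cat(sprintf("  truncation distance: %g\n", x$truncation))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a PCNM basis to CSV
#'
#' Site label column plus `V1..Vk` columns; the truncation and eigenvalues
#' are written as commented header lines.
#'
#' @param basis a `"pcnm_basis"` object.
#' @param path output file path.
#' @export
write_pcnm <- function(basis, path) {
  hdr <- c(sprintf("# truncation=%.17g metric=%s",
                   basis$truncation, basis$metric_used),
           sprintf("# eigenvalue %s=%.17g",
                   colnames(basis$vectors), basis$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(site = rownames(basis$vectors), basis$vectors,
                   check.names = FALSE)
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
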