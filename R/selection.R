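# Predictor reduction chain: coefficient-of-variation screening of the raw
# environmental battery, permutation forward selection against the community,
# and principal-component reduction of the selected set.

#' Coefficient-of-variation screening of environmental variables
#'
#' CV is computed as `100 * sd / |mean|` (sample sd, denominator n-1).
#' Variables with CV strictly below `cv_low` are dropped as uninformative;
#' variables with CV strictly above `cv_high` are dropped as dominated by
#' zeros or outliers. Boundary values are kept. Variables with
#' `|mean| < 1e-12` get infinite CV and fall in the high-CV bin. The screen
#' is invariant to positive rescaling of any variable.
#'
#' @param env an [env_matrix].
#' @param cv_low,cv_high bounds in percent (defaults 40 and 80).
#' @return an object of class `"screening_report"`: `cv_values` (named, in
#'   percent), `kept`, `dropped_low`, `dropped_high`.
#' @export
cv_screen <- function(env, cv_low = 40, cv_high = 80) {
  X <- unclass(as.matrix(env))
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  cv <- ifelse(abs(mu) < 1e-12, Inf, 100 * s / abs(mu))
  names(cv) <- colnames(X)
  low <- cv < cv_low
  high <- cv > cv_high
  out <- list(cv_values = cv,
              kept = colnames(X)[!low & !high],
              dropped_low = colnames(X)[low],
              dropped_high = colnames(X)[high],
              cv_low = cv_low, cv_high = cv_high)
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("CV screening [%g%%, %g%%]: kept %d, dropped %d low-CV, %d high-CV\n",
              x$cv_low, x$cv_high, length(x$kept),
              length(x$dropped_low), length(x$dropped_high)))
  invisible(x)
}

#' Permutation forward selection of predictors for a multivariate response
#'
#' Greedy forward selection: at each step the candidate giving the largest
#' increase in unadjusted R-squared enters, subject to two stopping rules
#' (double stopping): a permutation test at level `alpha`, and a ceiling on
#' the cumulative adjusted R-squared at the adjusted R-squared of the global
#' model containing all candidates. The ceiling is checked after a
#' significant variable enters, halting further selection; a variable that
#' passes the permutation test is never discarded by the ceiling, so a lone
#' strong predictor among many noise candidates (which can drag the global
#' adjusted R-squared below its own) is still selected.
#'
#' The permutation statistic is the maximum R-squared increment over all
#' remaining candidates, recomputed for each row permutation of the current
#' partial residuals of `Yt`. Comparing max to max keeps the probability of
#' admitting any variable on pure-noise candidates close to `alpha`
#' regardless of how many candidates compete; testing only the winning
#' candidate against a single-candidate null would be anti-conservative.
#'
#' @param Yt transformed response from [transform_response()].
#' @param candidates labelled predictor block (matrix, data frame or
#'   [pcnm] basis).
#' @param alpha significance level for entry (default 0.05).
#' @param nperm number of permutations (at least 19; default 999).
#' @param seed integer seed; results are deterministic given the seed.
#' @param use_global_stop apply the adjusted-R-squared ceiling (default
#'   `TRUE`).
#' @return an object of class `"forward_selection"`: `order` (labels in
#'   inclusion order), `pvalues`, `r2_path` (cumulative unadjusted,
#'   strictly increasing), `adj_r2_path`, `stop_reason`
#'   (`"alpha"`, `"global_adjr2"` or `"exhausted"`), `global_adj_r2`.
#' @export
forward_select <- function(Yt, candidates, alpha = 0.05, nperm = 999L,
                           seed = 1L, use_global_stop = TRUE) {
  Yt <- as.matrix(Yt)
  n <- nrow(Yt)
  if (nperm < 19) stop("nperm must be at least 19")
  C0 <- .as_block(candidates, n)
  if (is.null(colnames(C0)) && ncol(C0))
    colnames(C0) <- paste0("v", seq_len(ncol(C0)))
  empty <- structure(list(order = character(0), pvalues = numeric(0),
                          r2_path = numeric(0), adj_r2_path = numeric(0),
                          stop_reason = "exhausted",
                          global_adj_r2 = NA_real_),
                     class = "forward_selection")
  if (ncol(C0) == 0L) return(empty)
  set.seed(as.integer(seed))
  totss <- sum(Yt^2)
  if (totss <= 0) stop("zero-variance response")
  pG <- .project_r2(Yt, C0)
  global_adj <- adjusted_r2(pG$r2, n, pG$rank)

  # working copies: columns centered/scaled, then residualized as variables
  # enter; Yres holds the partial residuals of Yt on the selected block
  Cres <- .prep_block(C0, n)
  labs <- colnames(Cres)
  Yres <- Yt
  avail <- seq_len(ncol(Cres))
  sel <- integer(0); pvals <- r2path <- adjpath <- numeric(0)
  r2_cum <- 0
  stop_reason <- "exhausted"
  inc_stats <- function(Cm, Ym, norms2) {
    # R2 increment (in SS units) for each candidate, candidates orthogonal
    # to the selected block by construction
    rowSums(crossprod(Cm, Ym)^2) / norms2
  }
  while (length(avail)) {
    Ca <- Cres[, avail, drop = FALSE]
    norms2 <- colSums(Ca^2)
    live <- norms2 > 1e-10
    if (!any(live)) { stop_reason <- "exhausted"; break }
    norms2[!live] <- Inf
    stat <- inc_stats(Ca, Yres, norms2)
    obs <- max(stat)
    if (obs <= totss * 1e-12) { stop_reason <- "exhausted"; break }
    pick <- avail[which.max(stat)]
    exceed <- 0L
    for (b in seq_len(nperm)) {
      Yp <- Yres[sample.int(n), , drop = FALSE]
      if (max(inc_stats(Ca, Yp, norms2)) >= obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (nperm + 1)
    if (p > alpha) { stop_reason <- "alpha"; break }
    r2_new <- r2_cum + obs / totss
    adj_new <- adjusted_r2(min(r2_new, 1), n, length(sel) + 1L)
    sel <- c(sel, pick)
    pvals <- c(pvals, p)
    r2path <- c(r2path, r2_new)
    adjpath <- c(adjpath, adj_new)
    r2_cum <- r2_new
    u <- Cres[, pick] / sqrt(sum(Cres[, pick]^2))
    Yres <- Yres - u %*% crossprod(u, Yres)
    avail <- setdiff(avail, pick)
    if (length(avail))
      Cres[, avail] <- Cres[, avail, drop = FALSE] -
        u %*% crossprod(u, Cres[, avail, drop = FALSE])
    if (use_global_stop && adj_new > global_adj + 1e-12) {
      stop_reason <- "global_adjr2"; break
    }
  }
  structure(list(order = labs[sel], pvalues = pvals, r2_path = r2path,
                 adj_r2_path = adjpath, stop_reason = stop_reason,
                 global_adj_r2 = global_adj),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection: %d variable(s), stop = %s (global adj R2 %.4f)\n",
              length(x$order), x$stop_reason, x$global_adj_r2))
  if (length(x$order))
    print(data.frame(variable = x$order, p = x$pvalues,
                     cum_r2 = round(x$r2_path, 4),
                     cum_adj_r2 = round(x$adj_r2_path, 4)),
          row.names = FALSE)
  invisible(x)
}

#' PCA reduction of a predictor block
#'
#' Correlation-matrix PCA (variables standardized, appropriate for batteries
#' mixing units). Retains the smallest number of leading axes whose
#' cumulative explained proportion reaches `threshold`.
#'
#' @param block labelled predictor block with at least one variable; no
#'   zero-variance columns.
#' @param threshold cumulative proportion to retain (default 0.90);
#'   `threshold = 1` keeps all axes with nonzero eigenvalue.
#' @return an object of class `"pca_axes"`: `scores` (sites x k, columns
#'   `PC1..PCk`), `explained` (all axes, descending), `cumulative`, `k`.
#' @export
pca_reduce <- function(block, threshold = 0.90) {
  X <- .as_block(block, NROW(block))
  if (ncol(X) < 1) stop("pca_reduce needs at least one variable")
  if (nrow(X) < 2) stop("pca_reduce needs more than one site")
  s <- apply(X, 2, stats::sd)
  if (any(s < 1e-12))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[s < 1e-12], collapse = ", "))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  explained <- ev / sum(ev)
  cumulative <- cumsum(explained)
  k <- which(cumulative >= threshold - 1e-12)[1L]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, explained = explained,
                 cumulative = cumulative, k = as.integer(k),
                 threshold = threshold),
            class = "pca_axes")
}

#' @export
print.pca_axes <- function(x, ...) {
  cat(sprintf("PCA reduction: %d axis/axes retained (>= %g%% cumulative; reached %.1f%%)\n",
              x$k, 100 * x$threshold, 100 * x$cumulative[x$k]))
  invisible(x)
}
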