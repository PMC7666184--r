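# Stratified random-removal null model for the change in explained variance
# (delta R2) and its permutation p-value.

#' Stratified subsample of species by abundance
#'
#' Species are binned into `n_strata` strata by quantiles of
#' `log10(total abundance + 1)`; a subsample of `size` species is drawn
#' uniformly within strata with proportional allocation (largest-remainder
#' rounding), so the retained set resembles the original relative-abundance
#' distribution. Deterministic given `seed`.
#'
#' @param Y a [community_matrix].
#' @param n_strata number of abundance strata (default 4); richness must be
#'   at least `2 * n_strata`.
#' @param size number of species to retain (default: full richness).
#' @param seed integer seed.
#' @return an object of class `"stratified_subsample"`: `species_ids`
#'   retained (original column order), `strata_bounds` (quantile edges on
#'   the log scale), `per_stratum_counts`, `strata` (stratum index per
#'   original species).
#' @export
stratified_subsample <- function(Y, n_strata = 4L, size = NULL, seed = 1L) {
  Ym <- unclass(as.matrix(Y))
  tot <- colSums(Ym)
  S <- length(tot)
  lab <- colnames(Ym) %||% paste0("sp", seq_len(S))
  if (S < 2L * n_strata)
    stop("richness ", S, " too small for ", n_strata, " strata")
  if (is.null(size)) size <- S
  size <- as.integer(size)
  if (size < 1 || size > S) stop("size must be in [1, richness]")
  lt <- log10(tot + 1)
  br <- unique(stats::quantile(lt, probs = seq(0, 1, length.out = n_strata + 1),
                               names = FALSE))
  strata <- if (length(br) > 2)
    cut(lt, br, include.lowest = TRUE, labels = FALSE)
  else
    rep(1L, S)
  nh <- tabulate(strata)
  H <- length(nh)
  # proportional allocation, largest-remainder rounding
  exact <- size * nh / S
  alloc <- floor(exact)
  rem <- size - sum(alloc)
  if (rem > 0) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  alloc <- pmin(alloc, nh)
  short <- size - sum(alloc)
  if (short > 0) {  # capacity spill-over after capping
    room <- which(alloc < nh)
    for (h in room) {
      add <- min(short, nh[h] - alloc[h])
      alloc[h] <- alloc[h] + add
      short <- short - add
      if (short == 0) break
    }
  }
  set.seed(as.integer(seed))
  keep <- unlist(lapply(seq_len(H), function(h) {
    pool <- which(strata == h)
    pool[sample.int(length(pool), alloc[h])]
  }))
  keep <- sort(keep)
  structure(list(species_ids = lab[keep],
                 strata_bounds = br,
                 per_stratum_counts = alloc,
                 strata = strata),
            class = "stratified_subsample")
}

#' Null distribution of delta R2 under random species removal
#'
#' Each replicate builds a stratified subsample of the community (default:
#' the full richness, so stratification only records the abundance
#' structure), computes its reference partition, removes
#' `floor(removal_fraction * richness)` species uniformly at random without
#' replacement, recomputes the partition on the re-transformed reduced
#' matrix, and records the before-minus-after difference in the configured
#' component. Replicates use a replicate-indexed seed stream, so the whole
#' distribution is deterministic given `config$seed`. A replicate whose
#' reduced matrix is degenerate (all-empty sites, zero-variance response or
#' a saturated model) is redrawn up to 10 times, then an error is raised.
#'
#' @param Y a [community_matrix].
#' @param X environmental predictor block (frozen).
#' @param W spatial predictor block (frozen).
#' @param config a [run_config()]; uses `null_nrep`, `removal_fraction`,
#'   `transform`, `component`, `tail`, `n_strata`, `subsample_fraction`,
#'   `seed`.
#' @param observed the observed delta R2 to test (e.g. from [delta_r2()] of
#'   a rarity-ordered cascade); `NULL` gives the distribution without a
#'   p-value.
#' @return an object of class `"null_distribution"`: `deltas`, `observed`,
#'   `p_value`, `nrep`, `seed`, `component`, `tail`.
#' @export
null_distribution <- function(Y, X, W, config = run_config(),
                              observed = NULL) {
  Ym <- unclass(as.matrix(Y))
  S <- ncol(Ym)
  lab <- colnames(Ym) %||% paste0("sp", seq_len(S))
  colnames(Ym) <- lab
  nrep <- config$null_nrep
  comp <- config$component
  full_sub <- config$subsample_fraction >= 1
  sub_size <- max(2L, as.integer(round(config$subsample_fraction * S)))
  # reference partition reused when every replicate subsamples the full set
  ref_full <- if (full_sub)
    .component_value(varpart2(transform_response(Ym, config$transform), X, W),
                     comp)
  deltas <- numeric(nrep)
  for (r in seq_len(nrep)) {
    base_seed <- (as.integer(config$seed) + 101L * r) %% 2147483629L
    val <- NA_real_
    for (try in 0:10) {
      rs <- (base_seed + 7919L * try) %% 2147483629L
      val <- tryCatch({
        if (full_sub) {
          sub_ids <- lab
          ref <- ref_full
        } else {
          sub <- stratified_subsample(Ym, config$n_strata, sub_size, seed = rs)
          sub_ids <- sub$species_ids
          Ysub <- Ym[, sub_ids, drop = FALSE]
          ref <- .component_value(
            varpart2(transform_response(Ysub, config$transform), X, W), comp)
        }
        set.seed(rs)
        n_remove <- floor(config$removal_fraction * length(sub_ids))
        drop_ids <- sample(sub_ids, n_remove)
        Yred <- Ym[, setdiff(sub_ids, drop_ids), drop = FALSE]
        if (all(rowSums(Yred) == 0)) stop("degenerate: all sites empty")
        after <- .component_value(
          varpart2(transform_response(Yred, config$transform), X, W), comp)
        ref - after
      }, error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val))
      stop("degenerate replicate ", r, " after 10 redraws")
    deltas[r] <- val
  }
  p <- if (is.null(observed)) NA_real_
       else p_value(observed, deltas, config$tail)
  structure(list(deltas = deltas, observed = observed %||% NA_real_,
                 p_value = p, nrep = nrep, seed = config$seed,
                 component = comp, tail = config$tail,
                 n_strata = config$n_strata,
                 subsample_fraction = config$subsample_fraction),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Null distribution of delta R2 (%s, %s): %d replicates\n",
              x$component, x$tail, x$nrep))
  cat(sprintf("  null quantiles: %s\n",
              paste(signif(stats::quantile(x$deltas, c(.025, .5, .975)), 3),
                    collapse = " / ")))
  if (is.finite(x$observed))
    cat(sprintf("  observed = %.*f, p = %.4g\n",
                digits, x$observed, x$p_value))
  invisible(x)
}

#' Permutation p-value against a null vector
#'
#' Add-one formula: `p = (1 + extreme count) / (n + 1)`, never exactly zero.
#' Two-sided compares absolute values; `"lower"`/`"upper"` are the
#' one-tailed forms.
#'
#' @param observed observed statistic.
#' @param deltas vector of null statistics.
#' @param tail `"two_sided"`, `"lower"` or `"upper"`.
#' @return the p-value, in `[1/(n+1), 1]`.
#' @export
p_value <- function(observed, deltas, tail = c("two_sided", "lower", "upper")) {
  tail <- match.arg(tail)
  if (!length(deltas)) stop("empty null vector")
  k <- switch(tail,
              two_sided = sum(abs(deltas) >= abs(observed)),
              lower = sum(deltas <= observed),
              upper = sum(deltas >= observed))
  (1 + k) / (length(deltas) + 1)
}
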