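# The full analysis chain: align tables, transform the community, screen
# and forward-select environmental variables, reduce them by PCA, build and
# forward-select PCNM spatial filters, and partition the variance.

#' Run the full variation-partitioning chain
#'
#' Chains the stages in the order screen -> forward-select raw environmental
#' variables -> PCA on the selected set -> PCNM construction ->
#' forward-select PCNMs -> two-component partition. The resulting predictor
#' blocks (PCA axis scores and selected PCNM vectors) are the ones the
#' removal cascade and null model freeze.
#'
#' @param community a [community_matrix].
#' @param env an [env_matrix].
#' @param coords a [site_coords] object.
#' @param config a [run_config()].
#' @param verbose report alignment drops (default `TRUE`).
#' @return an object of class `"varpart_pipeline"`: `varpart` (the
#'   [varpart2()] result), `screening`, `env_selection`, `pca`,
#'   `pcnm_basis`, `pcnm_selection`, predictor blocks `X` and `W`,
#'   `data` (the aligned triple), `config`.
#' @export
varpart_pipeline <- function(community, env, coords, config = run_config(),
                             verbose = TRUE) {
  al <- align_sites(community, env, coords, verbose = verbose)
  Yt <- transform_response(al$community, config$transform)

  screening <- cv_screen(al$env, config$cv_low, config$cv_high)
  if (!length(screening$kept))
    stop("CV screening removed every environmental variable")
  env_kept <- al$env[, screening$kept, drop = FALSE]

  env_sel <- forward_select(Yt, env_kept, alpha = config$forward_alpha,
                            nperm = config$forward_nperm,
                            seed = config$seed)
  pca <- if (length(env_sel$order))
    pca_reduce(env_kept[, env_sel$order, drop = FALSE],
               config$pca_threshold)
  X <- if (length(env_sel$order)) pca$scores
       else matrix(numeric(0), nrow(Yt), 0)

  D <- pairwise_distances(al$coords)
  metric <- if (attr(al$coords, "crs_mode") == "lonlat") "haversine_km"
            else "euclidean"
  basis <- pcnm(D, metric = metric)
  pcnm_sel <- forward_select(Yt, basis$vectors, alpha = config$forward_alpha,
                             nperm = config$forward_nperm,
                             seed = config$seed + 1L)
  W <- basis$vectors[, pcnm_sel$order, drop = FALSE]

  vp <- varpart2(Yt, X, W)
  structure(list(varpart = vp, screening = screening,
                 env_selection = env_sel,
                 pca = if (length(env_sel$order)) pca else NULL,
                 pcnm_basis = basis, pcnm_selection = pcnm_sel,
                 X = X, W = W, data = al, config = config),
            class = "varpart_pipeline")
}

#' @export
print.varpart_pipeline <- function(x, ...) {
  cat("Variation-partitioning pipeline\n")
  print(x$screening)
  cat(sprintf("  env forward selection: %d variable(s) [%s]\n",
              length(x$env_selection$order), x$env_selection$stop_reason))
  if (!is.null(x$pca))
    cat(sprintf("  PCA: %d axis/axes (cumulative %.1f%%)\n",
                x$pca$k, 100 * x$pca$cumulative[x$pca$k]))
  cat(sprintf("  PCNM: %d candidate vector(s), %d selected [%s]\n",
              ncol(x$pcnm_basis$vectors), length(x$pcnm_selection$order),
              x$pcnm_selection$stop_reason))
  print(x$varpart)
  invisible(x)
}
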