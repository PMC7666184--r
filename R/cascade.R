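# The species-removal cascade: rank species by commonness, delete them one
# at a time (rarest-first or commonest-first) down to half the original
# richness, re-transform and re-partition at every step, and summarize the
# change in explained variance.

#' Rank species from rarest to commonest
#'
#' Default criterion is total abundance (column sums); `"occupancy"` ranks
#' by the number of sites where a species is present. Ties are broken by the
#' other criterion, then by species label (lexicographic), so the ranking is
#' deterministic.
#'
#' @param Y a [community_matrix].
#' @param criterion `"total_abundance"` or `"occupancy"`.
#' @return an object of class `"rarity_ranking"`: `species_ids` ordered
#'   rarest to commonest, `criterion`, `values` (criterion value per species
#'   in ranked order), `ties` (groups of species tied on the criterion).
#' @export
rank_species <- function(Y, criterion = c("total_abundance", "occupancy")) {
  criterion <- match.arg(criterion)
  Y <- unclass(as.matrix(Y))
  if (ncol(Y) < 2) stop("need at least 2 species to rank")
  tot <- colSums(Y)
  occ <- colSums(Y > 0)
  lab <- colnames(Y) %||% paste0("sp", seq_len(ncol(Y)))
  ord <- if (criterion == "total_abundance")
    order(tot, occ, lab, method = "radix")
  else
    order(occ, tot, lab, method = "radix")
  primary <- if (criterion == "total_abundance") tot else occ
  tie_groups <- split(lab, primary)
  tie_groups <- unname(tie_groups[vapply(tie_groups, length, 1L) > 1])
  structure(list(species_ids = lab[ord], criterion = criterion,
                 values = primary[ord], ties = tie_groups),
            class = "rarity_ranking")
}

#' @export
print.rarity_ranking <- function(x, ...) {
  cat(sprintf("Rarity ranking (%s): %d species, rarest = %s, commonest = %s\n",
              x$criterion, length(x$species_ids),
              x$species_ids[1L], x$species_ids[length(x$species_ids)]))
  if (length(x$ties))
    cat("  ", length(x$ties), "tie group(s) broken deterministically\n")
  invisible(x)
}

#' Run the species-removal cascade
#'
#' Step 0 is the reference partition of the full community. At step `s` the
#' first `s` species of the rarity ranking (or of its reversal for
#' `"remove_common_first"`) are deleted, the configured transform is
#' re-applied to the reduced matrix (row totals change under Hellinger), and
#' the partition recomputed with the predictor blocks frozen at their
#' full-community selection. The cascade stops when richness reaches
#' `(1 - removal_fraction)` of the original, i.e. after
#' `floor(removal_fraction * S)` steps.
#'
#' @param Y a [community_matrix].
#' @param X environmental predictor block (frozen).
#' @param W spatial predictor block (frozen).
#' @param direction `"remove_rare_first"` or `"remove_common_first"`.
#' @param config a [run_config()].
#' @return an object of class `"cascade_trace"`: `direction`, `steps` (list
#'   of `step`, `removed`, `varpart`), `max_steps`, `n_species`, `ranking`,
#'   `transform`.
#' @export
run_cascade <- function(Y, X, W,
                        direction = c("remove_rare_first",
                                      "remove_common_first"),
                        config = run_config()) {
  direction <- match.arg(direction)
  Ym <- unclass(as.matrix(Y))
  S <- ncol(Ym)
  ranking <- rank_species(Ym, config$rarity_criterion)
  removal_order <- if (direction == "remove_rare_first")
    ranking$species_ids else rev(ranking$species_ids)
  max_steps <- floor(config$removal_fraction * S)
  if (max_steps < 1)
    stop("removal_fraction * richness below 1: nothing to remove")
  steps <- vector("list", max_steps + 1L)
  for (s in 0:max_steps) {
    removed <- removal_order[seq_len(s)]
    keep <- !(colnames(Ym) %in% removed)
    Ys <- Ym[, keep, drop = FALSE]
    if (all(rowSums(Ys) == 0))
      stop("all sites empty at cascade step ", s)
    Yt <- transform_response(Ys, config$transform)
    steps[[s + 1L]] <- list(step = s, removed = removed,
                            varpart = varpart2(Yt, X, W))
  }
  structure(list(direction = direction, steps = steps,
                 max_steps = max_steps, n_species = S,
                 ranking = ranking, transform = config$transform),
            class = "cascade_trace")
}

#' @export
as.data.frame.cascade_trace <- function(x, ...) {
  rows <- lapply(x$steps, function(st) {
    vp <- st$varpart
    data.frame(
      step = st$step,
      direction = x$direction,
      species_removed = if (st$step == 0) "" else st$removed[st$step],
      frac_env_adj = vp$frac_a,
      frac_space_adj = vp$frac_c,
      frac_shared_adj = vp$frac_b,
      frac_resid_adj = vp$frac_d,
      r2_total_adj = vp$frac_a + vp$frac_b + vp$frac_c,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.cascade_trace <- function(x, digits = 4, ...) {
  cat(sprintf("Removal cascade (%s, %s transform): %d of %d species removed\n",
              x$direction, x$transform, x$max_steps, x$n_species))
  df <- as.data.frame(x)
  df[-(1:3)] <- round(df[-(1:3)], digits)
  print(utils::head(df, 8), row.names = FALSE)
  if (nrow(df) > 8) cat("  ... (", nrow(df) - 8, " more steps)\n", sep = "")
  cat(sprintf("Delta R2 (explained_total): %.4f\n",
              delta_r2(x, "explained_total")))
  invisible(x)
}

#' Correlogram-style plot of a cascade trace
#'
#' Adjusted fractions against the number of species removed: environment
#' (filled black), space (open), shared (grey), residual (red).
#'
#' @param x a `"cascade_trace"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cascade_trace <- function(x, ...) {
  df <- as.data.frame(x)
  ylim <- range(df$frac_env_adj, df$frac_space_adj,
                df$frac_shared_adj, df$frac_resid_adj)
  graphics::plot(df$step, df$frac_resid_adj, type = "n", ylim = ylim,
                 xlab = "species removed", ylab = "adjusted fraction",
                 main = paste("Removal cascade:", x$direction), ...)
  pts <- function(yv, pch, col) {
    graphics::lines(df$step, yv, col = col)
    graphics::points(df$step, yv, pch = pch, col = col, bg = col)
  }
  pts(df$frac_env_adj, 21, "black")
  pts(df$frac_space_adj, 1, "black")
  pts(df$frac_shared_adj, 21, "grey55")
  pts(df$frac_resid_adj, 21, "red3")
  graphics::legend("topleft",
                   legend = c("environment [a]", "space [c]",
                              "shared [b]", "residual [d]"),
                   pch = c(16, 1, 16, 16),
                   col = c("black", "black", "grey55", "red3"),
                   bty = "n", cex = 0.85)
  invisible(df)
}

#' Change in a partition component across a cascade
#'
#' `component(step 0) - component(final step)` — the "before minus after"
#' contrast. With the default `"explained_total"`
#' (`frac_a + frac_b + frac_c`) a positive value means removal reduced the
#' variance explained; `"frac_d"` gives the literal residual-variation
#' reading with the opposite sign.
#'
#' @param trace a `"cascade_trace"`.
#' @param component `"explained_total"`, `"frac_d"`, `"frac_a"` or
#'   `"frac_c"`.
#' @return the signed difference.
#' @export
delta_r2 <- function(trace, component = c("explained_total", "frac_d",
                                          "frac_a", "frac_c")) {
  component <- match.arg(component)
  if (!inherits(trace, "cascade_trace")) stop("trace must be a cascade_trace")
  if (length(trace$steps) != trace$max_steps + 1L)
    stop("incomplete cascade trace")
  .component_value(trace$steps[[1L]]$varpart, component) -
    .component_value(trace$steps[[length(trace$steps)]]$varpart, component)
}

.component_value <- function(vp, component) {
  switch(component,
         explained_total = vp$frac_a + vp$frac_b + vp$frac_c,
         frac_d = vp$frac_d,
         frac_a = vp$frac_a,
         frac_c = vp$frac_c,
         stop("unknown component: ", component))
}

#' Simpson dominance of a community
#'
#' The dominance form of the Simpson index, the probability that two
#' randomly drawn individuals are conspecific:
#' `lambda = sum((n_i / N)^2)` over species totals `n_i`.
#'
#' @param Y a [community_matrix].
#' @return an object of class `"dominance_summary"`: `simpson` and
#'   `rank_abundance` (species totals, descending).
#' @export
simpson_dominance <- function(Y) {
  tot <- colSums(unclass(as.matrix(Y)))
  N <- sum(tot)
  if (N <= 0) stop("all-zero community matrix")
  p <- tot / N
  structure(list(simpson = sum(p^2),
                 rank_abundance = sort(tot, decreasing = TRUE)),
            class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf("Simpson dominance: %.4f over %d species (top species %.1f%% of individuals)\n",
              x$simpson, length(x$rank_abundance),
              100 * x$rank_abundance[1L] / sum(x$rank_abundance)))
  invisible(x)
}
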