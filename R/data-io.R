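# Tabular data types and delimited-file I/O shared by all analysis stages.
# Site labels are matched case-sensitively after whitespace stripping;
# missing cells are an error at read time (no imputation).

#' Construct a site-by-species community matrix
#'
#' A community matrix holds non-negative abundances (counts allowed) with
#' sites as rows and species as columns. Labels are stripped of surrounding
#' whitespace and matched case-sensitively everywhere in the package.
#'
#' @param values numeric matrix, sites in rows, species in columns.
#' @param site_ids,species_ids row and column labels; default taken from
#'   `dimnames(values)`.
#' @return the validated matrix with class `"community_matrix"`.
#' @export
community_matrix <- function(values, site_ids = rownames(values),
                             species_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids) || is.null(species_ids))
    stop("community matrix requires site and species labels")
  site_ids <- trimws(as.character(site_ids))
  species_ids <- trimws(as.character(species_ids))
  .check_labels(site_ids, "site")
  .check_labels(species_ids, "species")
  if (anyNA(values) || any(!is.finite(values)))
    stop("community matrix contains missing or non-finite values")
  if (any(values < 0))
    stop("negative abundance in community matrix")
  if (nrow(values) < 3)
    stop("community matrix needs at least 3 sites")
  empty <- rowSums(values) == 0
  if (any(empty))
    stop("site(s) with no individuals: ",
         paste(site_ids[empty], collapse = ", "))
  values <- matrix(as.numeric(values), nrow(values), ncol(values))
  dimnames(values) <- list(site_ids, species_ids)
  structure(values, class = c("community_matrix", "matrix", "array"))
}

#' Construct a site-by-variable environmental matrix
#'
#' @param values numeric matrix of environmental measurements (heterogeneous
#'   units allowed, negatives allowed).
#' @param site_ids,var_ids row and column labels.
#' @return the validated matrix with class `"env_matrix"`.
#' @export
env_matrix <- function(values, site_ids = rownames(values),
                       var_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids) || is.null(var_ids))
    stop("environmental matrix requires site and variable labels")
  site_ids <- trimws(as.character(site_ids))
  var_ids <- trimws(as.character(var_ids))
  .check_labels(site_ids, "site")
  .check_labels(var_ids, "variable")
  if (anyNA(values) || any(!is.finite(values)))
    stop("environmental matrix contains missing or non-finite values")
  values <- matrix(as.numeric(values), nrow(values), ncol(values))
  dimnames(values) <- list(site_ids, var_ids)
  structure(values, class = c("env_matrix", "matrix", "array"))
}

#' Construct site coordinates
#'
#' Coordinates are planar x/y or geographic longitude/latitude. Exactly
#' coincident sites are an error (PCNM construction requires distinct
#' positions); no jitter is applied.
#'
#' @param site_ids site labels.
#' @param x,y coordinates; for `crs_mode = "lonlat"`, `x` is longitude and
#'   `y` latitude, in decimal degrees.
#' @param crs_mode `"planar"` or `"lonlat"`.
#' @return a data frame with columns `site`, `x`, `y`, class `"site_coords"`,
#'   carrying `crs_mode` as an attribute.
#' @export
site_coords <- function(site_ids, x, y, crs_mode = c("planar", "lonlat")) {
  crs_mode <- match.arg(crs_mode)
  site_ids <- trimws(as.character(site_ids))
  .check_labels(site_ids, "site")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(site_ids) || length(y) != length(site_ids))
    stop("coordinate vectors must match the number of sites")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("coordinates must be finite")
  dup <- duplicated(cbind(x, y))
  if (any(dup))
    stop("coincident sites: ", paste(site_ids[dup], collapse = ", "))
  out <- data.frame(site = site_ids, x = x, y = y,
                    stringsAsFactors = FALSE)
  attr(out, "crs_mode") <- crs_mode
  class(out) <- c("site_coords", "data.frame")
  out
}

.check_labels <- function(lab, what) {
  if (anyDuplicated(lab))
    stop("duplicate ", what, " label: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  if (any(!nzchar(lab)))
    stop("empty ", what, " label")
  invisible(lab)
}

#' Read a delimited table as a typed matrix
#'
#' Expects a CSV (RFC-4180, UTF-8, "." decimal) with a header row of column
#' labels and a first column of site labels. Parsing is strict: any
#' non-numeric or empty data cell is an error, as are ragged rows and
#' duplicate labels.
#'
#' @param path file path.
#' @param kind `"community"`, `"env"` or `"coords"`.
#' @param crs_mode for `kind = "coords"` only; if `NULL`, inferred from the
#'   column names (`lon`/`lat`-like names give `"lonlat"`, otherwise
#'   `"planar"`).
#' @return a [community_matrix], [env_matrix] or [site_coords] object.
#' @export
read_matrix <- function(path, kind = c("community", "env", "coords"),
                        crs_mode = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fill = FALSE,
                         strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 2) stop("expected a label column plus data columns: ", path)
  labels <- trimws(raw[[1L]])
  vals <- vapply(seq_len(ncol(raw) - 1L), function(j) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- is.na(v)
    if (any(bad))
      stop("non-numeric or missing cell in column '", names(raw)[j + 1L],
           "', row ", which(bad)[1L], " of ", path)
    v
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(labels, trimws(names(raw)[-1L])))
  switch(kind,
    community = community_matrix(vals),
    env = env_matrix(vals),
    coords = {
      if (ncol(vals) != 2L)
        stop("coordinate file must have exactly two coordinate columns")
      nm <- tolower(colnames(vals))
      if (is.null(crs_mode))
        crs_mode <- if (any(grepl("^lon|^lat", nm))) "lonlat" else "planar"
      if (nm[1L] %in% c("lat", "latitude") || nm[2L] %in% c("lon", "longitude"))
        vals <- vals[, 2:1]  # accept lat,lon order; store as x=lon, y=lat
      site_coords(labels, vals[, 1L], vals[, 2L], crs_mode)
    })
}

#' Align a community matrix, environmental matrix and coordinates on sites
#'
#' Inner-joins the three tables on site labels; the community matrix's row
#' order wins. Labels dropped from each table are reported via `message()`.
#'
#' @param community a [community_matrix].
#' @param env an [env_matrix].
#' @param coords a [site_coords] object.
#' @param verbose report dropped labels (default `TRUE`).
#' @return a list with elements `community`, `env`, `coords`, site-aligned.
#' @export
align_sites <- function(community, env, coords, verbose = TRUE) {
  cs <- rownames(community); es <- rownames(env); xs <- coords$site
  common <- cs[cs %in% es & cs %in% xs]
  if (length(common) < 3)
    stop("fewer than 3 sites shared across the three tables")
  report <- function(all, tag) {
    drop <- setdiff(all, common)
    if (verbose && length(drop))
      message("align_sites: dropped from ", tag, ": ",
              paste(drop, collapse = ", "))
  }
  report(cs, "community"); report(es, "env"); report(xs, "coords")
  list(
    community = community_matrix(community[common, , drop = FALSE]),
    env = env_matrix(env[common, , drop = FALSE]),
    coords = site_coords(common,
                         coords$x[match(common, xs)],
                         coords$y[match(common, xs)],
                         attr(coords, "crs_mode"))
  )
}

#' Run configuration
#'
#' Bundles the tunable constants of the analysis chain. Defaults follow the
#' study design this package reimplements: CV screening bounds of 40% and
#' 80%, PCA retention at 90% cumulative explanation, forward-selection alpha
#' 0.05 with 999 permutations, removal of 50% of the original richness, and
#' 999 null-model repetitions.
#'
#' @param seed integer master seed.
#' @param transform community transform: `"hellinger"`, `"presence_absence"`
#'   or `"none"`.
#' @param cv_low,cv_high CV screening bounds in percent; variables with
#'   CV strictly below `cv_low` or strictly above `cv_high` are dropped.
#' @param pca_threshold cumulative proportion of variance to retain.
#' @param forward_alpha,forward_nperm forward-selection significance level
#'   and permutation count.
#' @param removal_fraction fraction of species removed by the cascade and
#'   the null model; values above 0.5 are allowed but warned about.
#' @param null_nrep number of null-model repetitions (at least 19).
#' @param n_strata number of abundance strata for the stratified subsample.
#' @param subsample_fraction fraction of species kept in each null-model
#'   subsample before removal (1 = full richness).
#' @param tail tail convention for null-model p-values.
#' @param component which partition component `delta_r2` and the null model
#'   track by default.
#' @param rarity_criterion species ranking criterion for the cascade.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       transform = c("hellinger", "presence_absence", "none"),
                       cv_low = 40, cv_high = 80,
                       pca_threshold = 0.90,
                       forward_alpha = 0.05, forward_nperm = 999L,
                       removal_fraction = 0.50,
                       null_nrep = 999L,
                       n_strata = 4L,
                       subsample_fraction = 1,
                       tail = c("two_sided", "lower", "upper"),
                       component = c("explained_total", "frac_d",
                                     "frac_a", "frac_c"),
                       rarity_criterion = c("total_abundance", "occupancy")) {
  cfg <- list(
    seed = as.integer(seed),
    transform = match.arg(transform),
    cv_low = as.numeric(cv_low), cv_high = as.numeric(cv_high),
    pca_threshold = as.numeric(pca_threshold),
    forward_alpha = as.numeric(forward_alpha),
    forward_nperm = as.integer(forward_nperm),
    removal_fraction = as.numeric(removal_fraction),
    null_nrep = as.integer(null_nrep),
    n_strata = as.integer(n_strata),
    subsample_fraction = as.numeric(subsample_fraction),
    tail = match.arg(tail),
    component = match.arg(component),
    rarity_criterion = match.arg(rarity_criterion)
  )
  if (cfg$removal_fraction <= 0) stop("removal_fraction must be positive")
  if (cfg$removal_fraction > 0.5)
    warning("removal_fraction above 0.5 removes more than half the community")
  if (cfg$null_nrep < 19) stop("null_nrep must be at least 19")
  if (cfg$pca_threshold <= 0 || cfg$pca_threshold > 1)
    stop("pca_threshold must be in (0, 1]")
  if (cfg$cv_low < 0 || cfg$cv_high < cfg$cv_low)
    stop("require 0 <= cv_low <= cv_high")
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The file may set any subset of the [run_config()] fields; unknown keys are
#' an error, unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `"run_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Write a cascade trace to CSV
#'
#' One row per removal step with the adjusted fractions. Numbers are written
#' with 17 significant digits so a round-trip via [read_trace()] reproduces
#' them exactly.
#'
#' @param trace a `"cascade_trace"` from [run_cascade()].
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "step"
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE),
    error = function(e) stop("cannot write trace to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a cascade trace written by [write_trace()]
#'
#' @param path file path.
#' @return a data frame with the trace columns.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
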