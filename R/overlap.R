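#' Bootstrap significance of feature-list overlap
#'
#' Tests whether the observed number of features shared by several
#' prioritized lists exceeds what random lists of the same sizes drawn from
#' the feature universe would share. Each repetition draws every list
#' uniformly without replacement from the universe and counts the features
#' common to all of them; the p-value uses the standard permutation
#' correction `(1 + #{rep >= observed}) / (reps + 1)` so it can never be 0.
#'
#' @param universe_size Number of features in the universe (e.g. 384).
#' @param list_sizes Integer vector of list sizes (>= 2 lists).
#' @param observed Observed count of features common to all lists.
#' @param reps Bootstrap repetitions (default 100000).
#' @param seed Integer seed.
#' @return List of class `overlap_result`: `p`, `observed`, `expected`
#'   (Monte-Carlo mean), `reps`, `list_sizes`, `universe_size`, `seed`.
#' @export
bootstrap_overlap <- function(universe_size, list_sizes, observed,
                              reps = 100000, seed = 1) {
  stopifnot(length(list_sizes) >= 2, all(list_sizes <= universe_size),
            reps >= 1)
  if (observed > min(list_sizes))
    stop("observed overlap exceeds the smallest list")
  set.seed(seed)
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    tally <- integer(universe_size)
    for (s in list_sizes) {
      idx <- sample.int(universe_size, s)
      tally[idx] <- tally[idx] + 1L
    }
    counts[r] <- sum(tally == length(list_sizes))
  }
  structure(list(p = (1 + sum(counts >= observed)) / (reps + 1),
                 observed = observed, expected = mean(counts), reps = reps,
                 list_sizes = list_sizes, universe_size = universe_size,
                 seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %d shared of lists (%s) from %d features: p = %.4g (%d reps, E = %.2f)\n",
    x$observed, paste(x$list_sizes, collapse = ", "), x$universe_size,
    x$p, x$reps, x$expected))
  invisible(x)
}

#' Hypergeometric category enrichment of a prioritized feature list
#'
#' For every category of the manifest (both the statistic family --
#' mean/min/max/variance -- and the constituent family --
#' distance/angle/height/meta/endpoint), counts how many of the prioritized
#' features fall in the category and tests over-representation with the
#' upper-tail hypergeometric test. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param prioritized Character vector of prioritized feature names (must be
#'   a subset of the registry names).
#' @param registry A [feature_registry] (default manifest if `NULL`).
#' @return data.frame with one row per category: `family`, `category`, `k`,
#'   `n`, `K`, `N`, `fold`, `p`.
#' @export
enrich_category <- function(prioritized, registry = NULL) {
  registry <- registry %||% feature_registry()
  unknown <- setdiff(prioritized, registry$name)
  if (length(unknown))
    stop("features not in the registry: ", paste(unknown, collapse = ", "))
  N <- nrow(registry)
  n <- length(prioritized)
  in_list <- registry$name %in% prioritized
  one <- function(family, members) {
    K <- sum(members)
    k <- sum(members & in_list)
    data.frame(family = family,
               category = NA_character_, k = k, n = n, K = K, N = N,
               fold = if (K == 0 || k == 0) 0 else (k / n) / (K / N),
               p = if (K == 0) 1 else
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }
  rows <- list()
  for (s in unique(registry$statistic[registry$statistic != "none"])) {
    r <- one("statistic", registry$statistic == s); r$category <- s
    rows[[length(rows) + 1]] <- r
  }
  for (cc in unique(registry$category)) {
    r <- one("constituent", registry$category == cc); r$category <- cc
    rows[[length(rows) + 1]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear discriminant projection of a feature matrix
#'
#' Projects all features onto the discriminant axes (at most
#' `min(#groups - 1, 2)` dimensions are returned) for visualizing group
#' separation. Zero-variance and within-group-constant features are dropped
#' with a note before fitting; collinearity warnings from the fit are
#' suppressed (expected when features outnumber trials).
#'
#' @param features Numeric matrix, trials x features.
#' @param labels Group label per trial (>= 2 groups, each with >= 2 trials).
#' @param standardize Standardize features before fitting (default FALSE:
#'   the projection runs on the engineered features as-is).
#' @return Matrix, trials x d (d <= 2), columns `d1` (and `d2`), attribute
#'   `dropped` = removed feature names.
#' @export
lda_project <- function(features, labels, standardize = FALSE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 trials")
  if (standardize) features <- zscore_fit_apply(features, skip = "")$train
  # drop features the discriminant fit would reject as within-group constant
  grp <- factor(labels)
  centered <- features - apply(features, 2, function(col)
    stats::ave(col, grp))
  within_sd <- sqrt(diag(stats::var(centered)))
  keep <- is.finite(within_sd) & within_sd >= 1e-4
  if (!any(keep)) stop("no feature varies within groups")
  dropped <- colnames(features)[!keep]
  fit <- suppressWarnings(
    MASS::lda(features[, keep, drop = FALSE], grouping = factor(labels)))
  proj <- stats::predict(fit, features[, keep, drop = FALSE])$x
  d <- min(ncol(proj), 2L)
  proj <- proj[, seq_len(d), drop = FALSE]
  colnames(proj) <- paste0("d", seq_len(d))
  attr(proj, "dropped") <- dropped
  proj
}

#' Centroid distances in a discriminant projection
#'
#' Quantifies group separability: `intra` holds the euclidean distances of
#' the reference group's samples to their own centroid; `inter[[g]]` the
#' distances of group g's samples to the reference centroid. A larger mean
#' inter- than intra-group distance indicates separation.
#'
#' @param projection Matrix of projected coordinates (e.g. [lda_project]).
#' @param labels Group label per row.
#' @param reference Reference group label.
#' @return List with `intra` (numeric vector) and `inter` (named list of
#'   numeric vectors, one per non-reference group).
#' @export
centroid_distances <- function(projection, labels, reference) {
  projection <- as.matrix(projection)
  labels <- as.character(labels)
  if (!reference %in% labels) stop("reference group not present: ", reference)
  centroid <- colMeans(projection[labels == reference, , drop = FALSE])
  dist_to <- function(rows)
    sqrt(rowSums(sweep(projection[rows, , drop = FALSE], 2, centroid)^2))
  others <- setdiff(unique(labels), reference)
  list(intra = dist_to(labels == reference),
       inter = stats::setNames(
         lapply(others, function(g) dist_to(labels == g)), others))
}
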