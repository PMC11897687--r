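#' Bundle a feature matrix with its trial structure
#'
#' @param features Numeric matrix, trials x features, with column names.
#' @param labels Group label per trial (two groups for classification).
#' @param mouse_ids Mouse identifier per trial; every mouse must carry a
#'   single label, and have at most two trials (one analysis is run per
#'   beam).
#' @param informative Optional character vector naming features known to
#'   carry signal (from a simulation's ground truth).
#' @return List of class `experiment_dataset`.
#' @export
experiment_dataset <- function(features, labels, mouse_ids,
                               informative = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            nrow(features) == length(mouse_ids),
            !is.null(colnames(features)))
  labels <- as.character(labels); mouse_ids <- as.character(mouse_ids)
  per_mouse <- tapply(labels, mouse_ids, function(l) length(unique(l)))
  if (any(per_mouse > 1))
    stop("a mouse carries more than one group label: ",
         paste(names(per_mouse)[per_mouse > 1], collapse = ", "))
  if (any(table(mouse_ids) > 2))
    stop("more than two trials for a mouse; run one analysis per beam")
  structure(list(features = features, labels = labels,
                 mouse_ids = mouse_ids, informative = informative),
            class = "experiment_dataset")
}

#' Build an experiment dataset from a feature table
#'
#' Selects one beam and (optionally) two groups from the output of
#' [build_feature_table] and returns the matrix form used by
#' [run_nested_lomo].
#'
#' @param feature_table Output of [build_feature_table].
#' @param beam Beam type to keep (`NULL` = all rows; analyses are meant to
#'   run per beam).
#' @param groups Optional character vector of group labels to keep.
#' @return An [experiment_dataset].
#' @export
dataset_from_feature_table <- function(feature_table, beam = NULL,
                                       groups = NULL) {
  tab <- feature_table
  if (!is.null(beam)) tab <- tab[tab$beam == beam, , drop = FALSE]
  if (!is.null(groups)) tab <- tab[tab$group %in% groups, , drop = FALSE]
  if (!nrow(tab)) stop("no trials left after filtering")
  feat_cols <- setdiff(names(tab), id_columns())
  experiment_dataset(as.matrix(tab[, feat_cols, drop = FALSE]),
                     tab$group, tab$mouse_id)
}

#' Cross-validation configuration
#'
#' @param n_select Number of features retained by feature selection.
#' @param rfe_step Fraction of remaining features eliminated per recursive
#'   feature elimination round (`ceiling(rfe_step * remaining)`, floor 1).
#' @param hyper_grid Named list of candidate hyperparameter values; the
#'   order of each vector is the declared tie-break ordering. Supported
#'   names: `num_trees`, `max_depth` (0 = unlimited), `min_node_size`.
#' @param rfe_num_trees Trees used for the forests inside the elimination
#'   loop.
#' @param chance_level Chance accuracy for a balanced two-group design.
#' @param seed Master seed; all per-split seeds derive from it by a fixed
#'   counter scheme, so results are reproducible end to end.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_select = 50, rfe_step = 0.05,
                      hyper_grid = list(num_trees = c(100, 300),
                                        max_depth = c(3, 5, 0),
                                        min_node_size = c(1, 3)),
                      rfe_num_trees = 100, chance_level = 0.5, seed = 1) {
  stopifnot(rfe_step > 0, rfe_step < 1, n_select >= 1,
            length(hyper_grid) >= 1)
  structure(list(n_select = n_select, rfe_step = rfe_step,
                 hyper_grid = hyper_grid, rfe_num_trees = rfe_num_trees,
                 chance_level = chance_level, seed = as.integer(seed)),
            class = "cv_config")
}

split_seed <- function(seed, outer, inner = 0L, extra = 0L) {
  as.integer((abs(seed) + 10007 * outer + 101 * inner + extra) %% 2147483647)
}

#' Leave-one-mouse-out splits
#'
#' One split per mouse: all of that mouse's trials form the held-out side,
#' everything else the training side.
#'
#' @param dataset An [experiment_dataset].
#' @return List of lists with `mouse`, `train` and `test` row indices.
#' @export
lomo_splits <- function(dataset) {
  mice <- sort(unique(dataset$mouse_ids))
  if (length(mice) < 3) stop("need at least 3 mice for leave-one-mouse-out")
  cls <- table(tapply(dataset$labels, dataset$mouse_ids, unique))
  if (any(cls < 2))
    stop("degenerate design: a class would vanish from some training side")
  lapply(mice, function(m) {
    test <- which(dataset$mouse_ids == m)
    list(mouse = m, train = setdiff(seq_along(dataset$mouse_ids), test),
         test = test)
  })
}

#' Z-score normalization fit on the training rows only
#'
#' Per-feature standardization `(x - mean) / sd` with the sample (n - 1) SD,
#' both estimated on the training matrix and then applied unchanged to any
#' other matrix. Features with zero training SD map to 0 and are flagged;
#' columns named in `skip` (by default the binary `sex` column) pass through
#' untouched.
#'
#' @param train Training matrix.
#' @param ... Further matrices to transform with the training statistics.
#' @param skip Column names excluded from scaling.
#' @return List with `train`, one transformed matrix per `...` argument,
#'   `center`, `scale` and `constant` (flagged zero-SD features).
#' @export
zscore_fit_apply <- function(train, ..., skip = "sex") {
  stopifnot(nrow(train) >= 2)
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  constant <- colnames(train)[scale == 0]
  keep <- colnames(train) %in% skip
  center[keep] <- 0; scale[keep] <- 1
  apply_one <- function(m) {
    out <- sweep(m, 2, center, "-")
    out <- sweep(out, 2, ifelse(scale == 0, 1, scale), "/")
    out[, scale == 0] <- 0
    out
  }
  others <- lapply(list(...), apply_one)
  c(list(train = apply_one(train)), others,
    list(center = center, scale = scale,
         constant = setdiff(constant, skip)))
}

# Balanced class handling: impurity weights inversely proportional to class
# frequency plus a stratified bootstrap that draws the same number of
# observations from each class for every tree, so the majority class cannot
# dominate terminal votes when leave-one-mouse-out unbalances the training
# side.
fit_rf <- function(x, y, hyper = list(), num_trees = NULL, seed = 1) {
  y <- droplevels(y)
  tab <- table(y)
  cw <- as.numeric(length(y) / (length(tab) * tab))
  md <- hyper$max_depth %||% 0
  ranger::ranger(
    x = x, y = y,
    num.trees = num_trees %||% hyper$num_trees %||% 100,
    max.depth = if (md > 0) md else NULL,
    min.node.size = hyper$min_node_size %||% 1,
    class.weights = cw,
    sample.fraction = rep(min(tab) / length(y), length(tab)),
    replace = TRUE,
    importance = "impurity",
    num.threads = 1, seed = seed, classification = TRUE,
    respect.unordered.factors = TRUE, verbose = FALSE
  )
}

rf_accuracy <- function(fit, x, y) {
  pred <- stats::predict(fit, data = x, num.threads = 1,
                         seed = 1L)$predictions
  mean(as.character(pred) == as.character(y))
}

#' Recursive feature elimination with a random-forest estimator
#'
#' Repeatedly fits a forest (balanced class weights), drops the
#' `ceiling(rfe_step * remaining)` least important features by mean decrease
#' in impurity, and stops at `n_select` features.
#'
#' @param x Training matrix (already standardized).
#' @param y Factor of labels.
#' @param config A [cv_config].
#' @param seed Seed for the elimination forests.
#' @return Character vector of the `n_select` surviving feature names.
#' @export
rfe_select <- function(x, y, config, seed = 1) {
  if (config$n_select >= ncol(x))
    stop("n_select must be smaller than the number of features")
  keep <- colnames(x)
  round <- 0L
  while (length(keep) > config$n_select) {
    round <- round + 1L
    fit <- fit_rf(x[, keep, drop = FALSE], y,
                  num_trees = config$rfe_num_trees,
                  seed = split_seed(seed, 0L, 0L, round))
    imp <- fit$variable.importance
    drop_n <- min(max(1L, ceiling(config$rfe_step * length(keep))),
                  length(keep) - config$n_select)
    keep <- names(sort(imp, decreasing = TRUE))[seq_len(length(keep) - drop_n)]
  }
  keep
}

expand_hyper_grid <- function(hyper_grid) {
  grid <- expand.grid(hyper_grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

#' Inner feature selection and hyperparameter tuning
#'
#' For each inner leave-one-mouse-out split of the supplied training data:
#' (i) standardize with statistics from the inner-training rows, (ii) run
#' [rfe_select] down to `n_select` features, (iii) score every hyperparameter
#' combination of the grid on the held-out validation mouse using those
#' features, and (iv) refit a forest on all features with the tuned
#' hyperparameters and rank features by impurity importance, keeping the top
#' `n_select` as that split's ranked list.
#'
#' @param features Training feature matrix (raw, not yet standardized).
#' @param labels,mouse_ids Per-row group labels and mouse ids.
#' @param config A [cv_config].
#' @param seed_base Outer-split index used in the per-split seed derivation.
#' @return List with `ranked_lists` (one character vector per inner split)
#'   and `hypers` (one named list per inner split).
#' @export
inner_select_and_tune <- function(features, labels, mouse_ids, config,
                                  seed_base = 0L) {
  combos <- expand_hyper_grid(config$hyper_grid)
  if (!length(combos)) stop("empty hyperparameter grid")
  levels_all <- sort(unique(labels))
  inner <- lomo_splits(experiment_dataset(features, labels, mouse_ids))
  ranked_lists <- list(); hypers <- list()
  for (i in seq_along(inner)) {
    sp <- inner[[i]]
    z <- zscore_fit_apply(features[sp$train, , drop = FALSE],
                          features[sp$test, , drop = FALSE])
    xtr <- z$train; xval <- z[[2]]
    ytr <- factor(labels[sp$train], levels = levels_all)
    yval <- labels[sp$test]
    seed_i <- split_seed(config$seed, seed_base, i)
    selected <- rfe_select(xtr, ytr, config, seed = seed_i)
    scores <- vapply(seq_along(combos), function(k) {
      fit <- fit_rf(xtr[, selected, drop = FALSE], ytr, hyper = combos[[k]],
                    seed = split_seed(config$seed, seed_base, i, 1000L + k))
      rf_accuracy(fit, xval[, selected, drop = FALSE], yval)
    }, numeric(1))
    best <- combos[[which.max(scores)]]   # ties: first in grid order
    final <- fit_rf(xtr, ytr, hyper = best,
                    seed = split_seed(config$seed, seed_base, i, 5000L))
    imp <- sort(final$variable.importance, decreasing = TRUE)
    ranked_lists[[i]] <- names(imp)[seq_len(config$n_select)]
    hypers[[i]] <- best
  }
  list(ranked_lists = ranked_lists, hypers = hypers)
}

#' Consensus ranking of per-split feature lists
#'
#' Features are ordered by occurrence count across lists (descending), then
#' by mean within-list rank (ascending), then by name; the top `n_select`
#' are returned.
#'
#' @param ranked_lists List of character vectors (ranked, best first).
#' @param n_select Length of the consensus list.
#' @return Character vector of length `min(n_select, #distinct features)`.
#' @export
consensus_rank <- function(ranked_lists, n_select = 50) {
  if (!length(ranked_lists)) stop("need at least one ranked list")
  all_feats <- unique(unlist(ranked_lists))
  occurrence <- vapply(all_feats, function(f)
    sum(vapply(ranked_lists, function(l) f %in% l, logical(1))), numeric(1))
  mean_rank <- vapply(all_feats, function(f) {
    r <- vapply(ranked_lists, function(l) {
      m <- match(f, l); if (is.na(m)) NA_real_ else as.numeric(m)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-occurrence, mean_rank, all_feats)
  all_feats[ord][seq_len(min(n_select, length(all_feats)))]
}

#' Mode of per-split hyperparameters
#'
#' Per hyperparameter, the most frequent value across splits; ties resolve
#' to the value listed first in the grid's declared ordering and are
#' flagged.
#'
#' @param hypers List of named lists (one per split).
#' @param hyper_grid The candidate grid (supplies the tie-break ordering).
#' @return Named list of selected values, attribute `ties` naming tied keys.
#' @export
mode_hyperparams <- function(hypers, hyper_grid) {
  if (!length(hypers)) stop("need at least one hyperparameter set")
  keys <- names(hypers[[1]])
  if (!all(vapply(hypers, function(h) setequal(names(h), keys), logical(1))))
    stop("inconsistent hyperparameter keys across splits")
  ties <- character()
  out <- lapply(keys, function(k) {
    vals <- vapply(hypers, function(h) h[[k]], numeric(1))
    counts <- table(vals)
    winners <- as.numeric(names(counts)[counts == max(counts)])
    if (length(winners) > 1) ties <<- c(ties, k)
    ordering <- hyper_grid[[k]] %||% sort(winners)
    winners[order(match(winners, ordering))][1]
  })
  names(out) <- keys
  attr(out, "ties") <- ties
  out
}

#' Two-stage nested leave-one-mouse-out cross-validation
#'
#' For every outer split (one mouse held out), the inner loop
#' ([inner_select_and_tune]) runs entirely on the training side and yields a
#' consensus feature list ([consensus_rank]) and modal hyperparameters
#' ([mode_hyperparams]); a final forest is trained on the standardized
#' training trials restricted to the consensus features and scored on the
#' held-out mouse's trials (accuracy averaged over its <= 2 trials). Nothing
#' from a held-out mouse influences its own split's scaling, selection or
#' tuning.
#'
#' @param dataset An [experiment_dataset] (two groups).
#' @param config A [cv_config].
#' @return List of class `cv_result`: `per_animal` (data.frame with
#'   `mouse_id`, `group`, `accuracy`, `n_trials`), `mean_accuracy`,
#'   `consensus_features` (experiment-level consensus over the per-split
#'   consensus lists), `final_hyperparams`, `wilcoxon` (test vs chance, when
#'   >= 6 animals), `outer` (per-split details).
#' @export
run_nested_lomo <- function(dataset, config = cv_config()) {
  splits <- lomo_splits(dataset)
  levels_all <- sort(unique(dataset$labels))
  if (length(levels_all) != 2)
    stop("classification expects exactly 2 groups, got ",
         length(levels_all))
  outer <- list()
  per_animal <- list()
  for (o in seq_along(splits)) {
    sp <- splits[[o]]
    inner <- inner_select_and_tune(dataset$features[sp$train, , drop = FALSE],
                                   dataset$labels[sp$train],
                                   dataset$mouse_ids[sp$train], config,
                                   seed_base = o)
    feats <- consensus_rank(inner$ranked_lists, config$n_select)
    hyper <- mode_hyperparams(inner$hypers, config$hyper_grid)
    z <- zscore_fit_apply(dataset$features[sp$train, , drop = FALSE],
                          dataset$features[sp$test, , drop = FALSE])
    ytr <- factor(dataset$labels[sp$train], levels = levels_all)
    fit <- fit_rf(z$train[, feats, drop = FALSE], ytr, hyper = hyper,
                  seed = split_seed(config$seed, o, 0L, 9000L))
    acc <- rf_accuracy(fit, z[[2]][, feats, drop = FALSE],
                       dataset$labels[sp$test])
    outer[[o]] <- list(mouse = sp$mouse, consensus = feats,
                       hyperparams = hyper, accuracy = acc)
    per_animal[[o]] <- data.frame(
      mouse_id = sp$mouse,
      group = unique(dataset$labels[sp$test]),
      accuracy = acc, n_trials = length(sp$test),
      stringsAsFactors = FALSE)
  }
  per_animal <- do.call(rbind, per_animal)
  consensus <- consensus_rank(lapply(outer, `[[`, "consensus"),
                              config$n_select)
  final_hyper <- mode_hyperparams(lapply(outer, `[[`, "hyperparams"),
                                  config$hyper_grid)
  wil <- if (nrow(per_animal) >= 6)
    wilcoxon_vs_chance(per_animal$accuracy, config$chance_level) else NULL
  structure(list(per_animal = per_animal,
                 mean_accuracy = mean(per_animal$accuracy),
                 consensus_features = consensus,
                 final_hyperparams = final_hyper,
                 wilcoxon = wil, outer = outer, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", nrow(x$per_animal), "animals, mean accuracy",
      sprintf("%.3f", x$mean_accuracy), "\n")
  if (!is.null(x$wilcoxon))
    cat(sprintf("  Wilcoxon vs chance: W = %g, p = %.3g%s\n",
                x$wilcoxon$W, x$wilcoxon$p,
                if (x$wilcoxon$degenerate) " (degenerate)" else ""))
  cat("  top features:", paste(utils::head(x$consensus_features, 5),
                               collapse = ", "), "...\n")
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Two-sided test of per-animal accuracies against the chance level; zero
#' differences are dropped (signed-rank convention). When every accuracy
#' equals chance the test is degenerate and `p = 1` is returned with a flag.
#'
#' @param accuracies Per-animal accuracies.
#' @param chance Chance level (default 0.5).
#' @return List with `W` (sum of positive ranks), `p`, `n_nonzero`,
#'   `degenerate`.
#' @export
wilcoxon_vs_chance <- function(accuracies, chance = 0.5) {
  d <- accuracies - chance
  nz <- d[d != 0]
  if (!length(nz))
    return(list(W = 0, p = 1, n_nonzero = 0L, degenerate = TRUE))
  res <- suppressWarnings(
    stats::wilcox.test(accuracies, mu = chance, alternative = "two.sided"))
  list(W = unname(res$statistic), p = res$p.value,
       n_nonzero = length(nz), degenerate = FALSE)
}

#' Train on one cohort, predict another
#'
#' Runs the full inner selection/tuning loop on cohort A alone (its own
#' leave-one-mouse-out splits), derives the consensus features and modal
#' hyperparameters, standardizes both cohorts with statistics fit on A,
#' trains one forest on all of A and reports per-animal accuracy on every
#' mouse of cohort B.
#'
#' @param train_dataset,test_dataset [experiment_dataset]s over the same
#'   feature manifest.
#' @param config A [cv_config].
#' @return List with `per_animal` (data.frame over B's mice),
#'   `mean_accuracy`, `consensus_features`, `hyperparams`, and
#'   `predictions` (per-trial predicted labels on B).
#' @export
transfer_predict <- function(train_dataset, test_dataset,
                             config = cv_config()) {
  if (!identical(colnames(train_dataset$features),
                 colnames(test_dataset$features)))
    stop("feature manifests of the two cohorts differ")
  levels_all <- sort(unique(train_dataset$labels))
  inner <- inner_select_and_tune(train_dataset$features,
                                 train_dataset$labels,
                                 train_dataset$mouse_ids, config,
                                 seed_base = 0L)
  feats <- consensus_rank(inner$ranked_lists, config$n_select)
  hyper <- mode_hyperparams(inner$hypers, config$hyper_grid)
  z <- zscore_fit_apply(train_dataset$features, test_dataset$features)
  ytr <- factor(train_dataset$labels, levels = levels_all)
  fit <- fit_rf(z$train[, feats, drop = FALSE], ytr, hyper = hyper,
                seed = split_seed(config$seed, 0L, 0L, 9000L))
  pred <- stats::predict(fit, data = z[[2]][, feats, drop = FALSE],
                         num.threads = 1, seed = 1L)$predictions
  pred <- as.character(pred)
  ok <- pred == test_dataset$labels
  mice <- sort(unique(test_dataset$mouse_ids))
  per_animal <- do.call(rbind, lapply(mice, function(m) {
    idx <- test_dataset$mouse_ids == m
    data.frame(mouse_id = m, group = unique(test_dataset$labels[idx]),
               accuracy = mean(ok[idx]), n_trials = sum(idx),
               stringsAsFactors = FALSE)
  }))
  list(per_animal = per_animal, mean_accuracy = mean(per_animal$accuracy),
       consensus_features = feats, hyperparams = hyper,
       predictions = data.frame(mouse_id = test_dataset$mouse_ids,
                                label = test_dataset$labels,
                                predicted = pred,
                                stringsAsFactors = FALSE))
}
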