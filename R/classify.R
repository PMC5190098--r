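#' Random-forest configuration
#'
#' @param n_trees number of trees in the ensemble (default 100).
#' @param max_features per-split candidate features: "sqrt" (default,
#'   floor(sqrt(p))) or a positive integer.
#' @param seed integer RNG seed; training is reproducible given the seed.
#' @param class_weighting "none" (default) or "balanced" (weights inversely
#'   proportional to class frequencies).
#' @return an object of class \code{forest_config}.
#' @export
forest_config <- function(n_trees = 100L, max_features = "sqrt",
                          seed = 1L, class_weighting = c("none", "balanced")) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be >= 1", call. = FALSE)
  class_weighting <- match.arg(class_weighting)
  structure(list(n_trees = n_trees, max_features = max_features,
                 seed = as.integer(seed), class_weighting = class_weighting),
            class = "forest_config")
}

resolve_mtry <- function(max_features, p) {
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  mf <- as.integer(max_features)
  if (is.na(mf) || mf < 1L || mf > p) {
    stop("`max_features` must be \"sqrt\" or an integer in [1, n_features]",
         call. = FALSE)
  }
  mf
}

#' Train a random forest on encoded peptide features
#'
#' Majority-vote ensemble of Gini-impurity decision trees. Deterministic for
#' a fixed \code{config$seed} and training data.
#'
#' @param features numeric matrix (rows = samples).
#' @param labels binary vector (1 = positive site, 0 = negative).
#' @param config a \code{\link{forest_config}}.
#' @return an object of class \code{trained_forest} with fields
#'   \code{config}, \code{fit} (the randomForest ensemble) and
#'   \code{feature_count}.
#' @export
train_forest <- function(features, labels, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop("`features` rows and `labels` length differ", call. = FALSE)
  }
  if (nrow(features) < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("`labels` must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class; both classes are required",
         call. = FALSE)
  }
  y <- factor(labels, levels = c(0, 1))
  classwt <- NULL
  if (config$class_weighting == "balanced") {
    freq <- table(y)
    classwt <- as.numeric(sum(freq) / (2 * freq))
  }
  fit <- withr::with_seed(config$seed, randomForest::randomForest(
    x = features, y = y,
    ntree = config$n_trees,
    mtry = resolve_mtry(config$max_features, ncol(features)),
    classwt = classwt))
  structure(list(config = config, fit = fit,
                 feature_count = ncol(features)),
            class = "trained_forest")
}

#' Vote-fraction scores of a trained forest
#'
#' The score of a sample is the fraction of trees voting for the positive
#' class; the downstream site decision is \code{score >= threshold}.
#'
#' @param model a \code{\link{trained_forest}}.
#' @param features numeric matrix with \code{model$feature_count} columns.
#' @return numeric vector of scores in [0, 1].
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "trained_forest"))
  features <- as.matrix(features)
  if (ncol(features) != model$feature_count) {
    stop(sprintf("feature matrix has %d columns but the forest was trained on %d",
                 ncol(features), model$feature_count), call. = FALSE)
  }
  unname(stats::predict(model$fit, features, type = "prob")[, "1"])
}

#' Gini feature importances of a trained forest
#'
#' Mean decrease in Gini impurity per feature, normalized to sum to 1,
#' together with the feature ranking (most important first).
#'
#' @param model a \code{\link{trained_forest}}.
#' @return list with \code{importance} (named, sums to 1) and
#'   \code{ranking} (feature indices in decreasing importance order).
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "trained_forest")) {
    stop("`model` must be a trained_forest", call. = FALSE)
  }
  raw <- model$fit$importance[, "MeanDecreaseGini"]
  total <- sum(raw)
  imp <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  names(imp) <- rownames(model$fit$importance)
  list(importance = imp, ranking = order(imp, decreasing = TRUE))
}

#' Save a prediction bundle (coupling model + forest)
#'
#' A prediction run needs a single bundle recording the target residue, the
#' window half-width, the forest configuration, the fitted probability
#' tables and the ensemble, plus a format-version string.
#'
#' @param coupling a \code{\link{coupling_model}}.
#' @param forest a \code{\link{trained_forest}}.
#' @param path output path (RDS).
#' @export
write_bundle <- function(coupling, forest, path) {
  stopifnot(inherits(coupling, "coupling_model"),
            inherits(forest, "trained_forest"))
  if (forest$feature_count != 2L * coupling$xi) {
    stop("forest feature count does not match 2*xi of the coupling model",
         call. = FALSE)
  }
  saveRDS(list(format = "hydroxysite-bundle-1",
               target = coupling$target, xi = coupling$xi,
               coupling = coupling, forest = forest), path)
  invisible(path)
}

#' Load a prediction bundle written by \code{\link{write_bundle}}
#'
#' @param path bundle path.
#' @return list with \code{target}, \code{xi}, \code{coupling},
#'   \code{forest}.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("bundle file not found: '%s'", path), call. = FALSE)
  }
  b <- readRDS(path)
  if (!identical(b$format, "hydroxysite-bundle-1")) {
    stop(sprintf("'%s' is not a hydroxysite prediction bundle", path),
         call. = FALSE)
  }
  b
}
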