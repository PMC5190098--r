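#' Confusion counts for a binary site predictor
#'
#' Follows the intuitive parameterization: totals per class plus the two
#' error counts. \code{miss_pos} is the number of true hydroxylation sites
#' predicted as non-sites; \code{false_pos} the number of non-sites
#' predicted as sites.
#'
#' @param n_pos total true sites (N+), >= 1.
#' @param n_neg total non-sites (N-), >= 1.
#' @param miss_pos true sites predicted negative, in [0, n_pos].
#' @param false_pos non-sites predicted positive, in [0, n_neg].
#' @return an object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(n_pos, n_neg, miss_pos, false_pos) {
  vals <- vapply(list(n_pos, n_neg, miss_pos, false_pos), as.numeric,
                 numeric(1))
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("all counts must be non-negative numbers", call. = FALSE)
  }
  if (vals[1] < 1 || vals[2] < 1) {
    stop("n_pos and n_neg must both be >= 1", call. = FALSE)
  }
  if (vals[3] > vals[1]) stop("miss_pos cannot exceed n_pos", call. = FALSE)
  if (vals[4] > vals[2]) stop("false_pos cannot exceed n_neg", call. = FALSE)
  structure(list(n_pos = vals[1], n_neg = vals[2],
                 miss_pos = vals[3], false_pos = vals[4]),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Uses the intuitive formulation:
#' \deqn{Sn = 1 - miss\_pos/N^+,\quad Sp = 1 - false\_pos/N^-,}
#' \deqn{Acc = 1 - (miss\_pos + false\_pos)/(N^+ + N^-),}
#' \deqn{MCC = \frac{1 - (miss\_pos/N^+ + false\_pos/N^-)}
#'   {\sqrt{(1 + (false\_pos - miss\_pos)/N^+)(1 + (miss\_pos - false\_pos)/N^-)}}}
#' which is algebraically identical to the standard Matthews correlation
#' computed from TP/TN/FP/FN. When the MCC denominator vanishes (all
#' predictions in one class) MCC is defined as 0, with a warning.
#'
#' @param counts a \code{\link{confusion_counts}}.
#' @param scores,labels optional per-sample scores and 0/1 labels; when
#'   given, a ROC curve and AUC are attached to the report.
#' @param threshold decision threshold recorded in the report.
#' @return an object of class \code{metrics_report} with fields
#'   \code{counts}, \code{sn}, \code{sp}, \code{acc}, \code{mcc}, and (when
#'   scores are supplied) \code{roc}, \code{auc}, \code{scores},
#'   \code{labels}.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL,
                            threshold = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  np <- counts$n_pos; nn <- counts$n_neg
  m <- counts$miss_pos; f <- counts$false_pos

  sn <- 1 - m / np
  sp <- 1 - f / nn
  acc <- 1 - (m + f) / (np + nn)
  denom_sq <- (1 + (f - m) / np) * (1 + (m - f) / nn)
  if (denom_sq <= 0) {
    warning("MCC denominator is zero (all predictions in one class); MCC set to 0")
    mcc <- 0
  } else {
    mcc <- (1 - (m / np + f / nn)) / sqrt(denom_sq)
  }
  rep <- structure(list(counts = counts, sn = sn, sp = sp, acc = acc,
                        mcc = mcc, threshold = threshold,
                        roc = NULL, auc = NA_real_,
                        scores = scores, labels = labels),
                   class = "metrics_report")
  if (!is.null(scores)) {
    r <- roc_curve(scores, labels)
    rep$roc <- r$points
    rep$auc <- r$auc
  }
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  Acc (%%)  MCC    Sn (%%)  Sp (%%)%s\n",
              if (!is.na(x$auc)) "  AUC" else ""))
  cat(sprintf("  %-8.2f %-6.3f %-7.2f %-6.2f%s\n",
              100 * x$acc, x$mcc, 100 * x$sn, 100 * x$sp,
              if (!is.na(x$auc)) sprintf("  %.3f", x$auc) else ""))
  cat(sprintf("  N+ = %g (missed %g), N- = %g (false positives %g)\n",
              x$counts$n_pos, x$counts$miss_pos,
              x$counts$n_neg, x$counts$false_pos))
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' One row in the conventional comparison-table layout (Acc \%, MCC, Sn \%,
#' Sp \%, AUC) plus the raw counts; ROC points optionally exported alongside
#' as a two-column TSV.
#'
#' @param report a \code{metrics_report}.
#' @param path output TSV path.
#' @param roc_path optional path for the ROC points (fpr, tpr).
#' @export
write_metrics <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  df <- data.frame(acc_pct = 100 * report$acc, mcc = report$mcc,
                   sn_pct = 100 * report$sn, sp_pct = 100 * report$sp,
                   auc = report$auc,
                   n_pos = report$counts$n_pos, n_neg = report$counts$n_neg,
                   miss_pos = report$counts$miss_pos,
                   false_pos = report$counts$false_pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc_path) && !is.null(report$roc)) {
    utils::write.table(report$roc[, c("fpr", "tpr")], roc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' ROC curve and AUC from scores
#'
#' Sweeps the decision threshold over all distinct score values (plus
#' sentinels), calling a sample positive when \code{score >= threshold}.
#' AUC is the trapezoidal area, which equals the Mann-Whitney statistic
#' (fraction of positive/negative pairs ranked concordantly, ties counted
#' one half).
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector of the same length.
#' @return list with \code{points} (data frame \code{threshold},
#'   \code{fpr}, \code{tpr}, from (0,0) to (1,1)) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    stop("`labels` must contain both classes (0 and 1)", call. = FALSE)
  }
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / nn,
      tpr = sum(pred & labels == 1) / np)
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

# Shared fold driver. `folds` is a list of integer index vectors partitioning
# 1..n (test sets). Returns per-sample scores in original order.
# protocol "strict": refit the coupling tables on the training samples of
# every fold; "paper_style": tables fitted once on the full dataset, only
# the forest is refit per fold.
eval_folds <- function(dataset, folds, forest_config, protocol, smoothing) {
  windows <- c(dataset$positives$window, dataset$negatives$window)
  ids <- c(dataset$positives$source_id, dataset$negatives$source_id)
  cpos <- c(dataset$positives$center_position, dataset$negatives$center_position)
  labels <- c(rep(1L, nrow(dataset$positives)),
              rep(0L, nrow(dataset$negatives)))
  n <- length(windows)
  scores <- rep(NA_real_, n)

  if (protocol == "paper_style") {
    model_full <- fit_model(dataset, smoothing)
    X_full <- encode(windows, model_full)
  }
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    if (length(unique(labels[train])) < 2L) {
      stop("a fold's training partition lost one class; subsets too small",
           call. = FALSE)
    }
    if (protocol == "strict") {
      sub <- subset_dataset(dataset, windows, ids, cpos, labels, train)
      model <- fit_model(sub, smoothing)
      X_train <- encode(windows[train], model)
      X_test <- encode(windows[fold], model)
    } else {
      X_train <- X_full[train, , drop = FALSE]
      X_test <- X_full[fold, , drop = FALSE]
    }
    forest <- train_forest(X_train, labels[train], forest_config)
    scores[fold] <- predict_scores(forest, X_test)
  }
  list(scores = scores, labels = labels)
}

# Rebuild a benchmark_dataset from a subset of sample indices (training
# partition of a fold). Screening invariants already hold; bypass rebuild.
subset_dataset <- function(dataset, windows, ids, cpos, labels, idx) {
  df <- data.frame(window = windows[idx], center = dataset$target,
                   label = ifelse(labels[idx] == 1L, "positive", "negative"),
                   source_id = ids[idx], center_position = cpos[idx],
                   stringsAsFactors = FALSE)
  structure(list(target = dataset$target, xi = dataset$xi,
                 positives = df[df$label == "positive", , drop = FALSE],
                 negatives = df[df$label == "negative", , drop = FALSE],
                 screening = NULL),
            class = "benchmark_dataset")
}

finalize_eval <- function(res, threshold) {
  pred <- res$scores >= threshold
  counts <- confusion_counts(
    n_pos = sum(res$labels == 1L), n_neg = sum(res$labels == 0L),
    miss_pos = sum(!pred & res$labels == 1L),
    false_pos = sum(pred & res$labels == 0L))
  compute_metrics(counts, scores = res$scores, labels = res$labels,
                  threshold = threshold)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sample is singled out in turn and scored by a predictor trained on
#' the remaining samples. Under \code{protocol = "strict"} both the
#' conditional-probability tables and the forest are refit on the n-1
#' training samples of every fold (no leakage); under
#' \code{"paper_style"} the tables are fitted once on the full dataset and
#' only the forest is refit per fold.
#'
#' @param dataset a \code{\link{benchmark_dataset}} (>= 2 samples per
#'   subset).
#' @param forest_config a \code{\link{forest_config}}.
#' @param protocol "strict" (default) or "paper_style".
#' @param smoothing see \code{\link{fit_class_tables}}.
#' @param threshold vote-fraction decision threshold (default 0.5).
#' @return a \code{metrics_report} with per-sample scores, ROC and AUC.
#' @export
jackknife <- function(dataset, forest_config = forest_config(),
                      protocol = c("strict", "paper_style"),
                      smoothing = "none", threshold = 0.5) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  protocol <- match.arg(protocol)
  if (nrow(dataset$positives) < 2L || nrow(dataset$negatives) < 2L) {
    stop("jackknife needs at least 2 samples in each subset", call. = FALSE)
  }
  n <- nrow(dataset$positives) + nrow(dataset$negatives)
  folds <- as.list(seq_len(n))
  finalize_eval(eval_folds(dataset, folds, forest_config, protocol, smoothing),
                threshold)
}

# Label-stratified fold assignment over samples ordered positives first.
# Returns a list of k test-index vectors partitioning 1..(npos+nneg), each
# fold's positive count within one of npos/k. k = n degenerates to the
# singleton folds of the jackknife, in sample order.
stratified_folds <- function(npos, nneg, k, seed) {
  n <- npos + nneg
  if (k == n) return(as.list(seq_len(n)))
  assign <- withr::with_seed(as.integer(seed), {
    a <- integer(n)
    a[seq_len(npos)] <- sample(rep_len(seq_len(k), npos))
    a[npos + seq_len(nneg)] <- sample(rep_len(seq_len(k), nneg))
    a
  })
  unname(split(seq_len(n), assign))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label and reproducible from \code{seed}; each
#' sample is tested exactly once. With \code{k} equal to the dataset size
#' the folds are the singletons in sample order, i.e. exactly the jackknife
#' protocol.
#'
#' @inheritParams jackknife
#' @param k number of folds (2 <= k <= dataset size).
#' @param seed seed for the fold assignment.
#' @return a \code{metrics_report}.
#' @export
kfold <- function(dataset, k, forest_config = forest_config(),
                  protocol = c("strict", "paper_style"),
                  smoothing = "none", threshold = 0.5, seed = 1L) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  protocol <- match.arg(protocol)
  npos <- nrow(dataset$positives)
  nneg <- nrow(dataset$negatives)
  n <- npos + nneg
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > n) {
    stop(sprintf("`k` must be in [2, %d]", n), call. = FALSE)
  }
  folds <- stratified_folds(npos, nneg, k, seed)
  finalize_eval(eval_folds(dataset, folds, forest_config, protocol, smoothing),
                threshold)
}

#' Evaluate candidate window half-widths
#'
#' Builds a benchmark per candidate xi from the same annotated proteins and
#' evaluates each under the same protocol, returning one metrics row per xi.
#'
#' @param annotated_list list of \code{\link{annotated_protein}}.
#' @param target center residue letter.
#' @param xi_values integer vector of candidate half-widths.
#' @param forest_config a \code{\link{forest_config}}.
#' @param protocol passed to the evaluator.
#' @param method "kfold" (default, with \code{k}) or "jackknife".
#' @param k folds for \code{method = "kfold"}.
#' @param smoothing,threshold,seed as in \code{\link{kfold}}.
#' @return data frame with columns \code{xi}, \code{n_pos}, \code{n_neg},
#'   \code{acc}, \code{mcc}, \code{sn}, \code{sp}, \code{auc}.
#' @export
select_window_size <- function(annotated_list, target, xi_values,
                               forest_config = forest_config(),
                               protocol = "strict",
                               method = c("kfold", "jackknife"),
                               k = 5L, smoothing = "none", threshold = 0.5,
                               seed = 1L) {
  if (!length(xi_values)) stop("`xi_values` must be non-empty", call. = FALSE)
  method <- match.arg(method)
  rows <- lapply(as.integer(xi_values), function(xi) {
    ds <- build_benchmark(annotated_list, target, xi)
    rep <- if (method == "jackknife") {
      jackknife(ds, forest_config, protocol, smoothing, threshold)
    } else {
      kfold(ds, k, forest_config, protocol, smoothing, threshold, seed)
    }
    data.frame(xi = xi, n_pos = nrow(ds$positives), n_neg = nrow(ds$negatives),
               acc = rep$acc, mcc = rep$mcc, sn = rep$sn, sp = rep$sp,
               auc = rep$auc)
  })
  do.call(rbind, rows)
}
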