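# Sequence-coupled conditional-probability tables.
#
# For a window R[-xi] ... R[-1] * R[+1] ... R[+xi] centered on the candidate
# residue, each class (positive = true sites, negative = non-sites) is
# summarized by:
#   - marginal distributions of the residues at positions -1 and +1
#     (their inner neighbor is always the center residue, so no
#     conditioning is informative there), and
#   - for every outer position, the distribution of its residue conditioned
#     on the nearest neighbor toward the center:
#     p(R[-k] = a | R[-(k-1)] = b) on the left, p(R[+k] = a | R[+(k-1)] = b)
#     on the right, k = 2..xi.
# A sample is encoded as the positive-class probability of each of its 2*xi
# flank residues minus the negative-class probability, giving a vector in
# [-1, 1]^(2*xi). X is a first-class 21st symbol so terminal padding
# participates in the tables like any residue.

# Split windows into an n x (2*xi+1) character matrix; validates length.
window_matrix <- function(windows, xi) {
  width <- 2L * xi + 1L
  if (any(nchar(windows) != width)) {
    stop(sprintf("all windows must have length 2*xi+1 = %d", width),
         call. = FALSE)
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = width, byrow = TRUE)
}

count_vector <- function(symbols) {
  tab <- table(factor(symbols, levels = ALPHABET))
  as.numeric(tab)
}

# counts[a, b] for pairs (outer symbol a, inner symbol b)
count_matrix <- function(outer, inner) {
  table(factor(outer, levels = ALPHABET), factor(inner, levels = ALPHABET))
}

normalize_marginal <- function(counts, n, alpha) {
  p <- (counts + alpha) / (n + length(ALPHABET) * alpha)
  names(p) <- ALPHABET
  p
}

normalize_conditional <- function(counts, alpha) {
  counts <- unclass(counts)
  colsum <- colSums(counts)
  if (alpha > 0) {
    p <- sweep(counts + alpha, 2, colsum + nrow(counts) * alpha, "/")
  } else {
    p <- counts
    seen <- colsum > 0
    p[, seen] <- sweep(counts[, seen, drop = FALSE], 2, colsum[seen], "/")
    # never-observed conditioning symbol: column stays identically 0
  }
  dimnames(p) <- list(ALPHABET, ALPHABET)
  p
}

parse_smoothing <- function(smoothing) {
  if (is.numeric(smoothing)) {
    alpha <- as.numeric(smoothing)
    if (alpha < 0) stop("smoothing pseudo-count must be >= 0", call. = FALSE)
    return(alpha)
  }
  if (identical(smoothing, "none")) return(0)
  m <- regmatches(smoothing,
                  regexec("^laplace\\(([0-9.eE+-]+)\\)$", smoothing))[[1]]
  if (length(m) == 2L) {
    alpha <- as.numeric(m[2])
    if (is.na(alpha) || alpha < 0) {
      stop("smoothing pseudo-count must be >= 0", call. = FALSE)
    }
    return(alpha)
  }
  stop("`smoothing` must be \"none\", \"laplace(alpha)\" or a number",
       call. = FALSE)
}

#' Fit single-class conditional-probability tables
#'
#' Estimates, from the windows of one class, the marginal residue
#' distributions at positions -1 and +1 and, for every other flank position,
#' the distribution of its residue conditioned on its nearest neighbor
#' toward the center. All probabilities are relative frequencies; with the
#' default \code{smoothing = "none"} a conditioning symbol never observed at
#' a slot yields an identically-zero column, while \code{"laplace(a)"} adds
#' the pseudo-count \code{a} to every pair count.
#'
#' @param windows character vector of (2*xi+1)-length windows.
#' @param xi window half-width.
#' @param smoothing "none" (default), "laplace(alpha)", or a numeric
#'   pseudo-count.
#' @return an object of class \code{class_tables}: \code{xi},
#'   \code{alphabet}, \code{marginal_minus1}, \code{marginal_plus1}, and
#'   \code{conditionals}, a list keyed by position ("-2".."-xi",
#'   "+2".."+xi") of 21 x 21 matrices \code{P[a, b] = p(outer = a | inner = b)}.
#' @export
fit_class_tables <- function(windows, xi = 10L, smoothing = "none") {
  if (inherits(windows, "data.frame")) windows <- windows$window
  if (!length(windows)) stop("cannot fit tables from an empty sample list",
                             call. = FALSE)
  xi <- as.integer(xi)
  alpha <- parse_smoothing(smoothing)
  M <- window_matrix(windows, xi)
  n <- nrow(M)
  center <- xi + 1L

  conditionals <- list()
  for (k in seq2(2L, xi)) {
    # left: outer position -k at column center-k, inner neighbor -(k-1)
    conditionals[[sprintf("-%d", k)]] <- normalize_conditional(
      count_matrix(M[, center - k], M[, center - k + 1L]), alpha)
    # right: outer position +k at column center+k, inner neighbor +(k-1)
    conditionals[[sprintf("+%d", k)]] <- normalize_conditional(
      count_matrix(M[, center + k], M[, center + k - 1L]), alpha)
  }
  structure(list(
    xi = xi, alphabet = ALPHABET,
    marginal_minus1 = normalize_marginal(count_vector(M[, center - 1L]), n, alpha),
    marginal_plus1 = normalize_marginal(count_vector(M[, center + 1L]), n, alpha),
    conditionals = conditionals),
    class = "class_tables")
}

#' Fit a two-class coupling model from a benchmark dataset
#'
#' Positive-class tables are fitted on the positive subset only and
#' negative-class tables on the negative subset only.
#'
#' @param dataset a \code{\link{benchmark_dataset}}.
#' @param smoothing see \code{\link{fit_class_tables}}.
#' @return an object of class \code{coupling_model}: \code{target},
#'   \code{xi}, \code{smoothing}, \code{positive} and \code{negative}
#'   \code{class_tables}.
#' @export
fit_model <- function(dataset, smoothing = "none") {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  if (nrow(dataset$positives) == 0L || nrow(dataset$negatives) == 0L) {
    stop("both subsets must be non-empty to fit a coupling model",
         call. = FALSE)
  }
  structure(list(
    target = dataset$target, xi = dataset$xi, smoothing = smoothing,
    positive = fit_class_tables(dataset$positives$window, dataset$xi, smoothing),
    negative = fit_class_tables(dataset$negatives$window, dataset$xi, smoothing)),
    class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf(
    "<coupling_model> target %s, xi = %d, smoothing = %s (%d features)\n",
    x$target, x$xi,
    if (is.numeric(x$smoothing)) format(x$smoothing) else x$smoothing,
    2L * x$xi))
  invisible(x)
}

# Per-class probability of each flank residue of each window, as an
# n x 2*xi matrix (columns -xi..-1, +1..+xi).
class_probabilities <- function(M, tables) {
  xi <- tables$xi
  center <- xi + 1L
  n <- nrow(M)
  out <- matrix(NA_real_, n, 2L * xi, dimnames = list(NULL, feature_names(xi)))
  out[, sprintf("m%d", 1L)] <- tables$marginal_minus1[M[, center - 1L]]
  out[, sprintf("p%d", 1L)] <- tables$marginal_plus1[M[, center + 1L]]
  for (k in seq2(2L, xi)) {
    cl <- tables$conditionals[[sprintf("-%d", k)]]
    out[, sprintf("m%d", k)] <- cl[cbind(M[, center - k], M[, center - k + 1L])]
    cr <- tables$conditionals[[sprintf("+%d", k)]]
    out[, sprintf("p%d", k)] <- cr[cbind(M[, center + k], M[, center + k - 1L])]
  }
  out
}

#' Encode windows as sequence-coupled difference features
#'
#' Each window becomes the 2*xi-vector of positive-class minus
#' negative-class probabilities of its flank residues, ordered
#' -xi, ..., -1, +1, ..., +xi (feature names "m&lt;k&gt;", "p&lt;k&gt;").
#'
#' @param windows character vector of windows (or a sample data frame with a
#'   \code{window} column).
#' @param model a \code{\link{coupling_model}}.
#' @return numeric matrix with one row per window and 2*xi columns; every
#'   entry lies in [-1, 1].
#' @export
encode <- function(windows, model) {
  stopifnot(inherits(model, "coupling_model"))
  if (inherits(windows, "data.frame")) windows <- windows$window
  M <- window_matrix(windows, model$xi)
  class_probabilities(M, model$positive) - class_probabilities(M, model$negative)
}

#' Encode a whole benchmark dataset
#'
#' @param dataset a \code{\link{benchmark_dataset}}.
#' @param model a \code{\link{coupling_model}}.
#' @return list with \code{features} (rows: positives then negatives, each
#'   in subset order; 2*xi columns) and \code{labels} (1 = positive,
#'   0 = negative).
#' @export
encode_dataset <- function(dataset, model) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  windows <- c(dataset$positives$window, dataset$negatives$window)
  list(features = encode(windows, model),
       labels = c(rep(1L, nrow(dataset$positives)),
                  rep(0L, nrow(dataset$negatives))))
}

#' Write a coupling model to a structured text file
#'
#' Plain-text key/value + table layout; \code{\link{read_coupling_model}}
#' round-trips exactly (probabilities serialized at full double precision).
#'
#' @param model a \code{\link{coupling_model}}.
#' @param path output path.
#' @export
write_coupling_model <- function(model, path) {
  stopifnot(inherits(model, "coupling_model"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# hydroxysite coupling model v1",
    paste0("target\t", model$target),
    paste0("xi\t", model$xi),
    paste0("smoothing\t", if (is.numeric(model$smoothing))
      fmt(model$smoothing) else model$smoothing))
  for (cls in c("positive", "negative")) {
    tb <- model[[cls]]
    lines <- c(lines,
               paste0("[", cls, " marginal -1]"),
               paste(ALPHABET, fmt(tb$marginal_minus1), sep = "\t"),
               paste0("[", cls, " marginal +1]"),
               paste(ALPHABET, fmt(tb$marginal_plus1), sep = "\t"))
    for (pos in names(tb$conditionals)) {
      m <- tb$conditionals[[pos]]
      lines <- c(lines, paste0("[", cls, " conditional ", pos, "]"),
                 vapply(seq_len(nrow(m)), function(i) {
                   paste(c(ALPHABET[i], fmt(m[i, ])), collapse = "\t")
                 }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a coupling model written by \code{\link{write_coupling_model}}
#'
#' @param path input path.
#' @return a \code{\link{coupling_model}}.
#' @export
read_coupling_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(lines[1:3], "\t", fixed = TRUE)
  header <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
  xi <- as.integer(header[["xi"]])
  smoothing <- header[["smoothing"]]
  if (grepl("^[0-9.eE+-]+$", smoothing)) smoothing <- as.numeric(smoothing)

  body <- lines[-(1:3)]
  section_at <- which(startsWith(body, "["))
  sections <- list()
  for (i in seq_along(section_at)) {
    from <- section_at[i] + 1L
    to <- if (i < length(section_at)) section_at[i + 1L] - 1L else length(body)
    name <- gsub("^\\[|\\]$", "", body[section_at[i]])
    sections[[name]] <- body[from:to]
  }
  read_marg <- function(block) {
    parts <- strsplit(block, "\t", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                    vapply(parts, `[`, character(1), 1))[ALPHABET]
  }
  read_cond <- function(block) {
    parts <- strsplit(block, "\t", fixed = TRUE)
    m <- t(vapply(parts, function(p) as.numeric(p[-1]),
                  numeric(length(ALPHABET))))
    dimnames(m) <- list(vapply(parts, `[`, character(1), 1), ALPHABET)
    m[ALPHABET, ]
  }
  tables_for <- function(cls) {
    ks <- seq2(2L, xi)
    # fit order: -k and +k interleaved per k
    cond_names <- as.vector(rbind(sprintf("-%d", ks), sprintf("+%d", ks)))
    conds <- lapply(cond_names, function(pos) {
      read_cond(sections[[paste(cls, "conditional", pos)]])
    })
    names(conds) <- cond_names
    structure(list(
      xi = xi, alphabet = ALPHABET,
      marginal_minus1 = read_marg(sections[[paste(cls, "marginal -1")]]),
      marginal_plus1 = read_marg(sections[[paste(cls, "marginal +1")]]),
      conditionals = conds), class = "class_tables")
  }
  structure(list(target = header[["target"]], xi = xi, smoothing = smoothing,
                 positive = tables_for("positive"),
                 negative = tables_for("negative")),
            class = "coupling_model")
}
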