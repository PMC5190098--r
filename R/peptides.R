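#' Protein record
#'
#' A single protein sequence with an accession-like identifier. The sequence
#' is normalized on construction: uppercased, whitespace removed, and any
#' letter outside the 20 standard amino acids mapped to the dummy residue
#' \code{X}.
#'
#' @param id accession-like identifier (single string).
#' @param sequence amino-acid sequence (single string); normalized.
#' @return an object of class \code{protein_record} with fields \code{id}
#'   and \code{sequence}.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  sequence <- normalize_sequence(sequence)
  if (!nzchar(sequence)) {
    stop(sprintf("protein '%s' has an empty sequence", id), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Annotated protein
#'
#' A protein together with the 1-based positions of its experimentally
#' verified hydroxylation sites. Positions must index a residue equal to the
#' dataset's target letter; this is checked when windows are extracted
#' (the annotation object itself only checks bounds, so it can be built
#' before the target residue is chosen).
#'
#' @param protein a \code{\link{protein_record}}.
#' @param sites integer vector of 1-based site positions (possibly empty).
#' @return an object of class \code{annotated_protein}.
#' @export
annotated_protein <- function(protein, sites = integer(0)) {
  stopifnot(inherits(protein, "protein_record"))
  sites <- sort(unique(as.integer(sites)))
  L <- nchar(protein$sequence)
  if (length(sites) && (any(sites < 1L) || any(sites > L))) {
    stop(sprintf("site positions out of range [1, %d] for protein '%s'",
                 L, protein$id), call. = FALSE)
  }
  structure(list(protein = protein, sites = sites),
            class = "annotated_protein")
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are normalized (uppercased; non-standard letters mapped to
#' \code{X}). The record identifier is the header text up to the first
#' whitespace. Order is preserved.
#'
#' @param path path to a FASTA file.
#' @return list of \code{\link{protein_record}} objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: '%s'", path), call. = FALSE)
  }
  # BStringSet: accept any byte content, then run our own normalizer so that
  # lowercase input and unusual letters (B, J, O, U, Z, *) survive parsing.
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    if (!nzchar(seqs[i])) {
      stop(sprintf("FASTA record '%s' has an empty sequence", ids[i]),
           call. = FALSE)
    }
    protein_record(ids[i], seqs[i])
  })
}

#' Read site annotations from a TSV file
#'
#' Expects a header line and columns \code{protein_id} and \code{position}
#' (1-based).
#'
#' @param path path to the annotation TSV.
#' @return data frame with columns \code{protein_id}, \code{position}.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns 'protein_id' and 'position'",
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df[, need]
}

#' Attach site annotations to proteins
#'
#' @param proteins list of \code{\link{protein_record}}.
#' @param annotations data frame from \code{\link{read_site_annotations}}.
#' @return list of \code{\link{annotated_protein}}, in input order; proteins
#'   without annotation rows get an empty site set.
#' @export
annotate_proteins <- function(proteins, annotations) {
  lapply(proteins, function(p) {
    sites <- annotations$position[annotations$protein_id == p$id]
    annotated_protein(p, sites)
  })
}

# Build the (2*xi+1)-residue window centered at 1-based position `center`,
# padding out-of-range slots with X.
window_at <- function(chars, center, xi) {
  idx <- (center - xi):(center + xi)
  w <- rep("X", length(idx))
  ok <- idx >= 1L & idx <= length(chars)
  w[ok] <- chars[idx[ok]]
  paste(w, collapse = "")
}

#' Extract centered peptide windows from an annotated protein
#'
#' Slides a (2*xi+1)-residue window along the sequence and emits one sample
#' per occurrence of the target residue, X-padded at the termini. A sample is
#' labeled positive when its center position is an annotated site, negative
#' otherwise.
#'
#' @param annotated an \code{\link{annotated_protein}}.
#' @param target center residue letter ("P" or "K").
#' @param xi window half-width (window length is 2*xi+1).
#' @return data frame with columns \code{window}, \code{center},
#'   \code{label} ("positive"/"negative"), \code{source_id},
#'   \code{center_position}, ordered by center position.
#' @export
extract_samples <- function(annotated, target, xi = 10L) {
  stopifnot(inherits(annotated, "annotated_protein"))
  stop_if_not_single_residue(target)
  xi <- as.integer(xi)
  if (is.na(xi) || xi < 1L) stop("`xi` must be a positive integer", call. = FALSE)

  p <- annotated$protein
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sites <- annotated$sites
  bad <- sites[chars[sites] != target]
  if (length(bad)) {
    stop(sprintf(
      "protein '%s': annotated position(s) %s are '%s', not the target residue '%s'",
      p$id, paste(bad, collapse = ", "),
      paste(chars[bad], collapse = ","), target), call. = FALSE)
  }
  centers <- which(chars == target)
  if (!length(centers)) {
    return(data.frame(window = character(0), center = character(0),
                      label = character(0), source_id = character(0),
                      center_position = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    window = vapply(centers, function(c) window_at(chars, c, xi), character(1)),
    center = target,
    label = ifelse(centers %in% sites, "positive", "negative"),
    source_id = p$id,
    center_position = as.integer(centers),
    stringsAsFactors = FALSE
  )
}

#' Benchmark dataset of screened peptide samples
#'
#' Container for the positive (true-site) and negative (non-site) peptide
#' subsets used to train and evaluate a predictor for one target residue.
#' Invariants: every window has length 2*xi+1 with the target letter at its
#' center; no duplicate windows within a subset; no window occurs in both
#' subsets.
#'
#' @param target center residue letter.
#' @param xi window half-width.
#' @param positives,negatives sample data frames as produced by
#'   \code{\link{extract_samples}}.
#' @param screening optional list of screening statistics.
#' @return an object of class \code{benchmark_dataset}.
#' @export
benchmark_dataset <- function(target, xi, positives, negatives,
                              screening = NULL) {
  stop_if_not_single_residue(target)
  xi <- as.integer(xi)
  width <- 2L * xi + 1L
  for (nm in c("positives", "negatives")) {
    df <- if (nm == "positives") positives else negatives
    if (any(nchar(df$window) != width)) {
      stop(sprintf("%s contain windows whose length is not 2*xi+1 = %d",
                   nm, width), call. = FALSE)
    }
    if (any(substr(df$window, xi + 1L, xi + 1L) != target)) {
      stop(sprintf("%s contain windows whose center is not '%s'", nm, target),
           call. = FALSE)
    }
    if (anyDuplicated(df$window)) {
      stop(sprintf("duplicate windows within %s", nm), call. = FALSE)
    }
  }
  if (length(intersect(positives$window, negatives$window))) {
    stop("self-conflict: identical window present in both subsets",
         call. = FALSE)
  }
  structure(list(target = target, xi = xi,
                 positives = positives, negatives = negatives,
                 screening = screening),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf(
    "<benchmark_dataset> target %s, xi = %d: %d positive + %d negative = %d samples\n",
    x$target, x$xi, nrow(x$positives), nrow(x$negatives),
    nrow(x$positives) + nrow(x$negatives)))
  invisible(x)
}

#' Build a screened benchmark dataset from annotated proteins
#'
#' Concatenates the windows of all proteins, splits them into positive and
#' negative subsets, removes duplicate windows within each subset (keeping
#' the first occurrence in input order), and removes self-conflict windows
#' (windows occurring in both subsets) from both subsets.
#'
#' @param annotated_list list of \code{\link{annotated_protein}}.
#' @inheritParams extract_samples
#' @return a \code{\link{benchmark_dataset}}; its \code{screening} field
#'   records total windows extracted and the number of duplicates and
#'   conflicts removed per subset.
#' @export
build_benchmark <- function(annotated_list, target, xi = 10L) {
  all_samples <- do.call(rbind, lapply(annotated_list, extract_samples,
                                       target = target, xi = xi))
  if (is.null(all_samples) || nrow(all_samples) == 0L) {
    stop("no windows extracted: no protein contains the target residue",
         call. = FALSE)
  }
  pos <- all_samples[all_samples$label == "positive", , drop = FALSE]
  neg <- all_samples[all_samples$label == "negative", , drop = FALSE]

  dup_pos <- sum(duplicated(pos$window))
  dup_neg <- sum(duplicated(neg$window))
  pos <- pos[!duplicated(pos$window), , drop = FALSE]
  neg <- neg[!duplicated(neg$window), , drop = FALSE]

  conflict <- intersect(pos$window, neg$window)
  conflict_pos <- sum(pos$window %in% conflict)
  conflict_neg <- sum(neg$window %in% conflict)
  pos <- pos[!pos$window %in% conflict, , drop = FALSE]
  neg <- neg[!neg$window %in% conflict, , drop = FALSE]

  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop(paste0("screening left an empty ",
                if (nrow(pos) == 0L) "positive" else "negative",
                " subset: the dataset cannot support model fitting"),
         call. = FALSE)
  }
  rownames(pos) <- NULL
  rownames(neg) <- NULL
  benchmark_dataset(target, xi, pos, neg, screening = list(
    total_windows = nrow(all_samples),
    dup_removed_pos = dup_pos, dup_removed_neg = dup_neg,
    conflict_removed_pos = conflict_pos, conflict_removed_neg = conflict_neg))
}

#' Write a benchmark dataset to file
#'
#' Two dialects are supported. \code{format = "fasta"} (default) writes one
#' record per sample with header \code{>source_id|center_position|pos} (or
#' \code{|neg}) and the window as the sequence line. \code{format = "tsv"}
#' writes a header line and columns \code{window}, \code{label},
#' \code{source_id}, \code{center_position}. A write/read round trip
#' reproduces the dataset exactly.
#'
#' @param dataset a \code{\link{benchmark_dataset}}.
#' @param path output path.
#' @param format "fasta" or "tsv".
#' @export
write_benchmark <- function(dataset, path, format = c("fasta", "tsv")) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  format <- match.arg(format)
  df <- rbind(dataset$positives, dataset$negatives)
  if (format == "fasta") {
    lab <- ifelse(df$label == "positive", "pos", "neg")
    lines <- as.vector(rbind(
      sprintf(">%s|%d|%s", df$source_id, df$center_position, lab),
      df$window))
    writeLines(lines, path)
  } else {
    utils::write.table(
      df[, c("window", "label", "source_id", "center_position")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a benchmark dataset from file
#'
#' Auto-detects the dialect from the first character: \code{>} means the
#' FASTA dialect of \code{\link{write_benchmark}}, anything else the TSV
#' dialect (header line required).
#'
#' @param path input path.
#' @param target expected center residue letter.
#' @param xi expected window half-width; every window must have length
#'   2*xi+1.
#' @return a \code{\link{benchmark_dataset}}.
#' @export
read_benchmark <- function(path, target, xi = 10L) {
  stop_if_not_single_residue(target)
  xi <- as.integer(xi)
  if (!file.exists(path)) {
    stop(sprintf("benchmark file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("benchmark file '%s' is empty", path),
                           call. = FALSE)
  if (startsWith(lines[1], ">")) {
    df <- parse_benchmark_fasta(lines, path)
  } else {
    df <- parse_benchmark_tsv(path)
  }
  width <- 2L * xi + 1L
  badlen <- which(nchar(df$window) != width)
  if (length(badlen)) {
    stop(sprintf(
      "benchmark file '%s': window %d has length %d, expected 2*xi+1 = %d",
      path, badlen[1], nchar(df$window[badlen[1]]), width), call. = FALSE)
  }
  df$window <- normalize_sequence(df$window)
  df$center <- target
  pos <- df[df$label == "positive", , drop = FALSE]
  neg <- df[df$label == "negative", , drop = FALSE]
  rownames(pos) <- NULL
  rownames(neg) <- NULL
  cols <- c("window", "center", "label", "source_id", "center_position")
  benchmark_dataset(target, xi, pos[, cols], neg[, cols])
}

parse_benchmark_fasta <- function(lines, path) {
  hdr_idx <- which(startsWith(lines, ">"))
  if (!all(diff(hdr_idx) == 2L) || length(lines) != 2L * length(hdr_idx)) {
    stop(sprintf(
      "benchmark file '%s': expected alternating header/window lines", path),
      call. = FALSE)
  }
  hdr <- sub("^>", "", lines[hdr_idx])
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L |
                 !vapply(parts, function(p) p[3] %in% c("pos", "neg"),
                         logical(1)))
  if (length(bad)) {
    stop(sprintf(
      "benchmark file '%s', line %d: malformed header '>%s' (expected >source|position|pos|neg)",
      path, hdr_idx[bad[1]], hdr[bad[1]]), call. = FALSE)
  }
  data.frame(
    window = lines[hdr_idx + 1L],
    label = ifelse(vapply(parts, `[`, character(1), 3) == "pos",
                   "positive", "negative"),
    source_id = vapply(parts, `[`, character(1), 1),
    center_position = as.integer(vapply(parts, `[`, character(1), 2)),
    stringsAsFactors = FALSE)
}

parse_benchmark_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("window", "label", "source_id", "center_position")
  if (!all(need %in% names(df))) {
    stop(sprintf(
      "benchmark file '%s': TSV dialect needs columns %s",
      path, paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!df$label %in% c("positive", "negative"))
  if (length(bad)) {
    stop(sprintf("benchmark file '%s', line %d: label '%s' is not positive/negative",
                 path, bad[1] + 1L, df$label[bad[1]]), call. = FALSE)
  }
  df$center_position <- as.integer(df$center_position)
  df
}
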