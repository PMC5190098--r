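# Independent brute-force oracles and tiny fixture builders. These
# deliberately re-derive quantities with explicit loops / closed forms so
# they share no code path with the package implementation.

# Probability of residue `a` at signed window position `pos` (e.g. -1, +4),
# conditioned on residue `b` at the neighbor toward the center when
# abs(pos) >= 2, by direct scanning of the windows.
oracle_prob <- function(windows, xi, pos, a, b = NULL) {
  chars <- strsplit(windows, "", fixed = TRUE)
  col <- xi + 1L + pos
  if (abs(pos) == 1L) {
    hits <- 0L
    for (w in chars) if (w[col] == a) hits <- hits + 1L
    return(hits / length(windows))
  }
  inner <- col - sign(pos)
  num <- 0L; den <- 0L
  for (w in chars) {
    if (w[inner] == b) {
      den <- den + 1L
      if (w[col] == a) num <- num + 1L
    }
  }
  if (den == 0L) 0 else num / den
}

# Standard Matthews correlation from the TP/TN/FP/FN contingency table.
oracle_mcc <- function(n_pos, n_neg, miss_pos, false_pos) {
  tp <- n_pos - miss_pos; fn <- miss_pos
  tn <- n_neg - false_pos; fp <- false_pos
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  (tp * tn - fp * fn) / den
}

# AUC as the fraction of (positive, negative) pairs ranked concordantly,
# ties counted one half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (p in sp) for (n in sn) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(sp) * length(sn))
}

# Benchmark dataset from explicit window lists (bypasses protein plumbing).
make_bm <- function(pos_windows, neg_windows, xi, target = "P") {
  row <- function(w, lab, i) data.frame(
    window = w, center = target, label = lab,
    source_id = sprintf("%s%d", toupper(substr(lab, 1, 1)), i),
    center_position = xi + 1L, stringsAsFactors = FALSE)
  pos <- do.call(rbind, Map(row, pos_windows, "positive",
                            seq_along(pos_windows)))
  neg <- do.call(rbind, Map(row, neg_windows, "negative",
                            seq_along(neg_windows)))
  rownames(pos) <- rownames(neg) <- NULL
  benchmark_dataset(target, xi, pos, neg)
}

# Random windows over the 20 standard residues with the target at center.
rand_windows <- function(n, xi, target = "P") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    w <- sample(aa, 2 * xi + 1, replace = TRUE)
    w[xi + 1] <- target
    paste(w, collapse = "")
  }, character(1))
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
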