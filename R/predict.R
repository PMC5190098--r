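#' Scan a protein for predicted hydroxylation sites
#'
#' Builds an X-padded window around every occurrence of the target residue
#' (exactly as in \code{\link{extract_samples}}), encodes the windows with
#' the coupling model and scores them with the forest. The self-consistency
#' principle is enforced: a model trained for one center residue refuses to
#' score the other.
#'
#' @param protein a \code{\link{protein_record}}.
#' @param target residue to scan for ("P" or "K"); must equal the model's
#'   training target.
#' @param model a \code{\link{coupling_model}}.
#' @param forest a \code{\link{trained_forest}}.
#' @param threshold vote-fraction decision threshold in [0, 1].
#' @return data frame with one row per target occurrence, in position
#'   order: \code{protein_id}, \code{position} (1-based), \code{residue},
#'   \code{score}, \code{predicted}.
#' @export
scan_protein <- function(protein, target, model, forest, threshold = 0.5) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(model, "coupling_model"),
            inherits(forest, "trained_forest"))
  stop_if_not_single_residue(target)
  if (!identical(model$target, target)) {
    stop(sprintf(
      "self-consistency violation: model was trained for center residue '%s' but '%s' was requested",
      model$target, target), call. = FALSE)
  }
  if (forest$feature_count != 2L * model$xi) {
    stop("forest and coupling model disagree on the feature count",
         call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  samples <- extract_samples(annotated_protein(protein), target, model$xi)
  if (nrow(samples) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), score = numeric(0),
                      predicted = logical(0), stringsAsFactors = FALSE))
  }
  scores <- predict_scores(forest, encode(samples$window, model))
  data.frame(protein_id = protein$id, position = samples$center_position,
             residue = target, score = scores,
             predicted = scores >= threshold, stringsAsFactors = FALSE)
}

#' Batch site prediction over a FASTA file
#'
#' Scans every protein in \code{fasta_path} with the bundle's model and
#' writes a TSV report: comment lines summarizing each protein (number of
#' target residues and of predicted sites), then one data row per candidate
#' site with columns \code{protein_id}, \code{position}, \code{residue},
#' \code{score}, \code{predicted}. Proteins appear in input order.
#'
#' @param fasta_path query FASTA file.
#' @param bundle_path prediction bundle from \code{\link{write_bundle}}.
#' @param output_path output TSV path.
#' @param target residue to scan for; must match the bundle (checked before
#'   any scanning).
#' @param threshold decision threshold.
#' @return (invisibly) the combined prediction data frame.
#' @export
run_batch <- function(fasta_path, bundle_path, output_path,
                      target = NULL, threshold = 0.5) {
  bundle <- read_bundle(bundle_path)
  if (is.null(target)) target <- bundle$target
  if (!identical(target, bundle$target)) {
    stop(sprintf(
      "bundle was trained for center residue '%s' but '%s' was requested",
      bundle$target, target), call. = FALSE)
  }
  proteins <- read_fasta(fasta_path)

  per_protein <- lapply(proteins, scan_protein, target = target,
                        model = bundle$coupling, forest = bundle$forest,
                        threshold = threshold)
  summaries <- vapply(seq_along(proteins), function(i) {
    sprintf("# %s: %d %s residue(s), %d predicted site(s)",
            proteins[[i]]$id, nrow(per_protein[[i]]),
            target, sum(per_protein[[i]]$predicted))
  }, character(1))
  combined <- do.call(rbind, per_protein)

  con <- file(output_path, "w")
  on.exit(close(con))
  writeLines(summaries, con)
  utils::write.table(combined, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(combined)
}
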