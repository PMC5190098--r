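# Synthetic annotated proteins with known class-specific neighbor coupling.
#
# The generator emulates exactly the statistical structure the
# sequence-coupled encoder assumes: flanks of true sites are drawn outward
# from the center by a first-order Markov chain under a positive-class
# marginal/conditional table pair, flanks of non-sites under a
# negative-class pair. coupling_strength interpolates linearly between a
# shared background table set (0: the two classes are indistinguishable)
# and independently sampled class tables (1: maximal class signal).
# Flank residues exclude the target letter, so every occurrence of the
# target in a generated protein is a deliberately planted candidate site
# and windows never overlap (candidate centers are spaced > 2*xi apart).

#' Specification for the synthetic-data generator
#'
#' @param target center residue letter ("P" or "K").
#' @param xi window half-width.
#' @param n_proteins number of proteins to generate.
#' @param length_range integer (min, max) protein length; must admit at
#'   least one full window (min >= 2*xi+1).
#' @param site_density fraction of planted target residues that are true
#'   sites, in [0, 1].
#' @param coupling_strength in [0, 1]: 0 = positive and negative flank
#'   distributions identical, 1 = independently sampled class tables,
#'   intermediate values interpolate linearly entry-wise.
#' @param background probability vector over the 20 standard residues used
#'   for filler sequence between windows (default uniform); renormalized
#'   over the 19 non-target letters inside flanks.
#' @param concentration Dirichlet concentration for sampling the random
#'   probability tables (moderate values give tables without vanishingly
#'   rare symbols, keeping parameter recovery well-conditioned).
#' @param seed integer RNG seed; everything the generator draws is
#'   reproducible from it.
#' @return an object of class \code{generator_spec}.
#' @export
generator_spec <- function(target = "P", xi = 10L, n_proteins = 30L,
                           length_range = c(200L, 400L), site_density = 0.2,
                           coupling_strength = 1, background = NULL,
                           concentration = 5, seed = 1L) {
  stop_if_not_single_residue(target)
  xi <- as.integer(xi)
  if (xi < 1L) stop("`xi` must be >= 1", call. = FALSE)
  if (site_density < 0 || site_density > 1) {
    stop("`site_density` must be in [0, 1]", call. = FALSE)
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("`coupling_strength` must be in [0, 1]", call. = FALSE)
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1] > length_range[2]) {
    stop("`length_range` must be an increasing integer pair", call. = FALSE)
  }
  if (length_range[1] < 2L * xi + 1L) {
    stop(sprintf("`length_range` too small to host a window: min length must be >= 2*xi+1 = %d",
                 2L * xi + 1L), call. = FALSE)
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    if (length(background) != 20L || any(background < 0) ||
        abs(sum(background) - 1) > 1e-9) {
      stop("`background` must be a probability vector over the 20 residues",
           call. = FALSE)
    }
    background <- stats::setNames(as.numeric(background), AA20)
  }
  structure(list(target = target, xi = xi,
                 n_proteins = as.integer(n_proteins),
                 length_range = length_range, site_density = site_density,
                 coupling_strength = coupling_strength,
                 background = background, concentration = concentration,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Dirichlet draw over the flank alphabet, embedded into the 21-symbol
# alphabet with zero mass on the target letter and on X.
sample_distribution <- function(flank, concentration) {
  g <- stats::rgamma(length(flank), shape = concentration)
  p <- stats::setNames(rep(0, length(ALPHABET)), ALPHABET)
  p[flank] <- g / sum(g)
  p
}

sample_conditional <- function(flank, concentration) {
  m <- matrix(0, length(ALPHABET), length(ALPHABET),
              dimnames = list(ALPHABET, ALPHABET))
  for (b in flank) {
    g <- stats::rgamma(length(flank), shape = concentration)
    m[flank, b] <- g / sum(g)
  }
  m
}

# Draws the shared + class-specific tables and interpolates; must be called
# inside an established RNG state.
draw_tables <- function(spec) {
  flank <- setdiff(AA20, spec$target)
  one_set <- function() list(
    marginal = sample_distribution(flank, spec$concentration),
    conditional = sample_conditional(flank, spec$concentration))
  shared <- one_set()
  pos_ind <- one_set()
  neg_ind <- one_set()
  s <- spec$coupling_strength
  mix <- function(ind) list(
    marginal = (1 - s) * shared$marginal + s * ind$marginal,
    conditional = (1 - s) * shared$conditional + s * ind$conditional)
  structure(list(target = spec$target, xi = spec$xi,
                 coupling_strength = s,
                 positive = mix(pos_ind), negative = mix(neg_ind)),
            class = "synthetic_tables")
}

#' Generate the true class probability tables of a synthetic experiment
#'
#' One marginal distribution (used at positions -1 and +1) and one
#' outward conditional matrix \code{P[a, b] = p(outer = a | inner = b)}
#' (used at every other flank position) per class.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return an object of class \code{synthetic_tables} with fields
#'   \code{positive} and \code{negative}, each holding \code{marginal} and
#'   \code{conditional} over the 21-symbol alphabet.
#' @export
generate_tables <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, draw_tables(spec))
}

# Redraw the flanks of a planted candidate outward from the center:
# position -1 (or +1) from the marginal, each further position conditioned
# on its inner neighbor — the exact conditioning direction the encoder fits.
fill_flanks <- function(chars, center, xi, tables) {
  prev <- sample(ALPHABET, 1, prob = tables$marginal)
  chars[center - 1L] <- prev
  for (k in seq2(2L, xi)) {
    cur <- sample(ALPHABET, 1, prob = tables$conditional[, prev])
    chars[center - k] <- cur
    prev <- cur
  }
  prev <- sample(ALPHABET, 1, prob = tables$marginal)
  chars[center + 1L] <- prev
  for (k in seq2(2L, xi)) {
    cur <- sample(ALPHABET, 1, prob = tables$conditional[, prev])
    chars[center + k] <- cur
    prev <- cur
  }
  chars
}

#' Generate annotated synthetic proteins
#'
#' Filler sequence is drawn i.i.d. from the background (minus the target
#' letter); candidate centers are planted at spacings of 2*xi+2 so windows
#' never overlap; the flanks of each candidate are then redrawn from the
#' positive tables (true site, with probability \code{site_density}) or the
#' negative tables. Annotations record the true sites.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return list with \code{proteins} (list of
#'   \code{\link{annotated_protein}}) and \code{tables} (the
#'   \code{synthetic_tables} actually used).
#' @export
generate_proteins <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  flank <- setdiff(AA20, spec$target)
  bg <- spec$background[flank]
  bg <- bg / sum(bg)
  withr::with_seed(spec$seed, {
    tables <- draw_tables(spec)
    proteins <- lapply(seq_len(spec$n_proteins), function(i) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      chars <- sample(flank, L, replace = TRUE, prob = bg)
      centers <- seq(spec$xi + 1L, L - spec$xi, by = 2L * spec$xi + 2L)
      sites <- integer(0)
      for (p in centers) {
        chars[p] <- spec$target
        is_site <- stats::runif(1) < spec$site_density
        tb <- if (is_site) tables$positive else tables$negative
        chars <- fill_flanks(chars, p, spec$xi, tb)
        if (is_site) sites <- c(sites, p)
      }
      annotated_protein(
        protein_record(sprintf("SYN%04d", i), paste(chars, collapse = "")),
        sites)
    })
    list(proteins = proteins, tables = tables)
  })
}

#' Generate a screened synthetic benchmark dataset
#'
#' Convenience wrapper: \code{\link{generate_proteins}} followed by
#' \code{\link{build_benchmark}}.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return list with \code{dataset} (a \code{\link{benchmark_dataset}}),
#'   \code{proteins} and \code{tables}.
#' @export
generate_benchmark <- function(spec) {
  gen <- generate_proteins(spec)
  list(dataset = build_benchmark(gen$proteins, spec$target, spec$xi),
       proteins = gen$proteins, tables = gen$tables)
}

#' Write a synthetic experiment to disk
#'
#' FASTA + site-annotation TSV + a plain-text manifest recording the
#' generator settings and seed.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_synthetic <- function(spec, dir) {
  gen <- generate_proteins(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  sites <- file.path(dir, "sites.tsv")
  manifest <- file.path(dir, "manifest.txt")
  writeLines(unlist(lapply(gen$proteins, function(ap) {
    c(paste0(">", ap$protein$id), ap$protein$sequence)
  })), fasta)
  ann <- do.call(rbind, lapply(gen$proteins, function(ap) {
    if (!length(ap$sites)) return(NULL)
    data.frame(protein_id = ap$protein$id, position = ap$sites)
  }))
  if (is.null(ann)) ann <- data.frame(protein_id = character(0),
                                      position = integer(0))
  utils::write.table(ann, sites, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    "hydroxysite synthetic experiment",
    sprintf("target\t%s", spec$target),
    sprintf("xi\t%d", spec$xi),
    sprintf("n_proteins\t%d", spec$n_proteins),
    sprintf("length_range\t%d-%d", spec$length_range[1], spec$length_range[2]),
    sprintf("site_density\t%g", spec$site_density),
    sprintf("coupling_strength\t%g", spec$coupling_strength),
    sprintf("concentration\t%g", spec$concentration),
    sprintf("seed\t%d", spec$seed)), manifest)
  invisible(c(fasta = fasta, sites = sites, manifest = manifest))
}
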