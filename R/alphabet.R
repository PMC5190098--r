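#' @keywords internal
#' @importFrom randomForest randomForest
#' @importFrom stats predict
"_PACKAGE"

# The 20 standard amino acids in alphabetical one-letter order, plus the
# dummy residue X used both for terminal padding and as the sink for
# non-standard letters (B, J, O, U, Z, *, ...).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ALPHABET <- c(AA20, "X")

#' Normalize a protein sequence string
#'
#' Uppercases the sequence, strips whitespace, and maps every character
#' outside the 20 standard amino-acid letters to the dummy residue \code{X}.
#'
#' @param x character vector of raw sequences.
#' @return character vector of normalized sequences over the 21-letter
#'   alphabet (20 standard residues + \code{X}).
#' @examples
#' normalize_sequence("mkb u")  # "MKXX"
#' @export
normalize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[!ch %in% AA20] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# from:to that is empty (not reversed) when to < from
seq2 <- function(from, to) if (to < from) integer(0) else from:to

# Positions -xi..-1, +1..+xi as the canonical feature labels ("m10"..."p10").
feature_names <- function(xi) {
  c(paste0("m", xi:1), paste0("p", 1:xi))
}

stop_if_not_single_residue <- function(target) {
  if (!is.character(target) || length(target) != 1L || nchar(target) != 1L ||
      !target %in% AA20) {
    stop("`target` must be a single standard amino-acid letter (e.g. \"P\" or \"K\")",
         call. = FALSE)
  }
  invisible(target)
}
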