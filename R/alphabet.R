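#' The 20 canonical amino acids
#'
#' One-letter codes of the 20 standard residues, in the lexicographic order
#' used throughout the package to index the tri-peptide attribute space.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

N_TRIPEPTIDES <- 20L^3L

# residue positions of each of the 8000 attribute tri-peptides,
# first position varying slowest (lexicographic order)
.tri_pos1 <- rep(1:20, each = 400L)
.tri_pos2 <- rep(rep(1:20, each = 20L), times = 20L)
.tri_pos3 <- rep(1:20, times = 400L)

#' Tri-peptide attribute index
#'
#' The fixed bijection between the \eqn{20^3 = 8000} tri-peptides over the
#' 20-letter amino-acid alphabet and attribute positions \eqn{1..8000}.
#' Ordering is lexicographic over [AA_ALPHABET] and stable across runs, so
#' feature vectors, propensity tables and attribute weights are always
#' directly comparable.
#'
#' @return Character vector of length 8000; element `i` is the tri-peptide
#'   occupying attribute `i`.
#' @examples
#' head(tripeptide_index())   # "AAA" "AAC" "AAD" ...
#' @export
tripeptide_index <- function() {
  paste0(AA_ALPHABET[.tri_pos1], AA_ALPHABET[.tri_pos2], AA_ALPHABET[.tri_pos3])
}

#' Map tri-peptide strings to attribute indices
#'
#' @param tri Character vector of 3-letter tri-peptides.
#' @return Integer attribute indices in `1:8000`.
#' @export
tripeptide_to_index <- function(tri) {
  stopifnot(is.character(tri))
  bad <- nchar(tri) != 3L
  if (any(bad)) stop("tri-peptides must have exactly 3 residues: ",
                     paste(tri[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  m <- matrix(match(unlist(strsplit(tri, "")), AA_ALPHABET), nrow = 3L)
  if (anyNA(m)) stop("non-standard residue in tri-peptide(s): ",
                     paste(unique(tri[colSums(is.na(m)) > 0]), collapse = ", "))
  (m[1L, ] - 1L) * 400L + (m[2L, ] - 1L) * 20L + m[3L, ]
}

# integer-encode one peptide; errors name the first offending position
peptide_ints <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  chars <- strsplit(toupper(peptide), "")[[1]]
  ints <- match(chars, AA_ALPHABET)
  if (anyNA(ints)) {
    at <- which(is.na(ints))[1L]
    stop(sprintf("non-standard residue '%s' at position %d of peptide '%s'",
                 chars[at], at, peptide), call. = FALSE)
  }
  ints
}

# TRUE for sequences made only of the 20 canonical residues
is_standard_peptide <- function(x) {
  !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), toupper(x))
}
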