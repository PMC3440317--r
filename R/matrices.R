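#' Load a bundled amino-acid substitution matrix
#'
#' Returns one of the standard published substitution matrices used by the
#' tri-peptide similarity kernel, restricted to the 20 canonical residues.
#' The integer tables are bundled with the package as plain-text fixtures
#' (NCBI matrix format) and are never fetched at run time.
#'
#' @param name `"blosum62"` or `"pam160"` (case-insensitive).
#' @return A 20x20 symmetric integer matrix with residue dimnames, of class
#'   `"trip_submat"`; attribute `name` carries the matrix identifier.
#' @examples
#' m <- load_substitution_matrix("blosum62")
#' m["A", "A"]   # 4
#' @export
load_substitution_matrix <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  file <- switch(key,
    blosum62 = "BLOSUM62.txt",
    pam160   = "PAM160.txt",
    stop("unknown substitution matrix '", name,
         "'; available: blosum62, pam160", call. = FALSE)
  )
  path <- system.file("extdata", file, package = "tripitope", mustWork = TRUE)
  m <- read_ncbi_matrix(path)
  attr(m, "name") <- key
  class(m) <- c("trip_submat", class(m))
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix format used by BLAST and the NCBI
#' matrix distribution: `#` comment lines, a header row of residue letters,
#' then one labelled row of integer scores per residue. Only the 20
#' canonical residues are retained; the result is checked for symmetry and
#' completeness.
#'
#' @param path Path to the matrix file.
#' @return A 20x20 symmetric integer matrix with residue dimnames.
#' @export
read_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[[`, character(1L), 1L)
  vals <- lapply(body, function(x) as.integer(x[-1L]))
  if (any(lengths(vals) != length(header)))
    stop("malformed matrix file: row length does not match header: ", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rows, header)
  keep <- intersect(rownames(m), AA_ALPHABET)
  if (length(keep) != 20L)
    stop("matrix does not cover the 20 canonical residues: ", path)
  m <- m[AA_ALPHABET, AA_ALPHABET]
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric: ", path)
  storage.mode(m) <- "integer"
  m
}
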