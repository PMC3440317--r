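#' Sliding-window epitope prediction on a full-length protein
#'
#' Slides a length-`L` window along the protein at the given stride,
#' scores every window with the trained model, and calls windows with a
#' positive decision score putative epitopes. Windows containing
#' non-standard residues are skipped (their spans are attached as
#' `attr(, "skipped")`).
#'
#' @param sequence Full-length protein sequence (single string).
#' @param model A `"trip_model"` trained at window length `L`.
#' @param L Window length; defaults to the model's training length.
#' @param step Stride between window starts (default 1).
#' @param protein_id Identifier used in reports (default `"protein"`).
#' @return data.frame of class `"trip_predictions"` with columns
#'   `protein_id`, `start`, `end` (1-based inclusive), `peptide`, `score`,
#'   `call` (logical, `score > 0`).
#' @export
predict_protein <- function(sequence, model, L = model$L, step = 1L,
                            protein_id = "protein") {
  stopifnot(inherits(model, "trip_model"), step >= 1L)
  sequence <- toupper(as_peptide_chars(sequence)[[1L]])
  n <- nchar(sequence)
  if (n < L)
    stop(sprintf("sequence length %d is shorter than the window length %d",
                 n, L), call. = FALSE)
  starts <- seq.int(1L, n - L + 1L, by = step)
  peps <- substring(sequence, starts, starts + L - 1L)
  ok <- is_standard_peptide(peps)
  skipped <- data.frame(start = starts[!ok], end = starts[!ok] + L - 1L)
  starts <- starts[ok]; peps <- peps[ok]
  if (length(peps) == 0L)
    stop("every window contains non-standard residues", call. = FALSE)
  scores <- score_peptides(model, peps)
  out <- data.frame(protein_id = protein_id, start = starts,
                    end = starts + L - 1L, peptide = peps,
                    score = scores, call = scores > 0,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("trip_predictions", "data.frame")
  out
}

#' Merge overlapping positive windows into putative epitope regions
#'
#' Takes the union of all positively-called window spans and reports each
#' merged region with its best window score.
#'
#' @param predictions A `"trip_predictions"` data.frame.
#' @return data.frame `protein_id`, `start`, `end` (1-based inclusive),
#'   `n_windows`, `max_score`.
#' @export
merge_positive_spans <- function(predictions) {
  pos <- predictions[predictions$call, , drop = FALSE]
  if (nrow(pos) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_score = numeric()))
  out <- lapply(split(pos, pos$protein_id), function(p) {
    ir <- IRanges::IRanges(start = p$start, end = p$end)
    merged <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, merged)
    best <- tapply(p$score[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), max)
    nwin <- tabulate(S4Vectors::subjectHits(hits), nbins = length(merged))
    data.frame(protein_id = p$protein_id[1L],
               start = IRanges::start(merged), end = IRanges::end(merged),
               n_windows = nwin, max_score = as.numeric(best),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write predictions as TSV or BED
#'
#' The TSV report uses 1-based inclusive coordinates; the BED track uses
#' 0-based half-open coordinates with the score in column 5.
#'
#' @param predictions A `"trip_predictions"` data.frame.
#' @param path Output file.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(as.data.frame(predictions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_tsv
#' @export
write_predictions_bed <- function(predictions, path) {
  bed <- data.frame(chrom = predictions$protein_id,
                    chromStart = predictions$start - 1L,
                    chromEnd = predictions$end,
                    name = sprintf("%s_%d", predictions$protein_id,
                                   predictions$start),
                    score = sprintf("%.6g", predictions$score),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
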