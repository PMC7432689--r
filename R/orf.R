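## Longest open reading frame on the forward strand.
##
## An ORF is ATG ... {TAA,TAG,TGA} in one of the three forward frames with
## no internal in-frame stop codon; its length includes the stop codon.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest forward-strand open reading frame
#'
#' Scans the three forward reading frames for `ATG ... stop` stretches with
#' no internal in-frame stop, and returns the longest one. Ties are broken
#' by the 5'-most start, then the lowest frame index, so output is fully
#' deterministic. The reported length includes the stop codon.
#'
#' @param seq a single normalized sequence (character scalar, `DNAString`,
#'   or length-1 `DNAStringSet`).
#' @return list with elements `found` (logical), `start` (1-based index of
#'   the `A` of `ATG`), `end` (1-based inclusive index of the last stop-codon
#'   base), `length` (nucleotides, 0 when not found), and `frame`
#'   (0, 1 or 2; `NA` when not found). `start` and `end` are 0 when no ORF
#'   exists.
#' @export
find_longest_orf <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1)
  L <- nchar(seq)
  none <- list(found = FALSE, start = 0L, end = 0L, length = 0L,
               frame = NA_integer_)
  if (L < 6) return(none)
  best <- NULL
  for (f in 0:2) {
    first <- f + 1L
    if (first > L - 2L) next
    pos <- seq.int(first, L - 2L, by = 3L)   # codon start positions, 1-based
    codons <- substring(seq, pos, pos + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    # first in-frame stop strictly downstream of each ATG
    k <- findInterval(atg, stp) + 1L
    ok <- k <= length(stp)
    if (!any(ok)) next
    atg <- atg[ok]
    len <- (stp[k[ok]] - atg + 1L) * 3L
    i <- which(len == max(len))
    i <- i[which.min(atg[i])]          # 5'-most start among the longest
    cand <- list(found = TRUE,
                 start = pos[atg[i]],
                 end = pos[atg[i]] + len[i] - 1L,
                 length = len[i],
                 frame = f)
    if (is.null(best) ||
        cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start)) {
      best <- cand
    }
  }
  if (is.null(best)) none else best
}

#' Tabulate longest-ORF statistics for a set of transcripts
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector.
#' @return data.frame with columns `id`, `found`, `start`, `end`, `length`,
#'   `frame`, `coverage` (ORF length / transcript length).
#' @export
orf_table <- function(seqs) {
  ch <- as.character(seqs)
  ids <- if (!is.null(names(ch))) names(ch) else as.character(seq_along(ch))
  res <- lapply(ch, find_longest_orf)
  data.frame(
    id = ids,
    found = vapply(res, `[[`, logical(1), "found"),
    start = vapply(res, `[[`, integer(1), "start"),
    end = vapply(res, `[[`, integer(1), "end"),
    length = vapply(res, `[[`, integer(1), "length"),
    frame = vapply(res, `[[`, integer(1), "frame"),
    coverage = vapply(res, `[[`, integer(1), "length") / nchar(ch),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
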