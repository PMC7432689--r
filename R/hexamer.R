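## Hexamer usage-bias score.
##
## A table of in-frame coding hexamer frequencies F_c (step-3 windows
## anchored at each coding transcript's longest-ORF start) and noncoding
## frequencies F_nc (step-1 sliding windows) is estimated from labeled
## training sequences with a pseudocount. A transcript is then scored as
## the mean natural-log ratio log(F_c/F_nc) over its step-1 hexamer
## windows; windows containing N are skipped.

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste0, collapse = ""))
}

hexamer_counts <- function(seqs, step) {
  seqs <- Biostrings::DNAStringSet(as.character(seqs))
  m <- Biostrings::oligonucleotideFrequency(seqs, width = 6, step = step)
  colSums(m)
}

#' Build a coding/noncoding hexamer frequency table
#'
#' Coding frequencies are estimated from in-frame (step-3) hexamers within
#' each coding transcript's longest ORF; when a coding transcript has no
#' ORF, step-3 windows over the full sequence from position 1 are used.
#' Noncoding frequencies come from step-1 sliding windows over the
#' noncoding transcripts. Windows containing `N` are skipped. A pseudocount
#' is added to every one of the 4096 cells before normalization, so both
#' distributions sum to 1 with strictly positive entries.
#'
#' @param coding protein-coding(-like) training sequences
#'   ([Biostrings::DNAStringSet] or character).
#' @param noncoding noncoding training sequences.
#' @param pseudocount value added to every hexamer cell (default 1).
#' @return object of class `hexamer_table`: list with `f_c`, `f_nc`
#'   (named numerics over the 4096 hexamers), `pseudocount`, `k = 6`.
#' @export
build_hexamer_table <- function(coding, noncoding, pseudocount = 1) {
  coding <- as.character(coding)
  noncoding <- as.character(noncoding)
  if (!length(coding) || !length(noncoding)) {
    stop("both coding and noncoding collections must be non-empty")
  }
  regions <- vapply(coding, function(s) {
    orf <- find_longest_orf(s)
    if (orf$found) substr(s, orf$start, orf$end) else s
  }, character(1), USE.NAMES = FALSE)
  cod <- hexamer_counts(regions, step = 3)
  ncod <- hexamer_counts(noncoding, step = 1)
  if (sum(cod) == 0) stop("coding collection yields zero valid hexamers")
  if (sum(ncod) == 0) stop("noncoding collection yields zero valid hexamers")
  f_c <- (cod + pseudocount) / sum(cod + pseudocount)
  f_nc <- (ncod + pseudocount) / sum(ncod + pseudocount)
  structure(list(f_c = f_c, f_nc = f_nc, pseudocount = pseudocount, k = 6L),
            class = "hexamer_table")
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat(sprintf("<hexamer_table> 4096 hexamers, pseudocount = %g\n",
              x$pseudocount))
  invisible(x)
}

#' Write a hexamer table as TSV
#' @param table a `hexamer_table`.
#' @param path output path (columns `hexamer`, `f_c`, `f_nc`).
#' @return `path`, invisibly.
#' @export
write_hexamer_table <- function(table, path) {
  df <- data.frame(hexamer = names(table$f_c),
                   f_c = as.numeric(table$f_c),
                   f_nc = as.numeric(table$f_nc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hexamer table from TSV
#' @param path TSV written by [write_hexamer_table()].
#' @return a `hexamer_table`.
#' @export
read_hexamer_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(f_c = setNames(df$f_c, df$hexamer),
                 f_nc = setNames(df$f_nc, df$hexamer),
                 pseudocount = NA_real_, k = 6L),
            class = "hexamer_table")
}

#' Hexamer log-ratio score of a transcript
#'
#' `S_H = mean over windows of log(F_c(h) / F_nc(h))` with natural
#' logarithm. By default windows slide with step 1 over the whole
#' transcript (`m = L - 6 + 1` when the sequence has no `N`); windows
#' containing `N` are skipped and the mean taken over the remainder. If
#' every window is skipped the score is 0.
#'
#' @param seq a single normalized sequence of length >= 6.
#' @param table a `hexamer_table`.
#' @param step window step, 1 (default) or 3.
#' @return numeric scalar `S_H`.
#' @export
hexamer_score <- function(seq, table, step = 1) {
  seq <- as.character(seq)
  if (nchar(seq) < 6) stop("transcript shorter than 6 nt")
  stopifnot(step %in% c(1, 3))
  cnt <- hexamer_counts(seq, step = step)
  m <- sum(cnt)
  if (m == 0) return(0)
  sum(cnt * (log(table$f_c) - log(table$f_nc))) / m
}
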