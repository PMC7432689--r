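## k-mer frequency vectors, one-hot encoding, and the composite OFH
## feature vector [l_ORF, l_ORF/L, S_F, S_H].

#' k-mer frequency vector of a transcript
#'
#' Counts all step-1 windows of length `k`; windows containing `N` are
#' skipped. Frequencies are counts over the number of valid windows, so
#' the vector sums to 1 whenever at least one valid window exists (and is
#' all-zero otherwise). Entries are in lexicographic k-mer order over
#' A < C < G < T.
#'
#' @param seq a single normalized sequence.
#' @param k word length, 1..8 (default 6).
#' @return named numeric of length `4^k`.
#' @export
kmer_vector <- function(seq, k = 6) {
  seq <- as.character(seq)
  stopifnot(k >= 1, k <= 8)
  if (nchar(seq) < k) stop("transcript shorter than k")
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                              width = k)
  tot <- sum(cnt)
  if (tot == 0) return(cnt * 0)
  cnt / tot
}

#' k-mer frequency matrix for a set of transcripts
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector, all of
#'   length >= `k`.
#' @param k word length (default 6).
#' @return `4^k x N` matrix, one column per transcript.
#' @export
kmer_matrix <- function(seqs, k = 6) {
  seqs <- Biostrings::DNAStringSet(as.character(seqs))
  if (any(Biostrings::width(seqs) < k)) stop("transcript shorter than k")
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  tot <- rowSums(cnt)
  tot[tot == 0] <- 1
  t(cnt / tot)
}

ONEHOT_ROWS <- c("A", "T", "C", "G")

#' One-hot encode a transcript to a 4 x maxlen binary matrix
#'
#' Rows are A, T, C, G with codes (1,0,0,0), (0,1,0,0), (0,0,1,0),
#' (0,0,0,1). Transcripts longer than `maxlen` are truncated to their
#' first `maxlen` nucleotides (5' end); shorter ones are right-padded
#' with all-zero columns. `N` positions give all-zero columns.
#'
#' @param seq a single normalized sequence.
#' @param maxlen fixed matrix width (default 3000).
#' @return 4 x `maxlen` binary matrix with an `effective_len` attribute
#'   (`min(L, maxlen)`).
#' @export
one_hot <- function(seq, maxlen = 3000) {
  seq <- as.character(seq)
  stopifnot(maxlen >= 1)
  L <- nchar(seq)
  eff <- min(L, maxlen)
  m <- matrix(0, 4, maxlen, dimnames = list(ONEHOT_ROWS, NULL))
  if (eff > 0) {
    x <- utf8ToInt(substr(seq, 1, eff))
    row <- match(x, c(65L, 84L, 67L, 71L))   # A, T, C, G
    ok <- !is.na(row)
    m[cbind(row[ok], seq_len(eff)[ok])] <- 1
  }
  attr(m, "effective_len") <- eff
  m
}

#' One-hot encode a set of transcripts into a flat matrix
#'
#' Each transcript's 4 x `maxlen` encoding is flattened column-major into
#' a `(4 * maxlen)`-vector; the result has one column per transcript, the
#' layout the convolutional submodel consumes.
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector.
#' @param maxlen fixed encoding width.
#' @return `(4 * maxlen) x N` matrix.
#' @export
one_hot_matrix <- function(seqs, maxlen = 3000) {
  ch <- as.character(seqs)
  out <- matrix(0, 4 * maxlen, length(ch))
  for (j in seq_along(ch)) {
    L <- nchar(ch[j])
    eff <- min(L, maxlen)
    if (eff == 0) next
    x <- utf8ToInt(substr(ch[j], 1, eff))
    row <- match(x, c(65L, 84L, 67L, 71L))
    ok <- !is.na(row)
    out[(seq_len(eff)[ok] - 1L) * 4L + row[ok], j] <- 1
  }
  out
}

#' OFH feature vector of a transcript
#'
#' The four classic coding-potential summaries: longest-ORF length
#' (nucleotides), ORF coverage `l_ORF / L`, Fickett TESTCODE score `S_F`,
#' and hexamer score `S_H`.
#'
#' @param seq a single normalized sequence of length >= 6.
#' @param lookup a `fickett_lookup`.
#' @param table a `hexamer_table`.
#' @return named numeric `c(l_orf, orf_coverage, fickett, hexamer)`.
#' @export
ofh_vector <- function(seq, lookup, table) {
  seq <- as.character(seq)
  if (nchar(seq) < 6) stop("transcript shorter than 6 nt")
  orf <- find_longest_orf(seq)
  c(l_orf = as.numeric(orf$length),
    orf_coverage = orf$length / nchar(seq),
    fickett = fickett_score(seq, lookup),
    hexamer = hexamer_score(seq, table))
}

#' OFH feature matrix for a set of transcripts
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector.
#' @param lookup a `fickett_lookup`.
#' @param table a `hexamer_table`.
#' @return `4 x N` matrix with rows `l_orf`, `orf_coverage`, `fickett`,
#'   `hexamer`.
#' @export
ofh_matrix <- function(seqs, lookup, table) {
  ch <- as.character(seqs)
  out <- vapply(ch, ofh_vector, numeric(4), lookup = lookup, table = table,
                USE.NAMES = FALSE)
  rownames(out) <- c("l_orf", "orf_coverage", "fickett", "hexamer")
  out
}

#' Export per-transcript features as TSV
#'
#' Columns: `id`, `l_orf`, `orf_coverage`, `fickett`, `hexamer`, then one
#' column per k-mer (header is the k-mer string).
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param lookup a `fickett_lookup`.
#' @param table a `hexamer_table`.
#' @param path output TSV path.
#' @param k k-mer length (default 6).
#' @return the data.frame written, invisibly.
#' @export
write_feature_table <- function(seqs, lookup, table, path, k = 6) {
  ofh <- t(ofh_matrix(seqs, lookup, table))
  km <- t(kmer_matrix(seqs, k))
  ids <- if (!is.null(names(seqs))) names(seqs) else seq_len(nrow(ofh))
  df <- data.frame(id = ids, ofh, km, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
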