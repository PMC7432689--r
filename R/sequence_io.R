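## FASTA input/output and labeled-dataset assembly.
##
## Transcripts are carried as a named Biostrings::DNAStringSet over the
## alphabet {A,C,G,T,N}: names are the record identifiers, widths the
## transcript lengths. All downstream feature code assumes sequences have
## been normalized by read_fasta() / normalize_seq().

#' Normalize raw nucleotide strings to the {A,C,G,T,N} alphabet
#'
#' Uppercases, maps RNA `U` to `T`, and replaces any remaining character
#' outside `A,C,G,T,N` with `N`.
#'
#' @param x character vector of nucleotide strings.
#' @return list with `seq` (normalized character vector) and `n_replaced`
#'   (total count of characters that were replaced by `N`).
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  n_valid <- sum(nchar(gsub("[^ACGTN]", "", x, perl = TRUE)))
  n_replaced <- sum(nchar(x)) - n_valid
  if (n_replaced > 0) x <- gsub("[^ACGTN]", "N", x, perl = TRUE)
  list(seq = x, n_replaced = n_replaced)
}

#' Read transcripts from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token of each
#' header; multi-line sequence bodies are concatenated. Sequences are
#' normalized (uppercase, `U` to `T`); characters outside `A,C,G,T,U,N`
#' are replaced with `N` and reported in a single per-file warning.
#' Records with empty sequences are skipped with a warning.
#'
#' @param path path to a FASTA file.
#' @return named [Biostrings::DNAStringSet] of normalized sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  norm <- normalize_seq(as.character(raw))
  if (norm$n_replaced > 0) {
    warning(sprintf("%s: replaced %d non-ACGTUN character(s) with N",
                    path, norm$n_replaced))
  }
  keep <- nchar(norm$seq) > 0
  if (any(!keep)) {
    warning(sprintf("%s: skipped %d record(s) with empty sequence",
                    path, sum(!keep)))
  }
  out <- Biostrings::DNAStringSet(norm$seq[keep])
  names(out) <- ids[keep]
  out
}

#' Write transcripts to a FASTA file
#'
#' @param seqs named [Biostrings::DNAStringSet] (or character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Keep transcripts at or above a minimum length
#'
#' Mirrors the standard lncRNA dataset-construction step of discarding
#' transcripts shorter than 200 nt. The boundary is inclusive: a transcript
#' of exactly `min_len` nucleotides is kept.
#'
#' @param seqs [Biostrings::DNAStringSet] of transcripts.
#' @param min_len minimum length in nucleotides (default 200).
#' @return the subset with width `>= min_len`, order preserved.
#' @export
filter_min_length <- function(seqs, min_len = 200) {
  stopifnot(is.numeric(min_len), length(min_len) == 1, min_len >= 1)
  seqs[Biostrings::width(seqs) >= min_len]
}

#' Construct a labeled transcript dataset
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param labels integer vector parallel to `seqs`; 1 = lncRNA (positive
#'   class), 0 = protein-coding.
#' @return an object of class `lnc_dataset`.
#' @export
lnc_dataset <- function(seqs, labels) {
  labels <- as.integer(labels)
  if (length(seqs) != length(labels)) {
    stop("seqs and labels must have equal length")
  }
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (protein-coding) or 1 (lncRNA)")
  }
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    stop("duplicate transcript id in dataset: ", dup)
  }
  structure(list(seqs = seqs, labels = labels), class = "lnc_dataset")
}

#' @export
print.lnc_dataset <- function(x, ...) {
  cat(sprintf("<lnc_dataset> %d transcripts (%d lncRNA / %d protein-coding)\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
length.lnc_dataset <- function(x) length(x$labels)

#' Subset an lnc_dataset by index
#' @param x an `lnc_dataset`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.lnc_dataset` <- function(x, i, ...) {
  lnc_dataset(x$seqs[i], x$labels[i])
}

#' Assemble a labeled dataset from two class FASTA files
#'
#' Reads a lncRNA FASTA (labeled 1) and a protein-coding FASTA (labeled 0),
#' applies the minimum-length filter to each, and concatenates. Optionally
#' subsamples each class to `n_per_class` records with a reproducible seed.
#'
#' @param lnc_path FASTA of lncRNA transcripts.
#' @param pc_path FASTA of protein-coding transcripts.
#' @param min_len minimum transcript length (default 200).
#' @param n_per_class optional per-class subsample size.
#' @param seed RNG seed used for subsampling (required when `n_per_class`
#'   is given).
#' @return an `lnc_dataset`.
#' @export
assemble_dataset <- function(lnc_path, pc_path, min_len = 200,
                             n_per_class = NULL, seed = NULL) {
  lnc <- filter_min_length(read_fasta(lnc_path), min_len)
  pc <- filter_min_length(read_fasta(pc_path), min_len)
  shared <- intersect(names(lnc), names(pc))
  if (length(shared)) {
    stop("duplicate transcript id across classes: ", shared[1])
  }
  if (!is.null(n_per_class)) {
    if (is.null(seed)) stop("subsampling requires an explicit seed")
    if (n_per_class > length(lnc) || n_per_class > length(pc)) {
      stop("n_per_class exceeds available transcripts after filtering")
    }
    with_seed(seed, {
      lnc <- lnc[sort(sample.int(length(lnc), n_per_class))]
      pc <- pc[sort(sample.int(length(pc), n_per_class))]
    })
  }
  lnc_dataset(c(lnc, pc), c(rep(1L, length(lnc)), rep(0L, length(pc))))
}

#' Write a dataset manifest as TSV
#'
#' Columns: `id`, `label`, `length`.
#'
#' @param data an `lnc_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(data, path) {
  df <- data.frame(id = names(data$seqs),
                   label = data$labels,
                   length = Biostrings::width(data$seqs),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
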