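## Fickett TESTCODE coding-potential score.
##
## Eight statistics per transcript: for each base B in {A,C,G,T} a
## codon-position asymmetry value B_pos = MAX(B1,B2,B3)/(MIN(B1,B2,B3)+1),
## where B1..B3 count B at transcript positions congruent to 0,1,2 mod 3,
## and a composition fraction (count of B over non-N bases). Each statistic
## maps through a binned lookup to a probability-of-coding, and the score
## is the weighted sum of the eight probabilities. The lookup content is
## shipped as a versioned TSV under extdata (classic TESTCODE tables).

#' Load the Fickett TESTCODE lookup tables
#'
#' @param path TSV with columns `kind` (`position`/`content`/`weight`),
#'   `base`, `cutoff`, `prob`. Defaults to the table shipped with the
#'   package. Cutoffs are stored in descending order per statistic; a value
#'   `v` maps to the probability of the first bin with `v >= cutoff`.
#' @return object of class `fickett_lookup`: for each of `position` and
#'   `content`, a list with `cutoffs` (descending numeric), `prob`
#'   (4 x n matrix, rows A,C,G,T) and `weights` (named numeric of 4).
#' @export
fickett_lookup <- function(path = system.file("extdata", "fickett.tsv",
                                              package = "lncfuse")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  parse_kind <- function(kind) {
    sub <- tab[tab$kind == kind, ]
    cuts <- sort(unique(as.numeric(sub$cutoff)), decreasing = TRUE)
    prob <- matrix(NA_real_, 4, length(cuts), dimnames = list(bases, NULL))
    for (b in bases) {
      sb <- sub[sub$base == b, ]
      prob[b, ] <- sb$prob[match(cuts, as.numeric(sb$cutoff))]
    }
    w <- tab[tab$kind == "weight" & tab$cutoff == kind, ]
    list(cutoffs = cuts, prob = prob,
         weights = setNames(as.numeric(w$prob), w$base)[bases])
  }
  structure(list(position = parse_kind("position"),
                 content = parse_kind("content")),
            class = "fickett_lookup")
}

base_counts_by_codon_position <- function(seq) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- (seq_along(x) - 1L) %% 3L
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4, 3, dimnames = list(bases, NULL))
  for (p in 0:2) {
    tb <- table(factor(x[pos == p], levels = bases))
    counts[, p + 1L] <- as.integer(tb)
  }
  counts
}

#' Fickett codon-position asymmetry values
#'
#' For each base B, counts B at transcript positions congruent to 0, 1 and
#' 2 (mod 3), anchored at the 5' end, and returns
#' `MAX(B1,B2,B3) / (MIN(B1,B2,B3) + 1)`. `N` positions contribute to no
#' base count.
#'
#' @param seq a single normalized sequence of length >= 3.
#' @return named numeric of 4 (A, C, G, T).
#' @export
fickett_position_values <- function(seq) {
  seq <- as.character(seq)
  if (nchar(seq) < 3) stop("transcript too short for codon-position statistics")
  counts <- base_counts_by_codon_position(seq)
  apply(counts, 1, function(r) max(r) / (min(r) + 1))
}

#' Fickett base-composition fractions
#'
#' @param seq a single normalized sequence.
#' @return named numeric of 4: count of each base over the count of non-N
#'   bases (all zero if the sequence is entirely `N`).
#' @keywords internal
fickett_composition <- function(seq) {
  x <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  tb <- as.integer(table(factor(x, levels = bases)))
  tot <- sum(tb)
  if (tot == 0) return(setNames(rep(0, 4), bases))
  setNames(tb / tot, bases)
}

lookup_prob <- function(value, cutoffs, probs) {
  i <- which(value >= cutoffs)[1]
  if (is.na(i)) i <- length(cutoffs)   # cutoffs end at 0, so only if value<0
  probs[i]
}

#' Fickett TESTCODE score
#'
#' @param seq a single normalized sequence of length >= 3.
#' @param lookup a `fickett_lookup` object (default: shipped tables).
#' @return numeric scalar `S_F`.
#' @export
fickett_score <- function(seq, lookup = fickett_lookup()) {
  pv <- fickett_position_values(seq)
  cv <- fickett_composition(seq)
  s <- 0
  for (b in c("A", "C", "G", "T")) {
    s <- s + lookup$position$weights[[b]] *
      lookup_prob(pv[[b]], lookup$position$cutoffs, lookup$position$prob[b, ])
    s <- s + lookup$content$weights[[b]] *
      lookup_prob(cv[[b]], lookup$content$cutoffs, lookup$content$prob[b, ])
  }
  unname(s)
}
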