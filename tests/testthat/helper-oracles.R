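# Independent brute-force oracles, deliberately written with plain loops
# and none of the package's vectorized machinery.

oracle_orf <- function(seq) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(found = FALSE, start = 0L, end = 0L, length = 0L,
               frame = NA_integer_)
  if (L < 6) return(best)
  for (s in seq_len(L - 2)) {
    if (substr(seq, s, s + 2) != "ATG") next
    pos <- s + 3
    while (pos + 2 <= L) {
      codon <- substr(seq, pos, pos + 2)
      if (codon %in% stops) {
        len <- pos + 2 - s + 1
        better <- len > best$length ||
          (len == best$length && (!best$found || s < best$start))
        if (better) {
          best <- list(found = TRUE, start = as.integer(s),
                       end = as.integer(pos + 2),
                       length = as.integer(len),
                       frame = as.integer((s - 1) %% 3))
        }
        break
      }
      pos <- pos + 3
    }
  }
  best
}

# dictionary-count oracle: extract every window, drop those with N, and
# tally against the full lexicographic word list via factor levels
oracle_kmer <- function(seq, k) {
  bases <- c("A", "C", "G", "T")
  words <- ""
  for (i in seq_len(k)) {
    words <- as.vector(outer(words, bases, paste0))
  }
  words <- sort(words)
  starts <- seq_len(nchar(seq) - k + 1)
  win <- substring(seq, starts, starts + k - 1)
  win <- win[!grepl("N", win, fixed = TRUE)]
  counts <- as.numeric(table(factor(win, levels = words)))
  names(counts) <- words
  if (length(win) == 0) counts else counts / length(win)
}

oracle_hexamer <- function(seq, table, step = 1) {
  starts <- seq(1, nchar(seq) - 5, by = step)
  win <- substring(seq, starts, starts + 5)
  win <- win[!grepl("N", win, fixed = TRUE)]
  if (length(win) == 0) return(0)
  lr <- log(table$f_c / table$f_nc)
  mean(lr[win])
}

oracle_fickett_pos <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  out <- numeric(4)
  names(out) <- c("A", "C", "G", "T")
  for (b in names(out)) {
    cnt <- c(0, 0, 0)
    for (i in seq_along(x)) {
      if (x[i] == b) {
        slot <- ((i - 1) %% 3) + 1
        cnt[slot] <- cnt[slot] + 1
      }
    }
    out[b] <- max(cnt) / (min(cnt) + 1)
  }
  out
}

# straight-line TESTCODE arithmetic, independent of the package's
# lookup_prob() helper
oracle_fickett_score <- function(seq, lookup) {
  pv <- oracle_fickett_pos(seq)
  x <- strsplit(seq, "")[[1]]
  nn <- sum(x %in% c("A", "C", "G", "T"))
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cuts <- lookup$position$cutoffs
    i <- 1
    while (i < length(cuts) && pv[[b]] < cuts[i]) i <- i + 1
    score <- score + lookup$position$prob[b, i] * lookup$position$weights[[b]]
    comp <- if (nn == 0) 0 else sum(x == b) / nn
    cuts <- lookup$content$cutoffs
    i <- 1
    while (i < length(cuts) && comp < cuts[i]) i <- i + 1
    score <- score + lookup$content$prob[b, i] * lookup$content$weights[[b]]
  }
  unname(score)
}

oracle_one_hot <- function(seq, maxlen) {
  m <- matrix(0, 4, maxlen, dimnames = list(c("A", "T", "C", "G"), NULL))
  codes <- list(A = c(1, 0, 0, 0), T = c(0, 1, 0, 0),
                C = c(0, 0, 1, 0), G = c(0, 0, 0, 1))
  x <- strsplit(seq, "")[[1]]
  for (i in seq_len(min(length(x), maxlen))) {
    if (x[i] %in% names(codes)) m[, i] <- codes[[x[i]]]
  }
  m
}

oracle_confusion <- function(pred, y) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y)) {
    if (pred[i] == 1 && y[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && y[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && y[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && y[i] == 1) fn <- fn + 1
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}
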