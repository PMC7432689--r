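## Synthetic transcript generator.
##
## Emulates the discriminative structure the classifier exploits:
## "coding-like" transcripts carry one long codon-usage-biased ORF flanked
## by random UTRs; "noncoding-like" transcripts are i.i.d.-composition
## sequences of matched length range, rejection-sampled so no long
## spurious ORF survives. Labels follow the package convention:
## lncRNA-like = 1 (positive), protein-coding-like = 0.

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

#' Default skewed codon-usage distribution
#'
#' A stylized bias over the 61 sense codons rather than any organism's
#' measured table, keeping the package download-free. Most of the mass
#' (`purine_mass`) sits on the 27 purine-only (A/G) codons with a
#' geometric decay; these are shift-closed (no stop codon is purine-only),
#' so out-of-frame windows over a biased ORF still fall inside the
#' in-frame hexamer support, mimicking how real codon usage produces a
#' frame-robust hexamer signal. The remaining sense codons share the rest
#' of the mass uniformly.
#'
#' @param purine_mass total probability on purine-only codons (default
#'   0.75).
#' @param decay geometric decay rate across the purine codons (default
#'   0.9).
#' @return named numeric over the 61 sense codons, summing to 1.
#' @export
default_codon_bias <- function(purine_mass = 0.75, decay = 0.9) {
  b <- c("A", "C", "G", "T")
  codons <- sort(apply(expand.grid(b, b, b)[, 3:1], 1, paste0,
                       collapse = ""))
  codons <- setdiff(codons, GENETIC_STOPS)
  pur <- grepl("^[AG]+$", codons)
  w <- numeric(length(codons))
  w[pur] <- decay^(seq_len(sum(pur)) - 1)
  w[pur] <- purine_mass * w[pur] / sum(w[pur])
  w[!pur] <- (1 - purine_mass) / sum(!pur)
  setNames(w, codons)
}

#' Generator configuration
#'
#' @param n_per_class transcripts per class (default 1000).
#' @param length_range transcript length bounds in nucleotides; minimum
#'   must be >= 200 (the lncRNA length definition).
#' @param codon_bias distribution over the 61 sense codons used for
#'   coding-class ORFs (default: [default_codon_bias()]).
#' @param orf_fraction_range target ORF coverage interval for the coding
#'   class (default `c(0.5, 0.9)`).
#' @param gc_target GC fraction of the noncoding class (default 0.5).
#' @param max_noncoding_orf maximum spurious longest-ORF length allowed in
#'   a noncoding transcript (default 120 nt).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling cap per noncoding transcript.
#' @return object of class `lnc_generator_config`.
#' @export
generator_config <- function(n_per_class = 1000,
                             length_range = c(200, 1000),
                             codon_bias = default_codon_bias(),
                             orf_fraction_range = c(0.5, 0.9),
                             gc_target = 0.5,
                             max_noncoding_orf = 120,
                             seed = 1,
                             max_attempts = 2000) {
  stopifnot(n_per_class >= 1,
            length(length_range) == 2, length_range[1] >= 200,
            length_range[1] <= length_range[2],
            length(orf_fraction_range) == 2,
            orf_fraction_range[1] > 0, orf_fraction_range[2] <= 1,
            orf_fraction_range[1] <= orf_fraction_range[2],
            gc_target > 0, gc_target < 1,
            max_noncoding_orf >= 6, max_attempts >= 1)
  if (abs(sum(codon_bias) - 1) > 1e-6 ||
      !setequal(names(codon_bias), names(default_codon_bias()))) {
    stop("codon_bias must be a distribution over the 61 sense codons")
  }
  if (length_range[1] < 150 + 3) {
    stop("minimum length cannot fit a >=150 nt ORF")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 codon_bias = codon_bias,
                 orf_fraction_range = orf_fraction_range,
                 gc_target = gc_target,
                 max_noncoding_orf = as.integer(max_noncoding_orf),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "lnc_generator_config")
}

random_nt <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# uniform integer draw immune to sample()'s scalar expansion
draw_length <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1) - 1L
}

one_coding_seq <- function(config) {
  L <- draw_length(config$length_range)
  frac <- runif(1, config$orf_fraction_range[1],
                config$orf_fraction_range[2])
  n_codon <- max(floor(frac * L / 3), 51L)   # ORF of at least 153 nt
  n_codon <- min(n_codon, L %/% 3)
  orf <- paste0("ATG",
                paste(sample(names(config$codon_bias), n_codon - 2L,
                             replace = TRUE, prob = config$codon_bias),
                      collapse = ""),
                sample(GENETIC_STOPS, 1))
  rest <- L - 3L * n_codon
  u5 <- sample(0:rest, 1)
  paste0(random_nt(u5), orf, random_nt(rest - u5))
}

#' Generate coding-like transcripts (label 0)
#'
#' Each transcript is a random 5' UTR, then `ATG` + codons drawn from the
#' configured codon bias (stops excluded internally) + a stop codon, then
#' a random 3' UTR, with the ORF sized to a coverage drawn from
#' `orf_fraction_range` (and at least 153 nt). The realized longest ORF
#' is at least the constructed one; chance upstream extensions may make
#' it longer.
#'
#' @param config an `lnc_generator_config`.
#' @return named [Biostrings::DNAStringSet] (`pct_*` ids).
#' @export
generate_coding <- function(config) {
  seqs <- with_seed(config$seed + 1L, {
    vapply(seq_len(config$n_per_class),
           function(i) one_coding_seq(config), character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("pct_%05d", seq_along(seqs))
  out
}

#' Generate noncoding-like transcripts (label 1)
#'
#' Sequences are drawn position-wise from the composition implied by
#' `gc_target` (A = T, G = C) and rejection-sampled until the longest ORF
#' is at most `max_noncoding_orf` nucleotides.
#'
#' @param config an `lnc_generator_config`.
#' @return named [Biostrings::DNAStringSet] (`lnc_*` ids).
#' @export
generate_noncoding <- function(config) {
  g <- config$gc_target
  probs <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)  # A, C, G, T
  seqs <- with_seed(config$seed + 2L, {
    vapply(seq_len(config$n_per_class), function(i) {
      L <- draw_length(config$length_range)
      for (attempt in seq_len(config$max_attempts)) {
        s <- random_nt(L, probs)
        if (find_longest_orf(s)$length <= config$max_noncoding_orf) {
          return(s)
        }
      }
      stop(sprintf(paste0("could not sample a %d nt noncoding sequence ",
                          "with longest ORF <= %d nt in %d attempts; ",
                          "raise max_noncoding_orf or shorten length_range"),
                   L, config$max_noncoding_orf, config$max_attempts))
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("lnc_%05d", seq_along(seqs))
  out
}

#' Generate a labeled synthetic benchmark
#'
#' Combines both classes, shuffles with the configured seed, and (when
#' `out_dir` is given) writes `benchmark.fa`, `labels.tsv` and a
#' plain-text `manifest.txt` recording the full configuration.
#'
#' @param config an `lnc_generator_config`.
#' @param out_dir optional output directory.
#' @return list with `dataset` (an `lnc_dataset`), `config`, and `paths`
#'   (NULL unless written).
#' @export
generate_benchmark <- function(config, out_dir = NULL) {
  coding <- generate_coding(config)
  noncoding <- generate_noncoding(config)
  seqs <- c(coding, noncoding)
  labels <- c(rep(0L, length(coding)), rep(1L, length(noncoding)))
  ord <- with_seed(config$seed + 3L, sample.int(length(labels)))
  data <- lnc_dataset(seqs[ord], labels[ord])
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "benchmark.fa")
    lab <- file.path(out_dir, "labels.tsv")
    man <- file.path(out_dir, "manifest.txt")
    write_fasta(data$seqs, fa)
    write_dataset_manifest(data, lab)
    writeLines(c(
      "# synthetic benchmark manifest",
      "# label convention: 1 = lncRNA-like (positive), 0 = coding-like",
      sprintf("n_per_class=%d", config$n_per_class),
      sprintf("length_range=%d,%d", config$length_range[1],
              config$length_range[2]),
      sprintf("orf_fraction_range=%g,%g", config$orf_fraction_range[1],
              config$orf_fraction_range[2]),
      sprintf("gc_target=%g", config$gc_target),
      sprintf("max_noncoding_orf=%d", config$max_noncoding_orf),
      sprintf("codon_bias=geometric over 61 sense codons (top=%s %.4f)",
              names(config$codon_bias)[which.max(config$codon_bias)],
              max(config$codon_bias)),
      sprintf("seed=%d", config$seed)
    ), man)
    paths <- list(fasta = fa, labels = lab, manifest = man)
  }
  list(dataset = data, config = config, paths = paths)
}

#' Hexamer-preserving shuffle negatives (stress mode)
#'
#' Optional harder negative set: per-transcript dinucleotide-preserving
#' shuffles are not enough to erase ORF structure, so this mode instead
#' shuffles coding transcripts codon-wise after destroying the start
#' codon, keeping overall composition while breaking the single long ORF.
#'
#' @param coding output of [generate_coding()].
#' @param config the generator configuration (for seed and the ORF cap).
#' @return named [Biostrings::DNAStringSet] of shuffled negatives
#'   (`shf_*` ids); transcripts whose shuffle still contains a long ORF
#'   are dropped.
#' @export
shuffle_negatives <- function(coding, config) {
  ch <- as.character(coding)
  seqs <- with_seed(config$seed + 4L, {
    vapply(ch, function(s) {
      x <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(x[sample.int(length(x))], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  keep <- vapply(seqs, function(s) {
    find_longest_orf(s)$length <= config$max_noncoding_orf
  }, logical(1))
  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- sprintf("shf_%05d", seq_len(sum(keep)))
  out
}
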