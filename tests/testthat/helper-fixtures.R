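# Shared fixtures, built in code at test time.

random_seq <- function(L, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  x <- sample(alphabet, L, replace = TRUE)
  if (n_prob > 0) {
    hit <- runif(L) < n_prob
    x[hit] <- "N"
  }
  paste(x, collapse = "")
}

write_tmp_fasta <- function(records, width = NULL) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (id in names(records)) {
    body <- records[[id]]
    if (!is.null(width)) {
      starts <- seq(1, nchar(body), by = width)
      body <- substring(body, starts, pmin(starts + width - 1, nchar(body)))
    }
    lines <- c(lines, paste0(">", id), body)
  }
  writeLines(lines, path)
  path
}

# a tiny hexamer table from fixed sequences, for feature-level tests
tiny_hexamer_table <- function() {
  set.seed(404)
  cod <- replicate(5, paste0("ATG", random_seq(90), "TAA"))
  ncod <- replicate(5, random_seq(120))
  build_hexamer_table(cod, ncod)
}

# small benchmark + fast config shared by model-level tests
tiny_benchmark <- function(n = 40, seed = 99) {
  generate_benchmark(generator_config(n_per_class = n, seed = seed,
                                      length_range = c(200, 500)))$dataset
}

tiny_config <- function(...) {
  fast_model_config(maxlen = 300, pretrain_epochs = 4, fusion_epochs = 3,
                    finetune_epochs = 2, batch_size = 32, ...)
}
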