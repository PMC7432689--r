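# Model layer: submodel construction, two-step training, prediction,
# and decision fusion. Training runs use a deliberately tiny benchmark
# and config so the whole file stays in the tens of seconds.

submodel_descriptor_dim <- function(sm) sm$core$out_dim

test_that("build_submodel wires the documented input and descriptor widths", {
  cfg <- model_config(ofh_hidden = c(64, 32), seed = 1, maxlen = 300)
  sm <- build_submodel("ofh", cfg)
  expect_equal(sm$core$nin, 4)
  expect_equal(submodel_descriptor_dim(sm), 32)
  km <- build_submodel("kmer", cfg)
  expect_equal(km$core$nin, 4096)   # 4^k with k = 6
  oh <- build_submodel("onehot", cfg)
  expect_equal(oh$core$maxlen, 300)
  expect_equal(submodel_descriptor_dim(oh), cfg$cnn_dense)
  expect_error(build_submodel("protein", cfg), "unknown modality")
})

test_that("submodel initialization is exactly reproducible under a seed", {
  cfg <- tiny_config(seed = 5)
  set.seed(5); a <- build_submodel("kmer", cfg)
  set.seed(5); b <- build_submodel("kmer", cfg)
  expect_identical(a$core$params, b$core$params)
  expect_identical(a$head, b$head)
})

test_that("pretraining learns on separable synthetic data and is seed-deterministic", {
  data <- tiny_benchmark(n = 40, seed = 12)
  cfg <- tiny_config(seed = 4)
  pre <- pretrain_submodels(data, cfg, modalities = c("ofh", "kmer"))
  for (m in names(pre$submodels)) {
    losses <- pre$losses[[m]]
    expect_lt(losses[length(losses)], losses[1])
  }
  pre2 <- pretrain_submodels(data, cfg, modalities = c("ofh", "kmer"))
  expect_identical(pre$submodels$ofh$core$params,
                   pre2$submodels$ofh$core$params)
  expect_identical(pre$submodels$kmer$core$params,
                   pre2$submodels$kmer$core$params)
  # single-class data is rejected
  one_class <- data[data$labels == 1]
  expect_error(pretrain_submodels(one_class, cfg), "both classes")
})

test_that("two-step contract: phase 1 freezes submodels, phase 2 updates every one", {
  data <- tiny_benchmark(n = 30, seed = 13)
  cfg <- tiny_config(seed = 6)
  pre <- pretrain_submodels(data, cfg)
  frozen_cfg <- do.call(model_config,
                        modifyList(unclass(cfg), list(finetune_epochs = 0)))
  m_frozen <- fuse_and_finetune(pre, frozen_cfg)
  for (m in names(pre$submodels)) {
    expect_identical(m_frozen$submodels[[m]]$core$params,
                     pre$submodels[[m]]$core$params,
                     label = paste("frozen", m))
  }
  m_tuned <- fuse_and_finetune(pre, cfg)
  for (m in names(pre$submodels)) {
    changed <- !identical(m_tuned$submodels[[m]]$core$params,
                          pre$submodels[[m]]$core$params)
    expect_true(changed, label = paste("fine-tuned", m))
  }
})

test_that("modality subsets realize the ablation architectures", {
  data <- tiny_benchmark(n = 30, seed = 14)
  cfg <- tiny_config(seed = 7)
  pre <- pretrain_submodels(data, cfg)
  single <- fuse_and_finetune(pre, cfg, modalities = "kmer")
  expect_equal(single$architecture, "kmer")
  expect_equal(names(single$submodels), "kmer")
  pair <- fuse_and_finetune(pre, cfg, modalities = c("ofh", "onehot"))
  expect_equal(pair$architecture, "ofh+onehot")
  full <- fuse_and_finetune(pre, cfg)
  expect_equal(full$architecture, "full_fusion")
  expect_error(fuse_and_finetune(pre, cfg, modalities = "spectro"),
               "not pretrained")
  # all variants predict through the same code path
  preds <- predict(pair, data$seqs[1:5])
  expect_equal(nrow(preds), 5)
})

test_that("prediction is deterministic, in range, order-equivariant, and flags short input", {
  data <- tiny_benchmark(n = 30, seed = 15)
  cfg <- tiny_config(seed = 8)
  model <- train_lnc_model(data, cfg)
  seqs <- data$seqs[1:20]
  p1 <- predict(model, seqs)
  p2 <- predict(model, seqs)
  expect_identical(p1, p2)
  expect_true(all(p1$p_lnc >= 0 & p1$p_lnc <= 1))
  expect_true(all(p1$label %in% c(0L, 1L)))
  # permutation of input order permutes, not changes, the probabilities
  perm <- sample(length(seqs))
  p3 <- predict(model, seqs[perm])
  expect_equal(p3$p_lnc[match(p1$id, p3$id)], p1$p_lnc, tolerance = 1e-12)
  # too-short transcripts get a flagged failure, not a silent guess
  mix <- c(Biostrings::DNAStringSet(c(tiny = "ATG")), seqs[1])
  pm <- predict(model, mix)
  expect_equal(pm$status, c("too_short", "ok"))
  expect_true(is.na(pm$p_lnc[1]) && is.na(pm$label[1]))
})

test_that("prediction separates the synthetic classes in the right direction", {
  data <- tiny_benchmark(n = 40, seed = 16)
  cfg <- tiny_config(seed = 9)
  holdout <- tiny_benchmark(n = 25, seed = 17)
  model <- train_lnc_model(data, cfg)
  preds <- predict(model, holdout$seqs)
  mean_lnc <- mean(preds$p_lnc[holdout$labels == 1])
  mean_pc <- mean(preds$p_lnc[holdout$labels == 0])
  expect_gt(mean_lnc, mean_pc)
})

test_that("decision fusion takes the majority vote and averages probabilities", {
  data <- tiny_benchmark(n = 30, seed = 18)
  cfg <- tiny_config(seed = 10)
  pre <- pretrain_submodels(data, cfg)
  seqs <- data$seqs[1:50]
  votes <- decision_fusion_vote(pre, seqs)
  tally <- votes$vote_ofh + votes$vote_kmer + votes$vote_onehot
  expect_equal(votes$label, as.integer(tally >= 2))
  expect_true(all(votes$p_lnc >= 0 & votes$p_lnc <= 1))
  pre2 <- pre
  pre2$submodels$onehot <- NULL
  expect_error(decision_fusion_vote(pre2, seqs), "three")
})

test_that("model archives round-trip with their bound tables", {
  data <- tiny_benchmark(n = 30, seed = 19)
  cfg <- tiny_config(seed = 11)
  model <- train_lnc_model(data, cfg, modalities = "ofh")
  path <- withr::local_tempfile(fileext = ".rds")
  save_lnc_model(model, path)
  back <- load_lnc_model(path)
  expect_equal(back$table$f_c, model$table$f_c)
  p1 <- predict(model, data$seqs[1:5])
  p2 <- predict(back, data$seqs[1:5])
  expect_identical(p1, p2)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_lnc_model(bad), "not an lnc_model")
})
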