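## Multimodal classifier: per-modality submodels, descriptor fusion, and
## the two-step (pretrain, then fine-tune) training schedule.

MODALITIES <- c("ofh", "kmer", "onehot")

#' Model configuration
#'
#' Architecture and optimization settings for the three submodels and the
#' fusion network. Defaults are sized for CPU training; the published
#' hexamer/one-hot hyper-parameters `k = 6` and `maxlen = 3000` are the
#' defaults for the feature layer.
#'
#' @param ofh_hidden dense widths of the OFH submodel (input width 4).
#' @param kmer_hidden dense widths of the k-mer submodel (input width
#'   `4^k`).
#' @param cnn_filters,cnn_kernel,cnn_pool,cnn_blocks convolutional module:
#'   each block is conv -> batch-norm -> ReLU -> max-pool.
#' @param cnn_dense dense widths after the convolutional blocks; the last
#'   width is the one-hot descriptor size.
#' @param fusion_hidden dense widths of the fusion network over the
#'   concatenated descriptors.
#' @param dropout dropout rate in `[0, 1)` applied to hidden layers.
#' @param learning_rate Adam learning rate for pretraining and fusion
#'   phase 1.
#' @param finetune_lr reduced learning rate for end-to-end fine-tuning.
#' @param batch_size mini-batch size.
#' @param pretrain_epochs epochs for each submodel's independent training.
#' @param fusion_epochs phase-1 epochs (fusion parameters only, submodels
#'   frozen).
#' @param finetune_epochs phase-2 epochs (all parameters, reduced rate).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param maxlen one-hot encoding width (default 3000).
#' @param k k-mer length (default 6).
#' @param threshold probability cutoff for the hard label (default 0.5).
#' @return object of class `lnc_model_config`.
#' @export
model_config <- function(ofh_hidden = c(64, 32),
                         kmer_hidden = c(128, 64),
                         cnn_filters = 32, cnn_kernel = 10, cnn_pool = 5,
                         cnn_blocks = 2, cnn_dense = 64,
                         fusion_hidden = 64,
                         dropout = 0.2,
                         learning_rate = 1e-3, finetune_lr = 1e-4,
                         batch_size = 128,
                         pretrain_epochs = 20, fusion_epochs = 10,
                         finetune_epochs = 10,
                         seed = 1, maxlen = 3000, k = 6, threshold = 0.5) {
  cfg <- list(ofh_hidden = ofh_hidden, kmer_hidden = kmer_hidden,
              cnn_filters = cnn_filters, cnn_kernel = cnn_kernel,
              cnn_pool = cnn_pool, cnn_blocks = cnn_blocks,
              cnn_dense = cnn_dense, fusion_hidden = fusion_hidden,
              dropout = dropout, learning_rate = learning_rate,
              finetune_lr = finetune_lr, batch_size = batch_size,
              pretrain_epochs = pretrain_epochs,
              fusion_epochs = fusion_epochs,
              finetune_epochs = finetune_epochs,
              seed = as.integer(seed), maxlen = as.integer(maxlen),
              k = as.integer(k), threshold = threshold)
  stopifnot(all(c(cfg$ofh_hidden, cfg$kmer_hidden, cfg$cnn_dense,
                  cfg$fusion_hidden) >= 1),
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$learning_rate > 0, cfg$finetune_lr > 0,
            cfg$batch_size >= 1,
            cfg$pretrain_epochs >= 0, cfg$fusion_epochs >= 0,
            cfg$finetune_epochs >= 0,
            cfg$maxlen >= 1, cfg$k >= 1, cfg$k <= 8)
  structure(cfg, class = "lnc_model_config")
}

#' A reduced configuration for CPU desk-scale runs
#'
#' Same architecture family as [model_config()] with fewer filters,
#' shorter one-hot window and fewer epochs, so a full three-modality
#' train/evaluate cycle on a few thousand synthetic transcripts stays in
#' the minutes range on one CPU.
#'
#' @param ... overrides passed on to [model_config()].
#' @return an `lnc_model_config`.
#' @export
fast_model_config <- function(...) {
  defaults <- list(ofh_hidden = c(32, 16), kmer_hidden = c(64, 32),
                   cnn_filters = 16, cnn_kernel = 10, cnn_pool = 10,
                   cnn_blocks = 1, cnn_dense = 32, fusion_hidden = 32,
                   dropout = 0.1, learning_rate = 2e-3, finetune_lr = 2e-4,
                   batch_size = 64, pretrain_epochs = 8, fusion_epochs = 6,
                   finetune_epochs = 3, maxlen = 500)
  do.call(model_config, modifyList(defaults, list(...)))
}

## ---- Feature preparation --------------------------------------------------

#' Prepare modality inputs for training or prediction
#'
#' Computes the OFH matrix (standardized with training-set mean/sd), the
#' k-mer frequency matrix, and the flattened one-hot matrix. When
#' `scaling` is `NULL` the standardization parameters are estimated from
#' these data (training); otherwise the supplied parameters are applied
#' (prediction).
#'
#' @param seqs [Biostrings::DNAStringSet].
#' @param config an `lnc_model_config`.
#' @param lookup a `fickett_lookup`.
#' @param table a `hexamer_table`.
#' @param scaling optional list with `mean`, `sd` for the OFH rows.
#' @return list with `x` (named list of modality matrices), `scaling`.
#' @export
prepare_features <- function(seqs, config, lookup, table, scaling = NULL) {
  ofh <- ofh_matrix(seqs, lookup, table)
  if (is.null(scaling)) {
    mu <- rowMeans(ofh)
    sg <- apply(ofh, 1, sd)
    sg[sg < 1e-8] <- 1
    scaling <- list(mean = mu, sd = sg)
  }
  ofh <- (ofh - scaling$mean) / scaling$sd
  list(x = list(ofh = ofh,
                kmer = kmer_matrix(seqs, config$k),
                onehot = one_hot_matrix(seqs, config$maxlen)),
       scaling = scaling)
}

## ---- Submodels ------------------------------------------------------------

#' Build an untrained submodel for one modality
#'
#' OFH and k-mer modalities are dense stacks; the one-hot modality is the
#' convolutional module (conv -> batch-norm -> ReLU -> max-pool blocks
#' followed by dense layers). Each submodel carries a 1-unit sigmoid head
#' for standalone training; the descriptor is the last hidden layer.
#' Initialization draws from the current RNG state.
#'
#' @param modality one of `"ofh"`, `"kmer"`, `"onehot"`.
#' @param config an `lnc_model_config`.
#' @return list with `modality`, `core`, `head`.
#' @export
build_submodel <- function(modality, config) {
  core <- switch(modality,
    ofh = mlp_new(4L, config$ofh_hidden, dropout = config$dropout),
    kmer = mlp_new(4L^config$k, config$kmer_hidden,
                   dropout = config$dropout),
    onehot = cnn_new(config$maxlen, config$cnn_filters, config$cnn_kernel,
                     config$cnn_pool, config$cnn_blocks, config$cnn_dense,
                     dropout = config$dropout),
    stop("unknown modality: ", modality)
  )
  list(modality = modality, core = core, head = head_new(core$out_dim))
}

#' Pretrain the per-modality submodels
#'
#' Step one of the two-step schedule: each submodel is trained
#' independently against the labels with binary cross-entropy. Features
#' (hexamer table, Fickett lookup, OFH scaling) are estimated from the
#' training data and bound to the result so prediction is self-contained.
#'
#' @param data an `lnc_dataset` containing both classes.
#' @param config an `lnc_model_config`.
#' @param modalities subset of `c("ofh","kmer","onehot")` to train.
#' @param lookup a `fickett_lookup` (default: shipped tables).
#' @param table optional pre-built `hexamer_table`; by default built from
#'   the training data (coding = label 0, noncoding = label 1).
#' @param verbose print per-epoch losses.
#' @return object of class `lnc_pretrained`: submodels plus the bound
#'   feature state and cached training features.
#' @export
pretrain_submodels <- function(data, config, modalities = MODALITIES,
                               lookup = fickett_lookup(), table = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(data, "lnc_dataset"))
  modalities <- match.arg(modalities, MODALITIES, several.ok = TRUE)
  y <- data$labels
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes")
  }
  if (is.null(table)) {
    table <- build_hexamer_table(data$seqs[y == 0L], data$seqs[y == 1L])
  }
  feats <- prepare_features(data$seqs, config, lookup, table)
  subs <- list()
  logs <- list()
  for (m in modalities) {
    with_seed(config$seed + match(m, MODALITIES), {
      sm <- build_submodel(m, config)
      tr <- train_module(sm$core, sm$head, feats$x[[m]], y,
                         epochs = config$pretrain_epochs,
                         lr = config$learning_rate,
                         batch_size = config$batch_size,
                         verbose = verbose)
      sm$core <- tr$mod
      sm$head <- tr$head
      subs[[m]] <- sm
      logs[[m]] <- tr$losses
    })
  }
  structure(list(submodels = subs, config = config, table = table,
                 lookup = lookup, scaling = feats$scaling,
                 features = feats$x, y = y, losses = logs),
            class = "lnc_pretrained")
}

descriptor_forward <- function(subs, x, train = FALSE) {
  fws <- lapply(names(subs), function(m) {
    module_forward(subs[[m]]$core, x[[m]], train = train)
  })
  names(fws) <- names(subs)
  D <- do.call(rbind, lapply(fws, `[[`, "out"))
  list(D = D, fws = fws)
}

#' Fuse pretrained submodels and fine-tune end to end
#'
#' Step two of the schedule. The selected submodels' descriptors are
#' concatenated into a dense fusion network with a sigmoid output.
#' Phase 1 trains only the fusion parameters with the submodels frozen
#' (inference mode, so batch-norm statistics are also untouched);
#' phase 2 unfreezes everything and fine-tunes at `finetune_lr`.
#'
#' @param pre an `lnc_pretrained` object.
#' @param config an `lnc_model_config`; defaults to the one used for
#'   pretraining.
#' @param modalities non-empty subset of the pretrained modalities,
#'   realizing the ablation architectures (single models, pairwise
#'   fusions, full fusion).
#' @param verbose print per-epoch losses.
#' @return object of class `lnc_model`.
#' @export
fuse_and_finetune <- function(pre, config = pre$config,
                              modalities = names(pre$submodels),
                              verbose = FALSE) {
  stopifnot(inherits(pre, "lnc_pretrained"), length(modalities) >= 1)
  if (!all(modalities %in% names(pre$submodels))) {
    stop("requested modality was not pretrained")
  }
  subs <- pre$submodels[modalities]
  x <- pre$features[modalities]
  y <- pre$y
  N <- length(y)
  d_in <- sum(vapply(subs, function(s) s$core$out_dim, numeric(1)))
  with_seed(config$seed + 101L, {
    fusion <- mlp_new(d_in, config$fusion_hidden, dropout = config$dropout)
    fhead <- head_new(fusion$out_dim)

    ## Phase 1: fusion parameters only; submodels frozen in inference mode.
    opt <- adam_new(); hopt <- adam_new()
    for (ep in seq_len(config$fusion_epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0
      for (s in seq(1, N, by = config$batch_size)) {
        bi <- ord[s:min(s + config$batch_size - 1, N)]
        xb <- lapply(x, function(mat) mat[, bi, drop = FALSE])
        df <- descriptor_forward(subs, xb, train = FALSE)
        ff <- mlp_forward(fusion, df$D, train = TRUE)
        p <- head_forward(fhead, ff$out)
        ep_loss <- ep_loss + bce_loss(p, y[bi]); nb <- nb + 1
        hb <- head_backward(fhead, ff$out, p, y[bi])
        fb <- mlp_backward(fusion, ff$cache, hb$dD)
        up <- adam_step(fusion$params, fb$grads, opt, config$learning_rate)
        fusion$params <- up$params; opt <- up$state
        uph <- adam_step(fhead, hb$grads, hopt, config$learning_rate)
        fhead <- uph$params; hopt <- uph$state
      }
      if (verbose) message(sprintf("  fusion epoch %d/%d  loss %.4f",
                                   ep, config$fusion_epochs, ep_loss / nb))
    }

    ## Phase 2: unfreeze everything, reduced learning rate.
    opts <- lapply(subs, function(s) adam_new())
    opt2 <- adam_new(); hopt2 <- adam_new()
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0
      for (s in seq(1, N, by = config$batch_size)) {
        bi <- ord[s:min(s + config$batch_size - 1, N)]
        xb <- lapply(x, function(mat) mat[, bi, drop = FALSE])
        df <- descriptor_forward(subs, xb, train = TRUE)
        for (m in names(subs)) subs[[m]]$core <- df$fws[[m]]$mod
        ff <- mlp_forward(fusion, df$D, train = TRUE)
        p <- head_forward(fhead, ff$out)
        ep_loss <- ep_loss + bce_loss(p, y[bi]); nb <- nb + 1
        hb <- head_backward(fhead, ff$out, p, y[bi])
        fb <- mlp_backward(fusion, ff$cache, hb$dD)
        up <- adam_step(fusion$params, fb$grads, opt2, config$finetune_lr)
        fusion$params <- up$params; opt2 <- up$state
        uph <- adam_step(fhead, hb$grads, hopt2, config$finetune_lr)
        fhead <- uph$params; hopt2 <- uph$state
        ## split the fusion-input gradient back to each submodel
        offset <- 0L
        for (m in names(subs)) {
          dm <- subs[[m]]$core$out_dim
          dD <- fb$dX[(offset + 1L):(offset + dm), , drop = FALSE]
          offset <- offset + dm
          mb <- module_backward(subs[[m]]$core, df$fws[[m]]$cache, dD)
          upm <- adam_step(subs[[m]]$core$params, mb$grads, opts[[m]],
                           config$finetune_lr)
          subs[[m]]$core$params <- upm$params
          opts[[m]] <- upm$state
        }
      }
      if (verbose) message(sprintf("  finetune epoch %d/%d  loss %.4f",
                                   ep, config$finetune_epochs, ep_loss / nb))
    }
  })
  arch <- if (length(modalities) == 3) "full_fusion"
          else paste(modalities, collapse = "+")
  structure(list(architecture = arch, submodels = subs, fusion = fusion,
                 fusion_head = fhead, config = config, table = pre$table,
                 lookup = pre$lookup, scaling = pre$scaling),
            class = "lnc_model")
}

#' Train a multimodal lncRNA classifier in one call
#'
#' Convenience wrapper running [pretrain_submodels()] then
#' [fuse_and_finetune()].
#'
#' @inheritParams pretrain_submodels
#' @return an `lnc_model`.
#' @export
train_lnc_model <- function(data, config = model_config(),
                            modalities = MODALITIES,
                            lookup = fickett_lookup(), table = NULL,
                            verbose = FALSE) {
  pre <- pretrain_submodels(data, config, modalities = modalities,
                            lookup = lookup, table = table,
                            verbose = verbose)
  fuse_and_finetune(pre, config, modalities = modalities, verbose = verbose)
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf("<lnc_model> architecture %s (k = %d, maxlen = %d)\n",
              x$architecture, x$config$k, x$config$maxlen))
  invisible(x)
}

## ---- Prediction -----------------------------------------------------------

model_probabilities <- function(model, seqs) {
  feats <- prepare_features(seqs, model$config, model$lookup, model$table,
                            scaling = model$scaling)
  df <- descriptor_forward(model$submodels,
                           feats$x[names(model$submodels)], train = FALSE)
  ff <- mlp_forward(model$fusion, df$D, train = FALSE)
  head_forward(model$fusion_head, ff$out)
}

#' Predict lncRNA probabilities for transcripts
#'
#' @param object an `lnc_model`.
#' @param seqs named [Biostrings::DNAStringSet] (or character vector) of
#'   normalized transcripts.
#' @param threshold probability cutoff for the hard label; defaults to the
#'   model configuration's threshold.
#' @param ... unused.
#' @return data.frame with columns `id`, `p_lnc` (probability of being a
#'   lncRNA), `label` (1 = lncRNA), and `status` (`"ok"`, or
#'   `"too_short"` for transcripts under 6 nt, which get `NA` results
#'   rather than a silent guess).
#' @export
predict.lnc_model <- function(object, seqs,
                              threshold = object$config$threshold, ...) {
  ch <- as.character(seqs)
  ids <- if (!is.null(names(ch))) names(ch) else as.character(seq_along(ch))
  ok <- nchar(ch) >= 6
  p <- rep(NA_real_, length(ch))
  if (any(ok)) {
    ss <- Biostrings::DNAStringSet(ch[ok])
    p[ok] <- model_probabilities(object, ss)
  }
  data.frame(id = ids, p_lnc = p,
             label = ifelse(is.na(p), NA_integer_,
                            as.integer(p >= threshold)),
             status = ifelse(ok, "ok", "too_short"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Majority-vote decision fusion over the three submodels
#'
#' Each pretrained submodel casts a hard vote through its own sigmoid
#' head; the majority (at least 2 of 3) wins. The reported probability is
#' the mean of the three submodel probabilities.
#'
#' @param pre an `lnc_pretrained` with all three modalities.
#' @param seqs transcripts to classify.
#' @param threshold per-submodel vote cutoff (default 0.5).
#' @return data.frame with `id`, `p_lnc`, `label`, and per-submodel vote
#'   columns.
#' @export
decision_fusion_vote <- function(pre, seqs, threshold = 0.5) {
  stopifnot(inherits(pre, "lnc_pretrained"))
  if (length(pre$submodels) < 3) {
    stop("decision fusion requires all three pretrained submodels")
  }
  feats <- prepare_features(seqs, pre$config, pre$lookup, pre$table,
                            scaling = pre$scaling)
  probs <- vapply(names(pre$submodels), function(m) {
    fw <- module_forward(pre$submodels[[m]]$core, feats$x[[m]],
                         train = FALSE)
    head_forward(pre$submodels[[m]]$head, fw$out)
  }, numeric(length(seqs)))
  probs <- matrix(probs, ncol = length(pre$submodels),
                  dimnames = list(NULL, names(pre$submodels)))
  votes <- probs >= threshold
  ids <- if (!is.null(names(seqs))) names(seqs)
         else as.character(seq_len(nrow(probs)))
  data.frame(id = ids,
             p_lnc = rowMeans(probs),
             label = as.integer(rowSums(votes) >= 2),
             vote_ofh = as.integer(votes[, "ofh"]),
             vote_kmer = as.integer(votes[, "kmer"]),
             vote_onehot = as.integer(votes[, "onehot"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- Persistence ----------------------------------------------------------

#' Save a trained model (with its bound feature tables) to a file
#'
#' The archive bundles network parameters, configuration, the hexamer
#' table and the Fickett lookup: predictions are undefined without the
#' training-time tables, so they travel together.
#'
#' @param model an `lnc_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_lnc_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_lnc_model()]
#' @param path archive path.
#' @return an `lnc_model`.
#' @export
load_lnc_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "lnc_model")) stop("not an lnc_model archive: ", path)
  model
}
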