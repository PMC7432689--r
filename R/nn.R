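## Minimal neural-network engine.
##
## No deep-learning backend is available in the target environment, so the
## submodels are implemented directly on BLAS matrix operations: dense
## stacks with ReLU and inverted dropout, and a 1-D convolutional module
## conv -> batch-norm -> ReLU -> max-pool realized through an im2col
## indexing scheme so each batch reduces to a single matrix multiply.
## Training is plain mini-batch Adam on binary cross-entropy; all
## stochasticity (init, shuffling, dropout) draws from R's RNG, so a
## set.seed() before build/train makes runs exactly reproducible on a
## single thread.
##
## Conventions: data matrices are (features x batch); dense weights are
## (out x in); a "module" is a list with $type, $params (named list of
## numeric arrays), and geometry fields; forward passes return a cache
## consumed by the matching backward pass, which returns gradients in the
## same named layout as $params.

he_init <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

## ---- Adam -----------------------------------------------------------------

adam_new <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- Dense (MLP) core -----------------------------------------------------

# hidden: vector of widths; descriptor = activations of the last hidden layer
mlp_new <- function(nin, hidden, dropout = 0) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  params <- list()
  sizes <- c(nin, hidden)
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- he_init(sizes[l + 1], sizes[l])
    params[[paste0("b", l)]] <- matrix(0, sizes[l + 1], 1)
  }
  list(type = "mlp", nin = nin, hidden = hidden, dropout = dropout,
       params = params, out_dim = hidden[length(hidden)])
}

mlp_forward <- function(mod, X, train = FALSE) {
  A <- X
  acts <- list(A)
  pre <- list()
  masks <- list()
  nl <- length(mod$hidden)
  for (l in seq_len(nl)) {
    Z <- mod$params[[paste0("W", l)]] %*% A +
      as.vector(mod$params[[paste0("b", l)]])
    A <- pmax(Z, 0)
    if (train && mod$dropout > 0) {
      mask <- matrix(runif(length(A)) >= mod$dropout, nrow(A), ncol(A)) /
        (1 - mod$dropout)
      A <- A * mask
      masks[[l]] <- mask
    }
    pre[[l]] <- Z
    acts[[l + 1]] <- A
  }
  list(out = A, cache = list(acts = acts, pre = pre, masks = masks))
}

# dOut: gradient wrt the descriptor (post-ReLU/dropout last hidden output)
mlp_backward <- function(mod, cache, dOut) {
  grads <- list()
  dA <- dOut
  for (l in rev(seq_along(mod$hidden))) {
    if (length(cache$masks) >= l && !is.null(cache$masks[[l]])) {
      dA <- dA * cache$masks[[l]]
    }
    dZ <- dA * (cache$pre[[l]] > 0)
    grads[[paste0("W", l)]] <- dZ %*% t(cache$acts[[l]])
    grads[[paste0("b", l)]] <- matrix(rowSums(dZ), ncol = 1)
    dA <- t(mod$params[[paste0("W", l)]]) %*% dZ
  }
  list(grads = grads, dX = dA)
}

## ---- 1-D convolutional core ----------------------------------------------

# Geometry for one conv block on (channels x len) inputs.
conv_block_geom <- function(in_ch, len, kernel, pool) {
  P <- len - kernel + 1L
  stopifnot(P >= 1)
  Pp <- P %/% pool
  stopifnot(Pp >= 1)
  # im2col index into a flattened (in_ch * len) column vector
  idx <- integer(in_ch * kernel * P)
  patch <- as.vector(outer(seq_len(in_ch), (0:(kernel - 1L)) * in_ch, `+`))
  for (p in seq_len(P)) {
    idx[((p - 1L) * in_ch * kernel + 1L):(p * in_ch * kernel)] <-
      patch + (p - 1L) * in_ch
  }
  list(in_ch = in_ch, len = len, kernel = kernel, pool = pool,
       P = P, Pp = Pp, idx = idx)
}

# blocks of conv(kernel) -> BN -> ReLU -> maxpool(pool), then dense hidden
cnn_new <- function(maxlen, filters, kernel, pool, blocks, dense_hidden,
                    dropout = 0) {
  stopifnot(blocks >= 1)
  geoms <- list()
  in_ch <- 4L
  len <- as.integer(maxlen)
  params <- list()
  bn <- list()
  for (bk in seq_len(blocks)) {
    g <- conv_block_geom(in_ch, len, kernel, pool)
    geoms[[bk]] <- g
    params[[paste0("convW", bk)]] <- he_init(filters, in_ch * kernel)
    params[[paste0("convb", bk)]] <- matrix(0, filters, 1)
    params[[paste0("gamma", bk)]] <- matrix(1, filters, 1)
    params[[paste0("beta", bk)]] <- matrix(0, filters, 1)
    bn[[bk]] <- list(mean = rep(0, filters), var = rep(1, filters))
    in_ch <- filters
    len <- g$Pp
  }
  flat <- filters * len
  mlp <- mlp_new(flat, dense_hidden, dropout = dropout)
  list(type = "cnn", maxlen = as.integer(maxlen), filters = filters,
       kernel = kernel, pool = pool, blocks = blocks, geoms = geoms,
       flat = flat, params = c(params, mlp$params), mlp_hidden = dense_hidden,
       dropout = dropout, bn = bn, bn_momentum = 0.9, bn_eps = 1e-5,
       out_dim = dense_hidden[length(dense_hidden)])
}

cnn_forward <- function(mod, X, train = FALSE) {
  B <- ncol(X)
  caches <- vector("list", mod$blocks)
  A <- X
  for (bk in seq_len(mod$blocks)) {
    g <- mod$geoms[[bk]]
    Acol <- A[g$idx, , drop = FALSE]
    dim(Acol) <- c(g$in_ch * g$kernel, g$P * B)
    Z <- mod$params[[paste0("convW", bk)]] %*% Acol +
      as.vector(mod$params[[paste0("convb", bk)]])
    if (train) {
      mu <- rowMeans(Z)
      va <- rowMeans(Z^2) - mu^2
      mod$bn[[bk]]$mean <- mod$bn_momentum * mod$bn[[bk]]$mean +
        (1 - mod$bn_momentum) * mu
      mod$bn[[bk]]$var <- mod$bn_momentum * mod$bn[[bk]]$var +
        (1 - mod$bn_momentum) * va
    } else {
      mu <- mod$bn[[bk]]$mean
      va <- mod$bn[[bk]]$var
    }
    inv_sd <- 1 / sqrt(va + mod$bn_eps)
    Zh <- (Z - mu) * inv_sd
    Y <- Zh * as.vector(mod$params[[paste0("gamma", bk)]]) +
      as.vector(mod$params[[paste0("beta", bk)]])
    R <- pmax(Y, 0)
    # max-pool over non-overlapping windows of g$pool along positions
    Ptrim <- g$Pp * g$pool
    Rt <- R
    dim(Rt) <- c(mod$filters, g$P, B)
    Rt <- Rt[, seq_len(Ptrim), , drop = FALSE]
    dim(Rt) <- c(mod$filters, g$pool, g$Pp * B)
    cur <- Rt[, 1, ]
    am <- matrix(1L, mod$filters, g$Pp * B)
    if (g$pool > 1) {
      for (j in 2:g$pool) {
        cand <- Rt[, j, ]
        sel <- cand > cur
        cur[sel] <- cand[sel]
        am[sel] <- j
      }
    }
    caches[[bk]] <- list(Acol = Acol, Z = Z, Zh = Zh, Y = Y, mu = mu,
                         inv_sd = inv_sd, am = am, B = B)
    A <- cur
    dim(A) <- c(mod$filters * g$Pp, B)
  }
  mlpmod <- list(type = "mlp", nin = mod$flat, hidden = mod$mlp_hidden,
                 dropout = mod$dropout, params = mod$params)
  mf <- mlp_forward(mlpmod, A, train = train)
  list(out = mf$out,
       cache = list(blocks = caches, flat_in = A, mlp = mf$cache),
       mod = mod)   # mod returned because BN running stats update in train mode
}

cnn_backward <- function(mod, cache, dOut, need_dX = FALSE) {
  mlpmod <- list(type = "mlp", nin = mod$flat, hidden = mod$mlp_hidden,
                 dropout = mod$dropout, params = mod$params)
  mb <- mlp_backward(mlpmod, cache$mlp, dOut)
  grads <- mb$grads
  dA <- mb$dX                       # (filters * Pp_last, B)
  for (bk in rev(seq_len(mod$blocks))) {
    g <- mod$geoms[[bk]]
    cc <- cache$blocks[[bk]]
    B <- cc$B
    # unpool: scatter gradients to argmax positions
    dA_mat <- dA
    dim(dA_mat) <- c(mod$filters, g$Pp * B)
    dR <- array(0, c(mod$filters, g$pool, g$Pp * B))
    f_idx <- rep(seq_len(mod$filters), times = g$Pp * B)
    q_idx <- rep(seq_len(g$Pp * B), each = mod$filters)
    lin <- f_idx + (as.vector(cc$am) - 1L) * mod$filters +
      (q_idx - 1L) * mod$filters * g$pool
    dR[lin] <- as.vector(dA_mat)
    dim(dR) <- c(mod$filters, g$pool * g$Pp, B)
    Ptrim <- g$Pp * g$pool
    dRfull <- array(0, c(mod$filters, g$P, B))
    dRfull[, seq_len(Ptrim), ] <- dR
    dim(dRfull) <- c(mod$filters, g$P * B)
    # ReLU
    dY <- dRfull * (cc$Y > 0)
    # batch-norm backward (per filter row, statistics over all columns)
    gamma <- as.vector(mod$params[[paste0("gamma", bk)]])
    grads[[paste0("gamma", bk)]] <- matrix(rowSums(dY * cc$Zh), ncol = 1)
    grads[[paste0("beta", bk)]] <- matrix(rowSums(dY), ncol = 1)
    dZh <- dY * gamma
    Nc <- ncol(dY)
    dZ <- (cc$inv_sd / Nc) *
      (Nc * dZh - rowSums(dZh) - cc$Zh * rowSums(dZh * cc$Zh))
    # conv
    grads[[paste0("convW", bk)]] <- dZ %*% t(cc$Acol)
    grads[[paste0("convb", bk)]] <- matrix(rowSums(dZ), ncol = 1)
    if (bk > 1 || need_dX) {
      dAcol <- t(mod$params[[paste0("convW", bk)]]) %*% dZ
      dim(dAcol) <- c(g$in_ch * g$kernel * g$P, B)
      dX <- rowsum(dAcol, group = g$idx)
      full <- matrix(0, g$in_ch * g$len, B)
      full[as.integer(rownames(dX)), ] <- dX
      dA <- full
    } else {
      dA <- NULL
    }
  }
  list(grads = grads, dX = dA)
}

## ---- Module dispatch ------------------------------------------------------

module_forward <- function(mod, X, train = FALSE) {
  if (mod$type == "mlp") {
    fw <- mlp_forward(mod, X, train = train)
    fw$mod <- mod
    fw
  } else {
    cnn_forward(mod, X, train = train)
  }
}

module_backward <- function(mod, cache, dOut) {
  if (mod$type == "mlp") mlp_backward(mod, cache, dOut)
  else cnn_backward(mod, cache, dOut)
}

## ---- Sigmoid head and loss ------------------------------------------------

head_new <- function(nin) {
  list(W = he_init(1, nin), b = matrix(0, 1, 1))
}

head_forward <- function(head, D) {
  as.vector(sigmoid_(head$W %*% D + as.vector(head$b)))
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# gradient of mean BCE wrt the pre-sigmoid logit: (p - y) / B
head_backward <- function(head, D, p, y) {
  B <- length(y)
  dZ <- matrix(p - y, 1, B) / B
  list(grads = list(W = dZ %*% t(D), b = matrix(sum(dZ), 1, 1)),
       dD = t(head$W) %*% dZ)
}

## ---- Standalone submodel training -----------------------------------------

# Trains module + sigmoid head with mini-batch Adam. X: (features x N).
train_module <- function(mod, head, X, y, epochs, lr, batch_size,
                         verbose = FALSE) {
  N <- ncol(X)
  opt <- adam_new()
  hopt <- adam_new()
  losses <- numeric(0)
  for (ep in seq_len(max(epochs, 0))) {
    ord <- sample.int(N)
    ep_loss <- 0
    nb <- 0
    for (s in seq(1, N, by = batch_size)) {
      bi <- ord[s:min(s + batch_size - 1, N)]
      Xb <- X[, bi, drop = FALSE]
      yb <- y[bi]
      fw <- module_forward(mod, Xb, train = TRUE)
      mod <- fw$mod
      p <- head_forward(head, fw$out)
      ep_loss <- ep_loss + bce_loss(p, yb)
      nb <- nb + 1
      hb <- head_backward(head, fw$out, p, yb)
      mb <- module_backward(mod, fw$cache, hb$dD)
      up <- adam_step(mod$params, mb$grads, opt, lr)
      mod$params <- up$params
      opt <- up$state
      uph <- adam_step(head, hb$grads, hopt, lr)
      head <- uph$params
      hopt <- uph$state
    }
    losses <- c(losses, ep_loss / nb)
    if (verbose) message(sprintf("  epoch %d/%d  loss %.4f",
                                 ep, epochs, ep_loss / nb))
  }
  list(mod = mod, head = head, losses = losses)
}
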