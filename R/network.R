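# Hybrid feedforward + LSTM network, implemented directly on base-R matrix
# algebra.  Layout: a feedforward stack embeds the static covariates; an
# LSTM runs over the visit sequence; the static embedding is concatenated
# to the LSTM output at every timestep and a linear head emits one
# standardized next-INR prediction per timestep (many-to-many, masked).
#
# Parameters live in a flat named list of matrices/vectors so that the Adam
# state can mirror the structure with a simple lapply.

#' Model configuration
#'
#' @param static_hidden_sizes Widths of the feedforward (rectifier) layers
#'   over the static covariates, default `c(16, 16)`.
#' @param static_embedding_size Width of the linear static embedding fused
#'   into every timestep, default 8.
#' @param lstm_hidden_size LSTM state width, default 32.
#' @param lstm_layers Number of stacked LSTM layers, default 1.
#' @param learning_rate Adam step size, default 0.001.
#' @param batch_size Sequences per mini-batch, default 64.
#' @param max_epochs Training epoch cap, default 100.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best weights restored), default 10.
#' @param feature_mode `"full"`, `"no_gene"` (drop the two genotype
#'   covariates) or `"no_time"` (train/evaluate on single-timestep
#'   histories).
#' @return A validated list of class `warfinr_config`.
#' @export
warfinr_config <- function(static_hidden_sizes = c(16, 16),
                           static_embedding_size = 8,
                           lstm_hidden_size = 32,
                           lstm_layers = 1,
                           learning_rate = 0.001,
                           batch_size = 64,
                           max_epochs = 100,
                           early_stop_patience = 10,
                           feature_mode = c("full", "no_gene", "no_time")) {
  feature_mode <- match.arg(feature_mode)
  cfg <- list(static_hidden_sizes = as.integer(static_hidden_sizes),
              static_embedding_size = as.integer(static_embedding_size),
              lstm_hidden_size = as.integer(lstm_hidden_size),
              lstm_layers = as.integer(lstm_layers),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              feature_mode = feature_mode)
  sizes <- c(cfg$static_hidden_sizes, cfg$static_embedding_size,
             cfg$lstm_hidden_size, cfg$lstm_layers, cfg$batch_size,
             cfg$max_epochs, cfg$early_stop_patience)
  if (any(sizes < 1)) stop_validation("all sizes/counts must be >= 1")
  if (cfg$learning_rate <= 0) stop_validation("learning_rate must be > 0")
  if (cfg$lstm_layers != 1L)
    stop_validation("only single-layer LSTM is implemented")
  class(cfg) <- "warfinr_config"
  cfg
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize an untrained network
#'
#' @param config A [warfinr_config()].
#' @param n_static Width of the static feature vector.
#' @param n_temporal Width of each timestep's feature row (4).
#' @param seed Integer seed for the weight draw.
#' @return Named list of parameter matrices (class `warfinr_params`).
#' @export
build_model <- function(config, n_static, n_temporal = 4, seed = 1) {
  set.seed(as.integer(seed))
  H <- config$lstm_hidden_size
  emb <- config$static_embedding_size
  params <- list()
  widths <- c(n_static, config$static_hidden_sizes)
  for (l in seq_along(config$static_hidden_sizes)) {
    params[[paste0("st_W", l)]] <- glorot(widths[l], widths[l + 1])
    params[[paste0("st_b", l)]] <- numeric(widths[l + 1])
  }
  params$emb_W <- glorot(widths[length(widths)], emb)
  params$emb_b <- numeric(emb)
  params$lstm_Wx <- glorot(n_temporal, 4 * H)
  params$lstm_Wh <- glorot(H, 4 * H)
  # forget-gate bias starts at 1 so early training retains state
  params$lstm_b <- rep(c(0, 1, 0, 0), each = H)
  # head sees the LSTM state, the static embedding and (skip connection)
  # the current visit's raw features; the skip makes the near-identity map
  # "next INR is close to the current INR" immediately reachable
  params$head_W <- glorot(H + emb + n_temporal, 1)
  params$head_b <- 0
  attr(params, "config") <- config
  attr(params, "n_static") <- n_static
  attr(params, "n_temporal") <- n_temporal
  class(params) <- "warfinr_params"
  params
}

#' @export
n_parameters <- function(params) sum(vapply(params, length, numeric(1)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Pad a list of standardized examples into batch arrays.
# Returns Xs (B x S), Xt (list over t of B x 4), Y (B x Tmax),
# mask (B x Tmax), len (B).
make_batch <- function(examples) {
  B <- length(examples)
  len <- vapply(examples, function(e) nrow(e$temporal), integer(1))
  Tmax <- max(len)
  S <- length(examples[[1]]$static_features)
  Xs <- do.call(rbind, lapply(examples, `[[`, "static_features"))
  Xt <- lapply(seq_len(Tmax), function(t) {
    m <- matrix(0, B, 4)
    for (b in seq_len(B)) if (t <= len[b]) m[b, ] <- examples[[b]]$temporal[t, ]
    m
  })
  Y <- matrix(0, B, Tmax)
  mask <- matrix(FALSE, B, Tmax)
  for (b in seq_len(B)) {
    Y[b, seq_len(len[b])] <- examples[[b]]$targets
    mask[b, seq_len(len[b])] <- examples[[b]]$mask
  }
  list(Xs = Xs, Xt = Xt, Y = Y, mask = mask, len = len, B = B, Tmax = Tmax)
}

# Forward pass.  Returns per-timestep outputs (B x Tmax) and, if cache=TRUE,
# everything the backward pass needs.
nn_forward <- function(params, batch, cache = FALSE) {
  cfg <- attr(params, "config")
  H <- cfg$lstm_hidden_size
  B <- batch$B; Tmax <- batch$Tmax
  nlay <- length(cfg$static_hidden_sizes)

  # static branch
  A <- list(batch$Xs)
  for (l in seq_len(nlay)) {
    Z <- A[[l]] %*% params[[paste0("st_W", l)]] +
      matrix(params[[paste0("st_b", l)]], B, length(params[[paste0("st_b", l)]]),
             byrow = TRUE)
    A[[l + 1]] <- pmax(Z, 0)
  }
  E <- A[[nlay + 1]] %*% params$emb_W +
    matrix(params$emb_b, B, length(params$emb_b), byrow = TRUE)

  # LSTM branch
  bmat <- matrix(params$lstm_b, B, 4 * H, byrow = TRUE)
  h <- matrix(0, B, H); cstate <- matrix(0, B, H)
  Yhat <- matrix(0, B, Tmax)
  st <- if (cache) vector("list", Tmax) else NULL
  emb_n <- ncol(E)
  wE <- params$head_W[H + seq_len(emb_n), 1, drop = FALSE]
  wX <- params$head_W[H + emb_n + seq_len(nrow(params$head_W) - H - emb_n),
                      1, drop = FALSE]
  headE <- drop(E %*% wE)
  for (t in seq_len(Tmax)) {
    G <- batch$Xt[[t]] %*% params$lstm_Wx + h %*% params$lstm_Wh + bmat
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, H + 1:H, drop = FALSE])
    g <- tanh(G[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(G[, 3 * H + 1:H, drop = FALSE])
    cprev <- cstate
    cstate <- f * cprev + i * g
    tc <- tanh(cstate)
    hprev <- h
    h <- o * tc
    Yhat[, t] <- drop(h %*% params$head_W[1:H, , drop = FALSE]) + headE +
      drop(batch$Xt[[t]] %*% wX) + params$head_b
    if (cache) st[[t]] <- list(i = i, f = f, g = g, o = o, c = cstate,
                               tc = tc, cprev = cprev, hprev = hprev, h = h)
  }
  out <- list(Yhat = Yhat)
  if (cache) {
    out$A <- A; out$E <- E; out$lstm <- st
  }
  out
}

# Masked mean-squared-error loss and full analytic gradient.
nn_loss_grad <- function(params, batch) {
  cfg <- attr(params, "config")
  H <- cfg$lstm_hidden_size
  nlay <- length(cfg$static_hidden_sizes)
  fw <- nn_forward(params, batch, cache = TRUE)
  M <- sum(batch$mask)
  diff <- (fw$Yhat - batch$Y) * batch$mask
  loss <- sum(diff^2) / M
  dY <- 2 * diff / M                      # B x Tmax

  grads <- lapply(params, function(p) p * 0)
  B <- batch$B
  emb_n <- ncol(fw$E)
  wH <- params$head_W[1:H, , drop = FALSE]
  wE <- params$head_W[H + seq_len(emb_n), , drop = FALSE]
  dE <- matrix(0, B, nrow(wE))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)

  for (t in rev(seq_len(batch$Tmax))) {
    s <- fw$lstm[[t]]
    dyt <- dY[, t]
    grads$head_W <- grads$head_W +
      rbind(crossprod(s$h, dyt), crossprod(fw$E, dyt),
            crossprod(batch$Xt[[t]], dyt))
    grads$head_b <- grads$head_b + sum(dyt)
    dE <- dE + dyt %*% t(wE[, 1])
    dh <- dyt %*% t(wH[, 1]) + dh_next
    do_ <- dh * s$tc
    dc <- dh * s$o * (1 - s$tc^2) + dc_next
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$cprev
    dc_next <- dc * s$f
    dG <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    grads$lstm_Wx <- grads$lstm_Wx + crossprod(batch$Xt[[t]], dG)
    grads$lstm_Wh <- grads$lstm_Wh + crossprod(s$hprev, dG)
    grads$lstm_b <- grads$lstm_b + colSums(dG)
    dh_next <- dG %*% t(params$lstm_Wh)
  }

  # static branch backward
  grads$emb_W <- crossprod(fw$A[[nlay + 1]], dE)
  grads$emb_b <- colSums(dE)
  dA <- dE %*% t(params$emb_W)
  for (l in rev(seq_len(nlay))) {
    dZ <- dA * (fw$A[[l + 1]] > 0)
    grads[[paste0("st_W", l)]] <- crossprod(fw$A[[l]], dZ)
    grads[[paste0("st_b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[paste0("st_W", l)]])
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Masked MSE of a set of standardized examples under fixed parameters.
eval_loss <- function(params, examples, chunk = 256L) {
  tot <- 0; m <- 0
  for (start in seq(1, length(examples), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(examples))
    b <- make_batch(examples[idx])
    fw <- nn_forward(params, b)
    tot <- tot + sum(((fw$Yhat - b$Y) * b$mask)^2)
    m <- m + sum(b$mask)
  }
  tot / m
}

#' Train the network with Adam, mini-batches and early stopping
#'
#' Minimizes the masked mean-squared error over valid timesteps in
#' mini-batches of `config$batch_size` padded sequences.  Training stops
#' when the validation loss has not improved for
#' `config$early_stop_patience` consecutive epochs (or at
#' `config$max_epochs`); the best-validation-epoch weights are restored.
#'
#' @param train_examples,val_examples Disjoint lists of standardized
#'   `training_example`s.
#' @param config A [warfinr_config()].
#' @param seed Integer seed (weight initialization and batch shuffling).
#' @return List: `params` (trained weights), `history` (data frame of
#'   per-epoch train/validation loss), `best_epoch`.
#' @export
train_network <- function(train_examples, val_examples, config, seed = 1) {
  if (length(train_examples) == 0) stop_validation("empty training set")
  set.seed(as.integer(seed))
  n_static <- length(train_examples[[1]]$static_features)
  params <- build_model(config, n_static, seed = derive_seed(seed, "init"))
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  stale <- 0L
  n_targets <- vapply(train_examples, function(e) sum(e$mask), numeric(1))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(train_examples))
    # mini-batches hold ~batch_size prediction targets (the sample unit is
    # the visit transition), grouping whole sequences
    cuts <- cumsum(n_targets[ord])
    bin <- pmin(1L + (cuts - 1e-9) %/% config$batch_size,
                ceiling(sum(n_targets) / config$batch_size))
    tot <- 0; m <- 0
    for (bb in unique(bin)) {
      idx <- ord[bin == bb]
      b <- make_batch(train_examples[idx])
      lg <- nn_loss_grad(params, b)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; check feature standardization and learning rate")
      up <- adam_step(params, lg$grads, state, config$learning_rate)
      params <- up$params; state <- up$state
      tot <- tot + lg$loss * sum(b$mask); m <- m + sum(b$mask)
    }
    val <- eval_loss(params, val_examples)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tot / m,
                                val_loss = val)
    if (val < best$loss - 1e-9) {
      best <- list(loss = val, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  list(params = best$params,
       history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
       best_epoch = best$epoch)
}

# Per-timestep predictions (standardized scale) for a list of standardized
# examples; returns a list of numeric vectors aligned with each example's
# targets.
predict_sequences <- function(params, examples, chunk = 256L) {
  out <- vector("list", length(examples))
  for (start in seq(1, length(examples), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(examples))
    b <- make_batch(examples[idx])
    fw <- nn_forward(params, b)
    for (j in seq_along(idx))
      out[[idx[j]]] <- fw$Yhat[j, seq_len(b$len[j])]
  }
  out
}
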