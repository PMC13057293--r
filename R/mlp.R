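# Minimal feed-forward network: blocks of dense -> batch-norm -> ReLU ->
# dropout, a final dense layer and 2-way softmax, trained with Nadam.
# Written in plain matrix algebra; problem sizes here (<= 800 inputs,
# ~1.6k samples) make this entirely adequate.

.bn_eps <- 1e-5
.bn_momentum <- 0.9

mlp_init <- function(input_dim, hidden, seed) {
  with_seed(seed, {
    dims <- c(input_dim, hidden)
    layers <- lapply(seq_along(hidden), function(l) {
      fan_in <- dims[l]
      list(W = matrix(rnorm(fan_in * hidden[l], sd = sqrt(2 / fan_in)),
                      fan_in, hidden[l]),
           b = rep(0, hidden[l]),
           gamma = rep(1, hidden[l]), beta = rep(0, hidden[l]),
           rmean = rep(0, hidden[l]), rvar = rep(1, hidden[l]))
    })
    out <- list(W = matrix(rnorm(hidden[length(hidden)] * 2,
                                 sd = sqrt(2 / hidden[length(hidden)])),
                           hidden[length(hidden)], 2),
                b = rep(0, 2))
    list(layers = layers, out = out)
  })
}

mlp_forward_train <- function(net, X, dropout) {
  cache <- list()
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2L, ly$b, "+")
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    istd <- 1 / sqrt(v + .bn_eps)
    Zhat <- sweep(sweep(Z, 2L, mu), 2L, istd, "*")
    Y <- sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    R <- pmax(Y, 0)
    if (dropout > 0) {
      mask <- matrix(rbinom(length(R), 1L, 1 - dropout), nrow(R)) / (1 - dropout)
      A2 <- R * mask
    } else {
      mask <- NULL
      A2 <- R
    }
    cache[[l]] <- list(A_in = A, Zhat = Zhat, istd = istd, Y = Y, mask = mask,
                       mu = mu, v = v)
    A <- A2
  }
  logits <- sweep(A %*% net$out$W, 2L, net$out$b, "+")
  list(cache = cache, A_last = A, logits = logits)
}

softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

mlp_backward <- function(net, fw, Yonehot, dropout) {
  B <- nrow(Yonehot)
  P <- softmax(fw$logits)
  dlogits <- (P - Yonehot) / B
  grads <- list(out = list(W = t(fw$A_last) %*% dlogits,
                           b = colSums(dlogits)),
                layers = vector("list", length(net$layers)))
  dA <- dlogits %*% t(net$out$W)
  for (l in rev(seq_along(net$layers))) {
    cc <- fw$cache[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dR <- dA * (cc$Y > 0)
    dgamma <- colSums(dR * cc$Zhat)
    dbeta <- colSums(dR)
    dZhat <- sweep(dR, 2L, net$layers[[l]]$gamma, "*")
    # batch-norm backward
    t1 <- sweep(dZhat, 2L, colMeans(dZhat))
    t2 <- sweep(cc$Zhat, 2L, colMeans(dZhat * cc$Zhat), "*")
    dZ <- sweep(t1 - t2, 2L, cc$istd, "*")
    grads$layers[[l]] <- list(W = t(cc$A_in) %*% dZ, b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(net$layers[[l]]$W)
  }
  grads
}

nadam_state <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(layers = lapply(net$layers, function(l)
    zero_like(l[c("W", "b", "gamma", "beta")])),
    out = zero_like(net$out)),
    v = list(layers = lapply(net$layers, function(l)
      zero_like(l[c("W", "b", "gamma", "beta")])),
      out = zero_like(net$out)),
    t = 0L)
}

nadam_update_param <- function(p, g, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                               eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  p <- p - lr * (b1 * mhat + (1 - b1) * g / (1 - b1^t)) / (sqrt(vhat) + eps)
  list(p = p, m = m, v = v)
}

nadam_step <- function(net, grads, st, lr) {
  st$t <- st$t + 1L
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      up <- nadam_update_param(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                               st$m$layers[[l]][[nm]], st$v$layers[[l]][[nm]],
                               st$t, lr)
      net$layers[[l]][[nm]] <- up$p
      st$m$layers[[l]][[nm]] <- up$m
      st$v$layers[[l]][[nm]] <- up$v
    }
  }
  for (nm in c("W", "b")) {
    up <- nadam_update_param(net$out[[nm]], grads$out[[nm]],
                             st$m$out[[nm]], st$v$out[[nm]], st$t, lr)
    net$out[[nm]] <- up$p
    st$m$out[[nm]] <- up$m
    st$v$out[[nm]] <- up$v
  }
  list(net = net, st = st)
}

mlp_infer_probs <- function(net, X) {
  A <- X
  for (ly in net$layers) {
    Z <- sweep(A %*% ly$W, 2L, ly$b, "+")
    Zhat <- sweep(sweep(Z, 2L, ly$rmean), 2L, 1 / sqrt(ly$rvar + .bn_eps), "*")
    A <- pmax(sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+"), 0)
  }
  softmax(sweep(A %*% net$out$W, 2L, net$out$b, "+"))[, 2]
}

cross_entropy <- function(p1, y) {
  p <- ifelse(y == 1L, p1, 1 - p1)
  -mean(log(pmax(p, 1e-12)))
}

# stratified index split: held-out validation fraction per class
val_split <- function(y, fraction) {
  val <- integer(0)
  for (c0 in unique(y)) {
    idx <- which(y == c0)
    nv <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx)[seq_len(nv)])
  }
  sort(val)
}

mlp_fit <- function(X, y, spec) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  net <- mlp_init(ncol(X), spec$hidden_sizes, spec$seed)
  st <- nadam_state(net)
  with_seed(spec$seed + 1L, {
    use_val <- spec$patience > 0L && spec$val_fraction > 0 &&
      all(table(y) >= 2L / spec$val_fraction)
    if (use_val) {
      vi <- val_split(y, spec$val_fraction)
      Xtr <- Xs[-vi, , drop = FALSE]; ytr <- y[-vi]
      Xv <- Xs[vi, , drop = FALSE]; yv <- y[vi]
    } else {
      Xtr <- Xs; ytr <- y
    }
    n <- nrow(Xtr)
    best <- list(loss = Inf, net = net, epoch = 0L)
    bad <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = spec$batch_size)) {
        bi <- ord[start:min(start + spec$batch_size - 1L, n)]
        if (length(bi) < 2L) next        # batch-norm needs >= 2 rows
        fw <- mlp_forward_train(net, Xtr[bi, , drop = FALSE], spec$dropout)
        # update running batch-norm statistics
        for (l in seq_along(net$layers)) {
          cc <- fw$cache[[l]]
          net$layers[[l]]$rmean <- .bn_momentum * net$layers[[l]]$rmean +
            (1 - .bn_momentum) * cc$mu
          net$layers[[l]]$rvar <- .bn_momentum * net$layers[[l]]$rvar +
            (1 - .bn_momentum) * cc$v
        }
        onehot <- cbind(1 - ytr[bi], ytr[bi])
        grads <- mlp_backward(net, fw, onehot, spec$dropout)
        up <- nadam_step(net, grads, st, spec$learning_rate)
        net <- up$net; st <- up$st
      }
      if (use_val) {
        vloss <- cross_entropy(mlp_infer_probs(net, Xv), yv)
        if (vloss < best$loss - 1e-6) {
          best <- list(loss = vloss, net = net, epoch = epoch)
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= spec$patience) break
        }
      }
    }
    if (use_val && is.finite(best$loss)) net <- best$net
  })
  list(net = net, mu = mu, sd = sdev)
}

mlp_predict <- function(fitted, X) {
  Xs <- sweep(sweep(X, 2L, fitted$mu), 2L, fitted$sd, "/")
  mlp_infer_probs(fitted$net, Xs)
}
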