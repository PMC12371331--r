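# Independent straight-line re-implementation of the full forward pass:
# explicit per-position / per-head loops, no reuse of the package's layer
# code.  Used as the reference the fused implementation must reproduce.

oracle_ln <- function(X, gamma, beta) {
  Y <- X
  for (l in seq_len(nrow(X))) {
    x <- X[l, ]
    mu <- mean(x)
    v <- mean((x - mu)^2)
    Y[l, ] <- gamma * (x - mu) / sqrt(v + 1e-5) + beta
  }
  Y
}

oracle_softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# kernel-size-1 convolution gate: one scalar score per position, softmax
# over positions, rows of LayerNorm(X) scaled by their weight
oracle_gate <- function(X, prm) {
  Z <- oracle_ln(X, prm$gamma, prm$beta)
  s <- numeric(nrow(Z))
  for (l in seq_len(nrow(Z))) s[l] <- sum(prm$w[1L, ] * Z[l, ]) + prm$b
  g <- oracle_softmax(s)
  for (l in seq_len(nrow(Z))) Z[l, ] <- g[l] * Z[l, ]
  Z
}

oracle_rope <- function(X, base) {
  d <- ncol(X)
  Y <- X
  for (l in seq_len(nrow(X))) {
    pos <- l - 1
    for (i in seq_len(d / 2)) {
      a <- pos * base^(-2 * (i - 1) / d)
      x1 <- X[l, 2 * i - 1]; x2 <- X[l, 2 * i]
      Y[l, 2 * i - 1] <- cos(a) * x1 - sin(a) * x2
      Y[l, 2 * i] <- sin(a) * x1 + cos(a) * x2
    }
  }
  Y
}

# queries from the q-side stream (its Wq, Wo), keys/values from the kv-side
# stream (its Wk, Wv); per-head scaled softmax attention
oracle_attend <- function(Hq, Hkv, prm_q, prm_kv, config) {
  Q <- oracle_rope(Hq %*% prm_q$Wq, config$rope_base)
  K <- oracle_rope(Hkv %*% prm_kv$Wk, config$rope_base)
  V <- Hkv %*% prm_kv$Wv
  dh <- config$d_model / config$n_heads
  scale <- if (config$scale_mode == "paper_d") dh else sqrt(dh)
  ctx <- matrix(0, nrow(Hq), config$d_model)
  for (h in seq_len(config$n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(nrow(Hq))) {
      logits <- numeric(nrow(Hkv))
      for (j in seq_len(nrow(Hkv))) {
        logits[j] <- sum(Q[i, cols] * K[j, cols]) / scale
      }
      a <- oracle_softmax(logits)
      for (cc in cols) ctx[i, cc] <- sum(a * V[, cc])
    }
  }
  ctx %*% prm_q$Wo
}

oracle_pool <- function(Ho, prm) {
  Z <- oracle_ln(Ho, prm$gamma, prm$beta)
  s <- numeric(nrow(Z))
  for (l in seq_len(nrow(Z))) s[l] <- sum(prm$w * Z[l, ]) + prm$b
  wts <- oracle_softmax(s)
  f <- numeric(ncol(Z))
  for (cc in seq_len(ncol(Z))) f[cc] <- sum(wts * Z[, cc])
  f
}

oracle_head <- function(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, prm) {
  f <- c(f_ab_wt + f_ag_wt, f_ab_mt + f_ag_mt)
  z1 <- as.numeric(t(prm$W1) %*% f) + prm$b1
  r <- pmax(z1, 0)
  z2 <- as.numeric(t(prm$W2) %*% r) + prm$b2
  sum(prm$W3 * tanh(z2)) + prm$b3
}

oracle_forward <- function(E, params, config) {
  stopifnot(config$conv_kernel == 1L, config$variant == "full")
  proj <- function(M) {
    X <- M %*% params$proj$W
    for (l in seq_len(nrow(X))) X[l, ] <- X[l, ] + params$proj$b
    X
  }
  Hp <- list(
    ab_wt = oracle_gate(proj(E$ab_wt), params$ab$gate),
    ag_wt = oracle_gate(proj(E$ag_wt), params$ag$gate),
    ab_mt = oracle_gate(proj(E$ab_mt), params$ab$gate),
    ag_mt = oracle_gate(proj(E$ag_mt), params$ag$gate)
  )
  Ho <- list(
    ab_wt = oracle_attend(Hp$ab_wt, Hp$ag_wt, params$ab, params$ag, config),
    ag_wt = oracle_attend(Hp$ag_wt, Hp$ab_wt, params$ag, params$ab, config),
    ab_mt = oracle_attend(Hp$ab_mt, Hp$ag_mt, params$ab, params$ag, config),
    ag_mt = oracle_attend(Hp$ag_mt, Hp$ab_mt, params$ag, params$ab, config)
  )
  oracle_head(
    oracle_pool(Ho$ab_wt, params$ab$pool),
    oracle_pool(Ho$ag_wt, params$ag$pool),
    oracle_pool(Ho$ab_mt, params$ab$pool),
    oracle_pool(Ho$ag_mt, params$ag$pool),
    params$head
  )
}

# Reference metric formulas, written out longhand.
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  rmse <- sqrt(sum((y - yhat)^2) / n)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  list(rmse = rmse, r2 = r2, pcc = pearson(y, yhat),
       spearman = pearson(rank(y), rank(yhat)))
}
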