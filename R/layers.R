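# Building blocks of the attention module, each as a cached forward and a
# matching analytic backward pass.  Shapes follow the L x d "rows are
# residues" convention throughout; `mask` is a logical validity vector over
# rows (padding positions are FALSE).  Backward passes are verified against
# central finite differences in the test suite.

ln_eps <- 1e-5

# rep(v, each = L) recycles a length-d vector across the columns of an
# L x d matrix without sweep()'s dispatch overhead; these run in the
# training inner loop.
layer_norm_f <- function(X, gamma, beta) {
  L <- nrow(X)
  mu <- .rowMeans(X, L, ncol(X))
  xc <- X - mu
  v <- .rowMeans(xc * xc, L, ncol(X))
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  Y <- xhat * rep(gamma, each = L) + rep(beta, each = L)
  list(out = Y, xhat = xhat, inv = inv, gamma = gamma)
}

layer_norm_b <- function(dY, cache) {
  L <- nrow(dY)
  dxhat <- dY * rep(cache$gamma, each = L)
  m1 <- .rowMeans(dxhat, L, ncol(dY))
  m2 <- .rowMeans(dxhat * cache$xhat, L, ncol(dY))
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX,
       dgamma = colSums(dY * cache$xhat),
       dbeta = colSums(dY))
}

masked_softmax_f <- function(s, mask) {
  if (!any(mask)) abort("softmax over an all-masked input is undefined")
  w <- numeric(length(s))
  sm <- s[mask]
  e <- exp(sm - max(sm))
  w[mask] <- e / sum(e)
  list(w = w, mask = mask)
}

masked_softmax_b <- function(dw, cache) {
  w <- cache$w
  ds <- w * (dw - sum(dw * w))
  ds[!cache$mask] <- 0
  ds
}

# Single-output-channel 1D convolution over sequence positions ("same"
# padding, odd kernel).  Z must already have masked rows zeroed.
conv1d_f <- function(Z, w, b) {
  k <- nrow(w); h <- (k - 1L) %/% 2L
  L <- nrow(Z)
  q <- Z %*% t(w)                      # q[i, j] = Z[i, ] . w[j, ]
  s <- rep(b, L)
  for (j in seq_len(k)) {
    t_off <- j - 1L - h                # source row = l + t_off
    src <- seq_len(L) + t_off
    ok <- src >= 1L & src <= L
    s[ok] <- s[ok] + q[src[ok], j]
  }
  list(s = s, Z = Z, w = w, k = k, h = h, L = L)
}

conv1d_b <- function(ds, cache) {
  k <- cache$k; h <- cache$h; L <- cache$L; Z <- cache$Z; w <- cache$w
  dq <- matrix(0, L, k)
  for (j in seq_len(k)) {
    t_off <- j - 1L - h
    src <- seq_len(L) + t_off
    ok <- src >= 1L & src <= L
    dq[src[ok], j] <- ds[ok]
  }
  dZ <- dq %*% w
  dw <- t(dq) %*% Z
  list(dZ = dZ, dw = dw, db = sum(ds))
}

conv_gate_f <- function(X, prm, mask) {
  ln <- layer_norm_f(X, prm$gamma, prm$beta)
  Z <- ln$out
  Zm <- Z
  if (!all(mask)) Zm[!mask, ] <- 0
  cv <- conv1d_f(Zm, prm$w, prm$b)
  sm <- masked_softmax_f(cv$s, mask)
  g <- sm$w
  Hp <- Z * g
  if (!all(mask)) Hp[!mask, ] <- 0
  list(out = Hp, weights = g, ln = ln, Z = Z, cv = cv, sm = sm, mask = mask)
}

conv_gate_b <- function(dHp, cache) {
  mask <- cache$mask
  if (!all(mask)) dHp[!mask, ] <- 0
  g <- cache$sm$w
  dZ <- dHp * g
  dg <- rowSums(dHp * cache$Z)
  ds <- masked_softmax_b(dg, cache$sm)
  cb <- conv1d_b(ds, cache$cv)
  dZm <- cb$dZ
  if (!all(mask)) dZm[!mask, ] <- 0
  lb <- layer_norm_b(dZ + dZm, cache$ln)
  list(dX = lb$dX,
       dprm = list(gamma = lb$dgamma, beta = lb$dbeta, w = cb$dw, b = cb$db))
}

.rope_memo <- new.env(parent = emptyenv())

rope_tables <- function(positions, d, base) {
  key <- paste0(d, "|", base, "|", paste(positions, collapse = ","))
  hit <- .rope_memo[[key]]
  if (!is.null(hit)) return(hit)
  P <- d %/% 2L
  theta <- base^(-2 * (seq_len(P) - 1L) / d)
  ang <- outer(positions, theta)
  out <- list(C = cos(ang), S = sin(ang))
  if (length(ls(.rope_memo)) > 512L) rm(list = ls(.rope_memo), envir = .rope_memo)
  .rope_memo[[key]] <- out
  out
}

rope_f <- function(X, positions, base) {
  d <- ncol(X)
  if (d %% 2L != 0L) abort("rotary position embedding needs an even width")
  tb <- rope_tables(positions, d, base)
  C <- tb$C; S <- tb$S
  odd <- seq(1L, d, 2L); even <- odd + 1L
  x1 <- X[, odd, drop = FALSE]; x2 <- X[, even, drop = FALSE]
  Y <- X
  Y[, odd] <- C * x1 - S * x2
  Y[, even] <- S * x1 + C * x2
  list(out = Y, C = C, S = S, odd = odd, even = even)
}

rope_b <- function(dY, cache) {
  dy1 <- dY[, cache$odd, drop = FALSE]; dy2 <- dY[, cache$even, drop = FALSE]
  dX <- dY
  dX[, cache$odd] <- cache$C * dy1 + cache$S * dy2
  dX[, cache$even] <- -cache$S * dy1 + cache$C * dy2
  dX
}

qkv_f <- function(Hp, Wq, Wk, Wv, positions, base) {
  Qlin <- Hp %*% Wq
  Klin <- Hp %*% Wk
  V <- Hp %*% Wv
  rq <- rope_f(Qlin, positions, base)
  rk <- rope_f(Klin, positions, base)
  list(Q = rq$out, K = rk$out, V = V, rq = rq, rk = rk, Hp = Hp)
}

qkv_b <- function(dQ, dK, dV, cache, Wq, Wk, Wv) {
  dQlin <- rope_b(dQ, cache$rq)
  dKlin <- rope_b(dK, cache$rk)
  Hp <- cache$Hp
  dHp <- dQlin %*% t(Wq) + dKlin %*% t(Wk) + dV %*% t(Wv)
  list(dHp = dHp,
       dWq = crossprod(Hp, dQlin),
       dWk = crossprod(Hp, dKlin),
       dWv = crossprod(Hp, dV))
}

attn_scale <- function(d_head, scale_mode) {
  if (scale_mode == "paper_d") d_head else sqrt(d_head)
}

cross_attention_f <- function(Q, K, V, key_mask, n_heads, scale_mode) {
  d_model <- ncol(Q)
  if (d_model %% n_heads != 0L) abort("n_heads must divide d_model")
  if (!any(key_mask)) abort("cross-attention with all keys masked is undefined")
  dh <- d_model %/% n_heads
  scale <- attn_scale(dh, scale_mode)
  Lq <- nrow(Q)
  ctx <- matrix(0, Lq, d_model)
  heads <- vector("list", n_heads)
  all_keys <- all(key_mask)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    logits <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / scale
    if (!all_keys) logits[, !key_mask] <- -Inf
    m <- logits[cbind(seq_len(Lq), max.col(logits, ties.method = "first"))]
    A <- exp(logits - m)
    if (!all_keys) A[, !key_mask] <- 0
    A <- A / .rowSums(A, Lq, ncol(A))
    ctx[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[h]] <- A
  }
  list(context = ctx, attention = heads, Q = Q, K = K, V = V,
       n_heads = n_heads, dh = dh, scale = scale, key_mask = key_mask)
}

cross_attention_b <- function(dCtx, cache) {
  n_heads <- cache$n_heads; dh <- cache$dh; scale <- cache$scale
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$attention[[h]]
    dCtxh <- dCtx[, idx, drop = FALSE]
    dA <- tcrossprod(dCtxh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dCtxh)
    dlog <- A * (dA - .rowSums(dA * A, nrow(A), ncol(A)))
    dQ[, idx] <- (dlog %*% cache$K[, idx, drop = FALSE]) / scale
    dK[, idx] <- (crossprod(dlog, cache$Q[, idx, drop = FALSE])) / scale
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

merge_f <- function(ctx, Wo) {
  list(out = ctx %*% Wo, ctx = ctx, Wo = Wo)
}

merge_b <- function(dHo, cache) {
  list(dCtx = dHo %*% t(cache$Wo), dWo = crossprod(cache$ctx, dHo))
}

conv_pool_f <- function(Ho, prm, mask) {
  ln <- layer_norm_f(Ho, prm$gamma, prm$beta)
  Z <- ln$out
  scores <- drop(Z %*% prm$w) + prm$b
  sm <- masked_softmax_f(scores, mask)
  wts <- sm$w
  f <- colSums(Z * wts)
  list(out = f, weights = wts, ln = ln, Z = Z, sm = sm, prm_w = prm$w)
}

conv_pool_b <- function(df, cache) {
  Z <- cache$Z; wts <- cache$sm$w
  dZ <- outer(wts, df)
  dwts <- drop(Z %*% df)
  dscores <- masked_softmax_b(dwts, cache$sm)
  dZ <- dZ + outer(dscores, cache$prm_w)
  dw <- colSums(Z * dscores)
  lb <- layer_norm_b(dZ, cache$ln)
  list(dHo = lb$dX,
       dprm = list(gamma = lb$dgamma, beta = lb$dbeta, w = dw,
                   b = sum(dscores)))
}

# Position-wise two-layer MLP used by the `mlp` ablation variant in place of
# the cross-attention block.
mlp_block_f <- function(Hp, prm) {
  L <- nrow(Hp)
  Z1 <- Hp %*% prm$W1 + rep(prm$b1, each = L)
  R <- pmax(Z1, 0)
  Ho <- R %*% prm$W2 + rep(prm$b2, each = L)
  list(out = Ho, Hp = Hp, Z1 = Z1, R = R)
}

mlp_block_b <- function(dHo, cache, prm) {
  dR <- dHo %*% t(prm$W2)
  dZ1 <- dR * (cache$Z1 > 0)
  list(dHp = dZ1 %*% t(prm$W1),
       dprm = list(W1 = crossprod(cache$Hp, dZ1), b1 = colSums(dZ1),
                   W2 = crossprod(cache$R, dHo), b2 = colSums(dHo)))
}

head_f <- function(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, prm, training, dropout) {
  fvec <- c(f_ab_wt + f_ag_wt, f_ab_mt + f_ag_mt)
  z1 <- drop(crossprod(prm$W1, fvec)) + prm$b1
  keep <- if (training && dropout > 0) {
    (runif(length(z1)) >= dropout) / (1 - dropout)
  } else rep(1, length(z1))
  z1d <- z1 * keep
  r <- pmax(z1d, 0)
  z2 <- drop(crossprod(prm$W2, r)) + prm$b2
  t2 <- tanh(z2)
  y <- sum(prm$W3 * t2) + prm$b3
  list(out = y, fvec = fvec, z1d = z1d, r = r, t2 = t2, keep = keep)
}

head_b <- function(dy, cache, prm) {
  dt2 <- dy * prm$W3
  dz2 <- dt2 * (1 - cache$t2^2)
  dr <- drop(prm$W2 %*% dz2)
  dz1 <- dr * (cache$z1d > 0) * cache$keep
  dfvec <- drop(prm$W1 %*% dz1)
  d <- length(dfvec) %/% 2L
  list(
    df = list(ab_wt = dfvec[seq_len(d)], ag_wt = dfvec[seq_len(d)],
              ab_mt = dfvec[d + seq_len(d)], ag_mt = dfvec[d + seq_len(d)]),
    dprm = list(W1 = outer(cache$fvec, dz1), b1 = dz1,
                W2 = outer(cache$r, dz2), b2 = dz2,
                W3 = dy * cache$t2, b3 = dy)
  )
}

# ---- exported thin wrappers over the cached implementations ----------------

#' Convolutional position gating
#'
#' Computes `H' = softmax(Conv1D(LayerNorm(H))) * LayerNorm(H)`: a
#' single-channel 1D convolution scores each sequence position, the scores
#' are softmax-normalised over valid positions, and each layer-normalised
#' row is scaled by its weight (masked rows get weight 0).
#'
#' @param H L x d input matrix.
#' @param params List with `gamma`, `beta` (layer-norm, length d), `w`
#'   (kernel-size x d convolution weights) and scalar bias `b`.
#' @param mask Logical validity vector (default: all valid).
#' @return List with `output` (the gated L x d matrix) and `weights`
#'   (position weights, summing to 1 over valid positions).
#' @export
conv_gate <- function(H, params, mask = NULL) {
  mask <- mask %||% rep(TRUE, nrow(H))
  r <- conv_gate_f(H, params, mask)
  list(output = r$out, weights = r$weights)
}

#' Rotary position embedding
#'
#' Rotates each consecutive dimension pair `(2i-1, 2i)` of row `m` by the
#' angle `pos_m * base^(-2(i-1)/d)`.  Position 0 leaves a row unchanged and
#' every pair's Euclidean norm is preserved, so attention logits between
#' rotated queries and keys depend only on relative positions.
#'
#' @param X L x d matrix, d even.
#' @param positions Integer vector of length L (0-based by convention).
#' @param base Rotation base (default 10000).
#' @return The rotated matrix.
#' @export
apply_rope <- function(X, positions, base = 10000) {
  rope_f(X, positions, base)$out
}

#' Query/key/value projection with rotary positions on Q and K
#'
#' @param H L x d gated input.
#' @param Wq,Wk,Wv d x d_model projection matrices.
#' @param positions Integer positions (default `0:(L-1)`).
#' @param base Rotary base.
#' @return List with matrices `Q`, `K` (position-rotated) and `V` (not
#'   rotated).
#' @export
project_qkv <- function(H, Wq, Wk, Wv, positions = NULL, base = 10000) {
  positions <- positions %||% (seq_len(nrow(H)) - 1)
  r <- qkv_f(H, Wq, Wk, Wv, positions, base)
  list(Q = r$Q, K = r$K, V = r$V)
}

#' Multi-head cross-attention
#'
#' Splits `Q`, `K`, `V` into `n_heads` contiguous head slices and computes
#' per head `softmax(Q K^T / scale) V` with masked keys excluded.  With
#' `scale_mode = "paper_d"` the denominator is the head dimension itself;
#' `"sqrt_d"` uses its square root (the conventional variant).
#'
#' @param Q Query matrix (L_q x d_model).
#' @param K,V Key/value matrices (L_k x d_model).
#' @param key_mask Logical validity of key positions.
#' @param n_heads Number of heads (must divide d_model).
#' @param scale_mode `"paper_d"` or `"sqrt_d"`.
#' @return List with `context` (L_q x d_model, heads re-concatenated) and
#'   `attention` (list of per-head L_q x L_k row-stochastic matrices).
#' @export
cross_attend <- function(Q, K, V, key_mask = NULL, n_heads = 1L,
                         scale_mode = c("paper_d", "sqrt_d")) {
  scale_mode <- match.arg(scale_mode)
  key_mask <- key_mask %||% rep(TRUE, nrow(K))
  r <- cross_attention_f(Q, K, V, key_mask, n_heads, scale_mode)
  list(context = r$context, attention = r$attention)
}

#' Merge attention heads through the output projection
#'
#' @param context L x d_model matrix of concatenated head outputs.
#' @param Wo d_model x d_model output projection.
#' @return L x d_model refined representation.
#' @export
multi_head_merge <- function(context, Wo) {
  if (ncol(context) != nrow(Wo)) abort("head widths inconsistent with Wo")
  context %*% Wo
}

#' Attention pooling of a refined representation to one vector
#'
#' Each layer-normalised row is scored by a linear map to a scalar, scores
#' are softmax-normalised over valid positions, and the weighted rows are
#' summed: a masked attention-pooling.
#'
#' @param H L x d_model refined matrix.
#' @param params List with `gamma`, `beta`, `w` (length d_model) and `b`.
#' @param mask Logical validity vector.
#' @return List with `f` (pooled vector, width d_model) and `weights`.
#' @export
conv_pool <- function(H, params, mask = NULL) {
  mask <- mask %||% rep(TRUE, nrow(H))
  r <- conv_pool_f(H, params, mask)
  list(f = r$out, weights = r$weights)
}

#' Regression head over pooled wild-type and mutant features
#'
#' Concatenates `(f_ab_wt + f_ag_wt, f_ab_mt + f_ag_mt)` and applies three
#' fully connected layers `W3 . tanh(W2 . relu(dropout(W1 . f)))`; dropout is
#' active only when `training = TRUE`.
#'
#' @param f_ab_wt,f_ag_wt,f_ab_mt,f_ag_mt Pooled vectors of width d_model.
#' @param params List with `W1`, `b1`, `W2`, `b2`, `W3`, `b3`.
#' @param training Apply dropout?
#' @param dropout Dropout rate in `[0, 1)`.
#' @return Scalar prediction (ddG, kcal/mol).
#' @export
predict_head <- function(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, params,
                         training = FALSE, dropout = 0) {
  ws <- c(length(f_ab_wt), length(f_ag_wt), length(f_ab_mt), length(f_ag_mt))
  if (length(unique(ws)) != 1L || 2L * ws[1L] != nrow(params$W1)) {
    abort("pooled feature widths inconsistent with W1")
  }
  head_f(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, params, training, dropout)$out
}
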