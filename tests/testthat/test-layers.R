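test_that("conv gate: constant rows get uniform weights; L = 1 passes LayerNorm through", {
  d <- 6L
  prm <- rand_norm_params(d, 1)
  # identical rows: every position scores the same, softmax is uniform
  H <- matrix(rep(rnorm(d), 5L), 5L, d, byrow = TRUE)
  g <- conv_gate(H, prm)
  expect_equal(g$weights, rep(1 / 5, 5L), tolerance = 1e-12)
  # singleton sequence: weight 1, output is LayerNorm(H)
  H1 <- matrix(rnorm(d), 1L, d)
  g1 <- conv_gate(H1, prm)
  expect_equal(g1$weights, 1)
  expect_equal(g1$output,
               attnddg:::layer_norm_f(H1, prm$gamma, prm$beta)$out)
  # weights over valid positions sum to 1 for random input
  Hr <- rand_matrix(7L, d, 2)
  expect_equal(sum(conv_gate(Hr, prm)$weights), 1, tolerance = 1e-12)
  # all-masked input is an error
  expect_error(conv_gate(Hr, prm, mask = rep(FALSE, 7L)), "all-masked")
})

test_that("rotary embedding is an identity at position 0 and preserves pair norms", {
  X <- rand_matrix(6L, 8L, 3)
  expect_equal(apply_rope(X, rep(0L, 6L)), X)
  Y <- apply_rope(X, 0:5)
  for (i in 1:4) {
    cols <- c(2L * i - 1L, 2L * i)
    expect_equal(sqrt(rowSums(Y[, cols]^2)), sqrt(rowSums(X[, cols]^2)),
                 tolerance = 1e-6)
  }
  expect_error(apply_rope(rand_matrix(3L, 5L, 1), 0:2), "even")
})

test_that("rotary attention logits depend only on relative position", {
  withr::with_seed(11, {
    for (trial in 1:50) {
      d <- sample(c(4L, 8L, 16L), 1L)
      q <- matrix(rnorm(d), 1L, d)
      k <- matrix(rnorm(d), 1L, d)
      m <- sample(0:30, 1L); n <- sample(0:30, 1L); s <- sample(1:20, 1L)
      dot1 <- sum(apply_rope(q, m) * apply_rope(k, n))
      dot2 <- sum(apply_rope(q, m + s) * apply_rope(k, n + s))
      expect_equal(dot1, dot2, tolerance = 1e-8)
    }
  })
})

test_that("project_qkv rotates Q and K but not V", {
  H <- rand_matrix(5L, 8L, 4)
  I8 <- diag(8)
  # identity projections at zero positions: Q = K = H
  r <- project_qkv(H, I8, I8, I8, positions = rep(0L, 5L))
  expect_equal(r$Q, H)
  expect_equal(r$K, H)
  expect_equal(r$V, H)
  # V ignores the positions vector entirely
  Wq <- rand_matrix(8L, 8L, 5); Wk <- rand_matrix(8L, 8L, 6)
  Wv <- rand_matrix(8L, 8L, 7)
  r1 <- project_qkv(H, Wq, Wk, Wv, positions = 0:4)
  r2 <- project_qkv(H, Wq, Wk, Wv, positions = c(5L, 0L, 9L, 2L, 7L))
  expect_identical(r1$V, r2$V)
  expect_false(isTRUE(all.equal(r1$Q, r2$Q)))
  # matches dense arithmetic on a small input
  r3 <- project_qkv(H, Wq, Wk, Wv, positions = 0:4)
  expect_equal(r3$V, H %*% Wv)
  expect_equal(r3$Q, apply_rope(H %*% Wq, 0:4))
})

test_that("cross-attention matches a brute-force loop and normalises rows", {
  withr::with_seed(21, {
    for (trial in 1:5) {
      Q <- matrix(rnorm(40), 5L, 8L); K <- matrix(rnorm(40), 5L, 8L)
      V <- matrix(rnorm(40), 5L, 8L)
      for (mode in c("paper_d", "sqrt_d")) {
        r <- cross_attend(Q, K, V, n_heads = 2L, scale_mode = mode)
        # brute force per head, per row
        dh <- 4L
        scale <- if (mode == "paper_d") dh else sqrt(dh)
        for (h in 1:2) {
          cols <- ((h - 1L) * dh + 1L):(h * dh)
          for (i in 1:5) {
            lg <- sapply(1:5, function(j) sum(Q[i, cols] * K[j, cols]) / scale)
            a <- exp(lg - max(lg)); a <- a / sum(a)
            expect_equal(r$attention[[h]][i, ], a, tolerance = 1e-5)
            expect_equal(r$context[i, cols], colSums(a * V[, cols]),
                         tolerance = 1e-5)
          }
          expect_equal(rowSums(r$attention[[h]]), rep(1, 5L), tolerance = 1e-12)
        }
      }
    }
  })
  # single unmasked key: every weight is 1 and context rows copy that value
  Q <- rand_matrix(4L, 6L, 1); K <- rand_matrix(3L, 6L, 2)
  V <- rand_matrix(3L, 6L, 3)
  mask <- c(FALSE, TRUE, FALSE)
  r <- cross_attend(Q, K, V, key_mask = mask, n_heads = 3L)
  for (A in r$attention) expect_equal(A[, 2], rep(1, 4L))
  expect_equal(r$context, matrix(V[2, ], 4L, 6L, byrow = TRUE))
  expect_error(cross_attend(Q, K, V, key_mask = rep(FALSE, 3L)), "all keys masked")
})

test_that("multi-head merge concatenates heads then projects", {
  ctx <- rand_matrix(5L, 8L, 8)
  expect_equal(multi_head_merge(ctx, diag(8)), ctx)
  Wo <- rand_matrix(8L, 8L, 9)
  expect_equal(multi_head_merge(ctx, Wo), ctx %*% Wo)
  expect_equal(dim(multi_head_merge(ctx, Wo)), c(5L, 8L))
  expect_error(multi_head_merge(ctx, diag(4)), "inconsistent")
})

test_that("attention pooling is a masked softmax-weighted sum of LayerNorm rows", {
  d <- 6L
  prm <- rand_pool_params(d, 10)
  # L = 1: f equals the layer-normalised single row
  H1 <- rand_matrix(1L, d, 11)
  p1 <- conv_pool(H1, prm)
  expect_equal(p1$weights, 1)
  expect_equal(p1$f, drop(attnddg:::layer_norm_f(H1, prm$gamma, prm$beta)$out))
  # weights sum to 1 over valid positions
  H <- rand_matrix(9L, d, 12)
  mask <- c(rep(TRUE, 6L), rep(FALSE, 3L))
  p <- conv_pool(H, prm, mask)
  expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  expect_equal(p$weights[7:9], rep(0, 3L))
  # appending masked padding rows leaves f unchanged
  p_short <- conv_pool(H[1:6, ], prm)
  expect_equal(p$f, p_short$f, tolerance = 1e-6)
  expect_error(conv_pool(H, prm, mask = rep(FALSE, 9L)), "all-masked")
})

test_that("prediction head matches hand arithmetic and is asymmetric in wt/mt", {
  # 2-unit toy network, checked by hand
  prm <- list(W1 = matrix(c(1, 0, 0, 1), 2L, 2L), b1 = c(0, 0),
              W2 = matrix(c(1, -1), 2L, 1L), b2 = 0.5,
              W3 = 2, b3 = 0.25)
  f_ab_wt <- 0.3; f_ag_wt <- 0.2; f_ab_mt <- -0.1; f_ag_mt <- 0.4
  # f = (0.5, 0.3); z1 = (0.5, 0.3); relu same; z2 = 0.5 - 0.3 + 0.5 = 0.7
  y_hand <- 2 * tanh(0.7) + 0.25
  expect_equal(predict_head(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, prm), y_hand,
               tolerance = 1e-6)
  # deterministic without dropout
  expect_identical(predict_head(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, prm),
                   predict_head(f_ab_wt, f_ag_wt, f_ab_mt, f_ag_mt, prm))
  # swapping the wt and mt pairs changes the prediction in general
  withr::with_seed(31, {
    d <- 4L
    prm2 <- list(W1 = matrix(rnorm(2 * d * 6), 2 * d, 6), b1 = rnorm(6),
                 W2 = matrix(rnorm(18), 6, 3), b2 = rnorm(3),
                 W3 = rnorm(3), b3 = rnorm(1))
    fw <- rnorm(d); fg <- rnorm(d); fmw <- rnorm(d); fmg <- rnorm(d)
    y1 <- predict_head(fw, fg, fmw, fmg, prm2)
    y2 <- predict_head(fmw, fmg, fw, fg, prm2)
    expect_false(isTRUE(all.equal(y1, y2)))
  })
  expect_error(predict_head(1:4, 1:4, 1:4, 1:3, prm), "width")
})

test_that("analytic gradients match central finite differences for every variant", {
  rec <- complex_records("G1", list(c(H = "MARKSV")), list(c(A = "TWENDYQ")),
                         "H:R3K;A:W2F", 1.2)
  spec <- embedder_spec(d = 10L, seed = 3L)
  E <- embed_complex(rec, spec)
  for (variant in c("full", "no_attention", "mlp")) {
    cfg <- attention_config(d_model = 8L, n_heads = 2L, dropout = 0,
                            hidden = c(6L, 4L), conv_kernel = 3L,
                            variant = variant)
    p <- init_model_params(10L, cfg, seed = 1L)
    fw <- attnddg:::forward_complex(E, p, cfg)
    g <- attnddg:::flatten_params(attnddg:::backward_complex(1, fw$cache, p, cfg))
    th <- attnddg:::flatten_params(p)
    expect_true(all(is.finite(g)))
    eps <- 1e-6
    idx <- withr::with_seed(7, sample(length(th), 30L))
    num <- vapply(idx, function(i) {
      tp <- th; tp[i] <- tp[i] + eps
      tm <- th; tm[i] <- tm[i] - eps
      (attnddg:::forward_complex(E, attnddg:::unflatten_params(tp, p), cfg)$y -
         attnddg:::forward_complex(E, attnddg:::unflatten_params(tm, p), cfg)$y) /
        (2 * eps)
    }, numeric(1))
    expect_equal(g[idx], num, tolerance = 1e-4,
                 label = paste("analytic grad", variant))
  }
})
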