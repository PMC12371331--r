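# The full model: configuration, parameter initialisation, fused forward
# pass over the four embedding streams, and the matching backward pass used
# by the trainer.  Antibody and antigen streams own separate weights; the
# wild-type and mutant complexes share them (siamese evaluation), which is
# what makes wild-type/mutant features comparable in the head.

#' Configure the attention module
#'
#' @param d_model Even positive integer, width after the input projection.
#' @param n_heads Number of attention heads; must divide `d_model`.
#' @param scale_mode `"paper_d"` divides attention logits by the head
#'   dimension (the printed form of the model); `"sqrt_d"` by its square
#'   root (the conventional transformer scaling).
#' @param dropout Dropout rate of the regression head, `[0, 1)`.
#' @param conv_kernel Odd kernel size of the position-gating convolution.
#' @param rope_base Rotary position embedding base.
#' @param hidden Integer vector of the two hidden widths of the regression
#'   head.
#' @param variant `"full"` (cross-attention), `"no_attention"` (pooling
#'   applied directly to the gated streams) or `"mlp"` (position-wise MLP of
#'   comparable parameter count in place of attention).
#' @param mlp_hidden Hidden width of the `"mlp"` variant; default `2 *
#'   d_model`, which matches the attention block's parameter count to within
#'   a few percent.
#' @return An `attnddg_config` list.
#' @export
attention_config <- function(d_model = 32L, n_heads = 4L,
                             scale_mode = c("paper_d", "sqrt_d"),
                             dropout = 0.1, conv_kernel = 1L,
                             rope_base = 10000, hidden = c(64L, 32L),
                             variant = c("full", "no_attention", "mlp"),
                             mlp_hidden = NULL) {
  scale_mode <- match.arg(scale_mode)
  variant <- match.arg(variant)
  d_model <- as.integer(d_model); n_heads <- as.integer(n_heads)
  if (d_model < 2L || d_model %% 2L != 0L) abort("d_model must be even and >= 2")
  if (d_model %% n_heads != 0L) abort("n_heads must divide d_model")
  if (conv_kernel %% 2L != 1L) abort("conv_kernel must be odd")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(d_model = d_model, n_heads = n_heads, scale_mode = scale_mode,
         dropout = dropout, conv_kernel = as.integer(conv_kernel),
         rope_base = rope_base, hidden = as.integer(hidden),
         variant = variant,
         mlp_hidden = as.integer(mlp_hidden %||% (2L * d_model))),
    class = "attnddg_config"
  )
}

rnorm_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(fan_in)), nr, nc)
}

init_stream_params <- function(config) {
  d <- config$d_model
  p <- list(
    gate = list(gamma = rep(1, d), beta = rep(0, d),
                w = rnorm_mat(config$conv_kernel, d, d), b = 0),
    pool = list(gamma = rep(1, d), beta = rep(0, d),
                w = rnorm(d, sd = 1 / sqrt(d)), b = 0)
  )
  if (config$variant == "full") {
    p$Wq <- rnorm_mat(d, d, d); p$Wk <- rnorm_mat(d, d, d)
    p$Wv <- rnorm_mat(d, d, d); p$Wo <- rnorm_mat(d, d, d)
  } else if (config$variant == "mlp") {
    h <- config$mlp_hidden
    p$mlp <- list(W1 = rnorm_mat(d, h, d), b1 = rep(0, h),
                  W2 = rnorm_mat(h, d, h), b2 = rep(0, d))
  }
  p
}

#' Initialise model parameters
#'
#' @param d_in Embedding dimension coming out of the (frozen) embedder.
#' @param config An [attention_config()].
#' @param seed Integer seed for the initial draw.
#' @return Nested parameter list (`proj`, `ab`, `ag`, `head`).
#' @export
init_model_params <- function(d_in, config, seed = 1L) {
  with_local_seed(mix_seed(seed, 99L), {
    d <- config$d_model
    h1 <- config$hidden[1L]; h2 <- config$hidden[2L]
    list(
      proj = list(W = rnorm_mat(d_in, d, d_in), b = rep(0, d)),
      ab = init_stream_params(config),
      ag = init_stream_params(config),
      head = list(W1 = rnorm_mat(2L * d, h1, 2L * d), b1 = rep(0, h1),
                  W2 = rnorm_mat(h1, h2, h1), b2 = rep(0, h2),
                  W3 = rnorm(h2, sd = 1 / sqrt(h2)), b3 = 0)
    )
  })
}

# ---- flatten / unflatten / zero helpers ------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, template) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    attributes(out) <- attributes(x)
    out
  }
  fill(template)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  out <- p
  out[] <- 0
  out
}

add_grads <- function(a, b) {
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_grads, s = s))
  a * s
}

#' Number of trainable parameters
#'
#' @param params Parameter list (or any nested numeric list).
#' @return Integer count.
#' @export
count_params <- function(params) length(flatten_params(params))

# ---- fused forward / backward ----------------------------------------------

stream_keys <- c("ab_wt", "ag_wt", "ab_mt", "ag_mt")
side_of <- c(ab_wt = "ab", ag_wt = "ag", ab_mt = "ab", ag_mt = "ag")

default_masks <- function(E) lapply(E[stream_keys], function(m) rep(TRUE, nrow(m)))

forward_complex <- function(E, params, config, masks = NULL, positions = NULL,
                            training = FALSE) {
  masks <- masks %||% default_masks(E)
  positions <- positions %||% lapply(E[stream_keys], function(m) seq_len(nrow(m)) - 1)
  cache <- list(masks = masks, positions = positions, E = E[stream_keys])
  # a side without mutations has identical wt/mt inputs: reuse its gated
  # representation and projections instead of recomputing them
  twin <- c(ab_mt = "ab_wt", ag_mt = "ag_wt")
  same_as <- function(key) {
    tw <- twin[key]
    !is.na(tw) && identical(E[[key]], E[[tw]]) &&
      identical(masks[[key]], masks[[tw]]) &&
      identical(positions[[key]], positions[[tw]])
  }
  reuse <- vapply(stream_keys, same_as, logical(1L))
  Hp <- list(); gate_c <- list()
  for (key in stream_keys) {
    if (reuse[[key]]) {
      Hp[[key]] <- Hp[[twin[key]]]
      gate_c[[key]] <- gate_c[[twin[key]]]
      next
    }
    side <- side_of[[key]]
    X <- E[[key]] %*% params$proj$W + rep(params$proj$b, each = nrow(E[[key]]))
    g <- conv_gate_f(X, params[[side]]$gate, masks[[key]])
    Hp[[key]] <- g$out
    gate_c[[key]] <- g
  }
  cache$gate <- gate_c

  Ho <- list()
  if (config$variant == "full") {
    qkv <- list()
    for (key in stream_keys) {
      if (reuse[[key]]) {
        qkv[[key]] <- qkv[[twin[key]]]
        next
      }
      side <- side_of[[key]]
      qkv[[key]] <- qkv_f(Hp[[key]], params[[side]]$Wq, params[[side]]$Wk,
                          params[[side]]$Wv, positions[[key]], config$rope_base)
    }
    cache$qkv <- qkv
    attn <- list(); mrg <- list()
    pairs <- list(
      ab_wt = c(q = "ab_wt", kv = "ag_wt"), ag_wt = c(q = "ag_wt", kv = "ab_wt"),
      ab_mt = c(q = "ab_mt", kv = "ag_mt"), ag_mt = c(q = "ag_mt", kv = "ab_mt")
    )
    for (key in stream_keys) {
      pr <- pairs[[key]]
      a <- cross_attention_f(qkv[[pr[["q"]]]]$Q, qkv[[pr[["kv"]]]]$K,
                             qkv[[pr[["kv"]]]]$V, masks[[pr[["kv"]]]],
                             config$n_heads, config$scale_mode)
      m <- merge_f(a$context, params[[side_of[[key]]]]$Wo)
      attn[[key]] <- a; mrg[[key]] <- m
      Ho[[key]] <- m$out
    }
    cache$attn <- attn; cache$mrg <- mrg; cache$pairs <- pairs
  } else if (config$variant == "mlp") {
    mlp <- list()
    for (key in stream_keys) {
      r <- mlp_block_f(Hp[[key]], params[[side_of[[key]]]]$mlp)
      mlp[[key]] <- r
      Ho[[key]] <- r$out
    }
    cache$mlp <- mlp
  } else {
    Ho <- Hp
  }
  cache$Hp <- Hp

  fpool <- list(); pool_c <- list()
  for (key in stream_keys) {
    r <- conv_pool_f(Ho[[key]], params[[side_of[[key]]]]$pool, masks[[key]])
    fpool[[key]] <- r$out
    pool_c[[key]] <- r
  }
  cache$pool <- pool_c

  hd <- head_f(fpool$ab_wt, fpool$ag_wt, fpool$ab_mt, fpool$ag_mt,
               params$head, training, config$dropout)
  cache$head <- hd

  state <- list(
    gated = Hp,
    gate_weights = lapply(gate_c, `[[`, "weights"),
    attention = if (config$variant == "full") lapply(cache$attn, `[[`, "attention"),
    refined = Ho,
    pooled = fpool,
    pool_weights = lapply(pool_c, `[[`, "weights"),
    joint = hd$fvec,
    y = hd$out
  )
  list(y = hd$out, state = state, cache = cache)
}

backward_complex <- function(dy, cache, params, config) {
  g <- zero_like(params)
  hb <- head_b(dy, cache$head, params$head)
  g$head <- hb$dprm

  dHo <- list()
  for (key in stream_keys) {
    pb <- conv_pool_b(hb$df[[key]], cache$pool[[key]])
    side <- side_of[[key]]
    g[[side]]$pool <- add_grads(g[[side]]$pool, pb$dprm)
    dHo[[key]] <- pb$dHo
  }

  dHp <- setNames(vector("list", 4L), stream_keys)
  if (config$variant == "full") {
    dQ <- list(); dK <- list(); dV <- list()
    for (key in stream_keys) {
      dQ[[key]] <- 0; dK[[key]] <- 0; dV[[key]] <- 0
    }
    for (key in stream_keys) {
      side <- side_of[[key]]
      mb <- merge_b(dHo[[key]], cache$mrg[[key]])
      g[[side]]$Wo <- g[[side]]$Wo + mb$dWo
      ab_ <- cross_attention_b(mb$dCtx, cache$attn[[key]])
      pr <- cache$pairs[[key]]
      dQ[[pr[["q"]]]] <- dQ[[pr[["q"]]]] + ab_$dQ
      dK[[pr[["kv"]]]] <- dK[[pr[["kv"]]]] + ab_$dK
      dV[[pr[["kv"]]]] <- dV[[pr[["kv"]]]] + ab_$dV
    }
    for (key in stream_keys) {
      side <- side_of[[key]]
      qb <- qkv_b(dQ[[key]], dK[[key]], dV[[key]], cache$qkv[[key]],
                  params[[side]]$Wq, params[[side]]$Wk, params[[side]]$Wv)
      g[[side]]$Wq <- g[[side]]$Wq + qb$dWq
      g[[side]]$Wk <- g[[side]]$Wk + qb$dWk
      g[[side]]$Wv <- g[[side]]$Wv + qb$dWv
      dHp[[key]] <- qb$dHp
    }
  } else if (config$variant == "mlp") {
    for (key in stream_keys) {
      side <- side_of[[key]]
      mb <- mlp_block_b(dHo[[key]], cache$mlp[[key]], params[[side]]$mlp)
      g[[side]]$mlp <- add_grads(g[[side]]$mlp, mb$dprm)
      dHp[[key]] <- mb$dHp
    }
  } else {
    dHp <- dHo
  }

  for (key in stream_keys) {
    side <- side_of[[key]]
    gb <- conv_gate_b(dHp[[key]], cache$gate[[key]])
    g[[side]]$gate <- add_grads(g[[side]]$gate, gb$dprm)
    dX <- gb$dX
    g$proj$W <- g$proj$W + crossprod(cache$E[[key]], dX)
    g$proj$b <- g$proj$b + colSums(dX)
  }
  g
}

#' Run the fused model forward pass
#'
#' Applies, in order: input projection, convolutional position gating,
#' rotary-position-embedded Q/K/V projection, dual multi-head
#' cross-attention (antibody queries against antigen keys and vice versa,
#' for the wild-type and the mutant complex), output-projection merge,
#' attention pooling, and the regression head.
#'
#' @param embeddings List with matrices `ab_wt`, `ag_wt`, `ab_mt`, `ag_mt`
#'   (e.g. from [embed_complex()]).
#' @param params Parameters from [init_model_params()] or a fitted model.
#' @param config An [attention_config()].
#' @param masks Optional list of logical validity vectors per stream
#'   (padding support); defaults to all-valid.
#' @param positions Optional list of integer position vectors per stream
#'   (0-based); defaults to `0:(L-1)`.
#' @param training Apply head dropout?
#' @return List with `y` (predicted ddG, kcal/mol) and `state` (gate
#'   weights, per-head attention matrices, refined matrices, pooled vectors,
#'   the joint feature and the prediction).
#' @export
model_forward <- function(embeddings, params, config, masks = NULL,
                          positions = NULL, training = FALSE) {
  r <- forward_complex(embeddings, params, config, masks, positions, training)
  list(y = r$y, state = r$state)
}

#' Predict ddG for one record with a given parameter set
#'
#' Convenience wrapper: embeds the record's four sequences and runs
#' [model_forward()].
#'
#' @param record One-row record tibble.
#' @param params Model parameters.
#' @param config An [attention_config()].
#' @param spec An [embedder_spec()].
#' @return List with `y` and `state` as in [model_forward()].
#' @export
forward_record <- function(record, params, config, spec) {
  E <- embed_complex(record, spec)
  model_forward(E, params, config)
}
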