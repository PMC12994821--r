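# Dual-channel autoencoder-Transformer fusion network.
#
# Each modality is compressed by a two-layer ReLU autoencoder into a
# latent vector, reshaped into n_tokens x d_model tokens, given sinusoidal
# positional encoding, and refined by a multi-head self-attention
# Transformer encoder stack (post-norm residual blocks). The two encoder
# outputs are concatenated through a linear fusion layer feeding (i) an
# MLP classifier with a sigmoid head and (ii) two modality-specific
# Transformer decoders that cross-attend to the fused representation and
# reconstruct each modality through its autoencoder decoder, giving the
# cycle-consistency terms that couple the two channels.

#' Architecture configuration
#'
#' @param input_dim_rna,input_dim_meth Input feature counts per modality.
#' @param ae_hidden_dim Autoencoder hidden width (both encoder layers of
#'   Eq.-style two-layer MLPs share this width).
#' @param n_tokens,d_model Latent tokenization: the autoencoder latent of
#'   length `n_tokens * d_model` is reshaped into `n_tokens` tokens of
#'   width `d_model` before positional encoding.
#' @param n_heads Attention heads per layer; must divide `d_model`.
#' @param n_encoder_layers Transformer encoder depth (default 3).
#' @param n_decoder_layers Transformer decoder depth for the
#'   cross-reconstruction paths (default 1, a lighter mirror of the
#'   encoder).
#' @param ffn_hidden_dim Feed-forward network hidden width.
#' @param fusion_dim Width of the fused representation.
#' @param mlp_hidden_dims Integer vector of classifier hidden widths.
#' @param mask_rate Training-time input-feature masking rate in \[0, 1).
#' @param loss_weights Named numeric vector with entries `cls`,
#'   `rec_rna`, `rec_meth`, `cyc_rna`, `cyc_meth`.
#' @return An `arch_config` list; `latent_dim` is derived as
#'   `n_tokens * d_model`.
#' @export
arch_config <- function(input_dim_rna, input_dim_meth,
                        ae_hidden_dim = 64L, n_tokens = 4L, d_model = 8L,
                        n_heads = 4L, n_encoder_layers = 3L,
                        n_decoder_layers = 1L, ffn_hidden_dim = 32L,
                        fusion_dim = NULL, mlp_hidden_dims = 32L,
                        mask_rate = 0.1,
                        loss_weights = c(cls = 1, rec_rna = 1, rec_meth = 1,
                                         cyc_rna = 1, cyc_meth = 1)) {
  cfg <- list(
    input_dim_rna = as.integer(input_dim_rna),
    input_dim_meth = as.integer(input_dim_meth),
    ae_hidden_dim = as.integer(ae_hidden_dim),
    n_tokens = as.integer(n_tokens), d_model = as.integer(d_model),
    n_heads = as.integer(n_heads),
    n_encoder_layers = as.integer(n_encoder_layers),
    n_decoder_layers = as.integer(n_decoder_layers),
    ffn_hidden_dim = as.integer(ffn_hidden_dim),
    mlp_hidden_dims = as.integer(mlp_hidden_dims),
    mask_rate = mask_rate,
    loss_weights = loss_weights
  )
  cfg$latent_dim <- cfg$n_tokens * cfg$d_model
  cfg$fusion_dim <- if (is.null(fusion_dim)) cfg$latent_dim
                    else as.integer(fusion_dim)
  dims <- unlist(cfg[c("input_dim_rna", "input_dim_meth", "ae_hidden_dim",
                       "n_tokens", "d_model", "n_heads", "n_encoder_layers",
                       "n_decoder_layers", "ffn_hidden_dim", "fusion_dim")])
  if (any(is.na(dims)) || any(dims < 1L))
    stop("all architecture dimensions must be positive")
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  if (cfg$d_model %% 2L != 0L)
    stop("d_model must be even for sinusoidal positional encoding")
  if (cfg$mask_rate < 0 || cfg$mask_rate >= 1)
    stop("mask_rate must be in [0, 1)")
  req <- c("cls", "rec_rna", "rec_meth", "cyc_rna", "cyc_meth")
  if (!all(req %in% names(cfg$loss_weights)))
    stop("loss_weights must name: ", paste(req, collapse = ", "))
  class(cfg) <- "arch_config"
  cfg
}

#' Sinusoidal positional encoding grid
#'
#' Entry (pos, 2i) is `sin(pos / 10000^(2i/d_model))` and (pos, 2i+1) is
#' the matching cosine, with `pos` and `i` counted from zero.
#'
#' @param n_tokens Number of positions.
#' @param d_model Embedding width; must be even.
#' @return An `n_tokens x d_model` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(n_tokens, d_model) {
  if (d_model %% 2L != 0L) stop("d_model must be even")
  pos <- seq_len(n_tokens) - 1
  i <- seq_len(d_model %/% 2L) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, n_tokens, d_model)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

# ---- parameter initialization ---------------------------------------------

xavier <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

init_attention_params <- function(d_model) {
  list(Wq = xavier(d_model, d_model), bq = numeric(d_model),
       Wk = xavier(d_model, d_model), bk = numeric(d_model),
       Wv = xavier(d_model, d_model), bv = numeric(d_model),
       Wo = xavier(d_model, d_model), bo = numeric(d_model))
}

init_block_common <- function(cfg) {
  list(ffnW1 = xavier(cfg$d_model, cfg$ffn_hidden_dim),
       ffnb1 = numeric(cfg$ffn_hidden_dim),
       ffnW2 = xavier(cfg$ffn_hidden_dim, cfg$d_model),
       ffnb2 = numeric(cfg$d_model))
}

ln_params <- function(d) list(g = rep(1, d), b = numeric(d))

#' Initialize a model
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for Xavier-uniform weight initialization.
#' @return An `omixfuse_model` holding the architecture and all
#'   parameters as gradient-enabled leaves.
#' @export
init_model <- function(arch, seed = 1L) {
  p <- with_seed(seed, {
    prm <- list()
    for (m in c("rna", "meth")) {
      dim_in <- if (m == "rna") arch$input_dim_rna else arch$input_dim_meth
      h <- arch$ae_hidden_dim
      l <- arch$latent_dim
      prm[[paste0(m, ".ae.W1")]] <- xavier(dim_in, h)
      prm[[paste0(m, ".ae.b1")]] <- numeric(h)
      prm[[paste0(m, ".ae.W2")]] <- xavier(h, l)
      prm[[paste0(m, ".ae.b2")]] <- numeric(l)
      prm[[paste0(m, ".ae.W3")]] <- xavier(l, h)
      prm[[paste0(m, ".ae.b3")]] <- numeric(h)
      prm[[paste0(m, ".ae.W4")]] <- xavier(h, dim_in)
      prm[[paste0(m, ".ae.b4")]] <- numeric(dim_in)
      for (k in seq_len(arch$n_encoder_layers)) {
        base <- sprintf("%s.enc%d.", m, k)
        att <- init_attention_params(arch$d_model)
        for (nm in names(att)) prm[[paste0(base, "att.", nm)]] <- att[[nm]]
        ln1 <- ln_params(arch$d_model); ln2 <- ln_params(arch$d_model)
        prm[[paste0(base, "ln1.g")]] <- ln1$g
        prm[[paste0(base, "ln1.b")]] <- ln1$b
        ffn <- init_block_common(arch)
        for (nm in names(ffn)) prm[[paste0(base, nm)]] <- ffn[[nm]]
        prm[[paste0(base, "ln2.g")]] <- ln2$g
        prm[[paste0(base, "ln2.b")]] <- ln2$b
      }
      for (k in seq_len(arch$n_decoder_layers)) {
        base <- sprintf("%s.dec%d.", m, k)
        for (blk in c("self", "cross")) {
          att <- init_attention_params(arch$d_model)
          for (nm in names(att))
            prm[[paste0(base, blk, ".", nm)]] <- att[[nm]]
        }
        for (i in 1:3) {
          ln <- ln_params(arch$d_model)
          prm[[sprintf("%sln%d.g", base, i)]] <- ln$g
          prm[[sprintf("%sln%d.b", base, i)]] <- ln$b
        }
        ffn <- init_block_common(arch)
        for (nm in names(ffn)) prm[[paste0(base, nm)]] <- ffn[[nm]]
      }
      prm[[paste0(m, ".seed.W")]] <- xavier(arch$fusion_dim, arch$latent_dim)
      prm[[paste0(m, ".seed.b")]] <- numeric(arch$latent_dim)
    }
    prm[["mem.W"]] <- xavier(arch$fusion_dim, arch$latent_dim)
    prm[["mem.b"]] <- numeric(arch$latent_dim)
    prm[["fusion.W"]] <- xavier(2L * arch$latent_dim, arch$fusion_dim)
    prm[["fusion.b"]] <- numeric(arch$fusion_dim)
    widths <- c(arch$fusion_dim, arch$mlp_hidden_dims, 1L)
    for (k in seq_len(length(widths) - 1L)) {
      prm[[sprintf("cls.W%d", k)]] <- xavier(widths[k], widths[k + 1L])
      prm[[sprintf("cls.b%d", k)]] <- numeric(widths[k + 1L])
    }
    prm
  })
  params <- lapply(p, tg_leaf, needs = TRUE)
  pe <- positional_encoding(arch$n_tokens, arch$d_model)
  structure(list(arch = arch, params = params,
                 pe_flat = as.numeric(t(pe)), init_seed = as.integer(seed)),
            class = "omixfuse_model")
}

#' @export
print.omixfuse_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$val), 0))
  cat(sprintf(
    "<omixfuse_model: %d + %d inputs, latent %d (%d tokens x %d), %d parameters>\n",
    x$arch$input_dim_rna, x$arch$input_dim_meth, x$arch$latent_dim,
    x$arch$n_tokens, x$arch$d_model, n_par))
  invisible(x)
}

# ---- graph builders --------------------------------------------------------

prm <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  p
}

linear_node <- function(model, x, wname, bname) {
  tg_addbias(tg_matmul(x, prm(model, wname)), prm(model, bname))
}

ae_encode_node <- function(model, x, m) {
  h1 <- tg_relu(linear_node(model, x, paste0(m, ".ae.W1"), paste0(m, ".ae.b1")))
  tg_relu(linear_node(model, h1, paste0(m, ".ae.W2"), paste0(m, ".ae.b2")))
}

ae_decode_node <- function(model, z, m) {
  h2 <- tg_relu(linear_node(model, z, paste0(m, ".ae.W3"), paste0(m, ".ae.b3")))
  tg_sigmoid(linear_node(model, h2, paste0(m, ".ae.W4"), paste0(m, ".ae.b4")))
}

attention_block_node <- function(model, q_in, kv_in, base, n_tokens_q,
                                 n_tokens_kv) {
  q <- linear_node(model, q_in, paste0(base, "Wq"), paste0(base, "bq"))
  k <- linear_node(model, kv_in, paste0(base, "Wk"), paste0(base, "bk"))
  v <- linear_node(model, kv_in, paste0(base, "Wv"), paste0(base, "bv"))
  att <- tg_mha(q, k, v, n_tokens_q, n_tokens_kv, model$arch$n_heads)
  linear_node(model, att, paste0(base, "Wo"), paste0(base, "bo"))
}

ffn_node <- function(model, x, base) {
  h <- tg_relu(linear_node(model, x, paste0(base, "ffnW1"),
                           paste0(base, "ffnb1")))
  linear_node(model, h, paste0(base, "ffnW2"), paste0(base, "ffnb2"))
}

post_norm <- function(model, x, sub, base_ln) {
  tg_layernorm(tg_add(x, sub), prm(model, paste0(base_ln, ".g")),
               prm(model, paste0(base_ln, ".b")))
}

encoder_stack_node <- function(model, x_stacked, m) {
  t_ <- model$arch$n_tokens
  x <- x_stacked
  for (k in seq_len(model$arch$n_encoder_layers)) {
    base <- sprintf("%s.enc%d.", m, k)
    att <- attention_block_node(model, x, x, paste0(base, "att."), t_, t_)
    x <- post_norm(model, x, att, paste0(base, "ln1"))
    x <- post_norm(model, x, ffn_node(model, x, base), paste0(base, "ln2"))
  }
  x
}

decoder_stack_node <- function(model, x_stacked, mem_stacked, m) {
  t_ <- model$arch$n_tokens
  x <- x_stacked
  for (k in seq_len(model$arch$n_decoder_layers)) {
    base <- sprintf("%s.dec%d.", m, k)
    self_att <- attention_block_node(model, x, x, paste0(base, "self."),
                                     t_, t_)
    x <- post_norm(model, x, self_att, paste0(base, "ln1"))
    cross_att <- attention_block_node(model, x, mem_stacked,
                                      paste0(base, "cross."), t_, t_)
    x <- post_norm(model, x, cross_att, paste0(base, "ln2"))
    x <- post_norm(model, x, ffn_node(model, x, base), paste0(base, "ln3"))
  }
  x
}

classifier_node <- function(model, fused) {
  h <- fused
  n_layers <- length(model$arch$mlp_hidden_dims) + 1L
  for (k in seq_len(n_layers - 1L)) {
    h <- tg_relu(linear_node(model, h, sprintf("cls.W%d", k),
                             sprintf("cls.b%d", k)))
  }
  tg_sigmoid(linear_node(model, h, sprintf("cls.W%d", n_layers),
                         sprintf("cls.b%d", n_layers)))
}

tokens_node <- function(model, z) {
  with_pe <- tg_addbias(z, tg_leaf(model$pe_flat))
  tg_stack_tokens(with_pe, model$arch$n_tokens, model$arch$d_model)
}

# Full forward pass on a batch of paired rows. `x_rna` / `x_meth` are
# numeric matrices (rows aligned pairs); either may be NULL for
# single-modality operation (a zero placeholder channel is substituted).
# Returns the graph heads plus the input leaves (gradient-enabled when
# `input_grad` is TRUE, as needed for integrated gradients).
model_forward <- function(model, x_rna, x_meth, training = FALSE,
                          input_grad = FALSE) {
  arch <- model$arch
  n <- if (!is.null(x_rna)) nrow(x_rna) else nrow(x_meth)
  if (is.null(x_rna)) x_rna <- matrix(0, n, arch$input_dim_rna)
  if (is.null(x_meth)) x_meth <- matrix(0, n, arch$input_dim_meth)
  if (ncol(x_rna) != arch$input_dim_rna)
    stop("expression input has ", ncol(x_rna), " features; expected ",
         arch$input_dim_rna)
  if (ncol(x_meth) != arch$input_dim_meth)
    stop("methylation input has ", ncol(x_meth), " features; expected ",
         arch$input_dim_meth)
  dimnames(x_rna) <- NULL
  dimnames(x_meth) <- NULL
  xr_leaf <- tg_leaf(x_rna, needs = input_grad)
  xm_leaf <- tg_leaf(x_meth, needs = input_grad)
  xr <- xr_leaf
  xm <- xm_leaf
  if (training && arch$mask_rate > 0) {
    mr <- matrix(stats::runif(length(x_rna)) >= arch$mask_rate,
                 nrow(x_rna), ncol(x_rna)) * 1
    mm <- matrix(stats::runif(length(x_meth)) >= arch$mask_rate,
                 nrow(x_meth), ncol(x_meth)) * 1
    xr <- tg_hadamard(xr, tg_leaf(mr))
    xm <- tg_hadamard(xm, tg_leaf(mm))
  }
  z_r <- ae_encode_node(model, xr, "rna")
  z_m <- ae_encode_node(model, xm, "meth")
  recon_rna <- ae_decode_node(model, z_r, "rna")
  recon_meth <- ae_decode_node(model, z_m, "meth")
  enc_r <- tg_unstack_tokens(encoder_stack_node(model, tokens_node(model, z_r),
                                                "rna"),
                             arch$n_tokens, arch$d_model)
  enc_m <- tg_unstack_tokens(encoder_stack_node(model, tokens_node(model, z_m),
                                                "meth"),
                             arch$n_tokens, arch$d_model)
  fused <- linear_node(model, tg_cbind(list(enc_r, enc_m)),
                       "fusion.W", "fusion.b")
  prob <- classifier_node(model, fused)
  mem <- tokens_node(model, linear_node(model, fused, "mem.W", "mem.b"))
  cyc <- lapply(c(rna = "rna", meth = "meth"), function(m) {
    seed_tok <- tokens_node(model, linear_node(model, fused,
                                               paste0(m, ".seed.W"),
                                               paste0(m, ".seed.b")))
    lat <- tg_unstack_tokens(decoder_stack_node(model, seed_tok, mem, m),
                             arch$n_tokens, arch$d_model)
    ae_decode_node(model, lat, m)
  })
  list(prob = prob, fused = fused,
       recon_rna = recon_rna, recon_meth = recon_meth,
       cyc_rna = cyc$rna, cyc_meth = cyc$meth,
       x_rna = xr_leaf, x_meth = xm_leaf,
       x_rna_raw = x_rna, x_meth_raw = x_meth)
}

# Weighted five-term loss on a forward pass. `active` switches off the
# reconstruction terms of an ablated modality.
model_loss_node <- function(model, fw, y, active = c("rna", "meth")) {
  w <- model$arch$loss_weights
  terms <- list(cls = tg_bce(fw$prob, y))
  weights <- c(w[["cls"]])
  if ("rna" %in% active) {
    terms$rec_rna <- tg_mse(fw$recon_rna, fw$x_rna_raw)
    terms$cyc_rna <- tg_mse(fw$cyc_rna, fw$x_rna_raw)
    weights <- c(weights, w[["rec_rna"]], w[["cyc_rna"]])
  }
  if ("meth" %in% active) {
    terms$rec_meth <- tg_mse(fw$recon_meth, fw$x_meth_raw)
    terms$cyc_meth <- tg_mse(fw$cyc_meth, fw$x_meth_raw)
    weights <- c(weights, w[["rec_meth"]], w[["cyc_meth"]])
  }
  total <- tg_wsum(terms[names(terms)], weights)
  breakdown <- vapply(terms, function(t) t$val[1L, 1L], 0)
  list(total = total, breakdown = c(breakdown, total = total$val[1L, 1L]))
}

# ---- numeric (non-graph) surfaces for the individual operations -----------

#' Encode inputs into the autoencoder latent space
#' @param model An `omixfuse_model`.
#' @param x Numeric matrix (samples x input features).
#' @param modality `"rna"` or `"meth"`.
#' @return The latent matrix (samples x latent_dim), ReLU-activated.
#' @export
ae_encode <- function(model, x, modality = c("rna", "meth")) {
  m <- match.arg(modality)
  dim_in <- if (m == "rna") model$arch$input_dim_rna
            else model$arch$input_dim_meth
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != dim_in) stop("input dimension mismatch")
  tg_val(ae_encode_node(model, tg_leaf(x), m))
}

#' Decode latent vectors back to input space
#'
#' ReLU hidden layer followed by a sigmoid output layer, so every
#' reconstructed component lies in (0, 1).
#' @param model An `omixfuse_model`.
#' @param z Numeric latent matrix (samples x latent_dim).
#' @param modality `"rna"` or `"meth"`.
#' @return The reconstruction matrix.
#' @export
ae_decode <- function(model, z, modality = c("rna", "meth")) {
  m <- match.arg(modality)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$arch$latent_dim) stop("latent dimension mismatch")
  tg_val(ae_decode_node(model, tg_leaf(z), m))
}

#' Scaled dot-product multi-head attention on token grids
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` per head on channel-sliced
#' subspaces, concatenates the heads and (optionally) applies an output
#' projection. Intended for single token grids; attention weights are
#' attached as the `"weights"` attribute (heads x query x key array).
#'
#' @param q,k,v Token grids (`n_tokens x d_model`); `k` and `v` must have
#'   equal token counts.
#' @param n_heads Number of heads; must divide `d_model`.
#' @param w_out,b_out Optional output projection.
#' @return The attended token grid.
#' @export
multi_head_attention <- function(q, k, v, n_heads, w_out = NULL, b_out = NULL) {
  if (ncol(q) %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  if (nrow(k) != nrow(v)) stop("key and value token counts must match")
  res <- mha_forward_core(q, k, v, nrow(q), nrow(k), n_heads)
  out <- res$out
  if (!is.null(w_out)) {
    out <- out %*% w_out
    if (!is.null(b_out)) out <- out + rep(b_out, each = nrow(out))
  }
  wts <- array(0, dim = c(n_heads, nrow(q), nrow(k)))
  for (h in seq_len(n_heads)) {
    for (i in seq_len(nrow(q))) wts[h, i, ] <- res$weights[[h]][[i]][1L, ]
  }
  attr(out, "weights") <- wts
  out
}

#' Position-wise feed-forward network
#'
#' `max(0, x W1 + b1) W2 + b2` applied to every token row.
#' @param x Token grid or batch matrix with `d_model` columns.
#' @param w1,b1,w2,b2 Layer weights and biases.
#' @return The transformed grid.
#' @export
feed_forward <- function(x, w1, b1, w2, b2) {
  h <- pmax(x %*% w1 + rep(b1, each = nrow(x)), 0)
  h %*% w2 + rep(b2, each = nrow(h))
}

#' Run a token grid through a model's Transformer encoder stack
#'
#' @param model An `omixfuse_model`.
#' @param tokens A `n_tokens x d_model` grid with positional encoding
#'   already added.
#' @param modality Which encoder stack to use.
#' @return The encoded `n_tokens x d_model` grid.
#' @export
transformer_encode <- function(model, tokens, modality = c("rna", "meth")) {
  m <- match.arg(modality)
  if (nrow(tokens) != model$arch$n_tokens ||
      ncol(tokens) != model$arch$d_model)
    stop("tokens must be n_tokens x d_model")
  tg_val(encoder_stack_node(model, tg_leaf(tokens), m))
}

#' Fuse two encoder outputs and classify
#'
#' @param model An `omixfuse_model`.
#' @param z_rna_tokens,z_meth_tokens Flattened encoder outputs (samples x
#'   latent_dim).
#' @return A list with `prob` (class probability per sample, in (0, 1))
#'   and `fused` (the fused representation, samples x fusion_dim).
#' @export
fuse_and_classify <- function(model, z_rna_tokens, z_meth_tokens) {
  if (!is.matrix(z_rna_tokens)) z_rna_tokens <- matrix(z_rna_tokens, nrow = 1L)
  if (!is.matrix(z_meth_tokens))
    z_meth_tokens <- matrix(z_meth_tokens, nrow = 1L)
  fused <- linear_node(model,
                       tg_cbind(list(tg_leaf(z_rna_tokens),
                                     tg_leaf(z_meth_tokens))),
                       "fusion.W", "fusion.b")
  list(prob = as.numeric(tg_val(classifier_node(model, fused))),
       fused = tg_val(fused))
}

#' Reconstruct one modality from the fused representation
#'
#' Routes the fused vector through the target modality's Transformer
#' decoder (self-attention, cross-attention over fusion-derived memory
#' tokens, feed-forward) and its autoencoder decoder.
#'
#' @param model An `omixfuse_model`.
#' @param fused Fused representation (samples x fusion_dim).
#' @param target `"rna"` or `"meth"`.
#' @return The reconstruction in the target modality's input space, with
#'   every component in (0, 1).
#' @export
cross_reconstruct <- function(model, fused, target = c("rna", "meth")) {
  m <- match.arg(target)
  if (!is.matrix(fused)) fused <- matrix(fused, nrow = 1L)
  if (ncol(fused) != model$arch$fusion_dim) stop("fusion dimension mismatch")
  fz <- tg_leaf(fused)
  mem <- tokens_node(model, linear_node(model, fz, "mem.W", "mem.b"))
  seed_tok <- tokens_node(model, linear_node(model, fz, paste0(m, ".seed.W"),
                                             paste0(m, ".seed.b")))
  lat <- tg_unstack_tokens(decoder_stack_node(model, seed_tok, mem, m),
                           model$arch$n_tokens, model$arch$d_model)
  tg_val(ae_decode_node(model, lat, m))
}

#' Random input-feature masking
#'
#' Training-time denoising mask: each entry is independently zeroed with
#' probability `mask_rate`. Draws from the session RNG; identity when
#' `mask_rate` is 0 or `training` is `FALSE`.
#'
#' @param x Numeric matrix or vector.
#' @param mask_rate Masking probability in \[0, 1).
#' @param training Apply the mask? (Evaluation passes are unmasked.)
#' @return `x` with masked entries set to zero.
#' @export
apply_feature_mask <- function(x, mask_rate, training = TRUE) {
  if (mask_rate < 0 || mask_rate >= 1) stop("mask_rate must be in [0, 1)")
  if (!training || mask_rate == 0) return(x)
  keep <- stats::runif(length(x)) >= mask_rate
  x * keep
}

#' Five-term training loss breakdown
#'
#' Weighted sum of binary cross-entropy on the class probability, two
#' own-path reconstruction mean squared errors and two cross-path
#' (cycle-consistency) mean squared errors. Predictions outside (0, 1)
#' are clipped to `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param prediction Predicted probabilities.
#' @param label Binary labels.
#' @param reconstructions List with `rec_rna`, `rec_meth`, `cyc_rna`,
#'   `cyc_meth` matrices.
#' @param inputs List with `rna` and `meth` input matrices.
#' @param weights Named loss weights (`cls`, `rec_rna`, `rec_meth`,
#'   `cyc_rna`, `cyc_meth`).
#' @return A list with each term and the weighted `total`.
#' @export
compute_loss <- function(prediction, label, reconstructions, inputs,
                         weights = c(cls = 1, rec_rna = 1, rec_meth = 1,
                                     cyc_rna = 1, cyc_meth = 1)) {
  eps <- 1e-7
  if (any(prediction <= 0 | prediction >= 1)) {
    warning("predictions outside (0, 1) clipped for the cross-entropy")
    prediction <- pmin(pmax(prediction, eps), 1 - eps)
  }
  mse <- function(a, b) mean((a - b)^2)
  terms <- c(
    cls = -mean(label * log(prediction) + (1 - label) * log(1 - prediction)),
    rec_rna = mse(reconstructions$rec_rna, inputs$rna),
    rec_meth = mse(reconstructions$rec_meth, inputs$meth),
    cyc_rna = mse(reconstructions$cyc_rna, inputs$rna),
    cyc_meth = mse(reconstructions$cyc_meth, inputs$meth)
  )
  total <- sum(weights[names(terms)] * terms)
  as.list(c(terms, total = total))
}

#' Evaluation-mode forward pass
#'
#' @param model An `omixfuse_model`.
#' @param x_rna,x_meth Numeric input matrices with aligned rows (either
#'   may be `NULL` for single-modality use; a zero placeholder channel is
#'   substituted).
#' @return A list with numeric `prob`, `fused`, and the four
#'   reconstructions.
#' @export
predict_pairs <- function(model, x_rna, x_meth) {
  fw <- model_forward(model, x_rna, x_meth, training = FALSE)
  list(prob = as.numeric(tg_val(fw$prob)), fused = tg_val(fw$fused),
       rec_rna = tg_val(fw$recon_rna), rec_meth = tg_val(fw$recon_meth),
       cyc_rna = tg_val(fw$cyc_rna), cyc_meth = tg_val(fw$cyc_meth))
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint as JSON
#'
#' Single-file text archive holding the architecture configuration and
#' every named weight array; loadable across versions by name.
#' @param model An `omixfuse_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  arch <- unclass(model$arch)
  arch$loss_weights <- as.list(arch$loss_weights)
  payload <- list(
    format = "omixfuse-checkpoint-1",
    arch = arch,
    init_seed = model$init_seed,
    params = lapply(model$params, function(p) {
      list(dim = dim(p$val), data = as.numeric(p$val))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return An `omixfuse_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "omixfuse-checkpoint-1"))
    stop("unrecognized checkpoint format")
  a <- payload$arch
  arch <- arch_config(
    input_dim_rna = a$input_dim_rna, input_dim_meth = a$input_dim_meth,
    ae_hidden_dim = a$ae_hidden_dim, n_tokens = a$n_tokens,
    d_model = a$d_model, n_heads = a$n_heads,
    n_encoder_layers = a$n_encoder_layers,
    n_decoder_layers = a$n_decoder_layers,
    ffn_hidden_dim = a$ffn_hidden_dim, fusion_dim = a$fusion_dim,
    mlp_hidden_dims = a$mlp_hidden_dims, mask_rate = a$mask_rate,
    loss_weights = unlist(a$loss_weights)
  )
  model <- init_model(arch, seed = payload$init_seed)
  for (nm in names(payload$params)) {
    spec_ <- payload$params[[nm]]
    val <- spec_$data
    if (!is.null(spec_$dim) && length(spec_$dim) == 2L)
      val <- matrix(val, spec_$dim[1L], spec_$dim[2L])
    else val <- matrix(val, nrow = 1L)
    if (is.null(model$params[[nm]]))
      model$params[[nm]] <- tg_leaf(val, needs = TRUE)
    else model$params[[nm]]$val <- val
  }
  model
}

# Deep-copy the parameter values (used for best-epoch checkpoints and
# freeze verification).
snapshot_params <- function(model) lapply(model$params, function(p) p$val)

restore_params <- function(model, snapshot) {
  for (nm in names(snapshot)) model$params[[nm]]$val <- snapshot[[nm]]
  invisible(model)
}
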