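# The network's individual operations against closed forms and an
# independent naive reference, plus finite-difference gradient checks of
# the full computation graph.

test_that("autoencoder encoding applies two ReLU layers", {
  model <- tiny_model()
  arch <- model$arch
  p <- arch$input_dim_rna
  # zero weights and biases -> zero latent
  for (nm in c("rna.ae.W1", "rna.ae.b1", "rna.ae.W2", "rna.ae.b2"))
    model$params[[nm]]$val <- model$params[[nm]]$val * 0
  x <- matrix(runif(p), 1L, p)
  expect_equal(ae_encode(model, x, "rna"),
               matrix(0, 1L, arch$latent_dim))
  # identity-embedding weights pass non-negative inputs through
  h <- arch$ae_hidden_dim
  l <- arch$latent_dim
  w1 <- matrix(0, p, h); diag(w1[seq_len(l), seq_len(l)]) <- 1
  w2 <- matrix(0, h, l); diag(w2[seq_len(l), seq_len(l)]) <- 1
  model$params[["rna.ae.W1"]]$val <- w1
  model$params[["rna.ae.W2"]]$val <- w2
  x2 <- matrix(0, 1L, p)
  x2[1, seq_len(l)] <- seq_len(l) / l
  expect_equal(ae_encode(model, x2, "rna")[1, ], x2[1, seq_len(l)])
  # negative pre-activations are exactly zeroed
  x3 <- -x2
  expect_equal(ae_encode(model, x3, "rna"), matrix(0, 1L, l))
  expect_error(ae_encode(model, matrix(0, 1L, p + 1L), "rna"), "mismatch")
})

test_that("autoencoder decoding ends in a sigmoid with range (0,1)", {
  model <- tiny_model()
  l <- model$arch$latent_dim
  zero_model <- tiny_model()
  for (nm in grep("^rna\\.ae\\.(W3|b3|W4|b4)", names(zero_model$params),
                  value = TRUE))
    zero_model$params[[nm]]$val <- zero_model$params[[nm]]$val * 0
  out <- ae_decode(zero_model, matrix(0, 1L, l), "rna")
  expect_equal(as.numeric(out), rep(0.5, ncol(out)))
  set.seed(1)
  for (i in 1:20) {
    z <- matrix(rnorm(l, sd = 3), 1L, l)
    rec <- ae_decode(model, z, "rna")
    expect_true(all(rec > 0 & rec < 1))
  }
  # large positive output bias saturates toward 1
  sat <- tiny_model()
  sat$params[["rna.ae.b4"]]$val <- sat$params[["rna.ae.b4"]]$val + 50
  expect_gt(min(ae_decode(sat, matrix(0, 1L, l), "rna")), 0.99)
})

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(4L, 6L)
  # position 0: sines are 0, cosines are 1
  expect_equal(pe[1L, c(1, 3, 5)], rep(0, 3))
  expect_equal(pe[1L, c(2, 4, 6)], rep(1, 3))
  # PE(1, 0) = sin(1) for any d_model
  expect_equal(pe[2L, 1L], sin(1), tolerance = 1e-9)
  expect_equal(positional_encoding(8L, 10L)[2L, 1L], sin(1),
               tolerance = 1e-9)
  # direct evaluation of the angle formula for a middle entry
  expect_equal(pe[3L, 3L], sin(2 / 10000^(2 / 6)), tolerance = 1e-12)
  expect_true(all(abs(positional_encoding(16L, 12L)) <= 1))
  expect_error(positional_encoding(4L, 5L), "even")
})

test_that("multi-head attention matches a naive single-head reference", {
  # independent brute-force reference for one head
  naive_attention <- function(q, k, v) {
    s <- q %*% t(k) / sqrt(ncol(k))
    w <- exp(s)
    w <- w / rowSums(w)
    w %*% v
  }
  set.seed(3)
  q <- matrix(rnorm(4), 2L, 2L)
  k <- matrix(rnorm(4), 2L, 2L)
  v <- matrix(rnorm(4), 2L, 2L)
  out <- multi_head_attention(q, k, v, n_heads = 1L)
  expect_equal(unclass(out), naive_attention(q, k, v),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("attention weights are softmax-normalized with expected symmetries", {
  set.seed(4)
  d <- 8L
  q <- matrix(rnorm(3 * d), 3L, d)
  k <- matrix(rnorm(3 * d), 3L, d)
  v <- matrix(rnorm(3 * d), 3L, d)
  out <- multi_head_attention(q, k, v, n_heads = 4L)
  w <- attr(out, "weights")
  expect_equal(apply(w, c(1, 2), sum), matrix(1, 4L, 3L), tolerance = 1e-9)
  # single key/value token: output equals V regardless of Q
  out1 <- multi_head_attention(q, k[1L, , drop = FALSE],
                               v[1L, , drop = FALSE], n_heads = 4L)
  expect_equal(unclass(out1), matrix(rep(v[1L, ], each = 3L), 3L),
               ignore_attr = TRUE)
  # identical keys -> uniform attention weights
  k_same <- rbind(k[1L, ], k[1L, ])
  out2 <- multi_head_attention(q, k_same, v[1:2, ], n_heads = 4L)
  expect_equal(attr(out2, "weights")[1L, 1L, ], c(0.5, 0.5))
  expect_error(multi_head_attention(q, k, v, n_heads = 3L), "divisible")
})

test_that("the feed-forward network is two linear layers around a ReLU", {
  set.seed(5)
  x <- matrix(rnorm(6), 2L, 3L)
  w1 <- matrix(rnorm(12), 3L, 4L)
  b1 <- rnorm(4)
  w2 <- matrix(rnorm(12), 4L, 3L)
  b2 <- rnorm(3)
  out <- feed_forward(x, w1, b1, w2, b2)
  expect_equal(out, pmax(x %*% w1 + rep(b1, each = 2L), 0) %*% w2 +
                 rep(b2, each = 2L))
  # zero weights: output is the broadcast output bias
  expect_equal(feed_forward(x, w1 * 0, b1 * 0, w2 * 0, b2),
               matrix(rep(b2, each = 2L), 2L))
  # identity composition on non-negative input
  id3 <- diag(3)
  pad <- rbind(diag(3), 0)
  expect_equal(feed_forward(abs(x), cbind(id3, 0), rep(0, 4), pad,
                            rep(0, 3)), abs(x))
})

test_that("the encoder stack preserves shape and is token-permutation equivariant", {
  model <- tiny_model()
  arch <- model$arch
  set.seed(6)
  tokens <- matrix(rnorm(arch$n_tokens * arch$d_model),
                   arch$n_tokens, arch$d_model)
  out <- transformer_encode(model, tokens, "rna")
  expect_equal(dim(out), c(arch$n_tokens, arch$d_model))
  # permuting tokens (with their encodings already inside `tokens`)
  # permutes the output identically: attention has no positional bias
  perm <- c(2L, 1L)
  out_perm <- transformer_encode(model, tokens[perm, ], "rna")
  expect_equal(out_perm, out[perm, ], tolerance = 1e-10)
})

test_that("fusion and classification give calibrated degenerate outputs", {
  model <- tiny_model()
  arch <- model$arch
  # zero classifier output layer -> probability exactly 0.5
  n_out <- length(arch$mlp_hidden_dims) + 1L
  model$params[[sprintf("cls.W%d", n_out)]]$val <-
    model$params[[sprintf("cls.W%d", n_out)]]$val * 0
  model$params[[sprintf("cls.b%d", n_out)]]$val <-
    model$params[[sprintf("cls.b%d", n_out)]]$val * 0
  set.seed(7)
  zr <- matrix(rnorm(arch$latent_dim), 1L)
  zm <- matrix(rnorm(arch$latent_dim), 1L)
  out <- fuse_and_classify(model, zr, zm)
  expect_equal(out$prob, 0.5)
  expect_equal(ncol(out$fused), arch$fusion_dim)
  # probabilities stay inside (0,1) for random weights
  fresh <- tiny_model(seed = 3)
  for (i in 1:10) {
    p <- fuse_and_classify(fresh, matrix(rnorm(arch$latent_dim), 1L),
                           matrix(rnorm(arch$latent_dim), 1L))$prob
    expect_true(p > 0 && p < 1)
  }
})

test_that("cross-modal reconstruction has the right range, dims and coupling", {
  model <- tiny_model()
  arch <- model$arch
  set.seed(8)
  fused <- matrix(rnorm(2L * arch$fusion_dim), 2L)
  rec_r <- cross_reconstruct(model, fused, "rna")
  rec_m <- cross_reconstruct(model, fused, "meth")
  expect_equal(ncol(rec_r), arch$input_dim_rna)
  expect_equal(ncol(rec_m), arch$input_dim_meth)
  expect_true(all(rec_r > 0 & rec_r < 1))
  expect_error(cross_reconstruct(model, fused[, -1L], "rna"), "mismatch")
  # the cycle loss for one modality depends on the OTHER modality's
  # encoder weights (cross-modal coupling through the fused vector)
  xr <- matrix(runif(2L * arch$input_dim_rna), 2L)
  xm <- matrix(runif(2L * arch$input_dim_meth), 2L)
  cyc_rna_loss <- function(w) {
    model$params[["meth.enc1.att.Wq"]]$val <- w
    fw <- omixfuse:::model_forward(model, xr, xm)
    mean((omixfuse:::tg_val(fw$cyc_rna) - xr)^2)
  }
  w0 <- model$params[["meth.enc1.att.Wq"]]$val
  g <- omixfuse:::fd_gradient(cyc_rna_loss, w0, eps = 1e-4)
  expect_gt(max(abs(g)), 0)
})

test_that("feature masking zeroes the configured fraction only in training", {
  x <- matrix(1, 100L, 100L)
  expect_identical(apply_feature_mask(x, 0), x)
  expect_identical(apply_feature_mask(x, 0.9, training = FALSE), x)
  set.seed(9)
  masked <- apply_feature_mask(x, 0.3)
  surv <- mean(masked == 1)
  expect_gt(surv, 0.67)
  expect_lt(surv, 0.73)
  heavy <- apply_feature_mask(x, 0.999)
  expect_lt(mean(heavy), 0.01)
  expect_error(apply_feature_mask(x, 1), "mask_rate")
})

test_that("the loss breakdown matches closed forms", {
  inputs <- list(rna = matrix(0.5, 2L, 3L), meth = matrix(0.5, 2L, 3L))
  perfect <- list(rec_rna = inputs$rna, rec_meth = inputs$meth,
                  cyc_rna = inputs$rna, cyc_meth = inputs$meth)
  out <- compute_loss(c(1 - 1e-9, 1e-9), c(1, 0), perfect, inputs)
  expect_lt(out$total, 1e-6)
  # p = 0.5 -> BCE = ln 2
  out2 <- compute_loss(c(0.5, 0.5), c(1, 0), perfect, inputs)
  expect_equal(out2$cls, log(2), tolerance = 1e-12)
  # constant offset c in every reconstructed dim -> MSE = c^2
  off <- perfect
  off$rec_rna <- inputs$rna + 0.3
  out3 <- compute_loss(c(0.5, 0.5), c(1, 0), off, inputs)
  expect_equal(out3$rec_rna, 0.09, tolerance = 1e-12)
  expect_equal(out3$total,
               out3$cls + out3$rec_rna + out3$rec_meth + out3$cyc_rna +
                 out3$cyc_meth)
  expect_warning(compute_loss(c(1.2, 0.5), c(1, 0), perfect, inputs),
                 "clipped")
})

test_that("evaluation-mode forward passes are deterministic", {
  model <- tiny_model(seed = 5)
  arch <- model$arch
  set.seed(10)
  xr <- matrix(runif(3L * arch$input_dim_rna), 3L)
  xm <- matrix(runif(3L * arch$input_dim_meth), 3L)
  a <- predict_pairs(model, xr, xm)
  b <- predict_pairs(model, xr, xm)
  expect_identical(a$prob, b$prob)
  expect_identical(a$cyc_meth, b$cyc_meth)
})

test_that("loss gradients agree with finite differences on a tiny config", {
  arch <- arch_config(input_dim_rna = 6L, input_dim_meth = 5L,
                      ae_hidden_dim = 4L, n_tokens = 2L, d_model = 4L,
                      n_heads = 2L, n_encoder_layers = 1L,
                      n_decoder_layers = 1L, ffn_hidden_dim = 3L,
                      mlp_hidden_dims = 3L, mask_rate = 0)
  model <- init_model(arch, seed = 2)
  set.seed(11)
  xr <- matrix(runif(4L * 6L), 4L)
  xm <- matrix(runif(4L * 5L), 4L)
  y <- c(1, 0, 1, 0)
  loss_of <- function() {
    fw <- omixfuse:::model_forward(model, xr, xm)
    omixfuse:::model_loss_node(model, fw, y)
  }
  l <- loss_of()
  omixfuse:::tg_zero_grads(model$params)
  omixfuse:::tg_backward(l$total)
  grads <- lapply(model$params, function(p) p$grad)
  # every named parameter group receives a nonzero gradient
  group_max <- vapply(grads, function(g) if (is.null(g)) 0 else max(abs(g)), 0)
  expect_true(all(group_max > 0))
  # spot-check several groups against central finite differences
  check <- c("rna.ae.W1", "meth.ae.W4", "rna.enc1.att.Wk", "fusion.W",
             "cls.W1", "meth.dec1.cross.Wv", "rna.enc1.ln1.g", "mem.W")
  for (nm in check) {
    p <- model$params[[nm]]
    idx <- seq_len(min(6L, length(p$val)))
    fd <- vapply(idx, function(i) {
      orig <- p$val[i]
      p$val[i] <- orig + 1e-5
      up <- loss_of()$breakdown[["total"]]
      p$val[i] <- orig - 1e-5
      dn <- loss_of()$breakdown[["total"]]
      p$val[i] <- orig
      (up - dn) / 2e-5
    }, 0)
    expect_equal(as.numeric(grads[[nm]])[idx], fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip exactly", {
  model <- tiny_model(seed = 9)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(names(back$params), names(model$params))
  for (nm in names(model$params))
    expect_equal(back$params[[nm]]$val, model$params[[nm]]$val,
                 tolerance = 1e-12)
  arch <- model$arch
  set.seed(12)
  xr <- matrix(runif(2L * arch$input_dim_rna), 2L)
  xm <- matrix(runif(2L * arch$input_dim_meth), 2L)
  expect_equal(predict_pairs(back, xr, xm)$prob,
               predict_pairs(model, xr, xm)$prob, tolerance = 1e-12)
})

test_that("architecture invariants are enforced", {
  expect_error(arch_config(10, 10, d_model = 6L, n_heads = 4L),
               "divisible")
  expect_error(arch_config(10, 10, d_model = 7L, n_heads = 7L), "even")
  expect_error(arch_config(0, 10), "positive")
  expect_error(arch_config(10, 10, mask_rate = 1), "mask_rate")
  cfg <- arch_config(10, 10, n_tokens = 3L, d_model = 4L, n_heads = 2L)
  expect_equal(cfg$latent_dim, 12L)
})
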