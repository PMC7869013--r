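test_that("configuration contracts are validated", {
  expect_error(ssnet_config(window_sizes = c(5, 5)))
  expect_error(ssnet_config(window_sizes = 2000))
  expect_error(ssnet_config(channels = 0))
  small <- ssnet_config(preset = "small")
  expect_equal(small$channels, 16L)
  expect_equal(small$n_conv, 2L)
  full <- ssnet_config()
  expect_equal(full$window_sizes, c(5L, 10L, 15L, 20L))
  expect_equal(full$channels, 128L)
  expect_equal(full$n_conv, 3L)
})

test_that("pooling returns the row maximum and the row range", {
  p <- pool_latent(matrix(c(1, 3, 2), nrow = 1))
  expect_equal(p$d, 3)
  expect_equal(p$v, 2)
  p <- pool_latent(matrix(5, nrow = 2, ncol = 7))
  expect_equal(p$v, c(0, 0))
  p <- pool_latent(matrix(c(1, 9, 4, 2, 8, 6), 2), mask = c(FALSE, TRUE, FALSE))
  expect_equal(p$d, c(4, 2))       # single valid column
  expect_equal(p$v, c(0, 0))
  expect_error(pool_latent(matrix(1, 2, 3), mask = rep(FALSE, 3)), "no valid columns")
})

test_that("binary cross-entropy matches hand-computed values and clips", {
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 1), -log(1e-7), tolerance = 1e-6)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("forward scores are probabilities for arbitrary weights and inputs", {
  cfg <- tiny_config()
  set.seed(17)
  for (i in 1:10) {
    w <- ssnet:::.init_weights(cfg)
    pt <- build_protein_tensor(decompose_chain(make_coil_trace(20 + i)))
    s <- ssnet_score(pt, as.numeric(runif(cfg$n_bits) < 0.4), w, cfg)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("a dead final layer scores 0.5 regardless of input", {
  cfg <- tiny_config()
  w <- tiny_weights(cfg)
  w$f2$W[] <- 0
  w$f2$b[] <- 0
  s <- ssnet_score(tiny_tensor(), random_bits(cfg$n_bits), w, cfg)
  expect_equal(s, 0.5)
})

test_that("range-pool vectors are nonnegative inside the forward pass", {
  cfg <- tiny_config()
  w <- tiny_weights(cfg)
  cache <- ssnet:::.forward(ssnet:::.tensor_segments(tiny_tensor()),
                            random_bits(cfg$n_bits), w, cfg, keep = TRUE)
  nb <- length(cfg$window_sizes); R <- cfg$channels
  for (bi in seq_len(nb)) {
    v <- cache$pooled[(bi - 1) * 2 * R + R + seq_len(R)]
    expect_true(all(v >= 0))
  }
})

test_that("perturbing masked padding positions never changes the score", {
  cfg <- tiny_config()
  w <- tiny_weights(cfg)
  pt <- tiny_tensor(35)
  fp <- random_bits(cfg$n_bits)
  s0 <- ssnet_score(pt, fp, w, cfg)
  set.seed(2)
  pt$values[, !pt$mask] <- rnorm(sum(!pt$mask) * 2) * 100
  expect_identical(ssnet_score(pt, fp, w, cfg), s0)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()  # R = 4 channels, ~30 positions
  w <- tiny_weights(cfg)
  set.seed(13)
  segs <- list(matrix(rnorm(2 * 18), 2), matrix(rnorm(2 * 12), 2))
  fp <- random_bits(cfg$n_bits)
  y <- 1
  loss_fn <- function(w) {
    s <- ssnet:::.forward(segs, fp, w, cfg)
    s <- min(max(s, 1e-7), 1 - 1e-7)
    -(y * log(s) + (1 - y) * log(1 - s))
  }
  cache <- ssnet:::.forward(segs, fp, w, cfg, keep = TRUE)
  an <- ssnet:::.backward(cache, w, cfg, dout = cache$score - y)$grads
  eps <- 1e-5
  check_block <- function(get, set) {
    g <- get(an)
    for (ii in sample(length(g), min(6, length(g)))) {
      wp <- set(w, ii, eps); wm <- set(w, ii, -eps)
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      expect_lt(abs(num - g[ii]) / max(abs(num) + abs(g[ii]), 1e-8), 1e-4)
    }
  }
  check_block(function(g) g$conv[[1]][[1]]$W,
              function(w, i, d) { w$conv[[1]][[1]]$W[i] <- w$conv[[1]][[1]]$W[i] + d; w })
  check_block(function(g) g$conv[[2]][[2]]$W,
              function(w, i, d) { w$conv[[2]][[2]]$W[i] <- w$conv[[2]][[2]]$W[i] + d; w })
  check_block(function(g) g$prot$W,
              function(w, i, d) { w$prot$W[i] <- w$prot$W[i] + d; w })
  check_block(function(g) g$lig$W,
              function(w, i, d) { w$lig$W[i] <- w$lig$W[i] + d; w })
  check_block(function(g) g$f1$W,
              function(w, i, d) { w$f1$W[i] <- w$f1$W[i] + d; w })
  check_block(function(g) g$f2$W,
              function(w, i, d) { w$f2$W[i] <- w$f2$W[i] + d; w })
})

test_that("affinity labeling applies the 100 nM / 10,000 nM rule", {
  lab <- label_by_affinity(c(50, 20000, 5000, 99.9, 10000.5, 100))
  expect_equal(as.character(lab),
               c("active", "inactive", "discard", "active", "inactive", "discard"))
  expect_error(label_by_affinity(-5), "positive")
  expect_error(label_by_affinity(c(10, 0)), "positive")
})

test_that("training is deterministic, balanced and loss-decreasing", {
  set.seed(19)
  # tiny planted dataset: 12 proteins x 8 ligands
  ds <- make_synthetic_dataset(n_proteins = 12, n_ligands = 8,
                               residues_per_protein = 50, motif_length = 20,
                               n_bits = 16, noise = 0, seed = 4)
  cfg <- tiny_config(epochs = 3L, seed = 9L)
  fit1 <- ssnet(ds$pairs, ds$tensors, ds$fingerprints, cfg)
  fit2 <- ssnet(ds$pairs, ds$tensors, ds$fingerprints, cfg)
  expect_identical(fit1$weights, fit2$weights)       # same seed, same weights
  expect_identical(fit1$training$loss, fit2$training$loss)
  # balanced sampling: every epoch sees n_pos positives + n_pos negatives
  expect_equal(fit1$training$n_neg, fit1$training$n_pos)
  expect_lt(fit1$training$loss[3], fit1$training$loss[1] + 1e-9)
  # residuals/simulate interface
  expect_equal(length(residuals(fit1)), nrow(ds$pairs))
  sim <- simulate(fit1, nsim = 2, seed = 1)
  expect_true(all(unlist(sim) %in% 0:1))
})

test_that("single-class training data is rejected", {
  ds <- make_synthetic_dataset(n_proteins = 6, n_ligands = 4,
                               residues_per_protein = 50, motif_length = 20,
                               n_bits = 16, noise = 0, seed = 4)
  pairs <- ds$pairs[ds$pairs$label == 1, ]
  expect_error(ssnet(pairs, ds$tensors, ds$fingerprints, tiny_config()),
               "positive and one negative")
})

test_that("checkpoints round-trip scores bit-exactly", {
  cfg <- tiny_config()
  w <- tiny_weights(cfg)
  fit <- structure(list(weights = w, config = cfg,
                        training = data.frame(epoch = 1, loss = 0.5),
                        pairs = data.frame(), threshold = 0.5,
                        format_version = 1L),
                   class = "ssnet")
  path <- tempfile(fileext = ".rds")
  save_ssnet(fit, path)
  fit2 <- load_ssnet(path)
  expect_identical(fit2$weights, fit$weights)
  pt <- tiny_tensor()
  fp <- random_bits(cfg$n_bits)
  expect_identical(ssnet_score(pt, fp, fit$weights, cfg),
                   ssnet_score(pt, fp, fit2$weights, fit2$config))
  bad <- tempfile(); saveRDS(list(1), bad)
  expect_error(load_ssnet(bad), "not an ssnet checkpoint")
})
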