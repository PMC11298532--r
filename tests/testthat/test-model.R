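test_that("class weights follow the inverse-frequency rule and its identity", {
  w <- class_weights(c(rep("A", 4), rep("B", 2)))
  expect_equal(unname(w[c("A", "B")]), c(0.75, 1.5))
  expect_equal(unname(class_weights(rep(c("x", "y", "z"), 10))), rep(1, 3))
  # sum_c w_c * n_c = n for any multiset
  set.seed(31)
  for (i in 1:20) {
    labs <- sample(letters[1:sample(2:8, 1)], sample(10:200, 1), replace = TRUE)
    w <- class_weights(labs)
    counts <- table(labs)
    expect_equal(sum(w[names(counts)] * as.numeric(counts)), length(labs))
  }
  expect_error(class_weights(character(0)), "empty")
})

test_that("the loss matches closed forms and a hand-computed weighted batch", {
  # near-one-hot logits -> CE ~ 0
  logits <- matrix(c(50, 0, 0, 0, 50, 0), 2, 3, byrow = TRUE)
  expect_equal(classifier_loss(logits, c(1L, 2L), rep(1, 3)), 0, tolerance = 1e-10)
  # uniform logits, K classes, unit weights -> log K
  K <- 7
  expect_equal(classifier_loss(matrix(0, 4, K), rep(2L, 4), rep(1, K)), log(K))
  # 3-sample batch, weights {A: 0.75, B: 1.5}: scalar arithmetic oracle
  lg <- matrix(c(1.2, -0.3,
                 0.1, 0.9,
                 -2.0, 0.4), 3, 2, byrow = TRUE)
  y <- c(1L, 2L, 1L)
  w <- c(0.75, 1.5)
  oracle <- 0
  for (i in 1:3) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    oracle <- oracle + w[y[i]] * (-log(p[y[i]]))
  }
  oracle <- oracle / 3
  expect_equal(classifier_loss(lg, y, w), oracle, tolerance = 1e-6)
  expect_error(classifier_loss(lg, c(1L, 3L, 1L), w), "label outside")
  # the mask-entropy term adds lambda * mean entropy
  M <- matrix(c(0.5, 0.5, 1, 0), 2, 2, byrow = TRUE)
  ent <- mean(-M * log(M + 1e-15))
  expect_equal(classifier_loss(lg[1:2, ], y[1:2], w, mask = M, lambda_sparse = 0.1),
               classifier_loss(lg[1:2, ], y[1:2], w) + 0.1 * ent)
})

test_that("ghost batch norm normalizes each virtual batch independently", {
  set.seed(32)
  x <- matrix(rnorm(512 * 6, mean = 3, sd = 2), 512, 6)
  x[1:256, 1] <- x[1:256, 1] + 10       # make the two halves differ
  st <- new.env()
  out <- sctab:::.gbn_fwd(x, gamma = rep(1, 6), beta = rep(0, 6), st, "k",
                          vbs = 256L, training = TRUE)$out
  # manual two-group oracle
  manual <- x
  for (idx in list(1:256, 257:512)) {
    xg <- x[idx, ]
    mu <- colMeans(xg)
    v <- colMeans((xg - rep(mu, each = 256))^2)
    manual[idx, ] <- (xg - rep(mu, each = 256)) / rep(sqrt(v + 1e-5), each = 256)
  }
  expect_equal(out, manual, tolerance = 1e-12)
  # plain BN over the whole batch differs on this input
  st2 <- new.env()
  plain <- sctab:::.gbn_fwd(x, rep(1, 6), rep(0, 6), st2, "k", vbs = NULL,
                            training = TRUE)$out
  expect_gt(max(abs(plain - out)), 0.1)
})

test_that("the feature transformer has the contracted output shape", {
  set.seed(33)
  cfg <- sctab_config(n_d = 128L, n_a = 64L, n_shared = 2L, n_independent = 2L)
  params <- sctab:::.sctab_init(cfg, 40L, 3L)
  px <- sctab:::.sctab_prefixes(cfg)
  out <- feature_transformer(matrix(rnorm(10 * 40), 10, 40), params,
                             c(px$shared, px$ind1), virtual_batch_size = NULL)
  expect_equal(dim(out), c(10L, 192L))    # n_d + n_a = 128 + 64
})

test_that("forward pass postconditions: simplex masks, determinism, shapes", {
  set.seed(34)
  cc <- tiny_corpus(n_cells = 120L, n_genes = 30L, n_types = 3L, seed = 12)
  cfg <- sctab_config(n_d = 8L, n_a = 4L, n_shared = 2L, n_independent = 2L,
                      batch_size = 64L, virtual_batch_size = 32L, max_epochs = 2L)
  va <- tiny_corpus(n_cells = 40L, n_genes = 30L, n_types = 3L, seed = 13)
  va$obs$donor_id <- paste0("v_", va$obs$donor_id)
  fit <- train_classifier(cc, va, "sctab", cfg, seed = 1)

  x <- as.matrix(cc$counts[1:10, ])
  x[2, ] <- x[1, ]                         # duplicate cell
  out <- sctab_forward(fit, x)
  expect_equal(unname(rowSums(out$mask)), rep(1, 10), tolerance = 1e-5)
  expect_true(all(out$mask >= 0))
  expect_equal(out$logits[1, ], out$logits[2, ])   # identical cells, identical logits
  expect_equal(dim(out$embedding), c(10L, 8L))
  expect_equal(dim(out$logits), c(10L, 3L))
})

test_that("prediction is batch-partition invariant and returns proper probabilities", {
  cc <- tiny_corpus(n_cells = 150L, n_genes = 25L, n_types = 3L, seed = 14)
  va <- tiny_corpus(n_cells = 50L, n_genes = 25L, n_types = 3L, seed = 15)
  va$obs$donor_id <- paste0("v_", va$obs$donor_id)
  cfg <- sctab_config(n_d = 8L, n_a = 4L, n_shared = 2L, n_independent = 2L,
                      batch_size = 64L, virtual_batch_size = 32L, max_epochs = 2L)
  fit <- train_classifier(cc, va, "sctab", cfg, seed = 2)
  p_big <- predict(fit, va, batch_size = 4096L)
  p_small <- predict(fit, va, batch_size = 7L)
  # identical up to floating-point reassociation across BLAS block sizes
  expect_equal(p_big$probs, p_small$probs, tolerance = 1e-9)
  expect_equal(rowSums(p_big$probs), rep(1, 50), tolerance = 1e-8)
  # single cell and empty input
  one <- predict(fit, subset_cells(va, 1L))
  expect_length(one$label, 1L)
  empty <- predict(fit, subset_cells(va, integer(0)))
  expect_length(empty$label, 0L)
})

test_that("training follows the stated schedule and is bit-deterministic", {
  cc <- tiny_corpus(n_cells = 100L, n_genes = 20L, n_types = 3L, seed = 16)
  va <- tiny_corpus(n_cells = 40L, n_genes = 20L, n_types = 3L, seed = 17)
  va$obs$donor_id <- paste0("v_", va$obs$donor_id)
  cfg <- linear_config(batch_size = 32L, max_epochs = 4L)
  f1 <- train_classifier(cc, va, "linear", cfg, seed = 9)
  f2 <- train_classifier(cc, va, "linear", cfg, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # lr at epoch k = lr0 * 0.9^(k-1)
  expect_equal(f1$history$lr, 5e-4 * 0.9^(0:3))
  # shared donors between train and val are refused
  expect_error(train_classifier(cc, cc, "linear", cfg), "share donors")
  # single-class training data is refused
  one <- cc; one$obs$cell_type <- "only"
  expect_error(train_classifier(one, va, "linear", cfg), "single class")
})

test_that("baseline architectures have the contracted parameter shapes", {
  cc <- tiny_corpus(n_cells = 80L, n_genes = 20L, n_types = 4L, seed = 18)
  va <- tiny_corpus(n_cells = 30L, n_genes = 20L, n_types = 4L, seed = 19)
  va$obs$donor_id <- paste0("v_", va$obs$donor_id)
  fl <- train_classifier(cc, va, "linear", linear_config(batch_size = 32L, max_epochs = 1L),
                         seed = 1)
  # single weight matrix + bias: genes x classes + classes parameters
  expect_equal(dim(fl$params[["head.W"]]), c(20L, 4L))
  expect_length(fl$params[["head.b"]], 4L)
  expect_length(fl$params, 2L)

  cfg_m <- mlp_config(n_hidden = 3L, hidden_size = 16L, batch_size = 32L, max_epochs = 1L)
  fm <- train_classifier(cc, va, "mlp", cfg_m, seed = 1)
  expect_equal(dim(fm$params[["fc1.W"]]), c(20L, 16L))
  expect_equal(dim(fm$params[["fc3.W"]]), c(16L, 16L))
  expect_equal(dim(fm$params[["head.W"]]), c(16L, 4L))
})

test_that("a linear model recovers linearly separable synthetic labels", {
  spec <- synthetic_spec(n_genes = 60L, n_cell_types = 4L, n_donors = 8L,
                         cells_per_donor = 80L, marker_genes_per_type = 8L,
                         marker_effect = 2.5, donor_shift_scale = 0.1,
                         dispersion = 0.1, seed = 55L)
  fx <- generate_corpus(spec)
  sp <- split_fixture(fx, seed = 1)
  # learning rate suited to this 60-gene toy (the default targets full-scale corpora)
  fit <- train_classifier(sp$train, sp$val, "linear",
                          linear_config(batch_size = 64L, learning_rate = 0.01,
                                        max_epochs = 30L, patience = 30L),
                          seed = 1)
  pred <- predict(fit, sp$test)
  expect_gte(macro_f1_conventional(pred$label, sp$test$obs$cell_type), 0.95)
})

test_that("widening the network never hurts validation macro F1 beyond noise", {
  spec <- synthetic_spec(n_genes = 80L, n_cell_types = 4L, n_donors = 8L,
                         cells_per_donor = 100L, marker_genes_per_type = 8L,
                         marker_effect = 2.5, donor_shift_scale = 0.1,
                         dispersion = 0.1, seed = 66L)
  fx <- generate_corpus(spec)
  sp <- split_fixture(fx, seed = 1)
  cfg <- function(nd, na) sctab_config(n_d = nd, n_a = na, n_shared = 2L,
                                       n_independent = 2L, batch_size = 128L,
                                       virtual_batch_size = 64L,
                                       max_epochs = 8L, patience = 8L)
  for (s in 1:2) {
    narrow <- train_classifier(sp$train, sp$val, "sctab", cfg(8L, 4L), seed = s)
    wide <- train_classifier(sp$train, sp$val, "sctab", cfg(32L, 16L), seed = s)
    expect_gte(wide$best_val_macro_f1, narrow$best_val_macro_f1 - 0.05)
  }
})

test_that("gene ranking is driven by mean mask value and is order-invariant", {
  set.seed(36)
  masks <- matrix(runif(40 * 10, 0, 0.01), 40, 10,
                  dimnames = list(NULL, sprintf("g%02d", 1:10)))
  labels <- rep(c("A", "B"), each = 20)
  masks[labels == "A", 4] <- 0.9          # concentrated on gene 4 for type A
  rk <- gene_ranking(masks, labels, top_k = 3L)
  expect_equal(rk[["A"]][1], "g04")
  perm <- sample(40)
  expect_equal(gene_ranking(masks[perm, ], labels[perm], top_k = 3L), rk)
  expect_error(gene_ranking(masks, labels, top_k = 100L), "top_k")
})

test_that("checkpoints round-trip through a single-file archive", {
  cc <- tiny_corpus(n_cells = 80L, n_genes = 15L, n_types = 3L, seed = 20)
  va <- tiny_corpus(n_cells = 30L, n_genes = 15L, n_types = 3L, seed = 21)
  va$obs$donor_id <- paste0("v_", va$obs$donor_id)
  fit <- train_classifier(cc, va, "sctab",
                          sctab_config(n_d = 8L, n_a = 4L, n_shared = 2L,
                                       n_independent = 2L, batch_size = 32L,
                                       virtual_batch_size = 16L, max_epochs = 2L),
                          seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(predict(back, va)$probs, predict(fit, va)$probs, tolerance = 1e-12)
  expect_equal(back$classes, fit$classes)
  expect_equal(back$genes, fit$genes)
})
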