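#' Model configurations
#'
#' `sctab_config()` holds the hyperparameters of the feature-attention
#' tabular classifier: a feature transformer of `n_shared` GLU blocks reused
#' across both invocations plus `n_independent` invocation-specific blocks,
#' a single decision step, an `n_d`-dimensional decision embedding and an
#' `n_a`-dimensional attention embedding, ghost batch normalization over
#' `virtual_batch_size` rows, a sparsity regularizer weight `lambda_sparse`,
#' and AdamW training with a step-wise learning-rate decay per epoch. The
#' defaults are the full-scale settings; reduce `n_d`/`n_a` and
#' `batch_size` for small corpora.
#'
#' @param n_d Decision embedding width (default 128).
#' @param n_a Attention embedding width (default 64).
#' @param n_shared Number of shared GLU blocks (default 3).
#' @param n_independent Number of invocation-specific GLU blocks (default 5).
#' @param n_steps Number of decision steps; only 1 is supported.
#' @param lambda_sparse Weight of the attention-mask entropy regularizer.
#' @param virtual_batch_size Ghost batch size (default 256).
#' @param batch_size Mini-batch size (default 2048).
#' @param learning_rate Initial AdamW learning rate (default 0.005).
#' @param lr_decay Multiplicative decay per epoch (default 0.9).
#' @param weight_decay Decoupled weight decay (default 0.05).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation macro F1.
#' @param min_delta Minimum macro F1 improvement to reset patience.
#' @param bn_momentum Momentum of the batch-norm running statistics.
#' @param augment_training_data Apply augmentation vectors during training.
#' @return A config list of class `sctab_config`.
#' @export
sctab_config <- function(n_d = 128L, n_a = 64L, n_shared = 3L, n_independent = 5L,
                         n_steps = 1L, lambda_sparse = 1e-5,
                         virtual_batch_size = 256L, batch_size = 2048L,
                         learning_rate = 0.005, lr_decay = 0.9, weight_decay = 0.05,
                         max_epochs = 50L, patience = 10L, min_delta = 1e-4,
                         bn_momentum = 0.1, augment_training_data = FALSE) {
  if (n_steps != 1L) stop("only a single decision step (n_steps = 1) is supported")
  stopifnot(n_d > 0, n_a > 0, n_shared > 0, n_independent > 0,
            virtual_batch_size > 0, batch_size > 0)
  structure(as.list(environment()), class = c("sctab_config", "model_config"))
}

#' @rdname sctab_config
#' @export
linear_config <- function(batch_size = 2048L, learning_rate = 5e-4, lr_decay = 0.9,
                          weight_decay = 0.01, max_epochs = 50L, patience = 10L,
                          min_delta = 1e-4, augment_training_data = FALSE) {
  structure(as.list(environment()), class = c("linear_config", "model_config"))
}

#' @rdname sctab_config
#' @param n_hidden Number of hidden layers (default 8).
#' @param hidden_size Hidden layer width (default 128).
#' @param dropout Dropout rate (default 0.1).
#' @export
mlp_config <- function(n_hidden = 8L, hidden_size = 128L, dropout = 0.1,
                       batch_size = 2048L, learning_rate = 0.002, lr_decay = 0.9,
                       weight_decay = 0.05, max_epochs = 50L, patience = 10L,
                       min_delta = 1e-4, augment_training_data = FALSE) {
  structure(as.list(environment()), class = c("mlp_config", "model_config"))
}

#' Inverse-frequency class weights
#'
#' `weight_c = n_samples / (n_classes * n_c)`, so that
#' `sum_c weight_c * n_c = n_samples` for any label multiset and balanced
#' classes get weight exactly 1.
#'
#' @param labels Character or factor vector of cell-type labels.
#' @return Named numeric vector of weights, one per observed class.
#' @export
class_weights <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  counts <- table(as.character(labels))
  n <- length(labels)
  w <- n / (length(counts) * as.numeric(counts))
  names(w) <- names(counts)
  w
}

# ---- parameter initialization ----------------------------------------------

.sctab_prefixes <- function(config) {
  list(shared = paste0("shared", seq_len(config$n_shared)),
       ind1 = paste0("ind1_", seq_len(config$n_independent)),
       ind2 = paste0("ind2_", seq_len(config$n_independent)))
}

.sctab_init <- function(config, n_genes, n_classes) {
  H <- config$n_d + config$n_a
  p <- list()
  p[["input_bn.gamma"]] <- rep(1, n_genes)
  p[["input_bn.beta"]] <- rep(0, n_genes)
  px <- .sctab_prefixes(config)
  for (i in seq_along(px$shared)) {
    p <- .glu_init(p, px$shared[i], if (i == 1L) n_genes else H, H)
  }
  for (nm in c(px$ind1, px$ind2)) p <- .glu_init(p, nm, H, H)
  p[["att.W"]] <- .glorot(config$n_a, n_genes)
  p[["att.gamma"]] <- rep(1, n_genes)
  p[["att.beta"]] <- rep(0, n_genes)
  p[["head.W"]] <- .glorot(config$n_d, n_classes)
  p[["head.b"]] <- rep(0, n_classes)
  p
}

.linear_init <- function(config, n_genes, n_classes) {
  list("head.W" = .glorot(n_genes, n_classes), "head.b" = rep(0, n_classes))
}

.mlp_init <- function(config, n_genes, n_classes) {
  p <- list()
  dims <- c(n_genes, rep(config$hidden_size, config$n_hidden))
  for (i in seq_len(config$n_hidden)) {
    p[[sprintf("fc%d.W", i)]] <- .glorot(dims[i], dims[i + 1])
    p[[sprintf("fc%d.b", i)]] <- rep(0, dims[i + 1])
  }
  p[["head.W"]] <- .glorot(config$hidden_size, n_classes)
  p[["head.b"]] <- rep(0, n_classes)
  p
}

# ---- forward / backward -----------------------------------------------------
# xn: batch x genes matrix of normalized (log1p, size-factor) expression.

.sctab_fwd <- function(xn, params, config, state, training) {
  n_d <- config$n_d; n_a <- config$n_a
  vbs <- config$virtual_batch_size
  mom <- config$bn_momentum
  px <- .sctab_prefixes(config)

  ibn <- .gbn_fwd(xn, params[["input_bn.gamma"]], params[["input_bn.beta"]],
                  state, "input_bn", vbs = NULL, training, mom)
  x0 <- ibn$out

  ft1 <- .ft_fwd(x0, params, c(px$shared, px$ind1), state, "@p1", vbs, training, mom)
  a0 <- ft1$out[, n_d + seq_len(n_a), drop = FALSE]

  att_pre <- a0 %*% params[["att.W"]]
  att_bn <- .gbn_fwd(att_pre, params[["att.gamma"]], params[["att.beta"]],
                     state, "att_bn", vbs, training, mom)
  M <- .entmax15_mat(att_bn$out)

  xm <- x0 * M
  ft2 <- .ft_fwd(xm, params, c(px$shared, px$ind2), state, "@p2", vbs, training, mom)
  d1 <- ft2$out[, seq_len(n_d), drop = FALSE]
  r <- pmax(d1, 0)
  logits <- .shift_cols(r %*% params[["head.W"]], params[["head.b"]])

  list(logits = logits, mask = M, embedding = d1,
       cache = list(x0 = x0, ibn = ibn$cache, ft1 = ft1$caches, a0 = a0,
                    att_bn = att_bn$cache, M = M, xm = xm, ft2 = ft2$caches,
                    d1 = d1, r = r))
}

.sctab_bwd <- function(dlogits, dM_extra, out, params, config, gr) {
  cc <- out$cache
  n_d <- config$n_d; n_a <- config$n_a
  B <- nrow(dlogits)

  .add_grad(gr, "head.W", crossprod(cc$r, dlogits))
  .add_grad(gr, "head.b", colSums(dlogits))
  dr <- dlogits %*% t(params[["head.W"]])
  dd1 <- dr * (cc$d1 > 0)

  dh2 <- cbind(dd1, matrix(0, B, n_a))
  dxm <- .ft_bwd(dh2, cc$ft2, params, gr)

  dx0 <- dxm * cc$M
  dM <- dxm * cc$x0
  if (!is.null(dM_extra)) dM <- dM + dM_extra

  datt_bn <- .entmax15_bwd(dM, cc$M)
  bnb <- .gbn_bwd(datt_bn, cc$att_bn)
  .add_grad(gr, "att.gamma", bnb$dgamma)
  .add_grad(gr, "att.beta", bnb$dbeta)
  .add_grad(gr, "att.W", crossprod(cc$a0, bnb$dx))
  da0 <- bnb$dx %*% t(params[["att.W"]])

  dh1 <- cbind(matrix(0, B, n_d), da0)
  dx0 <- dx0 + .ft_bwd(dh1, cc$ft1, params, gr)

  ibnb <- .gbn_bwd(dx0, cc$ibn)
  .add_grad(gr, "input_bn.gamma", ibnb$dgamma)
  .add_grad(gr, "input_bn.beta", ibnb$dbeta)
  invisible(NULL)
}

.linear_fwd <- function(xn, params, config, state, training) {
  logits <- .shift_cols(xn %*% params[["head.W"]], params[["head.b"]])
  list(logits = logits, cache = list(x = xn))
}

.linear_bwd <- function(dlogits, out, params, gr) {
  .add_grad(gr, "head.W", crossprod(out$cache$x, dlogits))
  .add_grad(gr, "head.b", colSums(dlogits))
  invisible(NULL)
}

.mlp_fwd <- function(xn, params, config, state, training) {
  h <- xn
  caches <- vector("list", config$n_hidden)
  for (i in seq_len(config$n_hidden)) {
    pre <- .shift_cols(h %*% params[[sprintf("fc%d.W", i)]], params[[sprintf("fc%d.b", i)]])
    r <- pmax(pre, 0)
    drop_mask <- NULL
    if (training && config$dropout > 0) {
      drop_mask <- matrix(stats::runif(length(r)) >= config$dropout, nrow(r), ncol(r)) /
        (1 - config$dropout)
      r <- r * drop_mask
    }
    caches[[i]] <- list(x = h, pre = pre, drop = drop_mask)
    h <- r
  }
  logits <- .shift_cols(h %*% params[["head.W"]], params[["head.b"]])
  list(logits = logits, cache = list(layers = caches, h = h))
}

.mlp_bwd <- function(dlogits, out, params, config, gr) {
  .add_grad(gr, "head.W", crossprod(out$cache$h, dlogits))
  .add_grad(gr, "head.b", colSums(dlogits))
  dh <- dlogits %*% t(params[["head.W"]])
  for (i in rev(seq_len(config$n_hidden))) {
    cc <- out$cache$layers[[i]]
    if (!is.null(cc$drop)) dh <- dh * cc$drop
    dh <- dh * (cc$pre > 0)
    .add_grad(gr, sprintf("fc%d.W", i), crossprod(cc$x, dh))
    .add_grad(gr, sprintf("fc%d.b", i), colSums(dh))
    dh <- dh %*% t(params[[sprintf("fc%d.W", i)]])
  }
  invisible(NULL)
}

#' Training loss: weighted cross-entropy plus mask-entropy regularizer
#'
#' The cross-entropy term weights each sample by the class weight of its
#' true label (mean over the batch). For the attention model the mask
#' entropy `mean(-M * log(M + 1e-15))` is added with weight `lambda_sparse`
#' to encourage sparse feature selection.
#'
#' @param logits batch x classes matrix.
#' @param mask Optional attention mask (batch x genes) for the sparsity term.
#' @param labels Integer class indices (1-based).
#' @param weights Numeric class-weight vector as from [class_weights()]
#'   (indexed by class position).
#' @param lambda_sparse Sparsity weight (0 disables the term).
#' @return Scalar loss value.
#' @export
classifier_loss <- function(logits, labels, weights, mask = NULL, lambda_sparse = 0) {
  if (any(labels < 1L | labels > ncol(logits))) stop("label outside class set")
  fw <- .wce_fwd_bwd(logits, labels, weights)
  loss <- fw$loss
  if (!is.null(mask) && lambda_sparse > 0) {
    loss <- loss + lambda_sparse * mean(-mask * log(mask + 1e-15))
  }
  loss
}

# gradient of the sparsity term wrt the mask
.sparse_grad <- function(M, lambda_sparse) {
  if (lambda_sparse <= 0) return(NULL)
  eps <- 1e-15
  -(log(M + eps) + M / (M + eps)) * (lambda_sparse / length(M))
}

# ---- training ---------------------------------------------------------------

.as_dense_normalized <- function(corpus) {
  if (corpus$layer == "raw") corpus <- normalize_corpus(corpus)
  as.matrix(corpus$counts)
}

# plain (non-ontology) macro F1 used for early stopping
.macro_f1 <- function(pred, truth, n_classes) {
  f1 <- numeric(0)
  for (c in seq_len(n_classes)) {
    support <- sum(truth == c)
    if (!support) next
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- support - tp
    f1 <- c(f1, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1)
}

#' Train a cell-type classifier
#'
#' Mini-batch AdamW training of the feature-attention model or one of the
#' baselines (`linear`, `mlp`) on a raw-count corpus, with optional
#' donor-difference augmentation applied per batch in normalized expression
#' space during training only. The learning rate at epoch `k` (0-based) is
#' `learning_rate * lr_decay^k`. After every epoch the validation loss and
#' macro F1 are recorded; training stops early when the validation macro F1
#' has not improved by `min_delta` for `patience` epochs, and the
#' best-epoch parameters are returned. Fully deterministic given `seed`.
#'
#' @param train,val [cell_corpus()] objects (raw layer) with disjoint donors;
#'   `obs$cell_type` supplies labels. Validation classes absent from
#'   training are dropped from the validation set with a warning.
#' @param model `"sctab"`, `"linear"`, or `"mlp"`.
#' @param config Matching config from [sctab_config()] etc.
#' @param augmentation Optional `augmentation_vectors` set
#'   (see [compute_augmentation_vectors()]); used when
#'   `config$augment_training_data` is `TRUE`.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param verbose Print per-epoch progress.
#' @return A `sctab_fit`: parameters, batch-norm state, config, `classes`,
#'   `genes`, per-epoch `history` data.frame, and `best_epoch`.
#' @export
train_classifier <- function(train, val, model = c("sctab", "linear", "mlp"),
                             config = NULL, augmentation = NULL, seed = 1L,
                             verbose = FALSE) {
  model <- match.arg(model)
  if (is.null(config)) {
    config <- switch(model, sctab = sctab_config(), linear = linear_config(),
                     mlp = mlp_config())
  }
  classes <- sort(unique(as.character(train$obs$cell_type)))
  if (length(classes) < 2L) stop("training data contains a single class; nothing to learn")
  if ("donor_id" %in% names(train$obs) && "donor_id" %in% names(val$obs)) {
    overlap <- intersect(unique(train$obs$donor_id), unique(val$obs$donor_id))
    if (length(overlap)) stop("train and val share donors: ", paste(overlap, collapse = ", "))
  }
  y_tr <- match(as.character(train$obs$cell_type), classes)
  keep_val <- as.character(val$obs$cell_type) %in% classes
  if (!all(keep_val)) {
    warning(sum(!keep_val), " validation cell(s) with classes absent from training dropped")
    val <- subset_cells(val, keep_val)
  }
  y_val <- match(as.character(val$obs$cell_type), classes)

  Xtr <- .as_dense_normalized(train)
  Xval <- .as_dense_normalized(val)
  n <- nrow(Xtr)
  G <- ncol(Xtr)
  C <- length(classes)
  w <- class_weights(train$obs$cell_type)[classes]

  use_aug <- isTRUE(config$augment_training_data)
  if (use_aug && is.null(augmentation)) {
    stop("config$augment_training_data is TRUE but no augmentation vectors supplied")
  }
  V <- if (use_aug) augmentation$vectors else NULL

  set.seed(seed)
  params <- switch(model,
                   sctab = .sctab_init(config, G, C),
                   linear = .linear_init(config, G, C),
                   mlp = .mlp_init(config, G, C))
  fwd <- switch(model, sctab = .sctab_fwd, linear = .linear_fwd, mlp = .mlp_fwd)
  state <- new.env()
  opt <- .adamw_init(params)

  batch <- min(config$batch_size, n)
  history <- data.frame()
  best_f1 <- -Inf; best_epoch <- 0L; best_params <- params
  best_state <- as.list(state); wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate * config$lr_decay^(epoch - 1L)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch)
    ep_loss <- 0; ep_n <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + batch - 1L, n)]
      xb <- Xtr[idx, , drop = FALSE]
      if (use_aug) {
        vi <- sample.int(nrow(V), length(idx), replace = TRUE)
        sg <- sample(c(-1, 1), length(idx), replace = TRUE)
        xb <- pmin(pmax(xb + V[vi, , drop = FALSE] * sg, 0), 9)
      }
      yb <- y_tr[idx]
      out <- fwd(xb, params, config, state, training = TRUE)
      ce <- .wce_fwd_bwd(out$logits, yb, w)
      loss <- ce$loss
      gr <- new.env()
      if (model == "sctab") {
        loss <- loss + config$lambda_sparse * mean(-out$mask * log(out$mask + 1e-15))
        .sctab_bwd(ce$dlogits, .sparse_grad(out$mask, config$lambda_sparse),
                   out, params, config, gr)
      } else if (model == "linear") {
        .linear_bwd(ce$dlogits, out, params, gr)
      } else {
        .mlp_bwd(ce$dlogits, out, params, config, gr)
      }
      upd <- .adamw_step(params, as.list(gr), opt, lr, config$weight_decay)
      params <- upd$params; opt <- upd$opt
      ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
    }

    ev <- .evaluate_split(Xval, y_val, params, fwd, config, state, w)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / ep_n,
      val_loss = ev$loss, val_macro_f1 = ev$macro_f1))
    if (verbose) {
      message(sprintf("epoch %d lr=%.5f train_loss=%.4f val_loss=%.4f val_f1=%.4f",
                      epoch, lr, ep_loss / ep_n, ev$loss, ev$macro_f1))
    }
    if (ev$macro_f1 > best_f1 + config$min_delta) {
      best_f1 <- ev$macro_f1; best_epoch <- epoch
      best_params <- params; best_state <- as.list(state); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  state_out <- new.env()
  for (k in names(best_state)) state_out[[k]] <- best_state[[k]]
  structure(list(model = model, params = best_params, state = state_out,
                 config = config, classes = classes, genes = train$genes,
                 history = history, best_epoch = best_epoch,
                 best_val_macro_f1 = best_f1, seed = seed),
            class = "sctab_fit")
}

.evaluate_split <- function(X, y, params, fwd, config, state, w, batch = 4096L) {
  n <- nrow(X)
  loss_sum <- 0; preds <- integer(n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    out <- fwd(X[idx, , drop = FALSE], params, config, state, training = FALSE)
    ce <- .wce_fwd_bwd(out$logits, y[idx], w)
    loss_sum <- loss_sum + ce$loss * length(idx)
    preds[idx] <- max.col(out$logits, ties.method = "first")
  }
  list(loss = loss_sum / n, macro_f1 = .macro_f1(preds, y, length(w)))
}

#' @export
print.sctab_fit <- function(x, ...) {
  cat(sprintf("sctab_fit [%s]: %d classes, %d genes, best epoch %d (val macro F1 %.4f)\n",
              x$model, length(x$classes), length(x$genes), x$best_epoch,
              x$best_val_macro_f1))
  invisible(x)
}

#' Predict cell types
#'
#' Evaluation-mode prediction: deterministic, uses batch-norm running
#' statistics, and is invariant to how cells are partitioned into batches.
#' Ties in the class probabilities are broken by the lowest class index.
#'
#' @param object A `sctab_fit`.
#' @param corpus A [cell_corpus()] (raw or normalized) or a raw count matrix.
#' @param batch_size Evaluation batch size.
#' @param return_mask Also return the per-cell feature-attention mask
#'   (attention model only).
#' @param ... Unused.
#' @return List with `label` (character), `probs` (cells x classes matrix),
#'   and optionally `mask`.
#' @export
predict.sctab_fit <- function(object, corpus, batch_size = 4096L,
                              return_mask = FALSE, ...) {
  if (is.matrix(corpus) || inherits(corpus, "Matrix")) {
    corpus <- cell_corpus(corpus,
                          data.frame(cell_id = paste0("cell", seq_len(nrow(corpus))),
                                     cell_type = NA_character_,
                                     stringsAsFactors = FALSE),
                          genes = if (is.null(colnames(corpus))) object$genes else colnames(corpus))
  }
  if (!identical(corpus$genes, object$genes)) {
    if (corpus$layer != "raw") stop("gene alignment requires a raw-layer corpus")
    corpus <- align_genes(corpus, object$genes)
  }
  X <- .as_dense_normalized(corpus)
  n <- nrow(X)
  if (!n) return(list(label = character(0),
                      probs = matrix(0, 0, length(object$classes),
                                     dimnames = list(NULL, object$classes))))
  fwd <- switch(object$model, sctab = .sctab_fwd, linear = .linear_fwd, mlp = .mlp_fwd)
  probs <- matrix(0, n, length(object$classes))
  masks <- if (return_mask && object$model == "sctab") matrix(0, n, length(object$genes)) else NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out <- fwd(X[idx, , drop = FALSE], object$params, object$config, object$state,
               training = FALSE)
    probs[idx, ] <- .softmax_rows(out$logits)
    if (!is.null(masks)) masks[idx, ] <- out$mask
  }
  colnames(probs) <- object$classes
  res <- list(label = object$classes[max.col(probs, ties.method = "first")],
              probs = probs)
  if (!is.null(masks)) {
    colnames(masks) <- object$genes
    res$mask <- masks
  }
  res
}

#' Single forward pass of the attention model
#'
#' Normalizes a raw-count batch, applies input batch normalization, runs the
#' feature transformer twice (unmasked to derive the attention mask via
#' 1.5-entmax, then on the masked input), and returns logits, the feature
#' mask (rows on the probability simplex), and the decision embedding.
#'
#' @param fit A `sctab_fit` with `model == "sctab"`.
#' @param x Raw count matrix (cells x genes, training gene order).
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return List with `logits`, `mask`, `embedding`.
#' @export
sctab_forward <- function(fit, x, training = FALSE) {
  stopifnot(inherits(fit, "sctab_fit"), fit$model == "sctab")
  xn <- lognorm_counts(as.matrix(x))
  out <- .sctab_fwd(xn, fit$params, fit$config, fit$state, training = training)
  out[c("logits", "mask", "embedding")]
}

#' Feature transformer (stand-alone)
#'
#' Runs a stack of GLU blocks (fully connected, ghost batch normalization
#' over `virtual_batch_size` rows, gated linear unit) with sqrt(0.5)-scaled
#' skip connections between consecutive blocks. Exposed mainly for
#' inspection and testing; the classifier calls it internally.
#'
#' @param x Input batch.
#' @param params Flat parameter list containing blocks named by `prefixes`.
#' @param prefixes Character vector of block prefixes in order.
#' @param virtual_batch_size Ghost batch size (`NULL` = whole batch).
#' @param training Batch vs running statistics.
#' @param state Environment holding running statistics (created if NULL).
#' @return Output matrix (batch x units).
#' @export
feature_transformer <- function(x, params, prefixes, virtual_batch_size = NULL,
                                training = TRUE, state = NULL) {
  if (is.null(state)) state <- new.env()
  .ft_fwd(x, params, prefixes, state, "@fx", virtual_batch_size, training, 0.1)$out
}

#' Rank genes by feature attention per cell type
#'
#' For each cell type, genes are ranked by the mean attention-mask value
#' over that type's cells; the top `top_k` genes are returned.
#'
#' @param masks cells x genes attention-mask matrix (e.g. from
#'   `predict(fit, corpus, return_mask = TRUE)$mask`).
#' @param labels Cell-type label per row of `masks`.
#' @param top_k Number of genes to keep per type (default 200).
#' @return Named list: cell type -> character vector of `top_k` gene IDs.
#' @export
gene_ranking <- function(masks, labels, top_k = 200L) {
  stopifnot(nrow(masks) == length(labels))
  if (top_k > ncol(masks)) stop("top_k exceeds the number of genes")
  genes <- colnames(masks)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(masks)))
  out <- list()
  for (ct in sort(unique(as.character(labels)))) {
    mu <- colMeans(masks[labels == ct, , drop = FALSE])
    out[[ct]] <- genes[order(mu, decreasing = TRUE)[seq_len(top_k)]]
  }
  out
}

#' Save / load a fitted classifier
#'
#' Single-file archive holding parameters, config, gene vocabulary, class
#' list, and normalization statistics.
#' @param fit A `sctab_fit`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  fit$state <- as.list(fit$state)
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  st <- new.env()
  for (k in names(fit$state)) st[[k]] <- fit$state[[k]]
  fit$state <- st
  fit
}
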