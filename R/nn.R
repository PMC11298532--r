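# Minimal reverse-mode neural-network primitives used by the classifiers.
# Parameters live in flat named lists of arrays; gradients are accumulated in
# an environment under the same names; batch-norm running statistics live in
# a separate mutable state environment (they are not optimized).

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.add_grad <- function(gr, name, value) {
  if (is.null(gr[[name]])) gr[[name]] <- value else gr[[name]] <- gr[[name]] + value
  invisible(NULL)
}

.scale_cols <- function(x, g) x * rep(g, each = nrow(x))
.shift_cols <- function(x, b) x + rep(b, each = nrow(x))

# ---- batch normalization with ghost (virtual) batches ----------------------
# Training statistics are computed per virtual batch of `vbs` rows (the final
# partial group is normalized on its own); evaluation uses running statistics
# accumulated with exponential momentum.

.bn_state_init <- function(state, key, k) {
  if (is.null(state[[key]])) state[[key]] <- list(mean = numeric(k), var = rep(1, k))
}

.gbn_fwd <- function(x, gamma, beta, state, key, vbs, training, momentum = 0.1, eps = 1e-5) {
  k <- ncol(x)
  .bn_state_init(state, key, k)
  if (!training) {
    rs <- state[[key]]
    xhat <- .scale_cols(.shift_cols(x, -rs$mean), 1 / sqrt(rs$var + eps))
    out <- .shift_cols(.scale_cols(xhat, gamma), beta)
    return(list(out = out, cache = NULL))
  }
  n <- nrow(x)
  if (is.null(vbs) || vbs >= n) vbs <- n
  starts <- seq(1L, n, by = vbs)
  xhat <- matrix(0, n, k)
  istd_g <- vector("list", length(starts))
  groups <- vector("list", length(starts))
  for (gi in seq_along(starts)) {
    idx <- starts[gi]:min(starts[gi] + vbs - 1L, n)
    xg <- x[idx, , drop = FALSE]
    mu <- colMeans(xg)
    ctr <- .shift_cols(xg, -mu)
    v <- colMeans(ctr * ctr)
    istd <- 1 / sqrt(v + eps)
    xhat[idx, ] <- .scale_cols(ctr, istd)
    istd_g[[gi]] <- istd
    groups[[gi]] <- idx
    rs <- state[[key]]
    state[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                         var = (1 - momentum) * rs$var + momentum * v)
  }
  out <- .shift_cols(.scale_cols(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, istd = istd_g, groups = groups, gamma = gamma))
}

.gbn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- .scale_cols(dout, cache$gamma)
  dx <- matrix(0, nrow(dout), ncol(dout))
  for (gi in seq_along(cache$groups)) {
    idx <- cache$groups[[gi]]
    dxh <- dxhat[idx, , drop = FALSE]
    xh <- xhat[idx, , drop = FALSE]
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xh)
    dx[idx, ] <- .scale_cols(dxh - .shift_cols(.scale_cols(xh, m2), m1), cache$istd[[gi]])
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- GLU block: FC (no bias) -> ghost BN -> gated linear unit --------------

.glu_init <- function(params, prefix, in_dim, units) {
  params[[paste0(prefix, ".W")]] <- .glorot(in_dim, 2L * units)
  params[[paste0(prefix, ".gamma")]] <- rep(1, 2L * units)
  params[[paste0(prefix, ".beta")]] <- rep(0, 2L * units)
  params
}

.glu_fwd <- function(x, params, prefix, state, state_key, vbs, training, momentum) {
  W <- params[[paste0(prefix, ".W")]]
  pre <- x %*% W
  bn <- .gbn_fwd(pre, params[[paste0(prefix, ".gamma")]], params[[paste0(prefix, ".beta")]],
                 state, state_key, vbs, training, momentum)
  u <- ncol(W) %/% 2L
  a <- bn$out[, seq_len(u), drop = FALSE]
  b <- bn$out[, u + seq_len(u), drop = FALSE]
  sig <- 1 / (1 + exp(-b))
  list(out = a * sig,
       cache = list(x = x, bn = bn$cache, a = a, sig = sig, prefix = prefix))
}

.glu_bwd <- function(dout, cache, params, gr) {
  a <- cache$a; sig <- cache$sig
  da <- dout * sig
  db <- dout * a * sig * (1 - sig)
  bnb <- .gbn_bwd(cbind(da, db), cache$bn)
  prefix <- cache$prefix
  .add_grad(gr, paste0(prefix, ".gamma"), bnb$dgamma)
  .add_grad(gr, paste0(prefix, ".beta"), bnb$dbeta)
  W <- params[[paste0(prefix, ".W")]]
  .add_grad(gr, paste0(prefix, ".W"), crossprod(cache$x, bnb$dx))
  bnb$dx %*% t(W)
}

# ---- feature transformer: shared + step-specific GLU blocks with skips -----
# Consecutive blocks are connected by skip connections scaled by sqrt(0.5);
# the first block (which changes dimensionality) has no skip.

.ft_fwd <- function(x, params, prefixes, state, key_suffix, vbs, training, momentum) {
  caches <- vector("list", length(prefixes))
  h <- NULL
  for (i in seq_along(prefixes)) {
    inp <- if (i == 1L) x else h
    g <- .glu_fwd(inp, params, prefixes[i], state,
                  paste0(prefixes[i], key_suffix), vbs, training, momentum)
    caches[[i]] <- g$cache
    h <- if (i == 1L) g$out else (g$out + h) * sqrt(0.5)
  }
  list(out = h, caches = caches)
}

.ft_bwd <- function(dh, caches, params, gr) {
  n <- length(caches)
  for (i in rev(seq_len(n))) {
    if (i > 1L) {
      d_in <- dh * sqrt(0.5)
      dx <- .glu_bwd(d_in, caches[[i]], params, gr)
      dh <- d_in + dx
    } else {
      dh <- .glu_bwd(dh, caches[[i]], params, gr)
    }
  }
  dh
}

# ---- AdamW ------------------------------------------------------------------
# Adam with decoupled weight decay; decay is not applied to batch-norm
# parameters or biases.

.adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamw_step <- function(params, grads, opt, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    decay_this <- weight_decay > 0 && grepl("\\.W$", nm)
    if (decay_this) step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

.softmax_rows <- function(logits) {
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

# Weighted cross-entropy over a batch: per-sample weight is the class weight
# of its true label; loss is the plain mean over the batch.
.wce_fwd_bwd <- function(logits, y, w_class) {
  n <- nrow(logits)
  p <- .softmax_rows(logits)
  w <- w_class[y]
  ll <- log(p[cbind(seq_len(n), y)] + 1e-30)
  loss <- mean(-w * ll)
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits * (w / n)
  list(loss = loss, dlogits = dlogits)
}
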