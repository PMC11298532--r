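#' Configuration for donor-difference augmentation vectors
#'
#' Defaults are the full-scale settings: subsample 500,000 training cells
#' evenly across cell types, zero out difference entries in [-0.25, 0.25],
#' clamp to [-1.5, 1.5], k-means with 50 clusters keeping clusters with more
#' than 2000 vectors, and sample 5000 vectors. `scale` shrinks all size
#' parameters proportionally for small corpora (e.g. `scale = 0.01`).
#'
#' @param n_subsample Cells subsampled (evenly across types) before centroids.
#' @param zero_band Half-width of the band zeroed for sparsity (0.25).
#' @param vector_clamp Symmetric clamp on vector entries (1.5).
#' @param n_clusters k-means cluster count (50).
#' @param min_cluster_size Keep vectors only from clusters larger than this (2000).
#' @param n_vectors Number of augmentation vectors sampled (5000).
#' @param expr_clamp Interval the augmented expression is clamped to ([0, 9]).
#' @param min_cells Minimum cells per (cell type, donor) pair for a centroid.
#' @param scale Proportional scale factor applied to all size parameters.
#' @param seed Integer seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(n_subsample = 500000L, zero_band = 0.25,
                                vector_clamp = 1.5, n_clusters = 50L,
                                min_cluster_size = 2000L, n_vectors = 5000L,
                                expr_clamp = c(0, 9), min_cells = 10L,
                                scale = 1, seed = 1L) {
  stopifnot(zero_band < vector_clamp, expr_clamp[1] >= 0, scale > 0)
  if (scale != 1) {
    n_subsample <- max(100L, as.integer(round(n_subsample * scale)))
    n_clusters <- max(2L, as.integer(round(n_clusters * scale * 10)))
    min_cluster_size <- max(2L, as.integer(round(min_cluster_size * scale)))
    n_vectors <- max(10L, as.integer(round(n_vectors * scale)))
  }
  structure(list(n_subsample = n_subsample, zero_band = zero_band,
                 vector_clamp = vector_clamp, n_clusters = n_clusters,
                 min_cluster_size = min_cluster_size, n_vectors = n_vectors,
                 expr_clamp = expr_clamp, min_cells = min_cells, seed = seed),
            class = "augmentation_config")
}

#' Compute donor-difference augmentation vectors
#'
#' Implements the six-step procedure on the training split (only): (1)
#' seeded subsample with equal per-type quotas; (2) mean centroids of
#' normalized expression per (cell type, donor) with at least
#' `min_cells` support; (3) all ordered donor-pair centroid differences
#' within each cell type; (4) entries in `(-zero_band, zero_band)` set to
#' zero; (5) entries clamped to `[-vector_clamp, vector_clamp]`; (6)
#' k-means over the difference vectors, keeping vectors from clusters
#' larger than `min_cluster_size` (to favour cell-type-independent donor
#' signatures) and sampling `n_vectors` uniformly without replacement.
#'
#' @param corpus Normalized-layer [cell_corpus()] of the training split (a
#'   raw corpus is normalized on the fly).
#' @param config An [augmentation_config()].
#' @return An `augmentation_vectors` object: `vectors` (n x genes),
#'   `provenance` data.frame (cell_type, donor_a, donor_b, cluster).
#' @export
compute_augmentation_vectors <- function(corpus, config = augmentation_config()) {
  stopifnot(inherits(corpus, "cell_corpus"), inherits(config, "augmentation_config"))
  if (corpus$layer == "raw") corpus <- normalize_corpus(corpus)
  obs <- corpus$obs
  if (!"donor_id" %in% names(obs)) stop("corpus obs must carry donor_id")

  set.seed(config$seed)

  # step 1: even subsample across cell types
  types <- unique(obs$cell_type)
  quota <- max(1L, floor(config$n_subsample / length(types)))
  take <- integer(0)
  for (ct in types) {
    pool <- which(obs$cell_type == ct)
    take <- c(take, if (length(pool) <= quota) pool else sample(pool, quota))
  }
  take <- sort(take)
  X <- as.matrix(corpus$counts[take, , drop = FALSE])
  sub_obs <- obs[take, , drop = FALSE]

  # step 2: centroids per (cell type, donor) with enough support
  key <- paste(sub_obs$cell_type, sub_obs$donor_id, sep = "\r")
  counts <- table(key)
  keep_keys <- names(counts)[counts >= config$min_cells]
  in_keep <- key %in% keep_keys
  cs <- rowsum(X[in_keep, , drop = FALSE], key[in_keep])
  cent <- cs / as.vector(counts[rownames(cs)])
  meta <- do.call(rbind, strsplit(rownames(cent), "\r", fixed = TRUE))

  # step 3: ordered donor-pair differences within each cell type
  diffs <- list(); prov <- list()
  for (ct in unique(meta[, 1])) {
    rows <- which(meta[, 1] == ct)
    if (length(rows) < 2L) next
    for (i in rows) for (j in rows) {
      if (i == j) next
      diffs[[length(diffs) + 1L]] <- cent[i, ] - cent[j, ]
      prov[[length(prov) + 1L]] <- c(ct, meta[i, 2], meta[j, 2])
    }
  }
  if (!length(diffs)) stop("no two donors share a cell type; cannot build augmentation vectors")
  D <- do.call(rbind, diffs)
  prov <- as.data.frame(do.call(rbind, prov), stringsAsFactors = FALSE)
  names(prov) <- c("cell_type", "donor_a", "donor_b")

  # steps 4-5: band zeroing then clamping
  D[abs(D) <= config$zero_band] <- 0
  D[D > config$vector_clamp] <- config$vector_clamp
  D[D < -config$vector_clamp] <- -config$vector_clamp

  # step 6: keep vectors from large k-means clusters, sample n_vectors
  k <- min(config$n_clusters, max(1L, nrow(D) - 1L))
  km <- suppressWarnings(stats::kmeans(D, centers = k, nstart = 10, iter.max = 100))
  sizes <- tabulate(km$cluster, nbins = k)
  big <- which(sizes > config$min_cluster_size)
  if (!length(big)) {
    stop("all k-means clusters have <= ", config$min_cluster_size,
         " vectors; reduce min_cluster_size (or the config scale)")
  }
  pool <- which(km$cluster %in% big)
  sel <- if (length(pool) > config$n_vectors) sort(sample(pool, config$n_vectors)) else pool
  prov$cluster <- km$cluster
  structure(list(vectors = D[sel, , drop = FALSE],
                 provenance = prov[sel, , drop = FALSE],
                 genes = corpus$genes, config = config),
            class = "augmentation_vectors")
}

#' @export
print.augmentation_vectors <- function(x, ...) {
  cat(sprintf("augmentation_vectors: %d vectors x %d genes (%.1f%% nonzero)\n",
              nrow(x$vectors), ncol(x$vectors), 100 * mean(x$vectors != 0)))
  invisible(x)
}

#' Apply an augmentation vector to normalized expression
#'
#' `x' = clamp(x +/- v, 0, 9)`: a vector is drawn uniformly from the set,
#' the sign uniformly from {+, -}, and the result clamped to the expression
#' interval. Used per observation during training only, never at evaluation.
#'
#' @param x Normalized expression row (or cells x genes matrix; each row is
#'   augmented independently).
#' @param vectors An `augmentation_vectors` set.
#' @return Augmented expression of the same shape.
#' @export
augment_expression <- function(x, vectors) {
  V <- vectors$vectors
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(xm) != ncol(V)) stop("gene dimension mismatch: x has ", ncol(xm),
                                ", vectors have ", ncol(V))
  cl <- vectors$config$expr_clamp
  vi <- sample.int(nrow(V), nrow(xm), replace = TRUE)
  sg <- sample(c(-1, 1), nrow(xm), replace = TRUE)
  out <- pmin(pmax(xm + V[vi, , drop = FALSE] * sg, cl[1]), cl[2])
  if (vec) drop(out) else out
}

#' Variance explained by cell type and donor
#'
#' Ordinary least squares of every gene's normalized expression on an
#' intercept plus one-hot cell type and one-hot donor (drop-first encoding
#' to keep the design full rank), returning the uniform average over genes
#' of the per-gene R squared. Comparing the score on raw versus augmented
#' data quantifies how much of the variance structure augmentation
#' preserves.
#'
#' @param corpus Normalized-layer [cell_corpus()] (raw is normalized first).
#' @return List with `r2` (scalar) and `design` (description string).
#' @export
variance_r2 <- function(corpus) {
  stopifnot(inherits(corpus, "cell_corpus"))
  if (corpus$layer == "raw") corpus <- normalize_corpus(corpus)
  obs <- corpus$obs
  if (length(unique(obs$cell_type)) < 2L || length(unique(obs$donor_id)) < 2L) {
    stop("need at least 2 cell types and 2 donors")
  }
  design <- stats::model.matrix(~ factor(cell_type) + factor(donor_id), data = obs)
  Y <- as.matrix(corpus$counts)
  qrd <- qr(design)
  fitted <- qr.fitted(qrd, Y)
  res <- Y - fitted
  ss_res <- colSums(res^2)
  mu <- colMeans(Y)
  ss_tot <- colSums(.shift_cols(Y, -mu)^2)
  r2 <- ifelse(ss_tot < 1e-12, ifelse(ss_res < 1e-12, 1, 0), 1 - ss_res / ss_tot)
  list(r2 = mean(r2),
       design = "y ~ 1 + onehot(cell_type) + onehot(donor_id), drop-first encoding")
}

#' Apply augmentation once to a whole corpus
#'
#' Convenience for the variance diagnostic: every cell is augmented exactly
#' once with a seeded draw; returns a normalized-layer corpus.
#' @param corpus A [cell_corpus()].
#' @param vectors An `augmentation_vectors` set.
#' @param seed Integer seed.
#' @export
augment_corpus <- function(corpus, vectors, seed = 1L) {
  if (corpus$layer == "raw") corpus <- normalize_corpus(corpus)
  X <- as.matrix(corpus$counts)
  Xa <- .with_seed(seed, augment_expression(X, vectors))
  out <- corpus
  out$counts <- Xa
  out
}
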