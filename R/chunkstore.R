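#' Chunked on-disk corpus store
#'
#' Training on bigger-than-memory corpora needs block reads: individual rows
#' are too small for efficient random access, so consecutive blocks of cells
#' are stored together, loaded whole, and shuffled in memory. The store holds
#' fixed-size row chunks as Parquet files plus a JSON manifest.
#'
#' @param corpus A [cell_corpus()].
#' @param path Store directory (created; must not already contain a store).
#' @param chunk_size Rows per chunk.
#' @return The store path, invisibly usable with [open_chunk_store()].
#' @export
write_chunk_store <- function(corpus, path, chunk_size = 1024L) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for the Parquet chunk store")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(corpus$counts)
  starts <- seq(1L, n, by = chunk_size)
  chunk_files <- character(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + chunk_size - 1L, n)
    block <- as.matrix(corpus$counts[idx, , drop = FALSE])
    df <- as.data.frame(block)
    names(df) <- corpus$genes
    df <- cbind(corpus$obs[idx, , drop = FALSE], df)
    chunk_files[i] <- sprintf("chunk-%05d.parquet", i)
    arrow::write_parquet(df, file.path(path, chunk_files[i]))
  }
  manifest <- list(n_rows = n, chunk_size = chunk_size,
                   n_chunks = length(starts), chunks = chunk_files,
                   genes = corpus$genes, layer = corpus$layer,
                   obs_columns = names(corpus$obs))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chunk_store
#' @export
open_chunk_store <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no chunk store manifest at ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  structure(list(path = path, manifest = manifest), class = "chunk_store")
}

.read_chunk <- function(store, i) {
  f <- file.path(store$path, store$manifest$chunks[i])
  df <- tryCatch(as.data.frame(arrow::read_parquet(f)),
                 error = function(e) stop("corrupted chunk '", basename(f), "': ",
                                          conditionMessage(e), call. = FALSE))
  df
}

#' Stream shuffled batches from a chunk store
#'
#' Reads whole chunks sequentially, shuffles rows within a buffer of at
#' least `shuffle_buffer` rows, and yields batches of `batch_size`. One
#' epoch yields every stored row exactly once; the last batch may be
#' smaller. Deterministic given `seed`.
#'
#' @param store A `chunk_store` from [open_chunk_store()].
#' @param batch_size Rows per batch.
#' @param shuffle_buffer Minimum rows in the shuffle buffer.
#' @param seed Integer seed.
#' @return An iterator: list with `next_batch()` (returns a list with `x`,
#'   the expression matrix, and `obs`, or `NULL` at end of epoch) and
#'   `reset()`.
#' @export
stream_batches <- function(store, batch_size, shuffle_buffer = 4L * batch_size, seed = 1L) {
  stopifnot(inherits(store, "chunk_store"))
  genes <- store$manifest$genes
  obs_cols <- store$manifest$obs_columns
  n_chunks <- store$manifest$n_chunks
  if (store$manifest$chunk_size < batch_size) {
    # still correct (buffer accumulates), but warn about the contract
    warning("chunk_size < batch_size; batches span multiple chunks")
  }

  env <- new.env()
  reset <- function() {
    env$rng <- .with_seed(seed, get(".Random.seed", globalenv()))
    env$chunk_i <- 0L
    env$buffer <- NULL
    env$done <- FALSE
  }
  draw <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$rng, globalenv())
    on.exit({
      env$rng <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  fill_buffer <- function(target) {
    while ((is.null(env$buffer) || nrow(env$buffer) < target) && env$chunk_i < n_chunks) {
      env$chunk_i <- env$chunk_i + 1L
      chunk <- .read_chunk(store, env$chunk_i)
      env$buffer <- if (is.null(env$buffer)) chunk else rbind(env$buffer, chunk)
    }
    if (!is.null(env$buffer) && nrow(env$buffer) > 1L) {
      perm <- draw(sample.int(nrow(env$buffer)))
      env$buffer <- env$buffer[perm, , drop = FALSE]
    }
  }
  next_batch <- function() {
    if (is.null(env$buffer) || nrow(env$buffer) < batch_size) {
      fill_buffer(max(shuffle_buffer, batch_size))
    }
    if (is.null(env$buffer) || nrow(env$buffer) == 0L) return(NULL)
    take <- min(batch_size, nrow(env$buffer))
    rows <- env$buffer[seq_len(take), , drop = FALSE]
    env$buffer <- env$buffer[-seq_len(take), , drop = FALSE]
    x <- as.matrix(rows[, genes, drop = FALSE])
    list(x = x, obs = rows[, obs_cols, drop = FALSE])
  }
  reset()
  list(next_batch = next_batch, reset = reset)
}
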