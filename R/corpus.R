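#' Cell-by-gene corpus container
#'
#' Bundles an expression matrix over a fixed, ordered gene vocabulary with
#' per-cell metadata. The raw layer holds non-negative integer counts; the
#' normalized layer holds size-factor (10,000) + log1p transformed values.
#'
#' @param counts cells x genes matrix (base matrix or `Matrix::dgCMatrix`).
#' @param obs data.frame with one row per cell; must contain `cell_id` and
#'   `cell_type`; typically also `donor_id`, `assay`, `dataset_id`,
#'   `is_primary`, `tissue`.
#' @param genes Character vector of gene IDs, one per column.
#' @param layer `"raw"` or `"normalized"`.
#' @return An object of class `cell_corpus`.
#' @export
cell_corpus <- function(counts, obs, genes = colnames(counts), layer = "raw") {
  layer <- match.arg(layer, c("raw", "normalized"))
  stopifnot(is.data.frame(obs), nrow(obs) == nrow(counts))
  if (is.null(genes)) stop("gene vocabulary required (genes or colnames(counts))")
  stopifnot(length(genes) == ncol(counts))
  if (!all(c("cell_id", "cell_type") %in% names(obs))) {
    stop("obs must contain cell_id and cell_type columns")
  }
  if (anyDuplicated(obs$cell_id)) stop("cell_id values must be unique")
  if (layer == "raw") {
    v <- if (inherits(counts, "sparseMatrix")) counts@x else counts
    if (length(v) && (min(v) < 0)) stop("raw layer contains negative entries")
    if (length(v) && any(v != floor(v))) stop("raw layer contains non-integer entries")
  }
  colnames(counts) <- genes
  rownames(counts) <- obs$cell_id
  structure(list(counts = counts, obs = obs, genes = as.character(genes), layer = layer),
            class = "cell_corpus")
}

#' @export
print.cell_corpus <- function(x, ...) {
  cat(sprintf("cell_corpus: %d cells x %d genes [%s layer], %d cell types, %d donors\n",
              nrow(x$counts), length(x$genes), x$layer,
              length(unique(x$obs$cell_type)),
              if ("donor_id" %in% names(x$obs)) length(unique(x$obs$donor_id)) else NA_integer_))
  invisible(x)
}

#' @export
dim.cell_corpus <- function(x) dim(x$counts)

#' Subset a corpus by cell index
#' @param corpus A [cell_corpus()].
#' @param idx Integer or logical index over cells.
#' @return A `cell_corpus` with the selected cells.
#' @export
subset_cells <- function(corpus, idx) {
  cell_corpus(corpus$counts[idx, , drop = FALSE],
              corpus$obs[idx, , drop = FALSE],
              genes = corpus$genes, layer = corpus$layer)
}

#' Size-factor + log1p normalization
#'
#' Scales each cell to 10,000 total counts and applies `log1p`:
#' `x -> log1p(10000 * x / sum(x))`. Cells with zero total count stay
#' all-zero and trigger a warning. Refuses to run on an already-normalized
#' layer so normalization is never silently applied twice.
#'
#' @param corpus A raw-layer [cell_corpus()].
#' @param size_factor Target total per cell (default 10,000).
#' @return A normalized-layer `cell_corpus`.
#' @export
normalize_corpus <- function(corpus, size_factor = 1e4) {
  stopifnot(inherits(corpus, "cell_corpus"))
  if (corpus$layer == "normalized") {
    stop("corpus is already normalized; refusing to normalize twice")
  }
  m <- lognorm_counts(corpus$counts, size_factor = size_factor)
  out <- corpus
  out$counts <- m
  out$layer <- "normalized"
  class(out) <- "cell_corpus"
  out
}

#' Low-level count normalization
#' @param m cells x genes count matrix (dense or sparse).
#' @param size_factor Target total per cell.
#' @return Matrix of the same shape and storage class, log1p-normalized.
#' @export
lognorm_counts <- function(m, size_factor = 1e4) {
  v <- if (inherits(m, "sparseMatrix")) m@x else m
  if (length(v) && min(v) < 0) stop("negative entries in count matrix")
  totals <- Matrix::rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total count left as all-zero rows")
    totals[zero] <- 1
  }
  if (inherits(m, "sparseMatrix")) {
    scaled <- Matrix::Diagonal(x = size_factor / totals) %*% m
    scaled@x <- log1p(scaled@x)
    methods::as(scaled, "CsparseMatrix")
  } else {
    log1p(m * (size_factor / totals))
  }
}

#' The 10x-based assay whitelist used by the corpus filter
#' @export
tenx_assays <- function() {
  c("10x 5' v2", "10x 3' v3", "10x 3' v2", "10x 5' v1", "10x 3' v1",
    "10x 3' transcription profiling", "10x 5' transcription profiling")
}

#' Filter a corpus for classifier training
#'
#' Applies, in order: (1) keep primary data only; (2) keep 10x-based assays;
#' (3) keep cells whose label is a subtype of the root ("native cell") term;
#' (4) drop cell types with fewer than `min_cells` unique cells; (5) drop
#' cell types observed in fewer than `min_donors` donors; (6) drop cell
#' types with fewer than `min_ancestors` transitive ancestors in the
#' ontology. Type-level criteria (4-6) drop every cell of a failing type and
#' are re-applied until a fixed point. Cells whose label is absent from the
#' ontology are dropped and reported. Thresholds are dataset dependent and
#' configurable.
#'
#' @param corpus Raw [cell_corpus()] whose `obs` carries `is_primary`,
#'   `assay`, `donor_id`.
#' @param graph A [cell_ontology()].
#' @param min_cells Minimum unique cells per type (default 5000).
#' @param min_donors Minimum donors per type (default 30).
#' @param min_ancestors Minimum transitive ancestors per type (default 7).
#' @param assays Assay whitelist (default [tenx_assays()]).
#' @return List with `corpus` (filtered) and `report` (a `filter_report`
#'   data.frame of per-criterion removal counts plus survivor summaries).
#' @export
filter_corpus <- function(corpus, graph,
                          min_cells = 5000L, min_donors = 30L,
                          min_ancestors = 7L, assays = tenx_assays()) {
  stopifnot(inherits(corpus, "cell_corpus"), inherits(graph, "cell_ontology"))
  obs <- corpus$obs
  n0 <- nrow(obs)
  keep <- rep(TRUE, n0)
  removed <- c(unknown_term = 0L, not_primary = 0L, assay = 0L, not_native = 0L,
               min_cells = 0L, min_donors = 0L, min_ancestors = 0L)

  unknown <- !(obs$cell_type %in% graph$terms)
  removed["unknown_term"] <- sum(unknown & keep)
  keep[unknown] <- FALSE

  if ("is_primary" %in% names(obs)) {
    drop <- !as.logical(obs$is_primary)
    removed["not_primary"] <- sum(drop & keep)
    keep[drop] <- FALSE
  }
  if ("assay" %in% names(obs)) {
    drop <- !(obs$assay %in% assays)
    removed["assay"] <- sum(drop & keep)
    keep[drop] <- FALSE
  }

  graph <- .with_anc_cache(graph)
  types_present <- unique(obs$cell_type[keep])
  native <- vapply(types_present, function(t) is_subtype(graph, t, graph$root), logical(1))
  drop_types <- types_present[!native]
  drop <- obs$cell_type %in% drop_types
  removed["not_native"] <- sum(drop & keep)
  keep[drop] <- FALSE

  anc_counts <- vapply(unique(obs$cell_type[keep]), function(t) ancestor_count(graph, t), integer(1))

  repeat {
    changed <- FALSE
    tab <- table(obs$cell_type[keep])
    small <- names(tab)[tab < min_cells]
    if (length(small)) {
      drop <- keep & obs$cell_type %in% small
      removed["min_cells"] <- removed["min_cells"] + sum(drop)
      keep[drop] <- FALSE
      changed <- TRUE
    }
    dt <- unique(data.frame(type = obs$cell_type[keep], donor = obs$donor_id[keep]))
    dcount <- table(dt$type)
    few <- names(dcount)[dcount < min_donors]
    if (length(few)) {
      drop <- keep & obs$cell_type %in% few
      removed["min_donors"] <- removed["min_donors"] + sum(drop)
      keep[drop] <- FALSE
      changed <- TRUE
    }
    types_now <- unique(obs$cell_type[keep])
    broad <- types_now[anc_counts[types_now] < min_ancestors]
    if (length(broad)) {
      drop <- keep & obs$cell_type %in% broad
      removed["min_ancestors"] <- removed["min_ancestors"] + sum(drop)
      keep[drop] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }

  report <- structure(
    list(removed = removed,
         n_input = n0, n_surviving = sum(keep),
         surviving_types = sort(unique(obs$cell_type[keep]))),
    class = "filter_report"
  )
  if (!any(keep)) {
    stop("no cells survive filtering; removals: ",
         paste(names(removed), removed, sep = "=", collapse = ", "))
  }
  list(corpus = subset_cells(corpus, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "cells in,", x$n_surviving, "surviving\n")
  for (k in names(x$removed)) cat(sprintf("  removed by %-14s %d\n", k, x$removed[[k]]))
  cat("  surviving cell types:", length(x$surviving_types), "\n")
  invisible(x)
}

#' Donor-based train/validation/test split
#'
#' Assigns whole donors to splits so that no donor's cells leak across
#' train, validation, and test. Assignment is a seeded uniform shuffle of
#' donor IDs; split sizes are `floor(fraction * n)` for validation and test
#' with the remainder going to train, preserving the 70-15-15 intent while
#' staying deterministic at small n.
#'
#' @param donors Character vector of donor IDs (duplicates allowed; the
#'   unique set is split).
#' @param fractions Numeric length-3 vector (train, val, test), must sum to 1.
#' @param seed Integer seed.
#' @return A named character vector donor -> `"train"|"val"|"test"` with
#'   attributes `fractions`, `seed`.
#' @export
donor_split <- function(donors, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  u <- unique(as.character(donors))
  if (length(u) < 3L) stop("need at least 3 donors to split")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(u)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- .with_seed(seed, sample(u))
  assign <- rep("train", n)
  if (n_val > 0) assign[seq_len(n_val)] <- "val"
  if (n_test > 0) assign[n_val + seq_len(n_test)] <- "test"
  out <- assign
  names(out) <- perm
  out <- out[u]  # report in input order
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

# Evaluate expr under a private RNG stream, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Incremental subsampling series
#'
#' Produces nested subsets of a corpus at increasing fractions, by cell or by
#' donor. Smaller subsets are strict subsets of larger ones: the 30% subset
#' contains every cell (or donor) of the 15% subset.
#'
#' @param corpus A [cell_corpus()].
#' @param mode `"cell"` or `"donor"`.
#' @param fractions Ascending fractions in (0, 1].
#' @param seed Integer seed.
#' @return Named list of `cell_corpus` objects, one per fraction.
#' @export
subsample_corpus <- function(corpus, mode = c("cell", "donor"), fractions, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (is.unsorted(fractions, strictly = TRUE)) stop("fractions must be strictly ascending")
  out <- list()
  if (mode == "cell") {
    n <- nrow(corpus$counts)
    perm <- .with_seed(seed, sample.int(n))
    for (f in fractions) {
      take <- sort(perm[seq_len(max(1L, round(f * n)))])
      out[[sprintf("%g", f)]] <- subset_cells(corpus, take)
    }
  } else {
    donors <- unique(corpus$obs$donor_id)
    perm <- .with_seed(seed, sample(donors))
    for (f in fractions) {
      sel <- perm[seq_len(max(1L, round(f * length(donors))))]
      out[[sprintf("%g", f)]] <- subset_cells(corpus, corpus$obs$donor_id %in% sel)
    }
  }
  out
}

#' Write / read a corpus as Matrix Market + TSV
#'
#' Plain-text on-disk representation: `matrix.mtx` (raw counts, cells x
#' genes), `genes.tsv`, `obs.tsv`.
#' @param corpus A [cell_corpus()].
#' @param dir Output directory (created if missing).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- corpus$counts
  if (!inherits(m, "sparseMatrix")) m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(corpus$genes, file.path(dir, "genes.tsv"))
  utils::write.table(corpus$obs, file.path(dir, "obs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(corpus$layer, file.path(dir, "layer.txt"))
  invisible(dir)
}

#' @rdname write_corpus
#' @return `read_corpus()` returns the reconstructed [cell_corpus()].
#' @export
read_corpus <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  obs <- utils::read.table(file.path(dir, "obs.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if ("is_primary" %in% names(obs)) obs$is_primary <- as.logical(obs$is_primary)
  layer_file <- file.path(dir, "layer.txt")
  layer <- if (file.exists(layer_file)) readLines(layer_file)[1] else "raw"
  cell_corpus(m, obs, genes = genes, layer = layer)
}

#' Align a query matrix to a training gene vocabulary
#'
#' Intersects on gene IDs, zero-fills genes missing from the query, and
#' warns when fewer than 80% of the vocabulary is covered.
#'
#' @param corpus A [cell_corpus()].
#' @param vocabulary Character vector of gene IDs in training order.
#' @return A `cell_corpus` whose columns exactly match `vocabulary`.
#' @export
align_genes <- function(corpus, vocabulary) {
  shared <- intersect(vocabulary, corpus$genes)
  coverage <- length(shared) / length(vocabulary)
  if (coverage < 0.8) {
    warning(sprintf("query covers only %.1f%% of the training gene vocabulary", 100 * coverage))
  }
  n <- nrow(corpus$counts)
  out <- Matrix::Matrix(0, nrow = n, ncol = length(vocabulary), sparse = TRUE)
  colnames(out) <- vocabulary
  out[, shared] <- corpus$counts[, shared, drop = FALSE]
  cell_corpus(methods::as(out, "CsparseMatrix"), corpus$obs,
              genes = vocabulary, layer = corpus$layer)
}
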