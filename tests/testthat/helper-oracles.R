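# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written as straight-line brute force, independent of the
# package's implementation paths.

# ---- entmax oracle: brute-force support enumeration -------------------------
# Maximize p'z + H_1.5(p) over the simplex by enumerating every candidate
# support set, solving sum_{i in S} (z_i/2 - tau)^2 = 1 for tau, keeping
# feasible KKT points, and returning the candidate with the best objective.

entmax_objective <- function(p, z) {
  sum(p * z) + sum(p - p^1.5) / (1.5 * 0.5)
}

entmax15_bruteforce <- function(z) {
  d <- length(z)
  zh <- z / 2
  best_val <- -Inf
  best_p <- NULL
  for (mask in 1:(2^d - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1))) != 0L)
    k <- length(S)
    Ssum <- sum(zh[S]); Q <- sum(zh[S]^2)
    disc <- Ssum^2 - k * (Q - 1)
    if (disc < 0) next
    for (tau in c((Ssum - sqrt(disc)) / k, (Ssum + sqrt(disc)) / k)) {
      s <- zh[S] - tau
      if (any(s < -1e-12)) next           # p must be non-negative on S
      if (any(zh[-S] - tau > 1e-12) && k < d) next  # KKT: off-support scores below tau
      p <- numeric(d)
      p[S] <- pmax(s, 0)^2
      if (abs(sum(p) - 1) > 1e-9) next
      val <- entmax_objective(p, z)
      if (val > best_val) {
        best_val <- val
        best_p <- p
      }
    }
  }
  best_p
}

# ---- conventional macro F1 (flat label comparison) --------------------------

macro_f1_conventional <- function(pred, truth) {
  classes <- sort(unique(truth))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

# ---- brute-force reachability on a parent list ------------------------------

reachable_bruteforce <- function(parents, a, b) {
  # TRUE iff b is reachable from a (or a == b) following child -> parent edges
  if (a == b) return(TRUE)
  frontier <- a
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

# random rooted DAG: a tree plus optional extra edges to earlier terms
random_dag <- function(n_terms, extra_edges = 2L, seed = 1L) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n_terms))
  parents <- list()
  parents[[terms[1]]] <- character(0)
  for (i in 2:n_terms) {
    parents[[terms[i]]] <- terms[sample.int(i - 1L, 1L)]
  }
  for (e in seq_len(extra_edges)) {
    i <- sample(3:n_terms, 1L)
    cand <- setdiff(terms[seq_len(i - 1L)], parents[[terms[i]]])
    if (length(cand)) parents[[terms[i]]] <- c(parents[[terms[i]]], sample(cand, 1L))
  }
  cell_ontology(terms, parents, root = terms[1])
}

# ---- small immune ontology with real Cell Ontology IDs ----------------------
# native cell -> lymphocyte -> {T cell -> alpha-beta T cell ->
# {CD4+ ab T cell, CD8+ ab T cell}, B cell}; plus myeloid leukocyte.

immune_ontology <- function() {
  ids <- c(native = "CL:0000003", lymphocyte = "CL:0000542",
           tcell = "CL:0000084", abt = "CL:0000789",
           cd4 = "CL:0000624", cd8 = "CL:0000625",
           bcell = "CL:0000236", myeloid = "CL:0000766")
  parents <- list()
  parents[[ids["native"]]] <- character(0)
  parents[[ids["lymphocyte"]]] <- ids[["native"]]
  parents[[ids["tcell"]]] <- ids[["lymphocyte"]]
  parents[[ids["abt"]]] <- ids[["tcell"]]
  parents[[ids["cd4"]]] <- ids[["abt"]]
  parents[[ids["cd8"]]] <- ids[["abt"]]
  parents[[ids["bcell"]]] <- ids[["lymphocyte"]]
  parents[[ids["myeloid"]]] <- ids[["native"]]
  list(graph = cell_ontology(unname(ids), parents, root = ids[["native"]]),
       ids = ids)
}

# flat ontology: k leaf labels directly under one root (ontology-corrected
# scoring then reduces to conventional flat scoring)
flat_ontology <- function(labels, root = "ROOT") {
  parents <- c(stats::setNames(list(character(0)), root),
               stats::setNames(rep(list(root), length(labels)), labels))
  cell_ontology(c(root, labels), parents, root = root)
}

# ---- small corpus builders --------------------------------------------------

tiny_corpus <- function(n_cells = 60L, n_genes = 20L, n_types = 3L, n_donors = 4L,
                        seed = 1L) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
  obs <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n_cells)),
    cell_type = sample(sprintf("TYPE%d", seq_len(n_types)), n_cells, replace = TRUE),
    donor_id = sample(sprintf("d%02d", seq_len(n_donors)), n_cells, replace = TRUE),
    assay = "10x 3' v3", dataset_id = "toy", is_primary = TRUE, tissue = "toy",
    stringsAsFactors = FALSE)
  cell_corpus(counts, obs, genes = sprintf("g%03d", seq_len(n_genes)))
}

# fixtures are expensive; build each preset once per test run
.fixture_env <- new.env()
cached_fixture <- function(name) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make_fixture(name)
  .fixture_env[[name]]
}

split_fixture <- function(fx, seed = 1L) {
  sp <- donor_split(fx$corpus$obs$donor_id, seed = seed)
  out <- lapply(c(train = "train", val = "val", test = "test"), function(w)
    subset_cells(fx$corpus, sp[fx$corpus$obs$donor_id] == w))
  if (!is.null(fx$truth) && length(fx$truth$holdout_types)) {
    keep <- fx$truth$training_label_set
    out$train <- subset_cells(out$train, out$train$obs$cell_type %in% keep)
    out$val <- subset_cells(out$val, out$val$obs$cell_type %in% keep)
  }
  out
}

# reduced-size configs used across training tests
test_sctab_config <- function(...) {
  sctab_config(n_d = 16L, n_a = 8L, n_shared = 2L, n_independent = 2L,
               batch_size = 256L, virtual_batch_size = 128L,
               max_epochs = 8L, patience = 8L, ...)
}
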