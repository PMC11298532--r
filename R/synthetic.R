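#' Specification for a synthetic scRNA-seq corpus
#'
#' The generator emulates the statistical structure the classifier assumes:
#' per-cell-type expression programs with planted marker genes, additive
#' per-donor shifts in log-mean space (so their signature in normalized
#' space mimics the additive augmentation model), negative-binomial counts
#' with a log-normal library size, optionally coarsened labels (a fraction
#' of cells relabeled to a random proper ancestor) and held-out cell types
#' that occur in cells but are excluded from the training label universe.
#'
#' @param n_genes Number of genes (default 2000).
#' @param ontology_depth,ontology_branching Shape of the generated term tree.
#' @param n_cell_types Number of fine types (assigned to leaves).
#' @param n_donors Number of donors.
#' @param cells_per_donor Cells per donor.
#' @param marker_genes_per_type Planted marker genes per type.
#' @param marker_effect Log-mean upshift of marker genes (default 2).
#' @param donor_shift_scale SD of the per-donor log-mean shift.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives deterministic `round(mu)` counts.
#' @param library_meanlog,library_sdlog Log-normal library size parameters;
#'   `library_sdlog = 0` gives a fixed library size.
#' @param frac_coarse_labels Fraction of cells relabeled to an ancestor.
#' @param holdout_types Number of types excluded from the training label set.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L, ontology_depth = 3L, ontology_branching = 2L,
                           n_cell_types = 8L, n_donors = 20L, cells_per_donor = 1000L,
                           marker_genes_per_type = 20L, marker_effect = 2,
                           donor_shift_scale = 0.2, dispersion = 0.15,
                           library_meanlog = log(1500), library_sdlog = 0.3,
                           frac_coarse_labels = 0, holdout_types = 0L, seed = 1L) {
  stopifnot(n_genes > 0, n_cell_types > 0, n_donors > 0, cells_per_donor > 0,
            frac_coarse_labels >= 0, frac_coarse_labels < 1, dispersion >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a toy cell-type ontology
#'
#' Balanced rooted tree of the requested depth and branching with CL-style
#' IDs; `diamond_edges` extra is_a edges (from a node to one of its
#' grandparent's other children) can be added to exercise DAG handling.
#'
#' @param spec A [synthetic_spec()] (or depth/branching passed directly).
#' @param diamond_edges Number of extra diamond edges (default 0).
#' @return A [cell_ontology()].
#' @export
generate_ontology <- function(spec, diamond_edges = 0L) {
  depth <- spec$ontology_depth; branch <- spec$ontology_branching
  root <- "CL:1000000"
  terms <- root
  parents <- list()
  parents[[root]] <- character(0)
  level <- root
  counter <- 0L
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branch)) {
        counter <- counter + 1L
        id <- sprintf("CL:%07d", 1000000L + counter)
        terms <- c(terms, id)
        parents[[id]] <- p
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  if (diamond_edges > 0L) {
    set.seed(spec$seed)
    inner <- setdiff(terms, c(root, level))
    for (i in seq_len(min(diamond_edges, length(level)))) {
      ch <- level[i]
      cand <- setdiff(inner, parents[[ch]])
      if (length(cand)) parents[[ch]] <- c(parents[[ch]], sample(cand, 1))
    }
  }
  cell_ontology(terms, parents, root = root)
}

.ontology_leaves <- function(graph) {
  graph$terms[lengths(graph$children[graph$terms]) == 0L]
}

#' Generate a synthetic raw-count corpus with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param graph Optional ontology (generated from `spec` when NULL).
#' @return List with `corpus` (raw [cell_corpus()]), `graph`, and `truth`
#'   (list: per-cell `fine_type`, `assigned`, markers, donor shifts,
#'   `holdout_types`, `training_label_set`).
#' @export
generate_corpus <- function(spec, graph = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(graph)) graph <- generate_ontology(spec)
  leaves <- .ontology_leaves(graph)
  if (spec$n_cell_types > length(leaves)) {
    stop("n_cell_types (", spec$n_cell_types, ") exceeds the ", length(leaves),
         " ontology leaves")
  }
  set.seed(spec$seed)
  G <- spec$n_genes
  types <- sort(sample(leaves, spec$n_cell_types))
  donors <- sprintf("donor%02d", seq_len(spec$n_donors))

  base <- stats::rnorm(G, 0, 1)
  markers <- list()
  pool <- seq_len(G)
  for (ct in types) {
    mk <- sample(pool, min(spec$marker_genes_per_type, length(pool)))
    pool <- setdiff(pool, mk)
    markers[[ct]] <- mk
  }
  mu <- sapply(types, function(ct) {
    m <- base
    m[markers[[ct]]] <- m[markers[[ct]]] + spec$marker_effect
    m
  })                                             # G x types
  delta <- matrix(stats::rnorm(G * spec$n_donors, 0, spec$donor_shift_scale),
                  G, spec$n_donors, dimnames = list(NULL, donors))

  n <- spec$n_donors * spec$cells_per_donor
  donor_of <- rep(donors, each = spec$cells_per_donor)
  type_of <- sample(types, n, replace = TRUE)
  lib <- if (spec$library_sdlog == 0) rep(exp(spec$library_meanlog), n) else
    stats::rlnorm(n, spec$library_meanlog, spec$library_sdlog)

  counts <- Matrix::Matrix(0, 1, 1)
  blocks <- vector("list", spec$n_donors)
  for (di in seq_along(donors)) {
    idx <- which(donor_of == donors[di])
    # softmax-normalized expected expression per (type, donor)
    eta <- mu + delta[, di]                      # G x types
    rate <- exp(eta)
    rate <- sweep(rate, 2L, colSums(rate), "/")
    mcell <- rate[, match(type_of[idx], types), drop = FALSE] *
      rep(lib[idx], each = G)                    # G x cells
    cnt <- if (spec$dispersion == 0) round(mcell) else
      matrix(stats::rnbinom(length(mcell), mu = mcell, size = 1 / spec$dispersion),
             G, length(idx))
    blocks[[di]] <- methods::as(Matrix::Matrix(t(cnt), sparse = TRUE), "CsparseMatrix")
  }
  counts <- do.call(rbind, blocks)

  assigned <- type_of
  if (spec$frac_coarse_labels > 0) {
    graph <- .with_anc_cache(graph)
    n_coarse <- round(spec$frac_coarse_labels * n)
    coarse_idx <- sample.int(n, n_coarse)
    for (i in coarse_idx) {
      anc <- term_ancestors(graph, type_of[i])
      anc_nonroot <- setdiff(anc, graph$root)
      pickpool <- if (length(anc_nonroot)) anc_nonroot else anc
      assigned[i] <- pickpool[sample.int(length(pickpool), 1)]
    }
  }

  holdout <- character(0)
  if (spec$holdout_types > 0L) {
    holdout <- sort(sample(types, spec$holdout_types))
  }

  obs <- data.frame(
    cell_id = sprintf("cell%06d", seq_len(n)),
    cell_type = assigned,
    donor_id = donor_of,
    assay = "10x 3' v3",
    dataset_id = "synthetic",
    is_primary = TRUE,
    tissue = "synthetic tissue",
    stringsAsFactors = FALSE
  )
  corpus <- cell_corpus(counts, obs, genes = sprintf("gene%05d", seq_len(G)))
  truth <- list(fine_type = type_of, assigned = assigned, donor = donor_of,
                markers = lapply(markers, function(i) sprintf("gene%05d", i)),
                donor_shift = delta, types = types, holdout_types = holdout,
                training_label_set = setdiff(types, holdout),
                library_size = lib, spec = spec)
  list(corpus = corpus, graph = graph, truth = truth)
}

#' Standard named fixtures
#'
#' Versioned presets regenerated identically from embedded seeds:
#' \describe{
#'   \item{separable-small}{2000 genes, 8 well-separated types, 20 donors,
#'     20,000 cells, weak donor shift: training smoke tests and parameter
#'     recovery.}
#'   \item{donor-shift}{500 genes, 5 types, 12 donors with strong donor
#'     batch effects: the augmentation-benefit setting.}
#'   \item{granularity-mixed}{30% of labels coarsened to ancestors:
#'     ontology-corrected metric tests.}
#'   \item{holdout-type}{8 types of which 2 are excluded from the training
#'     label universe, noisier programs: uncertainty evaluation.}
#'   \item{filter-edge}{hand-built corpus with cell types placed exactly on
#'     the filtering boundaries (4,999 vs 5,000 cells; 29 vs 30 donors;
#'     shallow vs deep ontology terms; non-primary and non-10x cells).}
#' }
#'
#' @param name Preset name; `standard_fixtures()` lists the names.
#' @return `fixture_spec()`: the `synthetic_spec` (or NULL for the
#'   hand-built preset); `make_fixture()`: list with `corpus`, `graph`,
#'   `truth` (plus `expected` for `filter-edge`).
#' @export
standard_fixtures <- function() {
  c("separable-small", "donor-shift", "granularity-mixed", "holdout-type", "filter-edge")
}

#' @rdname standard_fixtures
#' @export
fixture_spec <- function(name) {
  switch(match.arg(name, standard_fixtures()),
    "separable-small" = synthetic_spec(
      n_genes = 2000L, n_cell_types = 8L, n_donors = 20L, cells_per_donor = 1000L,
      marker_genes_per_type = 20L, marker_effect = 2, donor_shift_scale = 0.2,
      dispersion = 0.15, seed = 101L),
    "donor-shift" = synthetic_spec(
      n_genes = 500L, n_cell_types = 5L, n_donors = 12L, cells_per_donor = 400L,
      marker_genes_per_type = 12L, marker_effect = 1.5, donor_shift_scale = 0.55,
      dispersion = 0.3, seed = 202L),
    "granularity-mixed" = synthetic_spec(
      n_genes = 300L, n_cell_types = 6L, n_donors = 10L, cells_per_donor = 200L,
      marker_genes_per_type = 10L, marker_effect = 1.5, donor_shift_scale = 0.3,
      dispersion = 0.2, frac_coarse_labels = 0.3, seed = 303L),
    "holdout-type" = synthetic_spec(
      n_genes = 400L, n_cell_types = 8L, n_donors = 14L, cells_per_donor = 250L,
      marker_genes_per_type = 10L, marker_effect = 1.6, donor_shift_scale = 0.4,
      dispersion = 0.3, holdout_types = 2L, seed = 404L),
    "filter-edge" = NULL)
}

#' @rdname standard_fixtures
#' @export
make_fixture <- function(name) {
  name <- match.arg(name, standard_fixtures())
  if (name == "filter-edge") return(.make_filter_edge_fixture())
  generate_corpus(fixture_spec(name))
}

# Cell types placed exactly on the corpus-filter boundaries. The ontology is
# a depth-8 chain (leaves have 8 ancestors) plus one shallow term directly
# under the root (1 ancestor).
.make_filter_edge_fixture <- function(seed = 505L) {
  root <- "CL:2000000"
  chain <- sprintf("CL:%07d", 2000000L + 1:7)
  deep_types <- sprintf("CL:%07d", 2000100L + 1:4)
  shallow <- "CL:2000201"
  terms <- c(root, chain, deep_types, shallow)
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(as.list(c(root, chain[-7])), chain),
    stats::setNames(rep(list(chain[7]), 4), deep_types),
    stats::setNames(list(root), shallow)
  )
  graph <- cell_ontology(terms, parents, root = root)

  # design: type, n primary/10x cells, n donors (+ extra removed-first cells)
  design <- data.frame(
    type = c(deep_types, shallow),
    n = c(5000L, 4999L, 5200L, 5500L, 5100L),
    donors = c(30L, 35L, 29L, 32L, 31L),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  obs_list <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    donor_ids <- sprintf("fe_donor_%s_%02d", i, seq_len(d$donors))
    obs_list[[i]] <- data.frame(
      cell_type = d$type,
      donor_id = rep(donor_ids, length.out = d$n),
      assay = "10x 3' v3", is_primary = TRUE, stringsAsFactors = FALSE)
  }
  # removed-first cells attached to the surviving 5000-cell type
  extra <- data.frame(
    cell_type = design$type[1],
    donor_id = "fe_donor_1_01",
    assay = c(rep("10x 3' v3", 40), rep("Smart-seq2", 30)),
    is_primary = c(rep(FALSE, 40), rep(TRUE, 30)),
    stringsAsFactors = FALSE)
  unknown <- data.frame(cell_type = "CL:9999999", donor_id = "fe_donor_x",
                        assay = "10x 3' v3", is_primary = TRUE,
                        stringsAsFactors = FALSE)[rep(1, 10), ]
  obs <- do.call(rbind, c(obs_list, list(extra, unknown)))
  n <- nrow(obs)
  obs <- data.frame(cell_id = sprintf("fe%06d", seq_len(n)), obs,
                    dataset_id = "filter-edge", tissue = "synthetic tissue",
                    stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(
    stats::rpois(n * 30L, lambda = 2), nrow = n, ncol = 30L, sparse = TRUE)
  corpus <- cell_corpus(methods::as(counts, "CsparseMatrix"), obs,
                        genes = sprintf("gene%05d", 1:30))
  expected <- list(
    surviving_types = design$type[c(1, 4)],
    removed = list(min_cells = design$type[2], min_donors = design$type[3],
                   min_ancestors = shallow))
  list(corpus = corpus, graph = graph, truth = NULL, expected = expected)
}
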