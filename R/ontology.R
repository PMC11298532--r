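#' Cell-type ontology graphs
#'
#' A `cell_ontology` is a rooted directed acyclic graph of cell-type terms
#' connected by `is_a` edges (child -> parent). It backs subtype reasoning
#' during evaluation, the ancestor-count corpus filter, and the
#' information-content based fine-to-coarse label mapping.
#'
#' @param terms Character vector of term identifiers (CL-style strings).
#' @param parents Named list mapping each term to the character vector of its
#'   direct `is_a` parents (empty for the root).
#' @param root Identifier of the root term; every other term must reach it.
#' @param names Optional named character vector of human-readable term names.
#'
#' @return An object of class `cell_ontology` with elements `terms`,
#'   `parents`, `children`, `root`, and `term_names`.
#' @export
cell_ontology <- function(terms, parents, root, names = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    stop("duplicate term IDs: ", paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  if (!root %in% terms) stop("root term '", root, "' not among terms")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p[!is.na(p)]))
  bad <- setdiff(unlist(parents), terms)
  if (length(bad)) stop("parent terms not in term set: ", paste(bad, collapse = ", "))

  children <- lapply(terms, function(t) character(0))
  names(children) <- terms
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }

  g <- structure(
    list(terms = terms, parents = parents, children = children,
         root = root, term_names = names),
    class = "cell_ontology"
  )
  cycle <- .find_cycle_edge(g)
  if (!is.null(cycle)) {
    stop("ontology contains a cycle through edge ", cycle[1], " -> ", cycle[2])
  }
  # every non-root term must reach the root
  anc <- .ancestor_sets(g)
  unreachable <- setdiff(terms, c(root, names(anc)[vapply(anc, function(a) root %in% a, logical(1))]))
  if (length(unreachable)) {
    stop("terms do not reach the root via is_a edges: ",
         paste(unreachable, collapse = ", "))
  }
  g
}

#' @export
print.cell_ontology <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("cell_ontology: %d terms, %d is_a edges, root = %s\n",
              length(x$terms), n_edges, x$root))
  invisible(x)
}

# Kahn topological sort on child->parent edges; returns an offending edge if cyclic.
.find_cycle_edge <- function(g) {
  indeg <- lengths(g$parents)            # edges out of child; treat parent count as in-degree proxy
  # run Kahn over edges child -> parent
  remaining <- g$parents
  queue <- names(remaining)[lengths(remaining) == 0L]
  seen <- character(0)
  child_of <- g$children
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    seen <- c(seen, t)
    for (ch in child_of[[t]]) {
      remaining[[ch]] <- setdiff(remaining[[ch]], t)
      if (!length(remaining[[ch]])) queue <- c(queue, ch)
    }
  }
  if (length(seen) == length(g$terms)) return(NULL)
  stuck <- setdiff(g$terms, seen)
  c(stuck[1], remaining[[stuck[1]]][1])
}

# Memoised transitive ancestor sets for every term (named list, excludes self).
.ancestor_sets <- function(g) {
  cache <- attr(g, ".anc_cache")
  if (!is.null(cache)) return(cache)
  anc <- vector("list", length(g$terms))
  names(anc) <- g$terms
  order <- .topo_order(g)
  for (t in order) {
    ps <- g$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

# Topological order with parents before children.
.topo_order <- function(g) {
  remaining <- g$parents
  queue <- names(remaining)[lengths(remaining) == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    out <- c(out, t)
    for (ch in g$children[[t]]) {
      remaining[[ch]] <- setdiff(remaining[[ch]], t)
      if (!length(remaining[[ch]])) queue <- c(queue, ch)
    }
  }
  out
}

.with_anc_cache <- function(g) {
  if (is.null(attr(g, ".anc_cache"))) attr(g, ".anc_cache") <- .ancestor_sets(g)
  g
}

.check_terms <- function(g, terms, what = "term") {
  missing <- setdiff(unique(terms), g$terms)
  if (length(missing)) {
    stop("unknown ", what, "(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Load a cell-type ontology from OBO or OBO-Graphs JSON
#'
#' Reads `[Term]` stanzas of an OBO 1.2 flat file or the `nodes`/`edges`
#' arrays of an OBO-Graphs JSON file, keeps only `is_a` edges, and restricts
#' the graph to the descendants-or-self of `root_term`. Obsolete terms and
#' non-`is_a` relationships are dropped.
#'
#' @param source Path to an `.obo` or OBO-Graphs `.json` file.
#' @param root_term Term ID used as root (e.g. `"CL:0000003"`, native cell).
#' @return A [cell_ontology()].
#' @export
load_ontology <- function(source, root_term) {
  stopifnot(is.character(source), length(source) == 1L, file.exists(source))
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    parsed <- .parse_obograph_json(source)
  } else {
    parsed <- .parse_obo(source)
  }
  if (!root_term %in% parsed$terms) {
    stop("root term '", root_term, "' not found in ", source)
  }
  # restrict to descendants-or-self of the root before validation
  keep <- .descendants_closure(parsed, root_term)
  parents <- lapply(parsed$parents[keep], function(p) intersect(p, keep))
  nm <- parsed$names[intersect(names(parsed$names), keep)]
  cell_ontology(keep, parents, root = root_term, names = nm)
}

.descendants_closure <- function(parsed, root) {
  children <- list()
  for (t in parsed$terms) {
    for (p in parsed$parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  keep <- character(0)
  frontier <- root
  while (length(frontier)) {
    keep <- c(keep, frontier)
    frontier <- setdiff(unique(unlist(children[frontier], use.names = FALSE)), keep)
  }
  unique(keep)
}

.parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); parents <- list(); nms <- character(0)
  cur <- NULL; cur_parents <- character(0); cur_name <- NA_character_
  in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      parents[[cur]] <<- cur_parents
      if (!is.na(cur_name)) nms[cur] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character(0); cur_name <- NA_character_
      in_term <- TRUE; obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur_name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  # drop dangling parents (outside the file)
  parents <- lapply(parents, function(p) intersect(p, terms))
  list(terms = terms, parents = parents, names = nms)
}

.parse_obograph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  graph <- j$graphs[[1]]
  strip <- function(id) {
    # OBO-Graphs use IRIs like http://purl.obolibrary.org/obo/CL_0000084
    id <- sub("^.*/", "", id)
    gsub("_", ":", id)
  }
  nodes <- graph$nodes
  terms <- vapply(nodes, function(n) strip(n$id), character(1))
  deprecated <- vapply(nodes, function(n) {
    isTRUE(n$meta$deprecated)
  }, logical(1))
  nms <- vapply(nodes, function(n) if (is.null(n$lbl)) NA_character_ else n$lbl, character(1))
  terms_keep <- terms[!deprecated]
  parents <- lapply(terms_keep, function(t) character(0))
  names(parents) <- terms_keep
  for (e in graph$edges) {
    if (!identical(e$pred, "is_a")) next
    ch <- strip(e$sub); pa <- strip(e$obj)
    if (ch %in% terms_keep && pa %in% terms_keep) {
      parents[[ch]] <- c(parents[[ch]], pa)
    }
  }
  names(nms) <- terms
  list(terms = terms_keep, parents = parents, names = nms[terms_keep])
}

#' Subtype test on the ontology
#'
#' `is_subtype(g, a, b)` is `TRUE` iff `a == b` or `a` is a transitive
#' descendant of `b` along `is_a` edges — e.g. a CD4-positive, alpha-beta
#' T cell is a subtype of T cell.
#'
#' @param graph A [cell_ontology()].
#' @param a,b Term IDs present in the graph.
#' @return Logical flag.
#' @export
is_subtype <- function(graph, a, b) {
  .check_terms(graph, c(a, b))
  if (a == b) return(TRUE)
  anc <- .ancestor_sets(graph)
  b %in% anc[[a]]
}

#' Transitive ancestors of a term
#' @param graph A [cell_ontology()].
#' @param term Term ID.
#' @return Character vector of ancestor term IDs (excluding `term` itself).
#' @export
term_ancestors <- function(graph, term) {
  .check_terms(graph, term)
  .ancestor_sets(graph)[[term]]
}

#' Transitive descendants of a term
#' @inheritParams term_ancestors
#' @return Character vector of descendant term IDs (excluding `term`).
#' @export
term_descendants <- function(graph, term) {
  .check_terms(graph, term)
  anc <- .ancestor_sets(graph)
  graph$terms[vapply(anc, function(a) term %in% a, logical(1))]
}

#' Number of transitive ancestors of a term
#'
#' Shared ancestors along multiple paths are counted once. This is the count
#' used by the corpus filter that removes overly broad cell-type labels
#' (fewer than seven ancestors by default).
#'
#' @inheritParams term_ancestors
#' @return Non-negative integer.
#' @export
ancestor_count <- function(graph, term) {
  length(term_ancestors(graph, term))
}

#' Information-content scores for every term
#'
#' Scores term specificity on a 0-100 scale where 100 is a maximally specific
#' term with no subclasses. When no precomputed score table is supplied the
#' count-based surrogate
#' `IC(t) = 100 * (1 - log(1 + n_descendants(t)) / log(1 + n_terms))`
#' is used; it is 100 at leaves and non-increasing from child to parent.
#' Precomputed scores (e.g. Ubergraph-derived) can be passed as `override`
#' and take precedence.
#'
#' @param graph A [cell_ontology()].
#' @param override Optional named numeric vector of precomputed scores.
#' @return A data.frame with columns `term`, `n_ancestors`, `n_descendants`,
#'   `information_content`.
#' @export
information_content <- function(graph, override = NULL) {
  stopifnot(length(graph$terms) > 0L)
  anc <- .ancestor_sets(graph)
  n_anc <- lengths(anc)
  n_desc <- integer(length(graph$terms))
  names(n_desc) <- graph$terms
  for (t in graph$terms) {
    for (p in anc[[t]]) n_desc[[p]] <- n_desc[[p]] + 1L
  }
  n_terms <- length(graph$terms)
  ic <- 100 * (1 - log1p(n_desc) / log1p(n_terms))
  if (!is.null(override)) {
    stopifnot(!is.null(names(override)))
    hit <- intersect(names(override), graph$terms)
    ic[hit] <- override[hit]
  }
  data.frame(
    term = graph$terms,
    n_ancestors = as.integer(n_anc[graph$terms]),
    n_descendants = as.integer(n_desc[graph$terms]),
    information_content = unname(ic[graph$terms]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build a fine-to-coarse label map from information content
#'
#' Candidate coarse labels are all terms with information content at most
#' `threshold`. Each observed term is assigned to the candidate among its
#' ancestors-or-self with the highest information content (ties broken by
#' lexicographic term ID); e.g. with candidates T cell (IC 55) and lymphocyte
#' (IC 40), alpha-beta T cell maps to T cell. Observed terms with no
#' candidate ancestor are returned in `unmapped`.
#'
#' @param graph A [cell_ontology()].
#' @param stats Score table from [information_content()] (or same shape).
#' @param observed_terms Terms to map; must be in the graph.
#' @param threshold Information-content cutoff for coarse labels (default 60).
#' @return A `coarse_map`: list with `mapping` (named character vector),
#'   `unmapped`, `threshold`, `candidates`.
#' @export
build_coarse_map <- function(graph, stats, observed_terms, threshold = 60) {
  .check_terms(graph, observed_terms, "observed term")
  ic <- stats$information_content
  names(ic) <- stats$term
  candidates <- stats$term[ic[stats$term] <= threshold]
  if (!length(candidates)) stop("no terms with information content <= ", threshold)
  anc <- .ancestor_sets(graph)
  mapping <- character(0); unmapped <- character(0)
  for (t in unique(observed_terms)) {
    cand <- intersect(c(t, anc[[t]]), candidates)
    if (!length(cand)) {
      unmapped <- c(unmapped, t)
      next
    }
    best_ic <- max(ic[cand])
    best <- sort(cand[ic[cand] == best_ic])[1]   # lexicographic tie-break
    mapping[t] <- best
  }
  structure(
    list(mapping = mapping, unmapped = unmapped,
         threshold = threshold, candidates = candidates),
    class = "coarse_map"
  )
}

#' Map fine-grained predictions onto coarse labels
#'
#' Applies a [build_coarse_map()] element-wise, so that e.g. predictions of
#' mature T cell subtypes all count as predicting the coarse mature T cell
#' label. Idempotent on coarse labels.
#'
#' @param preds Character vector of predicted term IDs.
#' @param coarse_map A `coarse_map`.
#' @return Character vector of the same length with coarse labels.
#' @export
aggregate_predictions <- function(preds, coarse_map) {
  stopifnot(inherits(coarse_map, "coarse_map"))
  if (!length(preds)) return(character(0))
  missing <- setdiff(unique(preds), names(coarse_map$mapping))
  if (length(missing)) {
    stop("terms without a coarse mapping: ", paste(missing, collapse = ", "))
  }
  unname(coarse_map$mapping[preds])
}

#' Write / read term score tables
#'
#' Tab-delimited (term_id, value) serialization for coarse maps and
#' information-content tables.
#' @param x A `coarse_map` or data.frame from [information_content()].
#' @param path Output TSV path.
#' @export
write_term_table <- function(x, path) {
  if (inherits(x, "coarse_map")) {
    df <- data.frame(term_id = names(x$mapping), value = unname(x$mapping))
  } else {
    df <- data.frame(term_id = x$term, value = x$information_content)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
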