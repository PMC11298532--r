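write_toy_obo <- function(path, cycle = FALSE) {
  lines <- c(
    "format-version: 1.2", "",
    "[Term]", "id: CL:0000000", "name: cell", "",
    "[Term]", "id: CL:0000001", "name: left", "is_a: CL:0000000 ! cell", "",
    "[Term]", "id: CL:0000002", "name: right", "is_a: CL:0000000", "",
    "[Term]", "id: CL:0000003", "name: left-leaf", "is_a: CL:0000001", "",
    "[Term]", "id: CL:0000004", "name: right-leaf", "is_a: CL:0000002", "")
  if (cycle) lines <- c(lines, "[Term]", "id: CL:0000005",
                        "is_a: CL:0000003", "")
  writeLines(lines, path)
  path
}

test_that("OBO loading restricts to the root's descendants and keeps is_a edges", {
  f <- write_toy_obo(withr::local_tempfile(fileext = ".obo"))
  g <- load_ontology(f, "CL:0000000")
  expect_s3_class(g, "cell_ontology")
  expect_length(g$terms, 5L)
  expect_equal(sum(lengths(g$parents)), 4L)
  expect_equal(g$term_names[["CL:0000003"]], "left-leaf")

  # rooting at a leaf keeps just that term
  leaf <- load_ontology(f, "CL:0000003")
  expect_length(leaf$terms, 1L)
  expect_equal(sum(lengths(leaf$parents)), 0L)

  expect_error(load_ontology(f, "CL:9999999"), "root term")
})

test_that("a cyclic ontology is rejected with the offending edge named", {
  g <- immune_ontology()
  parents <- g$graph$parents
  # add a back-edge: native cell becomes a child of T cell
  parents[[g$ids[["native"]]]] <- g$ids[["tcell"]]
  expect_error(cell_ontology(g$graph$terms, parents, root = g$ids[["native"]]),
               "cycle")
})

test_that("OBO-Graphs JSON loading matches the OBO reader", {
  f <- write_toy_obo(withr::local_tempfile(fileext = ".obo"))
  g_obo <- load_ontology(f, "CL:0000000")
  iri <- function(id) paste0("http://purl.obolibrary.org/obo/", gsub(":", "_", id))
  nodes <- lapply(g_obo$terms, function(t) list(id = iri(t), lbl = g_obo$term_names[[t]]))
  edges <- list()
  for (t in g_obo$terms) for (p in g_obo$parents[[t]]) {
    edges[[length(edges) + 1]] <- list(sub = iri(t), pred = "is_a", obj = iri(p))
  }
  # a non-is_a edge must be ignored
  edges[[length(edges) + 1]] <- list(sub = iri("CL:0000003"), pred = "part_of",
                                     obj = iri("CL:0000004"))
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(graphs = list(list(nodes = nodes, edges = edges))),
                       jf, auto_unbox = TRUE)
  g_json <- load_ontology(jf, "CL:0000000")
  expect_setequal(g_json$terms, g_obo$terms)
  expect_equal(g_json$parents[g_obo$terms], g_obo$parents[g_obo$terms])
})

test_that("is_subtype follows the T-cell worked cases and errors on unknown terms", {
  io <- immune_ontology()
  g <- io$graph; ids <- io$ids
  # a CD4-positive, alpha-beta T cell is a T cell
  expect_true(is_subtype(g, ids[["cd4"]], ids[["tcell"]]))
  expect_false(is_subtype(g, ids[["tcell"]], ids[["cd4"]]))
  expect_true(is_subtype(g, ids[["tcell"]], ids[["tcell"]]))
  expect_error(is_subtype(g, "CL:0009999", ids[["tcell"]]), "unknown")
})

test_that("is_subtype is reflexive/transitive and matches brute-force reachability", {
  for (seed in 1:6) {
    g <- random_dag(n_terms = sample(10:50, 1), extra_edges = 4L, seed = seed)
    terms <- sample(g$terms, min(12, length(g$terms)))
    for (a in terms) {
      expect_true(is_subtype(g, a, a))
      for (b in terms) {
        expect_identical(is_subtype(g, a, b),
                         reachable_bruteforce(g$parents, a, b),
                         info = sprintf("seed %d: %s vs %s", seed, a, b))
      }
    }
  }
})

test_that("ancestor_count counts distinct transitive ancestors", {
  # chain: root -> a -> b -> leaf
  chain <- cell_ontology(
    c("r", "a", "b", "leaf"),
    list(r = character(0), a = "r", b = "a", leaf = "b"), root = "r")
  expect_equal(ancestor_count(chain, "r"), 0L)
  expect_equal(ancestor_count(chain, "leaf"), 3L)

  # diamond: apex with two parents sharing one grandparent -> 3 not 4
  diamond <- cell_ontology(
    c("r", "l", "m", "x"),
    list(r = character(0), l = "r", m = "r", x = c("l", "m")), root = "r")
  expect_equal(ancestor_count(diamond, "x"), 3L)
})

test_that("information content is 100 at leaves, minimal at the root, monotone", {
  io <- immune_ontology()
  ic <- information_content(io$graph)
  scores <- stats::setNames(ic$information_content, ic$term)
  leaves <- ic$term[ic$n_descendants == 0]
  expect_true(all(scores[leaves] == 100))
  expect_equal(unname(which.min(scores)), which(ic$term == io$graph$root))
  # child >= parent along every edge, on random DAGs too
  for (seed in 1:4) {
    g <- random_dag(30, extra_edges = 3L, seed = seed)
    s <- information_content(g)
    sc <- stats::setNames(s$information_content, s$term)
    for (t in g$terms) for (p in g$parents[[t]]) {
      expect_gte(sc[[t]], sc[[p]])
    }
  }
  # override table takes precedence
  ov <- c(55, 40)
  names(ov) <- c(io$ids[["tcell"]], io$ids[["lymphocyte"]])
  ic2 <- information_content(io$graph, override = ov)
  expect_equal(ic2$information_content[ic2$term == io$ids[["tcell"]]], 55)
})

test_that("coarse map picks the highest-IC candidate ancestor", {
  io <- immune_ontology()
  ids <- io$ids
  ic <- information_content(io$graph)
  # pin the worked example: candidates T cell (55) and lymphocyte (40)
  ov <- c(55, 40, 58)
  names(ov) <- c(ids[["tcell"]], ids[["lymphocyte"]], ids[["bcell"]])
  stats <- information_content(io$graph, override = ov)
  cm <- build_coarse_map(io$graph, stats,
                         observed_terms = c(ids[["abt"]], ids[["tcell"]], ids[["bcell"]]),
                         threshold = 60)
  expect_equal(unname(cm$mapping[ids[["abt"]]]), ids[["tcell"]])
  # a term that is itself a candidate maps to itself
  expect_equal(unname(cm$mapping[ids[["tcell"]]]), ids[["tcell"]])
  expect_equal(unname(cm$mapping[ids[["bcell"]]]), ids[["bcell"]])
})

test_that("coarse map ties break lexicographically and unmapped terms are reported", {
  # diamond: apex under two parents with identical IC
  g <- cell_ontology(c("r", "pa", "pb", "x"),
                     list(r = character(0), pa = "r", pb = "r", x = c("pa", "pb")),
                     root = "r")
  stats <- information_content(g)
  stats$information_content[stats$term %in% c("pa", "pb")] <- 50
  stats$information_content[stats$term == "x"] <- 100
  stats$information_content[stats$term == "r"] <- 5
  cm <- build_coarse_map(g, stats, observed_terms = "x", threshold = 60)
  expect_equal(unname(cm$mapping[["x"]]), "pa")   # lexicographic tie-break

  # threshold so low that nothing qualifies -> error
  expect_error(build_coarse_map(g, stats, "x", threshold = -1), "no terms")
})

test_that("aggregate_predictions maps element-wise, preserves length, is idempotent", {
  io <- immune_ontology()
  ids <- io$ids
  ov <- c(55, 40, 58)
  names(ov) <- c(ids[["tcell"]], ids[["lymphocyte"]], ids[["bcell"]])
  stats <- information_content(io$graph, override = ov)
  cm <- build_coarse_map(io$graph, stats,
                         observed_terms = c(ids[["cd4"]], ids[["cd8"]], ids[["bcell"]],
                                            ids[["tcell"]]),
                         threshold = 60)
  preds <- c(ids[["cd4"]], ids[["cd8"]], ids[["bcell"]])
  out <- aggregate_predictions(preds, cm)
  expect_equal(out, c(ids[["tcell"]], ids[["tcell"]], ids[["bcell"]]))
  expect_equal(aggregate_predictions(out, cm), out)   # idempotent on coarse labels
  expect_equal(aggregate_predictions(character(0), cm), character(0))
  expect_error(aggregate_predictions("CL:0000766", cm), "without a coarse mapping")
})

test_that("ontologies round-trip through the OBO writer", {
  io <- immune_ontology()
  f <- withr::local_tempfile(fileext = ".obo")
  write_ontology_obo(io$graph, f)
  g2 <- load_ontology(f, io$graph$root)
  expect_setequal(g2$terms, io$graph$terms)
  expect_equal(g2$parents[io$graph$terms], io$graph$parents[io$graph$terms])
})
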