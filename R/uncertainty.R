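#' Deep-ensemble prediction and uncertainty
#'
#' Averages predicted class probabilities across independently trained
#' ensemble members (each differing only in its initialization/shuffle
#' seed) and scores per-cell uncertainty as one minus the maximum averaged
#' probability.
#'
#' @param members List of `sctab_fit` objects sharing class set and gene
#'   vocabulary.
#' @param corpus A [cell_corpus()] to predict on.
#' @return An `ensemble_prediction`: `mean_probs` (cells x classes),
#'   `label`, `uncertainty` (in [0, 1]), `member_count`.
#' @export
ensemble_predict <- function(members, corpus) {
  stopifnot(length(members) >= 1L)
  classes <- members[[1]]$classes
  genes <- members[[1]]$genes
  for (m in members) {
    if (!identical(m$classes, classes)) stop("ensemble members disagree on the class set")
    if (!identical(m$genes, genes)) stop("ensemble members disagree on the gene vocabulary")
  }
  probs <- NULL
  for (m in members) {
    p <- predict(m, corpus)$probs
    probs <- if (is.null(probs)) p else probs + p
  }
  probs <- probs / length(members)
  structure(list(mean_probs = probs,
                 label = classes[max.col(probs, ties.method = "first")],
                 uncertainty = 1 - apply(probs, 1L, max),
                 member_count = length(members)),
            class = "ensemble_prediction")
}

#' Assign cells to uncertainty evaluation groups
#'
#' Group 1: truth present in the training label set and the prediction is
#' ontology-correct. Group 2: truth trainable but the prediction is wrong.
#' Group 3: truth absent from the training label set (out-of-distribution).
#' By default a truth that is a subtype of some training label is NOT
#' counted as Group 3 (the ontology-corrected metric makes such cells
#' classifiable); set `exclude_subtypes = FALSE` for the strict
#' set-membership rule. Group 3 membership depends only on the label sets,
#' never on the predictions.
#'
#' @param preds,truths Term IDs per cell.
#' @param graph A [cell_ontology()].
#' @param training_label_set Character vector of labels seen in training.
#' @param exclude_subtypes See description.
#' @return Character vector in `c("G1", "G2", "G3")`.
#' @export
assign_groups <- function(preds, truths, graph, training_label_set,
                          exclude_subtypes = TRUE) {
  .check_terms(graph, c(preds, truths, training_label_set))
  graph <- .with_anc_cache(graph)
  u_truth <- unique(truths)
  in_train <- stats::setNames(u_truth %in% training_label_set, u_truth)
  if (exclude_subtypes) {
    for (t in u_truth[!in_train[u_truth]]) {
      if (any(vapply(training_label_set, function(l) is_subtype(graph, t, l), logical(1)))) {
        in_train[t] <- TRUE
      }
    }
  }
  out <- character(length(preds))
  for (i in seq_along(preds)) {
    if (!in_train[[truths[i]]]) {
      out[i] <- "G3"
    } else {
      out[i] <- if (ontology_correct(preds[i], truths[i], graph)) "G1" else "G2"
    }
  }
  out
}

#' ROC-AUC separation of an uncertainty score
#'
#' Area under the ROC curve of the uncertainty score for distinguishing a
#' positive group (incorrect or out-of-distribution cells) from the
#' reference Group 1, computed via the rank (Mann-Whitney) statistic with
#' midranks for ties. 0.5 means no separation, 1.0 perfect separation.
#'
#' @param uncertainty Numeric score per cell.
#' @param groups Group label per cell (from [assign_groups()]).
#' @param positive Which group is the positive class (`"G2"` or `"G3"`).
#' @param reference Reference group (default `"G1"`).
#' @return ROC-AUC in [0, 1].
#' @export
separation_rocauc <- function(uncertainty, groups, positive = c("G2", "G3"),
                              reference = "G1") {
  positive <- match.arg(positive)
  pos <- uncertainty[groups == positive]
  neg <- uncertainty[groups == reference]
  if (!length(pos)) stop("positive group ", positive, " is empty")
  if (!length(neg)) stop("reference group ", reference, " is empty")
  r <- rank(c(neg, pos))
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
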