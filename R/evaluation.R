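#' Ontology-corrected correctness of one prediction
#'
#' A prediction is right if it equals the truth or is a subtype of it (the
#' model agrees up to the annotation granularity the author provided, e.g.
#' predicting CD4-positive, alpha-beta T cell for a cell labeled T cell).
#' Predicting a parent of the truth — or any unrelated term — is wrong.
#'
#' @param pred,truth Term IDs in the graph.
#' @param graph A [cell_ontology()].
#' @return `TRUE` (right) or `FALSE` (wrong).
#' @export
ontology_correct <- function(pred, truth, graph) {
  is_subtype(graph, pred, truth)
}

#' Ontology-corrected macro F1
#'
#' Per-class F1 (`2tp / (2tp + fp + fn)`, 0/0 counted as 0) under
#' ontology-corrected confusion accounting: a prediction that is right by
#' the subtype rule is credited as a true positive of the TRUTH class; a
#' wrong prediction counts as a false positive of the predicted class and a
#' false negative of the truth class. The macro F1 is the unweighted mean
#' over classes with positive support in the truth set.
#'
#' @param preds,truths Equal-length character vectors of term IDs.
#' @param graph A [cell_ontology()].
#' @return An `evaluation_report`: `per_class` data.frame (precision,
#'   recall, f1, support) and `macro_f1`.
#' @export
ontology_macro_f1 <- function(preds, truths, graph) {
  if (!length(preds)) stop("empty input")
  stopifnot(length(preds) == length(truths))
  .check_terms(graph, c(preds, truths))
  graph <- .with_anc_cache(graph)

  # vectorised subtype test over the distinct (pred, truth) pairs
  pairs <- unique(data.frame(p = preds, t = truths, stringsAsFactors = FALSE))
  pairs$right <- mapply(function(p, t) is_subtype(graph, p, t), pairs$p, pairs$t)
  right <- pairs$right[match(paste0(preds, "\r", truths), paste0(pairs$p, "\r", pairs$t))]

  classes <- sort(unique(truths))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(preds)) {
    if (right[i]) {
      tp[truths[i]] <- tp[truths[i]] + 1
    } else {
      fn[truths[i]] <- fn[truths[i]] + 1
      if (preds[i] %in% classes) fp[preds[i]] <- fp[preds[i]] + 1
    }
  }
  support <- as.numeric(table(factor(truths, levels = classes)))
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  per_class <- data.frame(class = classes, precision = unname(prec),
                          recall = unname(rec), f1 = unname(f1),
                          support = support, stringsAsFactors = FALSE)
  structure(list(per_class = per_class, macro_f1 = mean(f1)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: macro F1 = %.4f over %d classes\n",
              x$macro_f1, nrow(x$per_class)))
  invisible(x)
}

#' Macro F1 by group
#'
#' [ontology_macro_f1()] restricted to each level of a grouping label
#' (tissue, assay, organ system, ...). Empty groups are omitted with a
#' warning.
#'
#' @inheritParams ontology_macro_f1
#' @param group_labels Grouping label per cell, aligned with `preds`.
#' @return Named list group -> `evaluation_report`.
#' @export
grouped_macro_f1 <- function(preds, truths, graph, group_labels) {
  stopifnot(length(group_labels) == length(preds))
  out <- list()
  for (g in sort(unique(as.character(group_labels)))) {
    idx <- group_labels == g
    if (!any(idx)) {
      warning("empty group '", g, "' omitted")
      next
    }
    out[[g]] <- ontology_macro_f1(preds[idx], truths[idx], graph)
  }
  out
}

#' Evaluate on coarse labels
#'
#' Maps BOTH predictions and truths through a fine-to-coarse map (so that
#' e.g. all mature T cell subtype predictions count as predicting mature
#' T cell), then scores with [ontology_macro_f1()] on the same graph.
#'
#' @inheritParams ontology_macro_f1
#' @param coarse_map A [build_coarse_map()] result covering both label sets.
#' @return An `evaluation_report` on the coarse labels.
#' @export
coarse_evaluate <- function(preds, truths, coarse_map, graph) {
  ontology_macro_f1(aggregate_predictions(preds, coarse_map),
                    aggregate_predictions(truths, coarse_map),
                    graph)
}

#' Signature-gene separation score
#'
#' How well a linear (ridge-penalized logistic) classifier separates one
#' cell type from all others using only a gene subset (e.g. the top
#' attention-ranked genes), measured by the area under the
#' precision-recall curve on the training and test splits. A small
#' train-test gap indicates the signature generalizes.
#'
#' @param train,test [cell_corpus()] objects (raw or normalized).
#' @param gene_subset Character vector of gene IDs (subset of the vocabulary).
#' @param target_type Cell type treated as the positive class.
#' @return List with `auprc_train`, `auprc_test`, `gap`.
#' @export
signature_separation <- function(train, test, gene_subset, target_type) {
  missing <- setdiff(gene_subset, train$genes)
  if (length(missing)) stop("genes not in vocabulary: ", paste(utils::head(missing, 5), collapse = ", "))
  for (nm in c("train", "test")) {
    cc <- get(nm)
    if (!target_type %in% cc$obs$cell_type) {
      stop("target type '", target_type, "' absent from the ", nm, " split")
    }
  }
  prep <- function(cc) {
    if (cc$layer == "raw") cc <- normalize_corpus(cc)
    list(x = as.matrix(cc$counts[, gene_subset, drop = FALSE]),
         y = as.integer(cc$obs$cell_type == target_type))
  }
  tr <- prep(train); te <- prep(test)
  fit <- glmnet::glmnet(tr$x, tr$y, family = "binomial", alpha = 0,
                        lambda = 1e-3, standardize = TRUE)
  score_tr <- as.numeric(stats::predict(fit, tr$x))
  score_te <- as.numeric(stats::predict(fit, te$x))
  a_tr <- auprc(score_tr, tr$y)
  a_te <- auprc(score_te, te$y)
  list(auprc_train = a_tr, auprc_test = a_te, gap = a_tr - a_te)
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: precision integrated over recall increments
#' at each positive, with ties on the score handled by averaging within tie
#' groups.
#'
#' @param score Numeric classifier scores (higher = more positive).
#' @param y 0/1 labels.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(score, y) {
  stopifnot(length(score) == length(y), any(y == 1))
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; score <- score[ord]
  # collapse score ties so a tie group contributes a single operating point
  grp <- cumsum(!duplicated(score))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp / n_cum
  rec <- tp / sum(y)
  prev_rec <- c(0, rec[-length(rec)])
  sum((rec - prev_rec) * prec)
}
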