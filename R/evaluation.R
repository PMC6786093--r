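#' Random hold-out split of the causal edges
#'
#' Samples a fraction of the known causal edges uniformly at random as an
#' independent test set; the rest form the training set. Deterministic for
#' a fixed seed (the caller's RNG state is left untouched).
#'
#' @param net A `bipartite_network`.
#' @param test_fraction Fraction of edges held out, in (0, 1). Default 0.2.
#' @param seed Integer seed.
#' @return An `edge_split`: list with `train_edges`, `test_edges` (data
#'   frames with `mirna_id`, `disease_name`) and the `seed`.
#' @export
split_holdout <- function(net, test_fraction = 0.2, seed) {
  if (!(is.numeric(test_fraction) && test_fraction > 0 && test_fraction < 1)) {
    stop_usage("test_fraction must lie strictly between 0 and 1")
  }
  edges <- network_edges(net)
  n <- nrow(edges)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test > n - 1) {
    stop_usage("test fraction %g would leave an empty train or test set (%d edges)",
               test_fraction, n)
  }
  withr::local_seed(seed)
  test_idx <- sample.int(n, n_test)
  new_edge_split(edges[-test_idx, , drop = FALSE],
                 edges[test_idx, , drop = FALSE], seed)
}

new_edge_split <- function(train_edges, test_edges, seed) {
  rownames(train_edges) <- rownames(test_edges) <- NULL
  structure(list(train_edges = train_edges, test_edges = test_edges, seed = seed),
            class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("edge_split: %d train / %d test edges (seed %s)\n",
              nrow(x$train_edges), nrow(x$test_edges), format(x$seed)))
  invisible(x)
}

#' k-fold partition of a set of edges
#'
#' Shuffles the edges once and deals them into `k` folds whose sizes differ
#' by at most one; each fold serves once as the test set.
#'
#' @param edges Data frame of edges (`mirna_id`, `disease_name`), or a
#'   `bipartite_network` whose edges are taken.
#' @param k Number of folds, `2 <= k <=` number of edges.
#' @param seed Integer seed.
#' @return List of `k` `edge_split` objects.
#' @export
kfold_splits <- function(edges, k, seed) {
  if (inherits(edges, "bipartite_network")) edges <- network_edges(edges)
  n <- nrow(edges)
  if (!is_count(k) || k < 2 || k > n) {
    stop_usage("k must be between 2 and the number of edges (%d)", n)
  }
  withr::local_seed(seed)
  fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
  lapply(seq_len(k), function(f) {
    new_edge_split(edges[fold != f, , drop = FALSE],
                   edges[fold == f, , drop = FALSE], seed)
  })
}

#' ROC curve and AUC from scores and labels
#'
#' AUC is the Mann-Whitney U statistic normalised by `n_pos * n_neg`, with
#' ties given half credit, computed from midranks; this equals the
#' trapezoidal area under the ROC curve drawn through the distinct score
#' thresholds.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive), same length.
#' @return Object of class `roc_result`: `auc`, `roc_points` (data frame of
#'   `fpr`, `tpr`, monotone in both coordinates), `n_pos`, `n_neg`, and
#'   `n_discarded` (0 here; filled by [evaluate_split()]).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_usage("ROC needs at least one positive and one negative")
  }
  r <- rank(scores)   # midranks: ties half-credited
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  at <- c(which(diff(s) != 0), length(s))   # last index of each tie block
  pts <- data.frame(fpr = c(0, fp[at] / n_neg), tpr = c(0, tp[at] / n_pos))
  structure(list(auc = auc, roc_points = pts, n_pos = n_pos, n_neg = n_neg,
                 n_discarded = 0L),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d pos / %d neg, %d test edges discarded)\n",
              x$auc, x$n_pos, x$n_neg, x$n_discarded))
  invisible(x)
}

#' Evaluate one train/test split without information leakage
#'
#' Rebuilds the causal network from the training edges alone, recomputes
#' every similarity matrix and propagation operator from that training
#' network (test edges contribute nothing to the model), then scores the
#' retained test edges as positives against the non-edge pairs over the
#' training entities as negatives. Test edges whose miRNA or disease does
#' not occur in any training edge are discarded and counted, since no score
#' exists for them.
#'
#' @param split An `edge_split`.
#' @param ontology Optional `disease_ontology` for semantic similarity.
#' @param config A [default_config()] list. `negative_ratio` controls
#'   negative sampling: `Inf` (default) scores every non-edge pair over the
#'   training entities; a finite value samples that many negatives per
#'   positive (seeded by the split's seed).
#' @param keep_fit Also return the fitted model (for inspection of the
#'   training-derived matrices).
#' @return A `roc_result` with `n_discarded` filled in (and `fit` attached
#'   when `keep_fit = TRUE`).
#' @export
evaluate_split <- function(split, ontology = NULL, config = default_config(),
                           keep_fit = FALSE) {
  train_net <- network_from_edges(split$train_edges)
  fit <- fit_causal_lp(train_net, ontology, config)
  scores <- fit$scores
  te <- split$test_edges
  in_train <- te$mirna_id %in% train_net$mirnas &
    te$disease_name %in% train_net$diseases
  n_discarded <- sum(!in_train)
  te <- te[in_train, , drop = FALSE]
  if (nrow(te) == 0) {
    stop_format("no test edge is scoreable: every test entity is absent from training")
  }
  pos_idx <- cbind(match(te$mirna_id, train_net$mirnas),
                   match(te$disease_name, train_net$diseases))
  known <- train_net$adjacency == 1L
  test_mask <- matrix(FALSE, nrow(known), ncol(known))
  test_mask[pos_idx] <- TRUE
  neg_mask <- !known & !test_mask
  neg_scores <- scores[neg_mask]
  if (is.finite(config$negative_ratio)) {
    withr::local_seed(split$seed)
    n_neg <- min(length(neg_scores), ceiling(config$negative_ratio * nrow(te)))
    neg_scores <- sample(neg_scores, n_neg)
  }
  res <- roc_auc(c(scores[pos_idx], neg_scores),
                 c(rep(1L, nrow(te)), rep(0L, length(neg_scores))))
  res$n_discarded <- n_discarded
  if (keep_fit) res$fit <- fit
  res
}

#' Repeated randomized evaluation
#'
#' Repeats the hold-out or k-fold protocol with per-repeat seeds
#' `base_seed + 0, 1, ...` and summarises the AUCs. For `protocol =
#' "kfold"` each repeat partitions the causal edges of `net` into `k` folds
#' and averages the per-fold AUCs.
#'
#' @param net A `bipartite_network`.
#' @param protocol `"holdout"` or `"kfold"`.
#' @param repeats Number of repeated runs.
#' @param base_seed Integer; repeat `i` uses seed `base_seed + i - 1`.
#' @param ontology Optional `disease_ontology`.
#' @param config A [default_config()] list (supplies `test_fraction` / `k`).
#' @return List of class `eval_summary`: per-run `aucs`, their `mean` and
#'   `sd`, total `n_discarded`, the protocol and the configuration.
#' @export
repeat_evaluation <- function(net, protocol = c("holdout", "kfold"),
                              repeats = 10, base_seed = 1,
                              ontology = NULL, config = default_config()) {
  protocol <- match.arg(protocol)
  if (!is_count(repeats)) stop_usage("repeats must be a positive integer")
  aucs <- numeric(repeats)
  discarded <- 0L
  for (i in seq_len(repeats)) {
    seed_i <- base_seed + i - 1
    if (protocol == "holdout") {
      split <- split_holdout(net, config$test_fraction, seed_i)
      res <- evaluate_split(split, ontology, config)
      aucs[i] <- res$auc
      discarded <- discarded + res$n_discarded
    } else {
      folds <- kfold_splits(net, config$k, seed_i)
      fold_res <- lapply(folds, evaluate_split, ontology = ontology, config = config)
      aucs[i] <- mean(vapply(fold_res, `[[`, numeric(1), "auc"))
      discarded <- discarded + sum(vapply(fold_res, `[[`, integer(1), "n_discarded"))
    }
  }
  structure(list(aucs = aucs, mean = mean(aucs),
                 sd = if (repeats > 1) stats::sd(aucs) else 0,
                 n_discarded = discarded, protocol = protocol,
                 repeats = repeats, base_seed = base_seed, config = config),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("eval_summary (%s, %d repeats): mean AUC %.4f (sd %.4f)\n",
              x$protocol, x$repeats, x$mean, x$sd))
  invisible(x)
}

#' Write an evaluation summary to JSON
#'
#' @param summary An `eval_summary`.
#' @param path Output JSON path.
#' @export
write_evaluation_json <- function(summary, path) {
  jsonlite::write_json(
    list(protocol = summary$protocol, repeats = summary$repeats,
         base_seed = summary$base_seed, aucs = summary$aucs,
         mean_auc = summary$mean, sd_auc = summary$sd,
         n_discarded = summary$n_discarded,
         config = unclass(summary$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC points to TSV for plotting
#'
#' @param roc A `roc_result`.
#' @param path Output TSV path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$roc_points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
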