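#' Integrate similarity components into one kernel
#'
#' The primary (semantic or functional) similarity is averaged with the
#' Gaussian interaction-profile kernel where it is defined, with the kernel
#' taking over wherever the primary similarity is `NA` (unresolvable
#' entities); the result is then blended with the hub promoted index:
#' `S = (1 - hpi_weight) * (w * primary + (1 - w) * gip) + hpi_weight * HPI`.
#'
#' @param primary_sim Semantic (disease side) or functional (miRNA side)
#'   `similarity_matrix`; may contain `NA` entries.
#' @param gip Interaction-profile kernel over the same labels.
#' @param hpi Hub-promoted-index matrix over the same labels.
#' @param mix_weight Weight `w` of the primary similarity against the
#'   kernel, in `[0, 1]`. Default 0.5.
#' @param hpi_weight Weight `lambda` of the hub adjustment, in `[0, 1]`.
#'   Default 0.5.
#' @return A fully defined `similarity_matrix` of kind `integrated`.
#' @export
integrate_similarities <- function(primary_sim, gip, hpi,
                                   mix_weight = 0.5, hpi_weight = 0.5) {
  stopifnot(is_prob(mix_weight), is_prob(hpi_weight))
  labels <- rownames(gip)
  if (!identical(rownames(primary_sim), labels) || !identical(rownames(hpi), labels)) {
    stop_usage("similarity matrices to integrate carry different labels")
  }
  S <- mix_weight * unclass(primary_sim) + (1 - mix_weight) * unclass(gip)
  S[is.na(S)] <- unclass(gip)[is.na(S)]
  S <- (1 - hpi_weight) * S + hpi_weight * unclass(hpi)
  similarity_matrix(S, labels, kind = "integrated")
}

#' Row-normalise a similarity matrix into a propagation operator
#'
#' Each row is divided by its sum. A row with zero mass becomes a unit
#' self-loop rather than a uniform row, so isolated entities keep their own
#' labels instead of leaking mass to everything.
#'
#' @param sim Nonnegative square matrix (typically an integrated
#'   `similarity_matrix`).
#' @return A `transition_matrix`: row-stochastic (rows sum to 1 within
#'   1e-10), nonnegative, labels preserved.
#' @export
row_normalize <- function(sim) {
  M <- unclass(sim)
  if (anyNA(M) || any(M < 0)) {
    stop_usage("row_normalize expects a fully defined nonnegative matrix")
  }
  rs <- rowSums(M)
  zero <- rs == 0
  W <- M / ifelse(rs == 0, 1, rs)
  if (any(zero)) W[zero, ] <- diag(nrow(M))[zero, , drop = FALSE]
  structure(W, class = c("transition_matrix", "matrix", "array"))
}

#' Label propagation with restart
#'
#' Iterates `F <- alpha * W %*% F + (1 - alpha) * Y` from `F = Y` until the
#' largest absolute change falls below `tol`. For a row-stochastic `W` and
#' `alpha < 1` this converges geometrically to the closed form
#' `(1 - alpha) * solve(I - alpha W) %*% Y`, with every entry in
#' `[0, max(Y)]`.
#'
#' @param W A `transition_matrix` (row-stochastic).
#' @param Y Known-label matrix (binary), rows matching `W`.
#' @param alpha Propagation/restart trade-off in `[0, 1)`; `alpha = 0`
#'   returns `Y` unchanged. Default 0.5.
#' @param tol Convergence threshold on the max-abs update. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000.
#' @return The stationary score matrix, same shape as `Y`, with an
#'   `iterations` attribute.
#' @export
label_propagate <- function(W, Y, alpha = 0.5, tol = 1e-6, max_iter = 1000) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha < 1, tol > 0, is_count(max_iter))
  W <- unclass(W)
  Y <- as.matrix(Y)
  if (nrow(W) != ncol(W) || nrow(Y) != nrow(W)) {
    stop_usage("label matrix rows must match the transition matrix")
  }
  if (max(abs(rowSums(W) - 1)) > 1e-10 || any(W < 0)) {
    stop_usage("W is not row-stochastic")
  }
  storage.mode(Y) <- "double"
  F_cur <- Y
  restart <- (1 - alpha) * Y
  for (it in seq_len(max_iter)) {
    F_new <- alpha * (W %*% F_cur) + restart
    delta <- max(abs(F_new - F_cur))
    F_cur <- F_new
    if (delta < tol) {
      attr(F_cur, "iterations") <- it
      return(F_cur)
    }
  }
  stop_numeric("label propagation did not converge in %d iterations (residual %.3g)",
               max_iter, delta)
}

#' Fuse the two one-sided propagation results
#'
#' The miRNA-side and disease-side propagations score every pair
#' independently; the final causal-association score is their elementwise
#' arithmetic mean, which keeps the `[0, 1]` interpretation.
#'
#' @param f_mirna miRNA-side result, miRNAs x diseases.
#' @param f_disease Disease-side result oriented back to miRNAs x diseases
#'   (i.e. already transposed if the propagation ran on the disease axis).
#' @return A `score_matrix` (miRNAs x diseases, entries in `[0, 1]`).
#' @export
fuse_scores <- function(f_mirna, f_disease) {
  if (!identical(dim(f_mirna), dim(f_disease))) {
    stop_usage("cannot fuse score matrices of different shapes")
  }
  S <- (unclass(f_mirna) + unclass(f_disease)) / 2
  if (anyNA(S) || any(!is.finite(S))) stop_numeric("non-finite fused scores")
  structure(pmin(pmax(S, 0), 1),
            class = c("score_matrix", "matrix", "array"))
}

#' Default model configuration
#'
#' All tunable hyperparameters of the prediction pipeline in one list.
#' The optimised values used for the published large-scale runs are not
#' recoverable; these defaults follow the conventions of the underlying
#' methods and are meant to be tuned by k-fold cross-validation on a
#' training set.
#'
#' @param delta Semantic contribution decay, in (0, 1).
#' @param bandwidth_scale Interaction-kernel bandwidth multiplier (> 0).
#' @param mix_weight Primary-vs-kernel mixing weight `w` in `[0, 1]`.
#' @param hpi_weight Hub-promoted-index blend `lambda` in `[0, 1]`.
#' @param alpha Propagation/restart trade-off in `[0, 1)`.
#' @param tol Propagation convergence threshold.
#' @param max_iter Propagation iteration cap.
#' @param test_fraction Hold-out fraction for the independent test split.
#' @param k Number of cross-validation folds.
#' @param repeats Number of repeated evaluation runs.
#' @param negative_ratio Negatives per positive in evaluation; `Inf` (the
#'   default) uses every non-edge pair over the training entities.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(delta = 0.5, bandwidth_scale = 1, mix_weight = 0.5,
                           hpi_weight = 0.5, alpha = 0.5, tol = 1e-6,
                           max_iter = 1000, test_fraction = 0.2, k = 10,
                           repeats = 10, negative_ratio = Inf) {
  cfg <- list(delta = delta, bandwidth_scale = bandwidth_scale,
              mix_weight = mix_weight, hpi_weight = hpi_weight, alpha = alpha,
              tol = tol, max_iter = max_iter, test_fraction = test_fraction,
              k = k, repeats = repeats, negative_ratio = negative_ratio)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  ok <- is_prob(cfg$mix_weight) && is_prob(cfg$hpi_weight) &&
    is.numeric(cfg$alpha) && cfg$alpha >= 0 && cfg$alpha < 1 &&
    is.numeric(cfg$delta) && cfg$delta > 0 && cfg$delta < 1 &&
    is.numeric(cfg$bandwidth_scale) && cfg$bandwidth_scale > 0 &&
    is.numeric(cfg$tol) && cfg$tol > 0 && is_count(cfg$max_iter) &&
    is.numeric(cfg$test_fraction) && cfg$test_fraction > 0 && cfg$test_fraction < 1 &&
    is_count(cfg$k) && cfg$k >= 2 && is_count(cfg$repeats) &&
    (is.infinite(cfg$negative_ratio) || cfg$negative_ratio > 0)
  if (!ok) stop_usage("configuration value out of range")
  invisible(cfg)
}

#' Fit the full causal-association scoring model
#'
#' Runs the whole pipeline on a causal bipartite network: disease semantic
#' similarity (when an ontology is supplied), miRNA functional similarity,
#' interaction-profile kernels and hub promoted index on both sides,
#' integration into row-stochastic operators, one label propagation per
#' side with the known causal adjacency as labels, and score fusion.
#'
#' @param net A `bipartite_network` of known causal associations.
#' @param ontology Optional `disease_ontology`; when `NULL`, semantic and
#'   functional similarity are undefined everywhere and the model runs on
#'   interaction kernels plus hub index alone.
#' @param config A [default_config()] list.
#' @return Object of class `causal_lp_fit`: the fused `scores`
#'   (miRNAs x diseases), the per-side integrated similarities and
#'   transition operators, the component similarity matrices, and the
#'   configuration.
#' @export
fit_causal_lp <- function(net, ontology = NULL, config = default_config()) {
  validate_config(config)
  if (!is.null(ontology)) {
    sem <- semantic_similarity_matrix(ontology, net$diseases, delta = config$delta)
    fun <- functional_similarity(net, sem)
  } else {
    sem <- similarity_matrix(matrix(NA_real_, length(net$diseases), length(net$diseases)),
                             net$diseases, kind = "semantic")
    fun <- similarity_matrix(matrix(NA_real_, length(net$mirnas), length(net$mirnas)),
                             net$mirnas, kind = "functional")
  }
  gip_m <- gip_kernel(net, "mirna", config$bandwidth_scale)
  gip_d <- gip_kernel(net, "disease", config$bandwidth_scale)
  hpi_m <- hub_promoted_index(net, "mirna")
  hpi_d <- hub_promoted_index(net, "disease")
  sim_m <- integrate_similarities(fun, gip_m, hpi_m, config$mix_weight, config$hpi_weight)
  sim_d <- integrate_similarities(sem, gip_d, hpi_d, config$mix_weight, config$hpi_weight)
  W_m <- row_normalize(sim_m)
  W_d <- row_normalize(sim_d)
  Y <- net$adjacency
  f_m <- label_propagate(W_m, Y, config$alpha, config$tol, config$max_iter)
  f_d <- label_propagate(W_d, t(Y), config$alpha, config$tol, config$max_iter)
  scores <- fuse_scores(f_m, t(f_d))
  dimnames(scores) <- dimnames(Y)
  structure(list(scores = scores, net = net,
                 sim_mirna = sim_m, sim_disease = sim_d,
                 components = list(semantic = sem, functional = fun,
                                   gip_mirna = gip_m, gip_disease = gip_d,
                                   hpi_mirna = hpi_m, hpi_disease = hpi_d),
                 W_mirna = W_m, W_disease = W_d, config = config),
            class = "causal_lp_fit")
}

#' @export
print.causal_lp_fit <- function(x, ...) {
  cat(sprintf("causal_lp_fit: %d miRNAs x %d diseases, alpha = %g\n",
              nrow(x$scores), ncol(x$scores), x$config$alpha))
  invisible(x)
}

#' Rank candidate partners for a miRNA or a disease
#'
#' Orders all partners of the query by fused score, descending; ties are
#' broken lexicographically by entity name so rankings are deterministic.
#'
#' @param fit A `causal_lp_fit` (or a bare score matrix with dimnames, in
#'   which case `net` must be given for `exclude_known`).
#' @param query A miRNA id or disease name present in the score labels.
#' @param top_k Number of candidates to return; `Inf` for all.
#' @param exclude_known Drop pairs already in the known causal network.
#' @param net Optional `bipartite_network` overriding `fit$net`.
#' @return Data frame with columns `mirna_id`, `disease_name`, `score`,
#'   `rank`, `known_causal`.
#' @export
rank_candidates <- function(fit, query, top_k = 5, exclude_known = TRUE,
                            net = NULL) {
  scores <- if (inherits(fit, "causal_lp_fit")) fit$scores else fit
  net <- net %||% (if (inherits(fit, "causal_lp_fit")) fit$net else NULL)
  mirnas <- rownames(scores); diseases <- colnames(scores)
  if (query %in% mirnas) {
    s <- scores[query, ]
    out <- data.frame(mirna_id = query, disease_name = diseases, score = s,
                      stringsAsFactors = FALSE)
    known <- if (!is.null(net)) net$adjacency[query, ] == 1L else rep(FALSE, length(s))
    partner <- out$disease_name
  } else if (query %in% diseases) {
    s <- scores[, query]
    out <- data.frame(mirna_id = mirnas, disease_name = query, score = s,
                      stringsAsFactors = FALSE)
    known <- if (!is.null(net)) net$adjacency[, query] == 1L else rep(FALSE, length(s))
    partner <- out$mirna_id
  } else {
    near <- unique(c(utils::head(agrep(query, mirnas, value = TRUE, ignore.case = TRUE), 3),
                     utils::head(agrep(query, diseases, value = TRUE, ignore.case = TRUE), 3)))
    stop_usage("query '%s' is neither a miRNA nor a disease in the model%s", query,
               if (length(near)) paste0("; nearest labels: ", paste(near, collapse = ", ")) else "")
  }
  out$known_causal <- as.integer(known)
  ord <- lex_order(-out$score, partner)
  out <- out[ord, , drop = FALSE]
  if (exclude_known) out <- out[out$known_causal == 0L, , drop = FALSE]
  out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("mirna_id", "disease_name", "score", "rank", "known_causal")]
}

#' Export fused scores as a long TSV
#'
#' One row per miRNA-disease pair with the fused score, the rank of the
#' miRNA within its disease column, and the known-causal flag.
#'
#' @param fit A `causal_lp_fit`.
#' @param path Output TSV path.
#' @export
write_score_tsv <- function(fit, path) {
  scores <- fit$scores
  long <- expand.grid(mirna_id = rownames(scores), disease_name = colnames(scores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$score <- as.vector(unclass(scores))
  long$known_causal <- as.integer(as.vector(fit$net$adjacency) == 1L)
  rank_in <- apply(-unclass(scores), 2, rank, ties.method = "min")
  long$rank_within_disease <- as.vector(rank_in)
  long <- long[lex_order(long$disease_name, long$rank_within_disease, long$mirna_id), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
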