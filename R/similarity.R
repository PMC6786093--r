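#' Construct a similarity matrix object
#'
#' A square symmetric matrix with entries in `[0, 1]` and labelled rows and
#' columns. Entries may be `NA` where a similarity is undefined (for example
#' a disease that does not resolve in the ontology): `NA` means "no
#' evidence", not "dissimilar", and downstream integration falls back to the
#' topological kernel there.
#'
#' @param values Square numeric matrix.
#' @param labels Entity labels (row and column names).
#' @param kind One of `semantic`, `functional`, `gip`, `hpi`, `integrated`.
#' @return The matrix with dimnames set and a `kind` attribute, classed
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              kind = c("semantic", "functional", "gip",
                                       "hpi", "integrated")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  dimnames(values) <- list(labels, labels)
  finite <- !is.na(values)
  if (any(values[finite] < -1e-12 | values[finite] > 1 + 1e-12)) {
    stop_numeric("%s similarity has entries outside [0, 1]", kind)
  }
  values[finite] <- pmin(pmax(values[finite], 0), 1)
  asym <- abs(values - t(values))
  if (any(!is.na(asym)) && max(asym, na.rm = TRUE) > 1e-12) {
    stop_numeric("%s similarity is not symmetric", kind)
  }
  structure(values, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d x %d, %d undefined entries\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Semantic contribution profile of a disease
#'
#' Wang-style directed-acyclic-graph semantics on MeSH tree numbers: the
#' disease's own node(s) contribute 1, and each ancestor term contributes the
#' maximum over descending paths of `delta` per step. A disease with several
#' tree numbers takes the union of ancestor sets with the per-term maximum,
#' which preserves the unit self-contribution.
#'
#' @param ontology A `disease_ontology`.
#' @param disease Disease name (matched case-insensitively).
#' @param delta Contribution decay per edge, in (0, 1). Default 0.5.
#' @return Object of class `semantic_profile`: the disease, a named vector of
#'   ancestor-term contributions, and their sum `total_value`.
#' @export
semantic_profile <- function(ontology, disease, delta = 0.5) {
  stopifnot(is.numeric(delta), delta > 0, delta < 1)
  tns <- resolve_disease(ontology, disease)
  if (is.null(tns)) {
    stop(structure(class = c("mc_no_ontology", "mc_format_error", "error", "condition"),
                   list(message = sprintf("disease '%s' does not resolve in the ontology", disease),
                        call = sys.call())))
  }
  contributions <- numeric(0)
  for (tn in tns) {
    anc <- treenum_ancestors(tn)   # self first
    vals <- delta^(seq_along(anc) - 1)
    for (i in seq_along(anc)) {
      prev <- contributions[anc[i]]
      if (is.na(prev) || vals[i] > prev) contributions[anc[i]] <- vals[i]
    }
  }
  structure(list(disease = disease, contributions = contributions,
                 total_value = sum(contributions)),
            class = "semantic_profile")
}

#' Semantic similarity between two disease profiles
#'
#' The shared-ancestor ratio: contributions of terms present in both
#' profiles, summed from both sides, over the two total semantic values.
#'
#' @param p1,p2 `semantic_profile` objects built with the same `delta`.
#' @return A similarity in `[0, 1]`; 1 for identical profiles, 0 for
#'   profiles sharing no ancestor.
#' @export
disease_similarity <- function(p1, p2) {
  shared <- intersect(names(p1$contributions), names(p2$contributions))
  if (length(shared) == 0) return(0)
  sum(p1$contributions[shared] + p2$contributions[shared]) /
    (p1$total_value + p2$total_value)
}

#' Pairwise disease semantic similarity matrix
#'
#' Diseases that fail to resolve in the ontology get `NA` rows/columns
#' rather than zeros, so that integration can fall back to the interaction
#' kernel for them.
#'
#' @param ontology A `disease_ontology`.
#' @param diseases Character vector of disease names.
#' @inheritParams semantic_profile
#' @return A `similarity_matrix` of kind `semantic`.
#' @export
semantic_similarity_matrix <- function(ontology, diseases, delta = 0.5) {
  n <- length(diseases)
  profiles <- lapply(diseases, function(d) {
    tryCatch(semantic_profile(ontology, d, delta),
             mc_no_ontology = function(e) NULL)
  })
  ok <- !vapply(profiles, is.null, logical(1))
  values <- matrix(NA_real_, n, n)
  if (any(ok)) {
    prof <- profiles[ok]
    terms <- unique(unlist(lapply(prof, function(p) names(p$contributions))))
    C <- matrix(0, length(terms), length(prof), dimnames = list(terms, NULL))
    for (j in seq_along(prof)) {
      C[names(prof[[j]]$contributions), j] <- prof[[j]]$contributions
    }
    B <- (C > 0) + 0
    num <- crossprod(C, B) + crossprod(B, C)
    dv <- vapply(prof, function(p) p$total_value, numeric(1))
    sub <- num / outer(dv, dv, `+`)
    values[ok, ok] <- (sub + t(sub)) / 2   # remove float asymmetry
  }
  similarity_matrix(values, diseases, kind = "semantic")
}

#' miRNA functional similarity (best-match average)
#'
#' Two miRNAs are functionally similar when their associated disease sets
#' are semantically similar: each disease on one side is matched to its most
#' similar disease on the other side, and the matches are averaged over both
#' sides. miRNAs whose disease sets contain no semantically resolvable
#' disease get `NA` entries (undefined, not zero).
#'
#' @param net A `bipartite_network`; its columns must match the rows of
#'   `disease_sim`.
#' @param disease_sim A `similarity_matrix` over `net$diseases` (typically
#'   kind `semantic`, possibly with `NA` rows).
#' @return A `similarity_matrix` of kind `functional` over `net$mirnas`.
#' @export
functional_similarity <- function(net, disease_sim) {
  if (!identical(rownames(disease_sim), net$diseases)) {
    stop_usage("disease similarity labels do not match the network's diseases")
  }
  defined <- !apply(is.na(disease_sim), 1, all)
  sets <- lapply(seq_along(net$mirnas),
                 function(i) which(net$adjacency[i, ] == 1L & defined))
  m <- length(net$mirnas)
  values <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    Di <- sets[[i]]
    if (length(Di) == 0) next
    values[i, i] <- 1
    for (j in seq_len(m)) {
      if (j >= i) next
      Dj <- sets[[j]]
      if (length(Dj) == 0) next
      S <- disease_sim[Di, Dj, drop = FALSE]
      bma <- (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) /
        (length(Di) + length(Dj))
      values[i, j] <- values[j, i] <- bma
    }
  }
  similarity_matrix(values, net$mirnas, kind = "functional")
}

#' Gaussian interaction profile kernel
#'
#' Each entity's interaction profile is its binary row (miRNA side) or
#' column (disease side) of the causal adjacency matrix; the kernel is
#' `exp(-gamma * ||IP_i - IP_j||^2)` with the bandwidth normalised by the
#' mean squared profile norm: `gamma = bandwidth_scale / mean(||IP||^2)`.
#'
#' @param net A `bipartite_network`.
#' @param side `"mirna"` (rows) or `"disease"` (columns).
#' @param bandwidth_scale Positive bandwidth multiplier; default 1, the
#'   original interaction-profile kernel convention.
#' @return A `similarity_matrix` of kind `gip`; entries in (0, 1], unit
#'   diagonal.
#' @export
gip_kernel <- function(net, side = c("mirna", "disease"), bandwidth_scale = 1) {
  side <- match.arg(side)
  stopifnot(is.numeric(bandwidth_scale), bandwidth_scale > 0)
  P <- if (side == "mirna") net$adjacency else t(net$adjacency)
  storage.mode(P) <- "double"
  norms2 <- rowSums(P^2)
  mean_norm2 <- mean(norms2)
  if (mean_norm2 == 0) {
    stop_numeric("all interaction profiles are zero; kernel bandwidth undefined")
  }
  gamma <- bandwidth_scale / mean_norm2
  G <- P %*% t(P)
  d2 <- outer(norms2, norms2, `+`) - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_matrix(K, rownames(P), kind = "gip")
}

#' Hub promoted index
#'
#' Neighbourhood-overlap score over the bipartite graph:
#' `|N(i) inter N(j)| / min(|N(i)|, |N(j)|)`. Favouring the smaller degree in
#' the denominator promotes links towards hubs. Self-similarity is 1; pairs
#' where either entity has degree zero score 0.
#'
#' @inheritParams gip_kernel
#' @return A `similarity_matrix` of kind `hpi`.
#' @export
hub_promoted_index <- function(net, side = c("mirna", "disease")) {
  side <- match.arg(side)
  A <- if (side == "mirna") net$adjacency else t(net$adjacency)
  storage.mode(A) <- "double"
  inter <- A %*% t(A)
  deg <- rowSums(A)
  denom <- outer(deg, deg, pmin)
  H <- ifelse(denom > 0, inter / denom, 0)
  H <- (H + t(H)) / 2
  diag(H) <- 1
  similarity_matrix(H, rownames(A), kind = "hpi")
}

#' Write a similarity matrix to labelled TSV
#'
#' @param sim A `similarity_matrix`.
#' @param path Output path. Row and column headers are the entity names.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(entity = rownames(sim), unclass(sim)[,, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
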