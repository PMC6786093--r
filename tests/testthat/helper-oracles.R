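# Shared fixtures and naive brute-force oracles. Oracles are deliberately
# written as plain double loops / exhaustive enumerations, independent of the
# vectorized implementations they check.

toy_records <- function() {
  new_records(data.frame(
    mirna_id = c("hsa-mir-1", "hsa-mir-1", "hsa-mir-2"),
    disease_name = c("d1", "d2", "d2"),
    evidence_code = "Target", pmid = NA_integer_, causal = TRUE,
    stringsAsFactors = FALSE))
}

new_records <- function(df) {
  class(df) <- c("assoc_records", "data.frame")
  df
}

# small deterministic bipartite network from an explicit adjacency
net_from_adj <- function(A, mirnas = sprintf("hsa-mir-%d", seq_len(nrow(A))),
                         diseases = sprintf("disease %d", seq_len(ncol(A)))) {
  storage.mode(A) <- "integer"
  dimnames(A) <- list(mirnas, diseases)
  structure(list(mirnas = mirnas, diseases = diseases, adjacency = A),
            class = "bipartite_network")
}

random_net <- function(m, d, p = 0.5, seed = 1) {
  withr::local_seed(seed)
  A <- matrix(rbinom(m * d, 1, p), m, d)
  net_from_adj(A)
}

# two-level toy ontology: diseases at C01.01 / C01.02, plus one at the root
chain_ontology <- function() {
  mircausal:::new_disease_ontology(
    list("leaf one" = "C01.01", "leaf two" = "C01.02", "root term" = "C01",
         "far away" = "D02.01"))
}

oracle_gip <- function(A, side, bw = 1) {
  P <- if (side == "mirna") A else t(A)
  n <- nrow(P)
  gamma <- bw / mean(sapply(seq_len(n), function(i) sum(P[i, ]^2)))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  }
  K
}

oracle_hpi <- function(A, side) {
  P <- if (side == "mirna") A else t(A)
  n <- nrow(P)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Ni <- which(P[i, ] == 1); Nj <- which(P[j, ] == 1)
    H[i, j] <- if (i == j) 1 else if (min(length(Ni), length(Nj)) == 0) 0 else
      length(intersect(Ni, Nj)) / min(length(Ni), length(Nj))
  }
  H
}

# Wang-style semantic contribution by explicit path enumeration over prefixes
oracle_semantic_profile <- function(treenums, delta) {
  contrib <- numeric(0)
  for (tn in treenums) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
    for (k in seq_along(parts)) {
      term <- paste(parts[seq_len(k)], collapse = ".")
      val <- delta^(length(parts) - k)
      if (is.na(contrib[term]) || val > contrib[term]) contrib[term] <- val
    }
  }
  contrib
}

oracle_disease_sim <- function(tn1, tn2, delta) {
  c1 <- oracle_semantic_profile(tn1, delta)
  c2 <- oracle_semantic_profile(tn2, delta)
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

oracle_functional <- function(A, S) {
  m <- nrow(A)
  FS <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    Di <- which(A[i, ] == 1); Dj <- which(A[j, ] == 1)
    if (!length(Di) || !length(Dj)) next
    best_ij <- sapply(Di, function(d) max(S[d, Dj]))
    best_ji <- sapply(Dj, function(d) max(S[d, Di]))
    FS[i, j] <- (sum(best_ij) + sum(best_ji)) / (length(Di) + length(Dj))
  }
  FS
}

# exhaustive pairwise concordance with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

oracle_snp_count <- function(intervals, snps) {
  counts <- setNames(rep(0L, length(unique(intervals$mirna_id))),
                     sort(unique(intervals$mirna_id)))
  for (r in seq_len(nrow(intervals))) {
    for (s in seq_len(nrow(snps))) {
      if (snps$chrom[s] == intervals$chrom[r] &&
          snps$pos[s] >= intervals$start[r] && snps$pos[s] <= intervals$end[r]) {
        counts[intervals$mirna_id[r]] <- counts[intervals$mirna_id[r]] + 1L
      }
    }
  }
  counts
}

default_synth <- function(seed) {
  sim <- suppressMessages(generate_network(synthetic_spec(seed = seed)))
  sim$ontology <- generate_ontology(sim$network$diseases, sim$disease_blocks,
                                    seed = seed)
  sim
}
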