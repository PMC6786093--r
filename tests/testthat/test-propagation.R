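sim2 <- function(off, kind) {
  similarity_matrix(matrix(c(1, off, off, 1), 2), c("a", "b"), kind = kind)
}

test_that("similarity integration honours its limiting weights and hand case", {
  primary <- sim2(1 / 3, "functional")
  gip <- sim2(exp(-2), "gip")
  hpi <- sim2(1 / 2, "hpi")
  expect_equal(unclass(integrate_similarities(primary, gip, hpi, 1, 0)),
               unclass(primary), ignore_attr = TRUE)
  expect_equal(unclass(integrate_similarities(primary, gip, hpi, 0, 0)),
               unclass(gip), ignore_attr = TRUE)
  S <- integrate_similarities(primary, gip, hpi, 0.5, 0.5)
  expect_equal(S[1, 2], 0.5 * (0.5 * (1 / 3) + 0.5 * exp(-2)) + 0.5 * 0.5)
})

test_that("undefined primary entries fall back to the interaction kernel", {
  primary <- similarity_matrix(matrix(c(1, NA, NA, NA), 2), c("a", "b"), "functional")
  gip <- sim2(0.3, "gip")
  hpi <- sim2(0, "hpi")
  S <- integrate_similarities(primary, gip, hpi, 0.5, 0)
  expect_equal(S[1, 2], 0.3)        # undefined -> kernel value
  expect_equal(S[2, 2], 1)          # undefined diagonal -> kernel diagonal
  expect_false(anyNA(unclass(S)))
  bad <- similarity_matrix(matrix(c(1, 0, 0, 1), 2), c("x", "y"), "gip")
  expect_error(integrate_similarities(primary, bad, hpi), class = "mc_usage_error")
})

test_that("row normalisation yields a stochastic operator with self-loop fallback", {
  expect_equal(unclass(row_normalize(diag(3))), diag(3))
  expect_equal(unclass(row_normalize(matrix(1, 2, 2))), matrix(0.5, 2, 2))
  M <- diag(3); M[1, 2] <- 3
  W <- row_normalize(M)
  expect_equal(rowSums(unclass(W)), rep(1, 3))
  # an all-zero row becomes a unit self-loop, not a uniform row
  Z <- rbind(c(0, 0), c(1, 1))
  WZ <- unclass(row_normalize(Z))
  expect_equal(WZ[1, ], c(1, 0))
})

test_that("label propagation matches its closed form and limits", {
  W <- row_normalize(matrix(0.5, 2, 2))
  Y <- matrix(c(1, 0), 2, 1)
  expect_equal(label_propagate(W, Y, alpha = 0), Y, ignore_attr = TRUE)
  expect_equal(as.numeric(label_propagate(matrix(1, 1, 1), matrix(1), alpha = 0.7)),
               1, tolerance = 1e-5)
  F2 <- label_propagate(W, Y, alpha = 0.5, tol = 1e-10)
  expect_equal(as.numeric(F2), c(0.75, 0.25), tolerance = 1e-8)
  # closed-form oracle on random row-stochastic systems
  for (seed in 1:10) {
    withr::with_seed(seed, {
      W10 <- matrix(runif(100), 10)
      Y10 <- matrix(rbinom(30, 1, 0.3), 10)
    })
    W10 <- row_normalize(W10)
    alpha <- 0.6
    it <- label_propagate(W10, Y10, alpha, tol = 1e-8)
    closed <- (1 - alpha) * solve(diag(10) - alpha * unclass(W10)) %*% Y10
    expect_equal(unclass(it), closed, ignore_attr = TRUE, tolerance = 1e-7)
    expect_true(all(it >= 0 & it <= 1))
  }
  slow <- row_normalize(matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  expect_error(label_propagate(slow, matrix(c(1, 0), 2, 1), alpha = 0.99,
                               tol = 1e-14, max_iter = 3),
               class = "mc_numeric_error")
})

test_that("adding a known label never decreases any propagated score", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      W <- matrix(runif(36), 6)
      Y <- matrix(rbinom(24, 1, 0.3), 6, 4)
    })
    W <- row_normalize(W)
    zero_cells <- which(Y == 0, arr.ind = TRUE)
    base <- label_propagate(W, Y, 0.5, tol = 1e-12)
    flip <- zero_cells[1, , drop = FALSE]
    Y2 <- Y; Y2[flip] <- 1
    bumped <- label_propagate(W, Y2, 0.5, tol = 1e-12)
    # each solve carries its own stopping residual (~tol); allow that slack
    expect_true(all(bumped - base >= -1e-10))
  }
})

test_that("score fusion is the elementwise mean with shape checking", {
  a <- matrix(c(0, 1, 0.5, 0.2), 2)
  expect_equal(unclass(fuse_scores(a, a)), a, ignore_attr = TRUE)
  expect_equal(unclass(fuse_scores(matrix(0, 1, 1), matrix(1, 1, 1)))[1, 1], 0.5)
  expect_error(fuse_scores(a, matrix(0, 3, 2)), class = "mc_usage_error")
})

test_that("entity permutation permutes but does not change fused scores", {
  sim <- default_synth(5)
  net <- sim$network
  fit <- fit_causal_lp(net, NULL)
  withr::with_seed(2, {
    pm <- sample(length(net$mirnas)); pd <- sample(length(net$diseases))
  })
  perm <- structure(list(mirnas = net$mirnas[pm], diseases = net$diseases[pd],
                         adjacency = net$adjacency[pm, pd]),
                    class = "bipartite_network")
  fit_p <- fit_causal_lp(perm, NULL)
  expect_equal(unclass(fit_p$scores)[order(pm), order(pd)],
               unclass(fit$scores), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("candidate ranking is descending, deterministic and respects exclusions", {
  scores <- matrix(c(0.9, 0.5, 0.1,
                     0.5, 0.5, 0.3), nrow = 3,
                   dimnames = list(c("hsa-mir-1", "hsa-mir-2", "hsa-mir-3"),
                                   c("d one", "d two")))
  net <- net_from_adj(rbind(c(1, 0), c(0, 0), c(0, 1)),
                      rownames(scores), colnames(scores))
  ranked <- rank_candidates(scores, "d one", top_k = 3, exclude_known = FALSE, net = net)
  expect_equal(ranked$score, c(0.9, 0.5, 0.1))
  expect_equal(ranked$rank, 1:3)
  # tie at 0.5 in column two: lexicographic miRNA order breaks it
  tied <- rank_candidates(scores, "d two", top_k = 3, exclude_known = FALSE, net = net)
  expect_equal(tied$mirna_id, c("hsa-mir-1", "hsa-mir-2", "hsa-mir-3"))
  # known causal pair dropped when requested
  excl <- rank_candidates(scores, "d one", top_k = 3, exclude_known = TRUE, net = net)
  expect_equal(nrow(excl), 2)
  expect_false("hsa-mir-1" %in% excl$mirna_id)
  expect_error(rank_candidates(scores, "nonexistent", net = net),
               class = "mc_usage_error")
})
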