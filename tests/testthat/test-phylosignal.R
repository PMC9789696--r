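test_that("phylogenetic covariance matches path-depth arithmetic", {
  # 2 tips at depth t
  tr2 <- ape::read.tree(text = "(A:3,B:3);")
  C2 <- phylo_vcv(tr2)
  expect_equal(unname(C2), rbind(c(3, 0), c(0, 3)))
  # balanced 4-tip, all edges 1
  tr4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  C4 <- phylo_vcv(tr4, c("a", "b", "c", "d"))
  expect_equal(unname(diag(C4)), rep(2, 4))
  expect_equal(C4["a", "b"], 1)
  expect_equal(C4["a", "c"], 0)
  # random 16-tip tree vs brute-force MRCA-depth oracle
  set.seed(3)
  tr <- ape::rtree(16)
  C <- phylo_vcv(tr)
  depth <- ape::node.depth.edgelength(tr)
  oracle <- patristic_oracle(tr)
  tipd <- depth[seq_len(16)]
  Cor <- outer(tipd[match(rownames(C), tr$tip.label)],
               tipd[match(colnames(C), tr$tip.label)], "+") - oracle[rownames(C), colnames(C)]
  Cor <- Cor / 2
  expect_equal(C, Cor, tolerance = 1e-12, ignore_attr = TRUE)
  eg <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(eg > -1e-10))
  expect_error(phylo_vcv(tr, c("a", "nope")), "absent")
})

test_that("Blomberg's K matches a hand GLS evaluation on a 4-tip case", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  x <- c(a = 1.2, b = 0.8, c = -0.9, d = -1.4)
  # hand evaluation with explicit matrix arithmetic
  C <- rbind(c(2, 1, 0, 0), c(1, 2, 0, 0), c(0, 0, 2, 1), c(0, 0, 1, 2))
  dimnames(C) <- list(names(x), names(x))
  iC <- solve(C)
  one <- rep(1, 4)
  ahat <- drop(one %*% iC %*% x) / drop(one %*% iC %*% one)
  mse0 <- sum((x - ahat)^2) / 3
  mse <- drop(t(x - ahat) %*% iC %*% (x - ahat)) / 3
  K_hand <- (mse0 / mse) / ((sum(diag(C)) - 4 / sum(iC)) / 3)
  expect_equal(blomberg_k(tr, x), K_hand, tolerance = 1e-10)
  expect_error(blomberg_k(tr, c(a = 1, b = 1, c = 1, d = 1)), "constant")
})

test_that("K is affine-invariant and near 1 under Brownian motion", {
  set.seed(10)
  tr <- ape::rcoal(32)
  C <- phylo_vcv(tr)
  x <- draw_lambda_trait(C, 1)
  expect_equal(blomberg_k(tr, 5 * x + 3), blomberg_k(tr, x), tolerance = 1e-9)
  K <- replicate(150, blomberg_k(tr, draw_lambda_trait(C, 1), C = C))
  expect_gt(mean(K), 0.85)
  expect_lt(mean(K), 1.15)
  # permuted tips lose signal
  Kp <- replicate(150, blomberg_k(tr, setNames(sample(x), names(x)), C = C))
  expect_lt(mean(Kp), 0.6)
})

test_that("K permutation test is reproducible and detects strong signal", {
  set.seed(12)
  tr <- ape::rcoal(32)
  C <- phylo_vcv(tr)
  x <- draw_lambda_trait(C, 1)
  r1 <- k_permutation_p(tr, x, n_perm = 200, seed = 99, C = C)
  r2 <- k_permutation_p(tr, x, n_perm = 200, seed = 99, C = C)
  expect_identical(r1$K_perm, r2$K_perm)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  # power: BM traits give small p in most replicates
  ps <- replicate(40, k_permutation_p(tr, draw_lambda_trait(C, 1),
                                      n_perm = 200, C = C)$p)
  expect_gte(mean(ps <= 0.05), 0.9)
  expect_error(k_permutation_p(tr, x, n_perm = 0), "n_perm")
})

test_that("lambda transform identities hold and the MLE dominates the null", {
  set.seed(13)
  tr <- ape::rcoal(24)
  C <- phylo_vcv(tr)
  # lambda = 1 leaves C unchanged; lambda = 0 zeroes off-diagonals
  C1 <- C * 1; diag(C1) <- diag(C)
  expect_equal(C1, C)
  C0 <- C * 0; diag(C0) <- diag(C)
  expect_true(all(C0[upper.tri(C0)] == 0))
  x <- draw_lambda_trait(C, 0.7)
  fit <- pagel_lambda(tr, x, C = C)
  expect_gte(fit$logL_lambda, fit$logL_0 - 1e-6)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
  expect_gte(fit$p, 0)
  expect_lte(fit$p, 1)
  # boundary dominance
  ll <- function(l) jawspace:::lambda_loglik(l, C, x)
  expect_gte(fit$logL_lambda, ll(0) - 1e-6)
  expect_gte(fit$logL_lambda, ll(1) - 1e-6)
})

test_that("lambda estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(14)
  tr <- ape::rcoal(32)
  x <- draw_lambda_trait(phylo_vcv(tr), 0.8)
  fit <- pagel_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(fit$lambda, min(1, ref$lambda), tolerance = 0.02)
  kref <- phytools::phylosig(tr, x, method = "K")
  expect_equal(blomberg_k(tr, x), as.numeric(kref), tolerance = 1e-6)
})

test_that("patristic distances match the path-sum oracle", {
  tr2 <- ape::read.tree(text = "(A:3,B:3);")
  expect_equal(phylogenetic_distances(tr2)["A", "B"], 6)
  set.seed(15)
  tr <- ape::rtree(12)
  D <- phylogenetic_distances(tr)
  expect_equal(D, patristic_oracle(tr)[rownames(D), colnames(D)],
               tolerance = 1e-12)
  # ultrametric: all root-spanning pairs equal
  tru <- ape::rcoal(10)
  Du <- phylogenetic_distances(tru)
  root_kids <- tru$edge[tru$edge[, 1] == 11, 2]
  left <- jawspace:::tips_under(tru, root_kids[1])
  right <- jawspace:::tips_under(tru, root_kids[2])
  span <- as.vector(Du[left, right])
  expect_lt(diff(range(span)), 1e-9)
})

test_that("Mantel r is symmetric, bounded, and exact on identical matrices", {
  set.seed(16)
  M1 <- as.matrix(dist(matrix(rnorm(40), 20)))
  M2 <- as.matrix(dist(matrix(rnorm(40), 20)))
  ids <- paste0("t", 1:20)
  dimnames(M1) <- dimnames(M2) <- list(ids, ids)
  a <- mantel_test(M1, M2, n_perm = 99, seed = 1)
  b <- mantel_test(M2, M1, n_perm = 99, seed = 1)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_lte(abs(a$r), 1)
  self <- mantel_test(M1, M1, n_perm = 199, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)
  expect_error(mantel_test(M1, M2[1:19, 1:19]), "absent")
})

test_that("Mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  M1 <- as.matrix(dist(matrix(rnorm(30), 15)))
  M2 <- as.matrix(dist(matrix(rnorm(30), 15)))
  mine <- mantel_test(M1, M2, n_perm = 1)
  ref <- vegan::mantel(as.dist(M1), as.dist(M2), permutations = 9)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Monte-Carlo Mantel p tracks the exact enumeration at n = 5", {
  set.seed(18)
  M1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  M2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  ids <- paste0("t", 1:5)
  dimnames(M1) <- dimnames(M2) <- list(ids, ids)
  ex <- mantel_test(M1, M2, exact = TRUE)
  expect_equal(ex$n_perm, 120L)
  mc <- mantel_test(M1, M2, n_perm = 2000, seed = 3)
  se <- sqrt(ex$p * (1 - ex$p) / 2000)
  expect_lt(abs(mc$p - ex$p), 2 * se + 1 / 2001)
})
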