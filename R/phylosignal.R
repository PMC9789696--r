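#' Phylogenetic covariance matrix of a time tree
#'
#' C_ij is the shared path length from the root to the most recent common
#' ancestor of tips i and j; diag(C) is each tip's root-to-tip depth. This is
#' the Brownian-motion covariance structure used by K and lambda.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxa optional taxon ids; the matrix is restricted and ordered to
#'   them (all must be tips).
#' @return symmetric PSD matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree, taxa = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) stop("tips absent from tree: ", paste(missing, collapse = ", "))
    C <- C[taxa, taxa]
  }
  C
}

# align a named trait vector to matrix/tree order
align_trait <- function(trait, ids) {
  if (is.null(names(trait))) {
    if (length(trait) != length(ids)) stop("unnamed trait of wrong length")
    names(trait) <- ids
    return(trait)
  }
  missing <- setdiff(ids, names(trait))
  if (length(missing)) stop("trait missing for: ", paste(missing, collapse = ", "))
  trait[ids]
}

#' Blomberg's K statistic
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically corrected mean (ordinary vs GLS error under the tree's
#' Brownian covariance) to its Brownian-motion expectation:
#' \deqn{K = \frac{MSE_0 / MSE}{[tr(C) - n/\sum C^{-1}] / (n-1)}}
#' with the phylogenetic mean \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)}.
#' K is about 1 for traits evolving by Brownian motion on the tree and falls
#' below 1 when relatives resemble each other less than BM predicts.
#'
#' @param tree rooted `phylo` with branch lengths (or precomputed covariance
#'   via `C`).
#' @param trait named numeric vector over the tips.
#' @param C optional precomputed covariance matrix (overrides `tree`).
#' @return K (non-negative scalar).
#' @export
blomberg_k <- function(tree, trait, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  x <- align_trait(trait, rownames(C))
  n <- length(x)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips")
  if (stats::sd(x) == 0) stop("constant trait: phylogenetic signal undefined")
  invC <- tryCatch(solve(C), error = function(e) {
    stop("singular phylogenetic covariance; enforce a minimum branch length")
  })
  k_from_invC(x, C, invC)
}

k_from_invC <- function(x, C, invC) {
  n <- length(x)
  ahat <- sum(invC %*% x) / sum(invC)
  xc <- x - ahat
  mse0 <- sum(xc^2) / (n - 1)
  mse <- drop(crossprod(xc, invC %*% xc)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(invC)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation p-value for Blomberg's K
#'
#' Tip values are shuffled across the tips of the fixed tree; the one-tailed
#' p-value is (1 + #\{permuted K >= observed K\}) / (n_perm + 1), testing for
#' more signal than a random tip arrangement.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param trait named numeric vector over the tips.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param C optional precomputed covariance matrix.
#' @return list with `K`, `p`, `n_perm`, and the permuted values `K_perm`.
#' @export
k_permutation_p <- function(tree, trait, n_perm = 1000L, seed = NULL, C = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(C)) C <- phylo_vcv(tree)
  x <- align_trait(trait, rownames(C))
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant trait: phylogenetic signal undefined")
  invC <- solve(C)
  K_obs <- k_from_invC(x, C, invC)
  if (!is.null(seed)) set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(x), numeric(n))
  # vectorized K over permutation columns
  s <- sum(invC)
  ahat <- colSums(invC %*% P) / s
  Pc <- sweep(P, 2L, ahat)
  mse0 <- colSums(Pc^2)
  mse <- colSums(Pc * (invC %*% Pc))
  expected <- (sum(diag(C)) - n / s) / (n - 1)
  K_perm <- (mse0 / mse) / expected
  list(K = K_obs, p = (1 + sum(K_perm >= K_obs)) / (n_perm + 1),
       n_perm = as.integer(n_perm), K_perm = K_perm)
}

# profile log-likelihood of the lambda model at a given lambda
lambda_loglik <- function(lambda, C, x) {
  n <- length(x)
  V <- C * lambda
  diag(V) <- diag(C)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  z <- backsolve(L, forwardsolve(t(L), x))          # V^{-1} x
  o <- backsolve(L, forwardsolve(t(L), rep(1, n)))  # V^{-1} 1
  mu <- sum(o * x) / sum(o)
  q <- sum((x - mu) * backsolve(L, forwardsolve(t(L), x - mu)))
  sigma2 <- q / n
  if (sigma2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Lambda multiplies the off-diagonal elements of the Brownian covariance C:
#' lambda = 1 is pure Brownian motion, lambda = 0 is phylogenetic
#' independence. The profile log-likelihood (GLS mean and ML variance
#' substituted analytically) is maximized over [0, lambda_max]; the p-value
#' is a likelihood-ratio test of lambda-hat against lambda = 0 on chi-square
#' with 1 df.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param trait named numeric vector over the tips.
#' @param lambda_max upper search bound (default 1, for which C(lambda) is
#'   guaranteed positive semi-definite).
#' @param C optional precomputed covariance matrix.
#' @return list with `lambda`, `sigma2`, `logL_lambda`, `logL_0`, `p`.
#' @export
pagel_lambda <- function(tree, trait, lambda_max = 1, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  x <- align_trait(trait, rownames(C))
  n <- length(x)
  if (n < 4L) stop("lambda estimation needs at least 4 tips")
  if (stats::sd(x) == 0) stop("constant trait: phylogenetic signal undefined")
  f <- function(l) lambda_loglik(l, C, x)
  opt <- stats::optimize(f, interval = c(0, lambda_max), maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, f(0)), c(lambda_max, f(lambda_max)))
  best <- cand[which.max(cand[, 2L]), ]
  if (!is.finite(best[2L])) stop("lambda likelihood did not converge (singular covariance)")
  lam <- best[1L]; logL <- best[2L]
  logL0 <- f(0)
  # recover sigma2 at the optimum
  V <- C * lam; diag(V) <- diag(C)
  L <- chol(V)
  o <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  mu <- sum(o * x) / sum(o)
  sigma2 <- sum((x - mu) * backsolve(L, forwardsolve(t(L), x - mu))) / n
  stat <- max(0, 2 * (logL - logL0))
  list(lambda = lam, sigma2 = sigma2, logL_lambda = logL, logL_0 = logL0,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the tip-to-tip path, the phylogenetic
#' distances correlated against phenetic distances in the Mantel test.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param taxa optional taxon ids to restrict/order the matrix to.
#' @return symmetric matrix with tip-label dimnames.
#' @export
phylogenetic_distances <- function(tree, taxa = NULL) {
  D <- stats::cophenetic(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(D))
    if (length(missing)) stop("tips absent from tree: ", paste(missing, collapse = ", "))
    D <- D[taxa, taxa]
  }
  (D + t(D)) / 2
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices over the
#' same taxa; significance comes from simultaneous row/column permutation of
#' the second matrix. Used here to correlate phenetic (morphospace) and
#' phylogenetic (patristic) distances: a low correlation indicates
#' morphological convergence (homoplasy) decoupling shape from phylogeny.
#'
#' @param D1,D2 symmetric distance matrices; if both have dimnames, D2 is
#'   aligned to D1's taxon order.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param method correlation type, "pearson" (default) or "spearman".
#' @param alternative "two.sided" (default) or "greater".
#' @param exact if TRUE (n <= 7 only), enumerate all n! permutations and
#'   return the exact tail probability instead of a Monte-Carlo estimate.
#' @return a `mantel_result`: list with `r`, `p`, `n_perm`, `method`,
#'   `alternative`, and the permuted statistics `r_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 1000L, seed = NULL,
                        method = c("pearson", "spearman"),
                        alternative = c("two.sided", "greater"),
                        exact = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    missing <- setdiff(rownames(D1), rownames(D2))
    if (length(missing)) stop("taxa absent from D2: ", paste(missing, collapse = ", "))
    D2 <- D2[rownames(D1), rownames(D1)]
  } else if (!all(dim(D1) == dim(D2))) {
    stop("distance matrices differ in size")
  }
  n <- nrow(D1)
  if (n < 4L) stop("Mantel test needs at least 4 taxa")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  corfun <- function(v2) stats::cor(v1, v2, method = method)
  r_obs <- corfun(D2[ut])
  tail_count <- function(r_perm) {
    if (alternative == "two.sided") sum(abs(r_perm) >= abs(r_obs) - 1e-12)
    else sum(r_perm >= r_obs - 1e-12)
  }
  if (exact) {
    if (n > 7L) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) corfun(D2[p, p][ut]), numeric(1))
    p <- tail_count(r_perm) / length(perms)
    n_perm <- length(perms)
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      corfun(D2[p, p][ut])
    }, numeric(1))
    p <- (1 + tail_count(r_perm)) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm),
                 method = method, alternative = alternative, r_perm = r_perm,
                 exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test (", x$method, ", ", x$alternative, "): r = ",
      format(x$r, digits = 4), ", p = ", format(x$p, digits = 4),
      " (", if (x$exact) "exact, " else "", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Permutation p-value for Pagel's lambda
#'
#' Literal-reading companion to the likelihood-ratio test: tip values are
#' shuffled and lambda re-estimated, with p = (1 + #\{lambda_perm >=
#' lambda_obs\}) / (n_perm + 1).
#'
#' @inheritParams k_permutation_p
#' @param lambda_max upper search bound passed to [pagel_lambda()].
#' @return list with `lambda`, `p`, `n_perm`.
#' @export
lambda_permutation_p <- function(tree, trait, n_perm = 1000L, seed = NULL,
                                 lambda_max = 1, C = NULL) {
  if (is.null(C)) C <- phylo_vcv(tree)
  x <- align_trait(trait, rownames(C))
  obs <- pagel_lambda(tree, x, lambda_max = lambda_max, C = C)
  if (!is.null(seed)) set.seed(seed)
  lam_perm <- vapply(seq_len(n_perm), function(i) {
    xp <- stats::setNames(sample(x), names(x))
    pagel_lambda(tree, xp, lambda_max = lambda_max, C = C)$lambda
  }, numeric(1))
  list(lambda = obs$lambda, p = (1 + sum(lam_perm >= obs$lambda)) / (n_perm + 1),
       n_perm = as.integer(n_perm))
}
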