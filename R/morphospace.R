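#' Fit a PCA morphospace on the coefficient matrix
#'
#' Deterministic SVD-based principal component analysis of the taxa x
#' features matrix of normalized Fourier coefficients. Covariance PCA
#' (centred, unscaled) is the default since coefficients share a scale after
#' first-ellipse normalization; zero-variance columns (b1, c1) are tolerated.
#' Axis signs are fixed so the largest-magnitude loading of each axis is
#' positive, making runs reproducible.
#'
#' @param X numeric matrix, taxa in rows (rownames = taxon ids), features in
#'   columns.
#' @param center center columns (default TRUE).
#' @param scale divide columns by their standard deviation (default FALSE;
#'   zero-variance columns are left unscaled).
#' @return a `morphospace`: list with `mean_vector`, `scale` (divisors or
#'   NULL), `axes` (features x r orthonormal loadings), `eigenvalues`,
#'   `variance_proportions`, `scores` (taxa x r), `feature_names`.
#' @export
fit_pca <- function(X, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("PCA needs at least 3 taxa")
  if (is.null(rownames(X))) rownames(X) <- paste0("t", seq_len(n))
  mu <- if (center) colMeans(X) else rep(0, p)
  Xc <- sweep(X, 2L, mu)
  sc <- NULL
  if (scale) {
    sc <- apply(Xc, 2L, stats::sd)
    sc[sc == 0] <- 1
    Xc <- sweep(Xc, 2L, sc, "/")
  }
  sv <- svd(Xc)
  r <- min(n - 1L, p)
  d <- sv$d[seq_len(r)]
  eig <- d^2 / (n - 1L)
  eig[eig < 0] <- 0
  axes <- sv$v[, seq_len(r), drop = FALSE]
  # deterministic sign: largest |loading| positive per axis
  for (j in seq_len(r)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) {
      axes[, j] <- -axes[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(d, r, r)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(r)))
  dimnames(axes) <- list(colnames(X), paste0("PC", seq_len(r)))
  structure(list(mean_vector = mu, scale = sc, axes = axes, eigenvalues = eig,
                 variance_proportions = if (sum(eig) > 0) eig / sum(eig) else eig,
                 scores = scores, feature_names = colnames(X)),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  vp <- x$variance_proportions
  k <- min(3L, length(vp))
  cat("<morphospace> ", nrow(x$scores), " taxa, ", length(vp), " axes; ",
      paste(sprintf("PC %d (%.0f%% of variance)", seq_len(k), 100 * vp[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variance table of a morphospace
#' @param ms a `morphospace`.
#' @return data.frame with `axis`, `eigenvalue`, `proportion`,
#'   `cumulative`, and a `label` column in the reporting style
#'   "PC 1 (59\% of variance)".
#' @export
variance_table <- function(ms) {
  vp <- ms$variance_proportions
  data.frame(axis = paste0("PC", seq_along(vp)),
             eigenvalue = ms$eigenvalues,
             proportion = vp,
             cumulative = cumsum(vp),
             label = sprintf("PC %d (%.0f%% of variance)", seq_along(vp), 100 * vp))
}

#' Project a shape-feature vector into a fitted morphospace
#'
#' `scores = axes^T (vector - mean)`, so taxa already in the fit project onto
#' their stored scores; vectors not in the fit are placed passively
#' (leave-out placement of an unknown).
#'
#' @param ms a `morphospace`.
#' @param v shape-feature vector (length must match the fit).
#' @return PC-score vector.
#' @export
project_shape <- function(ms, v) {
  if (length(v) != length(ms$mean_vector)) {
    stop("vector length ", length(v), " does not match morphospace (",
         length(ms$mean_vector), ")")
  }
  vc <- v - ms$mean_vector
  if (!is.null(ms$scale)) vc <- vc / ms$scale
  drop(crossprod(ms$axes, vc))
}

#' Reconstruct the outline at a morphospace position
#'
#' Maps PC coordinates back to a coefficient vector
#' (mean + sum coords_i * axis_i) and traces the corresponding outline —
#' this is the machinery behind background shape grids on morphospace plots.
#'
#' @param ms a `morphospace`.
#' @param coords PC-score vector (length <= number of axes; shorter vectors
#'   hold the remaining axes at 0).
#' @param n_points points to trace (default 300).
#' @return an `outline`.
#' @export
reconstruct_shape <- function(ms, coords, n_points = 300L) {
  r <- ncol(ms$axes)
  if (length(coords) > r) stop("coords dimension exceeds number of axes")
  delta <- drop(ms$axes[, seq_along(coords), drop = FALSE] %*% coords)
  if (!is.null(ms$scale)) delta <- delta * ms$scale
  inverse_efa(vector_to_coeffs(ms$mean_vector + delta), n_points = n_points)
}

#' Phenetic distance matrix in morphospace
#'
#' Euclidean distances between PC-score vectors. With all PCs (the default)
#' this equals the Euclidean distance between centred coefficient vectors
#' (orthonormal isometry).
#'
#' @param ms a `morphospace`.
#' @param pcs which PCs to use (default: all).
#' @return symmetric distance matrix with taxon dimnames.
#' @export
phenetic_distances <- function(ms, pcs = NULL) {
  S <- ms$scores
  if (!is.null(pcs)) S <- S[, pcs, drop = FALSE]
  D <- as.matrix(stats::dist(S))
  (D + t(D)) / 2
}
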