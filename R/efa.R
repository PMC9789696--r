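#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes the discrete elliptic Fourier coefficients (Kuhl & Giardina) of a
#' closed polygonal outline: x(t) and y(t) are expanded as Fourier series in
#' arc length t over the perimeter T, giving per-harmonic quadruples
#' \eqn{(a_n, b_n, c_n, d_n)} from the x- and y-increments of the chain. The
#' formulas are exact for the piecewise-linear curve through the points, so
#' uneven point spacing is handled correctly.
#'
#' @param x an `outline`.
#' @param n_harmonics number of harmonics N (default 25).
#' @return an `efa_decomposition`: list with `taxon_id`, `clade`,
#'   `n_harmonics`, `coeffs` (N x 4 matrix, columns a, b, c, d), `dc`
#'   (A0, C0 centroid terms), and `norm_record`.
#' @export
efa_decompose <- function(x, n_harmonics = 25L) {
  N <- as.integer(n_harmonics)
  pts <- x$points
  k <- nrow(pts)
  if (k < 2L * N + 1L) {
    stop("outline '", x$taxon_id, "': ", k, " points cannot support ", N,
         " harmonics (need >= ", 2L * N + 1L, ", Nyquist limit)")
  }
  dxy <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
  dt <- sqrt(rowSums(dxy^2))
  if (any(dt == 0)) stop("outline '", x$taxon_id, "': repeated consecutive points")
  t1 <- cumsum(dt)                 # arc length at segment ends
  t0 <- c(0, t1[-k])               # arc length at segment starts
  T <- t1[k]
  # DC terms: arc-length mean of the piecewise-linear x(t), y(t)
  dc <- colSums((pts + dxy / 2) * dt) / T
  # harmonic terms: for each n, T/(2 pi^2 n^2) * sum slope * d(cos|sin)
  w <- 2 * pi * outer(1:N, t1 / T)          # N x k phase at segment ends
  w0 <- 2 * pi * outer(1:N, t0 / T)
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  slope_x <- dxy[, 1L] / dt
  slope_y <- dxy[, 2L] / dt
  fac <- T / (2 * pi^2 * (1:N)^2)
  a <- fac * as.vector(dcos %*% slope_x)
  b <- fac * as.vector(dsin %*% slope_x)
  cc <- fac * as.vector(dcos %*% slope_y)
  d <- fac * as.vector(dsin %*% slope_y)
  coeffs <- cbind(a = a, b = b, c = cc, d = d)
  if (any(!is.finite(coeffs))) stop("non-finite Fourier coefficients")
  structure(list(taxon_id = x$taxon_id, clade = x$clade, n_harmonics = N,
                 coeffs = coeffs, dc = dc,
                 norm_record = list(normalized = FALSE, scale_factor = NA_real_,
                                    rotation = NA_real_, start_phase = NA_real_)),
            class = "efa_decomposition")
}

#' @export
print.efa_decomposition <- function(x, ...) {
  cat("<efa_decomposition> ", x$taxon_id, ", ", x$n_harmonics, " harmonics, ",
      if (isTRUE(x$norm_record$normalized)) "normalized" else "raw", "\n", sep = "")
  invisible(x)
}

# rotate coefficient pairs: shape rotation by -psi, start-point shift theta
transform_coeffs <- function(coeffs, psi, theta, scale) {
  N <- nrow(coeffs)
  out <- coeffs
  cp <- cos(psi); sp <- sin(psi)
  for (n in seq_len(N)) {
    M <- matrix(coeffs[n, ], 2L, 2L, byrow = TRUE)  # [a b; c d]
    ct <- cos(n * theta); st <- sin(n * theta)
    M2 <- rbind(c(cp, sp), c(-sp, cp)) %*% M %*% rbind(c(ct, -st), c(st, ct))
    out[n, ] <- c(M2[1L, ], M2[2L, ])
  }
  out / scale
}

#' Normalize an elliptic Fourier decomposition
#'
#' Standard first-ellipse normalization: the starting point is shifted to the
#' first-harmonic semi-major axis, the shape is rotated so that axis lies
#' along x, and all coefficients are divided by the semi-major axis length.
#' After normalization the first harmonic satisfies a1 = 1, b1 = c1 = 0, and
#' d1 (signed by travel direction) is the first-ellipse aspect ratio, so size,
#' rotation, and starting point are removed. The residual half-period
#' ambiguity of the starting point is resolved deterministically by picking,
#' of the two candidate normalizations, the lexicographically larger
#' coefficient vector.
#'
#' @param decomp an unnormalized `efa_decomposition`.
#' @return the normalized `efa_decomposition`; `norm_record` stores the scale
#'   factor, rotation and start-phase that were removed, and the original dc
#'   offset (dc is reset to the origin).
#' @export
efa_normalize <- function(decomp) {
  if (isTRUE(decomp$norm_record$normalized)) return(decomp)
  co <- decomp$coeffs
  a1 <- co[1L, 1L]; b1 <- co[1L, 2L]; c1 <- co[1L, 3L]; d1 <- co[1L, 4L]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-24) stop("degenerate first harmonic")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # pick theta giving the SEMI-MAJOR axis at the start point
  len <- function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }
  if (len(theta + pi / 2) > len(theta)) theta <- theta + pi / 2
  cand <- lapply(c(theta, theta + pi), function(th) {
    as <- a1 * cos(th) + b1 * sin(th)
    cs <- c1 * cos(th) + d1 * sin(th)
    psi <- atan2(cs, as)
    E <- sqrt(as^2 + cs^2)
    if (E < 1e-12) stop("degenerate first-harmonic ellipse")
    list(coeffs = transform_coeffs(co, psi, th, E), psi = psi, theta = th, E = E)
  })
  # deterministic tie-break between the two start-point branches
  v1 <- as.vector(t(cand[[1L]]$coeffs)); v2 <- as.vector(t(cand[[2L]]$coeffs))
  diff <- v1 - v2
  first <- which(abs(diff) > 1e-9)[1L]
  pick <- if (is.na(first) || diff[first] > 0) cand[[1L]] else cand[[2L]]
  decomp$coeffs <- pick$coeffs
  decomp$coeffs[1L, 2L:3L] <- 0     # b1, c1 exactly zero by construction
  decomp$norm_record <- list(normalized = TRUE, scale_factor = pick$E,
                             rotation = pick$psi, start_phase = pick$theta,
                             dc_original = decomp$dc)
  decomp$dc <- c(0, 0)
  decomp
}

#' Per-harmonic power profile
#'
#' Harmonic power \eqn{P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2} and its
#' cumulative proportion \eqn{F_n}, a standard measure of how much shape
#' information the first n harmonics retain.
#'
#' @param decomp an `efa_decomposition`.
#' @return a `harmonic_power_profile`: data.frame with columns `harmonic`,
#'   `power`, `cumulative` (F_N = 1 exactly).
#' @export
harmonic_power <- function(decomp) {
  P <- rowSums(decomp$coeffs^2) / 2
  total <- sum(P)
  if (total <= 0) stop("all-zero decomposition has no harmonic power")
  F <- cumsum(P) / total
  F[length(F)] <- 1
  structure(data.frame(harmonic = seq_along(P), power = P, cumulative = F),
            class = c("harmonic_power_profile", "data.frame"))
}

#' Minimal number of harmonics reaching a cumulative-power threshold
#'
#' @param profile a `harmonic_power_profile`.
#' @param threshold required cumulative power proportion (default 0.99, the
#'   conventional shape-information cut-off).
#' @return smallest n with F_n >= threshold.
#' @export
choose_harmonics <- function(profile, threshold = 0.99) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  hit <- which(profile$cumulative >= threshold - 1e-12)
  if (!length(hit)) {
    stop("cumulative power never reaches ", threshold,
         "; increase the number of harmonics")
  }
  profile$harmonic[hit[1L]]
}

#' Reconstruct an outline from an elliptic Fourier decomposition
#'
#' Traces the truncated Fourier series at `n_points` equally spaced
#' parameter values. With all harmonics this reproduces the source outline up
#' to discretization error; with fewer it gives a smoothed shape.
#'
#' @param decomp an `efa_decomposition`.
#' @param n_points number of points to trace (default 300).
#' @param n_harmonics number of harmonics to use (default: all).
#' @return an `outline`. A degenerate (all-zero-coefficient) decomposition
#'   yields a single repeated point, returned with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
inverse_efa <- function(decomp, n_points = 300L, n_harmonics = decomp$n_harmonics) {
  N <- as.integer(n_harmonics)
  if (N > decomp$n_harmonics) stop("n_harmonics exceeds decomposition order")
  tt <- 2 * pi * (0:(n_points - 1L)) / n_points
  co <- decomp$coeffs
  xs <- rep(decomp$dc[1L], n_points)
  ys <- rep(decomp$dc[2L], n_points)
  for (n in seq_len(N)) {
    cn <- cos(n * tt); sn <- sin(n * tt)
    xs <- xs + co[n, 1L] * cn + co[n, 2L] * sn
    ys <- ys + co[n, 3L] * cn + co[n, 4L] * sn
  }
  pts <- cbind(xs, ys)
  if (max(dist(pts[c(1L, ceiling(n_points / 3), ceiling(2 * n_points / 3)), ])) < 1e-12) {
    warning("degenerate reconstruction: all coefficients ~0, single point")
    out <- structure(list(taxon_id = decomp$taxon_id, points = pts,
                          clade = decomp$clade, source = "inverse_efa"),
                     class = "outline")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  outline(pts, taxon_id = decomp$taxon_id, clade = decomp$clade,
          source = "inverse_efa")
}

#' Flatten a normalized decomposition to a shape-feature vector
#'
#' Fixed order (a1, b1, c1, d1, a2, ...), length 4 N. The entries pinned by
#' normalization (b1, c1) are retained; they carry zero variance and are
#' harmless to the ordination while keeping the vector invertible.
#'
#' @param decomp a normalized `efa_decomposition`.
#' @param n_harmonics harmonics to keep (default: all).
#' @return named numeric vector (a1, b1, c1, d1, a2, ...).
#' @export
coeffs_to_vector <- function(decomp, n_harmonics = decomp$n_harmonics) {
  if (!isTRUE(decomp$norm_record$normalized)) {
    stop("coeffs_to_vector requires a normalized decomposition")
  }
  N <- as.integer(n_harmonics)
  if (N > decomp$n_harmonics) stop("n_harmonics exceeds decomposition order")
  v <- as.vector(t(decomp$coeffs[seq_len(N), , drop = FALSE]))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), N), rep(seq_len(N), each = 4L))
  v
}

#' Rebuild a decomposition from a shape-feature vector
#' @param v numeric vector of length 4 N in (a1, b1, c1, d1, a2, ...) order.
#' @param taxon_id id for the rebuilt decomposition.
#' @return a normalized-form `efa_decomposition` centred at the origin.
#' @export
vector_to_coeffs <- function(v, taxon_id = "reconstruction") {
  if (length(v) %% 4L != 0L) stop("vector length must be a multiple of 4")
  N <- length(v) %/% 4L
  coeffs <- matrix(v, N, 4L, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c", "d")))
  structure(list(taxon_id = taxon_id, clade = "unknown", n_harmonics = N,
                 coeffs = coeffs, dc = c(0, 0),
                 norm_record = list(normalized = TRUE, scale_factor = 1,
                                    rotation = 0, start_phase = 0)),
            class = "efa_decomposition")
}

#' Decompose and normalize every outline in a set
#' @param x a prepared `outline_set` (common point count).
#' @param n_harmonics harmonics per outline (default 25).
#' @return named list of normalized `efa_decomposition` objects.
#' @export
efa_decompose_set <- function(x, n_harmonics = 25L) {
  lapply(x$outlines, function(o) efa_normalize(efa_decompose(o, n_harmonics)))
}

#' Assemble the taxa-by-coefficients matrix for ordination
#' @param decomps list of normalized decompositions (e.g. from
#'   [efa_decompose_set()]).
#' @param n_harmonics harmonics to keep.
#' @return numeric matrix, one row per taxon, 4 N columns.
#' @export
efa_matrix <- function(decomps, n_harmonics = decomps[[1L]]$n_harmonics) {
  rows <- lapply(decomps, coeffs_to_vector, n_harmonics = n_harmonics)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(decomps, function(d) d$taxon_id, character(1))
  X
}

#' Write a coefficient table with its normalization sidecar
#' @param decomps list of normalized decompositions.
#' @param path TSV output path; a JSON sidecar `<path>.norm.json` records the
#'   normalization parameters per taxon.
#' @return `path`, invisibly.
#' @export
write_coeff_table <- function(decomps, path) {
  X <- efa_matrix(decomps)
  df <- data.frame(taxon_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  norms <- lapply(decomps, function(d) d$norm_record)
  names(norms) <- vapply(decomps, function(d) d$taxon_id, character(1))
  jsonlite::write_json(norms, paste0(path, ".norm.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
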