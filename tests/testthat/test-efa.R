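test_that("a circle is a single-harmonic shape", {
  d <- efa_decompose(circle_outline(256), 10)
  pr <- harmonic_power(d)
  expect_gte(pr$cumulative[1], 0.999)
  expect_equal(unname(abs(d$coeffs[1, 1])), 1, tolerance = 1e-3)
  expect_equal(unname(abs(d$coeffs[1, 4])), 1, tolerance = 1e-3)
  expect_lt(abs(d$coeffs[1, 2]) + abs(d$coeffs[1, 3]), 1e-6)
  expect_equal(choose_harmonics(pr, 0.99), 1L)
})

test_that("ellipse coefficients match dense integration of the continuous Fourier integrals", {
  d <- efa_decompose(ellipse_outline(4096), 10)
  oracle <- fourier_integral_oracle(function(t) 2 * cos(t),
                                    function(t) sin(t), 10)
  expect_equal(d$coeffs[1, ], oracle[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # arc-length parametrization: even harmonics vanish by symmetry and
  # odd-harmonic power decays steeply (harmonic 1 dominates)
  pw <- rowSums(d$coeffs^2) / 2
  expect_true(all(pw[c(2, 4, 6, 8, 10)] / sum(pw) < 1e-10))
  expect_gt(pw[1] / sum(pw), 0.99)
  expect_true(all(diff(pw[c(1, 3, 5, 7, 9)]) < 0))
})

test_that("Nyquist and degeneracy guards trigger", {
  expect_error(efa_decompose(circle_outline(16), 10), "Nyquist")
  z <- vector_to_coeffs(rep(0, 40))
  expect_error(harmonic_power(structure(list(coeffs = matrix(0, 10, 4)),
                                        class = "efa_decomposition")),
               "power")
  expect_warning(o <- inverse_efa(z, 50), "degenerate")
  expect_true(isTRUE(attr(o, "degenerate")))
})

test_that("normalization removes scale, rotation and starting point", {
  base <- random_smooth_outline(1)
  rot <- function(p, ang) p %*% rbind(c(cos(ang), sin(ang)),
                                      c(-sin(ang), cos(ang)))
  n0 <- efa_normalize(efa_decompose(base, 12))
  scaled <- outline(37.2 * base$points, "s")
  rotated <- outline(rot(base$points, pi / 2), "r")
  shifted <- outline(base$points[c(41:300, 1:40), ], "p")
  for (other in list(scaled, rotated, shifted)) {
    nn <- efa_normalize(efa_decompose(other, 12))
    expect_lt(max(abs(nn$coeffs - n0$coeffs)), 1e-6)
  }
  expect_equal(unname(n0$coeffs[1, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(n0$coeffs[1, 2]), 0)
  expect_equal(unname(n0$coeffs[1, 3]), 0)
  expect_gt(n0$coeffs[1, 1], 0)
  z2 <- vector_to_coeffs(rep(0, 8))
  z2$norm_record$normalized <- FALSE
  expect_error(efa_normalize(z2), "degenerate")
})

test_that("total harmonic power is invariant under rotation and start shift", {
  for (s in 1:20) {
    o <- random_smooth_outline(s)
    p0 <- sum(harmonic_power(efa_decompose(o, 12))$power)
    shift <- outline(o$points[c(101:300, 1:100), ], "sh")
    ang <- s / 3
    rotd <- outline(o$points %*% rbind(c(cos(ang), sin(ang)),
                                       c(-sin(ang), cos(ang))), "ro")
    expect_equal(sum(harmonic_power(efa_decompose(shift, 12))$power), p0,
                 tolerance = 1e-6)
    expect_equal(sum(harmonic_power(efa_decompose(rotd, 12))$power), p0,
                 tolerance = 1e-6)
  }
})

test_that("cumulative power is a proper distribution over harmonics", {
  for (s in 1:100) {
    pr <- harmonic_power(efa_decompose(random_smooth_outline(s), 10))
    expect_true(all(pr$power >= 0))
    expect_true(all(diff(pr$cumulative) >= -1e-15))
    expect_identical(pr$cumulative[10], 1)
  }
  # direct read-off example: F = (0.7, 0.9, 0.985, 0.992, 1)
  fake <- structure(list(coeffs = cbind(sqrt(2 * c(0.7, 0.2, 0.085, 0.007, 0.008)),
                                        0, 0, 0),
                         n_harmonics = 5L), class = "efa_decomposition")
  pr <- harmonic_power(fake)
  expect_equal(choose_harmonics(pr, 0.99), 4L)
  expect_error(choose_harmonics(pr, 1 + 1e-9), "threshold")
})

test_that("inverse reconstruction converges to the source shape", {
  o <- random_smooth_outline(5)
  d <- efa_normalize(efa_decompose(o, 25))
  full <- inverse_efa(d, 300, 25)
  few <- inverse_efa(d, 300, 3)
  ref <- inverse_efa(d, 300, 25)
  # nearest-point error of truncated vs full reconstruction
  nearest_err <- function(a, b) {
    mean(vapply(seq_len(nrow(a$points)), function(i) {
      min(sqrt(colSums((t(b$points) - a$points[i, ])^2)))
    }, numeric(1)))
  }
  expect_lt(nearest_err(full, ref), nearest_err(few, ref))
  # error decreases with sampling density of the source
  errs <- vapply(c(100, 300, 1000), function(k) {
    ok <- resample_equal_arclength(o, k)
    dk <- efa_decompose(ok, 25)
    rec <- inverse_efa(dk, k, 25)
    nearest_err(rec, ok)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-12))
  # full-order reconstruction: mean point-to-curve distance within 0.5% of
  # centroid size (dense tracing approximates the continuous curve)
  cs <- sqrt(mean(rowSums(sweep(o$points, 2, colMeans(o$points))^2)))
  d300 <- efa_decompose(o, 25)
  expect_lt(nearest_err(o, inverse_efa(d300, 3000, 25)) / cs, 0.005)
})

test_that("coefficient vectors round-trip and demand normalization", {
  d <- efa_normalize(efa_decompose(random_smooth_outline(2), 25))
  v <- coeffs_to_vector(d)
  expect_length(v, 100L)
  expect_identical(names(v)[1:5], c("a1", "b1", "c1", "d1", "a2"))
  back <- vector_to_coeffs(v)
  expect_equal(back$coeffs, d$coeffs, ignore_attr = TRUE)
  raw <- efa_decompose(random_smooth_outline(2), 25)
  expect_error(coeffs_to_vector(raw), "normalized")
  # identical shapes give identical vectors
  d2 <- efa_normalize(efa_decompose(random_smooth_outline(2), 25))
  expect_identical(coeffs_to_vector(d2), v)
})

test_that("mirrored shapes differ by a consistent sign pattern, not magnitude", {
  o <- random_smooth_outline(3)
  m <- ensure_ccw(mirror_outline(o))
  n1 <- efa_normalize(efa_decompose(o, 12))
  n2 <- efa_normalize(efa_decompose(m, 12))
  expect_equal(abs(n1$coeffs), abs(n2$coeffs), tolerance = 1e-6)
})
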