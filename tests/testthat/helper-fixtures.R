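# shared fixtures and independent oracles

circle_outline <- function(n = 256, r = 1) {
  th <- 2 * pi * (0:(n - 1)) / n
  outline(cbind(r * cos(th), r * sin(th)), "circle")
}

ellipse_outline <- function(n = 256, a = 2, b = 1) {
  th <- 2 * pi * (0:(n - 1)) / n
  outline(cbind(a * cos(th), b * sin(th)), "ellipse")
}

unit_square <- function() {
  outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "square")
}

# smooth random closed shape from random low-order Fourier coefficients
random_smooth_outline <- function(seed, n = 300, n_harm = 6) {
  set.seed(seed)
  co <- matrix(0, n_harm, 4)
  co[1, ] <- c(1, 0, 0, 0.5)
  if (n_harm > 1) {
    for (h in 2:n_harm) co[h, ] <- rnorm(4, 0, 0.12 / h^2)
  }
  d <- structure(list(taxon_id = paste0("rand", seed), clade = "unknown",
                      n_harmonics = n_harm, coeffs = co, dc = c(0, 0),
                      norm_record = list(normalized = FALSE)),
                 class = "efa_decomposition")
  inverse_efa(d, n_points = n)
}

# oracle: Fourier coefficients of the arc-length-parametrized continuous
# curve by dense midpoint-rule integration of the Fourier integrals
fourier_integral_oracle <- function(fx, fy, n_harm, M = 2e5) {
  th <- 2 * pi * (0:M) / M
  x <- fx(th); y <- fy(th)
  dx <- diff(x); dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  T <- sum(dt)
  tm <- cumsum(dt) - dt / 2
  xm <- (x[-1] + x[-(M + 1)]) / 2
  ym <- (y[-1] + y[-(M + 1)]) / 2
  co <- matrix(0, n_harm, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (nh in seq_len(n_harm)) {
    cn <- cos(2 * pi * nh * tm / T); sn <- sin(2 * pi * nh * tm / T)
    co[nh, ] <- (2 / T) * c(sum(xm * cn * dt), sum(xm * sn * dt),
                            sum(ym * cn * dt), sum(ym * sn * dt))
  }
  co
}

# oracle: exhaustive average-linkage agglomeration (unweighted arithmetic
# average of all between-cluster pairs), lowest-index tie-break
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
    }
    heights[step] <- bestd
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members[[step]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, members = members)
}

# cluster membership sets of an hclust result, in merge order
hclust_members <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", nrow(h$merge))
  leaf_ids <- as.integer(sub("x", "", h$labels))  # labels "x<i>" -> original index
  for (m in seq_len(nrow(h$merge))) {
    grab <- function(v) {
      if (v < 0) leaf_ids[-v] else sets[[v]]
    }
    sets[[m]] <- sort(c(grab(h$merge[m, 1]), grab(h$merge[m, 2])))
  }
  sets
}

# oracle: patristic distances by independent root-path arithmetic
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(i) {
    nodes <- i
    while (parent[i] != 0) { i <- parent[i]; nodes <- c(nodes, i) }
    nodes
  }
  depth <- function(i) {
    s <- 0
    while (parent[i] != 0) { s <- s + plen[i]; i <- parent[i] }
    s
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mrca <- max(intersect(path_to_root(i), path_to_root(j)))
    D[i, j] <- D[j, i] <- depth(i) + depth(j) - 2 * depth(mrca)
  }
  D
}

# draw a trait with covariance C(lambda) on a tree
draw_lambda_trait <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  setNames(drop(t(chol(Cl)) %*% rnorm(nrow(C))), rownames(C))
}
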