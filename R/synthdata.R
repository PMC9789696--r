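#' Scenario configuration for the synthetic jaw generator
#'
#' Bundles the knobs of the simulation study: a comparator sample of
#' `n_taxa` jaws in `n_clades` groups (mirroring the three-group
#' acanthodian / elasmobranch / holocephalan design), Brownian shape
#' evolution on a birth-death time tree with tunable phylogenetic signal
#' `lambda_true`, clade mean-shape offsets, optional cross-clade
#' convergence, digitization noise, and the phylogenetic/stratigraphic
#' degradation the ensemble must integrate over.
#'
#' @param n_taxa comparator taxa (default 41; one unknown is added on top).
#' @param n_clades number of clades (default 3).
#' @param bm_rate Brownian variance per Myr of the leading shape coefficient
#'   (default 1e-4 on the unit-semi-major-axis coefficient scale).
#' @param lambda_true generating Pagel's lambda in [0, 1] (default 1, pure
#'   Brownian motion).
#' @param clade_effect_size size of clade mean offsets on thickness- and
#'   curvature-like coefficients (default 0.25, a clear-separation regime in
#'   which clade membership is recoverable from shape while the groups still
#'   overlap visibly in morphospace).
#' @param convergence_pairs explicit list of cross-clade taxon pairs forced
#'   to near-identical shapes, or NULL.
#' @param convergence_frac alternatively, the fraction of taxa to involve in
#'   auto-chosen cross-clade convergent pairs (default 0).
#' @param noise_sd Gaussian digitization noise on outline coordinates
#'   (default 0.005).
#' @param polytomy_fraction fraction of internal nodes collapsed in the
#'   degraded input topology (default 0.5).
#' @param range_width_myr stratigraphic range width per tip (default 10).
#' @param root_age tree depth in Myr (default 60, a Devonian-scale clade age).
#' @param birth,death birth-death rates per Myr (defaults 0.15 / 0.05).
#' @param n_points outline points per specimen (default 300).
#' @param n_harmonics harmonics carried by the generator (default 25).
#' @param unknown_clade clade index the unknown is drawn from (default 1).
#' @param unknown_difficulty scales the unknown's clade offset toward the
#'   grand mean (1 = full effect size, 0 = uninformative).
#' @param seed integer seed making the dataset fully reproducible.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_taxa = 41L, n_clades = 3L, bm_rate = 1e-4,
                            lambda_true = 1, clade_effect_size = 0.25,
                            convergence_pairs = NULL, convergence_frac = 0,
                            noise_sd = 0.005, polytomy_fraction = 0.5,
                            range_width_myr = 10, root_age = 60,
                            birth = 0.15, death = 0.05, n_points = 300L,
                            n_harmonics = 25L, unknown_clade = 1L,
                            unknown_difficulty = 1, seed = 1L) {
  stopifnot(bm_rate >= 0, noise_sd >= 0, lambda_true >= 0, lambda_true <= 1,
            n_taxa >= 3L * n_clades, polytomy_fraction >= 0,
            polytomy_fraction <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate an ultrametric birth-death time tree
#'
#' Birth-death tree conditioned on the number of tips, rescaled to a target
#' root age. Retries (with a logged count) if simulation degenerates.
#'
#' @param n_taxa number of tips.
#' @param birth,death rates (birth > death >= 0).
#' @param root_age depth of the root in Myr.
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` with tips `t1..tn`; attribute `retries`
#'   counts resimulations.
#' @export
simulate_tree <- function(n_taxa, birth = 0.15, death = 0.05, root_age = 60,
                          seed = NULL) {
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  retries <- 0L
  tree <- NULL
  while (is.null(tree)) {
    tree <- tryCatch(ape::rphylo(n_taxa, birth, death, fossils = FALSE),
                     error = function(e) NULL)
    if (is.null(tree)) {
      retries <- retries + 1L
      if (retries > 100L) stop("birth-death simulation kept failing")
    }
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * root_age / depth
  attr(tree, "retries") <- retries
  tree
}

# tips descending from a node
tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Assign tips to clades by carving subtrees out of the tree
#'
#' Produces `n_clades` groups of tips: the first `n_clades - 1` are
#' monophyletic subtrees of roughly n / n_clades tips each, chosen greedily
#' among mutually disjoint internal nodes; the remaining tips form the last
#' group, a paraphyletic grade — mirroring comparative samples made of crown
#' clades plus a stem grade. Deterministic given the tree.
#'
#' @param tree a rooted `phylo`.
#' @param n_clades number of groups (default 3).
#' @param min_size minimum tips per group (default 3).
#' @return named character vector: tip label -> clade name ("clade1", ...).
#' @export
assign_clades <- function(tree, n_clades = 3L, min_size = 3L) {
  n <- length(tree$tip.label)
  if (n < n_clades * min_size) stop("tree too small for the requested clades")
  internal <- unique(tree$edge[, 1L])
  internal <- setdiff(internal, n + 1L)              # exclude the root
  tipsets <- lapply(internal, tips_under, tree = tree)
  names(tipsets) <- internal
  target <- n / n_clades
  chosen <- list()
  taken <- character(0)
  for (g in seq_len(n_clades - 1L)) {
    groups_left <- n_clades - g
    ok <- vapply(tipsets, function(ts) {
      length(ts) >= min_size &&
        !any(ts %in% taken) &&
        (n - length(taken) - length(ts)) >= min_size * groups_left
    }, logical(1))
    if (!any(ok)) stop("could not carve ", n_clades, " clades of size >= ",
                       min_size, " out of this tree")
    cand <- which(ok)
    sizes <- lengths(tipsets[cand])
    pick <- cand[order(abs(sizes - target), as.integer(names(tipsets)[cand]))][1L]
    chosen[[g]] <- tipsets[[pick]]
    taken <- c(taken, tipsets[[pick]])
  }
  chosen[[n_clades]] <- setdiff(tree$tip.label, taken)   # the grade
  out <- character(0)
  for (i in seq_along(chosen)) out[chosen[[i]]] <- paste0("clade", i)
  out[tree$tip.label]
}

# per-coefficient Brownian SDs: variance on harmonics 1-6 with n^-2 decay;
# a1, b1, c1 are pinned by normalization and never vary
coeff_sds <- function(n_harmonics, bm_rate, max_harmonic = 6L) {
  sds <- numeric(4L * n_harmonics)
  names(sds) <- paste0(rep(c("a", "b", "c", "d"), n_harmonics),
                       rep(seq_len(n_harmonics), each = 4L))
  for (h in seq_len(min(max_harmonic, n_harmonics))) {
    sds[((h - 1L) * 4L + 1L):(h * 4L)] <- sqrt(bm_rate) / h^2
  }
  sds[c("a1", "b1", "c1")] <- 0
  sds
}

# clade mean-offset directions: thickness-like (d1) and curvature-like
# (harmonic 2-3) coefficient combinations, unit-normalized
clade_directions <- function(n_harmonics, n_clades) {
  p <- 4L * n_harmonics
  nm <- names(coeff_sds(n_harmonics, 1))
  base <- list(c(d1 = 1, a2 = 0.5, d2 = 0.3),
               c(d1 = -1, c2 = 0.5, a2 = -0.3),
               c(a2 = -0.6, b2 = 0.5, d2 = -0.4, a3 = 0.3))
  dirs <- matrix(0, n_clades, p, dimnames = list(paste0("clade", seq_len(n_clades)), nm))
  for (i in seq_len(n_clades)) {
    b <- base[[((i - 1L) %% 3L) + 1L]]
    if (i > 3L) b <- b * (-1)^(i %/% 3L)   # extra clades reuse flipped directions
    dirs[i, names(b)] <- b
    dirs[i, ] <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
  }
  dirs
}

#' Simulate coefficient deviations on a tree
#'
#' Draws per-taxon deviations of normalized Fourier coefficients under
#' multivariate Brownian motion with covariance C(lambda_true) across taxa
#' and independent coefficients whose SDs decay as harmonic^-2 (harmonics
#' 1-6 carry the variance, so 25 harmonics retain ~99\% of the power by
#' construction). Clade mean offsets are added on thickness- and
#' curvature-like coefficient combinations; convergence pairs overwrite the
#' second member's deviation with the first member's plus small noise.
#'
#' @param tree ultrametric `phylo` over the comparators.
#' @param config a [scenario_config()].
#' @param clades named clade assignment (default: [assign_clades()]).
#' @return matrix taxa x 4 n_harmonics of coefficient deviations, with
#'   attributes `clades` and `convergence_pairs`.
#' @export
simulate_shape_traits <- function(tree, config, clades = NULL) {
  if (is.null(clades)) clades <- assign_clades(tree, config$n_clades)
  taxa <- tree$tip.label
  n <- length(taxa)
  p <- 4L * config$n_harmonics
  C <- phylo_vcv(tree)[taxa, taxa]
  Cl <- C * config$lambda_true
  diag(Cl) <- diag(C)
  L <- t(chol(Cl + diag(1e-10 * mean(diag(C)), n)))
  sds <- coeff_sds(config$n_harmonics, config$bm_rate)
  Z <- matrix(stats::rnorm(n * p), n, p)
  M <- (L %*% Z) * rep(sds, each = n)
  dimnames(M) <- list(taxa, names(sds))
  dirs <- clade_directions(config$n_harmonics, config$n_clades)
  M <- M + config$clade_effect_size * dirs[clades[taxa], , drop = FALSE]
  pairs <- config$convergence_pairs
  if (is.null(pairs) && config$convergence_frac > 0) {
    pairs <- auto_convergence_pairs(clades, config$convergence_frac)
  }
  if (!is.null(pairs)) {
    marg <- sds * sqrt(mean(diag(C)))
    for (pr in pairs) {
      M[pr[2L], ] <- M[pr[1L], ] + stats::rnorm(p, 0, 0.15 * marg)
    }
  }
  attr(M, "clades") <- clades
  attr(M, "convergence_pairs") <- pairs
  M
}

#' Choose cross-clade convergence pairs
#' @param clades named clade assignment.
#' @param frac fraction of taxa to involve (each pair involves 2 taxa).
#' @return list of length-2 character vectors (taxon pairs across clades).
#' @export
auto_convergence_pairs <- function(clades, frac) {
  n_pairs <- max(1L, floor(frac * length(clades) / 2))
  lv <- unique(clades)
  if (length(lv) < 2L) stop("need at least 2 clades for convergence pairs")
  by_clade <- split(names(clades), clades)
  pairs <- list()
  for (i in seq_len(n_pairs)) {
    c1 <- lv[((i - 1L) %% length(lv)) + 1L]
    c2 <- lv[(i %% length(lv)) + 1L]
    a <- by_clade[[c1]][((i - 1L) %/% length(lv)) %% length(by_clade[[c1]]) + 1L]
    b <- by_clade[[c2]][((i - 1L) %/% length(lv)) %% length(by_clade[[c2]]) + 1L]
    pairs[[i]] <- c(a, b)
  }
  pairs
}

#' Jaw-like template shape
#'
#' An elongate biconvex closed curve with a posterior knob — an ellipse-like
#' body with a localized radial bump — standing in for a generic lower-jaw
#' outline. Returned as a normalized elliptic Fourier decomposition ready to
#' receive coefficient deviations.
#'
#' @param n_harmonics harmonics (default 25).
#' @param n_points sampling points (default 300).
#' @return a normalized `efa_decomposition` (synthetic template, not any
#'   real specimen).
#' @export
base_jaw_template <- function(n_harmonics = 25L, n_points = 300L) {
  th <- 2 * pi * (0:(n_points - 1L)) / n_points
  bump <- 0.25 * exp(-((th - 2.9) / 0.35)^2)
  xs <- (1 + bump) * cos(th)
  ys <- (0.35 + bump) * sin(th)
  o <- outline(cbind(xs, ys), taxon_id = "template", source = "synthetic template")
  efa_normalize(efa_decompose(o, n_harmonics))
}

#' Turn coefficient deviations into outlines
#'
#' Adds each taxon's deviation to the template's normalized coefficients,
#' traces the outline, and adds Gaussian digitization noise. Deviations
#' producing an invalid outline are damped by halves (logged in attribute
#' `damped`).
#'
#' @param base normalized template decomposition (default
#'   [base_jaw_template()]).
#' @param deviations matrix taxa x 4 N from [simulate_shape_traits()].
#' @param config a [scenario_config()] (uses `n_points`, `noise_sd`).
#' @return an `outline_set` with clade labels from the deviations attribute.
#' @export
traits_to_outlines <- function(base, deviations, config) {
  base_v <- coeffs_to_vector(base)
  clades <- attr(deviations, "clades")
  damped <- character(0)
  outs <- lapply(rownames(deviations), function(id) {
    dev <- deviations[id, ]
    for (try in 0:6) {
      v <- base_v + dev * 0.5^try
      o <- tryCatch({
        oo <- inverse_efa(vector_to_coeffs(v, taxon_id = id),
                          n_points = config$n_points)
        if (isTRUE(attr(oo, "degenerate"))) stop("degenerate")
        if (config$noise_sd > 0) {
          pts <- oo$points + stats::rnorm(length(oo$points), 0, config$noise_sd)
          oo <- outline(pts, taxon_id = id, source = "synthetic")
        }
        outline_orientation(oo)   # validity check
        oo
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(o)) {
        if (try > 0) damped <<- c(damped, id)
        o$clade <- if (!is.null(clades) && id %in% names(clades)) clades[[id]] else "unknown"
        return(o)
      }
    }
    stop("could not build a valid outline for '", id, "'")
  })
  res <- outline_set(outs, n_resampled = config$n_points)
  attr(res, "damped") <- damped
  res
}

#' Degrade a tree into an uncertain input topology
#'
#' Collapses a fraction of the internal nodes into polytomies and gives each
#' tip a stratigraphic range of the stated width centred on its true age
#' (truncated at 0) — the phylogenetic and stratigraphic uncertainty the
#' ensemble integrates over.
#'
#' @param tree a rooted binary `phylo` with branch lengths.
#' @param polytomy_fraction fraction of non-root internal nodes to collapse.
#' @param range_width_myr stratigraphic range width (Myr).
#' @param seed optional integer seed.
#' @param root_age age of the root in Ma (default: tree depth, i.e. tips at
#'   the youngest tip age 0).
#' @return list with `topology` (possibly multifurcating, no branch
#'   lengths) and `ranges` (StratRange data.frame).
#' @export
degrade_topology <- function(tree, polytomy_fraction = 0.5,
                             range_width_myr = 10, seed = NULL,
                             root_age = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  if (is.null(root_age)) root_age <- max(depth[seq_len(n)])
  true_age <- pmax(0, root_age - depth[seq_len(n)])
  ranges <- data.frame(taxon_id = tree$tip.label,
                       age_max_ma = true_age + range_width_myr / 2,
                       age_min_ma = pmax(0, true_age - range_width_myr / 2),
                       unit_name = "synthetic_unit")
  topo <- tree
  internal <- setdiff(unique(tree$edge[, 1L]), n + 1L)
  n_collapse <- round(polytomy_fraction * length(internal))
  if (n_collapse > 0) {
    victims <- sample(internal, n_collapse)
    topo$edge.length[match(victims, topo$edge[, 2L])] <- 0
    topo <- ape::di2multi(topo, tol = 1e-12)
  }
  topo$edge.length <- NULL
  list(topology = topo, ranges = ranges)
}

#' Generate a full synthetic jaw dataset
#'
#' End-to-end generator: time tree, clade assignment, Brownian coefficient
#' deviations with clade effects (and optional convergence), jaw outlines
#' with digitization noise, one unknown specimen drawn from a designated
#' clade, a degraded input topology with stratigraphic ranges, and a
#' ground-truth record sufficient to score any recovery experiment.
#'
#' @param config a [scenario_config()].
#' @param outlines if FALSE, skip outline tracing and return coefficient
#'   deviations only (faster for purely statistical experiments).
#' @return a `synthetic_dataset`: list with `outlines` (or NULL), `traits`,
#'   `tree`, `topology`, `ranges`, `labels`, `truth`.
#' @export
simulate_jaw_dataset <- function(config = scenario_config(), outlines = TRUE) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa, config$birth, config$death,
                        config$root_age)
  clades <- assign_clades(tree, config$n_clades)
  traits <- simulate_shape_traits(tree, config, clades)
  # unknown specimen: clade offset scaled by difficulty + independent draw
  sds <- coeff_sds(config$n_harmonics, config$bm_rate)
  marg <- sds * sqrt(config$root_age)
  dirs <- clade_directions(config$n_harmonics, config$n_clades)
  true_clade <- paste0("clade", config$unknown_clade)
  unk <- config$unknown_difficulty * config$clade_effect_size * dirs[true_clade, ] +
    stats::rnorm(length(sds), 0, marg)
  traits_all <- rbind(traits, unknown = unk)
  cl_all <- c(attr(traits, "clades"), unknown = "unknown")
  attr(traits_all, "clades") <- cl_all
  attr(traits_all, "convergence_pairs") <- attr(traits, "convergence_pairs")
  outs <- NULL
  if (outlines) {
    base <- base_jaw_template(config$n_harmonics, config$n_points)
    outs <- traits_to_outlines(base, traits_all, config)
  }
  deg <- degrade_topology(tree, config$polytomy_fraction,
                          config$range_width_myr)
  labels <- data.frame(taxon_id = rownames(traits_all),
                       clade = unname(cl_all[rownames(traits_all)]),
                       mirror = 0L,
                       role = c(rep("comparator", nrow(traits)), "unknown"))
  structure(list(outlines = outs, traits = traits_all, tree = tree,
                 topology = deg$topology, ranges = deg$ranges, labels = labels,
                 truth = list(clades = clades, lambda_true = config$lambda_true,
                              convergence_pairs = attr(traits, "convergence_pairs"),
                              unknown_clade = true_clade, seed = config$seed,
                              config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$traits) - 1L, " comparators + 1 unknown (",
      x$truth$unknown_clade, "), lambda_true = ", x$truth$lambda_true,
      ", seed = ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits the same TPS / TSV / Newick formats the pipeline reads, so
#' end-to-end tests exercise real I/O.
#'
#' @param ds a `synthetic_dataset` (generated with outlines).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_dataset <- function(ds, dir) {
  if (is.null(ds$outlines)) stop("dataset was generated without outlines")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tps = file.path(dir, "outlines.tps"),
             labels = file.path(dir, "labels.tsv"),
             topology = file.path(dir, "topology.nwk"),
             ranges = file.path(dir, "ranges.tsv"))
  write_tps(ds$outlines, paths["tps"])
  utils::write.table(ds$labels, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(ds$topology, file = paths["topology"])
  utils::write.table(ds$ranges, paths["ranges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
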