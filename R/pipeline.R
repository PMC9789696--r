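#' Pipeline run configuration
#'
#' Collects every stage setting with defaults matching the study design the
#' package emulates: 25 harmonics (retaining ~99\% of cumulative harmonic
#' power), covariance PCA with the unknown included in the ordination,
#' phenetic distances over all PCs, complete-linkage HCA, and signal tests
#' repeated over 1,000 trees with 1,000 permutations each.
#'
#' @param n_harmonics harmonics for EFA (default 25).
#' @param n_points resampled points per outline (default 300).
#' @param power_threshold cumulative-power threshold reported alongside the
#'   harmonic choice (default 0.99).
#' @param pca_scale use correlation PCA instead of covariance (default
#'   FALSE).
#' @param include_unknown include the unknown in the ordination (default
#'   TRUE) or project it passively.
#' @param linkage HCA linkage (default "complete").
#' @param hca_pcs PCs used for HCA distances (default NULL = all PCs).
#' @param k_neighbors neighbours for the clade vote (default 5).
#' @param signal_trait morphospace variable for K and lambda: a PC name like
#'   "PC1" (default) or index.
#' @param n_trees ensemble size (default 1000).
#' @param n_perm permutations per test (default 1000).
#' @param min_branch minimum branch length in Myr (default 1).
#' @param master_seed master seed (default 1).
#' @return a `run_config` list.
#' @export
run_config <- function(n_harmonics = 25L, n_points = 300L,
                       power_threshold = 0.99, pca_scale = FALSE,
                       include_unknown = TRUE, linkage = "complete",
                       hca_pcs = NULL, k_neighbors = 5L,
                       signal_trait = "PC1", n_trees = 1000L, n_perm = 1000L,
                       min_branch = 1, master_seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full placement-and-signal pipeline
#'
#' Outlines + labels + topology + stratigraphic ranges in; elliptic Fourier
#' decomposition, PCA morphospace, hierarchical clustering and
#' nearest-neighbour placement of the unknown, and the tree-ensemble
#' phylogenetic-signal battery out, as one structured report.
#'
#' @param outlines an `outline_set` (all specimens, unknown included) or a
#'   path to a TPS file.
#' @param labels label data.frame (see [read_labels()]) or TSV path.
#' @param topology rooted `phylo` over the comparators (may contain
#'   polytomies) or Newick path.
#' @param ranges stratigraphic range data.frame or TSV path.
#' @param config a [run_config()].
#' @param outdir if given, all artifacts (TSV/JSON/Newick) are written there.
#' @return a `run_report`: list with `variance`, `scores`, `unknown_scores`,
#'   `cumulative_power`, `n_harmonics_99`, `placement`, `ensemble`,
#'   `morphospace`, `dendrogram`, `distances`, `provenance`.
#' @export
run_pipeline <- function(outlines, labels, topology, ranges,
                         config = run_config(), outdir = NULL) {
  if (is.character(outlines)) outlines <- read_tps(outlines)
  if (is.character(labels)) labels <- read_labels(labels)
  if (is.character(topology)) topology <- ape::read.tree(topology)
  if (is.character(ranges)) ranges <- read_strat_ranges(ranges)
  outlines <- apply_labels(outlines, labels)
  unknown_ids <- labels$taxon_id[labels$role == "unknown"]
  if (length(unknown_ids) != 1L) stop("exactly one 'unknown' role expected, got ",
                                      length(unknown_ids))
  unknown <- unknown_ids
  comparators <- setdiff(labels$taxon_id, unknown)
  miss <- setdiff(comparators, topology$tip.label)
  if (length(miss)) stop("comparators absent from topology: ",
                         paste(miss, collapse = ", "))
  # EFA; harmonic power is profiled at a higher check order so the
  # cumulative proportion at n_harmonics is informative, not trivially 1
  prepped <- prepare_outlines(outlines, k = config$n_points)
  decomps <- efa_decompose_set(prepped, n_harmonics = config$n_harmonics)
  n_check <- min(2L * config$n_harmonics, (config$n_points - 1L) %/% 2L)
  check <- efa_decompose_set(prepped, n_harmonics = n_check)
  cum_power <- vapply(check, function(d) {
    harmonic_power(d)$cumulative[config$n_harmonics]
  }, numeric(1))
  n99 <- max(vapply(check, function(d) {
    choose_harmonics(harmonic_power(d), config$power_threshold)
  }, numeric(1)))
  # ordination
  X <- efa_matrix(decomps, config$n_harmonics)
  if (config$include_unknown) {
    ms <- fit_pca(X, scale = config$pca_scale)
    unknown_scores <- ms$scores[unknown, ]
  } else {
    ms <- fit_pca(X[comparators, , drop = FALSE], scale = config$pca_scale)
    unknown_scores <- project_shape(ms, X[unknown, ])
  }
  # distances, clustering, placement
  if (config$include_unknown) {
    D <- phenetic_distances(ms, pcs = config$hca_pcs)
  } else {
    S <- rbind(ms$scores, matrix(unknown_scores, 1L,
                                 dimnames = list(unknown, NULL)))
    if (!is.null(config$hca_pcs)) S <- S[, config$hca_pcs, drop = FALSE]
    D <- as.matrix(stats::dist(S))
  }
  dend <- hca(D, linkage = config$linkage)
  clade_map <- stats::setNames(labels$clade, labels$taxon_id)
  placement <- nearest_neighbors(D, unknown, k = config$k_neighbors,
                                 clades = clade_map, dend = dend)
  # ensemble signal tests on the comparators (the unknown has no tip)
  trait_col <- if (is.character(config$signal_trait)) {
    match(config$signal_trait, colnames(ms$scores))
  } else as.integer(config$signal_trait)
  if (is.na(trait_col)) stop("signal_trait not found among PC scores")
  trait <- ms$scores[comparators, trait_col]
  D_comp <- D[comparators, comparators]
  ens <- ensemble_signal(topology, ranges, trait, D_comp,
                         n_trees = config$n_trees, n_perm = config$n_perm,
                         min_branch = config$min_branch,
                         master_seed = config$master_seed)
  report <- structure(list(
    variance = variance_table(ms),
    scores = ms$scores,
    unknown = unknown,
    unknown_scores = unknown_scores,
    cumulative_power = cum_power,
    n_harmonics_99 = n99,
    placement = placement,
    ensemble = ens,
    morphospace = ms,
    dendrogram = dend,
    distances = D,
    clades = clade_map,
    provenance = list(config = unclass(config),
                      package_version = as.character(utils::packageVersion("jawspace")),
                      n_taxa = length(comparators), unknown = unknown)),
    class = "run_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  vp <- x$variance$proportion
  k <- min(3L, length(vp))
  cat("Morphospace: ", paste(x$variance$label[seq_len(k)], collapse = ", "),
      "\n", sep = "")
  us <- x$unknown_scores
  cat("The specimen '", x$unknown, "' plots at ",
      format(round(us[1L], 3), trim = TRUE), "/",
      format(round(us[2L], 3), trim = TRUE), " (PC1/PC2)\n", sep = "")
  print(x$placement)
  print(x$ensemble)
  invisible(x)
}

#' Write all pipeline artifacts
#'
#' Scores, variance table, distance matrix, dendrogram Newick, placement
#' JSON/TSV, ensemble trace CSV, and a JSON + Markdown report. Outputs are
#' deterministic: identical config and seed give byte-identical files.
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  utils::write.table(data.frame(taxon_id = rownames(report$scores),
                                report$scores, check.names = FALSE),
                     p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$variance, p("variance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(taxon_id = rownames(report$distances),
                                report$distances, check.names = FALSE),
                     p("distances.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram_newick(report$dendrogram, p("dendrogram.nwk"))
  utils::write.table(report$placement$neighbors, p("placement.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(unknown = report$placement$unknown,
                            clade_vote = report$placement$clade_vote,
                            k = report$placement$k,
                            neighbors = report$placement$neighbors,
                            dendrogram_sister = report$placement$dendrogram_sister),
                       p("placement.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$ensemble$replicates, p("ensemble_trace.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(variance = report$variance,
                            unknown_scores = report$unknown_scores,
                            cumulative_power = as.list(report$cumulative_power),
                            ensemble_summary = report$ensemble$summary,
                            provenance = report$provenance),
                       p("report.json"), auto_unbox = TRUE, digits = NA)
  md <- c("# Placement report", "",
          paste0("- ", report$variance$label[seq_len(min(3L, nrow(report$variance)))]),
          sprintf("- The specimen '%s' plots at %s/%s (PC1/PC2)", report$unknown,
                  format(round(report$unknown_scores[1L], 3), trim = TRUE),
                  format(round(report$unknown_scores[2L], 3), trim = TRUE)),
          sprintf("- Nearest comparator: %s (%s)",
                  report$placement$neighbors$taxon_id[1L],
                  report$placement$neighbors$clade[1L]),
          sprintf("- Clade vote (k=%d): %s", report$placement$k,
                  report$placement$clade_vote),
          "",
          utils::capture.output(print(report$ensemble)))
  writeLines(md, p("report.md"))
  invisible(c(scores = p("scores.tsv"), report = p("report.json")))
}

#' Render the standard figure set
#'
#' Morphospace scatter with a background grid of reconstructed shapes and
#' clade colours; the HCA dendrogram; ensemble histograms of K and lambda;
#' and the ensemble histogram of the Mantel R statistic.
#'
#' @param report a `run_report`.
#' @param outdir output directory.
#' @param grid_n background grid resolution per axis (default 5).
#' @return character vector of the four figure paths.
#' @export
render_figures <- function(report, outdir, grid_n = 5L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ms <- report$morphospace
  paths <- file.path(outdir, c("morphospace.png", "dendrogram.png",
                               "ensemble_K_lambda.png", "ensemble_mantel.png"))
  cl <- report$clades[rownames(ms$scores)]
  pal <- stats::setNames(grDevices::hcl.colors(max(3L, length(unique(cl))), "Dark 3"),
                         sort(unique(cl)))
  grDevices::png(paths[1L], 900, 700)
  s <- ms$scores
  xr <- range(s[, 1L]); yr <- range(s[, 2L])
  graphics::plot(s[, 1L], s[, 2L], type = "n",
                 xlab = report$variance$label[1L], ylab = report$variance$label[2L],
                 main = "Jaw morphospace")
  gx <- seq(xr[1L], xr[2L], length.out = grid_n)
  gy <- seq(yr[1L], yr[2L], length.out = grid_n)
  sc <- 0.35 * min(diff(xr), diff(yr)) / grid_n
  for (i in gx) for (j in gy) {
    o <- reconstruct_shape(ms, c(i, j), n_points = 80L)
    pts <- o$points
    pts <- pts - rep(colMeans(pts), each = nrow(pts))
    pts <- pts / max(abs(pts)) * sc
    graphics::polygon(i + pts[, 1L], j + pts[, 2L], border = "grey80")
  }
  graphics::points(s[, 1L], s[, 2L], pch = 19, col = pal[cl])
  graphics::text(s[, 1L], s[, 2L], rownames(s), cex = 0.6, pos = 3)
  graphics::legend("topright", legend = names(pal), col = pal, pch = 19, bty = "n")
  grDevices::dev.off()
  grDevices::png(paths[2L], 900, 700)
  graphics::plot(stats::as.dendrogram(report$dendrogram),
                 main = paste0("HCA (", attr(report$dendrogram, "linkage"),
                               " linkage)"), cex = 0.7)
  grDevices::dev.off()
  reps <- report$ensemble$replicates
  grDevices::png(paths[3L], 900, 450)
  graphics::par(mfrow = c(1, 2))
  graphics::hist(reps$K, breaks = 20, main = "Blomberg's K", xlab = "K")
  graphics::hist(reps$lambda, breaks = 20, main = "Pagel's lambda",
                 xlab = "lambda")
  grDevices::dev.off()
  grDevices::png(paths[4L], 600, 450)
  graphics::hist(reps$mantel_r, breaks = 20, main = "Mantel R over the tree ensemble",
                 xlab = "R statistic")
  grDevices::dev.off()
  paths
}
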