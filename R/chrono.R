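#' Randomly resolve polytomies to a binary tree
#'
#' Every multifurcating node is replaced by a random binary subtree over its
#' children, sampled uniformly over all rooted binary refinements by
#' sequential attachment: starting from two children, each further child
#' joins at one of the 2k-1 possible positions (any edge of the local
#' subtree, or above its root), which makes every refinement equally likely.
#' Branch lengths are dropped — resolution feeds [time_calibrate()], which
#' assigns them.
#'
#' @param tree a `phylo`, possibly multifurcating; its basal node is taken
#'   as the root (a basal multifurcation is treated as a root polytomy, not
#'   as an unrooted tree).
#' @param seed optional integer seed.
#' @return a strictly binary rooted `phylo` (topology only).
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  if (length(tree$tip.label) < 2L) stop("tree needs at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  nested <- phylo_to_nested(tree)
  resolved <- resolve_nested(nested)
  ape::read.tree(text = paste0(nested_to_newick(resolved), ";"))
}

# phylo -> recursive list; leaves are tip labels (character)
phylo_to_nested <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    lapply(children[[as.character(node)]], build)
  }
  build(n + 1L)
}

nested_to_newick <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(vapply(x, nested_to_newick, character(1)), collapse = ","), ")")
}

# resolve every polytomy in a nested tree, bottom-up; child subtrees are
# opaque units in the local resolution (attachment never reaches inside them)
resolve_nested <- function(x) {
  if (is.character(x)) return(x)
  kids <- lapply(x, resolve_nested)
  if (length(kids) <= 2L) return(kids)
  # local tree over child indices: integer leaves, built by sequential
  # attachment at one of the 2k-1 positions (any node's parent edge; the
  # root position means a new root)
  loc <- list(1L, 2L)
  for (j in 3L:length(kids)) {
    pos <- sample.int(count_nodes(loc), 1L)
    loc <- attach_at(loc, j, pos)
  }
  substitute_units(loc, kids)
}

count_nodes <- function(x) {
  if (!is.list(x)) return(1L)
  1L + sum(vapply(x, count_nodes, integer(1)))
}

# attach `unit` above the pos-th node of x in pre-order (pos = 1 is the root)
attach_at <- function(x, unit, pos) {
  if (pos == 1L) return(list(unit, x))
  used <- 1L
  for (i in seq_along(x)) {
    sub <- count_nodes(x[[i]])
    if (pos - used <= sub) {
      x[[i]] <- attach_at(x[[i]], unit, pos - used)
      return(x)
    }
    used <- used + sub
  }
  stop("attachment position out of range")
}

substitute_units <- function(loc, kids) {
  if (!is.list(loc)) return(kids[[loc]])
  lapply(loc, substitute_units, kids = kids)
}

#' Randomize fossil tip ages within stratigraphic ranges
#'
#' Draws each tip's age uniformly and independently within the bounds of its
#' chronostratigraphic unit of first appearance, propagating dating
#' uncertainty into the tree ensemble.
#'
#' @param ranges data.frame with columns `taxon_id`, `age_max_ma`,
#'   `age_min_ma` (Ma before present, age_max >= age_min >= 0).
#' @param seed optional integer seed.
#' @return named numeric vector of sampled tip ages (Ma).
#' @export
randomize_tip_ages <- function(ranges, seed = NULL) {
  req <- c("taxon_id", "age_max_ma", "age_min_ma")
  if (!all(req %in% names(ranges))) {
    stop("ranges need columns: ", paste(req, collapse = ", "))
  }
  if (any(ranges$age_min_ma < 0) || any(ranges$age_max_ma < ranges$age_min_ma)) {
    stop("invalid stratigraphic ranges (need age_max >= age_min >= 0)")
  }
  if (!is.null(seed)) set.seed(seed)
  ages <- stats::runif(nrow(ranges), ranges$age_min_ma, ranges$age_max_ma)
  stats::setNames(ages, ranges$taxon_id)
}

#' Time-calibrate a binary topology from tip ages
#'
#' Basic fossil calibration: working from the tips rootward, each node is
#' placed `min_branch` Myr older than its oldest child, so every branch is at
#' least `min_branch` long and tips terminate at their sampled ages. With
#' `min_branch = 0`, zero-length branches can arise and are flagged with a
#' warning (the Brownian covariance may become singular downstream).
#'
#' @param topology a strictly binary rooted `phylo`.
#' @param tip_ages named vector of tip ages (Ma) covering all tips.
#' @param min_branch minimum branch length in Myr (default 1).
#' @return a `phylo` with branch lengths in Myr and attribute `tip_ages`.
#' @export
time_calibrate <- function(topology, tip_ages, min_branch = 1) {
  # rooted-binary check on child counts (a basal multifurcation must fail)
  if (any(tabulate(topology$edge[, 1L]) > 2L)) {
    stop("topology must be binary; resolve polytomies first")
  }
  tips <- topology$tip.label
  missing <- setdiff(tips, names(tip_ages))
  if (length(missing)) stop("missing tip ages: ", paste(missing, collapse = ", "))
  n <- length(tips)
  nnode <- topology$Nnode
  age <- numeric(n + nnode)
  age[seq_len(n)] <- tip_ages[tips]
  ed <- ape::reorder.phylo(topology, "postorder")$edge
  for (i in seq_len(nrow(ed))) {
    p <- ed[i, 1L]; ch <- ed[i, 2L]
    age[p] <- max(age[p], age[ch] + min_branch)
  }
  out <- topology
  out$edge.length <- age[out$edge[, 1L]] - age[out$edge[, 2L]]
  if (any(out$edge.length < 0)) stop("internal error: negative branch length")
  if (min_branch == 0 && any(out$edge.length == 0)) {
    warning("zero-length branches in calibrated tree")
  }
  attr(out, "tip_ages") <- tip_ages[tips]
  attr(out, "root_age") <- age[n + 1L]
  out
}

#' Ensemble of signal statistics over tree uncertainty
#'
#' Repeats the phylogenetic-signal battery over `n_trees` replicate trees,
#' each built by a fresh random polytomy resolution, fresh stratigraphic
#' tip-age draws, and basic time calibration, and summarizes every statistic
#' as mean and SD. Per-replicate tree seeds are derived deterministically
#' from `master_seed`; the permutation seed is derived once and shared by
#' all replicates, so a degenerate input (binary topology, point ages) gives
#' SD exactly 0 for every statistic including permutation p-values.
#'
#' @param topology rooted `phylo` (may contain polytomies), tips covering
#'   the trait taxa.
#' @param ranges stratigraphic range data.frame (see
#'   [randomize_tip_ages()]); tips absent from `ranges` get age 0.
#' @param trait named numeric vector (e.g. PC1 scores) over comparator taxa.
#' @param phenetic_D phenetic distance matrix over (at least) the trait taxa.
#' @param n_trees replicate trees (default 1000).
#' @param n_perm permutations per K and Mantel test (default 1000).
#' @param min_branch minimum branch length in Myr (default 1).
#' @param master_seed integer master seed (default 1).
#' @return an `ensemble_summary`: list with `summary` (statistic, mean, sd),
#'   `replicates` (per-tree data.frame), `n_trees`, `n_perm`, `master_seed`,
#'   `retries`.
#' @export
ensemble_signal <- function(topology, ranges, trait, phenetic_D,
                            n_trees = 1000L, n_perm = 1000L, min_branch = 1,
                            master_seed = 1L) {
  taxa <- names(trait)
  missing <- setdiff(taxa, topology$tip.label)
  if (length(missing)) stop("trait taxa absent from topology: ",
                            paste(missing, collapse = ", "))
  phenetic_D <- as.matrix(phenetic_D)[taxa, taxa]
  extra <- setdiff(topology$tip.label, c(ranges$taxon_id))
  if (length(extra)) {
    ranges <- rbind(ranges[, c("taxon_id", "age_max_ma", "age_min_ma")],
                    data.frame(taxon_id = extra, age_max_ma = 0, age_min_ma = 0))
  }
  set.seed(as.integer(master_seed))
  tree_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n_trees)
  perm_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  stat_names <- c("K", "p_K", "lambda", "p_lambda", "mantel_r", "mantel_p")
  reps <- matrix(NA_real_, n_trees, length(stat_names),
                 dimnames = list(NULL, stat_names))
  root_ages <- numeric(n_trees)
  retries <- 0L
  pool <- 0L
  for (r in seq_len(n_trees)) {
    done <- FALSE
    while (!done) {
      pool <- pool + 1L
      if (pool > length(tree_seeds)) stop("too many ensemble retries")
      res <- tryCatch({
        set.seed(tree_seeds[pool])
        bin <- resolve_polytomies(topology)
        ages <- randomize_tip_ages(ranges)
        tt <- time_calibrate(bin, ages, min_branch = min_branch)
        tt <- ape::keep.tip(tt, taxa)
        C <- phylo_vcv(tt, taxa)
        kk <- k_permutation_p(tt, trait, n_perm = n_perm, seed = perm_seed, C = C)
        ll <- pagel_lambda(tt, trait, C = C)
        pd <- phylogenetic_distances(tt, taxa)
        mt <- mantel_test(phenetic_D, pd, n_perm = n_perm, seed = perm_seed)
        list(stats = c(kk$K, kk$p, ll$lambda, ll$p, mt$r, mt$p),
             root_age = attr(tt, "root_age"))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        retries <- retries + 1L
      } else {
        reps[r, ] <- res$stats
        root_ages[r] <- if (is.null(res$root_age)) NA_real_ else res$root_age
        done <- TRUE
      }
    }
  }
  repdf <- data.frame(replicate = seq_len(n_trees), reps, root_age = root_ages)
  summ <- data.frame(statistic = stat_names,
                     mean = colMeans(reps),
                     sd = apply(reps, 2L, stats::sd),
                     row.names = NULL)
  structure(list(summary = summ, replicates = repdf,
                 n_trees = as.integer(n_trees), n_perm = as.integer(n_perm),
                 master_seed = as.integer(master_seed), retries = retries),
            class = "ensemble_summary")
}

# "0.501 ± 0.071" style formatting
format_pm <- function(mean, sd, digits = 3) {
  paste0(format(round(mean, digits), trim = TRUE), " ± ",
         format(round(sd, digits), trim = TRUE))
}

#' @export
print.ensemble_summary <- function(x, ...) {
  s <- x$summary
  g <- function(stat, col) s[s$statistic == stat, col]
  cat("Phylogenetic signal over ", x$n_trees, " trees (mean ± SD):\n", sep = "")
  cat("  K (equal to ", format_pm(g("K", "mean"), g("K", "sd")),
      "; p-value = ", format_pm(g("p_K", "mean"), g("p_K", "sd")), ")\n", sep = "")
  cat("  lambda (equal to ", format_pm(g("lambda", "mean"), g("lambda", "sd")),
      "; p-value = ", format_pm(g("p_lambda", "mean"), g("p_lambda", "sd"), 4),
      ")\n", sep = "")
  cat("  Mantel (R statistic = ", format_pm(g("mantel_r", "mean"), g("mantel_r", "sd")),
      "; p-value = ", format_pm(g("mantel_p", "mean"), g("mantel_p", "sd")), ")\n",
      sep = "")
  if (x$retries > 0) cat("  (", x$retries, " replicate retries)\n", sep = "")
  invisible(x)
}

#' Read a stratigraphic range table
#' @param path TSV with columns `taxon_id`, `age_max_ma`, `age_min_ma` and
#'   optionally `unit_name`.
#' @return data.frame of ranges.
#' @export
read_strat_ranges <- function(path) {
  rg <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("taxon_id", "age_max_ma", "age_min_ma")
  if (!all(req %in% names(rg))) {
    stop("range table needs columns: ", paste(req, collapse = ", "))
  }
  rg
}
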