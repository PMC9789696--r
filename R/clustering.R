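#' Hierarchical cluster analysis of phenetic distances
#'
#' Agglomerative clustering of taxa on a phenetic distance matrix via
#' `stats::hclust`. Taxa are sorted lexicographically before clustering so
#' that distance ties resolve identically regardless of input order.
#'
#' @param D symmetric distance matrix with taxon dimnames (e.g. from
#'   [phenetic_distances()]).
#' @param linkage one of "complete" (default), "single", "average", "ward"
#'   (Ward's criterion on squared distances, `ward.D2`).
#' @return an `hclust` object with attribute `linkage`.
#' @export
hca <- function(D, linkage = c("complete", "single", "average", "ward")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  if (anyNA(D) || any(!is.finite(D))) stop("distance matrix contains NA/Inf")
  if (nrow(D) < 2L) stop("need at least 2 taxa")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  method <- if (linkage == "ward") "ward.D2" else linkage
  h <- stats::hclust(stats::as.dist(D), method = method)
  attr(h, "linkage") <- linkage
  h
}

#' Cophenetic distances of a dendrogram
#' @param h an `hclust` object.
#' @return symmetric ultrametric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(h) {
  as.matrix(stats::cophenetic(h))
}

#' Export a dendrogram as Newick with branch lengths
#' @param h an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Sister taxa of a leaf in a dendrogram
#'
#' The other leaves of the smallest cluster containing `taxon` — the
#' dendrogram neighbours used when reading off a specimen's closest relatives.
#'
#' @param h an `hclust` object.
#' @param taxon leaf label.
#' @return character vector of sister leaf labels.
#' @export
dendro_sister <- function(h, taxon) {
  i <- match(taxon, h$labels)
  if (is.na(i)) stop("taxon '", taxon, "' not in dendrogram")
  # find the first merge involving leaf i, then collect leaves of the sibling
  leaves_of <- function(node) {
    if (node < 0) return(h$labels[-node])
    unlist(lapply(h$merge[node, ], leaves_of))
  }
  for (m in seq_len(nrow(h$merge))) {
    row <- h$merge[m, ]
    if (any(row == -i)) {
      sib <- row[row != -i]
      return(leaves_of(sib))
    }
  }
  stop("leaf never merged; corrupt dendrogram")
}

#' Nearest-neighbour placement of an unknown specimen
#'
#' Ranks all comparators by phenetic distance to the query and reports the
#' k nearest with their clade labels plus a majority clade vote. Distance
#' ties are broken lexicographically and flagged.
#'
#' @param D symmetric distance matrix containing the query.
#' @param query taxon id of the specimen to place.
#' @param k number of neighbours to vote over (default 5).
#' @param clades named character vector mapping taxon id to clade label; ids
#'   absent from it are labelled "unknown".
#' @param dend optional `hclust` over the same taxa; if given, the
#'   dendrogram sister taxa of the query are reported too.
#' @return a `placement_report`: list with `unknown`, `neighbors`
#'   (data.frame rank/taxon_id/distance/clade), `clade_vote`, `vote_table`,
#'   `tied_distances`, `tied_vote`, `dendrogram_sister`.
#' @export
nearest_neighbors <- function(D, query, k = 5L, clades = NULL, dend = NULL) {
  D <- as.matrix(D)
  if (!query %in% rownames(D)) stop("query '", query, "' absent from distances")
  d <- D[query, setdiff(colnames(D), query)]
  k <- as.integer(k)
  if (k < 1L || k > length(d)) stop("k must be in [1, n-1]")
  ord <- order(d, names(d))            # lexicographic tie-break
  ranked <- d[ord]
  tied <- anyDuplicated(signif(ranked[seq_len(min(k + 1L, length(ranked)))], 12)) > 0
  cl <- if (is.null(clades)) rep("unknown", length(ranked)) else {
    ifelse(is.na(clades[names(ranked)]), "unknown", clades[names(ranked)])
  }
  nb <- data.frame(rank = seq_along(ranked), taxon_id = names(ranked),
                   distance = unname(ranked), clade = unname(cl),
                   row.names = NULL)
  topk <- nb$clade[seq_len(k)]
  tab <- sort(table(topk), decreasing = TRUE)
  tied_vote <- length(tab) > 1L && tab[1L] == tab[2L]
  vote <- if (tied_vote) sort(names(tab)[tab == tab[1L]])[1L] else names(tab)[1L]
  sis <- if (!is.null(dend)) dendro_sister(dend, query) else character(0)
  structure(list(unknown = query, neighbors = nb, k = as.integer(k),
                 clade_vote = vote, vote_table = tab,
                 tied_distances = tied, tied_vote = tied_vote,
                 dendrogram_sister = sis),
            class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat("<placement_report> ", x$unknown, "\n", sep = "")
  cat("  closest: ", paste(sprintf("%s (%.4g, %s)",
                                   x$neighbors$taxon_id[seq_len(min(3L, nrow(x$neighbors)))],
                                   x$neighbors$distance[seq_len(min(3L, nrow(x$neighbors)))],
                                   x$neighbors$clade[seq_len(min(3L, nrow(x$neighbors)))]),
                           collapse = ", "), "\n", sep = "")
  cat("  clade vote (k=", x$k, "): ", x$clade_vote,
      if (x$tied_vote) " [tied]", "\n", sep = "")
  if (length(x$dendrogram_sister)) {
    cat("  dendrogram sister: ", paste(x$dendrogram_sister, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
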