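#' Closed outline of a lower jaw
#'
#' Constructs and validates an `outline`: an ordered closed polygon of 2D
#' points with a taxon id and a clade label. Closure is implicit — the first
#' point must not be repeated as the last. Consecutive duplicate points are
#' collapsed (with a warning) because they carry no arc length.
#'
#' @param points numeric matrix or data.frame with two columns (x, y).
#' @param taxon_id character scalar identifying the specimen.
#' @param clade clade label (e.g. "Acanthodii", "Elasmobranchii",
#'   "Holocephali", "unknown").
#' @param source free-text provenance.
#' @return an object of class `outline` with fields `taxon_id`, `points`
#'   (n x 2 matrix), `clade`, `source`.
#' @export
outline <- function(points, taxon_id = "specimen", clade = "unknown",
                    source = "") {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("outline points must have two columns (x, y)")
  storage.mode(pts) <- "double"
  if (anyNA(pts) || any(!is.finite(pts))) {
    stop("outline '", taxon_id, "': non-finite coordinates")
  }
  # drop an explicit closing point duplicating the start
  n <- nrow(pts)
  if (n >= 2L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  # collapse consecutive duplicates (wrapping pair handled above)
  dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
  if (any(dup)) {
    warning("outline '", taxon_id, "': collapsed ", sum(dup),
            " consecutive duplicate point(s)")
    pts <- pts[!dup, , drop = FALSE]
  }
  if (nrow(pts) < 3L) stop("outline '", taxon_id, "' needs at least 3 distinct points")
  if (outline_perimeter_mat(pts) <= 0) stop("outline '", taxon_id, "': zero perimeter")
  structure(list(taxon_id = as.character(taxon_id), points = pts,
                 clade = as.character(clade), source = as.character(source)),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat("<outline> ", x$taxon_id, " [", x$clade, "], ",
      nrow(x$points), " points, perimeter ",
      format(outline_perimeter(x), digits = 5), "\n", sep = "")
  invisible(x)
}

# edge lengths of the closed polygon (wrap included)
outline_edge_lengths <- function(pts) {
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sqrt(rowSums((nxt - pts)^2))
}

outline_perimeter_mat <- function(pts) sum(outline_edge_lengths(pts))

#' Perimeter of a closed outline
#' @param x an `outline`.
#' @return perimeter of the closed polygon.
#' @export
outline_perimeter <- function(x) outline_perimeter_mat(x$points)

#' Signed area and orientation of an outline
#'
#' Orientation follows the sign of the shoelace area: positive signed area is
#' counter-clockwise. All outlines are flipped to counter-clockwise before
#' Fourier decomposition so every specimen enters with one convention.
#'
#' @param x an `outline`.
#' @return `"counterclockwise"` or `"clockwise"`.
#' @export
outline_orientation <- function(x) {
  a <- shoelace_area(x$points)
  scale2 <- max(abs(x$points))^2
  if (abs(a) <= 1e-12 * max(scale2, 1)) {
    stop("outline '", x$taxon_id,
         "': zero signed area (degenerate or self-intersecting)")
  }
  if (a > 0) "counterclockwise" else "clockwise"
}

shoelace_area <- function(pts) {
  xs <- pts[, 1L]; ys <- pts[, 2L]
  xs2 <- c(xs[-1L], xs[1L]); ys2 <- c(ys[-1L], ys[1L])
  sum(xs * ys2 - xs2 * ys) / 2
}

#' Force counter-clockwise orientation
#' @param x an `outline`.
#' @return the outline, reversed if it was clockwise (the first point stays
#'   first).
#' @export
ensure_ccw <- function(x) {
  if (outline_orientation(x) == "clockwise") {
    n <- nrow(x$points)
    x$points <- x$points[c(1L, n:2L), , drop = FALSE]
  }
  x
}

#' Mirror an outline left-right
#' @param x an `outline`.
#' @return the outline with x-coordinates negated (orientation flips).
#' @export
mirror_outline <- function(x) {
  x$points[, 1L] <- -x$points[, 1L]
  x
}

#' Resample an outline at equal arc-length spacing
#'
#' Places `k` points at equal arc-length intervals along the closed polygon,
#' starting at the original first point. Linear interpolation along edges;
#' the polygonal perimeter is preserved to first order and all downstream
#' Fourier machinery assumes this equal spacing.
#'
#' @param x an `outline`.
#' @param k number of points (>= 8); default 300 resolves 25 harmonics with
#'   a comfortable Nyquist margin.
#' @return the resampled `outline`.
#' @export
resample_equal_arclength <- function(x, k = 300L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  pts <- x$points
  el <- outline_edge_lengths(pts)
  per <- sum(el)
  if (per <= 0) stop("outline '", x$taxon_id, "': zero perimeter")
  cum <- c(0, cumsum(el))          # arc length at each vertex, cum[n+1] = perimeter
  target <- per * (0:(k - 1L)) / k
  seg <- findInterval(target, cum, rightmost.closed = FALSE, all.inside = TRUE)
  frac <- (target - cum[seg]) / el[seg]
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  newpts <- pts[seg, , drop = FALSE] * (1 - frac) + nxt[seg, , drop = FALSE] * frac
  x$points <- newpts
  x
}

#' Set of outlines sharing a resampled point count
#'
#' @param outlines list of `outline` objects with unique taxon ids.
#' @param n_resampled point count after equal-arc-length resampling, or `NA`
#'   if the set has not been prepared yet.
#' @return an `outline_set`: list with `outlines` (named by taxon id) and
#'   `n_resampled`.
#' @export
outline_set <- function(outlines, n_resampled = NA_integer_) {
  ids <- vapply(outlines, function(o) o$taxon_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate taxon ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(outlines) <- ids
  structure(list(outlines = outlines, n_resampled = as.integer(n_resampled)),
            class = "outline_set")
}

#' @export
print.outline_set <- function(x, ...) {
  cat("<outline_set> ", length(x$outlines), " outlines",
      if (!is.na(x$n_resampled)) paste0(", resampled to ", x$n_resampled, " points"),
      "\n", sep = "")
  invisible(x)
}

#' Resample every outline in a set to a common point count
#' @param x an `outline_set`.
#' @param k common point count.
#' @param ccw flip all outlines counter-clockwise first (default TRUE).
#' @return the prepared `outline_set` with `n_resampled = k`.
#' @export
prepare_outlines <- function(x, k = 300L, ccw = TRUE) {
  outs <- lapply(x$outlines, function(o) {
    if (ccw) o <- ensure_ccw(o)
    resample_equal_arclength(o, k)
  })
  outline_set(outs, n_resampled = k)
}

#' Read a TPS outline file
#'
#' Accepts the outline dialect: records of `LM=0`, `OUTLINES=1`,
#' `POINTS=<n>`, n lines of `x y`, and an `ID=<taxon>` line. `IMAGE=` lines
#' are ignored; `SCALE=` is recorded in the outline's `source`.
#'
#' @param path path to a TPS file.
#' @return an `outline_set`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  outs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i])) {
      stop("TPS parse error at line ", i, ": expected 'LM=' starting a record")
    }
    rec <- rec + 1L
    i <- i + 1L
    if (i > length(lines) || !grepl("^OUTLINES\\s*=", lines[i])) {
      stop("TPS record ", rec, ": expected 'OUTLINES=' after 'LM='")
    }
    i <- i + 1L
    if (i > length(lines) || !grepl("^POINTS\\s*=", lines[i])) {
      stop("TPS record ", rec, ": expected 'POINTS='")
    }
    npts <- as.integer(sub("^POINTS\\s*=\\s*", "", lines[i]))
    i <- i + 1L
    coords <- matrix(NA_real_, npts, 2L)
    for (j in seq_len(npts)) {
      if (i > length(lines) || grepl("^(ID|IMAGE|SCALE|LM)\\s*=", lines[i])) {
        stop("TPS record ", rec, ": POINTS=", npts,
             " declared but only ", j - 1L, " coordinate pairs found")
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1L]]))
      if (length(xy) != 2L || anyNA(xy)) {
        stop("TPS record ", rec, ": bad coordinate line '", lines[i], "'")
      }
      coords[j, ] <- xy
      i <- i + 1L
    }
    if (i <= length(lines) && grepl("^[-0-9.]", lines[i])) {
      stop("TPS record ", rec, ": more coordinate pairs than POINTS=", npts)
    }
    id <- NULL; scale <- NA_real_
    while (i <= length(lines) && grepl("^(ID|IMAGE|SCALE)\\s*=", lines[i])) {
      if (grepl("^ID\\s*=", lines[i])) id <- sub("^ID\\s*=\\s*", "", lines[i])
      if (grepl("^SCALE\\s*=", lines[i])) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i]))
      }
      i <- i + 1L
    }
    if (is.null(id)) stop("TPS record ", rec, ": missing ID= line")
    src <- if (is.na(scale)) "tps" else paste0("tps; SCALE=", scale)
    outs[[length(outs) + 1L]] <- outline(coords, taxon_id = id, source = src)
  }
  outline_set(outs)
}

#' Write an outline set as a TPS outline file
#' @param x an `outline_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (o in x$outlines) {
    writeLines(c("LM=0", "OUTLINES=1", paste0("POINTS=", nrow(o$points))), con)
    writeLines(sprintf("%.10g %.10g", o$points[, 1L], o$points[, 2L]), con)
    writeLines(paste0("ID=", o$taxon_id), con)
  }
  invisible(path)
}

#' Read a single-outline XY CSV
#'
#' Two numeric columns x, y (header optional), one row per point in outline
#' order.
#'
#' @param path path to the CSV file.
#' @param taxon_id taxon id to assign (default: file base name).
#' @param clade clade label.
#' @return an `outline`.
#' @export
read_outline_csv <- function(path, taxon_id = NULL, clade = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("empty or unreadable outline CSV: ", path))
  if (nrow(raw) == 0L) stop("empty outline CSV: ", path)
  # tolerate a header row of column names
  first <- suppressWarnings(as.numeric(unlist(raw[1L, ])))
  if (anyNA(first)) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("empty outline CSV: ", path)
  if (ncol(raw) != 2L) stop("outline CSV must have exactly two columns: ", path)
  xy <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  xy <- matrix(xy, ncol = 2L)
  bad <- which(rowSums(is.na(xy)) > 0)
  if (length(bad)) stop("non-numeric cell in ", path, " at data row ", bad[1L])
  if (is.null(taxon_id)) taxon_id <- sub("\\.[^.]*$", "", basename(path))
  outline(xy, taxon_id = taxon_id, clade = clade, source = path)
}

#' Read a clade label table
#'
#' TSV with columns `taxon_id`, `clade`, `mirror` (0/1), `role`
#' (comparator|unknown). Missing optional columns default to mirror = 0,
#' role = comparator.
#'
#' @param path path to the TSV file.
#' @return data.frame with those four columns.
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "clade") %in% names(lab))) {
    stop("label table needs 'taxon_id' and 'clade' columns")
  }
  if (is.null(lab$mirror)) lab$mirror <- 0L
  if (is.null(lab$role)) lab$role <- "comparator"
  if (anyDuplicated(lab$taxon_id)) stop("duplicate taxon_id in label table")
  lab[, c("taxon_id", "clade", "mirror", "role")]
}

#' Attach clade labels (and apply mirroring) to an outline set
#' @param x an `outline_set`.
#' @param labels data.frame as returned by [read_labels()].
#' @return the labelled `outline_set`.
#' @export
apply_labels <- function(x, labels) {
  missing <- setdiff(names(x$outlines), labels$taxon_id)
  if (length(missing)) {
    stop("taxa without labels: ", paste(missing, collapse = ", "))
  }
  idx <- match(names(x$outlines), labels$taxon_id)
  x$outlines <- Map(function(o, cl, mir) {
    o$clade <- cl
    if (isTRUE(mir == 1)) o <- mirror_outline(o)
    o
  }, x$outlines, labels$clade[idx], labels$mirror[idx])
  outline_set(x$outlines, x$n_resampled)
}
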