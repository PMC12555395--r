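#' Labeled plant point cloud
#'
#' The unit of data every stage of the pipeline consumes and produces: an
#' `N x 3` coordinate matrix plus an optional length-`N` integer vector of
#' per-point organ labels (contiguous internal class ids `0..P-1`).
#'
#' @param coords Numeric `N x 3` matrix of XYZ coordinates (finite).
#' @param labels Optional integer vector of length `N` with values `>= 0`,
#'   or `NULL` for an unlabeled cloud.
#' @param source_id Free-text provenance tag.
#' @return An object of class `labeled_cloud`: a list with elements
#'   `coords`, `labels`, `source_id`.
#' @examples
#' cl <- labeled_cloud(matrix(rnorm(30), 10, 3), labels = rep(0L, 10))
#' n_points(cl)
#' @export
labeled_cloud <- function(coords, labels = NULL, source_id = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have exactly 3 columns")
  if (nrow(coords) < 1L) stop("a cloud must contain at least one point")
  if (!all(is.finite(coords))) stop("coords must be finite")
  storage.mode(coords) <- "double"
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels must have one entry per point")
    if (anyNA(labels) || any(labels < 0L))
      stop("labels must be non-negative integers")
  }
  structure(list(coords = coords, labels = labels, source_id = source_id),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points%s%s\n", nrow(x$coords),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", %d classes present", length(unique(x$labels))),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A [labeled_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' Label map from raw file codes to contiguous internal class ids
#'
#' Public plant datasets code organs non-contiguously (stem = 0, leaf = 1,
#' soil = 3); one-hot training targets need contiguous ids, so raw codes are
#' remapped on read. The default map sends soil's raw code 3 to internal id 2.
#'
#' @param raw_to_internal Named integer vector: names are raw file codes,
#'   values the internal ids. Must be injective with contiguous ids `0..P-1`.
#' @param class_names Character vector of class names ordered by internal id.
#' @return A `label_map` object.
#' @examples
#' lm <- label_map()          # stem=0, leaf=1, soil: raw 3 -> internal 2
#' lm$raw_to_internal
#' @export
label_map <- function(raw_to_internal = c("0" = 0L, "1" = 1L, "3" = 2L),
                      class_names = c("stem", "leaf", "soil")) {
  ids <- as.integer(raw_to_internal)
  if (anyDuplicated(ids)) stop("label map must be injective")
  if (!setequal(ids, seq_along(ids) - 1L))
    stop("internal ids must be contiguous 0..P-1")
  if (length(class_names) != length(ids))
    stop("class_names must have one entry per class")
  structure(list(raw_to_internal = raw_to_internal, class_names = class_names),
            class = "label_map")
}

remap_labels <- function(raw, map, path = "<memory>") {
  key <- as.character(raw)
  hit <- match(key, names(map$raw_to_internal))
  if (anyNA(hit)) {
    bad <- unique(key[is.na(hit)])
    stop(sprintf("unknown label code(s) %s in %s (not in label map)",
                 paste(bad, collapse = ", "), path))
  }
  as.integer(map$raw_to_internal[hit])
}

#' Read a labeled point cloud from disk
#'
#' Two plain-text dialects are supported: `xyz_label_text` (one point per
#' line, `x y z [label]`, whitespace separated, `#` comment lines skipped)
#' and `ascii_ply` (ASCII PLY with per-vertex `x y z` and an optional integer
#' `label` property). Raw label codes are remapped to contiguous internal ids
#' through `label_map`; point order is preserved as in the file.
#'
#' @param path Path to the file.
#' @param label_map A [label_map()]; ignored for unlabeled files.
#' @param dialect `"xyz_label_text"` (default) or `"ascii_ply"`.
#' @return A [labeled_cloud()].
#' @export
read_labeled_cloud <- function(path, label_map = gcassn::label_map(),
                               dialect = c("xyz_label_text", "ascii_ply")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "xyz_label_text") read_xyz_text(path, label_map)
  else read_ascii_ply(path, label_map)
}

read_xyz_text <- function(path, map) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("no point records in ", path)
  toks <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(toks)
  if (any(nf != nf[1L]))
    stop(sprintf("parse error in %s at line %d: expected %d fields, got %d",
                 path, keep[which(nf != nf[1L])[1L]], nf[1L],
                 nf[nf != nf[1L]][1L]))
  if (!nf[1L] %in% c(3L, 4L))
    stop(sprintf("parse error in %s at line %d: need 'x y z [label]'",
                 path, keep[1L]))
  vals <- suppressWarnings(vapply(toks, function(t) as.numeric(t[1:3]),
                                  numeric(3)))
  bad <- which(colSums(is.na(vals)) > 0L)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: non-numeric coordinate",
                 path, keep[bad[1L]]))
  coords <- t(vals)
  labels <- NULL
  if (nf[1L] == 4L) {
    rawlab <- vapply(toks, function(t) t[4L], character(1))
    labels <- remap_labels(rawlab, map, path)
  }
  labeled_cloud(coords, labels, source_id = basename(path))
}

read_ascii_ply <- function(path, map) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 3L || trimws(raw[1L]) != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(raw))
  if (is.na(endh)) stop("parse error in ", path, ": missing end_header")
  header <- trimws(raw[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  vline <- grep("^element\\s+vertex\\s+\\d+", header, value = TRUE)
  if (length(vline) != 1L) stop("parse error in ", path, ": vertex element")
  nv <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1", vline))
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property\\s", header, value = TRUE))
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) stop("parse error in ", path, ": x/y/z properties missing")
  labcol <- match("label", props)
  body <- raw[endh + seq_len(nv)]
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks)
  if (any(nf < length(props)))
    stop(sprintf("parse error in %s at line %d: short vertex record",
                 path, endh + which(nf < length(props))[1L]))
  coords <- t(vapply(toks, function(t) as.numeric(t[need]), numeric(3)))
  if (any(!is.finite(coords))) stop("non-numeric coordinate in ", path)
  labels <- if (!is.na(labcol))
    remap_labels(vapply(toks, function(t) t[labcol], character(1)), map, path)
  labeled_cloud(coords, labels, source_id = basename(path))
}

#' Write a labeled point cloud to disk
#'
#' Inverse of [read_labeled_cloud()]. Labels are written as internal ids
#' passed through the inverse of `label_map` (so a round trip through the
#' same map is the identity).
#'
#' @inheritParams read_labeled_cloud
#' @param cloud A [labeled_cloud()].
#' @param digits Significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_labeled_cloud <- function(cloud, path, label_map = gcassn::label_map(),
                                dialect = c("xyz_label_text", "ascii_ply"),
                                digits = 8) {
  dialect <- match.arg(dialect)
  co <- formatC(cloud$coords, format = "g", digits = digits)
  rawlab <- NULL
  if (!is.null(cloud$labels)) {
    inv <- names(label_map$raw_to_internal)[
      match(cloud$labels, as.integer(label_map$raw_to_internal))]
    if (anyNA(inv)) stop("cloud contains labels outside the label map")
    rawlab <- inv
  }
  if (dialect == "xyz_label_text") {
    rows <- paste(co[, 1], co[, 2], co[, 3])
    if (!is.null(rawlab)) rows <- paste(rows, rawlab)
    writeLines(rows, path)
  } else {
    n <- nrow(co)
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", n),
                "property float x", "property float y", "property float z",
                if (!is.null(rawlab)) "property int label",
                "end_header")
    rows <- paste(co[, 1], co[, 2], co[, 3])
    if (!is.null(rawlab)) rows <- paste(rows, rawlab)
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' Randomly subsample (or pad) a cloud to a fixed size
#'
#' Plant scans run to millions of points; a fixed-size random subsample
#' (2,048 points by convention) represents the cloud for the network. When
#' the cloud has fewer than `n_points` points, every point is kept and the
#' deficit is drawn with replacement so small synthetic clouds stay usable.
#'
#' @param cloud A [labeled_cloud()].
#' @param n_points Target number of points (positive integer).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A [labeled_cloud()] with exactly `n_points` points; labels travel
#'   with their points.
#' @export
random_sample <- function(cloud, n_points = 2048L, seed = 1L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) stop("n_points must be >= 1")
  n <- nrow(cloud$coords)
  idx <- with_seed(seed, {
    if (n >= n_points) sample.int(n, n_points)
    else c(seq_len(n), sample.int(n, n_points - n, replace = TRUE))
  })
  labeled_cloud(cloud$coords[idx, , drop = FALSE],
                if (!is.null(cloud$labels)) cloud$labels[idx],
                cloud$source_id)
}

#' Center a cloud and scale it to the unit sphere
#'
#' Subtracts the centroid and divides by the maximum point norm, so the
#' output is centered at the origin with all points inside the unit ball
#' (a degenerate all-coincident cloud maps to all zeros). Labels unchanged.
#'
#' @param cloud A [labeled_cloud()].
#' @param mode `"unit_sphere"` (default), `"center"` (centroid only) or
#'   `"none"`.
#' @return A normalized [labeled_cloud()].
#' @export
normalize_cloud <- function(cloud, mode = c("unit_sphere", "center", "none")) {
  mode <- match.arg(mode)
  if (!all(is.finite(cloud$coords))) stop("coords must be finite")
  if (mode == "none") return(cloud)
  ctr <- colMeans(cloud$coords)
  co <- sweep(cloud$coords, 2L, ctr)
  if (mode == "unit_sphere") {
    r <- sqrt(max(rowSums(co^2)))
    if (r > 0) co <- co / r
  }
  labeled_cloud(co, cloud$labels, cloud$source_id)
}

#' Split a list of clouds into train and test sets
#'
#' @param clouds List of [labeled_cloud()] objects (at least 2).
#' @param train_fraction Fraction of clouds in the training set (default 0.8,
#'   the 8:2 convention).
#' @param seed Integer seed for the shuffle.
#' @return A list with class `dataset_split`: `train`, `test` (disjoint,
#'   exhaustive lists of clouds), `train_idx`, `test_idx`, `seed`.
#' @export
split_dataset <- function(clouds, train_fraction = 0.8, seed = 1L) {
  if (length(clouds) < 2L) stop("need at least 2 clouds to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  n <- length(clouds)
  n_train <- max(1L, min(n - 1L, as.integer(round(train_fraction * n))))
  perm <- with_seed(seed, sample.int(n))
  tr <- sort(perm[seq_len(n_train)])
  te <- sort(perm[(n_train + 1L):n])
  structure(list(train = clouds[tr], test = clouds[te],
                 train_idx = tr, test_idx = te, seed = seed),
            class = "dataset_split")
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
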