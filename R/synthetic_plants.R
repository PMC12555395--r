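#' Specification of a synthetic plant point cloud
#'
#' The generator emulates the structural pathologies of real plant scans:
#' curved, branching stems swept as tubes around cubic-spline axes; leaves
#' as parabolically bent elliptical surfaces attached to the stems;
#' an optional soil plane; uneven (top-heavier) point density; and a
#' label-ambiguous transition zone at the stem-leaf junctions where labels
#' follow the nearest-organ-surface rule.
#'
#' All lengths are in the same arbitrary unit as the output coordinates
#' (a plant of height ~1).
#'
#' @param n_points Total points to emit (>= 64).
#' @param stem List: `height`, tube `radius`, `curvature` (lateral
#'   amplitude of the axis spline), `n_branches`, `branch_angle`
#'   (degrees, range from vertical for branch axes).
#' @param leaves List: `count`, `length`, `width`, `bend` (parabolic
#'   out-of-plane amplitude), `jitter` (attachment position jitter).
#' @param soil List: `present`, `extent` (half-width of the plane),
#'   `thickness` (vertical jitter sd).
#' @param class_balance Optional numeric vector of target point fractions
#'   per present organ class (stem, leaf, soil order, normalized
#'   internally). `NULL` (default) allocates points proportionally to organ
#'   surface area.
#' @param density_gradient >= 0; 0 is area-uniform sampling, larger values
#'   weight sampling toward the top of the plant (self-occlusion proxy).
#' @param junction_blend Radius of the label-ambiguous zone around organ
#'   attachment points, in length units.
#' @param surface_noise Isotropic Gaussian jitter sd applied to every
#'   surface sample.
#' @param seed Integer seed; generation is bitwise deterministic per seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_points = 2048L,
                       stem = list(height = 1, radius = 0.025,
                                   curvature = 0.12, n_branches = 2L,
                                   branch_angle = c(25, 60)),
                       leaves = list(count = 6L, length = 0.32,
                                     width = 0.16, bend = 0.2,
                                     jitter = 0.02),
                       soil = list(present = TRUE, extent = 0.5,
                                   thickness = 0.015),
                       class_balance = NULL,
                       density_gradient = 0.6,
                       junction_blend = 0.04,
                       surface_noise = 0.004,
                       seed = 1L) {
  n_points <- as.integer(n_points)
  if (n_points < 64L) stop("n_points must be at least 64")
  if (stem$height <= 0 || stem$radius <= 0)
    stop("stem height and radius must be positive")
  if (leaves$count > 0 && (leaves$length <= 0 || leaves$width <= 0))
    stop("infeasible spec: zero-area leaf")
  if (density_gradient < 0) stop("density_gradient must be >= 0")
  if (junction_blend < 0 || junction_blend > 1)
    stop("junction_blend must be in [0, 1]")
  structure(list(n_points = n_points, stem = stem, leaves = leaves,
                 soil = soil, class_balance = class_balance,
                 density_gradient = density_gradient,
                 junction_blend = junction_blend,
                 surface_noise = surface_noise, seed = as.integer(seed)),
            class = "plant_spec")
}

# Smooth 3D axis through jittered control points; returns a dense polyline.
spline_axis <- function(base, tip, lateral_amp, n_ctrl = 4L, n_out = 160L) {
  tt <- seq(0, 1, length.out = n_ctrl + 2L)
  ctrl <- outer(1 - tt, base) + outer(tt, tip)
  mid <- 2:(n_ctrl + 1L)
  ctrl[mid, 1] <- ctrl[mid, 1] + stats::rnorm(n_ctrl, sd = lateral_amp)
  ctrl[mid, 2] <- ctrl[mid, 2] + stats::rnorm(n_ctrl, sd = lateral_amp)
  s <- seq(0, 1, length.out = n_out)
  cbind(stats::spline(tt, ctrl[, 1], xout = s)$y,
        stats::spline(tt, ctrl[, 2], xout = s)$y,
        stats::spline(tt, ctrl[, 3], xout = s)$y)
}

polyline_lengths <- function(ax) {
  d <- diff(ax)
  sqrt(rowSums(d^2))
}

# Arc-length-uniform positions and unit tangents along a polyline.
sample_on_axis <- function(ax, u) {
  seg <- polyline_lengths(ax)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- u * L
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
            length(seg))
  frac <- (s - cum[i]) / pmax(seg[i], 1e-12)
  pos <- ax[i, , drop = FALSE] +
    (ax[i + 1L, , drop = FALSE] - ax[i, , drop = FALSE]) * frac
  tang <- (ax[i + 1L, , drop = FALSE] - ax[i, , drop = FALSE]) /
    pmax(seg[i], 1e-12)
  list(pos = pos, tangent = tang)
}

# Orthonormal basis pair perpendicular to unit vectors (rows of tang).
perp_frame <- function(tang) {
  ref <- matrix(rep(c(1, 0, 0), each = nrow(tang)), ncol = 3L)
  near <- abs(tang[, 1]) > 0.9
  ref[near, ] <- matrix(rep(c(0, 1, 0), each = sum(near)), ncol = 3L)
  n1 <- cbind(tang[, 2] * ref[, 3] - tang[, 3] * ref[, 2],
              tang[, 3] * ref[, 1] - tang[, 1] * ref[, 3],
              tang[, 1] * ref[, 2] - tang[, 2] * ref[, 1])
  n1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

sample_tube <- function(ax, radius, n, noise_sd) {
  on <- sample_on_axis(ax, stats::runif(n))
  fr <- perp_frame(on$tangent)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- on$pos + radius * (fr$n1 * cos(th) + fr$n2 * sin(th))
  pts + matrix(stats::rnorm(3 * n, sd = noise_sd), n)
}

# A bent elliptical leaf surface attached at `base`, growing along `dir`.
# Returns a sampler closure and a dense reference sample of the surface.
make_leaf <- function(base, dir, len, wid, bend, noise_sd) {
  dir <- dir / sqrt(sum(dir^2))
  up <- c(0, 0, 1)
  v <- c(dir[2] * up[3] - dir[3] * up[2],
         dir[3] * up[1] - dir[1] * up[3],
         dir[1] * up[2] - dir[2] * up[1])
  if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0)
  v <- v / sqrt(sum(v^2))
  w <- c(dir[2] * v[3] - dir[3] * v[2],
         dir[3] * v[1] - dir[1] * v[3],
         dir[1] * v[2] - dir[2] * v[1])
  surf <- function(s, q, noise = TRUE) {
    # s in [0,1] along the midrib, q in [-1,1] across (ellipse-bounded)
    n <- length(s)
    half <- (wid / 2) * sqrt(pmax(0, 1 - ((s - 0.5) / 0.5)^2))
    pts <- matrix(base, n, 3L, byrow = TRUE) +
      outer(s * len, dir) + outer(q * half, v) + outer(bend * s^2, w)
    if (noise) pts <- pts + matrix(stats::rnorm(3 * n, sd = noise_sd), n)
    pts
  }
  gs <- as.matrix(expand.grid(s = seq(0.02, 0.98, length.out = 24),
                              q = seq(-0.98, 0.98, length.out = 12)))
  keep <- abs(gs[, 2]) <= sqrt(pmax(0, 1 - ((gs[, 1] - 0.5) / 0.5)^2))
  list(surf = surf, ref = surf(gs[keep, 1], gs[keep, 2], noise = FALSE),
       area = pi * (len / 2) * (wid / 2))
}

sample_leaf <- function(leaf, n) {
  # uniform on the unit disk, mapped to (s, q): area-uniform on the ellipse
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  leaf$surf(s = (r * cos(th) + 1) / 2, q = r * sin(th))
}

# Min distance from each query point to a polyline (segment-exact).
dist_to_polyline <- function(Q, ax) {
  best <- rep(Inf, nrow(Q))
  for (i in seq_len(nrow(ax) - 1L)) {
    a <- ax[i, ]; b <- ax[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((Q[, 1] - a[1]) * ab[1] + (Q[, 2] - a[2]) * ab[2] +
            (Q[, 3] - a[3]) * ab[3]) / max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    dx <- Q[, 1] - (a[1] + t * ab[1])
    dy <- Q[, 2] - (a[2] + t * ab[2])
    dz <- Q[, 3] - (a[3] + t * ab[3])
    best <- pmin(best, sqrt(dx^2 + dy^2 + dz^2))
  }
  best
}

dist_to_points <- function(Q, P) {
  qq <- rowSums(Q^2)
  pp <- rowSums(P^2)
  d2 <- outer(qq, pp, "+") - 2 * tcrossprod(Q, P)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Nearest-organ-surface labels for arbitrary points
#'
#' Geometric oracle: assigns each point the label of its nearest organ
#' surface (stem tube, leaf surface, soil plane), using the generating
#' geometry stored by [generate_plant()]. Used internally for the
#' junction-blend zone and available for consistency checks.
#'
#' @param coords Numeric `N x 3` matrix.
#' @param geometry The `geometry` attribute of a generated cloud.
#' @return Integer labels (stem 0, leaf 1, soil 2).
#' @export
nearest_organ_labels <- function(coords, geometry) {
  n <- nrow(coords)
  d_stem <- rep(Inf, n)
  for (st in geometry$stems)
    d_stem <- pmin(d_stem, abs(dist_to_polyline(coords, st$axis) - st$radius))
  d_leaf <- rep(Inf, n)
  for (lf in geometry$leaves)
    d_leaf <- pmin(d_leaf, dist_to_points(coords, lf))
  d_soil <- if (is.null(geometry$soil)) rep(Inf, n)
            else abs(coords[, 3] - geometry$soil$z)
  lab <- max.col(-cbind(d_stem, d_leaf, d_soil), ties.method = "first") - 1L
  lab
}

#' Generate one labeled synthetic plant point cloud
#'
#' Points are sampled area-uniformly on the organ surfaces, re-weighted by
#' the density gradient (top-heavier when positive), and labeled stem = 0,
#' leaf = 1, soil = 2. Inside the junction-blend zone around attachment
#' points, labels follow the nearest-organ-surface rule, deliberately
#' producing the hard stem-to-petiole boundary cases real scans show.
#' The generating geometry is attached as `attr(cloud, "geometry")`.
#'
#' @param spec A [plant_spec()].
#' @return A [labeled_cloud()] with exactly `spec$n_points` points.
#' @export
generate_plant <- function(spec) {
  with_seed(spec$seed, generate_plant_impl(spec))
}

generate_plant_impl <- function(spec) {
  st <- spec$stem
  lv <- spec$leaves
  noise_sd <- spec$surface_noise

  # --- stems: main axis plus branches
  main <- spline_axis(c(0, 0, 0), c(0, 0, st$height), st$curvature)
  stems <- list(list(axis = main, radius = st$radius))
  junctions <- NULL
  n_br <- st$n_branches %||% 0L
  if (n_br > 0) for (b in seq_len(n_br)) {
    u0 <- stats::runif(1, 0.35, 0.8)
    at <- sample_on_axis(main, u0)
    ang <- stats::runif(1, st$branch_angle[1], st$branch_angle[2]) * pi / 180
    az <- stats::runif(1, 0, 2 * pi)
    dir <- c(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang))
    blen <- st$height * stats::runif(1, 0.25, 0.45)
    br <- spline_axis(as.vector(at$pos), as.vector(at$pos) + dir * blen,
                      st$curvature * 0.5)
    stems[[length(stems) + 1L]] <- list(axis = br, radius = st$radius * 0.6)
    junctions <- rbind(junctions, at$pos)
  }

  # --- leaves attached along the stems (tips preferred)
  leaves <- list()
  if (lv$count > 0) for (i in seq_len(lv$count)) {
    host <- stems[[1L + (i %% length(stems))]]
    u0 <- stats::runif(1, 0.45, 1)
    at <- sample_on_axis(host$axis, u0)
    base <- as.vector(at$pos) + stats::rnorm(3, sd = lv$jitter)
    ang <- stats::runif(1, 35, 75) * pi / 180
    az <- stats::runif(1, 0, 2 * pi)
    dir <- c(sin(ang) * cos(az), sin(ang) * sin(az), cos(ang))
    # stand_off emulates a petiole: the blade starts slightly off the stem
    base <- base + dir * (lv$stand_off %||% 0)
    leaves[[i]] <- make_leaf(base, dir, lv$length, lv$width, lv$bend,
                             noise_sd)
    junctions <- rbind(junctions, matrix(base, 1L))
  }

  soil_on <- isTRUE(spec$soil$present)

  # --- area-proportional allocation of the sampling pool
  stem_area <- sum(vapply(stems, function(s)
    2 * pi * s$radius * sum(polyline_lengths(s$axis)), numeric(1)))
  leaf_area <- if (length(leaves)) sum(vapply(leaves, `[[`, numeric(1),
                                              "area")) else 0
  soil_area <- if (soil_on) (2 * spec$soil$extent)^2 * 0.35 else 0
  areas <- c(stem_area, leaf_area, soil_area)
  share <- if (is.null(spec$class_balance)) areas / sum(areas)
           else {
             cb <- spec$class_balance * (areas > 0)
             cb / sum(cb)
           }
  pool_n <- 2L * spec$n_points
  alloc <- pmax(ifelse(areas > 0, 32L, 0L), round(pool_n * share))

  pts <- NULL
  labs <- integer(0)
  if (alloc[1] > 0) {
    per <- vapply(stems, function(s)
      2 * pi * s$radius * sum(polyline_lengths(s$axis)), numeric(1))
    cnt <- pmax(8L, round(alloc[1] * per / sum(per)))
    for (j in seq_along(stems)) {
      pts <- rbind(pts, sample_tube(stems[[j]]$axis, stems[[j]]$radius,
                                    cnt[j], noise_sd))
      labs <- c(labs, rep(0L, cnt[j]))
    }
  }
  if (alloc[2] > 0 && length(leaves)) {
    cnt <- rep(ceiling(alloc[2] / length(leaves)), length(leaves))
    for (j in seq_along(leaves)) {
      pts <- rbind(pts, sample_leaf(leaves[[j]], cnt[j]))
      labs <- c(labs, rep(1L, cnt[j]))
    }
  }
  if (alloc[3] > 0) {
    ns <- alloc[3]
    sp <- cbind(stats::runif(ns, -spec$soil$extent, spec$soil$extent),
                stats::runif(ns, -spec$soil$extent, spec$soil$extent),
                stats::rnorm(ns, 0, spec$soil$thickness))
    pts <- rbind(pts, sp)
    labs <- c(labs, rep(2L, ns))
  }

  # --- density-gradient resampling to exactly n_points
  h <- (pts[, 3] - min(pts[, 3])) /
    max(max(pts[, 3]) - min(pts[, 3]), 1e-12)
  wts <- exp(spec$density_gradient * 2 * h)
  classes <- sort(unique(labs))
  quota <- pmax(1L, round(0.02 * spec$n_points))
  take <- integer(0)
  for (cl in classes) {
    own <- which(labs == cl)
    take <- c(take, own[sample.int(length(own), min(quota, length(own)),
                                   prob = wts[own])])
  }
  rest <- setdiff(seq_len(nrow(pts)), take)
  need <- spec$n_points - length(take)
  take <- c(take, rest[sample.int(length(rest), need, prob = wts[rest])])
  take <- sort(take)
  pts <- pts[take, , drop = FALSE]
  labs <- labs[take]

  geometry <- list(stems = stems,
                   leaves = lapply(leaves, `[[`, "ref"),
                   soil = if (soil_on) list(z = 0, extent = spec$soil$extent,
                                            thickness = spec$soil$thickness),
                   junctions = junctions,
                   blend = spec$junction_blend,
                   noise_sd = noise_sd)

  # --- junction blend zone: nearest-organ-surface labels
  if (!is.null(junctions) && spec$junction_blend > 0) {
    d2j <- rep(Inf, nrow(pts))
    for (r in seq_len(nrow(junctions)))
      d2j <- pmin(d2j, sqrt((pts[, 1] - junctions[r, 1])^2 +
                              (pts[, 2] - junctions[r, 2])^2 +
                              (pts[, 3] - junctions[r, 3])^2))
    in_blend <- d2j <= spec$junction_blend
    if (any(in_blend))
      labs[in_blend] <- nearest_organ_labels(
        pts[in_blend, , drop = FALSE], geometry)
  }

  cloud <- labeled_cloud(pts, labs,
                         source_id = sprintf("synthetic seed=%d", spec$seed))
  attr(cloud, "geometry") <- geometry
  cloud
}

#' Generate a dataset of varied synthetic plants
#'
#' Each plant's continuous geometric parameters are drawn by perturbing the
#' template's values by a relative `+/- variation`; per-plant seeds are
#' derived deterministically from the master seed, so the whole dataset is
#' reproducible.
#'
#' @param spec_template A [plant_spec()].
#' @param n_plants Number of plants (>= 1).
#' @param seed Master seed.
#' @param variation Relative perturbation amplitude (>= 0, e.g. 0.2).
#' @return List of `n_plants` labeled clouds.
#' @export
generate_dataset <- function(spec_template, n_plants, seed = 1L,
                             variation = 0.2) {
  if (n_plants < 1L) stop("n_plants must be >= 1")
  if (variation < 0) stop("variation must be >= 0")
  if (!inherits(spec_template, "plant_spec")) stop("invalid template")
  jig <- function(x, f) x * (1 + stats::runif(length(x), -f, f))
  lapply(seq_len(n_plants), function(i) {
    sp <- with_seed(seed + 7919L * i, {
      s <- spec_template
      s$stem$height <- jig(s$stem$height, variation)
      s$stem$radius <- jig(s$stem$radius, variation)
      s$stem$curvature <- jig(s$stem$curvature, variation)
      s$leaves$length <- jig(s$leaves$length, variation)
      s$leaves$width <- jig(s$leaves$width, variation)
      s$leaves$bend <- jig(s$leaves$bend, variation)
      s$soil$extent <- jig(s$soil$extent, variation)
      s$density_gradient <- jig(s$density_gradient, variation)
      s$seed <- (seed + 104729L * i) %% 2000000000L
      s
    })
    generate_plant(sp)
  })
}
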