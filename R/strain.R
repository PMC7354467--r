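# Diastole-to-systole displacement and per-point systolic wall strain.
# Displacement is the distance from each diastolic sample point to the
# systolic surface along the outward surface normal (normal-ray projection,
# with an unsigned closest-point fallback when the ray misses); strain is
# that displacement normalised by the local baseline (diastolic) radius,
# i.e. a dimensionless radial strain delta-r / r.

#' Centerline polyline
#'
#' An ordered 3D polyline with cumulative arc length and arc-length
#' fractions. The measurement substrate for tortuosity, curvature, station
#' diameters and the strain normaliser.
#'
#' @param points n x 3 matrix of polyline points (mm).
#' @return An object of class `centerline` with fields `points`, `arclen`
#'   (cumulative, mm) and `s` (arc-length fraction in `[0, 1]`).
#' @export
centerline <- function(points) {
  points <- as_xyz_matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points", call. = FALSE)
  al <- polyline_arclength(points)
  if (any(diff(al) <= 0))
    stop("centerline arc length must be strictly increasing (repeated points?)",
         call. = FALSE)
  structure(list(points = points, arclen = al, s = al / al[length(al)]),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), x$arclen[length(x$arclen)]))
  invisible(x)
}

# Linear interpolation of a centerline at ~n points for nearest-point queries.
densify_centerline <- function(cl, n = 400) {
  if (!inherits(cl, "centerline")) cl <- centerline(cl)
  if (nrow(cl$points) >= n) return(cl)
  s_new <- seq(0, 1, length.out = n)
  pts <- vapply(1:3, function(j) approx(cl$s, cl$points[, j], xout = s_new)$y,
                numeric(n))
  centerline(pts)
}

# Local baseline radius, station and outward radial unit vector of each point
# relative to a centerline.
local_radius <- function(points, cl) {
  points <- as_xyz_matrix(points)
  if (inherits(cl, "centerline")) {
    dense <- densify_centerline(cl)
    ref <- dense$points
    sref <- dense$s
  } else {
    ref <- as_xyz_matrix(cl)
    sref <- rep(0, nrow(ref))
  }
  if (nrow(ref) == 1L) {
    rad <- sweep(points, 2, ref[1, ])
    r <- sqrt(rowSums(rad^2))
    return(list(radius = r, station = rep(0, nrow(points)),
                radial_unit = rad / pmax(r, .Machine$double.eps)))
  }
  near <- nn1(points, ref)
  rad <- points - ref[near$idx, , drop = FALSE]
  r <- sqrt(rowSums(rad^2))
  list(radius = r, station = sref[near$idx],
       radial_unit = rad / pmax(r, .Machine$double.eps))
}

#' Extract the centerline of a tubular surface mesh
#'
#' Works on open tubes (exactly two boundary rings). Each vertex gets a
#' normalised axial coordinate `u = d1 / (d1 + d2)` from its graph-geodesic
#' distances to the two boundary rings; vertices are binned along `u`, bin
#' centroids form the raw centerline, which is then smoothed with a
#' low-order spline. Endpoints are anchored at the boundary-ring centroids.
#'
#' @param mesh A [surface_mesh()] with tube topology.
#' @param n_stations Number of centerline stations (default 50).
#' @return A [centerline()].
#' @export
extract_centerline <- function(mesh, n_stations = 50) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  # boundary edges = edges on exactly one face
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  boundary <- names(tab)[tab == 1L]
  if (length(boundary) == 0L)
    stop("mesh has no boundary: not an open tube (closed surface)", call. = FALSE)
  bmat <- do.call(rbind, lapply(strsplit(boundary, " "), as.integer))
  gb <- igraph::graph_from_edgelist(bmat, directed = FALSE)
  comp <- igraph::components(gb)
  ring_ids <- which(comp$csize > 2)
  loops <- sum(comp$csize > 2)
  if (loops != 2L)
    stop(sprintf("mesh is not an open tube: found %d boundary loop(s), need 2", loops),
         call. = FALSE)
  members <- split(seq_len(comp$no * 0 + length(comp$membership)), comp$membership)
  ring1 <- members[[ring_ids[1]]]
  ring2 <- members[[ring_ids[2]]]
  ring1 <- ring1[ring1 <= nrow(v)]
  ring2 <- ring2[ring2 <= nrow(v)]

  # harmonic axial coordinate: solve the graph Laplace equation with u = 0
  # on one boundary ring and u = 1 on the other. Harmonic interpolation has
  # smooth, ring-aligned level sets, unlike graph-geodesic distances whose
  # within-ring scatter cuts rings across bins and biases bin centroids
  # off-axis.
  eu <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  elen <- sqrt(rowSums((v[eu[, 1], , drop = FALSE] - v[eu[, 2], , drop = FALSE])^2))
  wts <- 1 / pmax(elen, .Machine$double.eps)
  nv <- nrow(v)
  W <- Matrix::sparseMatrix(i = c(eu[, 1], eu[, 2]), j = c(eu[, 2], eu[, 1]),
                            x = c(wts, wts), dims = c(nv, nv))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  boundary_v <- c(ring1, ring2)
  interior <- setdiff(seq_len(nv), boundary_v)
  u <- numeric(nv)
  u[ring2] <- 1
  if (length(interior)) {
    u[interior] <- as.numeric(Matrix::solve(
      L[interior, interior, drop = FALSE],
      -L[interior, boundary_v, drop = FALSE] %*% u[boundary_v]))
  }

  # local-linear kernel regression of each coordinate against u: every
  # cross-section ring enters the estimate with smoothly varying weights, so
  # no ring is ever split at a hard bin edge (split rings bias a bin
  # centroid off-axis by a sizeable fraction of the radius). Local-LINEAR
  # fitting is used because the local-constant average has first-order bias
  # at the open ends, where the centerline still carries full curvature.
  s_out <- seq(0, 1, length.out = max(n_stations, 10L))
  h <- max(1.5 / length(s_out), 0.015)
  sm <- vapply(s_out, function(s0) {
    w <- exp(-0.5 * ((u - s0) / h)^2)
    keep <- w > 1e-6
    ww <- w[keep]
    du <- u[keep] - s0
    X <- cbind(1, du)
    XtW <- t(X * ww)
    beta <- solve(XtW %*% X, XtW %*% v[keep, , drop = FALSE])
    beta[1, ]
  }, numeric(3))
  sm <- t(sm)
  # endpoints anchored at the boundary-ring centroids
  sm[1, ] <- colMeans(v[ring1, , drop = FALSE])
  sm[nrow(sm), ] <- colMeans(v[ring2, , drop = FALSE])
  centerline(sm)
}

#' Diastole-to-systole displacement field
#'
#' For each diastolic sample point, casts a ray along the outward surface
#' normal and returns the distance to the first intersection with the
#' systolic surface. Points whose ray misses within `cutoff` fall back to
#' the unsigned closest-point distance to the systolic surface; the number
#' of fallbacks is reported. Both phases are assumed to share one frame
#' (CTA cardiac phases are reconstructed in the same scanner coordinates),
#' so no alignment is applied.
#'
#' @param diastole A `point_cloud` carrying `normals` (as produced by
#'   [resample_surface()]), or a [surface_mesh()] (vertices with area-weighted
#'   vertex normals are used).
#' @param systole The systolic [surface_mesh()].
#' @param cutoff Maximum accepted ray distance (mm). Default 3 x the median
#'   local radius when a centerline is available, otherwise half the systolic
#'   bounding-box diagonal.
#' @param centerline Optional [centerline()] used for the default cutoff.
#' @return List with `displacement` (mm, per point), `hit` (logical: ray
#'   branch), `n_fallback`, and the `points`/`normals` used.
#' @export
displacement_field <- function(diastole, systole, cutoff = NULL, centerline = NULL) {
  stopifnot(inherits(systole, "surface_mesh"))
  validate_mesh(systole)
  if (inherits(diastole, "surface_mesh")) {
    pts <- diastole$vertices
    nrm <- vertex_normals(diastole)
    centerline <- centerline %||% diastole$centerline
  } else if (inherits(diastole, "point_cloud")) {
    pts <- diastole$points
    nrm <- diastole$normals
    if (is.null(nrm))
      stop("diastolic point cloud has no normals; resample from a mesh or supply a surface_mesh",
           call. = FALSE)
  } else {
    stop("`diastole` must be a point_cloud or surface_mesh", call. = FALSE)
  }
  if (is.null(cutoff)) {
    cutoff <- if (!is.null(centerline)) {
      3 * stats::median(local_radius(pts, centerline)$radius)
    } else {
      bbox_diagonal(systole$vertices) / 2
    }
  }
  t_hit <- .cpp_ray_mesh(as_xyz_matrix(pts), as_xyz_matrix(nrm),
                         as_xyz_matrix(systole$vertices), systole$faces, cutoff)
  miss <- is.na(t_hit)
  disp <- t_hit
  if (any(miss)) {
    disp[miss] <- .cpp_point_mesh_dist(as_xyz_matrix(pts[miss, , drop = FALSE]),
                                       as_xyz_matrix(systole$vertices), systole$faces)
  }
  list(displacement = disp, hit = !miss, n_fallback = sum(miss),
       points = pts, normals = nrm)
}

# Area-weighted vertex normals (outward for outward-wound faces).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])  # 2*area-weighted normal
  nrm <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (col in 1:3) {
      acc <- tapply(cr[, col], f[, j], sum)
      nrm[as.integer(names(acc)), col] <- nrm[as.integer(names(acc)), col] + acc
    }
  }
  nrm / pmax(sqrt(rowSums(nrm^2)), .Machine$double.eps)
}

#' Per-point systolic strain field
#'
#' Strain at diastolic point i is `displacement_i / r_i`, where `r_i` is the
#' local baseline radius: the distance from the point to its nearest
#' centerline point on the diastolic centerline. Points with `r_i` below
#' `radius_floor` are flagged invalid and excluded from summaries.
#'
#' @param displacements Result of [displacement_field()] (or a numeric
#'   vector, in which case `points` must be supplied).
#' @param cl The diastolic [centerline()] (a single 3D point is accepted as a
#'   degenerate centerline, e.g. a sphere center).
#' @param points Diastolic points (needed when `displacements` is a bare
#'   vector).
#' @param radius_floor Minimum valid baseline radius (mm). Default 0.1.
#' @return A `data.frame` of class `strain_field` with columns `x`, `y`,
#'   `z`, `displacement` (mm), `radius` (mm), `strain` (dimensionless),
#'   `station` (arc fraction), `valid`.
#' @export
strain_field <- function(displacements, cl, points = NULL, radius_floor = 0.1) {
  if (is.list(displacements) && !is.null(displacements$displacement)) {
    points <- displacements$points
    disp <- displacements$displacement
  } else {
    disp <- as.numeric(displacements)
    if (is.null(points)) stop("`points` required with a bare displacement vector",
                              call. = FALSE)
  }
  points <- as_xyz_matrix(points)
  stopifnot(length(disp) == nrow(points))
  if (is.numeric(cl) && is.null(dim(cl)) && length(cl) == 3L) cl <- matrix(cl, 1, 3)
  loc <- local_radius(points, cl)
  valid <- loc$radius >= radius_floor & is.finite(disp)
  strain <- ifelse(valid, disp / loc$radius, NA_real_)
  out <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                    displacement = disp, radius = loc$radius, strain = strain,
                    station = loc$station, valid = valid)
  class(out) <- c("strain_field", "data.frame")
  out
}

#' Summarise strain over a station window
#'
#' @param field A `strain_field`.
#' @param window Length-2 numeric `c(lo, hi)` with `0 <= lo < hi <= 1`
#'   (arc-length fractions).
#' @return List with `mean`, `peak`, `peak_station` and `n_points` over valid
#'   points whose station falls in the window.
#' @export
strain_at_station <- function(field, window = c(0.4, 0.6)) {
  stopifnot(inherits(field, "strain_field"))
  if (length(window) != 2L || window[1] < 0 || window[2] > 1 || window[1] >= window[2])
    stop("`window` must be c(lo, hi) with 0 <= lo < hi <= 1", call. = FALSE)
  sel <- field$valid & field$station >= window[1] & field$station <= window[2]
  if (!any(sel))
    stop(sprintf("no valid strain points in station window [%.2f, %.2f]",
                 window[1], window[2]), call. = FALSE)
  st <- field$strain[sel]
  list(mean = mean(st), peak = max(st),
       peak_station = field$station[sel][which.max(st)], n_points = sum(sel))
}
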