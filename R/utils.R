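# Internal utilities: seeded evaluation, rigid-transform algebra, nearest
# neighbours. Not exported except where noted.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# 1-nearest-neighbour of each row of `query` among rows of `ref` (both n x 3).
nn1 <- function(query, ref) {
  .cpp_nn1(as_xyz_matrix(query), as_xyz_matrix(ref))
}

as_xyz_matrix <- function(x, arg = "points") {
  if (inherits(x, "point_cloud")) x <- x$points
  if (inherits(x, "surface_mesh")) x <- x$vertices
  if (inherits(x, "centerline")) x <- x$points
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("`%s` must have 3 columns", arg), call. = FALSE)
  x
}

#' Rigid transform (rotation + translation)
#'
#' A proper rigid-body transform in 3D: `y = R x + t` with `det(R) = +1`
#' (no scaling, no reflection). Alignment in this package is rigid only:
#' size variation is deliberately retained so it can surface as a shape mode.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric 3-vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("`rotation` is not orthogonal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (det = +1): reflections are not rigid transforms",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix, `point_cloud`, or `surface_mesh`.
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_rigid <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  tf <- function(m) sweep(m %*% t(transform$rotation), 2, transform$translation, "+")
  if (inherits(points, "surface_mesh")) {
    points$vertices <- tf(points$vertices)
    if (!is.null(points$centerline))
      points$centerline$points <- tf(points$centerline$points)
    return(points)
  }
  if (inherits(points, "point_cloud")) {
    points$points <- tf(points$points)
    if (!is.null(points$normals))
      points$normals <- points$normals %*% t(transform$rotation)
    return(points)
  }
  tf(as_xyz_matrix(points))
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`. `invert_rigid(a)` returns the inverse transform.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' Rotation angle of a rigid transform
#'
#' @param transform A [rigid_transform()] or a 3x3 rotation matrix.
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation else transform
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  ang * 180 / pi
}

#' Random rigid transform
#'
#' Rotation axis uniform on the sphere, rotation angle uniform in
#' `[0, max_angle_deg]`, translation components uniform in
#' `[-max_translation, max_translation]`.
#'
#' @param max_angle_deg Maximum rotation angle (degrees).
#' @param max_translation Maximum translation per axis (mm).
#' @param seed Optional integer seed.
#' @return A `rigid_transform`.
#' @export
random_rigid <- function(max_angle_deg = 30, max_translation = 50, seed = NULL) {
  with_seed(seed, {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, max_angle_deg) * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    rigid_transform(R, runif(3, -max_translation, max_translation))
  })
}

# Least-squares rigid fit (Kabsch): returns the rigid_transform T minimizing
# ||T(source) - target||, given row-wise correspondence.
kabsch <- function(source, target) {
  source <- as_xyz_matrix(source)
  target <- as_xyz_matrix(target)
  stopifnot(nrow(source) == nrow(target))
  cs <- colMeans(source)
  ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

# Cumulative arc length of a polyline (first entry 0).
polyline_arclength <- function(points) {
  points <- as_xyz_matrix(points)
  if (nrow(points) < 2L) return(0)
  seg <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(seg))
}

bbox_diagonal <- function(points) {
  points <- as_xyz_matrix(points)
  sqrt(sum((apply(points, 2, max) - apply(points, 2, min))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
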