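# PCA shape atlas: decomposition of corresponded, aligned point clouds into
# orthonormal shape modes with per-subject mode scores ("shape vectors"),
# template deformation along modes, and projection of new subjects. The SVD
# is taken on the subjects x 3N data matrix rather than forming the 3N x 3N
# covariance -- mathematically identical and feasible at N = 15,000.

#' Fit the PCA shape atlas
#'
#' Flattens each corresponded cloud to a 3N shape vector (x1, y1, z1, x2,
#' ...), centers columns on the mean shape, and takes the SVD. Eigenvalues
#' are singular values squared over (n_subjects - 1); at most n_subjects - 1
#' modes are non-null. Mode sign is made deterministic by orienting each
#' eigenvector to have non-negative inner product with the template's radial
#' inflation direction (points minus template centroid, normalised); exact
#' ties fall back to a positive first nonzero component.
#'
#' @param corresponded A `shape_template` from [build_template()], or a
#'   subjects x N x 3 array of corresponded clouds (>= 3 subjects).
#' @param subject_ids Optional subject ids (taken from the input if present).
#' @param variance_threshold Cumulative-variance level reported as
#'   `n_modes_retained` (default 0.90).
#' @return Object of class `shape_atlas`: `template` (mean shape, N x 3),
#'   `modes` (3N x m orthonormal matrix), `eigenvalues` (mm^2, non-increasing),
#'   `variance_fractions`, `scores` (subjects x m, mm; the shape vectors),
#'   `subject_ids`, `n_modes_retained_90`, `degenerate`.
#' @export
fit_pca <- function(corresponded, subject_ids = NULL, variance_threshold = 0.90) {
  if (inherits(corresponded, "shape_template")) {
    subject_ids <- subject_ids %||% corresponded$subject_ids
    corresponded <- corresponded$corresponded
  }
  if (length(dim(corresponded)) != 3L || dim(corresponded)[3] != 3L)
    stop("`corresponded` must be a subjects x N x 3 array", call. = FALSE)
  n <- dim(corresponded)[1]
  N <- dim(corresponded)[2]
  if (n < 3L) stop("PCA needs >= 3 subjects for a non-trivial first mode", call. = FALSE)
  subject_ids <- subject_ids %||% dimnames(corresponded)[[1]] %||%
    sprintf("subject_%03d", seq_len(n))

  # rows = flattened shape vectors (x1, y1, z1, x2, ...)
  X <- matrix(NA_real_, n, 3 * N)
  for (i in seq_len(n)) X[i, ] <- as.vector(t(corresponded[i, , ]))
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = n, nv = min(n, 3 * N))
  eig <- sv$d^2 / (n - 1)

  scale_ref <- max(eig[1], .Machine$double.eps)
  keep <- which(eig > 1e-12 * scale_ref)
  degenerate <- length(keep) == 0L
  if (degenerate) {
    keep <- integer(0)
    modes <- matrix(0, 3 * N, 0)
    scores <- matrix(0, n, 0)
    eigv <- numeric(0)
    fracs <- numeric(0)
  } else {
    modes <- sv$v[, keep, drop = FALSE]
    eigv <- eig[keep]
    fracs <- eigv / sum(eigv)
    template_pts <- matrix(mean_shape, ncol = 3, byrow = TRUE)
    radial <- sweep(template_pts, 2, colMeans(template_pts))
    radial <- radial / pmax(sqrt(rowSums(radial^2)), .Machine$double.eps)
    radial_flat <- as.vector(t(radial))
    for (k in seq_along(keep)) {
      dp <- sum(modes[, k] * radial_flat)
      if (abs(dp) > 1e-9) {
        if (dp < 0) modes[, k] <- -modes[, k]
      } else {
        nz <- which(abs(modes[, k]) > 1e-12)[1]
        if (!is.na(nz) && modes[nz, k] < 0) modes[, k] <- -modes[, k]
      }
    }
    scores <- Xc %*% modes
  }
  rownames(scores) <- subject_ids
  if (ncol(scores)) colnames(scores) <- paste0("mode", seq_len(ncol(scores)))

  atlas <- structure(list(template = matrix(mean_shape, ncol = 3, byrow = TRUE),
                          mean_shape = mean_shape,
                          modes = modes, eigenvalues = eigv,
                          variance_fractions = fracs, scores = scores,
                          subject_ids = subject_ids,
                          n_points = N, n_subjects = n,
                          degenerate = degenerate),
                     class = "shape_atlas")
  atlas$n_modes_retained_90 <- if (degenerate) NA_integer_ else
    modes_for_variance(atlas, variance_threshold)
  atlas
}

#' @export
print.shape_atlas <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<shape_atlas> DEGENERATE (zero shape variance); %d subjects, %d points\n",
                x$n_subjects, x$n_points))
  } else {
    cat(sprintf("<shape_atlas> %d subjects, %d points, %d modes; mode 1 explains %.1f%%, %d mode(s) reach 90%%\n",
                x$n_subjects, x$n_points, length(x$eigenvalues),
                100 * x$variance_fractions[1], x$n_modes_retained_90))
  }
  invisible(x)
}

#' Number of modes needed to reach a cumulative variance fraction
#'
#' @param atlas A `shape_atlas`.
#' @param threshold Fraction in (0, 1].
#' @return Smallest k with cumulative variance fraction >= `threshold`.
#' @export
modes_for_variance <- function(atlas, threshold = 0.90) {
  stopifnot(inherits(atlas, "shape_atlas"))
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  if (atlas$degenerate)
    stop("atlas is degenerate (zero shape variance): no modes to retain", call. = FALSE)
  cum <- cumsum(atlas$variance_fractions)
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Deform the template along one shape mode
#'
#' Returns `template + c * sqrt(eigenvalue_k) * mode_k`, the standard +/-2 SD
#' visualisation of a mode's deformation. `|c| > 2` is allowed with a warning
#' (extrapolation beyond the fitted range).
#'
#' @param atlas A `shape_atlas`.
#' @param mode_k Mode index.
#' @param c Multiple of the mode SD, typically in `[-2, 2]`.
#' @return A [point_cloud()] of the deformed template.
#' @export
deform_template <- function(atlas, mode_k, c = 0) {
  stopifnot(inherits(atlas, "shape_atlas"))
  if (atlas$degenerate) stop("atlas is degenerate; no modes", call. = FALSE)
  if (mode_k < 1 || mode_k > length(atlas$eigenvalues))
    stop(sprintf("mode_k must be in 1..%d", length(atlas$eigenvalues)), call. = FALSE)
  if (abs(c) > 2)
    warning(sprintf("|c| = %.2f > 2 SD: extrapolating beyond the fitted shape range", abs(c)))
  flat <- atlas$mean_shape + c * sqrt(atlas$eigenvalues[mode_k]) * atlas$modes[, mode_k]
  point_cloud(matrix(flat, ncol = 3, byrow = TRUE),
              subject_id = sprintf("template_mode%d_%+.1fSD", mode_k, c))
}

#' Project a corresponded cloud onto the atlas modes
#'
#' Scores are the inner products of the centered flattened cloud with each
#' eigenvector; projecting a training subject reproduces its stored score row.
#'
#' @param atlas A `shape_atlas`.
#' @param corresponded_cloud N x 3 matrix or [point_cloud()], corresponded to
#'   the atlas template (same N and point order).
#' @return Numeric vector of mode scores (mm).
#' @export
project_subject <- function(atlas, corresponded_cloud) {
  stopifnot(inherits(atlas, "shape_atlas"))
  pts <- as_xyz_matrix(corresponded_cloud, "corresponded_cloud")
  if (nrow(pts) != atlas$n_points)
    stop(sprintf("cloud has %d points but atlas has %d", nrow(pts), atlas$n_points),
         call. = FALSE)
  as.numeric(crossprod(atlas$modes, as.vector(t(pts)) - atlas$mean_shape))
}

#' Reconstruct a subject from its mode scores
#'
#' `mean shape + sum_k score_k * mode_k`; with all modes kept this reproduces
#' the corresponded cloud exactly.
#'
#' @param atlas A `shape_atlas`.
#' @param scores Numeric score vector (length <= number of modes).
#' @return N x 3 matrix.
#' @export
reconstruct_subject <- function(atlas, scores) {
  stopifnot(inherits(atlas, "shape_atlas"))
  k <- length(scores)
  flat <- atlas$mean_shape +
    as.numeric(atlas$modes[, seq_len(k), drop = FALSE] %*% scores)
  matrix(flat, ncol = 3, byrow = TRUE)
}

#' Scree table of an atlas
#'
#' @param atlas A `shape_atlas`.
#' @return `data.frame` with mode index, eigenvalue, variance fraction and
#'   cumulative variance fraction.
#' @export
scree_table <- function(atlas) {
  stopifnot(inherits(atlas, "shape_atlas"))
  data.frame(mode = seq_along(atlas$eigenvalues),
             eigenvalue = atlas$eigenvalues,
             variance_fraction = atlas$variance_fractions,
             cumulative_fraction = cumsum(atlas$variance_fractions))
}

#' Save / load a shape atlas as a plain-text bundle
#'
#' The atlas is persisted as a directory of CSV files (template, modes,
#' eigenvalues, scores) plus a JSON metadata file -- a text-only container
#' that diffs and version-controls cleanly.
#'
#' @param atlas A `shape_atlas`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (for `save_atlas`) or the restored `shape_atlas`.
#' @export
save_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "shape_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(atlas$template), file.path(dir, "template.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(atlas$modes), file.path(dir, "modes.csv"), row.names = FALSE)
  write.csv(data.frame(eigenvalue = atlas$eigenvalues,
                       variance_fraction = atlas$variance_fractions),
            file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = atlas$subject_ids, atlas$scores,
                       check.names = FALSE),
            file.path(dir, "scores.csv"), row.names = FALSE)
  meta <- list(n_points = atlas$n_points, n_subjects = atlas$n_subjects,
               degenerate = atlas$degenerate,
               n_modes_retained_90 = atlas$n_modes_retained_90)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "atlas.json"))
  invisible(dir)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "atlas.json"))
  template <- as.matrix(read.csv(file.path(dir, "template.csv")))
  modes <- as.matrix(read.csv(file.path(dir, "modes.csv")))
  ev <- read.csv(file.path(dir, "eigenvalues.csv"))
  sc <- read.csv(file.path(dir, "scores.csv"), check.names = FALSE)
  scores <- as.matrix(sc[, -1, drop = FALSE])
  rownames(scores) <- sc$subject_id
  dimnames(template) <- NULL
  dimnames(modes) <- NULL
  structure(list(template = template, mean_shape = as.vector(t(template)),
                 modes = modes, eigenvalues = ev$eigenvalue,
                 variance_fractions = ev$variance_fraction, scores = scores,
                 subject_ids = sc$subject_id, n_points = meta$n_points,
                 n_subjects = meta$n_subjects, degenerate = meta$degenerate,
                 n_modes_retained_90 = meta$n_modes_retained_90),
            class = "shape_atlas")
}
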