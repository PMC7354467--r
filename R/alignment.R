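# Rigid alignment (iterative closest point), unbiased template construction
# by iterated re-alignment and re-averaging, and closest-point
# correspondence. Alignment is strictly rigid (rotation + translation, no
# scaling): overall aortic size is a shape feature and must survive into the
# PCA, where it is expected to dominate the first mode.

#' Rigid iterative-closest-point registration
#'
#' Aligns `source` onto `target` by alternating nearest-neighbour matching
#' (k-d tree) with least-squares rigid fitting (Kabsch/SVD). The RMS
#' nearest-neighbour distance is non-increasing across iterations.
#' Initialisation is multi-start: centroids superposed, principal axes
#' pre-aligned (signs disambiguated by a third-moment test), plus the three
#' 180-degree flips about the target principal axes -- near-symmetric tubes
#' otherwise trap ICP in an end-to-end flipped local optimum. Each start is
#' burned in for a few iterations and the best is run to convergence.
#'
#' @param source,target [point_cloud()]s or n x 3 matrices (>= 3
#'   non-collinear points each).
#' @param max_iter Maximum iterations. Default 100.
#' @param tol Stop when the RMSD improvement falls below this (mm).
#' @param init `"pca"` (default: full multi-start) or `"identity"`
#'   (centroid start only).
#' @param init_transform Optional extra starting [rigid_transform()] (e.g. a
#'   warm start from a previous alignment round).
#' @param burn_in Iterations used to rank the candidate starts; generous by
#'   default so candidates are effectively converged (they stop early once
#'   the RMSD improvement falls below `tol`) and basins are compared fairly.
#' @return List with `transform` (the [rigid_transform()] mapping source into
#'   the target frame), `aligned` (transformed source), `rmsd`, `history`
#'   (RMSD per iteration of the winning start), `iterations` and `converged`
#'   (non-convergence is flagged, not an error).
#' @export
icp_rigid <- function(source, target, max_iter = 100, tol = 1e-9,
                      init = c("pca", "identity"), init_transform = NULL,
                      burn_in = 40) {
  init <- match.arg(init)
  src_obj <- source
  P <- as_xyz_matrix(source, "source")
  Q <- as_xyz_matrix(target, "target")
  check_nondegenerate(P, "source")
  check_nondegenerate(Q, "target")

  cp <- colMeans(P)
  cq <- colMeans(Q)
  starts <- list(rigid_transform(diag(3), cq - cp))
  if (init == "pca") {
    R0 <- principal_axes_rotation(P, Q)
    Ut <- principal_axes(Q)
    for (flip in 0:3) {
      Rf <- if (flip == 0) R0 else {
        ax <- Ut[, flip]
        # Rodrigues for a 180-degree rotation: 2 a a^T - I
        (2 * tcrossprod(ax) - diag(3)) %*% R0
      }
      starts <- c(starts, list(rigid_transform(Rf, cq - as.numeric(Rf %*% cp))))
    }
  }
  if (!is.null(init_transform)) starts <- c(starts, list(init_transform))

  run <- function(tf, iters, tol_run = tol) {
    # one NN pass per iteration: the RMSD of the current pose is read off the
    # match step, and the rigid refit that follows can only decrease it
    history <- numeric(0)
    prev <- Inf
    converged <- FALSE
    rmsd <- NA_real_
    for (it in seq_len(iters)) {
      m <- nn1(apply_rigid(tf, P), Q)
      rmsd <- sqrt(mean(m$dist^2))
      history <- c(history, rmsd)
      if (prev - rmsd < tol_run) {
        converged <- tol_run <= tol
        break
      }
      prev <- rmsd
      tf <- kabsch(P, Q[m$idx, , drop = FALSE])
    }
    list(tf = tf, history = history, converged = converged, rmsd = rmsd)
  }

  if (length(starts) > 1L) {
    # rank candidates at a loose relative tolerance; only the winner is
    # polished to the requested tol. Ranking uses the SYMMETRIC RMSD
    # (source-to-target plus target-to-source): the one-directional RMSD can
    # prefer a mis-oriented pose that drapes the source over part of the
    # target while leaving target structure uncovered, which only the
    # reverse direction sees.
    scale <- bbox_diagonal(Q)
    burns <- lapply(starts, run, iters = burn_in, tol_run = max(tol, 1e-5 * scale))
    sym <- vapply(burns, function(b) {
      moved <- apply_rigid(b$tf, P)
      sqrt((mean(nn1(moved, Q)$dist^2) + mean(nn1(Q, moved)$dist^2)) / 2)
    }, numeric(1))
    best <- which.min(sym)
    warm <- burns[[best]]
    history <- warm$history
    converged <- warm$converged
    tf <- warm$tf
  } else {
    history <- numeric(0)
    converged <- FALSE
    tf <- starts[[1]]
  }
  if (!converged) {
    cont <- run(tf, max(0L, max_iter - length(history)))
    tf <- cont$tf
    history <- c(history, cont$history)
    converged <- cont$converged
  }
  aligned <- apply_rigid(tf, src_obj)
  list(transform = tf, aligned = aligned, rmsd = history[length(history)],
       history = history, iterations = length(history), converged = converged)
}

principal_axes <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
}

check_nondegenerate <- function(P, what) {
  if (nrow(P) < 3L)
    stop(sprintf("%s cloud has %d point(s); >= 3 non-collinear points required",
                 what, nrow(P)), call. = FALSE)
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] <= 1e-10 * max(sv[1], 1))
    stop(sprintf("%s cloud is degenerate (collinear points)", what), call. = FALSE)
}

# Rotation taking the principal axes of P onto those of Q, each axis sign-
# disambiguated by the third central moment along it (ties left as-is), with
# the last axis flipped if needed to keep det = +1.
principal_axes_rotation <- function(P, Q) {
  axes <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    U <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
    for (k in 1:3) {
      sk <- mean((Xc %*% U[, k])^3)
      if (abs(sk) > 1e-8 && sk < 0) U[, k] <- -U[, k]
    }
    if (det(U) < 0) U[, 3] <- -U[, 3]
    U
  }
  Us <- axes(P)
  Ut <- axes(Q)
  Ut %*% t(Us)
}

#' Initial reference subject for template construction
#'
#' The subject whose mid-ascending diameter is closest to the population mean
#' diameter; ties are broken by lexicographic subject id.
#'
#' @param cohort A `cohort_table` with `diameter_midaa` present for all rows.
#' @return The selected `subject_id` (character scalar).
#' @export
select_initial_reference <- function(cohort) {
  d <- cohort$diameter_midaa
  miss <- is.na(d)
  if (any(miss))
    stop(sprintf("missing mid-ascending diameter for subject(s): %s",
                 paste(cohort$subject_id[miss], collapse = ", ")), call. = FALSE)
  dev <- abs(d - mean(d))
  cand <- cohort$subject_id[dev <= min(dev) + 1e-12]
  sort(cand)[1]
}

#' Closest-point correspondence from a template to a subject
#'
#' For each template point, takes the closest point of the (rigidly aligned)
#' subject cloud as its correspondent. Output row order matches the template;
#' subject points may be used more than once. This closest-point scheme is
#' the minimal correspondence model consistent with rigid-only alignment; no
#' non-rigid registration is attempted.
#'
#' @param template_points N x 3 matrix (or `point_cloud`).
#' @param aligned_subject Subject cloud already in the template frame.
#' @return N x 3 matrix of corresponded subject points.
#' @export
correspond <- function(template_points, aligned_subject) {
  tp <- as_xyz_matrix(template_points, "template_points")
  sp <- as_xyz_matrix(aligned_subject, "aligned_subject")
  sp[nn1(tp, sp)$idx, , drop = FALSE]
}

#' Build the unbiased population template
#'
#' Round 0 aligns every subject to the reference cloud (ICP), corresponds
#' reference-to-subject, and averages the corresponded clouds into a first
#' template. Each subsequent round re-aligns all original clouds to the
#' current template, re-corresponds and re-averages; iteration stops when the
#' mean template point displacement between rounds drops below `tol`
#' (default 1e-3 x the population mean bounding-box diagonal) or after
#' `max_rounds`. Iterating the align/average cycle removes the bias toward
#' the initial reference subject.
#'
#' @param clouds List of [point_cloud()]s with equal point counts.
#' @param reference Subject id or index of the initial reference. Default:
#'   the subject whose bounding-box diagonal is closest to the population
#'   mean (a size-based proxy usable without a cohort table; use
#'   [select_initial_reference()] when diameters are available).
#' @param max_rounds Maximum align/average rounds. Default 10.
#' @param tol Mean template displacement tolerance (mm); see above.
#' @param icp_args List of extra arguments for [icp_rigid()]. The default
#'   `list(init = "identity")` encodes the cohort prior that CTA meshes share
#'   the scanner frame (patients are imaged supine, so aortas arrive roughly
#'   co-oriented): local refinement from that prior cannot fall into the
#'   end-to-end flipped pose that global multi-start can choose for
#'   strongly deformed, nearly flip-symmetric tubes. Pass
#'   `list(init = "pca")` for cohorts with arbitrary orientations.
#' @return List of class `shape_template`: `template` (N x 3), `transforms`
#'   (per-subject [rigid_transform()]s into the template frame),
#'   `corresponded` (subjects x N x 3 array), `subject_ids`, `history`
#'   (mean template change per round, mm), `iteration_count`, `converged`.
#' @export
build_template <- function(clouds, reference = NULL, max_rounds = 10, tol = NULL,
                           icp_args = list()) {
  stopifnot(is.list(clouds), length(clouds) >= 2L)
  n <- length(clouds)
  pts <- lapply(clouds, as_xyz_matrix)
  N <- vapply(pts, nrow, integer(1))
  if (length(unique(N)) != 1L)
    stop(sprintf("clouds have mismatched point counts: %s",
                 paste(unique(N), collapse = ", ")), call. = FALSE)
  N <- N[1]
  ids <- vapply(seq_along(clouds), function(i) {
    id <- if (inherits(clouds[[i]], "point_cloud")) clouds[[i]]$subject_id else ""
    if (nzchar(id)) id else sprintf("subject_%03d", i)
  }, character(1))
  if (n == 2L)
    message("build_template: only 2 subjects; template is the midpoint shape")

  if (is.null(reference)) {
    diag_len <- vapply(pts, bbox_diagonal, numeric(1))
    ref_idx <- which.min(abs(diag_len - mean(diag_len)))
  } else if (is.character(reference)) {
    ref_idx <- match(reference, ids)
    if (is.na(ref_idx)) stop(sprintf("reference subject '%s' not found", reference),
                             call. = FALSE)
  } else {
    ref_idx <- as.integer(reference)
  }
  tol <- tol %||% (1e-3 * mean(vapply(pts, bbox_diagonal, numeric(1))))
  # per-round ICP needs only to out-resolve the template stopping rule;
  # users can override via icp_args
  icp_args <- utils::modifyList(list(init = "identity", tol = tol / 10,
                                     max_iter = 60), icp_args)

  align_round <- function(target, warm) {
    corresponded <- array(NA_real_, c(n, N, 3))
    transforms <- vector("list", n)
    for (i in seq_len(n)) {
      args <- utils::modifyList(list(init_transform = warm[[i]]), icp_args)
      fit <- do.call(icp_rigid,
                     c(list(source = pts[[i]], target = target), args))
      transforms[[i]] <- fit$transform
      corresponded[i, , ] <- correspond(target, as_xyz_matrix(fit$aligned))
    }
    list(corresponded = corresponded, transforms = transforms)
  }

  template <- pts[[ref_idx]]
  history <- numeric(0)
  converged <- FALSE
  rounds <- 0L
  transforms <- vector("list", n)
  corresponded <- NULL
  for (round in seq_len(max_rounds)) {
    res <- align_round(template, transforms)
    new_template <- apply(res$corresponded, c(2, 3), mean)
    # remove the rigid gauge freedom: the averaged template may pick up a
    # small net rotation/translation each round; realigning it onto the
    # previous template keeps the frame fixed so the stopping rule sees only
    # genuine shape change
    if (round > 1L) {
      gauge <- kabsch(new_template, template)
      new_template <- apply_rigid(gauge, new_template)
    }
    change <- mean(sqrt(rowSums((new_template - template)^2)))
    history <- c(history, change)
    template <- new_template
    transforms <- res$transforms
    corresponded <- res$corresponded
    rounds <- round
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  names(transforms) <- ids
  dimnames(corresponded) <- list(ids, NULL, NULL)
  structure(list(template = template, transforms = transforms,
                 corresponded = corresponded, subject_ids = ids,
                 history = history, iteration_count = rounds,
                 converged = converged, tol = tol),
            class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("<shape_template> %d subjects, %d points, %d round(s), %s (last change %.3g mm)\n",
              length(x$subject_ids), nrow(x$template), x$iteration_count,
              if (x$converged) "converged" else "NOT converged",
              x$history[length(x$history)]))
  invisible(x)
}
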