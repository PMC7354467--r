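# Mode-descriptor correlations, two-group comparisons, the shape-mode
# logistic risk model versus the diameter-only baseline with ROC/AUC, and
# cluster analysis of the mode-score plane. Standard tests are delegated to
# base R (cor.test, wilcox.test, chisq.test, glm, kmeans); the ROC/AUC path
# is in-package and is cross-checked against the rank-sum identity.
# Raw p-values are reported by default (significance read at 0.05);
# Benjamini-Hochberg adjustment is available via `p_adjust`.

#' Pearson correlations of shape modes with descriptors
#'
#' One Pearson R and two-sided p-value (t distribution, n - 2 df) per
#' (mode, descriptor) pair, with pairwise deletion of missing values.
#' Zero-variance pairs are flagged `undefined` rather than failing.
#'
#' @param scores Subjects x modes matrix (e.g. `atlas$scores`).
#' @param descriptors Data frame of descriptor columns (e.g. a
#'   `cohort_table`), rows matching `scores`.
#' @param columns Descriptor column names to test; default: all numeric
#'   columns except identifiers.
#' @param modes Mode indices to test; default: all.
#' @param subset Optional logical/integer subject filter (e.g.
#'   `cohort$valve == "BAV"`).
#' @param p_adjust `"none"` (default: raw p at the 0.05 threshold) or a
#'   method of [stats::p.adjust()] such as `"BH"`; recorded in the result.
#' @return `data.frame` with `mode`, `descriptor`, `R`, `p`, `n`,
#'   `undefined`; attribute `p_adjust` records the method used.
#' @export
correlate_modes <- function(scores, descriptors, columns = NULL, modes = NULL,
                            subset = NULL, p_adjust = "none") {
  scores <- as.matrix(scores)
  if (!is.null(subset)) {
    scores <- scores[subset, , drop = FALSE]
    descriptors <- descriptors[subset, , drop = FALSE]
  }
  if (nrow(scores) != nrow(descriptors))
    stop("scores and descriptors must have matching rows", call. = FALSE)
  if (is.null(columns)) {
    num <- vapply(descriptors, is.numeric, logical(1))
    columns <- setdiff(names(descriptors)[num], c("subject_id"))
  }
  modes <- modes %||% seq_len(ncol(scores))
  res <- list()
  for (k in modes) {
    for (col in columns) {
      x <- scores[, k]
      y <- descriptors[[col]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        res[[length(res) + 1L]] <- data.frame(mode = k, descriptor = col,
                                              R = NA_real_, p = NA_real_, n = n,
                                              undefined = TRUE)
      } else {
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        res[[length(res) + 1L]] <- data.frame(mode = k, descriptor = col,
                                              R = unname(ct$estimate),
                                              p = ct$p.value, n = n,
                                              undefined = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (p_adjust != "none") out$p <- p.adjust(out$p, method = p_adjust)
  attr(out, "p_adjust") <- p_adjust
  out
}

#' Two-group comparison (Mann-Whitney or chi-square)
#'
#' `mann_whitney`: exact two-sided Mann-Whitney U for group sizes <= 20
#' without ties, normal approximation with tie correction otherwise.
#' `chi_square`: Pearson chi-square on the contingency table of `values` by
#' `groups`, without Yates continuity correction by default.
#'
#' @param values Numeric vector (`mann_whitney`) or categorical vector /
#'   2 x k table (`chi_square`).
#' @param groups Two-level grouping vector (ignored when `values` is already
#'   a table).
#' @param kind `"mann_whitney"` or `"chi_square"`.
#' @param correct Yates correction for chi-square. Default `FALSE`.
#' @return List with `statistic`, `p`, `kind`, `exact` (Mann-Whitney only).
#' @export
compare_groups <- function(values, groups = NULL, kind = c("mann_whitney", "chi_square"),
                           correct = FALSE) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("mann_whitney needs exactly two groups", call. = FALSE)
    x <- values[g == levels(g)[1]]
    y <- values[g == levels(g)[2]]
    if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
    exact <- max(length(x), length(y)) <= 20 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    list(statistic = unname(wt$statistic), p = wt$p.value, kind = kind, exact = exact)
  } else {
    tab <- if (is.table(values) || is.matrix(values)) as.table(as.matrix(values))
           else table(values, groups)
    if (any(tab < 1))
      stop("chi-square requires counts >= 1 in every cell", call. = FALSE)
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p = ct$p.value, kind = kind)
  }
}

#' ROC curve and AUC
#'
#' Threshold sweep over the distinct predicted values, with (0,0) and (1,1)
#' end points; AUC by trapezoid. The AUC equals the rank-sum statistic (the
#' probability that a random positive outranks a random negative, ties
#' half-counted) and is invariant to monotone transforms of the scores.
#'
#' @param probabilities Numeric predictions (higher = more positive).
#' @param labels Logical (or 0/1) outcome; both classes must be present.
#' @return List of class `roc_curve`: `points` (`data.frame` with
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(probabilities, labels) {
  labels <- as.logical(labels)
  if (length(probabilities) != length(labels)) stop("length mismatch", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("ROC requires both classes present", call. = FALSE)
  npos <- sum(labels)
  nneg <- sum(!labels)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & probabilities >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & probabilities >= t) / nneg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d thresholds)\n", x$auc, nrow(x$points) - 2L))
  invisible(x)
}

#' Logistic surgery-risk model on shape modes or diameter
#'
#' Maximum-likelihood logistic regression of the surgery label on either the
#' shape-mode scores retained at the 90% cumulative-variance level
#' (`predictor = "modes_90"`) or the aortic diameter alone
#' (`predictor = "diameter"`), with in-sample predicted probabilities, ROC
#' and AUC. No penalty is applied unless the fit is separable or fails to
#' converge, in which case a small ridge (1e-6) refit is used and flagged.
#'
#' @param scores Subjects x modes matrix, or a `shape_atlas`.
#' @param labels Logical surgery labels (>= 2 subjects per class).
#' @param predictor `"modes_90"` or `"diameter"`.
#' @param diameter Numeric vector (mm), required for the diameter baseline.
#' @param variance_threshold Cumulative-variance level for mode retention.
#' @param ridge Ridge penalty used only by the separability guard.
#' @return List of class `risk_model`: `predictor`, `coefficients`,
#'   `probabilities`, `roc`, `auc`, `n_modes` (modes_90 only),
#'   `ridge_active`, `gradient_norm`.
#' @export
fit_risk_model <- function(scores, labels, predictor = c("modes_90", "diameter"),
                           diameter = NULL, variance_threshold = 0.90,
                           ridge = 1e-6) {
  predictor <- match.arg(predictor)
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need >= 2 subjects in each class", call. = FALSE)

  if (predictor == "modes_90") {
    if (inherits(scores, "shape_atlas")) {
      k <- modes_for_variance(scores, variance_threshold)
      X <- scores$scores[, seq_len(k), drop = FALSE]
    } else {
      X <- as.matrix(scores)
      k <- ncol(X)
    }
    colnames(X) <- paste0("mode", seq_len(ncol(X)))
  } else {
    if (is.null(diameter)) stop("`diameter` required for the baseline model", call. = FALSE)
    X <- matrix(diameter, ncol = 1, dimnames = list(NULL, "diameter"))
    k <- NA_integer_
  }
  if (nrow(X) != length(labels)) stop("predictor/label length mismatch", call. = FALSE)

  df <- data.frame(y = labels, X, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  prob <- fit$fitted.values
  beta <- coef(fit)
  ridge_active <- FALSE
  separable <- !fit$converged || any(prob > 1 - 1e-10) || any(prob < 1e-10)
  if (separable || anyNA(beta)) {
    rf <- irls_ridge(cbind(1, X), labels, lambda = ridge)
    beta <- rf$beta
    names(beta) <- c("(Intercept)", colnames(X))
    prob <- rf$prob
    ridge_active <- TRUE
  }
  Xd <- cbind(1, X)
  grad <- as.numeric(crossprod(Xd, labels - prob))
  roc <- roc_curve(as.numeric(prob), labels)
  structure(list(predictor = predictor, coefficients = beta,
                 probabilities = as.numeric(prob), labels = labels, roc = roc,
                 auc = roc$auc, n_modes = k, ridge_active = ridge_active,
                 gradient_norm = sqrt(sum(grad^2))),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> predictor = %s%s: AUC = %.3f%s\n",
              x$predictor,
              if (!is.na(x$n_modes)) sprintf(" (%d modes)", x$n_modes) else "",
              x$auc,
              if (x$ridge_active) " [ridge guard active]" else ""))
  invisible(x)
}

# Newton/IRLS logistic fit with a small ridge penalty (separability guard).
irls_ridge <- function(Xd, y, lambda = 1e-6, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    p <- plogis(eta)
    wts <- pmax(p * (1 - p), 1e-12)
    g <- crossprod(Xd, y - p) - lambda * beta
    H <- crossprod(Xd * wts, Xd) + lambda * diag(ncol(Xd))
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = as.numeric(beta), prob = plogis(as.numeric(Xd %*% beta)))
}

#' Cluster subjects in the mode-score plane
#'
#' Seeded k-means (10 restarts) on the first two mode scores -- the plane in
#' which cohort subgroup structure is inspected. `k = "auto"` picks the
#' silhouette-maximising k in 2..6.
#'
#' @param scores Subjects x modes matrix (>= 2 columns) or `shape_atlas`.
#' @param k Number of clusters, or `"auto"`.
#' @param seed Optional integer seed.
#' @return List of class `mode_clusters`: `labels`, `k`, `silhouette` (mean
#'   width; `NA` with `degenerate = TRUE` when every point is its own
#'   cluster), `centers`.
#' @export
cluster_scores <- function(scores, k = "auto", seed = NULL) {
  if (inherits(scores, "shape_atlas")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least two mode-score columns", call. = FALSE)
  X <- scores[, 1:2, drop = FALSE]
  n <- nrow(X)
  pick <- function(kk) {
    if (kk > n) stop(sprintf("k = %d exceeds n = %d subjects", kk, n), call. = FALSE)
    if (kk == n) {
      # every point its own cluster: no within-cluster variance, silhouette
      # undefined -- report the degenerate partition without invoking kmeans
      return(list(labels = seq_len(n), k = kk, silhouette = NA_real_,
                  centers = X, degenerate = TRUE))
    }
    km <- kmeans(X, centers = kk, nstart = 10)
    degenerate <- kk < 2
    sil <- if (degenerate) NA_real_ else
      mean(cluster::silhouette(km$cluster, stats::dist(X))[, "sil_width"])
    list(labels = km$cluster, k = kk, silhouette = sil, centers = km$centers,
         degenerate = degenerate)
  }
  with_seed(seed, {
    if (identical(k, "auto")) {
      cand <- 2:min(6, n - 1)
      fits <- lapply(cand, pick)
      best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "silhouette"))]]
    } else {
      if (k < 2 && k != n) stop("k must be >= 2 or 'auto'", call. = FALSE)
      best <- pick(as.integer(k))
    }
    class(best) <- "mode_clusters"
    best
  })
}

#' Per-group summary of one shape mode with tests against control
#'
#' Mean and SD of the chosen mode score per group, plus a Mann-Whitney
#' p-value of each group against the control group, starred at the 0.05
#' threshold.
#'
#' @param scores Subjects x modes matrix or `shape_atlas`.
#' @param groups Group label per subject; must include `control`.
#' @param mode Mode index. Default 1.
#' @param control Name of the control group. Default `"control"`.
#' @param alpha Significance threshold. Default 0.05.
#' @return `data.frame` with `group`, `n`, `mean`, `sd`, `p_vs_control`,
#'   `significant`.
#' @export
group_mode_summary <- function(scores, groups, mode = 1, control = "control",
                               alpha = 0.05) {
  if (inherits(scores, "shape_atlas")) scores <- scores$scores
  x <- as.matrix(scores)[, mode]
  groups <- as.character(groups)
  if (!control %in% groups)
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  ctrl <- x[groups == control]
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    xg <- x[groups == g]
    p <- if (g == control) NA_real_ else
      compare_groups(c(xg, ctrl),
                     rep(c("g", "control"), c(length(xg), length(ctrl))))$p
    data.frame(group = g, n = length(xg), mean = mean(xg), sd = sd(xg),
               p_vs_control = p, significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
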